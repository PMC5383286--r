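# Nei-Gojobori (1986) synonymous/nonsynonymous counting under the
# vertebrate mitochondrial code, with equal-weight pathway averaging for
# multi-hit codons and Jukes-Cantor correction of the proportions.

.ng_cache <- new.env(parent = emptyenv())

ng_tables <- function() {
  if (!is.null(.ng_cache$sites)) return(.ng_cache)
  code <- mito_genetic_code()
  codons <- names(code)
  nt <- c("A", "C", "G", "T")

  # per-codon potential synonymous sites (stop-destined changes excluded,
  # sites renormalized to 3)
  sites <- matrix(NA_real_, nrow = 64, ncol = 2,
                  dimnames = list(codons, c("S", "N")))
  for (cd in codons) {
    if (code[[cd]] == "*") next
    syn <- 0L; valid <- 0L
    for (pos in 1:3) {
      for (b in setdiff(nt, substr(cd, pos, pos))) {
        mut <- cd
        substr(mut, pos, pos) <- b
        if (code[[mut]] == "*") next
        valid <- valid + 1L
        if (code[[mut]] == code[[cd]]) syn <- syn + 1L
      }
    }
    sites[cd, ] <- c(3 * syn / valid, 3 - 3 * syn / valid)
  }
  .ng_cache$sites <- sites

  # pathway-averaged (Sd, Nd) for every ordered pair of sense codons
  Sd <- matrix(NA_real_, 64, 64, dimnames = list(codons, codons))
  Nd <- Sd
  step_syn <- function(a, b) code[[a]] == code[[b]]
  for (a in codons) {
    if (code[[a]] == "*") next
    for (b in codons) {
      if (code[[b]] == "*") next
      diff_pos <- which(seq_chars(a) != seq_chars(b))
      k <- length(diff_pos)
      if (k == 0L) { Sd[a, b] <- 0; Nd[a, b] <- 0; next }
      perms <- all_perms(diff_pos)
      tot_s <- 0; tot_n <- 0; nvalid <- 0L
      for (ord in perms) {
        cur <- a; s <- 0L; n <- 0L; ok <- TRUE
        for (pos in ord) {
          nxt <- cur
          substr(nxt, pos, pos) <- substr(b, pos, pos)
          if (code[[nxt]] == "*") { ok <- FALSE; break }
          if (step_syn(cur, nxt)) s <- s + 1L else n <- n + 1L
          cur <- nxt
        }
        if (ok) { tot_s <- tot_s + s; tot_n <- tot_n + n
                  nvalid <- nvalid + 1L }
      }
      if (nvalid > 0L) {
        Sd[a, b] <- tot_s / nvalid
        Nd[a, b] <- tot_n / nvalid
      }  # else all pathways hit stops: pair stays NA and is skipped
    }
  }
  .ng_cache$Sd <- Sd
  .ng_cache$Nd <- Nd
  .ng_cache
}

all_perms <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (p in all_perms(x[-i])) out[[length(out) + 1L]] <- c(x[i], p)
  }
  out
}

#' Potential synonymous/nonsynonymous sites of one codon
#'
#' Classifies each of the nine single-nucleotide changes of a codon as
#' synonymous or nonsynonymous under the vertebrate mitochondrial code.
#' Changes creating stop codons are excluded and the site counts
#' renormalized so that S + N = 3.
#'
#' @param codon 3-mer over A/C/G/T; must not be a stop codon.
#' @return Named numeric vector \code{c(S = ..., N = ...)}.
#' @export
#' @examples
#' ng86_site_counts("GCT")  # fourfold third position: S = 1
ng86_site_counts <- function(codon) {
  codon <- toupper(codon)
  stopifnot(nchar(codon) == 3L, !grepl("[^ACGT]", codon))
  if (mito_genetic_code()[[codon]] == "*") {
    stop("stop codon has no site counts: ", codon)
  }
  tb <- ng_tables()
  c(S = tb$sites[codon, "S"], N = tb$sites[codon, "N"])
}

jc_correct <- function(p) {
  ifelse(is.na(p) | p >= 0.75, NA_real_, -0.75 * log(1 - 4 * p / 3))
}

#' Pairwise Nei-Gojobori Ka/Ks components
#'
#' Compares two equal-length coding-sense codon sequences. Codon pairs
#' containing gaps, ambiguity codes or stop codons are skipped. For
#' codons differing at more than one position, synonymous and
#' nonsynonymous differences are averaged over all mutational pathways
#' with equal weights, excluding pathways through stop codons. Potential
#' site counts are averaged between the two sequences and the
#' Jukes-Cantor correction \eqn{d = -\frac{3}{4}\ln(1 - \frac{4p}{3})}
#' is applied to both proportions; a proportion at or above 0.75 yields a
#' missing corrected rate.
#'
#' @param codons_a,codons_b Nucleotide strings (length divisible by 3) or
#'   character vectors of codons.
#' @return list with \code{S_sites}, \code{N_sites}, \code{Sd},
#'   \code{Nd}, \code{pS}, \code{pN}, \code{dS}, \code{dN},
#'   \code{n_codons} (codon pairs compared).
#' @export
#' @examples
#' ng86_pair("ATGAAA", "ATGAAG")$Sd  # one synonymous difference
ng86_pair <- function(codons_a, codons_b) {
  ca <- if (length(codons_a) == 1L) codon_split(clean_seq(codons_a,
        allow_gap = TRUE)) else toupper(codons_a)
  cb <- if (length(codons_b) == 1L) codon_split(clean_seq(codons_b,
        allow_gap = TRUE)) else toupper(codons_b)
  stopifnot(length(ca) == length(cb))
  tb <- ng_tables()
  code <- mito_genetic_code()
  ok <- !grepl("[^ACGT]", ca) & !grepl("[^ACGT]", cb)
  ok[ok] <- code[ca[ok]] != "*" & code[cb[ok]] != "*"
  ca <- ca[ok]; cb <- cb[ok]
  # drop codon pairs whose every pathway passes through a stop
  defined <- !is.na(tb$Sd[cbind(ca, cb)])
  ca <- ca[defined]; cb <- cb[defined]
  n <- length(ca)
  if (n == 0L) {
    return(list(S_sites = NA_real_, N_sites = NA_real_, Sd = NA_real_,
                Nd = NA_real_, pS = NA_real_, pN = NA_real_,
                dS = NA_real_, dN = NA_real_, n_codons = 0L))
  }
  S <- (sum(tb$sites[ca, "S"]) + sum(tb$sites[cb, "S"])) / 2
  N <- (sum(tb$sites[ca, "N"]) + sum(tb$sites[cb, "N"])) / 2
  Sd <- sum(tb$Sd[cbind(ca, cb)])
  Nd <- sum(tb$Nd[cbind(ca, cb)])
  pS <- Sd / S
  pN <- Nd / N
  list(S_sites = S, N_sites = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
       dS = jc_correct(pS), dN = jc_correct(pN), n_codons = n)
}

#' Gene-level Ka, Ks and omega
#'
#' Averages pairwise Nei-Gojobori estimates over all sequence pairs of a
#' codon alignment: Ka is the mean pairwise dN, Ks the mean pairwise dS,
#' and omega the ratio of means (mean dN over mean dS) -- a counting-style
#' gene-level estimate that stays stable when many pairwise dS are small.
#' Pairs with undefined corrected rates are dropped from the averages.
#'
#' @param codon_alignment Named character vector of equal-length aligned
#'   coding-sense sequences (stops already stripped; see
#'   \code{\link{strip_stops}}).
#' @param gene Gene label carried into the result.
#' @return Object of class \code{kaks_result}: list with \code{gene},
#'   \code{Ka}, \code{Ks}, \code{omega}, \code{n_pairs}.
#' @export
gene_kaks <- function(codon_alignment, gene = "gene") {
  aln <- vapply(codon_alignment, clean_seq, "", allow_gap = TRUE)
  stopifnot(length(aln) >= 2L, length(unique(nchar(aln))) == 1L)
  labs <- names(aln) %||% paste0("seq", seq_along(aln))
  prs <- utils::combn(length(aln), 2L)
  dN <- dS <- rep(NA_real_, ncol(prs))
  for (j in seq_len(ncol(prs))) {
    p <- ng86_pair(aln[[prs[1, j]]], aln[[prs[2, j]]])
    dN[j] <- p$dN; dS[j] <- p$dS
  }
  use <- !is.na(dN) & !is.na(dS)
  if (!any(use)) {
    return(structure(list(gene = gene, Ka = NA_real_, Ks = NA_real_,
                          omega = NA_real_, n_pairs = 0L),
                     class = "kaks_result"))
  }
  Ka <- mean(dN[use]); Ks <- mean(dS[use])
  structure(list(gene = gene, Ka = Ka, Ks = Ks,
                 omega = if (Ks > 0) Ka / Ks else NA_real_,
                 n_pairs = sum(use)),
            class = "kaks_result")
}

#' @export
print.kaks_result <- function(x, ...) {
  cat(sprintf("%s: Ka = %.4f, Ks = %.4f, omega = %s (%d pairs)\n",
              x$gene, x$Ka, x$Ks,
              ifelse(is.na(x$omega), "NA", sprintf("%.3f", x$omega)),
              x$n_pairs))
  invisible(x)
}
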