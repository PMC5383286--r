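# Independent brute-force oracles. Each oracle recomputes a quantity by
# direct enumeration, sharing no code path with the implementation it
# checks.

# -- NG86 oracle: exhaustive pathway enumeration per codon pair ---------

oracle_code <- local({
  gc <- Biostrings::getGeneticCode("2")
  stats::setNames(as.character(gc), names(gc))
})

oracle_is_stop <- function(codon) oracle_code[[codon]] == "*"

oracle_site_counts <- function(codon) {
  nt <- c("A", "C", "G", "T")
  syn <- 0; valid <- 0
  for (pos in 1:3) {
    for (b in setdiff(nt, substr(codon, pos, pos))) {
      mut <- codon
      substr(mut, pos, pos) <- b
      if (oracle_is_stop(mut)) next
      valid <- valid + 1
      if (oracle_code[[mut]] == oracle_code[[codon]]) syn <- syn + 1
    }
  }
  c(S = 3 * syn / valid, N = 3 - 3 * syn / valid)
}

# all orderings of a small vector, built by recursion
oracle_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in oracle_perms(v[-i])) out <- c(out, list(c(v[i], rest)))
  }
  out
}

oracle_pair_diffs <- function(a, b) {
  dp <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  if (!length(dp)) return(c(Sd = 0, Nd = 0))
  tot_s <- 0; tot_n <- 0; nv <- 0
  for (ord in oracle_perms(dp)) {
    cur <- a; s <- 0; n <- 0; ok <- TRUE
    for (pos in ord) {
      nxt <- cur
      substr(nxt, pos, pos) <- substr(b, pos, pos)
      if (oracle_is_stop(nxt)) { ok <- FALSE; break }
      if (oracle_code[[nxt]] == oracle_code[[cur]]) s <- s + 1 else
        n <- n + 1
      cur <- nxt
    }
    if (ok) { tot_s <- tot_s + s; tot_n <- tot_n + n; nv <- nv + 1 }
  }
  if (nv == 0) return(c(Sd = NA_real_, Nd = NA_real_))
  c(Sd = tot_s / nv, Nd = tot_n / nv)
}

# full NG86 on a pair of codon vectors, by direct enumeration
oracle_ng86 <- function(codons_a, codons_b) {
  S <- 0; N <- 0; Sd <- 0; Nd <- 0; n <- 0
  for (i in seq_along(codons_a)) {
    a <- codons_a[i]; b <- codons_b[i]
    if (grepl("[^ACGT]", a) || grepl("[^ACGT]", b)) next
    if (oracle_is_stop(a) || oracle_is_stop(b)) next
    d <- oracle_pair_diffs(a, b)
    if (anyNA(d)) next
    sa <- oracle_site_counts(a); sb <- oracle_site_counts(b)
    S <- S + (sa[["S"]] + sb[["S"]]) / 2
    N <- N + (sa[["N"]] + sb[["N"]]) / 2
    Sd <- Sd + d[["Sd"]]; Nd <- Nd + d[["Nd"]]
    n <- n + 1
  }
  pS <- Sd / S; pN <- Nd / N
  jc <- function(p) if (is.na(p) || p >= 0.75) NA_real_ else
    -0.75 * log(1 - 4 * p / 3)
  list(S_sites = S, N_sites = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
       dS = jc(pS), dN = jc(pN), n_codons = n)
}

# -- site classification oracle: per-column histogram -------------------

oracle_classify <- function(rows, policy = "complete") {
  mat <- do.call(rbind, strsplit(rows, ""))
  n_const <- n_sing <- n_pis <- 0; analyzed <- 0
  for (j in seq_len(ncol(mat))) {
    col <- mat[, j]
    if (policy == "complete" && any(col %in% c("-", "N"))) next
    col <- col[!col %in% c("-", "N")]
    if (length(col) < 2) next
    analyzed <- analyzed + 1
    tab <- table(col)
    if (length(tab) == 1) n_const <- n_const + 1
    else if (sum(tab >= 2) >= 2) n_pis <- n_pis + 1
    else n_sing <- n_sing + 1
  }
  list(n_constant = n_const, n_singleton = n_sing,
       n_parsimony_informative = n_pis,
       n_variable = n_sing + n_pis, n_analyzed = analyzed)
}

# -- tandem repeat oracle: cubic enumeration of maximal exact runs ------

oracle_tandem_candidates <- function(s, min_period = 2, max_period = 200,
                                     min_copies = 2, min_span = 8) {
  n <- nchar(s)
  cand <- list()
  for (p in min_period:min(max_period, n %/% 2)) {
    for (st in 1:(n - 2 * p + 1)) {
      # maximal on the left: the run must fail just before st
      if (st > 1 && substr(s, st - 1, st - 1) ==
          substr(s, st - 1 + p, st - 1 + p)) next
      # extend exact match s[i] == s[i+p]
      len <- 0
      while (st + len + p <= n &&
             substr(s, st + len, st + len) ==
             substr(s, st + len + p, st + len + p)) {
        len <- len + 1
      }
      if (len < p) next
      span <- len + p
      copies <- span / p
      if (copies < min_copies || span < min_span) next
      motif <- substr(s, st, st + p - 1)
      # fundamental period check (naive)
      fp <- p
      for (q in 1:(p - 1)) {
        if (p %% q == 0 &&
            motif == strrep(substr(motif, 1, q), p / q)) { fp <- q; break }
      }
      if (fp != p && fp >= min_period) next
      cand[[length(cand) + 1]] <- data.frame(
        motif = motif, period = p, copies = copies, start = st - 1,
        end = st - 1 + span, stringsAsFactors = FALSE)
    }
  }
  if (!length(cand)) return(data.frame(motif = character(0),
                                       period = integer(0),
                                       copies = numeric(0),
                                       start = integer(0),
                                       end = integer(0)))
  unique(do.call(rbind, cand))
}

# same published resolution rule, naive implementation
oracle_tandem <- function(s, ...) {
  cand <- oracle_tandem_candidates(s, ...)
  if (!nrow(cand)) return(cand)
  span <- cand$end - cand$start
  cand <- cand[order(-span, cand$period, cand$start), ]
  occ <- rep(FALSE, nchar(s))
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    cells <- (cand$start[i] + 1):cand$end[i]
    if (!any(occ[cells])) { keep[i] <- TRUE; occ[cells] <- TRUE }
  }
  out <- cand[keep, ]
  out <- out[order(out$start), ]
  rownames(out) <- NULL
  out
}

# -- tRNA fold oracle: naive enumeration over all partitions ------------

oracle_pair_score <- function(a, b) {
  k <- paste0(a, b)
  if (k %in% c("GC", "CG")) return(3)
  if (k %in% c("AT", "TA")) return(2)
  if (k %in% c("GT", "TG")) return(1)
  NA_real_
}

oracle_stem_score <- function(ch, s5a, s5b, s3a, s3b) {
  len <- s5b - s5a + 1
  sc <- 0; mm <- 0
  for (k in seq_len(len)) {
    v <- oracle_pair_score(ch[s5a + k - 1], ch[s3b - k + 1])
    if (is.na(v)) mm <- mm + 1 else sc <- sc + v
  }
  if (mm > 1) return(NA_real_)
  sc
}

# returns list(model, score) of the best structure, or NULL
oracle_fold <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  best_score <- -Inf; best_model <- NULL
  for (model in c("cloverleaf", "D-armless")) {
    for (u1 in 1:3) for (dl in 4:12) for (l2 in 0:2) {
      for (t in 4:5) for (tl in 5:9) {
        dvals <- if (model == "cloverleaf") 3:4 else 0
        for (d in dvals) {
          v <- n - (7 + u1 + 2 * d + dl + l2 + 5 + 7 + 5 + 2 * t + tl +
                      7 + 1)
          if (v < 3 || v > 23) next
          p <- 7 + u1
          d5 <- c(p + 1, p + d); p <- p + d
          dloop <- c(p + 1, p + dl); p <- p + dl
          d3 <- c(p + 1, p + d); p <- p + d + l2
          ac5 <- c(p + 1, p + 5); p <- p + 5 + 7
          ac3 <- c(p + 1, p + 5); p <- p + 5 + v
          t5 <- c(p + 1, p + t); p <- p + t + tl
          t3 <- c(p + 1, p + t); p <- p + t
          acc3 <- c(p + 1, p + 7)
          sc <- oracle_stem_score(ch, 1, 7, acc3[1], acc3[2])
          if (is.na(sc)) next
          if (model == "cloverleaf") {
            sd <- oracle_stem_score(ch, d5[1], d5[2], d3[1], d3[2])
            if (is.na(sd)) next
            sc <- sc + sd
          }
          sa <- oracle_stem_score(ch, ac5[1], ac5[2], ac3[1], ac3[2])
          if (is.na(sa)) next
          st <- oracle_stem_score(ch, t5[1], t5[2], t3[1], t3[2])
          if (is.na(st)) next
          tot <- sc + sa + st
          if (tot > best_score) { best_score <- tot; best_model <- model }
        }
      }
    }
  }
  if (is.null(best_model)) return(NULL)
  list(model = best_model, score = best_score)
}

# -- misc ---------------------------------------------------------------

random_dna <- function(n, probs = c(A = .25, C = .25, G = .25, T = .25)) {
  paste0(sample(names(probs), n, TRUE, prob = probs), collapse = "")
}

random_codons <- function(n) {
  stops <- c("TAA", "TAG", "AGA", "AGG")
  out <- character(n)
  for (i in seq_len(n)) {
    repeat {
      cd <- random_dna(3)
      if (!cd %in% stops) break
    }
    out[i] <- cd
  }
  out
}
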