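# Exact tandem-repeat detection for control regions. Exact matches only:
# the motifs of interest here are short (e.g. AAAC, AAACAAC) and exact,
# and exactness admits an unambiguous brute-force oracle. This is a
# deliberate divergence from mismatch-tolerant, alignment-scored repeat
# finders.

#' Lexicographically least rotation of a motif
#'
#' Canonical form under which phase-shifted motifs (e.g. \code{AACA} and
#' \code{AAAC}) tally together across a cohort.
#'
#' @param motif Nucleotide string.
#' @return The smallest rotation of \code{motif}.
#' @export
#' @examples
#' canonical_motif("ACAA")  # "AACA"
canonical_motif <- function(motif) {
  n <- nchar(motif)
  if (n <= 1L) return(motif)
  rots <- vapply(seq_len(n) - 1L, function(k) {
    paste0(substr(motif, k + 1L, n), substr(motif, 1L, k))
  }, "")
  min(rots)
}

#' Find exact tandem repeats
#'
#' Reports maximal runs of two or more adjacent exact copies of a motif
#' (fractional final copies allowed). For each period p the sequence is
#' scanned for maximal stretches where position i matches position i+p;
#' candidate calls are then resolved greedily: longest span first, ties
#' by smaller period, then leftmost start, dropping candidates that
#' overlap an accepted call.
#'
#' @param seq Nucleotide string (typically a control region).
#' @param min_period,max_period Motif length bounds; the default
#'   \code{min_period = 2} excludes homopolymer runs.
#' @param min_copies Minimum (possibly fractional) copy number.
#' @param min_span Minimum total span in bp.
#' @return data.frame with columns \code{motif}, \code{canonical_motif},
#'   \code{period}, \code{copies}, \code{start}, \code{end} (0-based
#'   half-open), ordered by start. Zero rows on repeat-free input.
#' @export
#' @examples
#' find_tandem_repeats(paste0("G", strrep("AAAC", 8), "G"))
find_tandem_repeats <- function(seq, min_period = 2L, max_period = 200L,
                                min_copies = 2, min_span = 8L) {
  s <- clean_seq(seq)
  n <- nchar(s)
  ch <- seq_chars(s)
  cand <- list()
  for (p in min_period:min(max_period, n %/% 2L)) {
    if (p > n - p) break
    m <- ch[1:(n - p)] == ch[(p + 1):n]
    r <- rle(m)
    pos <- 1L
    for (k in seq_along(r$lengths)) {
      if (r$values[k] && r$lengths[k] >= p) {
        st <- pos                     # 1-based start of the run
        span <- r$lengths[k] + p
        copies <- span / p
        if (copies >= min_copies && span >= min_span) {
          motif <- substr(s, st, st + p - 1L)
          # skip runs whose motif is itself periodic (reported at the
          # smaller fundamental period), unless that period is below
          # min_period (homopolymers surface at the smallest allowed
          # period via the tie-break)
          fp <- fundamental_period(motif)
          if (fp == p || fp < min_period) {
            cand[[length(cand) + 1L]] <- data.frame(
              motif = motif, period = p, copies = copies,
              start = st - 1L, end = st - 1L + span,
              stringsAsFactors = FALSE)
          }
        }
      }
      pos <- pos + r$lengths[k]
    }
  }
  if (!length(cand)) {
    return(data.frame(motif = character(0), canonical_motif = character(0),
                      period = integer(0), copies = numeric(0),
                      start = integer(0), end = integer(0)))
  }
  cand <- do.call(rbind, cand)
  resolve_repeat_calls(cand)
}

# A motif repeated at period p may also satisfy the run test at any
# multiple of its fundamental period; keep only the fundamental.
fundamental_period <- function(motif) {
  n <- nchar(motif)
  for (p in seq_len(n - 1L)) {
    if (n %% p == 0L &&
        motif == strrep(substr(motif, 1L, p), n %/% p)) {
      return(p)
    }
  }
  n
}

# Greedy resolution: longest span, then smallest period, then leftmost.
resolve_repeat_calls <- function(cand) {
  span <- cand$end - cand$start
  ord <- order(-span, cand$period, cand$start)
  cand <- cand[ord, , drop = FALSE]
  taken <- logical(0)
  acc <- list()
  occupied <- integer(0)
  for (i in seq_len(nrow(cand))) {
    cells <- (cand$start[i] + 1L):cand$end[i]
    if (!any(cells %in% occupied)) {
      acc[[length(acc) + 1L]] <- cand[i, ]
      occupied <- c(occupied, cells)
    }
  }
  out <- do.call(rbind, acc)
  out$canonical_motif <- vapply(out$motif, canonical_motif, "")
  out <- out[order(out$start),
             c("motif", "canonical_motif", "period", "copies",
               "start", "end")]
  rownames(out) <- NULL
  out
}

#' Control-region repeat architecture
#'
#' Tiles a control region into an ordered alternation of non-repeat
#' blocks and tandem-repeat blocks. Repeat calls must be non-overlapping
#' (as returned by \code{\link{find_tandem_repeats}}).
#'
#' @param cr_seq Control-region nucleotide string.
#' @param repeats Repeat table from \code{\link{find_tandem_repeats}};
#'   computed from \code{cr_seq} if missing.
#' @return Object of class \code{cr_architecture}: list with
#'   \code{blocks} (data.frame: \code{type} = \code{"unique"} or
#'   \code{"repeat"}, \code{start}, \code{end}, \code{motif},
#'   \code{copies}) and \code{cr_length}.
#' @export
cr_architecture <- function(cr_seq, repeats = NULL) {
  s <- clean_seq(cr_seq)
  n <- nchar(s)
  if (is.null(repeats)) repeats <- find_tandem_repeats(s)
  rep_tab <- repeats[order(repeats$start), , drop = FALSE]
  if (nrow(rep_tab) > 1L &&
      any(rep_tab$start[-1] < rep_tab$end[-nrow(rep_tab)])) {
    stop("repeat calls overlap after resolution")
  }
  blocks <- list()
  pos <- 0L
  add <- function(type, start, end, motif = NA_character_,
                  copies = NA_real_) {
    data.frame(type = type, start = start, end = end, motif = motif,
               copies = copies, stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(rep_tab))) {
    if (rep_tab$start[i] > pos) {
      blocks[[length(blocks) + 1L]] <- add("unique", pos, rep_tab$start[i])
    }
    blocks[[length(blocks) + 1L]] <- add("repeat", rep_tab$start[i],
                                         rep_tab$end[i], rep_tab$motif[i],
                                         rep_tab$copies[i])
    pos <- rep_tab$end[i]
  }
  if (pos < n) blocks[[length(blocks) + 1L]] <- add("unique", pos, n)
  blocks <- if (length(blocks)) do.call(rbind, blocks) else
    add("unique", 0L, n)
  structure(list(blocks = blocks, cr_length = n),
            class = "cr_architecture")
}

#' @export
print.cr_architecture <- function(x, ...) {
  cat(sprintf("control region, %d bp, %d block(s):\n", x$cr_length,
              nrow(x$blocks)))
  print.data.frame(x$blocks)
  invisible(x)
}

#' Motif prevalence across a cohort
#'
#' Counts, for each canonical motif, the number of species whose control
#' region carries at least one tandem repeat of that motif. Each species
#' is counted once per motif.
#'
#' @param cohort_architectures Named list of \code{cr_architecture}
#'   objects (names = species labels).
#' @return data.frame with \code{canonical_motif} and \code{n_species},
#'   sorted by decreasing prevalence.
#' @export
motif_prevalence <- function(cohort_architectures) {
  stopifnot(length(cohort_architectures) >= 1L)
  per_sp <- lapply(cohort_architectures, function(arch) {
    b <- arch$blocks
    unique(vapply(b$motif[b$type == "repeat"], canonical_motif, ""))
  })
  tab <- table(unlist(per_sp))
  if (!length(tab)) {
    return(data.frame(canonical_motif = character(0),
                      n_species = integer(0)))
  }
  out <- data.frame(canonical_motif = names(tab),
                    n_species = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_species, out$canonical_motif), ]
  rownames(out) <- NULL
  out
}
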