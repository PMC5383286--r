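#' The vertebrate mitochondrial genetic code
#'
#' Codon-to-amino-acid map (64 entries, stops as \code{"*"}) under the
#' vertebrate mitochondrial code: AGA/AGG are stops, TGA is Trp, ATA is
#' Met. Exactly four stop codons: TAA, TAG, AGA, AGG.
#'
#' @return Named character vector of length 64 (names are DNA codons).
#' @export
#' @examples
#' mito_genetic_code()[["TGA"]]  # "W"
mito_genetic_code <- function() {
  gc <- Biostrings::getGeneticCode("2")  # NCBI transl_table=2
  stopifnot(length(gc) == 64L, sum(gc == "*") == 4L,
            gc[["TGA"]] == "W", gc[["AGA"]] == "*")
  code <- as.character(gc)
  names(code) <- names(gc)
  code
}

#' Candidate mitochondrial start codons
#' @return Character vector: ATG, GTG, ATT, ATC, ATA.
#' @export
mito_start_codons <- function() c("ATG", "GTG", "ATT", "ATC", "ATA")

#' Mitochondrial stop codons
#' @return Character vector: TAA, TAG, AGA, AGG.
#' @export
mito_stop_codons <- function() c("TAA", "TAG", "AGA", "AGG")

#' Translate under the vertebrate mitochondrial code
#'
#' Translation proceeds codon by codon from \code{frame_offset} and stops
#' at the first stop codon or at the end of the sequence; trailing 1-2 nt
#' are ignored. Codons containing N or gaps translate to \code{"X"}.
#'
#' @param seq Coding-sense nucleotide string.
#' @param frame_offset 0, 1 or 2 nucleotides skipped before the first
#'   codon.
#' @return Amino-acid string (stop not included).
#' @export
#' @examples
#' translate_mt("ATGGCTTAA")  # "MA"
translate_mt <- function(seq, frame_offset = 0L) {
  s <- clean_seq(seq, allow_gap = TRUE)
  if (frame_offset > 0L) s <- substr(s, frame_offset + 1L, nchar(s))
  if (nchar(s) < 3L) stop("sequence shorter than one codon after offset")
  code <- mito_genetic_code()
  out <- character(0)
  for (cd in codon_split(s)) {
    aa <- if (grepl("[^ACGT]", cd)) "X" else code[[cd]]
    if (aa == "*") break
    out <- c(out, aa)
  }
  paste0(out, collapse = "")
}

# Excise gene-relative 1-based single-nucleotide insertions (e.g. the
# extra C at position 174 of ND3 in most shorebirds) before framing.
excise_inserts <- function(seq, inserts) {
  if (!length(inserts)) return(seq)
  keep <- setdiff(seq_len(nchar(seq)), as.integer(inserts))
  paste0(seq_chars(seq)[keep], collapse = "")
}

#' Start/stop codon report for one protein-coding gene
#'
#' Detects the initiation codon and the termination signal of a
#' coding-sense gene sequence. Genes whose length after excising
#' frameshift insertions is not a multiple of three are classified as
#' carrying an incomplete stop: a trailing \code{T} gives stop class
#' \code{"T--"}, trailing \code{TA} gives \code{"TA-"} (both completed to
#' TAA by post-transcriptional polyadenylation). A first codon outside
#' the mitochondrial start set is flagged nonstandard, not an error.
#'
#' @param gene_seq Coding-sense nucleotide string.
#' @param frameshift_inserts Gene-relative 1-based positions of
#'   single-nucleotide insertions to excise before framing.
#' @param gene,species Labels carried into the report.
#' @return Object of class \code{codon_report}: list with \code{gene},
#'   \code{species}, \code{start_codon}, \code{stop_codon},
#'   \code{complete_stop}, \code{standard_start}, \code{internal_stops}.
#' @export
#' @examples
#' start_stop_codons("ATGAAATAA")$stop_codon  # "TAA"
start_stop_codons <- function(gene_seq, frameshift_inserts = integer(0),
                              gene = "gene", species = "species") {
  s <- excise_inserts(clean_seq(gene_seq), frameshift_inserts)
  stopifnot(nchar(s) >= 6L)
  start <- substr(s, 1L, 3L)
  stops <- mito_stop_codons()
  rem <- nchar(s) %% 3L
  cods <- codon_split(s)
  if (rem == 0L) {
    last <- cods[length(cods)]
    complete <- last %in% stops
    stop_codon <- if (complete) last else last
    internal <- which(cods[-length(cods)] %in% stops)
  } else {
    tail_nt <- substr(s, nchar(s) - rem + 1L, nchar(s))
    complete <- FALSE
    stop_codon <- if (rem == 1L && tail_nt == "T") "T--"
      else if (rem == 2L && tail_nt == "TA") "TA-"
      else paste0(tail_nt, strrep("-", 3L - rem))
    internal <- which(cods %in% stops)
  }
  structure(list(
    gene = gene, species = species,
    start_codon = start, stop_codon = stop_codon,
    complete_stop = complete,
    standard_start = start %in% mito_start_codons(),
    internal_stops = as.integer(internal)
  ), class = "codon_report")
}

#' Start/stop usage matrices across a cohort
#'
#' Tallies the observed start and stop codons per gene across a list of
#' codon reports. Incomplete stops (\code{"T--"} and \code{"TA-"}) are
#' merged into the single class \code{"T-"}; reports with internal stops
#' are excluded with a warning.
#'
#' @param reports list of \code{codon_report}.
#' @return list with matrices \code{starts} and \code{stops} (gene x
#'   codon counts) and \code{atg_fraction}, the fraction (percent) of ATG
#'   among all tallied start codons.
#' @export
usage_matrix <- function(reports) {
  stopifnot(length(reports) >= 1L)
  bad <- vapply(reports, function(r) length(r$internal_stops) > 0L,
                logical(1))
  if (any(bad)) {
    warning(sum(bad), " report(s) with internal stop codons excluded ",
            "from usage tallies")
    reports <- reports[!bad]
  }
  if (!length(reports)) stop("no usable codon reports")
  genes <- unique(vapply(reports, `[[`, "", "gene"))
  stop_class <- function(sc) if (sc %in% c("T--", "TA-")) "T-" else sc
  starts <- vapply(reports, `[[`, "", "start_codon")
  stops <- vapply(reports, function(r) stop_class(r$stop_codon), "")
  gene_of <- vapply(reports, `[[`, "", "gene")
  m_start <- table(factor(gene_of, levels = genes), starts)
  m_stop <- table(factor(gene_of, levels = genes), stops)
  list(starts = unclass(m_start), stops = unclass(m_stop),
       atg_fraction = 100 * mean(starts == "ATG"))
}

#' Strip terminal stop codons from a codon alignment
#'
#' Removes trailing codon columns in which every ungapped codon is a stop
#' (the usual pre-processing before synonymous/nonsynonymous analysis).
#' If after that some sequences still end in a stop (mixed terminal
#' column), those stops are replaced by gap codons. An internal stop in
#' any sequence is an error naming the offending sequence.
#'
#' @param codon_alignment Named character vector of equal-length aligned
#'   coding-sense sequences; length divisible by 3.
#' @return The alignment with terminal stops removed.
#' @export
strip_stops <- function(codon_alignment) {
  aln <- vapply(codon_alignment, clean_seq, "", allow_gap = TRUE)
  L <- unique(nchar(aln))
  stopifnot(length(L) == 1L, L %% 3L == 0L)
  if (is.null(names(aln))) names(aln) <- paste0("seq", seq_along(aln))
  stops <- mito_stop_codons()
  mat <- do.call(rbind, lapply(aln, codon_split))
  # internal stops are fatal
  ncod <- ncol(mat)
  for (i in seq_len(nrow(mat))) {
    nonfinal <- mat[i, -ncod]
    if (any(nonfinal %in% stops)) {
      stop("internal stop codon in sequence '", rownames(mat)[i], "'")
    }
  }
  while (ncol(mat) > 0L) {
    last <- mat[, ncol(mat)]
    real <- last[!grepl("-", last)]
    if (length(real) && all(real %in% stops)) {
      mat <- mat[, -ncol(mat), drop = FALSE]
    } else break
  }
  if (ncol(mat) > 0L) {
    last <- mat[, ncol(mat)]
    mat[last %in% stops, ncol(mat)] <- "---"
  }
  out <- apply(mat, 1L, paste0, collapse = "")
  stats::setNames(out, names(aln))
}
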