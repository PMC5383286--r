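#' Read / build an alignment object
#'
#' A minimal alignment container: named character vector of equal-length
#' rows over \code{A,C,G,T,N,-}. FASTA alignments are read through
#' Biostrings.
#'
#' @param x Named character vector of aligned sequences, or a path to an
#'   aligned FASTA file.
#' @return Named character vector with class \code{mito_alignment}.
#' @export
as_alignment <- function(x) {
  if (length(x) == 1L && file.exists(x)) {
    ss <- Biostrings::readBStringSet(x)
    x <- stats::setNames(as.character(ss), names(ss))
  }
  aln <- vapply(x, clean_seq, "", allow_gap = TRUE)
  if (length(aln) < 2L) stop("alignment needs at least 2 sequences")
  if (length(unique(nchar(aln))) != 1L) {
    stop("alignment rows differ in length")
  }
  if (is.null(names(aln))) names(aln) <- paste0("seq", seq_along(aln))
  structure(aln, class = "mito_alignment")
}

aln_matrix <- function(aln) {
  do.call(rbind, lapply(unclass(aln), seq_chars))
}

# Columns retained under a deletion policy. Complete deletion removes
# every column containing a gap or N (the convention matching the
# "after removing termination codons and indels" concatenated length);
# pairwise deletion keeps all columns and handles missing data per pair.
analyzed_columns <- function(mat, deletion_policy) {
  if (deletion_policy == "complete") {
    which(colSums(mat == "-" | mat == "N") == 0L)
  } else {
    seq_len(ncol(mat))
  }
}

#' Classify alignment sites
#'
#' Per analyzed column: constant if a single state is present;
#' parsimony-informative if at least two states each occur in at least
#' two sequences; singleton if variable but not parsimony-informative.
#' Under \code{"complete"} deletion (default), columns containing any
#' gap or N are excluded before classification; under \code{"pairwise"},
#' gaps/N are ignored within each column and columns with fewer than two
#' determinate bases are excluded.
#'
#' @param aln A \code{mito_alignment} (or coercible).
#' @param deletion_policy \code{"complete"} or \code{"pairwise"}.
#' @return list with counts \code{n_constant}, \code{n_variable},
#'   \code{n_singleton}, \code{n_parsimony_informative},
#'   \code{n_analyzed}, \code{n_excluded} and percentages
#'   \code{pct_variable}, \code{pct_pis}, \code{pct_singleton} (of
#'   analyzed columns).
#' @export
#' @examples
#' classify_sites(c("AAA", "AAT", "AAT"))$n_singleton  # 1
classify_sites <- function(aln,
                           deletion_policy = c("complete", "pairwise")) {
  deletion_policy <- match.arg(deletion_policy)
  aln <- as_alignment(aln)
  mat <- aln_matrix(aln)
  cols <- analyzed_columns(mat, deletion_policy)
  n_const <- n_sing <- n_pis <- 0L
  analyzed <- 0L
  for (j in cols) {
    col <- mat[, j]
    col <- col[col != "-" & col != "N"]
    if (length(col) < 2L) next
    analyzed <- analyzed + 1L
    tab <- table(col)
    if (length(tab) == 1L) {
      n_const <- n_const + 1L
    } else if (sum(tab >= 2L) >= 2L) {
      n_pis <- n_pis + 1L
    } else {
      n_sing <- n_sing + 1L
    }
  }
  if (analyzed == 0L) stop("all columns excluded by deletion policy")
  n_var <- n_sing + n_pis
  list(n_constant = n_const, n_variable = n_var, n_singleton = n_sing,
       n_parsimony_informative = n_pis, n_analyzed = analyzed,
       n_excluded = ncol(mat) - analyzed,
       pct_variable = 100 * n_var / analyzed,
       pct_pis = 100 * n_pis / analyzed,
       pct_singleton = 100 * n_sing / analyzed)
}

#' Uncorrected pairwise distances
#'
#' Per pair of rows: mismatches divided by compared sites. Under
#' \code{"complete"} deletion every pair is compared on the same
#' gap/N-free columns; under \code{"pairwise"} each pair uses its own
#' determinate columns. A pair with no comparable site gets a missing
#' entry with a warning.
#'
#' @param aln A \code{mito_alignment} (or coercible).
#' @param deletion_policy \code{"complete"} or \code{"pairwise"}.
#' @return list with \code{matrix} (symmetric p-distance matrix, zero
#'   diagonal) and \code{average} (mean of the upper triangle -- the
#'   average uncorrected pairwise distance).
#' @export
#' @examples
#' p_distance(c(a = "ACGT", b = "ACGA"))$average  # 0.25
p_distance <- function(aln,
                       deletion_policy = c("complete", "pairwise")) {
  deletion_policy <- match.arg(deletion_policy)
  aln <- as_alignment(aln)
  mat <- aln_matrix(aln)
  n <- nrow(mat)
  if (deletion_policy == "complete") {
    mat <- mat[, analyzed_columns(mat, "complete"), drop = FALSE]
  }
  D <- matrix(0, n, n, dimnames = list(names(aln), names(aln)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      a <- mat[i, ]; b <- mat[j, ]
      cmp <- a != "-" & a != "N" & b != "-" & b != "N"
      if (!any(cmp)) {
        warning("no comparable sites between '", names(aln)[i],
                "' and '", names(aln)[j], "'")
        D[i, j] <- D[j, i] <- NA_real_
      } else {
        D[i, j] <- D[j, i] <- sum(a[cmp] != b[cmp]) / sum(cmp)
      }
    }
  }
  list(matrix = D, average = mean(D[upper.tri(D)], na.rm = TRUE))
}

#' Neighbor-joining tree from a p-distance result
#'
#' Distance-based agglomeration with the standard Q-criterion
#' (delegated to \code{ape::nj}); recovers additive distance matrices
#' exactly. Serves as the package's qualitative topology plumbing.
#'
#' @param dist A result of \code{\link{p_distance}} or a symmetric
#'   numeric matrix with dimnames.
#' @return An \code{ape::phylo} tree (unrooted).
#' @export
nj_tree <- function(dist) {
  m <- if (is.list(dist)) dist$matrix else dist
  if (anyNA(m)) stop("distance matrix has missing entries")
  if (nrow(m) < 3L) stop("neighbor joining needs at least 3 taxa")
  ape::nj(stats::as.dist(m))
}

#' Write a distance matrix in PHYLIP-style tab-separated form
#'
#' First line: number of taxa; then one row per taxon (label followed
#' by its distances, tab-separated).
#'
#' @param dist A \code{\link{p_distance}} result or symmetric matrix.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_phylip_dist <- function(dist, path) {
  m <- if (is.list(dist)) dist$matrix else dist
  lines <- c(as.character(nrow(m)),
             vapply(seq_len(nrow(m)), function(i) {
               paste(c(rownames(m)[i], format(m[i, ], digits = 10)),
                     collapse = "\t")
             }, ""))
  writeLines(lines, path)
  invisible(path)
}

#' Write a tree in Newick form
#' @param tree An \code{ape::phylo} object.
#' @param path Optional output path; if \code{NULL} the Newick string is
#'   returned.
#' @return Newick string (invisibly when written to file).
#' @export
write_newick <- function(tree, path = NULL) {
  s <- ape::write.tree(tree)
  if (is.null(path)) return(s)
  writeLines(s, path)
  invisible(s)
}

# Tip sets on the child side of every edge of an unrooted phylo tree.
edge_bipartitions <- function(tree) {
  n_tip <- length(tree$tip.label)
  desc <- vector("list", n_tip + tree$Nnode)
  for (i in seq_len(n_tip)) desc[[i]] <- i
  # postorder guarantees children are accumulated before their parents
  for (k in ape::postorder(tree)) {
    par <- tree$edge[k, 1]; chd <- tree$edge[k, 2]
    desc[[par]] <- c(desc[[par]], desc[[chd]])
  }
  lapply(seq_len(nrow(tree$edge)), function(k) {
    sort(desc[[tree$edge[k, 2]]])
  })
}

#' Is a label set monophyletic on an unrooted tree?
#'
#' TRUE iff the label set is one side of the bipartition induced by some
#' edge of the tree (trivial splits included: any single taxon and the
#' full taxon set are monophyletic).
#'
#' @param newick Newick string or \code{ape::phylo} tree.
#' @param label_set Character vector of tip labels.
#' @return logical.
#' @export
check_monophyly <- function(newick, label_set) {
  tree <- if (inherits(newick, "phylo")) newick else
    ape::read.tree(text = newick)
  tips <- tree$tip.label
  unknown <- setdiff(label_set, tips)
  if (length(unknown)) {
    stop("labels not in tree: ", paste(unknown, collapse = ", "))
  }
  idx <- sort(match(label_set, tips))
  if (length(idx) %in% c(1L, length(tips))) return(TRUE)
  all_tips <- seq_along(tips)
  for (side in edge_bipartitions(tree)) {
    if (identical(side, idx) ||
        identical(sort(setdiff(all_tips, side)), idx)) {
      return(TRUE)
    }
  }
  FALSE
}
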