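#' Construct a mitochondrial genome object
#'
#' A \code{mito_genome} holds one circular nucleotide sequence with its
#' identity metadata. Coordinates used elsewhere in the package are
#' 0-based half-open on this (heavy, reference) strand; all file I/O uses
#' the 1-based inclusive GenBank convention.
#'
#' @param sequence Nucleotide string over \code{A,C,G,T,N} (case
#'   insensitive).
#' @param id Free-text label (e.g. species name).
#' @param accession Accession string; may be empty.
#' @param circular Logical; vertebrate mitogenomes are circular.
#' @return Object of class \code{mito_genome}: a list with elements
#'   \code{id}, \code{accession}, \code{sequence}, \code{circular},
#'   \code{length}.
#' @export
#' @examples
#' g <- mito_genome("ACGTACGT", id = "toy")
#' g$length
mito_genome <- function(sequence, id = "genome", accession = "",
                        circular = TRUE) {
  s <- clean_seq(sequence)
  structure(
    list(id = id, accession = accession, sequence = s,
         circular = isTRUE(circular), length = nchar(s)),
    class = "mito_genome"
  )
}

#' @export
print.mito_genome <- function(x, ...) {
  cat(sprintf("mito_genome '%s'%s: %d bp, %s\n", x$id,
              if (nzchar(x$accession)) paste0(" (", x$accession, ")") else "",
              x$length, if (x$circular) "circular" else "linear"))
  invisible(x)
}

#' Construct a genome annotation
#'
#' Ordered, strand-aware feature coordinates for the 37 mitochondrial
#' genes plus control region. Internally 0-based half-open on the
#' reference (heavy) strand; features spanning the origin of the circular
#' molecule are marked \code{wrapped} (their \code{end} is less than
#' \code{start} and is interpreted modulo genome length).
#'
#' @param features data.frame with columns \code{name}, \code{kind}
#'   (\code{PCG}/\code{tRNA}/\code{rRNA}/\code{CR}), \code{start},
#'   \code{end} (0-based half-open), \code{strand} (\code{H}/\code{L});
#'   optional columns \code{wrapped} (logical) and \code{frameshift}
#'   (comma-separated gene-relative 1-based positions of single-nucleotide
#'   insertions excised before translation, \code{""} if none).
#' @param genome_id Label linking the annotation to its genome.
#' @return Object of class \code{mito_annotation} (a data.frame).
#' @export
mito_annotation <- function(features, genome_id = "genome") {
  req <- c("name", "kind", "start", "end", "strand")
  if (!all(req %in% names(features))) {
    stop("features must have columns: ", paste(req, collapse = ", "))
  }
  if (is.null(features$wrapped)) features$wrapped <- FALSE
  if (is.null(features$frameshift)) features$frameshift <- ""
  features$frameshift[is.na(features$frameshift)] <- ""
  if (anyDuplicated(features$name)) {
    stop("feature names must be unique: ",
         paste(unique(features$name[duplicated(features$name)]),
               collapse = ", "))
  }
  if (sum(features$kind == "CR") != 1L) {
    stop("annotation must contain exactly one CR feature")
  }
  features <- features[order(features$start), , drop = FALSE]
  rownames(features) <- NULL
  structure(features, genome_id = genome_id,
            class = c("mito_annotation", "data.frame"))
}

#' @export
print.mito_annotation <- function(x, ...) {
  cat(sprintf("mito_annotation for '%s': %d features\n",
              attr(x, "genome_id"), nrow(x)))
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}

feature_length <- function(f, genome_len) {
  ifelse(f$wrapped, (genome_len - f$start) + f$end, f$end - f$start)
}

# Parse frameshift column into integer vector.
parse_frameshift <- function(x) {
  if (is.na(x) || !nzchar(x)) return(integer(0))
  as.integer(strsplit(x, ",", fixed = TRUE)[[1]])
}

#' Parse a GenBank flat-file record
#'
#' Reads one GenBank record (text) describing an annotated mitogenome and
#' returns the genome plus its annotation in the package's internal
#' representation: 0-based half-open coordinates, complement-strand
#' features mapped to strand \code{L}, and raw feature labels normalized
#' to the canonical vocabulary (e.g. \code{"D-loop"} to \code{CR},
#' \code{"COX1"} to \code{COI}). Labels that cannot be mapped are kept
#' verbatim with a warning.
#'
#' Only \code{CDS}, \code{tRNA}, \code{rRNA} and \code{D-loop} features
#' are used (plain \code{gene} features duplicate the CDS spans).
#' \code{join(a..N,1..b)} locations are treated as origin-wrapped.
#'
#' @param record_text Character scalar or vector of lines.
#' @return list with elements \code{genome} (\code{mito_genome}) and
#'   \code{annotation} (\code{mito_annotation}).
#' @export
parse_genbank_record <- function(record_text) {
  lines <- if (length(record_text) == 1L) {
    strsplit(record_text, "\n", fixed = TRUE)[[1]]
  } else record_text

  locus <- grep("^LOCUS", lines, value = TRUE)
  id <- "genome"
  org <- grep("^\\s+ORGANISM\\s", lines, value = TRUE)
  if (length(org)) id <- trimws(sub("^\\s+ORGANISM\\s+", "", org[1]))
  acc_line <- grep("^ACCESSION", lines, value = TRUE)
  accession <- if (length(acc_line)) {
    strsplit(trimws(sub("^ACCESSION", "", acc_line[1])), "\\s+")[[1]][1]
  } else ""
  if (is.na(accession)) accession <- ""

  ori <- grep("^ORIGIN", lines)
  if (!length(ori)) stop("GenBank record has no ORIGIN sequence block")
  seq_lines <- lines[(ori[1] + 1L):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (!nzchar(sequence)) stop("GenBank record has an empty sequence")
  sequence <- gsub("[^ACGTN]", "N", sequence)

  feat_start <- grep("^FEATURES", lines)
  if (!length(feat_start)) stop("GenBank record has no FEATURES block")
  flines <- lines[(feat_start[1] + 1L):(ori[1] - 1L)]

  # fold the feature block into (key, location, qualifiers) entries
  is_head <- grepl("^ {5}\\S", flines)
  idx <- cumsum(is_head)
  ents <- split(flines[idx > 0], idx[idx > 0])

  rows <- list()
  for (ent in ents) {
    head_parts <- strsplit(trimws(ent[1]), "\\s+")[[1]]
    key <- head_parts[1]
    if (!key %in% c("CDS", "tRNA", "rRNA", "D-loop", "misc_feature")) next
    loc <- paste0(head_parts[-1], collapse = "")
    # location may continue on following lines until the first qualifier
    k <- 2L
    while (k <= length(ent) && !grepl("^\\s+/", ent[k])) {
      loc <- paste0(loc, gsub("\\s", "", ent[k])); k <- k + 1L
    }
    quals <- ent[grepl("^\\s+/", ent)]
    getq <- function(name) {
      q <- grep(sprintf("^\\s+/%s=", name), quals, value = TRUE)
      if (!length(q)) return(NA_character_)
      gsub('^[^=]+="?|"$', "", q[1])
    }
    label <- getq("gene")
    if (is.na(label)) label <- getq("product")
    if (key == "D-loop" ||
        (key == "misc_feature" && grepl("control region", getq("note") %||% "",
                                        ignore.case = TRUE))) {
      label <- "CR"
    }
    if (is.na(label)) next

    strand <- if (grepl("complement", loc)) "L" else "H"
    spans <- gsub("[^0-9.,]", "", gsub("complement|join|\\(|\\)|[<>]", "", loc))
    parts <- strsplit(spans, ",", fixed = TRUE)[[1]]
    coords <- lapply(parts, function(p) as.integer(strsplit(p, "\\.\\.")[[1]]))
    wrapped <- FALSE
    if (length(coords) == 1L) {
      a <- coords[[1]][1]; b <- coords[[1]][2]
      if (is.na(b)) b <- a
    } else {
      # join across the origin: (a..N, 1..b)
      a <- coords[[1]][1]; b <- coords[[length(coords)]][2]
      wrapped <- TRUE
    }
    canon <- normalize_region_name(label)
    if (is.na(canon)) {
      warning("unmappable feature label kept verbatim: ", label)
      canon <- label
      kind <- c(CDS = "PCG", tRNA = "tRNA", rRNA = "rRNA")[key]
      if (is.na(kind)) kind <- "CR"
    } else {
      kind <- unname(mito_vocabulary()[canon])
    }
    rows[[length(rows) + 1L]] <- data.frame(
      name = canon, kind = kind,
      start = a - 1L, end = b, strand = strand, wrapped = wrapped,
      frameshift = "", stringsAsFactors = FALSE
    )
  }
  if (!length(rows)) stop("no usable features found in GenBank record")
  feats <- do.call(rbind, rows)
  feats <- feats[!duplicated(feats$name), , drop = FALSE]

  genome <- mito_genome(sequence, id = id, accession = accession)
  list(genome = genome,
       annotation = mito_annotation(feats, genome_id = genome$id))
}

#' Load a genome from FASTA plus a feature table
#'
#' The feature table is tab-separated with header columns \code{name},
#' \code{kind}, \code{start}, \code{end}, \code{strand} and optionally
#' \code{wrapped}, \code{frameshift}; coordinates in the file are 1-based
#' inclusive and converted to the internal 0-based half-open convention.
#'
#' @param fasta_path Path to a single-record FASTA file.
#' @param feature_table_path Path to the tab-separated feature table.
#' @return list with \code{genome} and \code{annotation}, as
#'   \code{\link{parse_genbank_record}}.
#' @export
load_genome <- function(fasta_path, feature_table_path) {
  ss <- Biostrings::readDNAStringSet(fasta_path)
  if (length(ss) < 1L) stop("FASTA file contains no sequence")
  hdr <- strsplit(names(ss)[1], "\\s+")[[1]]
  genome <- mito_genome(as.character(ss[[1]]),
                        id = paste(hdr[-1], collapse = " ") %0% hdr[1],
                        accession = hdr[1])
  tab <- utils::read.delim(feature_table_path, stringsAsFactors = FALSE)
  req <- c("name", "kind", "start", "end", "strand")
  if (!all(req %in% names(tab))) {
    stop("feature table must have columns: ", paste(req, collapse = ", "))
  }
  if (is.null(tab$wrapped)) tab$wrapped <- tab$end < tab$start
  if (is.null(tab$frameshift)) tab$frameshift <- ""
  tab$frameshift[is.na(tab$frameshift)] <- ""
  bad <- !tab$wrapped & (tab$start < 1L | tab$end > genome$length |
                           tab$end < tab$start)
  if (any(bad)) {
    stop("coordinates outside sequence for: ",
         paste(tab$name[bad], collapse = ", "))
  }
  tab$start <- tab$start - 1L  # 1-based inclusive -> 0-based half-open
  list(genome = genome,
       annotation = mito_annotation(
         tab[, c("name", "kind", "start", "end", "strand", "wrapped",
                 "frameshift")],
         genome_id = genome$id))
}

`%0%` <- function(a, b) if (nzchar(a)) a else b

#' Write a genome as FASTA plus feature table
#'
#' Inverse of \code{\link{load_genome}}: coordinates are emitted 1-based
#' inclusive.
#'
#' @param genome A \code{mito_genome}.
#' @param annotation A \code{mito_annotation}.
#' @param fasta_path,feature_table_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_genome <- function(genome, annotation, fasta_path,
                         feature_table_path) {
  ss <- Biostrings::DNAStringSet(genome$sequence)
  names(ss) <- trimws(paste(genome$accession, genome$id))
  Biostrings::writeXStringSet(ss, fasta_path, width = 70L)
  tab <- as.data.frame(annotation)
  tab$start <- tab$start + 1L
  utils::write.table(tab, feature_table_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(fasta_path, feature_table_path))
}

#' Extract the nucleotide sequence of one feature
#'
#' Returns the reference-strand slice for strand \code{H} features and
#' the reverse complement (coding sense) for strand \code{L}; features
#' wrapped across the origin concatenate the two arcs.
#'
#' @param genome A \code{mito_genome}.
#' @param feature One-row data.frame (a row of a \code{mito_annotation})
#'   or list with \code{start}, \code{end}, \code{strand}, \code{wrapped}.
#' @param sense Either \code{"coding"} (default; L-strand features are
#'   reverse-complemented) or \code{"reference"}.
#' @return Nucleotide string.
#' @export
extract_feature_seq <- function(genome, feature, sense = c("coding",
                                                           "reference")) {
  sense <- match.arg(sense)
  st <- as.integer(feature$start); en <- as.integer(feature$end)
  wrapped <- isTRUE(feature$wrapped)
  if (wrapped) {
    s <- paste0(substr(genome$sequence, st + 1L, genome$length),
                substr(genome$sequence, 1L, en))
  } else {
    stopifnot(st >= 0L, en <= genome$length, st < en)
    s <- substr(genome$sequence, st + 1L, en)
  }
  if (sense == "coding" && identical(feature$strand, "L")) s <- revcomp(s)
  s
}

#' Gene layout: overlaps and intergenic spacers
#'
#' Walks adjacent feature pairs in reference-strand order (including the
#' circular junction between the last and first feature) and reports the
#' gap between them: negative gaps are gene overlaps, positive gaps
#' intergenic spacers, zero gaps abutments. Gap computation is
#' strand-agnostic on reference coordinates.
#'
#' @param annotation A \code{mito_annotation}.
#' @param genome The corresponding \code{mito_genome}.
#' @param circular Include the wrap-around junction (default TRUE).
#' @return Object of class \code{layout_report}: list with
#'   \code{adjacencies} (data.frame: \code{upstream}, \code{downstream},
#'   \code{gap}) and counts \code{n_overlaps}, \code{total_overlap_bp},
#'   \code{n_spacers}, \code{total_spacer_bp}.
#' @export
#' @examples
#' g <- mito_genome(strrep("ACGT", 10))
#' ann <- mito_annotation(data.frame(
#'   name = c("ND1", "CR"), kind = c("PCG", "CR"),
#'   start = c(0L, 8L), end = c(10L, 30L), strand = "H"))
#' gene_layout(ann, g)$total_overlap_bp
gene_layout <- function(annotation, genome, circular = TRUE) {
  f <- as.data.frame(annotation)
  if (is.unsorted(f$start)) {
    warning("features not ordered by start; sorting internally")
    f <- f[order(f$start), , drop = FALSE]
  }
  n <- nrow(f)
  if (n < 2L) stop("layout needs at least two features")
  up <- f$name[-n]; dn <- f$name[-1]
  gap <- f$start[-1] - f$end[-n]
  if (circular && genome$circular) {
    last <- n
    g_wrap <- if (isTRUE(f$wrapped[last])) {
      f$start[1] - f$end[last]           # wrapped feature ends at f$end on arc 2
    } else {
      (genome$length - f$end[last]) + f$start[1]
    }
    up <- c(up, f$name[last]); dn <- c(dn, f$name[1])
    gap <- c(gap, g_wrap)
  }
  adj <- data.frame(upstream = up, downstream = dn, gap = as.integer(gap),
                    stringsAsFactors = FALSE)
  structure(list(
    adjacencies = adj,
    n_overlaps = sum(adj$gap < 0L),
    total_overlap_bp = -sum(adj$gap[adj$gap < 0L]),
    n_spacers = sum(adj$gap > 0L),
    total_spacer_bp = sum(adj$gap[adj$gap > 0L])
  ), class = "layout_report")
}

#' @export
print.layout_report <- function(x, ...) {
  cat(sprintf("layout: %d overlaps (%d bp), %d spacers (%d bp)\n",
              x$n_overlaps, x$total_overlap_bp, x$n_spacers,
              x$total_spacer_bp))
  invisible(x)
}

#' Write an annotation report table
#'
#' One row per feature with 1-based coordinates, strand, size and the
#' intergenic gap to the next feature (negative = overlap), in the layout
#' of a classical mitogenome organization table.
#'
#' @param annotation A \code{mito_annotation}.
#' @param genome The \code{mito_genome}.
#' @param path Output path; if \code{NULL} the data.frame is returned.
#' @return The report data.frame, invisibly when written to file.
#' @export
write_annotation_table <- function(annotation, genome, path = NULL) {
  f <- as.data.frame(annotation)
  lay <- gene_layout(annotation, genome)
  gap_next <- lay$adjacencies$gap[match(f$name, lay$adjacencies$upstream)]
  out <- data.frame(
    name = f$name, kind = f$kind,
    start = f$start + 1L, end = f$end, strand = f$strand,
    size = feature_length(f, genome$length),
    gap_to_next = gap_next, stringsAsFactors = FALSE
  )
  if (is.null(path)) return(out)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(out)
}
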