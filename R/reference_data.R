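#' Published reference values for the 20-genome shorebird cohort
#'
#' The package ships two small plain-text reference tables for the 20
#' Charadriiformes mitogenome accessions the toolkit was built around:
#' \code{"genomes"} lists suborder, family, species, accession and
#' reported genome size (bp); \code{"composition"} lists the reported
#' whole-genome base percentages, AT content and AT/GC skews per
#' accession (2-dp values as published). These serve as desk-scale
#' inputs for cohort summaries and as expectations when the full
#' GenBank records are supplied for recomputation.
#'
#' @param which \code{"genomes"} or \code{"composition"}.
#' @return data.frame.
#' @export
#' @examples
#' sizes <- charadriiformes_reference("genomes")$size_bp
#' cohort_summary(sizes)$mean
charadriiformes_reference <- function(which = c("genomes",
                                                "composition")) {
  which <- match.arg(which)
  f <- system.file("extdata",
                   paste0("charadriiformes_", which, ".tsv"),
                   package = "mitocompare", mustWork = TRUE)
  utils::read.delim(f, stringsAsFactors = FALSE, check.names = FALSE)
}
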