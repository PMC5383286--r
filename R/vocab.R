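#' Canonical mitochondrial region vocabulary
#'
#' The 38 canonical region names used throughout the package: the 13
#' protein-coding genes, 22 tRNAs (the two leucine and two serine
#' isoacceptors distinguished by anticodon class), the two rRNAs, and the
#' control region (\code{CR}).
#'
#' @return Named character vector mapping canonical region name to its kind
#'   (\code{PCG}, \code{tRNA}, \code{rRNA} or \code{CR}).
#' @export
#' @examples
#' table(mito_vocabulary())
mito_vocabulary <- function() {
  c(
    ND1 = "PCG", ND2 = "PCG", COI = "PCG", COII = "PCG", ATP8 = "PCG",
    ATP6 = "PCG", COIII = "PCG", ND3 = "PCG", ND4L = "PCG", ND4 = "PCG",
    ND5 = "PCG", ND6 = "PCG", CYTB = "PCG",
    `12S` = "rRNA", `16S` = "rRNA",
    `tRNA-Phe` = "tRNA", `tRNA-Val` = "tRNA", `tRNA-Leu(UUR)` = "tRNA",
    `tRNA-Ile` = "tRNA", `tRNA-Gln` = "tRNA", `tRNA-Met` = "tRNA",
    `tRNA-Trp` = "tRNA", `tRNA-Ala` = "tRNA", `tRNA-Asn` = "tRNA",
    `tRNA-Cys` = "tRNA", `tRNA-Tyr` = "tRNA", `tRNA-Ser(UCN)` = "tRNA",
    `tRNA-Asp` = "tRNA", `tRNA-Lys` = "tRNA", `tRNA-Gly` = "tRNA",
    `tRNA-Arg` = "tRNA", `tRNA-His` = "tRNA", `tRNA-Ser(AGY)` = "tRNA",
    `tRNA-Leu(CUN)` = "tRNA", `tRNA-Glu` = "tRNA", `tRNA-Thr` = "tRNA",
    `tRNA-Pro` = "tRNA",
    CR = "CR"
  )
}

#' Avian mitochondrial gene order
#'
#' The conserved avian arrangement of the 37 genes plus control region on
#' the circular molecule, starting from tRNA-Phe. ND6 and eight tRNAs
#' (Gln, Ala, Asn, Cys, Tyr, Ser(UCN), Pro, Glu) lie on the light strand;
#' everything else on the heavy strand. This is the order observed across
#' Charadriiformes mitogenomes, which show no rearrangement.
#'
#' @return data.frame with columns \code{name}, \code{kind}, \code{strand}.
#' @export
avian_gene_order <- function() {
  ord <- c(
    "tRNA-Phe", "12S", "tRNA-Val", "16S", "tRNA-Leu(UUR)", "ND1",
    "tRNA-Ile", "tRNA-Gln", "tRNA-Met", "ND2", "tRNA-Trp", "tRNA-Ala",
    "tRNA-Asn", "tRNA-Cys", "tRNA-Tyr", "COI", "tRNA-Ser(UCN)",
    "tRNA-Asp", "COII", "tRNA-Lys", "ATP8", "ATP6", "COIII", "tRNA-Gly",
    "ND3", "tRNA-Arg", "ND4L", "ND4", "tRNA-His", "tRNA-Ser(AGY)",
    "tRNA-Leu(CUN)", "ND5", "CYTB", "tRNA-Thr", "tRNA-Pro", "ND6",
    "tRNA-Glu", "CR"
  )
  light <- c("tRNA-Gln", "tRNA-Ala", "tRNA-Asn", "tRNA-Cys", "tRNA-Tyr",
             "tRNA-Ser(UCN)", "tRNA-Pro", "ND6", "tRNA-Glu")
  vocab <- mito_vocabulary()
  data.frame(
    name = ord,
    kind = unname(vocab[ord]),
    strand = ifelse(ord %in% light, "L", "H"),
    stringsAsFactors = FALSE
  )
}

# Synonym map: raw GenBank gene/product labels -> canonical vocabulary.
# Keys are upper-cased and stripped of spaces/underscores before lookup.
region_synonyms <- function() {
  c(
    "ND1" = "ND1", "NAD1" = "ND1", "NADH1" = "ND1",
    "NADHDEHYDROGENASESUBUNIT1" = "ND1",
    "ND2" = "ND2", "NAD2" = "ND2", "NADHDEHYDROGENASESUBUNIT2" = "ND2",
    "ND3" = "ND3", "NAD3" = "ND3", "NADHDEHYDROGENASESUBUNIT3" = "ND3",
    "ND4" = "ND4", "NAD4" = "ND4", "NADHDEHYDROGENASESUBUNIT4" = "ND4",
    "ND4L" = "ND4L", "NAD4L" = "ND4L",
    "NADHDEHYDROGENASESUBUNIT4L" = "ND4L",
    "ND5" = "ND5", "NAD5" = "ND5", "NADHDEHYDROGENASESUBUNIT5" = "ND5",
    "ND6" = "ND6", "NAD6" = "ND6", "NADHDEHYDROGENASESUBUNIT6" = "ND6",
    "COI" = "COI", "COX1" = "COI", "CO1" = "COI", "COXI" = "COI",
    "CYTOCHROMECOXIDASESUBUNITI" = "COI",
    "CYTOCHROMECOXIDASESUBUNIT1" = "COI",
    "COII" = "COII", "COX2" = "COII", "CO2" = "COII", "COXII" = "COII",
    "CYTOCHROMECOXIDASESUBUNITII" = "COII",
    "CYTOCHROMECOXIDASESUBUNIT2" = "COII",
    "COIII" = "COIII", "COX3" = "COIII", "CO3" = "COIII",
    "COXIII" = "COIII", "CYTOCHROMECOXIDASESUBUNITIII" = "COIII",
    "CYTOCHROMECOXIDASESUBUNIT3" = "COIII",
    "ATP6" = "ATP6", "ATPASE6" = "ATP6", "ATPSYNTHASEF0SUBUNIT6" = "ATP6",
    "ATP8" = "ATP8", "ATPASE8" = "ATP8", "ATPSYNTHASEF0SUBUNIT8" = "ATP8",
    "CYTB" = "CYTB", "COB" = "CYTB", "CYTOCHROMEB" = "CYTB",
    "12S" = "12S", "12SRRNA" = "12S", "12SRIBOSOMALRNA" = "12S",
    "RRNS" = "12S", "SSURRNA" = "12S", "S-RRNA" = "12S",
    "16S" = "16S", "16SRRNA" = "16S", "16SRIBOSOMALRNA" = "16S",
    "RRNL" = "16S", "LSURRNA" = "16S", "L-RRNA" = "16S",
    "DLOOP" = "CR", "D-LOOP" = "CR", "CR" = "CR", "CONTROLREGION" = "CR",
    "TRNF" = "tRNA-Phe", "TRNA-PHE" = "tRNA-Phe",
    "TRNV" = "tRNA-Val", "TRNA-VAL" = "tRNA-Val",
    "TRNL2" = "tRNA-Leu(UUR)", "TRNA-LEU(UUR)" = "tRNA-Leu(UUR)",
    "TRNI" = "tRNA-Ile", "TRNA-ILE" = "tRNA-Ile",
    "TRNQ" = "tRNA-Gln", "TRNA-GLN" = "tRNA-Gln",
    "TRNM" = "tRNA-Met", "TRNA-MET" = "tRNA-Met",
    "TRNW" = "tRNA-Trp", "TRNA-TRP" = "tRNA-Trp",
    "TRNA" = "tRNA-Ala", "TRNA-ALA" = "tRNA-Ala",
    "TRNN" = "tRNA-Asn", "TRNA-ASN" = "tRNA-Asn",
    "TRNC" = "tRNA-Cys", "TRNA-CYS" = "tRNA-Cys",
    "TRNY" = "tRNA-Tyr", "TRNA-TYR" = "tRNA-Tyr",
    "TRNS2" = "tRNA-Ser(UCN)", "TRNA-SER(UCN)" = "tRNA-Ser(UCN)",
    "TRND" = "tRNA-Asp", "TRNA-ASP" = "tRNA-Asp",
    "TRNK" = "tRNA-Lys", "TRNA-LYS" = "tRNA-Lys",
    "TRNG" = "tRNA-Gly", "TRNA-GLY" = "tRNA-Gly",
    "TRNR" = "tRNA-Arg", "TRNA-ARG" = "tRNA-Arg",
    "TRNH" = "tRNA-His", "TRNA-HIS" = "tRNA-His",
    "TRNS1" = "tRNA-Ser(AGY)", "TRNA-SER(AGY)" = "tRNA-Ser(AGY)",
    "TRNL1" = "tRNA-Leu(CUN)", "TRNA-LEU(CUN)" = "tRNA-Leu(CUN)",
    "TRNE" = "tRNA-Glu", "TRNA-GLU" = "tRNA-Glu",
    "TRNT" = "tRNA-Thr", "TRNA-THR" = "tRNA-Thr",
    "TRNP" = "tRNA-Pro", "TRNA-PRO" = "tRNA-Pro"
  )
}

# Normalize a raw feature label to the canonical vocabulary; NA if unknown.
normalize_region_name <- function(raw) {
  syn <- region_synonyms()
  key <- toupper(gsub("[ _]", "", raw))
  # exact canonical names pass through untouched
  vocab <- names(mito_vocabulary())
  hit <- match(key, toupper(gsub("[ _]", "", vocab)))
  out <- ifelse(!is.na(hit), vocab[hit], unname(syn[key]))
  unname(out)
}
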