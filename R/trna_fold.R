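# Constrained cloverleaf secondary-structure prediction for
# mitochondrially encoded tRNAs (DNA alphabet; the CCA tail is not
# genome-encoded and is assumed absent). The search space is the set of
# admissible arm-boundary partitions; scoring is per base pair at
# integer granularity so that an exhaustive oracle is exact.

#' Folding parameters for the cloverleaf search
#'
#' Arm-length ranges (nt) and pair scores. Defaults: acceptor stem fixed
#' at 7 bp with one unpaired discriminator at the 3' end; D stem 3-4 bp
#' with loop 4-12 nt; anticodon stem 5 bp with 7-nt loop; variable
#' region 3-23 nt; T stem 4-5 bp with loop 5-9 nt. Pair scores follow
#' the standard thermodynamic ordering G:C = 3 > A:T = 2 > G:U = 1; at
#' most one mismatch per stem, scored 0. In the D-armless model the
#' whole D arm is replaced by an unpaired connector of 4-12 nt.
#'
#' @param ... Named overrides of the defaults listed above.
#' @return list of parameters (class \code{fold_params}).
#' @export
fold_params <- function(...) {
  p <- list(
    acceptor_len = 7L, link1 = 1:3, d_stem = 3:4, d_loop = 4:12,
    link2 = 0:2, ac_stem = 5L, ac_loop = 7L, var = 3:23, t_stem = 4:5,
    t_loop = 5:9, noD_connector = 4:12,
    pair_scores = c(GC = 3, AT = 2, GT = 1), max_mismatch = 1L
  )
  dots <- list(...)
  p[names(dots)] <- dots
  structure(p, class = "fold_params")
}

pair_score_one <- function(a, b, scores) {
  key <- paste0(sort(c(a, b)), collapse = "")
  if (key %in% c("CG", "GC")) return(scores[["GC"]])
  if (key %in% c("AT", "TA")) return(scores[["AT"]])
  if (key %in% c("GT", "TG")) return(scores[["GT"]])
  NA_real_  # mismatch
}

# Score a stem given 5' interval and 3' interval (both 1-based inclusive
# on the sequence, 3' side pairs antiparallel). Returns list(score,
# mismatches, paired) or NULL if over the mismatch budget.
score_stem <- function(ch, i5, i3, params) {
  len <- i5[2] - i5[1] + 1L
  sc <- 0; mm <- 0L
  paired <- logical(len)
  for (k in seq_len(len)) {
    a <- ch[i5[1] + k - 1L]
    b <- ch[i3[2] - k + 1L]
    s <- pair_score_one(a, b, params$pair_scores)
    if (is.na(s)) {
      mm <- mm + 1L
      if (mm > params$max_mismatch) return(NULL)
    } else {
      sc <- sc + s
      paired[k] <- TRUE
    }
  }
  list(score = sc, mismatches = mm, paired = paired)
}

#' Fold a mitochondrial tRNA into a cloverleaf
#'
#' Exhaustive search over all admissible arm-boundary partitions of the
#' sequence, returning the maximum-score structure. With
#' \code{allow_no_D} the D-armless model (as in mitochondrial
#' tRNA-Ser(AGY)) competes and wins only on strictly higher score; among
#' equal-scoring partitions the canonical (D-arm-present) model is
#' preferred, then smaller D-loop, in a fixed deterministic enumeration
#' order. If no partition satisfies the constraints the result has model
#' \code{"unfoldable"} (no error).
#'
#' @param seq tRNA gene sequence, coding sense, 55-95 nt.
#' @param params A \code{\link{fold_params}} object.
#' @param allow_no_D Allow the D-armless model to compete.
#' @return Object of class \code{trna_structure}: list with
#'   \code{model} (\code{"cloverleaf"}, \code{"D-armless"} or
#'   \code{"unfoldable"}), \code{score}, \code{anticodon},
#'   \code{dotbracket}, and \code{arms} (named list of 1-based inclusive
#'   intervals).
#' @export
fold_trna <- function(seq, params = fold_params(), allow_no_D = TRUE) {
  s <- clean_seq(seq)
  n <- nchar(s)
  if (n < 55L || n > 95L) stop("tRNA sequence must be 55-95 nt, got ", n)
  ch <- seq_chars(s)
  best <- NULL

  consider <- function(model, score, layout) {
    if (is.null(best)) { best <<- list(model = model, score = score,
                                       layout = layout); return() }
    better <- score > best$score ||
      (score == best$score && model == "cloverleaf" &&
         best$model == "D-armless")
    if (better) best <<- list(model = model, score = score,
                              layout = layout)
  }

  acc <- params$acceptor_len
  fixed <- acc + 2L * params$ac_stem + params$ac_loop + acc + 1L

  # canonical cloverleaf: enumerate D loop ascending so the smaller
  # D-loop is kept on ties
  for (dl in sort(params$d_loop)) for (d in params$d_stem) {
    for (u1 in params$link1) for (l2 in params$link2) {
      for (t in params$t_stem) for (tl in params$t_loop) {
        v <- n - (fixed + u1 + 2L * d + dl + l2 + 2L * t + tl)
        if (!(v %in% params$var)) next
        pos <- cloverleaf_layout(n, acc, u1, d, dl, l2, params$ac_stem,
                                 params$ac_loop, v, t, tl)
        sc <- layout_score(ch, pos, params)
        if (!is.null(sc)) consider("cloverleaf", sc$score,
                                   c(pos, list(stems = sc$stems)))
      }
    }
  }

  if (allow_no_D) {
    for (cn in sort(params$noD_connector)) {
      for (u1 in params$link1) for (l2 in params$link2) {
        for (t in params$t_stem) for (tl in params$t_loop) {
          v <- n - (fixed + u1 + cn + l2 + 2L * t + tl)
          if (!(v %in% params$var)) next
          pos <- cloverleaf_layout(n, acc, u1, NULL, cn, l2,
                                   params$ac_stem, params$ac_loop, v, t,
                                   tl)
          sc <- layout_score(ch, pos, params)
          if (!is.null(sc)) consider("D-armless", sc$score,
                                     c(pos, list(stems = sc$stems)))
        }
      }
    }
  }

  if (is.null(best)) {
    return(structure(list(model = "unfoldable", score = NA_real_,
                          anticodon = NA_character_,
                          dotbracket = NA_character_, arms = NULL),
                     class = "trna_structure"))
  }
  lay <- best$layout
  anticodon <- substr(s, lay$ac_loop[1] + 2L, lay$ac_loop[1] + 4L)
  structure(list(
    model = best$model, score = best$score, anticodon = anticodon,
    dotbracket = layout_dotbracket(n, lay),
    arms = lay
  ), class = "trna_structure")
}

# 1-based inclusive intervals of every element; d = NULL -> D-armless
# (d_loop interval then holds the unpaired connector).
cloverleaf_layout <- function(n, acc, u1, d, dl, l2, ac, acl, v, t, tl) {
  p <- 1L
  iv <- function(len) { out <- c(p, p + len - 1L); p <<- p + len; out }
  acc5 <- iv(acc)
  link1 <- iv(u1)
  if (!is.null(d)) {
    d5 <- iv(d); dloop <- iv(dl); d3 <- iv(d)
  } else {
    d5 <- NULL; dloop <- iv(dl); d3 <- NULL
  }
  link2 <- if (l2 > 0L) iv(l2) else NULL
  ac5 <- iv(ac); acloop <- iv(acl); ac3 <- iv(ac)
  varr <- iv(v)
  t5 <- iv(t); tloop <- iv(tl); t3 <- iv(t)
  acc3 <- iv(acc)
  disc <- iv(1L)
  stopifnot(p - 1L == n)
  list(acceptor5 = acc5, link1 = link1, d5 = d5, d_loop = dloop, d3 = d3,
       link2 = link2, ac5 = ac5, ac_loop = acloop, ac3 = ac3,
       variable = varr, t5 = t5, t_loop = tloop, t3 = t3,
       acceptor3 = acc3, discriminator = disc)
}

layout_score <- function(ch, pos, params) {
  stems <- list(acceptor = score_stem(ch, pos$acceptor5, pos$acceptor3,
                                      params))
  if (is.null(stems$acceptor)) return(NULL)
  if (!is.null(pos$d5)) {
    stems$d <- score_stem(ch, pos$d5, pos$d3, params)
    if (is.null(stems$d)) return(NULL)
  }
  stems$ac <- score_stem(ch, pos$ac5, pos$ac3, params)
  if (is.null(stems$ac)) return(NULL)
  stems$t <- score_stem(ch, pos$t5, pos$t3, params)
  if (is.null(stems$t)) return(NULL)
  list(score = sum(vapply(stems, `[[`, 0, "score")), stems = stems)
}

layout_dotbracket <- function(n, lay) {
  db <- rep(".", n)
  put <- function(i5, i3, paired) {
    len <- i5[2] - i5[1] + 1L
    for (k in seq_len(len)) {
      if (paired[k]) {
        db[i5[1] + k - 1L] <<- "("
        db[i3[2] - k + 1L] <<- ")"
      }
    }
  }
  put(lay$acceptor5, lay$acceptor3, lay$stems$acceptor$paired)
  if (!is.null(lay$d5)) put(lay$d5, lay$d3, lay$stems$d$paired)
  put(lay$ac5, lay$ac3, lay$stems$ac$paired)
  put(lay$t5, lay$t3, lay$stems$t$paired)
  paste0(db, collapse = "")
}

#' @export
print.trna_structure <- function(x, ...) {
  cat(sprintf("tRNA fold: %s, score %s, anticodon %s\n", x$model,
              ifelse(is.na(x$score), "NA", x$score),
              ifelse(is.na(x$anticodon), "NA", x$anticodon)))
  if (!is.na(x$dotbracket)) cat(x$dotbracket, "\n")
  invisible(x)
}

# amino acid (one-letter) expected for each canonical tRNA name
trna_name_aa <- function() {
  c(`tRNA-Phe` = "F", `tRNA-Val` = "V", `tRNA-Leu(UUR)` = "L",
    `tRNA-Ile` = "I", `tRNA-Gln` = "Q", `tRNA-Met` = "M",
    `tRNA-Trp` = "W", `tRNA-Ala` = "A", `tRNA-Asn` = "N",
    `tRNA-Cys` = "C", `tRNA-Tyr` = "Y", `tRNA-Ser(UCN)` = "S",
    `tRNA-Asp` = "D", `tRNA-Lys` = "K", `tRNA-Gly` = "G",
    `tRNA-Arg` = "R", `tRNA-His` = "H", `tRNA-Ser(AGY)` = "S",
    `tRNA-Leu(CUN)` = "L", `tRNA-Glu` = "E", `tRNA-Thr` = "T",
    `tRNA-Pro` = "P")
}

#' Does the folded anticodon match the tRNA's identity?
#'
#' Decodes the anticodon (the codon read is its reverse complement) under
#' the vertebrate mitochondrial code and checks that the amino acid
#' matches the tRNA's name. The serine and leucine isoacceptor classes
#' are distinguished by codon family: Ser(AGY) reads AGC/AGT, Ser(UCN)
#' reads TCN, Leu(UUR) reads TTA/TTG, Leu(CUN) reads CTN.
#'
#' @param structure A folded \code{trna_structure}.
#' @param gene_name Canonical tRNA name (see
#'   \code{\link{mito_vocabulary}}).
#' @return logical.
#' @export
anticodon_check <- function(structure, gene_name) {
  if (structure$model == "unfoldable") {
    stop("cannot check anticodon of an unfoldable structure")
  }
  aa_map <- trna_name_aa()
  if (!gene_name %in% names(aa_map)) {
    stop("unknown tRNA name: ", gene_name)
  }
  codon <- revcomp(structure$anticodon)
  aa <- mito_genetic_code()[[codon]]
  if (aa != aa_map[[gene_name]]) return(FALSE)
  switch(gene_name,
    `tRNA-Ser(AGY)` = substr(codon, 1, 2) == "AG",
    `tRNA-Ser(UCN)` = substr(codon, 1, 2) == "TC",
    `tRNA-Leu(UUR)` = substr(codon, 1, 2) == "TT",
    `tRNA-Leu(CUN)` = substr(codon, 1, 2) == "CT",
    TRUE)
}

#' Cohort tRNA folding report
#'
#' Folds every annotated tRNA of every genome in a cohort and reports
#' the structural class and arm lengths, the raw material for assessing
#' where arm variation concentrates (in mitochondrial tRNAs, mostly the
#' D arm).
#'
#' @param genomes list of \code{list(genome =, annotation =)} entries.
#' @param params A \code{\link{fold_params}}.
#' @return data.frame with one row per (species, tRNA): \code{species},
#'   \code{trna}, \code{class}, \code{score}, \code{length},
#'   \code{d_loop_len}, \code{ac_loop_len}, \code{t_loop_len},
#'   \code{var_len}, \code{anticodon}, \code{anticodon_ok}.
#' @export
cohort_fold_report <- function(genomes, params = fold_params()) {
  rows <- list()
  for (entry in genomes) {
    g <- entry$genome; ann <- as.data.frame(entry$annotation)
    trnas <- ann[ann$kind == "tRNA", , drop = FALSE]
    for (i in seq_len(nrow(trnas))) {
      seq <- extract_feature_seq(g, trnas[i, ], sense = "coding")
      st <- fold_trna(seq, params)
      ilen <- function(iv) if (is.null(iv)) NA_integer_ else
        iv[2] - iv[1] + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        species = g$id, trna = trnas$name[i],
        class = st$model,
        score = st$score, length = nchar(seq),
        d_loop_len = if (st$model == "cloverleaf")
          ilen(st$arms$d_loop) else NA_integer_,
        ac_loop_len = ilen(st$arms$ac_loop),
        t_loop_len = ilen(st$arms$t_loop),
        var_len = ilen(st$arms$variable),
        anticodon = st$anticodon,
        anticodon_ok = if (st$model == "unfoldable") NA else
          anticodon_check(st, trnas$name[i]),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
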