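# Synthetic mitogenome cohorts with known truth. The generator emulates
# the statistical structure the analysis stages assume: the conserved
# avian gene order (37 genes + control region, ND6 and eight tRNAs on
# the light strand), per-region base composition, planted gene overlaps
# realized as shared sequence, planted start/stop codons (including
# incomplete stops), planted control-region tandem repeats, designed
# tRNA cloverleaf structures, and codon-level sequence evolution along a
# tree with per-gene omega.

# standard mitochondrial tRNA anticodons (DNA alphabet)
trna_anticodons <- function() {
  c(`tRNA-Phe` = "GAA", `tRNA-Val` = "TAC", `tRNA-Leu(UUR)` = "TAA",
    `tRNA-Ile` = "GAT", `tRNA-Gln` = "TTG", `tRNA-Met` = "CAT",
    `tRNA-Trp` = "TCA", `tRNA-Ala` = "TGC", `tRNA-Asn` = "GTT",
    `tRNA-Cys` = "GCA", `tRNA-Tyr` = "GTA", `tRNA-Ser(UCN)` = "TGA",
    `tRNA-Asp` = "GTC", `tRNA-Lys` = "TTT", `tRNA-Gly` = "TCC",
    `tRNA-Arg` = "TCG", `tRNA-His` = "GTG", `tRNA-Ser(AGY)` = "GCT",
    `tRNA-Leu(CUN)` = "TAG", `tRNA-Glu` = "TTC", `tRNA-Thr` = "TGT",
    `tRNA-Pro` = "TGG")
}

#' Default simulation configuration
#'
#' The configuration describes one synthetic mitogenome in the image of
#' a typical shorebird mitogenome: avian gene order, ~16.7 kb, ten gene
#' overlaps totalling 35 bp (the largest, 10 bp, between ATP8 and ATP6),
#' seventeen intergenic spacers totalling 69 bp, an AT-rich control
#' region with planted tandem repeats, start/stop codon usage matching
#' the cohort-wide pattern (ATG dominant, GTG in COI and ND5, ATT in
#' ND3, incomplete T-- stops in COIII and ND4), and the single-C
#' frameshift insertion at position 174 of ND3.
#'
#' @param ... Named overrides (see the returned list for field names).
#' @return list of class \code{sim_config}.
#' @export
sim_config <- function(...) {
  pcg <- data.frame(
    gene  = c("ND1", "ND2", "COI", "COII", "ATP8", "ATP6", "COIII",
              "ND3", "ND4L", "ND4", "ND5", "CYTB", "ND6"),
    length = c(978L, 1041L, 1551L, 684L, 168L, 684L, 784L, 352L, 297L,
               1378L, 1818L, 1143L, 522L),
    start = c("ATA", "ATA", "GTG", "ATG", "ATG", "ATG", "ATG", "ATT",
              "ATG", "ATG", "GTG", "ATG", "ATG"),
    stop  = c("AGG", "TAG", "AGG", "TAA", "TAA", "TAA", "T--", "TAA",
              "TAA", "T--", "AGA", "TAA", "TAG"),
    stringsAsFactors = FALSE)
  overlaps <- data.frame(
    upstream   = c("16S", "tRNA-Ile", "tRNA-Gln", "tRNA-Cys", "COI",
                   "ATP8", "ATP6", "ND4L", "tRNA-Ser(AGY)", "tRNA-Thr"),
    downstream = c("tRNA-Leu(UUR)", "tRNA-Gln", "tRNA-Met", "tRNA-Tyr",
                   "tRNA-Ser(UCN)", "ATP6", "COIII", "ND4",
                   "tRNA-Leu(CUN)", "tRNA-Pro"),
    bp = c(1L, 2L, 1L, 1L, 9L, 10L, 1L, 7L, 1L, 2L),
    stringsAsFactors = FALSE)
  # 17 spacers, 1-12 bp, totalling 69 bp, on adjacencies free of overlaps
  spacers <- data.frame(
    upstream = c("tRNA-Phe", "12S", "tRNA-Val", "ND1", "ND2", "tRNA-Trp",
                 "tRNA-Ala", "tRNA-Asn", "tRNA-Tyr", "tRNA-Ser(UCN)",
                 "COII", "tRNA-Lys", "COIII", "tRNA-Gly", "ND3",
                 "tRNA-Arg", "ND5"),
    bp = c(1L, 1L, 1L, 2L, 1L, 2L, 12L, 9L, 1L, 3L, 1L, 2L, 1L, 8L, 6L,
           6L, 12L),
    stringsAsFactors = FALSE)
  cfg <- list(
    seed = 1L,
    pcg = pcg,
    rrna_lengths = c(`12S` = 975L, `16S` = 1595L),
    overlaps = overlaps,
    spacers = spacers,
    nd3_frameshift = 174L,
    # sampling probabilities (A, C, G, T) per region class
    comp_coding = c(A = 0.312, C = 0.306, G = 0.138, T = 0.244),
    comp_cr = c(A = 0.320, C = 0.274, G = 0.118, T = 0.288),
    cr_repeats = data.frame(motif = c("AAACAAC", "AAAC"),
                            copies = c(6, 8), stringsAsFactors = FALSE),
    cr_unique = c(320L, 250L, 530L),  # unique blocks between repeats
    trna_d_loop = 8L,        # default D-loop length; NA entries vary
    d_armless = "tRNA-Ser(AGY)"
  )
  dots <- list(...)
  cfg[names(dots)] <- dots
  structure(cfg, class = "sim_config")
}

sample_nt <- function(n, probs) {
  sample(names(probs), n, replace = TRUE, prob = probs)
}

# Shuffled base pool with exact target counts (largest-remainder
# rounding), so realized region composition hits the target to within
# rounding rather than sampling noise.
sample_nt_exact <- function(n, probs) {
  p <- probs / sum(probs)
  base <- floor(n * p)
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- n * p - base
    extra <- order(frac, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1L
  }
  sample(rep(names(p), base))
}

# Random non-stop codons drawn from an exact-composition base pool;
# stop codons arising from the shuffle are repaired by swapping their
# middle base with another codon's (multiset preserved).
sample_codons <- function(n, probs) {
  stops <- mito_stop_codons()
  pool <- sample_nt_exact(3L * n, probs)
  m <- matrix(pool, nrow = 3L)
  cods <- paste0(m[1, ], m[2, ], m[3, ])
  bad <- which(cods %in% stops)
  guard <- 0L
  while (length(bad) && guard < 10000L) {
    i <- bad[1]
    j <- sample.int(n, 1L)
    a <- cods[i]; b <- cods[j]
    na <- a; nb <- b
    substr(na, 2, 2) <- substr(b, 2, 2)
    substr(nb, 2, 2) <- substr(a, 2, 2)
    if (i != j && !na %in% stops && !nb %in% stops) {
      cods[i] <- na; cods[j] <- nb
    }
    bad <- which(cods %in% stops)
    guard <- guard + 1L
  }
  if (length(bad)) {
    # pathological pool; fall back to resampling the offenders
    for (i in bad) {
      repeat {
        cand <- paste0(sample_nt(1, probs), sample_nt(1, probs),
                       sample_nt(1, probs))
        if (!cand %in% stops) { cods[i] <- cand; break }
      }
    }
  }
  cods
}

# Forced sequence constraints that realize the planted overlaps while
# preserving every planted start/stop codon (see the methods vignette):
# the shared region of each PCG/PCG overlap is written once, containing
# the downstream start and the upstream stop in their respective frames.
overlap_forced <- function() {
  list(
    ATP6_prefix = "ATGCAACTAA",  # nt 8-10 = TAA is ATP8's stop
    ND4_prefix = "ATGCTAA",      # nt 5-7 = TAA is ND4L's stop
    COI_suffix = "CTACTAAGG",    # last codon AGG is COI's stop
    SerUCN_coding_tail = "CCTTAGTAG"  # revcomp(COI_suffix)
  )
}

# Sample a PCG sequence honoring planted codons and overlap constraints.
# Genes sharing an overlap region carry a fixed prefix (downstream gene:
# ATP6, ND4) or fixed suffix (upstream gene: ATP8, ND4L, COI); 2-nt
# guards complete the codons straddling a forced-region boundary and are
# resampled until no internal stop arises in the gene's own frame.
sim_pcg_seq <- function(gene, len, start, stop, probs) {
  forced <- overlap_forced()
  incomplete <- stop %in% c("T--", "TA-")
  tail_nt <- if (incomplete) sub("-+$", "", stop) else stop
  prefix <- switch(gene, ATP6 = forced$ATP6_prefix,
                   ND4 = forced$ND4_prefix, start)
  suffix <- switch(gene, ATP8 = forced$ATP6_prefix,
                   ND4L = forced$ND4_prefix, COI = forced$COI_suffix,
                   tail_nt)
  guard_pre <- if (gene %in% c("ATP6", "ND4")) 2L else 0L
  guard_suf <- if (gene %in% c("ATP8", "ND4L")) 2L else 0L
  body_len <- len - nchar(prefix) - nchar(suffix) - guard_pre - guard_suf
  stopifnot(body_len >= 3L, body_len %% 3L == 0L)
  ncod <- body_len %/% 3L
  for (attempt in 1:200) {
    g1 <- if (guard_pre) paste0(sample(c("A", "C", "G", "T"), guard_pre,
                                       TRUE), collapse = "") else ""
    g2 <- if (guard_suf) paste0(sample(c("A", "C", "G", "T"), guard_suf,
                                       TRUE), collapse = "") else ""
    s <- paste0(prefix, g1,
                paste0(sample_codons(ncod, probs), collapse = ""),
                g2, suffix)
    stopifnot(nchar(s) == len)
    if (!length(which_internal_stops(s, incomplete))) return(s)
  }
  stop("could not satisfy codon constraints for ", gene)
}

which_internal_stops <- function(s, incomplete) {
  cods <- codon_split(s)
  if (!incomplete) cods <- cods[-length(cods)]
  which(cods %in% mito_stop_codons())
}

# Design a tRNA gene sequence realizing a planted cloverleaf (or
# D-armless) structure with perfect stems: GC-biased stems, low-GC
# loops, the standard anticodon for the tRNA's identity.
design_trna <- function(name, d_loop_len = 8L, d_armless = FALSE,
                        force_coding_tail = NULL) {
  anticodon <- trna_anticodons()[[name]]
  pairs <- c("GC", "CG", "AT", "TA")
  pw <- c(0.35, 0.35, 0.15, 0.15)
  loop_nt <- function(n) paste0(sample(c("A", "T", "C"), n, TRUE,
                                       prob = c(0.5, 0.3, 0.2)),
                                collapse = "")
  stem <- function(n) {
    p <- sample(pairs, n, TRUE, prob = pw)
    list(left = paste0(substr(p, 1, 1), collapse = ""),
         right = paste0(rev(substr(p, 2, 2)), collapse = ""))
  }
  acc <- stem(7L); ac <- stem(5L); tt <- stem(5L)
  if (d_armless) {
    core <- paste0(loop_nt(2L), loop_nt(6L))  # link1 + connector
    dpart <- ""
  } else {
    d <- stem(3L)
    core <- paste0(loop_nt(2L), d$left, loop_nt(d_loop_len), d$right)
    dpart <- NULL
  }
  acl <- loop_nt(7L)
  substr(acl, 3L, 5L) <- anticodon
  s <- paste0(acc$left, core, loop_nt(1L),          # link2 = 1 nt
              ac$left, acl, ac$right,
              loop_nt(4L),                          # variable region
              tt$left, loop_nt(7L), tt$right,
              acc$right, loop_nt(1L))               # discriminator
  if (!is.null(force_coding_tail)) {
    k <- nchar(force_coding_tail)
    n <- nchar(s)
    substr(s, n - k + 1L, n) <- force_coding_tail
    # re-pair the acceptor 5' arm against the forced 3' arm
    acc3 <- substr(s, n - 7L, n - 1L)
    substr(s, 1L, 7L) <- revcomp(acc3)
    # re-pair the first T-stem position against the forced last nt of
    # the T 3' side (the nt just before the acceptor 3' arm)
    t3_last <- substr(s, n - 8L, n - 8L)
    t5_pos <- 7L + nchar(core) + 1L + 17L + 4L + 1L
    substr(s, t5_pos, t5_pos) <- chartr("ACGT", "TGCA", t3_last)
  }
  s
}

#' Generate one annotated synthetic mitogenome
#'
#' Builds a genome honoring the configured gene order and strands,
#' planted overlaps (overlapping features share sequence, the downstream
#' feature's sequence taking precedence), planted start/stop codons,
#' planted frameshift insertion, planted control-region repeats and
#' designed tRNA structures. Deterministic given \code{cfg$seed}.
#'
#' @param cfg A \code{\link{sim_config}}.
#' @return list with \code{genome} (\code{mito_genome}),
#'   \code{annotation} (\code{mito_annotation}) and \code{truth} (list
#'   of planted values; see \code{\link{write_truth}}).
#' @export
#' @examples
#' sim <- generate_mitogenome(sim_config(seed = 7))
#' sim$genome$length
generate_mitogenome <- function(cfg = sim_config()) {
  set.seed(cfg$seed)
  ord <- avian_gene_order()
  coding <- list()   # coding-sense sequence per feature
  truth <- list(seed = cfg$seed, gene_order = ord$name,
                strands = stats::setNames(ord$strand, ord$name))

  trna_tail <- overlap_forced()$SerUCN_coding_tail
  for (i in seq_len(nrow(ord))) {
    nm <- ord$name[i]
    kind <- ord$kind[i]
    coding[[nm]] <- switch(
      kind,
      PCG = {
        row <- cfg$pcg[cfg$pcg$gene == nm, ]
        len <- row$length
        if (nm == "ND3" && !is.na(cfg$nd3_frameshift)) len <- len - 1L
        s <- sim_pcg_seq(nm, len, row$start, row$stop, cfg$comp_coding)
        if (nm == "ND3" && !is.na(cfg$nd3_frameshift)) {
          p <- cfg$nd3_frameshift
          s <- paste0(substr(s, 1L, p - 1L), "C",
                      substr(s, p, nchar(s)))
        }
        s
      },
      rRNA = paste0(sample_nt_exact(cfg$rrna_lengths[[nm]],
                                    cfg$comp_coding), collapse = ""),
      tRNA = design_trna(
        nm, d_loop_len = cfg$trna_d_loop,
        d_armless = nm %in% cfg$d_armless,
        force_coding_tail = if (nm == "tRNA-Ser(UCN)") trna_tail),
      CR = sim_cr_seq(cfg)
    )
    if (kind == "CR") {
      cr <- coding[[nm]]
      truth$cr_repeats <- attr(cr, "repeats")
      coding[[nm]] <- as.character(cr)
    }
  }

  # assemble the reference strand left to right
  genome_str <- ""
  rows <- list()
  spacer_of <- stats::setNames(cfg$spacers$bp, cfg$spacers$upstream)
  overlap_of <- stats::setNames(cfg$overlaps$bp, cfg$overlaps$downstream)
  prev <- NULL
  for (i in seq_len(nrow(ord))) {
    nm <- ord$name[i]
    ref <- if (ord$strand[i] == "L") revcomp(coding[[nm]]) else
      coding[[nm]]
    gap <- 0L
    if (!is.null(prev)) {
      if (nm %in% names(overlap_of)) {
        k <- overlap_of[[nm]]
        if (k > nchar(coding[[prev]])) stop("overlap longer than gene")
        gap <- -k
      } else if (prev %in% names(spacer_of)) {
        gap <- spacer_of[[prev]]
      }
    }
    if (gap > 0L) {
      genome_str <- paste0(genome_str,
                           paste0(sample_nt(gap, cfg$comp_coding),
                                  collapse = ""))
    }
    st <- nchar(genome_str) - max(0L, -gap)
    genome_str <- paste0(substr(genome_str, 1L, st), ref)
    rows[[i]] <- data.frame(
      name = nm, kind = ord$kind[i], start = st,
      end = st + nchar(ref), strand = ord$strand[i], wrapped = FALSE,
      frameshift = if (nm == "ND3" && !is.na(cfg$nd3_frameshift))
        as.character(cfg$nd3_frameshift) else "",
      stringsAsFactors = FALSE)
    prev <- nm
  }
  feats <- do.call(rbind, rows)

  genome <- mito_genome(genome_str, id = sprintf("synthetic_%d", cfg$seed),
                        accession = sprintf("SYN%06d", cfg$seed))
  annotation <- mito_annotation(feats, genome_id = genome$id)

  truth$pcg <- cfg$pcg
  truth$overlaps <- cfg$overlaps
  truth$spacers <- cfg$spacers
  truth$genome_length <- genome$length
  truth$trna_class <- stats::setNames(
    ifelse(names(trna_anticodons()) %in% cfg$d_armless, "D-armless",
           "cloverleaf"), names(trna_anticodons()))
  truth$trna_anticodon <- trna_anticodons()
  list(genome = genome, annotation = annotation, truth = truth)
}

# Control region: unique blocks alternating with planted exact repeats;
# block boundaries are fixed so a planted repeat cannot extend into its
# flanks.
sim_cr_seq <- function(cfg) {
  reps <- cfg$cr_repeats
  uniq <- cfg$cr_unique
  stopifnot(length(uniq) == nrow(reps) + 1L)
  # compensate the unique-block base frequencies for the planted
  # repeats, so the whole CR hits the configured composition target
  rep_nt <- paste0(mapply(function(m, cp) {
    paste0(strrep(m, floor(cp)),
           substr(m, 1L, round((cp %% 1) * nchar(m))))
  }, reps$motif, reps$copies), collapse = "")
  total <- sum(uniq) + nchar(rep_nt)
  cnt_rep <- vapply(c("A", "C", "G", "T"), function(b) {
    nchar(rep_nt) - nchar(gsub(b, "", rep_nt, fixed = TRUE))
  }, numeric(1))
  probs_cr <- pmax((cfg$comp_cr[c("A", "C", "G", "T")] * total -
                      cnt_rep) / sum(uniq), 0)
  probs_cr <- probs_cr / sum(probs_cr)
  cfg$comp_cr <- probs_cr
  pieces <- character(0)
  rep_info <- list()
  pos <- 0L
  for (i in seq_len(nrow(reps) + 1L)) {
    u <- paste0(sample_nt_exact(uniq[i], cfg$comp_cr), collapse = "")
    pieces <- c(pieces, u)
    pos <- pos + nchar(u)
    if (i <= nrow(reps)) {
      motif <- reps$motif[i]
      span <- paste0(strrep(motif, floor(reps$copies[i])),
                     substr(motif, 1L,
                            round((reps$copies[i] %% 1) * nchar(motif))))
      # break the repeat at both flanks
      last_u <- pieces[length(pieces)]
      pm <- substr(motif, nchar(motif), nchar(motif))
      if (substr(last_u, nchar(last_u), nchar(last_u)) == pm) {
        substr(last_u, nchar(last_u), nchar(last_u)) <-
          setdiff(c("G", "C", "T", "A"), pm)[1]
        pieces[length(pieces)] <- last_u
      }
      rep_info[[i]] <- data.frame(
        motif = motif, period = nchar(motif), copies = reps$copies[i],
        start = pos, end = pos + nchar(span), stringsAsFactors = FALSE)
      pieces <- c(pieces, span)
      pos <- pos + nchar(span)
    }
  }
  # fix left edges of unique blocks that follow a repeat: the char just
  # after a planted span must not continue the period-p run
  s <- paste0(pieces, collapse = "")
  for (ri in rep_info) {
    after <- ri$end + 1L
    if (after <= nchar(s)) {
      p <- ri$period
      span <- ri$end - ri$start
      cont <- substr(ri$motif, ((span - p) %% p) + 1L,
                     ((span - p) %% p) + 1L)
      if (substr(s, after, after) == cont) {
        substr(s, after, after) <- setdiff(c("G", "C", "T", "A"), cont)[1]
      }
    }
  }
  structure(s, repeats = do.call(rbind, rep_info))
}

#' Write / read a truth record
#'
#' Serializes the planted-truth list of a synthetic genome as a flat
#' key-value text file (tab-separated \code{key<TAB>value} lines;
#' data.frame entries flattened as \code{key.row.column}).
#'
#' @param truth Truth list from \code{\link{generate_mitogenome}}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_truth <- function(truth, path) {
  lines <- character(0)
  emit <- function(key, value) {
    lines <<- c(lines, paste0(key, "\t", value))
  }
  walk <- function(x, prefix) {
    if (is.data.frame(x)) {
      for (r in seq_len(nrow(x))) for (cn in names(x)) {
        emit(paste(prefix, r, cn, sep = "."), x[[cn]][r])
      }
    } else if (is.list(x)) {
      for (nm in names(x)) walk(x[[nm]], paste(prefix, nm, sep = "."))
    } else if (!is.null(names(x)) && length(x) > 1L) {
      for (nm in names(x)) emit(paste(prefix, nm, sep = "."), x[[nm]])
    } else {
      emit(prefix, paste0(x, collapse = ","))
    }
  }
  for (nm in names(truth)) walk(truth[[nm]], nm)
  writeLines(lines, path)
  invisible(path)
}

#' Evolve a codon alignment along a tree
#'
#' Simulates codon sequences down a tree by acceptance-thinning of a
#' uniform single-nucleotide proposal process: each proposal is accepted
#' with relative rate multiplied by \code{kappa} if it is a transition
#' and by \code{omega} if it is nonsynonymous (vertebrate mitochondrial
#' code); proposals creating stop codons are always rejected. Branch
#' lengths are expected proposals per nucleotide site, which equals the
#' expected substitutions per site in the neutral case
#' (\code{kappa = 1, omega = 1}).
#'
#' @param tree \code{ape::phylo} tree or Newick string; if \code{NULL} a
#'   random topology with \code{n_taxa} tips is drawn and scaled so the
#'   mean tip-to-tip path length is \code{mean_pairwise}.
#' @param n_codons Codons per sequence.
#' @param omega Nonsynonymous/synonymous acceptance ratio.
#' @param kappa Transition/transversion rate ratio.
#' @param seed Integer seed (all randomness, including the tree).
#' @param n_taxa,mean_pairwise Used only when \code{tree} is NULL.
#' @return list with \code{alignment} (named character vector, class
#'   \code{mito_alignment}) and \code{truth} (list: omega, kappa, tree
#'   as Newick, n_codons, seed).
#' @export
#' @examples
#' sim <- evolve_gene_alignment(n_codons = 30, omega = 0.2, seed = 1,
#'                              n_taxa = 4)
#' gene_kaks(sim$alignment)
evolve_gene_alignment <- function(tree = NULL, n_codons = 500L,
                                  omega = 0.2, kappa = 1, seed = 1L,
                                  n_taxa = 20L, mean_pairwise = 0.4) {
  stopifnot(n_codons >= 1L, omega >= 0, kappa > 0)
  set.seed(seed)
  if (is.null(tree)) {
    tree <- ape::rtree(n_taxa)
    d <- ape::cophenetic.phylo(tree)
    tree$edge.length <- tree$edge.length *
      (mean_pairwise / mean(d[upper.tri(d)]))
  } else if (is.character(tree)) {
    tree <- ape::read.tree(text = tree)
  }
  code <- mito_genetic_code()
  stops <- mito_stop_codons()
  nt <- c("A", "C", "G", "T")
  ts_partner <- c(A = "G", G = "A", C = "T", T = "C")
  wmax <- max(1, kappa) * max(1, omega)

  root <- sample_codons(n_codons, c(A = .25, C = .25, G = .25, T = .25))
  n_tip <- length(tree$tip.label)
  seqs <- vector("list", n_tip + tree$Nnode)
  root_node <- n_tip + 1L
  seqs[[root_node]] <- root
  # preorder edge traversal: parents are simulated before children
  ord <- ape::reorder.phylo(tree, "cladewise")
  for (k in seq_len(nrow(ord$edge))) {
    par <- ord$edge[k, 1]; chd <- ord$edge[k, 2]
    b <- ord$edge.length[k]
    cods <- seqs[[par]]
    m <- stats::rpois(1L, b * 3 * n_codons)
    for (e in seq_len(m)) {
      pos <- sample.int(3L * n_codons, 1L)
      ci <- (pos - 1L) %/% 3L + 1L
      off <- (pos - 1L) %% 3L + 1L
      cod <- cods[ci]
      cur <- substr(cod, off, off)
      tgt <- sample(setdiff(nt, cur), 1L)
      mut <- cod
      substr(mut, off, off) <- tgt
      if (mut %in% stops) next
      w <- (if (tgt == ts_partner[[cur]]) kappa else 1) *
        (if (code[[mut]] == code[[cod]]) 1 else omega)
      if (stats::runif(1L) <= w / wmax) cods[ci] <- mut
    }
    seqs[[chd]] <- cods
  }
  aln <- vapply(seq_len(n_tip), function(i) {
    paste0(seqs[[i]], collapse = "")
  }, "")
  names(aln) <- tree$tip.label
  list(alignment = structure(aln, class = "mito_alignment"),
       truth = list(omega = omega, kappa = kappa,
                    tree = ape::write.tree(tree), n_codons = n_codons,
                    seed = seed))
}

#' Generate a synthetic mitogenome cohort
#'
#' Generates \code{n} genomes sharing one ancestral configuration:
#' protein-coding gene interiors are evolved along a common random tree
#' (per-gene omega), rRNAs receive independent substitutions, tRNA
#' D-loop lengths vary per species (the locus of planted arm variation),
#' and control-region repeat copy numbers vary per species, so genome
#' sizes vary the way real cohorts vary -- through the control region.
#'
#' @param n Number of genomes (>= 2).
#' @param cfg Shared ancestral \code{\link{sim_config}}.
#' @param omega_per_gene Named numeric; omega used for each PCG
#'   (defaults to a purifying spread with ATP8 highest and COI lowest).
#' @param mean_pairwise Mean pairwise divergence of the gene trees
#'   (proposals per nucleotide site).
#' @param out_dir If non-NULL, per-species FASTA + feature tables and a
#'   truth file are written there.
#' @return list with \code{entries} (per-species
#'   \code{list(genome, annotation)}), \code{alignments} (per-gene codon
#'   alignments of the evolved interiors plus planted flanks),
#'   \code{truth}.
#' @export
generate_cohort <- function(n = 20L, cfg = sim_config(),
                            omega_per_gene = NULL,
                            mean_pairwise = 0.5, out_dir = NULL) {
  stopifnot(n >= 2L)
  set.seed(cfg$seed)
  if (is.null(omega_per_gene)) {
    omega_per_gene <- c(ND1 = 0.05, ND2 = 0.08, COI = 0.01, COII = 0.03,
                        ATP8 = 0.16, ATP6 = 0.07, COIII = 0.02,
                        ND3 = 0.08, ND4L = 0.06, ND4 = 0.07, ND5 = 0.08,
                        CYTB = 0.04, ND6 = 0.10)
  }
  anc <- generate_mitogenome(cfg)
  tree <- ape::rtree(n)
  d <- ape::cophenetic.phylo(tree)
  tree$edge.length <- tree$edge.length * (mean_pairwise /
                                            mean(d[upper.tri(d)]))
  tree$tip.label <- sprintf("sp%02d", seq_len(n))

  # evolve each PCG interior (between planted prefix and suffix)
  pcg_seqs <- list()   # gene -> named vector of full per-species genes
  alignments <- list()
  anc_ann <- as.data.frame(anc$annotation)
  for (g in cfg$pcg$gene) {
    f <- anc_ann[anc_ann$name == g, ]
    full <- extract_feature_seq(anc$genome, f)
    ins <- parse_frameshift(f$frameshift)
    core <- excise_inserts(full, ins)
    pre_len <- pcg_fixed_prefix_len(g)
    suf_len <- pcg_fixed_suffix_len(g, core)
    mid <- substr(core, pre_len + 1L, nchar(core) - suf_len)
    stopifnot(nchar(mid) %% 3L == 0L)
    sim <- evolve_codons_on_tree(codon_split(mid), tree,
                                 omega_per_gene[[g]],
                                 seed = cfg$seed + match(g, cfg$pcg$gene))
    pre <- substr(core, 1L, pre_len)
    suf <- substr(core, nchar(core) - suf_len + 1L, nchar(core))
    genes <- vapply(sim, function(s) paste0(pre, s, suf), "")
    # alignments carry whole codons only: incomplete stop tails (1-2 nt)
    # are not alignable codon columns
    aln_suf <- if (suf_len %% 3L == 0L) suf else ""
    alignments[[g]] <- structure(
      vapply(sim, function(s) paste0(pre, s, aln_suf), ""),
      class = "mito_alignment")
    if (length(ins)) {
      genes <- vapply(genes, function(s) {
        paste0(substr(s, 1L, ins - 1L), "C", substr(s, ins, nchar(s)))
      }, "")
    }
    pcg_seqs[[g]] <- genes
  }

  entries <- vector("list", n)
  sizes <- integer(n)
  for (i in seq_len(n)) {
    sp_cfg <- cfg
    sp_cfg$seed <- cfg$seed + 1000L + i
    # per-species variation: D-loop lengths, CR copy numbers
    set.seed(sp_cfg$seed)
    sp_cfg$trna_d_loop <- sample(6:11, 1L)
    reps <- cfg$cr_repeats
    reps$copies <- pmax(2, reps$copies + sample(-2:3, nrow(reps), TRUE))
    sp_cfg$cr_repeats <- reps
    sim <- generate_mitogenome(sp_cfg)
    # splice the evolved PCGs of this species into its genome
    sim <- splice_pcgs(sim, lapply(pcg_seqs, `[[`, i), cfg)
    sim$genome$id <- tree$tip.label[i]
    sim$genome$accession <- sprintf("SYN%05d", i)
    attr(sim$annotation, "genome_id") <- sim$genome$id
    entries[[i]] <- list(genome = sim$genome,
                         annotation = sim$annotation,
                         truth = sim$truth)
    sizes[i] <- sim$genome$length
  }

  truth <- list(tree = ape::write.tree(tree),
                omega_per_gene = omega_per_gene, sizes = sizes,
                ancestor = anc$truth)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (e in entries) {
      base <- file.path(out_dir, e$genome$id)
      write_genome(e$genome, e$annotation, paste0(base, ".fasta"),
                   paste0(base, ".features.tsv"))
    }
    for (g in names(alignments)) {
      ss <- Biostrings::DNAStringSet(unclass(alignments[[g]]))
      Biostrings::writeXStringSet(ss, file.path(out_dir,
                                                paste0(g, ".aln.fasta")))
    }
    write_truth(truth, file.path(out_dir, "truth.tsv"))
  }
  list(entries = entries, alignments = alignments, truth = truth)
}

# length of the overlap-forced prefix (incl. start codon) of a PCG
pcg_fixed_prefix_len <- function(gene) {
  switch(gene, ATP6 = 12L, ND4 = 9L, 3L)
}

# length of the fixed tail: forced overlap suffixes, else the stop
pcg_fixed_suffix_len <- function(gene, core) {
  fixed <- switch(gene, ATP8 = 12L, ND4L = 9L, COI = 9L, NULL)
  if (!is.null(fixed)) return(fixed)
  rem <- nchar(core) %% 3L
  if (rem > 0L) rem else 3L
}

# Evolve a codon vector along a fixed tree; returns per-tip full strings.
evolve_codons_on_tree <- function(root_codons, tree, omega, seed,
                                  kappa = 1) {
  set.seed(seed)
  code <- mito_genetic_code()
  stops <- mito_stop_codons()
  nt <- c("A", "C", "G", "T")
  ts_partner <- c(A = "G", G = "A", C = "T", T = "C")
  wmax <- max(1, kappa) * max(1, omega)
  n_codons <- length(root_codons)
  n_tip <- length(tree$tip.label)
  seqs <- vector("list", n_tip + tree$Nnode)
  seqs[[n_tip + 1L]] <- root_codons
  ord <- ape::reorder.phylo(tree, "cladewise")
  for (k in seq_len(nrow(ord$edge))) {
    par <- ord$edge[k, 1]; chd <- ord$edge[k, 2]
    cods <- seqs[[par]]
    m <- stats::rpois(1L, ord$edge.length[k] * 3 * n_codons)
    for (e in seq_len(m)) {
      pos <- sample.int(3L * n_codons, 1L)
      ci <- (pos - 1L) %/% 3L + 1L
      off <- (pos - 1L) %% 3L + 1L
      cod <- cods[ci]
      cur <- substr(cod, off, off)
      tgt <- sample(setdiff(nt, cur), 1L)
      mut <- cod
      substr(mut, off, off) <- tgt
      if (mut %in% stops) next
      w <- (if (tgt == ts_partner[[cur]]) kappa else 1) *
        (if (code[[mut]] == code[[cod]]) 1 else omega)
      if (stats::runif(1L) <= w / wmax) cods[ci] <- mut
    }
    seqs[[chd]] <- cods
  }
  out <- lapply(seq_len(n_tip), function(i) paste0(seqs[[i]],
                                                   collapse = ""))
  names(out) <- tree$tip.label
  out
}

# Replace the PCG spans of a freshly generated genome with the evolved
# per-species gene sequences (same lengths, so coordinates are stable).
splice_pcgs <- function(sim, gene_seqs, cfg) {
  g <- sim$genome$sequence
  ann <- as.data.frame(sim$annotation)
  for (nm in names(gene_seqs)) {
    f <- ann[ann$name == nm, ]
    s <- gene_seqs[[nm]]
    ref <- if (f$strand == "L") revcomp(s) else s
    stopifnot(nchar(ref) == f$end - f$start)
    substr(g, f$start + 1L, f$end) <- ref
  }
  sim$genome$sequence <- g
  sim$genome$length <- nchar(g)
  sim
}
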