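test_that("generation is deterministic given the seed", {
  a <- generate_mitogenome(sim_config(seed = 9))
  b <- generate_mitogenome(sim_config(seed = 9))
  expect_identical(a$genome$sequence, b$genome$sequence)
  expect_identical(as.data.frame(a$annotation),
                   as.data.frame(b$annotation))
  c <- generate_mitogenome(sim_config(seed = 10))
  expect_false(identical(a$genome$sequence, c$genome$sequence))
})

test_that("generated genomes honor gene order, strands and layout", {
  sim <- fixture_sim()
  ann <- as.data.frame(sim$annotation)
  expect_equal(nrow(ann), 38L)
  expect_equal(ann$name, avian_gene_order()$name)
  expect_equal(ann$strand, avian_gene_order()$strand)
  expect_equal(ann$strand[ann$name == "ND6"], "L")
  expect_equal(sum(ann$strand == "L" & ann$kind == "tRNA"), 8L)
  lay <- gene_layout(sim$annotation, sim$genome)
  expect_equal(lay$n_overlaps, 10L)
  expect_equal(lay$total_overlap_bp, 35L)
  expect_equal(lay$n_spacers, 17L)
  expect_equal(lay$total_spacer_bp, 69L)
  # the largest overlap is the ATP8/ATP6 pair
  adj <- lay$adjacencies
  expect_equal(adj$gap[adj$upstream == "ATP8" & adj$downstream == "ATP6"],
               -10L)
  expect_equal(min(adj$gap), -10L)
})

test_that("overlapping features genuinely share sequence", {
  sim <- fixture_sim()
  ann <- as.data.frame(sim$annotation)
  atp8 <- ann[ann$name == "ATP8", ]
  atp6 <- ann[ann$name == "ATP6", ]
  expect_equal(atp8$end - atp6$start, 10L)
  shared <- substr(sim$genome$sequence, atp6$start + 1, atp8$end)
  expect_equal(nchar(shared), 10L)
  expect_equal(substr(extract_feature_seq(sim$genome, atp6), 1, 10),
               shared)
  expect_equal(substr(extract_feature_seq(sim$genome, atp8), 159, 168),
               shared)
})

test_that("region composition hits its targets within 1.5 points", {
  sim <- fixture_sim()
  cfg <- sim_config(seed = 42)
  ann <- as.data.frame(sim$annotation)
  for (rg in c("12S", "16S", "CR")) {
    f <- ann[ann$name == rg, ]
    cmp <- base_composition(extract_feature_seq(sim$genome, f))
    target <- if (rg == "CR") cfg$comp_cr else cfg$comp_coding
    expect_lt(abs(cmp$pct_A - 100 * target[["A"]]), 1.5, label = rg)
    expect_lt(abs(cmp$pct_T - 100 * target[["T"]]), 1.5, label = rg)
    expect_lt(abs(cmp$pct_G - 100 * target[["G"]]), 1.5, label = rg)
  }
})

test_that("planted CR repeats are recovered by the repeat finder", {
  sim <- fixture_sim()
  ann <- as.data.frame(sim$annotation)
  cr <- extract_feature_seq(sim$genome, ann[ann$name == "CR", ])
  reps <- find_tandem_repeats(cr)
  truth <- sim$truth$cr_repeats
  for (i in seq_len(nrow(truth))) {
    hit <- reps[reps$start == truth$start[i], ]
    expect_equal(nrow(hit), 1L)
    expect_equal(hit$motif, truth$motif[i])
    expect_equal(hit$copies, truth$copies[i])
  }
})

test_that("the evolver honors its limit cases and determinism", {
  tr <- ape::read.tree(text = "((a:0,b:0):0,(c:0,d:0):0);")
  sim <- evolve_gene_alignment(tree = tr, n_codons = 50, omega = 0.5,
                               seed = 3)
  aln <- unclass(sim$alignment)
  expect_equal(length(unique(aln)), 1L)
  expect_equal(p_distance(sim$alignment)$average, 0)
  s1 <- evolve_gene_alignment(n_codons = 60, omega = 0.3, seed = 5,
                              n_taxa = 5)
  s2 <- evolve_gene_alignment(n_codons = 60, omega = 0.3, seed = 5,
                              n_taxa = 5)
  expect_identical(unclass(s1$alignment), unclass(s2$alignment))
  expect_error(evolve_gene_alignment(n_codons = 0, seed = 1), "n_codons")
  # evolved sequences never contain stop codons
  s3 <- evolve_gene_alignment(n_codons = 100, omega = 1, seed = 7,
                              n_taxa = 6)
  for (s in unclass(s3$alignment)) {
    cods <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    expect_false(any(cods %in% mito_stop_codons()))
  }
})

test_that("cohort generation is self-consistent with its truth record", {
  coh <- fixture_cohort(n = 6)
  expect_length(coh$entries, 6L)
  sizes <- vapply(coh$entries, function(e) e$genome$length, 0L)
  expect_equal(sizes, coh$truth$sizes)
  cs <- cohort_summary(sizes)
  expect_equal(cs$mean, mean(sizes))
  # planted skew signs: positive AT skew, negative GC skew genome-wide
  for (e in coh$entries) {
    sk <- skews(base_composition(e$genome$sequence))
    expect_gt(sk$at_skew, 0)
    expect_lt(sk$gc_skew, 0)
  }
  # per-gene alignments have one row per species, equal lengths
  expect_setequal(names(coh$alignments), sim_config()$pcg$gene)
  for (g in names(coh$alignments)) {
    aln <- unclass(coh$alignments[[g]])
    expect_length(aln, 6L)
    expect_equal(length(unique(nchar(aln))), 1L)
  }
})

test_that("cohort files round-trip losslessly", {
  out <- withr::local_tempdir()
  coh <- generate_cohort(n = 3, cfg = sim_config(seed = 8),
                         out_dir = out)
  expect_true(file.exists(file.path(out, "truth.tsv")))
  e <- coh$entries[[1]]
  back <- load_genome(file.path(out, paste0(e$genome$id, ".fasta")),
                      file.path(out, paste0(e$genome$id,
                                            ".features.tsv")))
  expect_equal(back$genome$sequence, e$genome$sequence)
  expect_equal(as.data.frame(back$annotation)$start,
               as.data.frame(e$annotation)$start)
})

test_that("infeasible overlap configurations are rejected", {
  cfg <- sim_config(seed = 2)
  cfg$overlaps$bp[cfg$overlaps$downstream == "tRNA-Met"] <- 500L
  expect_error(generate_mitogenome(cfg), "overlap longer than gene")
})
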