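test_that("GenBank parsing converts coordinates, strands and names", {
  rec <- parse_genbank_record(genbank_fixture())
  expect_s3_class(rec$genome, "mito_genome")
  expect_equal(rec$genome$length, 120L)
  expect_equal(rec$genome$accession, "TEST0001")
  ann <- as.data.frame(rec$annotation)
  # 1-based inclusive 1..30 becomes 0-based half-open (0, 30)
  nd1 <- ann[ann$name == "ND1", ]
  expect_equal(c(nd1$start, nd1$end), c(0L, 30L))
  # complement-strand tRNA mapped to strand L with canonical name
  gln <- ann[ann$name == "tRNA-Gln", ]
  expect_equal(gln$strand, "L")
  # D-loop and product labels normalized to the vocabulary
  expect_true(all(c("CR", "12S") %in% ann$name))
  expect_equal(ann$kind[ann$name == "CR"], "CR")
})

test_that("missing sequence is a hard error, unknown labels warn", {
  txt <- sub("ORIGIN[\\s\\S]*", "ORIGIN\n//\n",
             genbank_fixture(), perl = TRUE)
  expect_error(parse_genbank_record(txt), "empty sequence")
  txt2 <- sub('/gene="ND1"', '/gene="mystery"', genbank_fixture(),
              fixed = TRUE)
  expect_warning(rec <- parse_genbank_record(txt2), "unmappable")
  expect_true("mystery" %in% as.data.frame(rec$annotation)$name)
})

test_that("parse -> write -> load round-trips coordinates exactly", {
  rec <- parse_genbank_record(genbank_fixture())
  fa <- withr::local_tempfile(fileext = ".fasta")
  tab <- withr::local_tempfile(fileext = ".tsv")
  write_genome(rec$genome, rec$annotation, fa, tab)
  back <- load_genome(fa, tab)
  expect_equal(back$genome$sequence, rec$genome$sequence)
  a <- as.data.frame(rec$annotation)
  b <- as.data.frame(back$annotation)
  expect_equal(b[c("name", "start", "end", "strand")],
               a[c("name", "start", "end", "strand")])
})

test_that("feature extraction is strand- and wrap-aware", {
  g <- mito_genome("AAACCCGGGTTT")
  f_h <- list(start = 0L, end = 6L, strand = "H", wrapped = FALSE)
  expect_equal(extract_feature_seq(g, f_h), "AAACCC")
  f_l <- list(start = 0L, end = 6L, strand = "L", wrapped = FALSE)
  expect_equal(extract_feature_seq(g, f_l), "GGGTTT")
  # reverse-complement extraction is an involution composed with a
  # strand flip
  expect_equal(extract_feature_seq(g, f_l, sense = "reference"),
               extract_feature_seq(g, f_h))
  f_w <- list(start = 9L, end = 3L, strand = "H", wrapped = TRUE)
  expect_equal(extract_feature_seq(g, f_w), "TTTAAA")
  expect_equal(nchar(extract_feature_seq(g, f_w)), (12 - 9) + 3)
})

test_that("gene layout reports overlaps, spacers and the circular junction", {
  g <- mito_genome(strrep("ACGT", 25))  # 100 bp
  ann <- mito_annotation(data.frame(
    name = c("ND1", "ND2", "CR"), kind = c("PCG", "PCG", "CR"),
    start = c(0L, 5L, 40L), end = c(10L, 20L, 90L), strand = "H"))
  lay <- gene_layout(ann, g)
  expect_equal(lay$adjacencies$gap, c(-5L, 20L, 10L))
  expect_equal(lay$n_overlaps, 1L)
  expect_equal(lay$total_overlap_bp, 5L)
  expect_equal(lay$n_spacers, 2L)
  expect_equal(lay$total_spacer_bp, 30L)
})

test_that("layout gap accounting reconstructs genome length", {
  set.seed(7)
  for (rep in 1:10) {
    n_feat <- sample(5:12, 1)
    len <- 500L
    cuts <- sort(sample(1:(len - 1), 2 * n_feat))
    starts <- cuts[seq(1, 2 * n_feat, 2)]
    ends <- cuts[seq(2, 2 * n_feat, 2)]
    ann <- mito_annotation(data.frame(
      name = c(sprintf("G%02d", seq_len(n_feat - 1)), "CR"),
      kind = c(rep("PCG", n_feat - 1), "CR"),
      start = starts, end = ends, strand = "H"))
    g <- mito_genome(paste0(sample(c("A", "C", "G", "T"), len, TRUE),
                            collapse = ""))
    lay <- gene_layout(ann, g)
    covered <- sum(ends - starts)
    # non-overlapping features: spacer total + covered = genome length
    expect_equal(lay$total_overlap_bp, 0L)
    expect_equal(lay$total_spacer_bp + covered, len)
  }
})

test_that("annotation report table round-trips through the file format", {
  sim <- fixture_sim()
  tab <- write_annotation_table(sim$annotation, sim$genome)
  expect_equal(names(tab)[1:5],
               c("name", "kind", "start", "end", "strand"))
  expect_equal(nrow(tab), 38L)
  expect_equal(tab$size,
               tab$end - tab$start + 1L)
})
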