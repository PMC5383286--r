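test_that("translation follows the vertebrate mitochondrial code", {
  expect_equal(translate_mt("ATGGCTTAA"), "MA")
  expect_equal(translate_mt("TGATGA"), "WW")   # TGA is Trp, not stop
  expect_equal(translate_mt("ATAAGA"), "M")    # AGA is stop
  expect_equal(translate_mt("CATGGCA", frame_offset = 1), "MA")
})

test_that("start/stop detection handles complete and incomplete stops", {
  r <- start_stop_codons("ATGAAATAA")
  expect_equal(r$start_codon, "ATG")
  expect_equal(r$stop_codon, "TAA")
  expect_true(r$complete_stop)
  expect_true(r$standard_start)

  # length 3k+1 ending in T: incomplete stop class T--
  r2 <- start_stop_codons("ATGAAACCCT")
  expect_equal(r2$stop_codon, "T--")
  expect_false(r2$complete_stop)
  r3 <- start_stop_codons("ATGAAACCCTA")
  expect_equal(r3$stop_codon, "TA-")
  expect_false(r3$complete_stop)

  # nonstandard start flagged, not fatal
  r4 <- start_stop_codons("CCCAAATAA")
  expect_false(r4$standard_start)

  # frameshift insertion excised before framing
  s <- "ATGAAATAA"
  with_ins <- paste0(substr(s, 1, 3), "C", substr(s, 4, 9))
  r5 <- start_stop_codons(with_ins, frameshift_inserts = 4L)
  expect_equal(r5$stop_codon, "TAA")
  expect_length(r5$internal_stops, 0)
})

test_that("planted start/stop codons are recovered from a synthetic genome", {
  sim <- fixture_sim()
  ann <- as.data.frame(sim$annotation)
  pcgs <- ann[ann$kind == "PCG", ]
  for (i in seq_len(nrow(pcgs))) {
    s <- extract_feature_seq(sim$genome, pcgs[i, ])
    ins <- if (nzchar(pcgs$frameshift[i]))
      as.integer(strsplit(pcgs$frameshift[i], ",")[[1]]) else integer(0)
    r <- start_stop_codons(s, ins, gene = pcgs$name[i])
    truth <- sim$truth$pcg[sim$truth$pcg$gene == pcgs$name[i], ]
    expect_equal(r$start_codon, truth$start, label = pcgs$name[i])
    expect_equal(r$stop_codon, truth$stop, label = pcgs$name[i])
    expect_length(r$internal_stops, 0)
  }
  # ND3 translates full length (no internal stop) once the extra C is
  # excised: 117 codons including the terminal stop
  nd3 <- ann[ann$name == "ND3", ]
  excised <- mitocompare:::excise_inserts(
    extract_feature_seq(sim$genome, nd3), 174L)
  expect_equal(nchar(excised) %% 3L, 0L)
  expect_equal(nchar(translate_mt(excised)), nchar(excised) / 3 - 1)
})

test_that("usage matrix tallies match a counting oracle", {
  reports <- list(
    start_stop_codons("ATGAAATAA", gene = "ND1", species = "a"),
    start_stop_codons("ATGAAATAA", gene = "ND1", species = "b"),
    start_stop_codons("GTGAAACCCT", gene = "ND1", species = "c"),
    start_stop_codons("ATGAAATAG", gene = "ND2", species = "a")
  )
  um <- usage_matrix(reports)
  expect_equal(sum(um$starts["ND1", ]), 3)
  expect_equal(sum(um$stops["ND2", ]), 1)
  expect_equal(um$starts["ND1", "ATG"], 2)
  # T-- and TA- merge into the single incomplete class
  expect_equal(um$stops["ND1", "T-"], 1)
  expect_equal(um$atg_fraction, 100 * 3 / 4)
  # reports with internal stops are excluded with a warning
  bad <- start_stop_codons("ATGTAAAAATAA", gene = "ND1", species = "d")
  expect_warning(um2 <- usage_matrix(c(reports, list(bad))),
                 "internal stop")
  expect_equal(sum(um2$starts), 4)
})

test_that("strip_stops removes terminal stops and rejects internal ones", {
  aln <- c(a = "ATGAAATAA", b = "ATGAAGAGG")
  out <- strip_stops(aln)
  expect_equal(unname(nchar(out)), c(6L, 6L))
  expect_equal(unname(out[1]), "ATGAAA")
  # already stopless input unchanged
  expect_equal(unname(strip_stops(out)), unname(out))
  # mixed terminal column: stop replaced by gap codon
  mix <- c(a = "ATGAAATAA", b = "ATGAAGAAG")
  out2 <- strip_stops(mix)
  expect_equal(unname(out2[1]), "ATGAAA---")
  expect_error(strip_stops(c(a = "ATGTAAAAA", b = "ATGAAAAAA")),
               "internal stop.*'a'")
})
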