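test_that("site classification follows the definitions", {
  s <- classify_sites(c("AAA", "AAT", "AAT"))
  expect_equal(s$n_singleton, 1L)
  expect_equal(s$n_parsimony_informative, 0L)
  expect_equal(s$n_constant, 2L)
  s2 <- classify_sites(c("AAT", "AAT", "AAC", "AAC"))
  expect_equal(s2$n_parsimony_informative, 1L)
  expect_error(classify_sites(c("---", "---")), "excluded")
})

test_that("site classification equals the per-column brute-force oracle", {
  set.seed(19)
  for (i in 1:40) {
    nrow <- sample(3:8, 1)
    ncol <- 30
    chars <- sample(c("A", "C", "G", "T", "-", "N"), nrow * ncol, TRUE,
                    prob = c(.25, .25, .2, .2, .05, .05))
    rows <- apply(matrix(chars, nrow), 1, paste0, collapse = "")
    names(rows) <- paste0("s", seq_len(nrow))
    for (policy in c("complete", "pairwise")) {
      got <- tryCatch(classify_sites(rows, policy), error = function(e) e)
      want <- oracle_classify(rows, policy)
      if (inherits(got, "error")) {
        expect_equal(want$n_analyzed, 0)
      } else {
        expect_equal(got$n_constant, want$n_constant)
        expect_equal(got$n_singleton, want$n_singleton)
        expect_equal(got$n_parsimony_informative,
                     want$n_parsimony_informative)
        # partition invariant
        expect_equal(got$n_variable,
                     got$n_singleton + got$n_parsimony_informative)
      }
    }
  }
})

test_that("p-distance matches direct mismatch counting", {
  expect_equal(p_distance(c(a = "ACGT", b = "ACGT"))$average, 0)
  expect_equal(p_distance(c(a = "ACGT", b = "ACGA"))$average, 0.25)
  # complete vs pairwise deletion differ in compared columns
  aln <- c(a = "ACGTA", b = "AC-TA", c = "ACGTT")
  pc <- p_distance(aln, "complete")
  pp <- p_distance(aln, "pairwise")
  expect_equal(pc$matrix["a", "c"], 1 / 4)  # gap column dropped for all
  expect_equal(pp$matrix["a", "c"], 1 / 5)
  # independent check against ape's raw distance
  m <- t(vapply(strsplit(tolower(aln), ""), identity, character(5)))
  dape <- as.matrix(ape::dist.dna(ape::as.DNAbin(m), model = "raw",
                                  pairwise.deletion = TRUE))
  expect_equal(unname(pp$matrix), unname(dape), tolerance = 1e-12)
})

test_that("p-distance is a metric on gap-free alignments", {
  set.seed(23)
  for (i in 1:10) {
    rows <- vapply(1:4, function(j) random_dna(60), "")
    names(rows) <- paste0("s", 1:4)
    D <- p_distance(rows)$matrix
    expect_equal(D, t(D))
    expect_true(all(diag(D) == 0))
    for (a in 1:4) for (b in 1:4) for (cc in 1:4) {
      expect_lte(D[a, b], D[a, cc] + D[cc, b] + 1e-12)
    }
  }
})

test_that("neighbor joining recovers additive trees exactly", {
  skip_if_not_installed("phangorn")
  set.seed(29)
  for (i in 1:10) {
    n <- sample(4:8, 1)
    true <- ape::rtree(n, br = function(k) stats::runif(k, 0.05, 0.4))
    D <- ape::cophenetic.phylo(true)
    est <- nj_tree(D[sort(rownames(D)), sort(colnames(D))])
    expect_equal(phangorn::RF.dist(ape::unroot(true), est), 0)
    # branch lengths of an additive matrix are recovered too
    expect_equal(sort(ape::cophenetic.phylo(est)[rownames(D),
                                                 colnames(D)][upper.tri(D)]),
                 sort(D[upper.tri(D)]), tolerance = 1e-8)
  }
  expect_error(nj_tree(matrix(0, 2, 2)), "3 taxa")
})

test_that("distance matrices round-trip through the PHYLIP-style format", {
  pd <- p_distance(c(a = "ACGTACGT", b = "ACGAACGA", c = "TCGTACGA"))
  f <- withr::local_tempfile(fileext = ".dist")
  write_phylip_dist(pd, f)
  lines <- readLines(f)
  expect_equal(lines[1], "3")
  back <- utils::read.table(text = lines[-1], row.names = 1)
  expect_equal(unname(as.matrix(back)), unname(pd$matrix),
               tolerance = 1e-9)
})

test_that("newick output round-trips through ape", {
  tr <- ape::rtree(5)
  s <- write_newick(tr)
  expect_true(startsWith(s, "("))
  back <- ape::read.tree(text = s)
  expect_setequal(back$tip.label, tr$tip.label)
})

test_that("monophyly check agrees with exhaustive bipartition enumeration", {
  set.seed(31)
  for (i in 1:15) {
    n <- sample(5:9, 1)
    tr <- ape::unroot(ape::rtree(n))
    tips <- tr$tip.label
    # oracle: all bipartitions from ape::prop.part on the unrooted tree
    pp <- ape::prop.part(tr)
    sides <- c(lapply(pp, function(idx) sort(tips[idx])),
               as.list(tips), list(tips))
    sides <- c(sides, lapply(sides, function(s) sort(setdiff(tips, s))))
    sides <- Filter(length, sides)
    key <- unique(vapply(sides, paste, "", collapse = "|"))
    lab <- sample(tips, sample(1:n, 1))
    want <- paste(sort(lab), collapse = "|") %in% key
    expect_equal(check_monophyly(tr, lab), want)
  }
  tr <- ape::rtree(4)
  expect_true(check_monophyly(tr, tr$tip.label))
  expect_true(check_monophyly(tr, tr$tip.label[1]))
  expect_error(check_monophyly(tr, "absent_taxon"), "not in tree")
})
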