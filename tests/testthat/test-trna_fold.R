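# A hand-built 72-nt tRNA with perfect G:C stems and A-rich loops.
# The D stem uses the maximum admissible length (4 bp) so no partition
# can match the planted score by absorbing a free end mismatch.
# Layout: acceptor(7) link(2) D5(4) Dloop(8) D3(4) link(1) AC5(5)
# ACloop(7, anticodon GAA at 3-5) AC3(5) var(4) T5(5) Tloop(7) T3(5)
# acceptor3(7) discriminator(1).
designed_trna <- function() {
  paste0("GGCGGCG", "AA", "GGCC", "AAAAAAAA", "GGCC", "A",
         "GCGCG", "AAGAAAA", "CGCGC", "AAAA",
         "GGCGC", "AAAAAAA", "GCGCC", "CGCCGCC", "A")
}
designed_score <- 7 * 3 + 4 * 3 + 5 * 3 + 5 * 3  # all G:C pairs

test_that("a designed perfect cloverleaf is recovered exactly", {
  st <- fold_trna(designed_trna())
  expect_equal(st$model, "cloverleaf")
  expect_equal(st$score, designed_score)
  expect_equal(st$arms$d_loop, c(14L, 21L))
  expect_equal(st$arms$ac_loop, c(32L, 38L))
  expect_equal(st$anticodon, "GAA")
  # dot-bracket is balanced and consistent with 21 pairs
  db <- strsplit(st$dotbracket, "")[[1]]
  expect_equal(sum(db == "("), sum(db == ")"))
  expect_equal(sum(db == "("), 7 + 4 + 5 + 5)
  depth <- cumsum((db == "(") - (db == ")"))
  expect_true(all(depth >= 0))
})

test_that("folding is deterministic and bounded by length limits", {
  s <- designed_trna()
  expect_identical(fold_trna(s), fold_trna(s))
  expect_error(fold_trna(random_dna(40)), "55-95")
})

test_that("the D-armless model wins only for D-armless sequences", {
  ser <- mitocompare:::design_trna("tRNA-Ser(AGY)", d_armless = TRUE)
  st <- fold_trna(ser)
  expect_equal(st$model, "D-armless")
  st2 <- fold_trna(designed_trna())
  expect_equal(st2$model, "cloverleaf")
  # without the D-armless model the serine tRNA may still fold, but
  # competition is restricted to cloverleaf partitions
  st3 <- fold_trna(ser, allow_no_D = FALSE)
  expect_true(st3$model %in% c("cloverleaf", "unfoldable"))
})

test_that("fold search equals exhaustive partition enumeration", {
  set.seed(59)
  cases <- list(designed_trna())
  for (i in 1:8) cases[[length(cases) + 1]] <- random_dna(sample(60:75, 1))
  for (nm in c("tRNA-Phe", "tRNA-Lys")) {
    cases[[length(cases) + 1]] <- mitocompare:::design_trna(nm)
  }
  for (s in cases) {
    got <- fold_trna(s)
    want <- oracle_fold(s)
    if (is.null(want)) {
      expect_equal(got$model, "unfoldable")
    } else {
      expect_equal(got$score, want$score, label = s)
      expect_equal(got$model, want$model, label = s)
    }
  }
})

test_that("anticodon identity check distinguishes isoacceptor classes", {
  phe <- fold_trna(mitocompare:::design_trna("tRNA-Phe"))
  expect_true(anticodon_check(phe, "tRNA-Phe"))
  expect_false(anticodon_check(phe, "tRNA-Val"))
  ser1 <- fold_trna(mitocompare:::design_trna("tRNA-Ser(AGY)",
                                              d_armless = TRUE))
  expect_true(anticodon_check(ser1, "tRNA-Ser(AGY)"))
  expect_false(anticodon_check(ser1, "tRNA-Ser(UCN)"))
  # all 22 canonical names are accepted by the name -> family map
  for (nm in names(mitocompare:::trna_name_aa())) {
    expect_silent(anticodon_check(phe, nm))
  }
  expect_error(anticodon_check(phe, "tRNA-Xyz"), "unknown")
})

test_that("cohort report recovers planted classes and planted D-loop variation", {
  coh <- fixture_cohort(n = 4)
  rep <- cohort_fold_report(coh$entries)
  expect_equal(nrow(rep), 4 * 22)
  ser <- rep[rep$trna == "tRNA-Ser(AGY)", ]
  expect_true(all(ser$class == "D-armless"))
  other <- rep[rep$trna != "tRNA-Ser(AGY)", ]
  expect_true(all(other$class == "cloverleaf"))
  expect_true(all(rep$anticodon_ok))
  # variation was planted in D-loop lengths, anticodon loop is fixed
  dvar <- stats::var(other$d_loop_len)
  avar <- stats::var(other$ac_loop_len)
  expect_gt(dvar, avar)
})
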