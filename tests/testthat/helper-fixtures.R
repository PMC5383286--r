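# Shared fixtures, built in code. Expensive simulations are cached per
# test run.

.fixtures <- new.env(parent = emptyenv())

fixture_sim <- function(seed = 42) {
  key <- paste0("sim", seed)
  if (is.null(.fixtures[[key]])) {
    .fixtures[[key]] <- generate_mitogenome(sim_config(seed = seed))
  }
  .fixtures[[key]]
}

fixture_cohort <- function(n = 6, seed = 42) {
  key <- paste0("cohort", n, "_", seed)
  if (is.null(.fixtures[[key]])) {
    .fixtures[[key]] <- generate_cohort(n = n,
                                        cfg = sim_config(seed = seed))
  }
  .fixtures[[key]]
}

# a small hand-written GenBank record: 3 features incl. a complement
# strand CDS and a D-loop, 120 bp
genbank_fixture <- function() {
  seq <- paste0(
    "ATGAAACCCGGGTTTACGTAGCTAGCTAGGCTAAACCTTGGAACCGGTTAAACGTACGTA",
    "CCGGAATTCCGGAATTCAGGTACCGATCGATCGATTAAGCCTTAGGCTTAAGGCCTTAAA")
  chunks <- substring(seq, seq(1, 120, 60), pmin(seq(1, 120, 60) + 59, 120))
  ori <- paste(vapply(seq_along(chunks), function(i) {
    sprintf("%9d %s", (i - 1) * 60 + 1,
            paste(substring(chunks[i], seq(1, 60, 10),
                            seq(10, 60, 10)), collapse = " "))
  }, ""), collapse = "\n")
  paste0(
    "LOCUS       TEST0001   120 bp    DNA     circular VRT 01-JAN-2017\n",
    "ACCESSION   TEST0001\n",
    "  ORGANISM  Testus fixturus\n",
    "FEATURES             Location/Qualifiers\n",
    "     CDS             1..30\n",
    "                     /gene=\"ND1\"\n",
    "     tRNA            complement(31..52)\n",
    "                     /product=\"tRNA-Gln\"\n",
    "     rRNA            53..80\n",
    "                     /product=\"12S ribosomal RNA\"\n",
    "     D-loop          81..120\n",
    "ORIGIN\n", tolower(ori), "\n//\n")
}
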