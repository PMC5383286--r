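# mitocompare

Comparative mitochondrial genomics for bird mitogenome cohorts, built
around shorebird (Charadriiformes) data: ~16.7-kb circular genomes
with the conserved avian arrangement of 13 protein-coding genes
(PCGs), 22 tRNAs, two rRNAs and a control region (CR), with ND6 and
eight tRNAs on the light strand. The package is aimed at researchers
characterizing a newly sequenced mitogenome against a cohort of
published relatives.

## What it computes

* **Genome organization** — gene overlaps and intergenic spacers on
  the circular molecule, including the origin-spanning junction.
* **Composition** — per-region base composition, AT content and the
  strand-asymmetry statistics
  `AT skew = (A − T)/(A + T)`, `GC skew = (G − C)/(G + C)`,
  with cohort summaries using the population SD (divisor *n*).
* **Codon usage** — start/stop codons under the vertebrate
  mitochondrial code (AGA/AGG stops, TGA = Trp, ATA = Met), including
  incomplete `T--`/`TA-` stops and annotated frameshift insertions
  such as the extra C at ND3 position 174.
* **Site variation and distances** — variable / parsimony-informative
  / singleton site classification, uncorrected p-distances,
  neighbor-joining trees and monophyly checks.
* **Selection** — pairwise Nei–Gojobori (NG86) Ka/Ks with equal-weight
  pathway averaging and Jukes–Cantor correction; per-gene
  ω = mean(dN)/mean(dS).
* **Control-region repeats** — exact tandem-repeat detection with
  greedy overlap resolution, CR block architecture, and cohort motif
  prevalence under least-rotation canonicalization.
* **tRNA structure** — constrained cloverleaf folding (acceptor 7 bp,
  D stem 3–4 bp, anticodon stem 5 bp, T stem 4–5 bp; pair scores
  G:C = 3, A:T = 2, G:U = 1, ≤1 mismatch per stem) with a competing
  D-armless model for tRNA-Ser(AGY).
* **Synthetic cohorts** — a generator that plants gene order,
  overlaps (as genuinely shared sequence), start/stop codons,
  composition targets, CR repeats and tRNA structures, plus a
  codon-level evolver with per-gene ω, so every stage is validated
  against known truth.

Inputs are GenBank flat files or FASTA plus a tab-separated feature
table (`name, kind, start, end, strand`, 1-based inclusive); outputs
are tab-separated report tables. A subcommand CLI wrapping the same
functions ships in `inst/cli/mitocompare`.

## A worked example

```r
library(mitocompare)

coh <- generate_cohort(n = 10, cfg = sim_config(seed = 1))
cmd_layout(coh$entries[[1]])$layout
#> layout: 10 overlaps (35 bp), 17 spacers (69 bp)

gen <- cmd_genes(coh$alignments)
gen[gen$gene %in% c("ATP8", "COI"), c("gene", "avg_p_distance", "omega")]
#>   gene avg_p_distance      omega
#> 3  COI     0.08314671 0.01065869
#> 5 ATP8     0.13373737 0.19343138
```

The layout line reports the planted organization: ten gene overlaps
totalling 35 bp (the largest between ATP8 and ATP6) and seventeen
spacers totalling 69 bp. In the gene table, ATP8 shows the fastest
evolution and weakest purifying selection (highest average p-distance
and ω) and COI the strongest constraint (ω near 0.01) — the pattern
the generator plants and that real shorebird cohorts show. All ω
values stay well below 1, the purifying-selection regime expected for
mitochondrial PCGs.

```r
head(cmd_cr(coh$entries)$prevalence, 3)
#>   canonical_motif n_species
#> 1            AAAC        10
#> 2         AAACAAC        10
#> 3            ACTT         3
```

Both planted CR motifs are recovered in every genome, alongside the
short incidental repeats any AT-rich sequence contains.

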