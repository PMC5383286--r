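---
title: "Comparative mitogenomics with mitocompare: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative mitogenomics with mitocompare}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitocompare)
```

## The analysis

`mitocompare` implements the standard comparative workflow for a cohort
of annotated vertebrate mitochondrial genomes, built around shorebird
(Charadriiformes) cohorts of roughly twenty ~16.7-kb circular genomes
carrying the conserved avian arrangement of 13 protein-coding genes
(PCGs), 22 tRNAs, two rRNAs and one control region (CR). ND6 and eight
tRNAs lie on the light strand; everything else on the heavy strand.
The stages are:

1. **Genome organization** — adjacent-feature gaps on the circular
   molecule: negative gaps are gene overlaps, positive gaps intergenic
   spacers. The circular junction (last feature back to the first) is
   included, because the CR-to-tRNA-Phe junction is a real adjacency of
   the molecule. Gap arithmetic is strand-agnostic on reference
   coordinates, since overlapping neighbours frequently sit on opposite
   strands.
2. **Composition and skews** — per region and per genome,
   $\mathrm{AT\,skew} = (A-T)/(A+T)$ and
   $\mathrm{GC\,skew} = (G-C)/(G+C)$. Both negate under reverse
   complement, which is the package's central composition invariant and
   a property test. PCGs are profiled on their coding strand by default
   (so ND6 is reported in coding sense); a `sense = "reference"` switch
   reports every region on the heavy strand instead, since either
   convention appears in the literature.
3. **Codon usage** — start/stop detection under the vertebrate
   mitochondrial code (AGA/AGG are stops, TGA is Trp, ATA is Met).
   Genes whose length is $3k+1$ or $3k+2$ after excising annotated
   single-nucleotide insertions are classified as incomplete stops
   (`T--`, `TA-`), completed in vivo by polyadenylation; summaries
   merge both into one `T-` class. Genes with internal stops in the
   annotated frame are excluded from usage tallies with a warning
   rather than silently reframed.
4. **Site variation and distances** — variable / parsimony-informative
   / singleton classification and uncorrected p-distances. The default
   deletion policy is *complete* (columns containing any gap or N are
   dropped), matching the convention of concatenated-PCG analyses that
   report post-indel lengths; *pairwise* deletion is available.
   Percentages are always relative to analyzed (post-deletion) columns.
5. **Selection** — pairwise Nei–Gojobori (1986) counting: potential
   synonymous/nonsynonymous sites per codon (stop-destined changes
   excluded, sites renormalized to 3), observed differences averaged
   with equal weights over all mutational pathways that avoid stops,
   Jukes–Cantor correction $d = -\tfrac34\ln(1-\tfrac43 p)$. The
   gene-level $\omega$ is a **ratio of means** (mean pairwise dN over
   mean pairwise dS), not a mean of ratios: many pairwise dS values in
   a closely related cohort are near zero, and the ratio of means is
   the stable counting-style estimate.
6. **Control-region repeats** — exact tandem repeats only. The motifs
   of interest (e.g. `AAAC`, `AAACAAC`) are short and exact, and
   exactness admits an unambiguous cubic brute-force oracle; this is a
   deliberate divergence from mismatch-tolerant, alignment-scored
   repeat finders, whose inventories depend on scoring parameters.
   Homopolymer runs are excluded by the default `min_period = 2`;
   overlapping calls are resolved greedily (longest span, then smallest
   period, then leftmost). Motifs are canonicalized to their least
   rotation so phase-shifted tallies merge across species.
7. **tRNA folding** — a constrained cloverleaf search rather than
   thermodynamic folding: acceptor stem fixed at 7 bp with one unpaired
   discriminator at the 3' end (the CCA tail is not genome-encoded),
   D stem 3–4 bp with a 4–12-nt loop, anticodon stem 5 bp with a 7-nt
   loop, 3–23-nt variable region, T stem 4–5 bp with a 5–9-nt loop.
   Pair scores G:C = 3, A:T = 2, G:U = 1, at most one mismatch per stem
   (scored 0): integer granularity keeps the exhaustive-enumeration
   oracle exact. A D-armless model (mitochondrial tRNA-Ser(AGY))
   competes when allowed and wins only on strictly higher score; ties
   prefer the canonical cloverleaf, then the smaller D-loop, in a fixed
   enumeration order, so folding is deterministic.
8. **Tree plumbing** — neighbor joining on p-distance matrices
   (delegated to `ape::nj`) plus an exact bipartition-based monophyly
   check. This is deliberately *qualitative* plumbing: likelihood and
   Bayesian inference, partitioning and model selection are out of
   scope, and topology claims are limited to clade membership, for
   which NJ on additive-enough distances is adequate.

## Coordinate and I/O conventions

Internally every feature is 0-based half-open on the reference (heavy)
strand; all file I/O (GenBank flat files, feature tables, reports) is
1-based inclusive. Features spanning the origin are marked wrapped and
concatenate their two arcs on extraction. Unknown bases (N) are
permitted: they count toward region totals but are excluded from skew
denominators and percentage numerators.

## The synthetic cohort generator

Every analysis stage is exercised against genomes with *planted truth*:

* **Gene order and strands** follow the avian arrangement exactly.
* **Overlaps are realized as genuinely shared sequence.** The shared
  region of each PCG/PCG overlap is written once and satisfies both
  reading frames by construction: the 10-bp ATP8/ATP6 overlap region
  is `ATGCAACTAA`, which begins with ATP6's ATG and ends (in ATP8's
  frame) with ATP8's TAA; analogous constructions cover ND4L/ND4 (7 bp)
  and COI/tRNA-Ser(UCN) (9 bp, where the tRNA's forced acceptor-side
  tail reverse-complements to COI's final codons). Two-nucleotide
  guard positions adjacent to forced regions are resampled until no
  internal stop arises. One-to-two-nucleotide tRNA/tRNA overlaps cost
  at most one acceptor-stem pairing, which the folding model's
  one-mismatch budget absorbs. Where constraints conflict, the
  downstream feature's sequence takes precedence.
* **Composition targets are hit exactly**, not in expectation: regions
  are filled from shuffled base pools with largest-remainder rounded
  counts (stop codons arising in PCG pools are repaired by
  composition-preserving swaps), so any region of at least 300 bp lands
  within ±1.5 percentage points of its target with margin to spare. The
  default targets are the observed cohort means of published shorebird
  mitogenomes (A 31.2%, C 30.6%, G 13.8%, T 24.4%; the CR more AT-rich),
  which also fixes the planted skew signs (positive AT, negative GC).
* **CR repeats** are planted between unique blocks whose boundary
  bases are adjusted so a planted run can neither extend into its
  flanks nor merge with a neighbour; the unique-block base pool is
  compensated for the repeats' composition so the whole CR still meets
  its target.
* **tRNAs are designed from their planted structures**: GC-biased
  perfect stems, low-GC loops, the standard anticodon for each
  identity, and a D-armless design for tRNA-Ser(AGY).
* **Codon evolution** is acceptance-thinning of a uniform
  single-nucleotide proposal process along a tree: a proposal is
  accepted with relative rate $\times\,\kappa$ if it is a transition
  and $\times\,\omega$ if nonsynonymous; proposals creating stops are
  always rejected. Branch lengths are expected *proposals* per
  nucleotide site, which equals expected substitutions per site in the
  neutral case. This gives exact stop avoidance and transparent
  $\omega$ semantics at desk scale, at the cost of not being a
  rate-matrix simulator.

### Why the generator's default `kappa` is 1

The estimator is classic equal-weight NG86, which assumes all point
mutations equally likely. Setting the generator's transition bias to 1
by default makes the recovery experiments a test of the *counting
machinery* rather than of model mismatch. With `kappa > 1` (realistic
mitochondrial values are 5–10), NG86 is known to understate potential
synonymous sites and hence overstate dS, biasing $\omega$ downward;
users can set `kappa` to explore exactly that bias, and should treat
absolute $\omega$ values from NG86 under strong transition bias as
conservative.

### Study-scale defaults

The default single-genome configuration reproduces the organization
statistics of a typical shorebird mitogenome: ten overlaps totalling
35 bp (maximum 10 bp at ATP8/ATP6), seventeen spacers totalling 69 bp,
GTG starts in COI and ND5, ATT in ND3, incomplete `T--` stops in COIII
and ND4, the single-C frameshift insertion at ND3 position 174, and a
CR carrying `AAACAAC` and `AAAC` tandem arrays. Cohorts share one
ancestral configuration and diverge through PCG interiors evolved
along a common random tree (default mean tip-to-tip divergence 0.5
proposals per site, which yields cohort-like p-distances of roughly
0.1–0.15 after purifying thinning), per-species D-loop lengths
(6–11 nt — the planted locus of tRNA arm variation), and per-species
CR repeat copy numbers, so genome size varies through the CR as it
does in real cohorts.

### What the generator does not emulate

Independent per-region pools mean no dinucleotide structure, no
among-site rate heterogeneity, no indel evolution, no rearrangements,
and rRNA/CR-unique sequence is drawn independently per species rather
than evolved (alignment-based stages consume the evolved PCG
alignments). Passing recovery tests therefore demonstrates that each
stage measures what was planted under the stated generative model —
not that the model captures every feature of real mitogenomes.

## Numerical choices and degenerate inputs

* Population SD (divisor $n$) throughout cohort summaries: the
  published size spread of the reference cohort (SD 179.66 around a
  16,807-bp mean, $n = 20$) reproduces exactly under divisor $n$ and
  not under $n-1$.
* Zero skew denominators, pairs with no comparable sites, and
  $p \ge 0.75$ in the Jukes–Cantor correction all yield missing values
  (never exceptions); all-pathways-through-stops codon pairs are
  skipped; unfoldable tRNAs return an explicit `unfoldable` result.
* With $\omega = 0$ the estimated Ka is *nearly* but not exactly zero:
  equal-weight pathway averaging can attribute small fractional
  nonsynonymous counts to multi-hit codons whose true history was
  purely synonymous. Tests assert Ka below $10^{-3}$, not zero.
* Table output is rounded to 2 decimals (the granularity of published
  composition tables); internal values keep full precision, and every
  report writer takes `digits = NA` for full-precision output.
* All simulation entry points take integer seeds and are byte-identical
  under repetition; derived seeds stay within 32-bit range.

## Problem sizes used in validation

Oracle-equivalence checks run NG86 against exhaustive pathway
enumeration on 200 random 30-codon pairs, site classification against
a per-column census on 200 random alignments, repeat detection against
a cubic enumerator on 300-bp strings, folding against full partition
enumeration on sequences up to 75 nt, and NJ against 50 random
additive trees. Selection recovery uses 20 taxa × 500 codons over 20
seeds per $\omega \in \{0.05, 0.2, 1.0\}$, asserting medians within
±30% and rank-order recovery in at least 95% of seed sets. These sizes
were chosen so the full validation runs comfortably on a laptop while
keeping every stochastic assertion far from its noise floor.

## Known limitations

* NG86 is a pairwise counting method; the per-gene $\omega$ it yields
  approximates, but does not reproduce, codon-model or tree-aware
  (e.g. counting-on-a-phylogeny) estimates. Ordering across genes is
  the robust output; absolute values carry the NG86 caveats above.
* The exact-repeat detector will fragment a degenerate tandem array
  that a mismatch-tolerant finder would report as one unit; prevalence
  *ordering* across motifs, not the total motif count, is the stable
  cohort statistic.
* The cloverleaf search scores base pairs, not stacking energies; it
  classifies arm architecture reliably (cloverleaf vs D-armless) but
  is not a substitute for thermodynamic structure prediction.
* GenBank parsing covers the feature types and location forms that
  occur in mitogenome records (`CDS`, `tRNA`, `rRNA`, `D-loop`,
  complement and origin-spanning joins); it is not a general-purpose
  flat-file parser.

## A worked example

```{r example, eval = FALSE}
library(mitocompare)

# a synthetic cohort with known truth
coh <- generate_cohort(n = 10, cfg = sim_config(seed = 1))

# organization of the first genome
cmd_layout(coh$entries[[1]])$layout

# cohort composition and skews
comp <- cmd_composition(coh$entries)
head(comp$genomes)

# per-gene variation, distances, selection
cmd_genes(coh$alignments)

# control-region repeat architecture and motif prevalence
cmd_cr(coh$entries)$prevalence

# tRNA structural classes
table(cmd_trna(coh$entries)$class)
```
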