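---
title: "Duplication-centred analysis of the soybean Cupin gene family"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Duplication-centred analysis of the soybean Cupin gene family}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cupinfam)
```

## Scope and data model

`cupinfam` analyses the evolution of a plant gene family — developed
around the 69-member soybean Cupin (germin / germin-like) family — from
four kinds of evidence: genome organization (where the members sit on
the 20 soybean chromosomes and how they duplicated), protein phylogeny,
synonymous/non-synonymous divergence of duplicate pairs, and allele
frequencies of wild versus cultivated accessions at SNPs inside the
genes.

Three published tables travel with the package as plain-TSV fixtures:
the 69-gene family table (locus, chromosome, coordinates, peptide
length, exon count), the 18 duplicate-pair table (duplication mode,
fragment-size class, Ka, Ks, Ka/Ks, date), and the 38-row selected-site
table (per-site allele counts in 17 wild and 14 cultivated accessions).
They are transcribed verbatim, including two quirks that deserve
comment:

* **Reversed coordinate pairs.** The family table prints minus-strand
  genes with start > end and carries no strand column. The loader keeps
  the raw pair and derives `strand` and normalized `start <= end`
  coordinates from the order.
* **Spans inconsistent with peptide length.** Eighteen printed spans
  are shorter than 3 bp per residue (e.g. a 108-bp span for a 221-aa
  protein), presumably truncated coordinates in the source. The loader
  flags these with a warning and retains them verbatim; silently
  "correcting" a published table would be invention, and none of the
  derived summaries depend on the inconsistent spans.

## Genome organization

`chromosome_summary()` tabulates members over the fixed 20-label
chromosome set, so absent chromosomes are reported explicitly.
`detect_tandem_clusters()` groups each chromosome's genes into maximal
runs whose inter-gene gap (next start minus previous end, boundary
inclusive) is at most `max_gap_bp`. The **cluster span** is defined as
`max(end) - min(start)`. The source describes its clusters with several
distance figures that are mutually inconsistent under any single
convention; we declare this one and use it everywhere. The default gap
of **20 kb** is chosen to be just wide enough to capture the family's
largest described same-cluster spacing (~19 kb between neighbours on
chromosome 19) while staying far below the distance between unrelated
gene neighbourhoods (the next-smallest inter-cluster gap on these
chromosomes is > 80 kb).

`classify_duplication()` implements the field's operational rule: a
pair is **tandem** when both genes share a chromosome within the gap
window, otherwise **segmental**. Segmental pairs are classed by the
duplicated block that covers them — **large** above 1 Mb, **small**
below — following the long/short fragment boundary the family analysis
uses. Blocks are an *input* (a TSV of paired spans); the package never
infers synteny blocks, which is a genome-scale problem out of scope
here. A segmental pair covered by no block keeps an `NA` class with a
warning rather than a guess.

## Phylogeny

Distances are **p-distances** (mismatches over comparable sites,
pairwise deletion of gap columns), the simplest distance consistent
with protein alignments of closely related paralogs. Trees are built
with the standard **Saitou–Nei neighbor-joining** agglomeration.
Numerical choices, all made for determinism across platforms:

* Q-matrix ties are broken by the lowest (row, column) index pair.
* Negative branch lengths — possible on non-additive inputs — are
  clamped to zero with the deficit moved to the sibling branch, the
  usual printable-tree compromise; the final trifurcation is clamped
  without transfer. On additive matrices the NJ reconstruction is exact
  (a property the tests verify against randomly generated trees of
  4–12 leaves, cross-checked against an independent implementation).

**Bootstrap** resamples alignment columns with replacement; the support
of each internal bipartition of the point-estimate tree is the
percentage of replicate trees containing it, and a fixed seed gives
bit-identical supports. **Paralog pairs** are extracted as cherries —
mutual sister leaves — whose joining vertex reaches `min_support`
(default 50, mirroring the convention of annotating only supports above
50%). Each leaf can appear in at most one pair by construction.

**Subgroups** are a presentation-level cut of the tree: edges are
ranked by depth (longest branch-length path down to a leaf) and cut
greedily, deepest first, skipping cuts that would strand a leafless
internal fragment, until the requested `k` leaf groups exist. The
family's subgroup count (ten) is a parameter, not something the package
re-derives: the member protein sequences are not published, so the real
subgroup structure cannot be recomputed, only emulated on synthetic
families with planted clades.

## Ka/Ks and duplication dating

The estimator is **Nei–Gojobori (1986)** counting with Jukes–Cantor
correction. The source names only the program it used, not the method;
NG86 is that program's classical counting family and, unlike its
successors, is fully specifiable from the literature — important
because the tests pin the implementation to a hand-enumerated oracle.
Conventions:

* Each codon position contributes `s/(s+n)` synonymous sites, where `s`
  and `n` count the synonymous and non-synonymous single-nucleotide
  changes at that position after eliminating changes to stop codons.
  Stop codons themselves contribute zero sites; `S + N = 3 x` compared
  codons exactly.
* Codons differing at 2–3 positions average their synonymous /
  non-synonymous difference counts over all minimal mutational
  pathways, excluding pathways through stop codons (with an
  all-pathways fallback for the degenerate case where every pathway is
  excluded).
* `d = -(3/4) ln(1 - 4p/3)` is applied to `ps = Sd/S` and `pn = Nd/N`;
  a proportion at or beyond 3/4 is flagged invalid rather than forced.
* A Ks of zero leaves the Ka/Ks ratio as an explicit undefined flag,
  never infinity, so summaries aggregate safely.

Codon alignments are either consumed directly or produced by
`backtranslate_alignment()`, which threads each CDS through its aligned
protein (gaps become `---`, trailing stop dropped, any translation
mismatch is an error naming the residue).

Dating uses the molecular-clock formula `T = Ks / (2 lambda)` with the
soybean synonymous rate `lambda = 6.1e-9` per site per year. Reported
rounding follows the published precision: rates to 4 decimals, dates to
2. Applied to the fixture's Ks column this formula reproduces every
printed date exactly, and the summary statistics (mean Ks 0.1682, mean
date 13.78 Mya, range 7.45–28.66 Mya, 8 segmental pairs under Ka/Ks
0.3) are recomputed from the rows rather than asserted. The printed Ka
and Ks values themselves cannot be recomputed — the underlying
nucleotide alignments were never published — so estimator correctness
is established on the hand oracle and on simulated sequences instead.

## Expression

`rpkm_normalize()` is the direct reads/kilobase/million arithmetic.
Clustering is agglomerative over gene rows with **1 − Pearson
correlation** distance and **average linkage** by default — the common
Cluster-3.0-style configuration for expression heat maps; Euclidean
distance and complete/single linkage are available, and a `log2(x+1)`
transform is offered but off by default since the source does not state
one. Constant rows are an error under correlation distance (their
correlation is undefined), which in practice means filtering to
expressed genes first with `expressed_filter()`. `cut_clusters()`
returns a k-group cut with labels renumbered by first appearance, since
the published group letters are presentation labels, not recoverable
quantities.

## Domestication selection scan

A SNP site is **selected** when the majority allele reverses between
the wild and cultivated panels: with `s_w` and `s_c` the signs of the
within-panel count differences, the rule is `s_w * s_c < 0`, or exactly
one panel tied while the other has a strict majority. The tie clause is
forced by the data: the published site list includes tied panels
(8A/8G against a 5/9 majority) among its selected sites, so a rule
requiring strict majorities on both sides could not reproduce the
table. Both-tied panels are not a reversal. The rule is symmetric in
the two panels and invariant to allele labelling, and every one of the
38 published sites classifies as selected under it. Counts are over
observed calls only — the published per-row totals vary below the 17/14
panel sizes, implying missing genotypes — and a site with an empty
panel is skipped with a warning. Whether *near*-ties (9/7 vs 7/9)
should also require a frequency-difference threshold is left
configurable upstream of this function by filtering sites; the strict
sign rule is the default because it is the only stated definition and
it reproduces the printed table.

`count_haplotypes()` reports distinct haplotype strings per panel and
the private ones, the arithmetic behind statements like "three wild
haplotypes, four cultivar haplotypes, one new under domestication".

## Synthetic data: what it emulates, what it does not

The generators stand in for the study's three external resources
(genome sequences, resequencing SNPs, RNA-seq), each with recorded
ground truth, and their defaults are the study's conditions: lambda
6.1e-9, duplication around the ~13-Mya genome duplication, panels of 17
wild and 14 cultivated accessions, a 69-gene family with 35 expressed
members in 11 conditions.

* `simulate_family()` evolves codon sequences by a uniform-rate Markov
  process: synonymous changes at rate lambda per NG86 synonymous site,
  non-synonymous at lambda times the target Ka/Ks, stop codons rejected.
  Expected pairwise Ks is `2 lambda T`; 50 replicate pairs of 500
  codons recover Ks 0.15 within ~1% in the mean. It does **not** model
  indels, rate heterogeneity, codon-usage bias or selection shifts, so
  passing recovery tests shows estimator correctness under the
  estimator's own assumptions, not robustness to real-sequence
  complications.
* `simulate_snp_panel()` draws binomial allele counts per site, with
  planted reversal sites at a chosen frequency contrast and neutral
  sites sharing one frequency per site (uniform 0.2–0.8) in both
  panels. Sites are unlinked, which keeps the null analytic:
  `null_reversal_prob()` computes the exact binomial reversal
  probability the classifier should attain on neutral sites. Real
  panels have linkage and ascertainment the generator ignores.
* `simulate_expression()` plants tissue-specific mean blocks with
  multiplicative log-normal noise and a configurable all-zero
  (unexpressed) subset; at zero noise a k-cut recovers the planted
  partition exactly, mirroring the 35-of-69 expressed structure by
  construction.

All generators are seed-deterministic.

## Problem sizes and runtime choices

The test suite and acceptance script run the recovery experiments at 50
replicates x 500 codons (Ka/Ks recovery), 20 random trees of 4–12
leaves (NJ exactness), 10,000 sites (classifier recall and null rate)
and 69 x 11 expression matrices — sizes at which the Monte-Carlo error
of each check is several times smaller than its tolerance while the
whole suite stays interactive. Bootstrap tests use 10–50 replicates;
the 1000-replicate setting of the original analysis is the documented
default of `bootstrap_support()` but is not exercised at full size in
tests, where support saturation is what is being checked.

## Known limitations

* Homolog discovery, domain confirmation, motif discovery, multiple
  alignment and synteny-block detection are out of scope; aligned
  sequences and block annotations are inputs.
* The NG86 estimator saturates (invalid Jukes–Cantor correction) near
  p = 3/4; deeply diverged pairs should use likelihood methods outside
  this package.
* Subgroup assignment and cluster letters reproduce group *structure*,
  not the published labels, which are presentational.
* The selection rule is the study's own descriptive statistic; it is
  not a population-genetic test and carries no significance measure —
  the analytic null rate exists precisely to show how often reversals
  arise by drift alone in panels this small.
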