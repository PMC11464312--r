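---
title: "Methods: family annotation, cis-element scanning, and treatment-response network inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: family annotation, cis-element scanning, and treatment-response network inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, rules and numerical choices behind
each stage of the pipeline, the design decisions taken where the
methodology was genuinely open, and what the synthetic-data generator
does and does not emulate.

## Coordinates and promoter windows

All internal coordinates are 0-based half-open on the forward genome
strand; GFF3's 1-based closed convention is converted exactly once, at
the I/O boundary. The transcription start site is the gene-span start on
the `+` strand and the last base (`end − 1`) on the `−` strand; when a
gene has several mRNAs the longest is canonical. A promoter is the
`window` bases (default 2,000 bp) immediately upstream of the TSS:
`[tss − window, tss)` for `+` genes and `[tss + 1, tss + 1 + window)`
reverse-complemented for `−` genes, so the returned sequence always
reads 5′→3′ toward the gene. Windows clipped at a contig edge are kept
and flagged rather than dropped, and windows are allowed to overlap
neighbouring genes — upstream genes are not masked, since on compact
plant genomes regulatory elements routinely sit inside or beyond a
neighbour. `N` bases never match any motif letter.

## Subfamily classification

Classification is a total function on genes with at least one AP2 domain
hit: two or more AP2 domains → AP2; one AP2 plus at least one B3 → RAV;
otherwise the residues at positions 14 and 19 of the reported domain
region decide between ERF (A, D) and DREB (V, E). The positions are
counted 1-based from the first residue of the reported envelope; because
different domain callers anchor envelopes slightly differently, the
anchoring is shiftable (`residue_offset`). Genes matching neither pair
are compared to user-supplied Soloist reference domains and called
Soloist at ≥ 70% identity; below that they fall back to ERF with an
`unresolved` flag — intermediate ERF/DREB residues are common in real
families and a hard error would be worse than a flagged call. Soloist
membership is fundamentally a phylogenetic notion, not a residue rule,
which is why it needs reference sequences rather than a motif test.

Tandem duplicates are pairs of family genes on one chromosome with at
most one intervening gene — counting *all* annotated genes, because
genomic adjacency is what a duplication event produces (a flag restricts
counting to family members) — that are homologous: same subfamily and
domain-region identity ≥ 70% by default, both configurable. Identity is
Hamming identity for equal-length domain regions and global-alignment
percent identity otherwise.

## Phylogeny

Distances between aligned domain regions use Poisson correction with
pairwise deletion: columns where either row has a gap are removed
per-pair (gap-vs-gap columns included — they carry no information for
the pair), and with `p` the fraction of differing retained sites,
`d = −ln(1 − p)`. `X` counts as a mismatch against anything by default
(it is an unknown residue; treating it as a match would bias distances
down) and can instead be deleted. A pair with no shared ungapped sites
or with `p = 1` is an error rather than an arbitrary large number.

Neighbor joining is the standard Saitou–Nei agglomeration. Two numerical
choices matter: ties in the Q-criterion are broken by the lexicographic
order of the joined subtrees' smallest leaf labels, so repeated runs and
platform differences cannot reorder the tree; and negative branch
lengths, which NJ can produce on non-additive inputs, are clamped to
zero with a count kept in the tree's `clamped` attribute. Bootstrap
support resamples alignment columns with replacement, rebuilds the tree
per replicate with the same distance settings (pairwise deletion is used
within replicates too), and reports for each internal edge the
percentage of replicate trees containing the same leaf bipartition;
replicates where a pair loses all shared sites are dropped and the
denominator adjusted. The module targets correctness on domain-sized
alignments (tens of taxa); it is not an ML/Bayesian tree program.

## Cis-element scanning

Two modes cover the ambiguity in how such scans are usually run. The
consensus mode reports every offset where the IUPAC pattern matches
exactly — degenerate letters expand to their base sets, overlapping
matches all count, and both strands are scanned by default (the reverse
complement of the pattern against the same oriented promoter, reported
with strand `−`).

The PWM mode reproduces exact p-value thresholding: counts plus a
pseudocount (default 0.1) become a log2 odds matrix against the
background (uniform by default; a promoter-composition background is an
option), scores are discretised at 10⁻³ bits, and the exact null score
distribution under the background is computed by convolving the columns'
score distributions. The threshold is the smallest *achievable* score
whose exact tail probability is ≤ α (default 0.001), and every hit
carries the exact tail probability of its own score. The discretisation
granularity trades table size against exactness; at 10⁻³ bits the
distribution is validated against exhaustive enumeration for widths ≤ 6
in the test suite. One property worth knowing: with a sharp, nearly 0/1
matrix the achievable tails are coarse and the achieved level can sit
well below α; the null-calibration checks therefore use a soft random
matrix, for which the achieved level is essentially α and the empirical
per-position hit rate on uniform sequence is ≈ 2α (two strands).

Candidate targets are genes whose promoters contain at least one hit for
*every* motif in the rule (the GCC box and the DRE/CRT core by default);
presence/absence drives the set, hit counts are retained but unused
downstream.

## Differential expression and response classes

The treatment comparisons use Welch's t-test on `log2(FPKM + 1)` with
Benjamini–Hochberg correction across genes; the reported fold change is
`log2((mean_t + 1)/(mean_c + 1))` on the FPKM scale. No specific count
model is assumed because the pipeline consumes FPKM, not reads; the
caller is deliberately simple and pluggable. Degenerate inputs are
flagged rather than silently handled: under two replicates per group
gives `p = NA` and a fold-change-only call; zero pooled variance with
unequal means gives `p = 0`. Calls are strict: `up` means
`log2fc > 1` *and* `fdr < 0.05`.

The expression floor is a strict `FPKM > 1` in at least one sample of a
group; for the flower group this pools all six stages, so
flower-expressed means expressed at any stage. A group-mean variant is
available by flag.

Response classes are defined on same-day calls (day 2 by default) under
the two treatments: differential in both and in the same direction → K1;
both-but-opposite or Aza-only → K2; ETH-only → K3; the classes are
disjoint and cover exactly the genes differential under at least one
treatment. Assigning opposite-direction responders to K2 mirrors the
composition of the motivating experiment, where the Aza-dependent class
comprises both opposite-direction and Aza-only factors.

## Edge inference, hubs, enrichment

A regulator→target edge is retained when the Pearson correlation (a
Spearman flag exists) across the sample scope satisfies `|r| > 0.8` and
`p < 0.05`, with the two-sided p from `t = r√((n−2)/(1−r²))`. The scope
defaults to the treatment-course samples (all treatments × days ×
replicates); stages-only and everything are options, because which
samples entered the published correlations is genuinely ambiguous.
Zero-variance expression vectors produce no edges instead of NaNs.
Per-class downstream sets are unions of the member regulators' targets,
restricted to the candidate set; hub scoring reports node degrees and
the seven-region overlap decomposition of the K1/K2/K3 target sets.
Enrichment is the generic upper-tail hypergeometric per term with BH
adjustment — the annotation map is an input, not a bundled database.

## The synthetic-data generator

The generator emulates the *design* of a cut-flower two-treatment
transcriptome study, not the texture of real sequencing data. Defaults
(chosen once, as the study conditions for all tests): 500 genes on 5
chromosomes, 40 family members in the canonical subfamily proportions
(35:57:125:6:4), 3 adjacent tandem pairs, 20 ERF/DREB regulators planted
in classes 6 K1 + 2 opposite + 5 Aza-only + 7 K3, 10 disjoint targets
per regulator, and samples covering three tissues, six flower stages and
a ck/ETH/Aza × 3 days × 3 replicates treatment course (27
treatment-course samples). Gene spacing is at least twice the promoter
window so planted promoters never overlap; tandem pairs sit 200 bp
apart.

Expression is log-normal: log2 FPKM = baseline + profile + planted
effect + regulator term + N(0, `noise_sd`), exponentiated to FPKM.
Baselines are N(3, 2) for background genes and N(5, 1) for family genes
(regulator cohorts are well-expressed; this also keeps planted fold
changes from being flattened by the +1 pseudocount at low abundance).
The planted treatment effect is ±3 log2 units at the classification day
(day 2); on other days each responsive gene follows its own random
trajectory with per-day weights in [−1, 1] — transient, delayed or
biphasic responses. This day-resolved trajectory is what keeps
same-class regulators statistically distinguishable: with a constant
effect across the course, all regulators of a class share one expression
axis and every target of one would correlate with all of them. In
addition every family gene carries an individual day/stage profile
(sd 2 log2 units, shared across treatments within a day so it cancels in
same-day contrasts), while background genes are flat over the course
(`bg_profile_sd = 0`) and carry structure only across tissues and
stages.

Planted targets inherit their temporal profile entirely through the
regulator term `sign × es × (TF deviation)` and have no day profile of
their own; otherwise the planted correlation could not reach its
configured magnitude. The coefficient `es` is derived per regulator from
the target correlation `target_edge_r` (default 0.95):
`r² = es²·v / (es²·v + σ²)` with `v` the regulator's expected
treatment-course variance (exact planted-pattern variance + expected
day-profile variance + noise variance) and σ the noise sd, giving
`es = √(r²σ² / ((1−r²)v))`. With `noise_sd → 0` and `edge_strength = 1`
the planted correlation is exactly ±1 and the planted day-2 fold change
is exact — the zero-noise recovery limit asserted in the tests.

What the generator does **not** emulate: count-level noise
(mean–variance coupling, zeros), isoforms, batch effects, genome base
composition, indel variation in domains, and methylation itself (Aza
enters only as a treatment label). Passing tests therefore demonstrate
that each stage recovers what its model assumes, under the stated noise
— not that the defaults match any particular real dataset.

Determinism: one config seed; each stage derives its own seed by a fixed
offset, so regenerating any stage in isolation reproduces it exactly,
and a full pipeline run (`run_pipeline()`) is byte-identical across
reruns of the same configuration, which the manifest's MD5 checksums
make checkable.

## Problem sizes used by the test and acceptance runs

Unit tests use cohorts of 30–250 genes; property tests run 200 random
scanner cases, 50 random additive trees at up to 12 taxa, exhaustive
enumeration of PWM distributions to width 6 and of hypergeometric
p-values to a universe of 15. The calibration checks use ~10⁶ scanned
promoter positions (PWM null) and 10⁴ genes (differential-expression
null); edge recovery averages 20 expression replicates of the default
500-gene cohort. The end-to-end check runs the full default
configuration, including 1,000 bootstrap replicates on the 40-taxon
domain alignment, twice.

## Known limitations

* The differential caller is a t-test on transformed FPKM; with three
  replicates its power is limited and borderline regulators can land
  just above the FDR cutoff. The interface accepts any caller producing
  the same call table.
* Co-expression cannot, even in principle, tell apart regulators whose
  response patterns are identical across the sampled conditions; the
  generator avoids this degeneracy by construction (trajectories and day
  profiles), real data may not.
* PWM p-values for `−` strand hits reuse the forward-strand null, which
  is exact for the default uniform background and an approximation for
  strand-asymmetric backgrounds.
* Bootstrap supports on domain-length alignments (~60 columns) are
  intrinsically noisy; they quantify column-resampling stability, not
  clade truth.
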