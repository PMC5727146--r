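---
title: "Dating genome duplications and screening for selection with Ks age distributions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dating genome duplications and screening for selection with Ks age distributions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ksage)
```

## The analysis in one paragraph

When a lineage undergoes a whole-genome duplication (WGD) or triplication
(WGT), it acquires a large cohort of paralogous gene pairs that are all the
same age. Synonymous substitutions accumulate roughly neutrally, so the
synonymous distance Ks between two homologous coding sequences acts as a
molecular clock: the Ks distribution of within-species paralog pairs shows a
density peak at the age of each polyploidy event, and the Ks distribution of
between-species ortholog pairs peaks at the speciation age. `ksage`
implements this classic comparative-transcriptome analysis end to end for
two or three closely related species: representative ORF selection, graph
clustering of protein similarities into orthogroups, Nei–Gojobori Ka/Ks
estimation on protein-guided codon alignments, log-Gaussian mixture
modelling of the resulting Ks samples, clock dating of the fitted peaks, and
a Ka/Ks screen for positively selected ortholog pairs. A codon-level
simulator with planted events provides ground truth, so every stage of the
pipeline is validated against data whose true history is known.

## The rate estimator

For each homolog pair the two proteins are aligned globally
(Needleman–Wunsch with affine gaps, BLOSUM62, gap open 10 / extend 1) and
the alignment is back-translated to codons under the guidance of the coding
sequences, so gaps are always whole codons. The counting estimator then
proceeds codon by codon:

* **Sites.** At each codon position, the three possible single-base changes
  are classified as synonymous or nonsynonymous; changes that would create a
  stop codon are excluded from both numerator and denominator. The
  synonymous fraction summed over the three positions gives the codon's
  synonymous site count `s`, with `n = 3 − s`, so `S + N` always equals
  three times the number of compared codon columns. `S` and `N` are averaged
  over the two sequences.
* **Differences.** For codons differing at `k` positions, all `k!` orderings
  of the single-base steps are enumerated, each step classified by whether
  it preserves the amino acid; orderings passing through a stop codon are
  excluded (all retained if none survives) and the per-ordering tallies are
  averaged. Summing over columns gives `Sd` and `Nd`.
* **Correction.** The proportions `pS = Sd/S` and `pN = Nd/N` are corrected
  for multiple hits with the Jukes–Cantor formula
  `d = −(3/4) ln(1 − (4/3) p)`, defined for `p < 3/4`; saturation beyond
  that bound is flagged rather than extrapolated.
* **Significance.** A two-sided Fisher's exact test on the 2×2 table of
  rounded differences against remaining sites
  (`[Sd, S−Sd; Nd, N−Nd]`) gives a per-pair p-value.

Equal weighting of substitution pathways (the original counting convention)
is used throughout; no transition/transversion weighting and no
maximum-likelihood codon model — those are deliberate non-goals, because the
whole analysis is calibrated around the counting estimator.

Both counting rules are verified exhaustively in the test suite: the site
fractions for all 61 sense codons and the pathway averages for all 61×61
codon pairs are compared against independent brute-force enumerations.

## From transcripts to homolog pairs

Transcript sets are reduced to one representative coding sequence per gene:
the longest transcript per gene is scanned for ATG-initiated ORFs in all six
frames, ORFs shorter than 300 nt or 50 aa are discarded, and the longest
surviving ORF wins (ties broken by smaller start, then + strand; transcript
ties by lexicographic id — the tie-breaks are fixed so reruns are
reproducible). ORF coordinates are 0-based half-open on the reported strand.

All representative proteins are then compared all-vs-all. An edge is kept
when percent identity ≥ 50, coverage of the shorter protein ≥ 0.5, and raw
alignment score ≥ 50. The identity threshold is the standard orthology-
pipeline setting; the score and coverage gates replace a BLAST e-value
cutoff, which has no meaning outside a database-search context — raw global
alignment scores against curated full-length translations carry the same
information without the database-size dependence. Edge weights are alignment
scores normalised by the geometric mean of the two self-alignment scores, so
they live in (0, 1] regardless of protein length.

The weighted graph is clustered with the Markov Cluster algorithm
(expansion/inflation iteration to a 1e-6 fixed point, inflation 1.5 — the
default of the widely used orthology pipelines; the column-stochastic matrix
is built over lexicographically sorted gene ids, which makes the procedure
invariant to input order). From the resulting orthogroups, pairs follow two
rules: an **ortholog pair** is emitted for every group containing exactly
one gene from each species of a species pair, regardless of other species'
contributions; a **paralog pair** for every group containing exactly two
genes of one species. Groups with three or more copies of a species
contribute no pairs — the rules are deliberately conservative.

## Mixture modelling, dating, and the selection screen

Ks values of each curve (one per species pair and one per species) are
log-transformed and fitted with Gaussian mixtures by EM for k = 1…4
components, each k restarted from several quantile-spread initialisations
(deterministic, so fits are exactly reproducible), convergence at a 1e-8
log-likelihood improvement or 500 iterations. The component count is chosen
by BIC; a BIC difference approximates twice the log Bayes factor under a
unit-information prior, which is the practical surrogate for Bayes-factor
model choice when the original tool's settings are unavailable. The default
fit range 0.005 ≤ Ks ≤ 2.0 excludes the zero-inflation spike of recent
tandem duplicates and allelic variants at the low end and the
JC-saturation regime at the high end; identical pairs (Ks = 0) cannot enter
a log-domain fit in any case. Components with weight ≥ 0.10 are reported as
peaks at exp(mu), and the heaviest is flagged dominant.

A peak is dated with the strict clock `T = Ks / (2 r)`, with
`r = 1.5e-8` synonymous substitutions per synonymous site per year, the
standard dicot rate; the factor 2 accounts for the two branches diverging
simultaneously. The linearity of this map (double the Ks, double the age)
is part of the test surface.

The selection screen runs on the within-genus ortholog curve after an
ordered exclusion ledger: identical pairs, pairs with undefined corrected
rates, pairs with only nonsynonymous or only synonymous substitutions, and
pairs with Ks above 0.1 (likely hidden paralogs at these divergence depths)
are removed in that fixed order, each pair counted in exactly one category,
and the categories partition the input — an invariant checked on every run.
Remaining pairs are called **positive** when Ka/Ks > 1 and **purifying**
otherwise; a ratio of exactly 1 is binned as purifying (the two-class
convention leaves equality undefined, and at these sequence lengths an exact
1 is a rounding event, not evidence of adaptation). The Fisher p-value is
reported but does not gate the positive class by default — the published
convention defines the class by the ratio alone — and a
`require_significance` switch applies the gate for users who want it. No
multiple-testing correction is applied by default for the same reason.

## The simulator and what it does (and does not) emulate

The simulator generates ancestral coding sequences (ATG + uniform sense
codons + stop), then propagates each gene family through an ordered event
list: speciations fork lineages, WGD/WGT events copy every gene 2 or 3 ways
with each extra copy retained independently with probability
`retention_prob`, and between events each surviving copy accumulates
substitutions. Event ages are expressed directly in expected Ks units and
split equally across the two branches of a split — only the pairwise sum is
identifiable to a pairwise estimator, so nothing is lost. Synonymous and
nonsynonymous substitution counts are drawn Poisson with expectations
`ks × S` and `omega × ks × N` and placed uniformly over the currently
eligible single-base changes, with stop-creating changes never eligible.
This process is intentionally matched to the counting estimator's
assumptions (uniform base exchange, no codon-usage bias, no site-rate
heterogeneity, no indels), which keeps recovery tests interpretable: a
planted-vs-estimated regression slope inside [0.8, 1.2] over Ks ∈
[0.02, 1.0] demonstrates estimator consistency, not realism of the
generator.

The default scenario mirrors a two-congener-plus-outgroup design: an
ancient WGD at Ks 0.75 shared by the whole clade, the genus/outgroup split
at Ks 0.5, a recent WGD at Ks 0.1, and the species split at Ks 0.05, with
per-family Ka/Ks 0.3 (a typical purifying average) and duplicate retention
0.25 as a plain stand-in for post-polyploid fractionation. The supported
event grammar also expresses triplication (WGT), since a recent event of
this kind is often ambiguous between duplication and triplication in Ks
data alone; duplication is the default.

What passing recovery tests therefore show is that the pipeline's
inference machinery is correct and well calibrated under its own model
assumptions. They do not show robustness to assembly artefacts, alternative
splicing residue, codon-usage bias, rate variation among lineages, or Ks
saturation noise — all present in real transcriptome data and outside this
generator's scope.

## Numerical and scale choices

* Alignment is exact DP (no heuristic seeding); all-vs-all comparison is
  O(n²) with a vectorised score-only prefilter before full alignments, which
  is comfortable for curated desk-scale gene sets (hundreds to a few
  thousand genes).
* MCL runs dense matrix iterations; the same desk-scale bound applies.
* Test and validation runs use 500 pairs of 300 codons for study-scale
  peak-recovery checks and 8–40 families for end-to-end pipeline checks;
  mixture recovery uses 1000–2000 draws. These sizes put Monte-Carlo error
  well inside the ±20% recovery bands while keeping the default suite quick.
* EM degeneracies are guarded: component standard deviations are floored at
  1e-3 log-units and responsibilities at 1e-8, so a component cannot
  collapse onto a point mass.
* All randomness is seed-scoped: generator functions set and restore the
  RNG state, so library calls never perturb a caller's stream, and a run
  manifest records the seed.

## Known limitations

* Ks saturation is flagged, not corrected; curves older than Ks ≈ 2 are
  outside the default fit range and the dating of broad ancient peaks
  inherits the JC correction's compression bias.
* The paralog-pair rule (exactly two copies) underestimates WGT cohorts,
  where three-copy groups are expected; the census of larger groups is
  reported but not paired.
* The strict clock uses a single rate for all lineages; rate differences
  between congeners fold directly into the age estimates.
* Fisher's test on rounded fractional counts is a pragmatic significance
  screen, not a likelihood-ratio test; it is reported per pair and should
  be treated as descriptive.
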