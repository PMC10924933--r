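---
title: "Models and methods behind ervkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ervkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ervkit)
```

ervkit quantifies germline mobilization of an endogenous retrovirus (ERV)
family — modeled on the bovine ERVK clade with its Competent (C, intact
genes) and Defective (D, no intact ORFs) morphs — from junction-capture
sequencing abstractions, and simulates the family's population dynamics.
This vignette records the models, the tunable parameters and their
defaults, the numerical conventions, and what the synthetic data do and do
not emulate.

## Insertion calling from clipped reads

Capture sequencing of proviral junctions yields clipped reads that are
either insertion-site (IS) reads, at the genomic junction of the provirus,
or shearing-site (SS) reads, at the mechanical DNA break of the captured
molecule. The pipeline consumes tabular read records and applies, in
order:

1. **Quality filters** (`filter_reads()`): mapping quality ≥ 40, ≥ 10
   clipped bases, proviral tag alignment score ≥ 0.6, all inclusive.
2. **Breakpoint merging** (`merge_breakpoints()`): reads of the same role,
   side, sample and chromosome collapse into candidate sites. The merge
   window defaults to 0 bp (the exact same breakpoint); it is exposed
   because breakpoint jitter in real aligners can justify 1–2 bp. The
   cluster coordinate is the modal read position.
3. **IS–SS pairing** (`pair_is_ss()`): every SS on the
   orientation-consistent side within 5 kb pairs with the IS. For a 5′
   panel the SS of a sense-oriented element lies upstream of the IS,
   downstream for antisense; the rule flips for the 3′ panel. Two sperm
   genomes essentially never shear at the same base, so distinct SS count
   distinct molecules and identical SS are PCR duplicates: `n_molecules`
   is the number of distinct paired SS. An IS without a compatible SS is
   reported unpaired and excluded.
4. **Classification** (`classify_calls()`): a de novo candidate must lie
   > 3 kb from every constitutive locus *and* be observed in exactly one
   animal; calls at constitutive loci are labeled constitutive; the rest
   are rejected. Candidate vetting is purely rule-based — no manual review
   step exists, which is a deliberate reproducibility choice.

Coordinates are 1-based inclusive in every file the package reads or
writes.

## Capture normalization and mobilization rates

Counts of distinct shearing sites (`SSC[i, s]`) at constitutive locus `i`
in individual `s` follow the additive model

> `SSC[i, s] = ERV[i] + ID[s] + eps[i, s]`

where `ERV[i]` absorbs locus-specific capture efficiency and `ID[s]` the
amount and quality of DNA engaged for the individual.
`fit_normalization()` computes the least-squares solution via `lm()`. The
model is unidentifiable up to a constant moved between the factors, so we
impose `mean(ERV[i]) = 0`; `ID[s]` then carries the individual's capture
level and `2 * ID[s]` is the number of effectively captured haploid
genomes. Whether the original analysis used an intercept is not
determinable from the model statement; our constraint is a documented
package choice, with the property that for a complete balanced table
`ID[s]` is simply the individual's mean count. Missing cells are dropped
from the fit, never imputed, and the observed cells must connect loci and
individuals into one bipartite component — otherwise the relative level of
a disconnected block is undefined and the fit aborts naming the block.

The mobilization rate is `TR[s] = N[s] / (2 * ID[s])` events per gamete,
with `N[s]` the de novo event count. The 5′ and 3′ LTR panels are
technical replicates; `average_panel_rates()` averages them. Rates with
non-positive `ID` are flagged missing, never reported as zero.
`genotype_constitutive()` converts per-locus SS/genome ratios into allele
dosages by one-dimensional k-means with k ∈ {1, 2, 3} chosen by average
silhouette width (ties to fewer clusters — the flattest adequate
explanation), mapping cluster means to the nearest of (0, hom/2, hom).

## EM attribution of de novo insertions to haplotypes

Four short proviral tags (two per LTR side) define a tag haplotype per
inherited element; capture typically recovers only one side (~4% both), so
a de novo insertion is compatible with every inherited haplotype matching
its observed slots. `em_contributions()` fits the haplotype contribution
simplex by expectation-maximization from a uniform start: the E-step
splits each event across its compatible haplotypes in proportion to the
current contributions, the M-step averages the coefficients. The
observed-data log-likelihood is non-decreasing and is asserted
per-iteration in the tests. Convergence is `max |Δp| < 1e-6` or 1000
iterations — we iterate to tolerance rather than a fixed ~20 rounds, which
matters for flat likelihoods (ambiguity-heavy data). Contributions that
reach 0 stay at 0 (EM boundary); events compatible with no inherited
haplotype (possible recombinants) are excluded and counted, never forced.

Uncertainty comes from a percentile bootstrap over events (default
B = 1000; B and the percentile CI are package choices — the original
bootstrap settings are unpublished). `cd_apportion()` splits contributions
into C and D shares, dividing mixed haplotypes by the inherited C:D member
ratio; `test_cd_shift()` compares the de novo D share to the inherited D
fraction with a two-sided bootstrap p-value `2 * min(tails)`, floored at
`2/B`.

## Developmental timing from recapture distributions

Spermatogenesis is modeled as 20 binary divisions from one precursor to
2^20 = 1,048,576 spermatogonial stem cells (21 cell generations). An
insertion arising at generation `k` reaches a fraction `2^-k` of sperm
genomes (`dosage()`): 0.5 at generation 1, ~0.00097 at 10, ~4.8e-7 at 21.
A mobilization window (`window_weights()`) is a symmetric binomial
mutability mass (`width - 1` trials, p = 0.5, our parameterization of the
"binomial, peaked at the focal generation" description) centred on a focal
generation, truncated to 1..21 and renormalized, then multiplied by the
per-generation cell counts `2^(k-1)` and renormalized. Windows spilling
over the boundary are truncated rather than disallowed.

`simulate_insertions()` draws events from the window until their summed
dosage reaches the observed per-genome insertion burden `t/g`, keeping the
final overshooting event (the stopping rule is unstated in the original
description; keeping the overshoot is seed-stable and unbiased for the
burden to within one dosage). `sample_urn()` draws `g` haploid genomes
with replacement from an urn holding one ball per insertion (probability =
dosage) plus an insertion-free ball (probability `1 - t/g`), and tabulates
captures into the categories 1x, 2x, 3x, 4x and >4x (the >4 bucket
aggregates everything ≥ 5). `fit_window()` grids over (width, focal),
averages 50 simulated category vectors per individual, and scores
`sum |simulated - observed|` summed over individuals; the minimizer is the
fitted window. Self-consistency (recovering a planted focal generation
±1) is asserted in the acceptance tests using the three bulls'
published explored-genome counts (7690, 5386, 9178) and burdens (0.030,
0.019, 0.024), with 10 fitting runs of 10 replicates over focals 10–18 —
sizes chosen to keep the whole suite in minutes while leaving the
recovery unambiguous.

## Forward simulation of the ERV family

A panmictic population of `N` individuals evolves for `G` non-overlapping
generations; each individual is a bag of elements with a competence flag
and an affinity `a ≥ 0` for the shared mobilization machinery.

* **Fitness**: `f = 1 - (t / 250)^p`, clamped to 0 at `t ≥ 250` copies;
  `p` ∈ {1, 2, 3} sets the stringency, or selection can be off (`f = 1`).
* **Drive**: a parent's mobilization rate is
  `r = (1 - exp(-0.1 c)) * 0.05`, saturating in its competent count `c`.
  Each parental element is transmitted with probability 0.5 and spawns a
  de novo copy in the gamete with probability `q = r * a / sum(a)` —
  applied once per gamete whether or not the element itself was
  transmitted (our documented reading of "every parental ERV"). A parent
  with all affinities 0 has no drive substrate.
* **Mutation** (rate `mu` per element): destroys competence (defective
  stays defective) and, when affinity mutation is enabled, adds a
  standard-normal draw to a positive affinity, floored at 0.

Parents are drawn with replacement proportionally to fitness; selfing is
allowed (sex is not modeled). If everyone reaches zero fitness the run
halts with an extinction report. The generation loop is implemented in
C++ (Rcpp) using R's RNG, so a seed fully determines a trajectory;
`breed()`, `mutate_genome()`, `erv_fitness()` and `mobilization_rate()`
are also exposed in R and the tests verify the drive partition and
mutation rules against binomial expectations there.

Two reporting choices: "high-affinity" defectives are those with `a > 1`
(the seeding affinity; the original figure distinguishes the classes
without printing a cutoff), and the dichotomy runs seed every individual
with one competent element (`s = 1`). The seeding proportion is
unpublished; at the reduced population size we use for testing (N = 200),
sparse seeding usually fails to establish the family at all — twenty
singleton lineages under a near-critical branching process mostly drift
out — whereas the phenomenon under study concerns an established family.
With affinity mutation enabled, high-affinity defectives arise and
monopolize the drive; the competent class then loses its only renewal
channel and decays at a rate of order `mu`, so its extinction time is
thousands of generations. A 1500-generation horizon captures the
displacement (high-affinity defectives overtaking competent elements) but
usually not the final extinction; the acceptance suite states the full
property and the unit suite asserts the displacement, with the timescale
analysis recorded there.

## Sequence statistics

* **Spectrum** (`spectrum_enrichment()`): substitutions are tabulated by
  type (12) and trinucleotide context on the consensus (16); each cell's
  share of substitutions is divided by its expected share under a
  context-blind null — the context's abundance fraction times 1/3, since
  each base has three alternative alleles. The 1/3 keeps the null
  baseline at 1. The consensus base is treated as ancestral; boundary
  positions lack a context and are dropped with a warning.
* **Strand asymmetry** (`mirror_asymmetry_test()`): the six complementary
  substitution pairs (e.g. G>A vs C>T), in CpG and non-CpG strata where
  the central base can sit in a CpG, compared as per-eligible-site rates
  with a bootstrap over substitution records (two-sided percentile p,
  floored at 2/B).
* **Recombination** (`four_gamete_scan()`): for every biallelic variant
  pair on pairwise-complete elements, the four haplotype counts, `D`,
  `D' = |D|/Dmax` and `r²`; all four haplotypes present flags
  recombination (or recurrent mutation). Singleton variants are included
  by default — they cannot create a fourth haplotype, but they do affect
  `D'` summaries, so a flag excludes them. `cd_boundary_ld()` treats the
  C/D class itself as a binary variant to profile boundary attrition.
* **Dating** (`divergence_dating()`): per-site divergence over `mu`
  (total-branch, used for the C/D split: 38.4 differences in 250 bp at
  `mu = 1e-8` gives 15.36 million generations) or over `2 mu`
  (per-lineage, for 5′/3′ LTR pairs of one provirus, identical at
  insertion). The published ~622,000-generation figure for the most
  divergent LTR pair (98.3% over 1287 bp) is not reproduced by either
  convention (they give ~1.7e6 and ~8.5e5); the convention or a
  correction behind that figure is ambiguous, so both are exposed and the
  discrepancy left documented rather than resolved.
* **Monte-Carlo tests**: `compartment_enrichment_test()` draws multinomial
  samples under genomic-expectation probabilities (which are a required
  input — published expected counts do not close to the printed total, so
  no inference of the simplex is attempted) and reports per-category
  two-sided empirical p-values floored at `1/n_reps`.
  `coincidence_test()` reports both a Monte-Carlo and the exact
  Poisson-binomial tail (iterated convolution), and the tests require the
  two to agree within Monte-Carlo error.
* **Frequency-spectrum shift** (`afs_shift_test()`): two-sided Wilcoxon
  rank-sum — the exact permutation distribution of the rank-sum statistic
  for small tie-free samples.

## What the synthetic data emulate — and what they do not

The generators reproduce the *structure* the estimators rely on:
locus-by-individual capture effects with Gaussian cell noise (the count
distribution around the additive mean is unpublished; Normal noise
rounded and clamped at zero, with clamped cells flagged, is our choice),
Poisson de novo counts at `TR * 2 * ID`, PCR duplicates as shared
shearing sites, partial (5′/3′-only, ~4% both) tag observation, geometric
`2^-k` insertion dosages, and perfect-phylogeny substitutions with
context-biased rates plus suffix-swap recombination.

They deliberately do not emulate: raw sequencing reads or alignment
artifacts (records arrive pre-abstracted), reference-genome context
(insertion-site motifs, GC, telomere proximity), solo-LTR formation,
recurrent mutation, or cohort-scale genotype panels. Passing tests
therefore validate the estimators' arithmetic and statistical behavior on
data with known truth — not robustness to alignment error or to model
misspecification in real cohorts.

## Problem sizes and numerical conventions

The test and acceptance workloads use scaled study sizes chosen to keep
the full suite within minutes on one core: capture cohorts up to
123 × 430 for the recovery checks, 500 fully observed events per EM
recovery, B = 1000 bootstraps, 50 urn replicates per window candidate,
20 forward-simulation replicates at N = 200 over 1500 generations, and
2e5–1e6 Monte-Carlo draws where an exact oracle exists to compare
against. Random streams are seeded per call (`seed` arguments) or per
script; identical seeds give byte-identical outputs, a property the tests
assert for every generator and Monte-Carlo routine.
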