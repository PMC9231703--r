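---
title: "Scoring gene dosage and expression: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring gene dosage and expression: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genedose)
```

This vignette explains the models and scoring rules the package implements,
the design choices made where the conventions in the literature were open or
inconsistent, and what the synthetic-data generators do and do not emulate.

## Dual-probe FISH interpretation

A dual-color FISH assay counts, in each scored nucleus, fluorescent spots
for a gene probe and for the centromere enumeration probe (CEP) of the same
chromosome. The CEP count is the control that separates two biologically
different routes to extra gene copies: focal *amplification* (gene copies
increase while the chromosome count does not) and *polysomy* (the whole
chromosome is gained, so both signals rise together).

`summarize_cells()` reduces a cell population to mean copies per cell of
each probe, the gene-to-centromere ratio, and the ranked *major clones* —
distinct (gene, CEP) count patterns by observed frequency. `classify_fish()`
then applies the rules:

* **Amplification**: reported ratio ≥ 2.0 (configurable). An amplified call
  still reports the CEP status separately, because chromosome-level gain can
  coexist with focal amplification. A second threshold (default ratio ≥ 5.0,
  the conventional high-level amplification cut in dual-probe scoring of
  other loci) adds a "High ampl" qualifier.
* **Polysomy, from the top major clone's integer counts (g, c)**: disomy at
  g = 2, low polysomy at g = 3 (copy number > 2 and ≤ 3), high at g ≥ 4;
  *balanced* iff g = c; CEP hemizygous deletion when c = 1 with g ≥ 2.

Two design points deserve justification:

1. **Clone counts, not means, decide the level.** Reference score tables
   call a sample with means 3.8/3.8 but modal clone 4:4 *high* polysomy,
   while 3.2/3.1 with clone 3:3 is *low*. Rounded means cannot reproduce
   both; the modal clone can, and it is also the more robust statistic under
   miscount noise. Similarly, the level is keyed to the *gene* count of the
   clone (a 2:3 clone is disomy, 3:4 is low), since the gene is what the
   assay is about and the CEP status is expressed through the
   balance/deletion fields.
2. **The level qualifier is omitted for widely split signals.** When the two
   probes' counts fall in different polysomy bands *and* differ by at least
   two copies (e.g. a 3:5 clone), neither "low" nor "high" describes both
   signals, and the call is rendered plain "Unbalanced polysomy". A 3:4
   clone (adjacent counts) keeps its gene-level qualifier. This is the one
   rendering rule consistent with every published row we use as fixtures.

The reported ratio is computed from the *rounded* reported means
(half-up, 1 decimal), which is how printed tables derive it; the unrounded
values stay in the object (`raw_*`), and `ratio_from_rounded_means = FALSE`
switches the convention. Rounding everywhere is round-half-up, not R's
round-half-even, to match printed tables.

Structural alterations (rearrangements that delete, duplicate or
translocate the locus) are identified cytogenetically on metaphases, not
inferrable from interphase counts — so `structural_alteration` is an input
annotation that prefixes the label ("SA, ..."), never an inference.

Ties between equally frequent clones are broken by ascending (gene, CEP),
for determinism; populations of cells with zero signals in both probes are
uninterpretable and rejected. Cells with zero counts are otherwise included
in the means — whether to exclude them is a lab convention the data formats
cannot decide, and inclusion is the conservative default.

## ΔΔCt relative quantification

With mean cycle thresholds over replicates,
ΔCt = Ct(target) − Ct(reference) per condition, ΔΔCt = ΔCt(sample) −
ΔCt(calibrator), and RQ = 2^(−ΔΔCt). The identities that make this
trustworthy are tested exactly: self-calibration gives RQ = 1, a global Ct
shift changes nothing, swapping sample and calibrator inverts RQ, and on
noiseless simulated designs the generating fold change is recovered to
machine precision.

The RQ spread is reported, by default, as the SD of per-replicate RQs
(replicate i paired across the four design cells, truncated to the shortest
replicate list) — the simplest estimator consistent with a replicate design
that prints an SD beside each RQ. Published tables do not state their
estimator, so a delta-method alternative (`rq_sd_estimator = "propagated"`)
is available.

Expression bands: high (RQ ≥ 50), moderate (20 ≤ RQ < 50), low
(1 < RQ < 20). The bands as printed start above 1 — the calibrator itself
sits at exactly 1.00 — so RQ ≤ 1 is labeled `baseline`. Reported RQ/SD are
rounded half-up to 2 decimals.

## ImmunoReactive Score

IRS = intensity grade (0 negative, 1+ weak, 2+ moderate, 3+ strong) ×
percent-positive bin score (0% → 0, 1–10% → 1, 11–50% → 2, 51–80% → 3,
> 80% → 4), range 0–12; 0 none, 1–3 low (negative), 4–8 moderate, 9–12 high
(≥ 4 positive; both published phrasings of the moderate/high boundary agree
that 8 is moderate and 9 is high). Percent positivity is a visually
estimated integer, so the bins are defined on integers and non-integer
input is an error rather than a silent binning decision.

Cohort summaries report positivity as numerator/denominator ("17/39") plus
a rounded percentage, and mean ± SD of percent-positive per tissue class.
The metastasis class is carried through summaries but the ordered
three-class comparison drivers use benign/DCIS/IDC. Two-rater blinded
scoring is an acquisition procedure, out of computational scope; a
consensus column (e.g. the raters' maximum) can simply be supplied as the
input score.

## Region peak area

A signal track is a step function: segments of constant signal. The peak
area of a region is Σ (overlap width × value) over segments, with partial
segments clipped to the region. Clipping is the only convention under which
the statistic is independent of how the track was binned; that invariance
(refinement, partition additivity to 1e-9 relative, linear scaling) is
tested directly. Coordinates are 0-based half-open internally (bedGraph
native); browser-style 1-based inclusive coordinates are converted only
behind an explicit `browser = TRUE` flag, avoiding silent off-by-one. The
default analysis window is the chr9 promoter region
chr9:36,571,990–36,574,891 (browser style) of the kinase gene the package's
default labels refer to; methylation comparisons default to the three
promoter CpG probes nearest the transcription start site, and any probe
list can be supplied.

## Statistical procedures

The named tests are implemented in the package rather than delegated, so
their conventions are explicit and testable; the corresponding base R
functions serve as independent oracles in the test suite, which requires
agreement to 1e-12 where the convention is identical:

* Pearson r with the exact t transform (n − 2 df, two-sided; two-sided is
  assumed where the source does not specify).
* Kendall's tau-b, `(C − D)/√((n0 − n1)(n0 − n2))`, with the tie-adjusted
  normal approximation for the p-value — the appropriate association
  measure for ordinal scores with heavy ties.
* Kruskal–Wallis H with tie correction; all observations tied yields
  H = 0, p = 1 by convention (the tie-correction denominator is guarded).
* Wilcoxon rank-sum with tie-corrected normal approximation and continuity
  correction; within 0.02 of the exact permutation distribution by n = 8
  per group.
* Welch t (pooled vs unequal variance being unstated in the sources,
  Welch is the safer default).
* Holm step-down adjustment, returned in input order.

The integration driver `cn_expression_report()` computes the pooled Pearson
correlation of log2 copy number with log2 expression, Kruskal–Wallis of each
variable across subtypes, and pairwise reference-vs-other rank-sum tests
with Holm adjustment. Cumulative link mixed models — sometimes used for
ordinal pairwise comparisons — are deliberately not implemented: they are an
off-the-shelf peripheral fit, and the rank-sum + Holm substitute is stated
in the report's `note` field wherever results are emitted.

## Synthetic data: what it emulates, and what it does not

Each generator is a pure function of (parameters, seed); one global seed is
salted with the stage name into independent substreams, so adding a stage
never perturbs another stage's draws, and generators restore the caller's
RNG state.

* **FISH populations**: mixtures of integer-count clones with symmetric ±1
  miscount noise (floored at 0). There is no published error model for spot
  scoring; ±1 is the minimal perturbation that exercises major-clone
  robustness. Not emulated: nuclear truncation artifacts, probe
  inefficiency, overlapping nuclei.
* **qPCR**: Gaussian replicate noise around design-cell means. Not
  emulated: amplification-efficiency deviations from 2.0, plate effects.
* **IHC cohorts**: per-compartment categorical intensity and integer
  percent draws under the constraints the scoring assumes (grade 0 ⇒ 0%,
  cytoplasmic staining only with nuclear staining). Not emulated: rater
  disagreement, spatial heterogeneity.
* **Signal tracks**: rectangular peaks over a binned tiling with
  truncated-at-0 Gaussian noise. Not emulated: read-depth count noise,
  fragment-length smearing.
* **Copy number/expression**: within-subtype bivariate normal with a target
  correlation plus subtype location shifts. Not emulated: heavy tails,
  measurement platform effects, confounding between subtype and depth.

Consequently, passing tests demonstrate that the *procedures* are correct
and calibrated (parameter recovery, type-I error in [0.04, 0.06] at
α = 0.05 over 2000 null Kruskal–Wallis datasets of 3 × 20), not that any
particular biological cohort will reproduce a given correlation. Headline
cohort statistics from consortium data (e.g. a pooled CN–expression
correlation of ~0.28 across 1551 tumors) require those cohorts; the package
emulates them with parameter-recovery tests at matched effect sizes
instead.

## Problem sizes and numerical choices

The test suite runs at sizes chosen to make sampling error negligible
relative to each tolerance: 10⁴ cells for mixture-frequency checks
(binomial SE ≈ 0.004 against a 0.02 band), n = 2000 for correlation
recovery at r = 0.5 (Fisher-z SE ≈ 0.022 against a ±0.05 band), 2000
replicates for rejection-rate calibration (SE ≈ 0.005 against a ±0.01
band), 100 random ordinal datasets (n ≤ 30) for the tau-b pair-counting
oracle. Exact identities (ΔΔCt, peak-area invariances, rule-table
equivalence over all 49 single-clone patterns with counts 0–6) are asserted
at 1e-12 or exactly.

Fixture row known to be internally inconsistent: one published cell line
prints ratio 1.1 beside means 3.1/3.0 (which give 1.0); its ratio is
excluded from fixtures as a probable typo, while its interpretation string
is still checked.

## Limitations

The FISH rules are transcribed from, and validated against, one published
score table; other laboratories' conventions (e.g. different low/high
polysomy cuts, mean-based levels) are reachable through the configuration
but not separately validated. The rank tests use asymptotic approximations
— adequate at the cohort sizes these pipelines see, and bounded against
exact permutation at small n in the tests, but not exact. The ΔΔCt model
assumes perfect doubling per cycle and a single reference gene.
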