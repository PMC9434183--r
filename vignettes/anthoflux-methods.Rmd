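---
title: "Models and methods behind anthoflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind anthoflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anthoflux)
```

anthoflux implements the computational core of a multi-omics analysis of
flower development across anthesis — the transition from closed buds to open
flowers. Its four analytical arms are: radiolabel (^14^C) flux
quantification, natural-abundance correction of ^13^C mass-isotopologue
distributions, stage-resolved profile statistics, and thresholded Pearson
correlation networks, together with an RNA-seq count funnel. A seeded
synthetic-data generator emulates each experimental design so that every
stage of the pipeline can be tested against known ground truth. This
vignette explains the models, the parameters that matter, and the design
choices that were genuinely open.

## The developmental design

The sampling design covers eight floret stages spanning roughly eight days
of development, with ages 7.25, 9.25, 10.25, 11.50, 13.25, 13.50, 14.25,
and 15.25 days and anthesis at 11.50 days. `flower_stages()` carries this
as data. Two points were deliberately left as metadata rather than
hard-coded interpretation:

* the youngest stage's age is reported both as 7.25 and 7.29 days in the
  field; we default to 7.25 and expose it as an argument;
* standard floral-stage nomenclature places anthesis at stage 13, but with
  11.50 days as the fourth of eight sampled ages only three sampled stages
  precede it, so a label-to-age map with four labelled preanthesis stages
  cannot be realised on this design. All computation therefore keys on
  `age_days` and on the `phase` derived from the (configurable) anthesis
  age; stage labels are decorative.

## Radiolabel flux estimation

A whole-inflorescence feeding experiment supplies, per replicate, the
radioactivity recovered in nine compound classes plus total uptake and
metabolised label. Two quantities are derived:

* **redistribution fractions**, `100 * bq_c / metabolized` — scale-invariant
  percentages of metabolised label per class. If the class sum deviates from
  the stated metabolised total the package warns and never silently
  renormalises, since the mismatch means label was lost or double-counted;
* **absolute fluxes**,
  `flux_c = (fraction_c / 100 * metabolized) / (SA * t)` in nmol hexose
  equivalents gFW^-1^ h^-1^, where `SA` is the specific activity of the
  precursor pool and `t` the feeding duration.

The specific activity is the crux. The experimentally correct divisor is
the *internal hexose-phosphate pool's* specific activity, which accounts
for isotopic dilution of the fed tracer; when only the feeding-solution
value (7 Bq nmol^-1^, 5 h here) is available, fluxes are lower-bound-biased
and the documentation of `absolute_flux()` says so. Recomputing the four
sink fluxes (sucrose, starch, cellulose, protein) from the packaged
reference partitioning with the feeding-solution value lands 8–16% below
the reference fluxes, consistent with modest pool dilution.

Fluxes are computed per replicate and then averaged ("mean of ratios"),
matching per-replicate experimental reporting; the estimate from
replicate-averaged label data ("ratio of means") is also returned because
the two differ whenever replicates differ and the difference is a useful
heterogeneity diagnostic. No sucrose-to-hexose stoichiometric rescaling is
applied: radioactivity already measures hexose-equivalent carbon.
`recovery` is treated as a measured pass-through and never recomputed — it
is not derivable from uptake and metabolised label in the reference data.

## Natural-abundance correction of isotopologue distributions

A measured mass-isotopologue distribution (MID) convolves tracer-derived
labelling with naturally occurring heavy isotopes of every atom in the
derivatised fragment. The correction model is linear:
`measured = C x`, where column `j` of `C` is the mass-shift distribution of
the species with `j` tracer carbons fixed as ^13^C (at the configured
tracer purity) and everything else at natural abundance, truncated to the
measured window. The corrected labelling `x` is recovered by non-negative
least squares and renormalised; mean fractional enrichment is
`E = sum(j * x_j) / n_tracer`.

Choices worth stating:

* **NNLS, not inverse-then-clip.** A plain matrix inverse followed by
  clipping negative entries breaks the sum-to-one guarantee under noise;
  NNLS keeps the estimate in the simplex up to renormalisation.
* **Abundance constants are data, not code.** Defaults are the standard
  terrestrial values (^13^C 0.0107, ^15^N 0.00364, ^2^H 0.000115,
  ^17^O/^18^O 0.00038/0.00205, ^29^Si/^30^Si 0.04685/0.03092,
  ^33^S/^34^S 0.0075/0.0425); all are configurable because correction
  conventions differ between laboratories.
* **Tracer purity defaults to 1.0** and enters as a binomial thinning of the
  fixed label positions.
* **Full-fragment correction when the formula is known**, carbon-backbone
  correction otherwise: derivatisation chemistry is often unreported.
* Measured channels beyond the tracer window carry no labelling information
  and are dropped (with a warning if they carry appreciable mass), which
  also makes the correction exactly stable under zero-padding.

The test suite validates the convolution against an exhaustive
isotopomer-enumeration oracle and round-trips noiseless simulated MIDs for
formulas up to eight carbons across the whole enrichment grid with error
below 10^-9^.

The reported "labelled amount" is `pool_amount * E` — our declared
convention; whether published per-metabolite label accumulations are pool ×
enrichment or a differently weighted sum is not stated in the source
material, so the definition is documented rather than assumed elsewhere.

## Stage-profile statistics

Raw abundances are normalised by fresh weight and internal standard
(`value / (fw_mg * istd)`); heatmap matrices take the log~2~ *of the stage
mean* (not the mean of logs, matching the display convention), optionally
row-standardised; boxplot tables divide replicate values by the compound's
mean at the youngest stage.

Pairwise group comparisons use a two-sample t-test computed from summary
statistics, with a compact letter display built by insert-and-absorb.
Two conventions were genuinely open:

* **Pooled versus Welch.** The default is the pooled (Student) test with
  `df = n1 + n2 - 2`; Welch is available via `var_equal = FALSE`.
* **What the printed dispersion means.** `spread = "sd"` (default) treats it
  as a per-replicate standard deviation, `"se"` as the standard error of
  the mean.

The defaults were fixed by reproducibility: published compact-letter
patterns for summary tables of this design (three phases, n = 3) are
reproduced exactly by the pooled/sd configuration for every cross-checked
row, while Welch-on-se reproduces none of the three-letter patterns. Raw
(not log) scale is used, which the same cross-checks support. No
multiple-testing correction is applied across compounds for letter
displays — the published convention reports raw thresholds at 0.05 with a
stricter bold flag at 0.01.

## Correlation networks

All-pairs Pearson correlations use pairwise-complete observations; p-values
come from the exact t transform `t = r * sqrt(n - 2) / sqrt(1 - r^2)`.
Edges require `p <= 0.05` *and* a strict threshold on signed r: 0.65 for
metabolite–metabolite networks, 0.80 for transcript–metabolite, 0.82 for
transcript–transcript. Although thresholds are sometimes written against
"r²" in figure legends, negative-correlation counts only make sense on
signed r, which is the interpretation used. Ties sitting exactly at a
threshold are excluded (strict inequality). Correlations are computed
across all stage-by-replicate samples by default, not stage means — the
choice is configurable because source material rarely states it; the two
options give different pair counts and any consumer of the counts should
report which was used. Raw p ≤ 0.05 without multiple-testing correction
matches the published convention for thousands of simultaneous pairs; a BH
mode would be easy to add but is deliberately not the default.

Node degree and betweenness centrality (shortest-path, unweighted,
unnormalised, via igraph) annotate every network; isolated nodes are
dropped. Networks export to GraphML (typed attributes) and edge-list CSV.

## The transcript funnel

Counts pass through four stages: (1) genes with fewer than ten reads in
total are removed (strict less-than; a per-sample mode exists); (2)
log~2~-CPM with a 0.5 pseudo-count; (3) a developmental trend filter; (4)
per-contrast differential tests and k-means profile clustering.

The trend filter encodes the assumption that real developmental change is
smooth and gradual: each gene is fit by least squares on a 3-df orthogonal
polynomial basis of floret age and tested against the intercept-only model
with an F-test, BH-adjusted across genes. A "second-degree polynomial with
3 df" is self-contradictory (degree two has two non-intercept df); the
3-df smooth basis honours the stated degrees of freedom and the smoothness
rationale, and the basis dimension is an argument.

Differential tests are ordinary Welch t-tests with BH within contrast.
Empirical-Bayes variance moderation is deliberately not reimplemented: the
funnel's structure is what this package provides, and an unmoderated test
keeps the statistics transparent. The cost is real and worth knowing: with
three replicates per stage the Welch test has ~4 df, so even 4-fold planted
changes reach near-complete recall at the raw 5% level but only ~60% recall
after BH at FDR 0.05. Analyses needing maximal per-contrast power should
use a moderated-variance tool; the funnel accepts its output unchanged.

K-means runs on row-standardised stage-mean profiles with 25 restarts under
a fixed seed; k defaults to 6 (the source material does not state one).
Each cluster is summarised by its centroid's step across the onset of
anthesis (last preanthesis stage → anthesis stage), so clusters with sudden
and opposite behaviour at flower opening can be identified directly.

## The synthetic-data generator

The generator reproduces the *structure* the analyses assume, with defaults
fixed to the study design: 8 stages × 3 replicates and ~130 classed
compounds for metabolites; negative-binomial counts with quadratic log-scale
age trends, a null fraction, and planted near-zero genes for transcripts
(3 replicates, library size 10^6^ with 10% CV); binomial labelling
convolved with natural abundance for MIDs; and five replicates at 30%
lognormal noise for the ^14^C experiment, matching the experimental n.
Multiplicative lognormal noise (mean 1) is the metabolomics convention for
abundances; fresh weight and internal standard are drawn with 10% CV around
30 mg and 1.0 and are baked into the raw values so normalisation recovers
the noiseless signal exactly at zero noise. Labelling positions are i.i.d.
per carbon at the true enrichment — the simplest model consistent with
total-incorporation reporting.

Each generator is inverse-consistent with its analysis counterpart: at zero
noise the estimators recover the planted truth to 10^-9^ or better, and at
the design noise levels the calibration tests quantify coverage, size and
power. What the generator does *not* emulate — chromatography artifacts,
batch effects, organ-level heterogeneity within florets, count outliers —
bounds what passing tests can say about real data: they certify the
estimators, not the instruments.

## Numerical and size choices

Problem sizes in the tests and the acceptance script are chosen to exercise
the statistics at full fidelity while staying quick: 130 compounds for
network counts, 2,000 null plus 200 alternative genes for filter
calibration, 500 repetitions of the five-replicate flux experiment, and an
exact 720-permutation null for the six-sample correlation cross-check.
Degenerate inputs are handled explicitly: zero-variance variables produce
missing correlations with a warning; constant profile rows cannot be
z-scored and are flagged; a zero reference-stage mean drops the compound;
zero metabolised label is an error, not a NaN. Missing cells are preserved
as missing throughout — an absent measurement is never coerced to zero.

## Known limitations

* Fluxes computed with the feeding-solution specific activity are lower
  bounds; per-replicate internal-pool specific activities, when available,
  should be passed explicitly.
* The letter display reproduces summary-statistic tests; it does not see
  replicate-level non-normality.
* The correlation p-values assume the t transform; at very small n the
  exact permutation null deviates by up to ~0.1 in p on single pairs.
* Unmoderated per-contrast tests trade power for transparency at n = 3.
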