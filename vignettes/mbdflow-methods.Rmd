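---
title: "Models and methods behind mbdflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mbdflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

mbdflow analyses enrichment-based (MBD-capture) cfDNA methylome
sequencing at the resolution of 300-bp genomic windows. This vignette
explains the models the package assumes, the parameters that matter and
why their defaults are what they are, what the synthetic-cohort generator
does and does not emulate, and the numerical choices made where the design
was genuinely open.

## The measurement model

An MBD capture experiment pulls down methylated DNA fragments, so the
number of fragments landing in a window grows with two things at once:
the window's methylation level β ∈ [0, 1] and its CpG count *d* (a window
with no CpGs cannot be captured no matter how "methylated" its region is,
and capture saturates once a fragment carries many methyl-CpGs). The
package models the expected fragment count of window *j* in a library of
*L* fragments as

> E[c_j] = L · w_j / Σ_k w_k, with w_j = b + β_j · g(d_j), g(d) = d^a / (k^a + d^a),

where *b* is a methylation-independent background capture level and
*g* is a monotone, saturating density response. Observed counts are
negative binomial around that mean with dispersion φ
(Var = μ + φμ²). This forward model is the package's own construction:
it reproduces the qualitative facts the downstream pipeline relies on —
enrichment grows with β and with CpG density, saturates at high density,
and is over-dispersed — and the calibration stage is designed to invert
exactly this class of model.

Counts are made comparable across samples by TMM normalization against a
pooled reference (trim 30% on M-values and 5% on A-values,
inverse-variance weights), giving nrpm = count / (library size × factor)
× 10⁶. The normalization factors are anchored to the pooled reference
(its own factor is exactly 1) rather than re-centered, so nrpm values are
directly comparable to the reference pool. A consequence worth knowing:
TMM's precision weights are not perfectly scale-free, so multiplying a
sample's counts by a constant reproduces its nrpm to within ~0.2%, not
exactly.

## Blind calibration of β-values

Because w_j confounds β and *d*, a raw nrpm value carries no absolute
methylation meaning. The package calibrates nrpm to β *blindly*, i.e.,
using only the density structure of a pooled reference sample, no
external standards:

1. windows are stratified by CpG count (strata 0, 1, ..., 9, 10–11,
   12–15, 16–19, 20–24, 25+);
2. within each stratum, `bg(d)` is the mean nrpm of the lowest decile —
   those windows are taken to be unmethylated;
3. `full(d)` is `bg(d) + (u(d) − bg(d)) / β₀`, where `u(d)` is the mean
   nrpm of the upper decile and β₀ is the methylation level those
   top-decile windows are assumed to average;
4. `full(d)` is made non-decreasing in *d* by weighted isotonic
   regression (pool-adjacent-violators weighted by stratum support), and
   under-supported strata (< 50 windows) are interpolated from their
   neighbors.

β̂ is then the linear read-off clamped to [0, 1]. The estimator only
works if every density stratum actually contains both unmethylated and
methylated windows; real genomes provide this (most CpG islands are
unmethylated but imprinted and silenced islands are not; open-sea DNA is
mostly methylated with hypomethylated domains), and the simulator
reproduces it.

Two constants deserve their own paragraph.

**The anchor β₀ = 0.9.** Ranking windows by *observed* nrpm selects both
the upper tail of the methylated mode and upward counting noise, so the
top decile's mean sits above the methylated-mode mean. Parameter recovery
against the package's own forward simulator across seeds puts the
top-decile mean at ≈ 0.89 of the true fully-methylated level; anchoring at
0.8 made every β̂ about 12% too small and broke the calibration inverse
property, so the default is 0.9. It is a configurable assumption about
the reference methylome, not a universal constant.

**The NA threshold (20 nrpm).** Windows whose calibrated dynamic range
`full(d) − bg(d)` is below `min_expected` cannot resolve a β and return
`NA`. At the package's default scale (2×10⁵ fragments over 20,000
windows) one fragment is 5 nrpm, so a 20-nrpm range is about four
fragments — the smallest denominator for which a β estimate is more than
counting noise. In practice this masks windows with fewer than ~4 CpGs,
which is also the regime where the capture assay is genuinely blind.

## Quality control

Two sample-level checks mirror standard practice for enrichment assays:
the *relative enrichment score* (count-weighted mean window CpG density
over the genome-wide mean; pass ≥ 2.5 — a failed capture gives ≈ 1), and
the *always-methylated window check*: a designated list of windows known
to be methylated in essentially all tissues must read out at β ≥ 0.8 in
at least 40% of cases, missing values counting as failures. The simulator
designates 200 such windows (a scaled stand-in for the hundreds used with
real genomes), drawn from the densest background (non-CGI) windows —
always-methylated CpG sites carry CpGs by definition, and a window
without measurable density could never pass the β ≥ 0.8 read-out. These
known-methylated windows are excluded from calibration fitting, where
they would contaminate the lowest-decile background estimate of their
density strata.

## Differential methylation

Each window gets a negative-binomial GLM on counts with a two-group
design. CpG density enters through the offset,
log(library size × factor × full(d) / 10⁶), so the group coefficient is
interpretable as a change in methylation signal rather than a density
effect. Dispersions are estimated per window and shrunk toward the fitted
mean–dispersion trend by empirical Bayes (the edgeR machinery — for this
standard step the package deliberately calls the field's reference
implementation rather than re-deriving it); significance is a
likelihood-ratio test (better small-sample calibration than Wald), BH
correction runs across the tested windows only (those passing the
nrpm > 1 prefilter), and biological relevance is enforced by a Δβ filter
on group mean β̂ differences — 0.5 for high-purity tissue contrasts, 0.3
for cfDNA contrasts, where tumor fractions dilute effects.

One asymmetry is intrinsic to the assay and shows up in every power
analysis: *hypomethylation of CpG-poor windows is invisible*. A window
with 0–1 CpGs contributes background-level counts whether methylated or
not, so a spiked β difference there cannot be recovered at any sample
size. Power statements in the tests and the acceptance script therefore
quantify recovery over assay-detectable windows (CpG count ≥ 5); on those,
recovery of Δβ = 0.8 spikes at FDR 0.001 is essentially complete with
10 + 10 samples. This is also why a capture assay predominantly reports
tumor-hypermethylated DMRs in CpG-dense context.

## Spike-in mixtures and dilution ladders

Mixtures are built at the count level: a multinomial downsample of
round(p·M) fragments from a tumor source plus M − round(p·M) from a
background source (or two backgrounds for negative mixtures). Count-level
mixing is the resolution the classifiers consume; read-level resampling
would only add an expensive identity operation. Mixture totals are drawn
log-uniformly over a configured range — real cfDNA libraries vary in
depth over orders of magnitude, and the classifier must not learn depth
as a feature.

The dilution ladder for limit-of-detection experiments mixes one deep
tumor source into one deep background (10⁶-fragment sources, 8×10⁵
fragments per rung, proportions 0–2%), with replicate ladders and the
median score per rung. Depth matters here: LoD is a property of the
score's small-signal behavior, and at routine depth the per-rung
counting noise swamps the sub-percent signal. This mirrors how such
experiments are run in practice, where dilution series are sequenced far
deeper than routine samples.

## Detection ensemble

Features are β̂ values over the detection windows with missing values
encoded as 0 — bounded, depth-invariant, and honest about "no signal"
(the alternative, nrpm features, is available but mixes depth into the
feature scale). Each of the (by default 100, here 20 in desk-scale runs)
members trains on mixtures whose *every* source falls into the member's
80% source subsets — the strict rule, so no member can be influenced by a
held-out source through either mixture component. Cutoffs maximize
balanced accuracy on out-of-bag median scores over a 0.01 grid, with ties
broken toward the smallest grid value (deterministic, and favors
sensitivity). Prediction for a sample related to a training source uses
only members that never saw that source, which is assertable from the
recorded subsets.

## Subtyping

Cell lines are labelled by marker expression with the threshold-of-nine
rule (ASCL1/NEUROD1 co-expressors are excluded from training;
POU2F3/YAP1-only samples form the double-negative class). Array β
profiles become pseudo count columns through the calibration lookup
(max probe β per window; windows without probes are *masked*, not
imputed — zeros would mimic hypomethylation). Marker windows are the 50
most hyper- and 50 most hypomethylated significant windows per contrast
of the target against each other expression group; with three contrasts
that is up to 300 windows per target before deduplication. Two ensembles
(NEUROD1-vs-rest, ASCL1-vs-rest, with ASCL1 sources undersampled to
within one source of the NEUROD1 + double-negative basis) are thresholded
sequentially: the NEUROD1 cutoff applies first, the ASCL1 cutoff is
optimized only over samples the NEUROD1 classifier left unclaimed, and
the pair is found by exhaustive 2-D grid search on the mean balanced
accuracy (lexicographically smallest optimal pair). Samples below the 4%
tumor-fraction gate are `not_evaluable`: below that fraction the
dilution experiments show the scores are not trustworthy, and a wrong
subtype call is worse than none.

## Methylation score and survival

The methylation score is the mean β̂ over the detection windows, with
missing windows excluded from numerator and denominator — zero-filling
would systematically deflate scores of shallow samples and turn depth
into spurious prognosis. Scores are dichotomized at the median (ties to
"low", so "high" means strictly above). Survival analysis is standard:
Kaplan–Meier/log-rank for groups, Cox proportional hazards for continuous
and dichotomized scores adjusted for age, sex and stage (encoded
limited/extensive), model comparison by AIC/BIC/concordance, and
proportional-hazards checks via scaled Schoenfeld residuals.

## What the simulator emulates, and what it does not

The generator reproduces the statistical structure the pipeline's
assumptions rest on: CGI-like bimodal CpG density organised in blocks (so
shores and shelves exist), a normal methylome bimodal within density
classes, tumor methylomes sharing pan-tumor DMRs (69% hypermethylated,
~75% in CGI/shore/shelf context, hypermethylation placed on unmethylated
islands), subtype-specific marker blocks, capture counts from the forward
model above, cfDNA as exact convex β mixtures at known tumor fraction,
array probes with truncated Gaussian noise (≥ 1 probe per covered
window, some windows with several), marker-gene expression, and
exponential survival with log-hazard linear in standardized tumor
fraction.

Default scale: 20,000 windows and 2×10⁵ fragments per library — small
enough for a desk run, while keeping per-window counts (≈ 10 on average,
~100 on methylated islands) in the regime of real window-level nrpm data.
The default dispersion φ = 0.005 represents technical resampling noise at
fixed β; biological variation between samples enters through the
methylome mixtures themselves, not through φ. Pipeline-level validation
(detector, subtyper, survival) uses 8,000-window cohorts with 20-member
ensembles — the problem sizes at which the full chain still exercises
every code path.

What passing tests do **not** show about real data: fragment-level
artifacts (GC bias, duplicates, mapping error) are absent; normal cfDNA
has no donor-to-donor methylome variation beyond counting noise, so real
classifier specificity will be lower than synthetic; copy-number signal
is absent (tumor fractions are inputs, never estimated); and the survival
generator's hazard depends on tumor fraction only, so the score–outcome
association emerges through the score's correlation with burden rather
than being wired in — which is the point, but also means covariate
confounding structures of real cohorts are not represented.

## Numerical choices and degenerate inputs

* Window coordinates are 0-based half-open; fragment midpoints
  floor((start+end)/2), boundary midpoints go to the right-hand window;
  trailing partial windows are dropped.
* Isotonic adjustment of `full(d)` uses weighted pool-adjacent-violators;
  empty calibration strata interpolate from neighbors with a warning.
* Mixtures requiring more fragments than a source holds raise an error
  naming the source; fragments on unknown contigs are tallied, not fatal.
* Non-convergent GLM windows are reported with p = 1 and flagged, never
  dropped silently; all-constant windows are forced to p = 1.
* Ensemble members drawing a single-class training subset are re-drawn
  (bounded retries), then error.
* The sequential cutoff search skips grid cells whose ASCL1-eligible set
  lacks a class; ties break to the lexicographically smallest pair.
* Every stochastic step derives its seed deterministically from the
  config seed and a step label, so a cohort, a mixture collection or a
  trained bundle is bit-reproducible from one integer.

## Known limitations

The blind calibration is a documented stand-in for an unpublished
procedure; its β₀ anchor is an assumption about the reference methylome.
The array conversion inherits the calibration's biases. Ensemble
determinism holds for single-threaded training. The subtype caller
assumes the three-class world of its training data; a sample from an
unrepresented class will be forced into one of the three calls above the
gate.
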