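---
title: "Presence/absence degradation of taxonomic profiles: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Presence/absence degradation of taxonomic profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(presaboost)
```

## The question the package operationalises

Host-phenotype classification from metagenomes is usually fed with
relative-abundance profiles: per-sample vectors of taxon proportions summing
to one. A recurring empirical observation is that *which* taxa are detected
often carries nearly all of the discriminative signal, with the actual
proportions adding little. `presaboost` turns that observation into a
controlled, repeatable experiment: degrade profiles to presence/absence at a
detection threshold, evaluate the same classifiers on the same
cross-validation splits for both profile types, and decide with a paired
statistic whether the degradation cost is real.

Because the interesting failure modes (detection limits, compositional
closure, batch structure) are properties of the data-generating process, the
package pairs the analysis pipeline with a generative simulator in which the
truth is planted, so every claim the pipeline makes can be checked against
what was actually put in.

## Profile model and degradation

A profile table holds fractions in [0, 1]; MetaPhlAn-style inputs are percent
on disk and divided by 100 on entry. All thresholds elsewhere in the package
are expressed in percent at the interface — the convention the field uses —
and converted once. Rank extraction keeps only rows whose *deepest* populated
rank matches the request, so genus rows are never double-counted with their
species, and strain-suffixed rows are excluded. When species rows leave
unclassified mass behind (row sums below 1), the default is to warn and leave
the mass visible; `renormalize = TRUE` restores closure explicitly. Rank
aggregation sums species sharing an ancestor and conserves per-sample mass to
machine precision.

Binarization maps an entry to 1 iff it is strictly positive **and** at least
the threshold. The boundary convention follows from forcing values *below*
the threshold to zero: a value exactly at the threshold survives. Degradation
always happens after any rank aggregation, never before, because the
scientific object is the rank-level profile. Binarizing an already binary
table at threshold 0 is the identity.

The default sweep {0, 0.0001, 0.001, 0.01, 0.1}% spans the support indicator
at one end and a threshold that erases most low-abundance taxa at the other.
Presence sets are nested along the sweep, which the tests assert per sample.

For 16S OTU tables the standard compendium filters are applied literally and
in order: samples with fewer than 100 reads are dropped first; OTU read and
prevalence filters (fewer than 10 reads, present in less than 1% of samples)
are then computed on the surviving samples; relative abundances are computed
before genus-unannotated OTUs are discarded, so dropped mass remains visible
in the row sums. Whether prevalence should be counted before or after the
sample filter is genuinely ambiguous; computing it on survivors is this
package's documented choice, not a claim about anyone else's code.

## The synthetic cohort generator

The generator is the package's definition of "study conditions", not a
tuning dial. Per taxon `t`: a baseline prevalence `pi_t ~ Beta(2, 4)` and a
log-abundance location `mu_t ~ N(0, 1.5^2)` (natural log). Per sample:
presence indicators `z_t ~ Bernoulli(pi_t^class)`, latent abundances
`exp(mu_t + sigma z)` with `sigma = 1` for present taxa, closure to
proportions, then counts from a multinomial at the sample's read depth;
observed relative abundance is counts/depth, so rows sum to one exactly and a
taxon at latent proportion `p` is detected with probability
`1 - (1 - p)^depth`.

Defaults describe a mid-sized shotgun-style case/control study: 200 vs 200
samples, 300 taxa, constant depth 1e5 reads. The depth was chosen so the
mechanical detection floor (1/depth = 1e-5 in relative abundance, i.e.
0.001%) sits where marker-based shotgun profiling typically loses species;
the simulator deliberately exposes depth as its only detection knob and does
not model profiler sensitivity separately.

Two disjoint biomarker regimes can be planted:

* **Prevalence-shift** taxa differ between classes in presence probability
  (default 20 taxa at |delta| = 0.4, alternating case-enriched and
  case-depleted, clipped to [0, 1]). Their optional `signal_location`
  parameter places them near the detection floor — `log(0.03)` puts their
  typical proportion around 1e-4 — which is how the threshold-sweep
  experiments make "rare biomarker" cohorts.
* **Abundance-shift** taxa are fully prevalent in both classes and differ
  only by a log-fold change (default log 3, alternating sign). Their
  log-abundance location is pinned one SD above the population mean rather
  than drawn: these are "present everywhere" taxa by definition, and keeping
  them clear of the detection floor is what makes the construction
  meaningful — a down-shifted taxon sitting near 1/depth would otherwise turn
  its fold change into an observed prevalence gap, and presence would carry
  label information the design promises it does not.

Even with that guarantee, presence/absence profiles of an abundance-shift
cohort are not exactly uninformative: shifting the proportions of 20 taxa
moves everyone else's proportions through closure, which nudges taxa near the
detection floor. On the default cohort this residual leakage leaves the
presence-profile classifier at AUC ≈ 0.5–0.58 against ≈ 1.0 for the abundance
profile — the contrast the framework exists to expose.

Multi-study collections share one draw of taxon parameters and planted
signals; each dataset then multiplies prevalences by `exp(N(0, b^2))`
(clipped) and shifts locations by `N(0, b^2)`, with `b` the batch-effect
scale. Rarefaction subsamples counts without replacement (multivariate
hypergeometric), so it can only lose detected taxa.

One integer seed governs everything; per-sample, per-dataset, per-fold
sub-streams are derived deterministically from it, so identical seeds give
bit-identical cohorts and evaluations.

### What the simulator does not emulate

No phylogenetic correlation between taxa, no longitudinal structure, no
strain-level variation, and no profiler-specific false positives: taxa are
conditionally independent given the planted parameters. Passing tests on
synthetic cohorts therefore demonstrate that the pipeline's statistics do
what they claim under a known sparse compositional generative model — not
that any particular real dataset will behave the same way.

## Classification protocol

Splits are stratified k-fold (default k = 10), repeated (default 20
repetitions; the heavier built-in experiments use 3–5 to keep runtimes in the
minutes), and materialised as an explicit reusable object: every arm —
abundance, each threshold, each classifier — sees the identical partitions,
which is what makes fold-level differences paired. Five classifier families
are wrapped behind one interface: random forest (500 trees, `sqrt(p)` split
candidates, Gini), lasso and elastic net (penalized logistic regression;
strength tuned by internal 5-fold stratified CV over 50 values log-uniform in
[1e-4, 10^-0.5]; elastic-net mixing over {0.1, 0.5, 0.7, 0.9, 0.95, 0.99,
1}), and SVMs with linear or RBF kernels.

Where the protocol is underdetermined, the package makes these documented
choices: case-scores are class probabilities for RF/lasso/enet and signed
decision values for SVMs (ranking metrics only need an ordering); hard calls
for precision/recall/F1 threshold probabilities at 0.5 and decision values at
0; features are left unscaled for RF while the penalized models standardize
on training data only; SVM cost is tuned over a 6-point log grid 1e-2…1e3 by
internal 5-fold CV maximizing AUC, mirroring the treatment of the penalized
models; and the lasso/enet strength grid is read as uniform in log10 because
its endpoints are written as powers of ten. Hyperparameter tuning never sees
test-fold samples, which the test suite asserts by intercepting the fitting
call.

LODO fits on the union of all datasets but one and scores the held-out
dataset, with the taxon universe unioned and absent taxa imputed as zero.

## The paired repeated-CV statistic

With `d_ji` the fold-level metric difference between two arms,
`sigma_j` the per-repetition SD over the k folds (n−1 divisor, recorded
here because conventions differ), and

SE = (1/R) Σ_j sigma_j / √k,

the 95% CI is `mean(d) ± t_{0.975, k−1} · SE` and `t = mean(d)/SE` with a
two-tailed p at k−1 degrees of freedom (multiplier 2.26 at k = 10). The CI
and the t-statistic share one SE definition — the repetition-averaged
standard error — because the two must be mutually consistent; the CI then has
width exactly `2 t_crit SE`, which is asserted as an invariant. Degenerate
spread (SE = 0) is reported as t = 0, p = 1 when the mean difference is also
zero, and as p = 0 with an explicit flag otherwise; real data never hits
this, but a self-comparison of one arm does, and it must come out as "no
difference" exactly.

This statistic is known to be anti-conservative under cross-validation's
overlapping training sets, so the package's null check *bounds* the rejection
rate (< 0.3 at nominal 0.05 over 50 simulated null pairs) rather than
asserting calibration. Corrected resampled t-tests are deliberately out of
scope.

## Differential features

Abundance mode uses a two-sided Mann-Whitney U per taxon: exact by
enumeration when the smaller group has at most eight observations and the
data are tie-free, otherwise the tie-corrected normal approximation with
continuity correction. Presence mode binarizes internally (default 0%) and
applies a two-sided Fisher exact test to the per-class presence counts. Both
modes are corrected with Benjamini-Hochberg across the taxa of one cohort and
one mode — the FDR family is per-cohort, per-mode, matching how per-dataset
significant-taxon counts are reported in this literature. Constant-zero taxa
get p = 1 by convention, flagged, and can never be significant.

Direction is assigned only at q < alpha: by the higher-prevalence group in
presence mode and the higher mean-rank group in abundance mode (mean rank,
not mean abundance, because it is the quantity the U statistic orders; a
documented stand-in where the convention is unstated). The concordance report
counts taxa significant in both modes among those significant in either,
direction conflicts among taxa significant in either mode (a conflict
requires both directions assigned), and the Spearman correlation of
−log10 p over the union of significant taxa.

## Numerical and degenerate-input choices

AUC is computed by midranks, algebraically identical to pair counting with
ties worth one half; AUPRC is average precision with tied scores collapsed
into single thresholds. Precision and F1 are reported as 0 when no sample is
called positive. Fisher p-values are clamped to 1 against floating-point
overshoot. Samples that draw zero present taxa are redrawn up to 100 times,
then reported as an error. The canonical TSV writer formats doubles with 17
significant digits so write/read round-trips are exact.

## Observed properties worth knowing

On the default prevalence-signal cohort, presence/absence and abundance
profiles classify identically within noise (mean AUC gap well under 0.03, no
rejection by the paired test), while the abundance-shift cohort splits the
two arms by ≈ 0.45 AUC. Sweeping thresholds on a detection-limited cohort
leaves AUC flat through 0.001% and then erodes it sharply.

Under the simulator's batch model, random forests do *not* show a CV-to-LODO
drop even at large batch scales: the shared multiplicative perturbation
shrinks the within-dataset class contrast as much as it shifts the
cross-dataset distributions, and LODO's nine-fold training-size advantage
dominates. The penalized linear models do show the canonical drop (mean LODO
AUC well below mean within-dataset CV AUC at batch scale 2.5). This is a
property of the batch model, not a claim about real cross-study transfer,
where tree ensembles are also known to degrade.

Problem sizes used by the built-in experiments: 200 vs 200 samples and 300
taxa for single-cohort runs (5 CV repetitions; 3 for the five-arm threshold
sweep), ten datasets of 40 vs 40 for the transfer experiments. These sizes
make every stochastic check reproducible in minutes on a single core while
keeping the Monte-Carlo error far below the asserted margins.

## Limitations

The generator's conditional independence between taxa understates the
correlation structure of real communities; the paired t-test is
anti-conservative by construction; compositionally-aware differential
methods (e.g. ratio-based transforms) are intentionally not implemented; and
nothing here profiles reads — the pipeline starts at taxonomic tables.
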