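---
title: "Methods: group-level encoding/decoding of anticipatory reward representations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: group-level encoding/decoding of anticipatory reward representations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The analysis problem

A subject anticipating a probabilistic reward sees a geometric cue whose
fill signals the mean of the upcoming reward distribution and whose color
signals its variability. Within one subject the perceptual features and the
reward features are perfectly confounded — fill *is* mean reward as far as
that subject's data are concerned — so no within-subject analysis can tell
a reward representation from a visual one. The design resolves this at the
group level: cue–outcome mappings are counterbalanced across subjects, so
that pooled over the group the perceptual and reward regressors are exactly
orthogonal. All models in this package are therefore fitted once per time
bin on the concatenated trials of all subjects, with fixed per-subject
intercepts; what they detect are multivariate activity patterns shared
across subjects and predictive of the reward dimension.

## Models and assumptions

Per 10 ms bin, with data matrix $X$ (trials × channels), numeric feature
$y$ and subject indicator matrix $S$:

* **Encoding MANOVA** $X = y\beta' + S\Gamma + E$. Hypothesis and error
  cross-products for the $y$ term give the Pillai–Bartlett trace
  $V = \sum_i \lambda_i/(1+\lambda_i)$, $\lambda_i$ the eigenvalues of
  $E^{-1}H$, tested via the standard F approximation — exact for a 1-df
  hypothesis, which is the default here. The implementation residualizes
  $X$ and $y$ against $S$ (Frisch–Waugh) and uses the identity
  $V = c'T^{-1}c / y'y$ with $T = X'X$ and $c = X'y$ (all quantities
  subject-centered), which makes permutation loops a single cross-product;
  its equality with `stats::manova` is pinned by tests to $10^{-10}$
  relative tolerance.
* **Decoding ANOVA** $y = Xb + Sc + e$, block F test of all channel
  coefficients against the $S$-only model. For a numeric single-df feature
  the overall encoding and decoding F statistics coincide algebraically;
  the two models differ in their *channel contribution* tests, and that
  difference is what the causal classification exploits.
* **Channel contributions.** Encoding: the $y$ term of $X_k \sim y + S$,
  uncorrected — sensitive to any marginal relation, direct or mediated.
  Decoding: the 1-df F for dropping channel $k$ from the full decoding
  model, computed via the squared-$t$ identity — sensitive only to *unique*
  predictive contribution. A channel that merely relays another channel's
  signal passes the first and fails the second (indirect); a channel
  correlated with an encoding channel's noise but not with $y$ fails the
  first and passes the second (brain-state context).

Assumptions worth stating: trials are exchangeable within subject under the
null (the permutation schemes rely on this); noise is treated as Gaussian
for the F approximations and the AIC conversion; subject effects are fixed
intercepts, not random effects — the group model asks whether a *common*
pattern exists, not how it varies across subjects.

## Decision rules and boundaries

Significance is strict ($p < \alpha$, default $\alpha = 0.05$). The
indeterminate band for the causal rules is $[\alpha, 0.10]$, closed at both
ends, so that every $(p_{enc}, p_{dec})$ pair maps to exactly one of
direct / possible-direct / indirect / context / undetermined. (The source
literature prints the band inconsistently as "0.5 < p < 0.10"; the only
internally consistent reading, adopted here, is 0.05–0.10.) Channels are
classified only in bins where the overall multivariate model survives
cluster correction; everything else is undetermined.

The cluster test forms clusters from maximal runs of consecutive bins with
uncorrected $p <$ `cluster_alpha` (default 0.05) and scores them by mass
(sum of F values); the null permutes $y$ within subject and records the
maximum cluster mass, and cluster p-values use add-one smoothing,
$(1+k)/(n_{perm}+1)$. Mass-vs-extent and the forming threshold are not
dictated by the method's definition, so both are configuration options with
these defaults.

## Cross-prediction and the stability statistic

The coefficient pattern $\beta_s$ fitted at source bin $s$ predicts target
bin $t$ as $\hat X_t = y\beta_s'$ after within-subject centering — subject
intercepts are nuisance parameters and are refit (equivalently, removed) at
the target; only the feature pattern is transferred. Explained variance is
multivariate, $1 - \mathrm{SSR}/\mathrm{SST}$ with both sums taken over all
channels about subject means; it is negative when the transferred pattern
mispredicts. Per target bin, trial labels are permuted within subject
(default 1000 times) and entries with $p > 0.05$ or negative explained
variance are set to zero.

Two properties of this zeroing rule are worth knowing. First, the diagonal
can never be zeroed: the in-bin model is evaluated against the very labels
it was fitted on, so its permutation p is structurally $\approx
1/(n_{perm}+1)$. Calibration claims about the zeroing rate therefore refer
to off-diagonal cells. Second, when models fitted on one feature are scored
against data arranged by another (the cross-feature transfer check), the
noise-level coefficients can align with a strong planted signal by chance
(sign is a coin flip), so isolated cells may pass the permutation test with
explained variance orders of magnitude below the within-feature fit; the
meaningful statement is that the transferred explained variance is
negligible, not that every cell is exactly zero.

The stability statistic sums the off-diagonal thresholded entries whose
source *and* target bins fall in the second half of the window (default
split at 1000 ms) and subtracts the first-half sum. Its null jointly
permutes the time labels of rows and columns (default 100,000 draws,
reduced in tests) — a permutation that provably preserves the total
off-diagonal sum, so only the split statistic varies. The same machinery on
the diagonal tests for a difference in in-bin encoding strength, and the
whole analysis can be repeated on the matrix row-normalized by each source
bin's own fit, which separates "the representation became more stable" from
"the models were simply fitted better in the second half".

## Model evidence

Residual sums of squares convert to AIC in the Gaussian form
$n\ln(\mathrm{RSS}/n) + 2k$, with additive constants omitted — differences
between models fitted to the same data are unaffected, which the tests
verify against `stats::AIC`. For the pooled (multivariate) comparison the
observations are trial–channel cells and RSS is the trace of the residual
cross-product; per-channel comparisons use single-channel regressions. All
compared models share the same parameter count, so the intercept bookkeeping
cancels. A metric (CV, SD decorrelated from mean reward, variance
decorrelated likewise) or a feature (mean vs variability) is preferred only
when the summed AIC margin exceeds 3. Decorrelation subtracts the metric's
mean within each mean-reward level, which makes it exactly orthogonal to
any function of the level and is idempotent. By default the sums run over
cluster-significant bins (all-bins is available), matching the logic that
individual channels are only interpreted where the overall model is
reliable.

## The synthetic-data generator

The generator emulates the study conditions the analysis assumes: a
3 × 3 factorial of mean reward (£1, £2, £3) by CV (0.08, 0.16, 0.24); every
cue equally often per subject; fill mapped to mean reward by one of two
assignments (half fill always medium, empty/full counterbalanced) and color
to CV by one of three rotations, crossed so that any multiple of six
subjects is exactly balanced; response-hand assignment alternating.
Channels are planted as:

* **direct**: $x = \beta(t)\,y + \eta + \varepsilon$, with $\beta(t)$ zero
  before the feature's onset latency and a shared noise component $\eta$
  where a context channel references the channel;
* **indirect**: an affine copy of its parent direct channel plus noise —
  all of its feature dependence is mediated;
* **context**: loads on the parent's shared noise only — correlated with
  the direct channel, exactly zero marginal dependence on $y$.

Reward outcome sets are the symmetric three-point construction
$\{m-\delta, m, m+\delta\}$ with $\delta = cv \cdot m\sqrt{3/2}$ and uniform
probabilities, which matches the stated mean and CV exactly with the fewest
assumptions; certainty equivalents invert the exponential utility
$u(c) = (1-e^{-ca})/a$ at the mean utility of the outcome set, with the
linear limit used for $|a| \le 10^{-8}$.

Representational drift is a spherical interpolation of the direct-channel
pattern between two random **orthogonal** unit patterns — orthogonalized so
that the planted drift magnitude is a fixed quarter turn rather than a
random angle, which would otherwise make the drift alternative
heterogeneous across replicates. Under `drift = "freeze"` the rotation
completes at the window midpoint and the pattern is constant thereafter;
`"none"` gives a stationary pattern.

What the generator does **not** emulate: spatially correlated sensor noise,
autocorrelated (1/f) noise in time, evoked transients unrelated to the
features, eye/muscle artifacts, or any biophysical forward model. Passing
tests therefore demonstrate that the statistics are correct and calibrated
under the design's idealized assumptions — not that real recordings satisfy
those assumptions.

## Preprocessing conventions

* Jump detection uses strict inequality (first differences exceeding
  3000 signal units); correction median-filters the full derivative with a
  21-sample window (the smallest odd window above 20) with reflect padding,
  and reconstructs by cumulative summation anchored at the first sample. A
  trace with no supra-threshold difference is returned untouched, which
  makes the operation idempotent. Correction runs per continuous channel
  trace.
* The low-pass is a first-order Butterworth applied forward once (matching
  the stated filter order); a zero-phase two-pass variant is available via
  `two_pass = TRUE`. The recursion is initialized at the DC steady state of
  the first sample so a constant trace passes through unchanged.
* Down-sampling is decimation by integer stride after filtering (the 80 Hz
  low-pass provides the anti-aliasing); baseline correction subtracts the
  per-trial, per-channel mean of the retained baseline-window samples, so
  the output's baseline mean is exactly zero.
* Bins are left-closed, right-open 10 ms intervals, centers reported at
  +5 ms; a −400..2000 ms window gives 240 bins and 0..2000 ms gives 200,
  with 2 samples per bin at 200 Hz.
* A trial flagged for several exclusion reasons is removed once and counted
  under each reason, so per-reason percentages need not sum to the total.

## Numerical and design choices

* Feature coding is numeric (1-df) by default — the decoding model predicts
  a scalar feature, and the encoding model is kept symmetric to it;
  categorical coding is available (`coding = "factor"`).
* "Significant" means $p < \alpha$ strictly, everywhere.
* Permutations of trial labels always act within subject, preserving the
  subject-intercept structure that the group concatenation relies on.
* All randomized procedures take explicit seeds and restore the caller's
  RNG state; replicated simulation studies derive per-replicate sub-seeds
  from a single master seed through one draw, never by seed arithmetic
  (seed + i patterns let streams collide across replicates and correlate
  them — this is observable as inflated family-wise error estimates).
* The utility fit minimizes squared error on the certainty-equivalent
  scale (the natural scale of the elicited data) over $a \in [-5, 5]$ per £
  with multistart at $\{-1, -0.1, 0, 0.1, 1\}$; a numerically zero RSS is
  floored (identically for both compared models) so the AIC comparison
  remains defined and penalties alone break ties.

## Simulation-study sizes

The calibration and recovery studies (`study_*` functions; also the basis
of `scripts/acceptance.R`) run at a desk scale chosen so that every
replicated experiment completes in seconds while leaving the tested
property unambiguous: 6 subjects × 108–216 trials, 2–6 channels, 6–25 bins,
120 permutations per cluster/cross-prediction test and 2000 time-label
permutations, with 100–1000 replicates depending on the study. Planted
effect sizes (e.g. β = 1.5 per £ at noise SD 0.5 for the classification
study, β = 1.2 at noise SD 1 for the stability study) are set where the
constituent tests have power near 1, since the properties under test —
label recovery, metric recovery, stability detection — are claims about the
algorithms at high SNR, while the null studies use the same designs with no
planted effect.

## Known limitations

* Clustering is over time only; no channel-adjacency (spatial) clustering.
* No source reconstruction, head modelling, or artifact inspection UI; the
  preprocessing chain starts from epoched traces.
* Fixed-effect subject intercepts mean the models quantify shared patterns;
  between-subject heterogeneity in pattern direction reduces power rather
  than being modelled.
* The zeroing rule's diagonal bias and the chance-alignment effect in
  cross-feature transfer (both described above) are properties of the
  procedure itself and are documented rather than "fixed".
* Ordinary least squares throughout; no regularized or cross-validated
  decoders.
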