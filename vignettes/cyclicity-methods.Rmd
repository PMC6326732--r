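---
title: "Cyclicity analysis: model, estimators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cyclicity analysis: model, estimators, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cyclicity)
```

## The model

Many multichannel physiological recordings — resting-state BOLD time
courses averaged over regions of interest being the motivating case — are
*cyclic but aperiodic*: channels pass through a consistent temporal
ordering ("leader–follower" structure) without a predictable period.
Classical spectral tools assume periodicity; lagged cross-correlation
assumes a common time scale.  Cyclicity analysis makes neither
assumption.  It treats the $d$-channel recording as a path
$X(u) \in \mathbb{R}^d$ and summarises it by the antisymmetric part of
its second-order iterated integral, the **lead matrix**

$$
A_{ij} \;=\; \tfrac{1}{2}\oint \bigl(x_i \, dx_j - x_j \, dx_i\bigr),
$$

i.e. the signed area enclosed by the projection of the closed path onto
the $(i, j)$ coordinate plane.  Iterated path integrals are invariant
under translation and under monotone reparameterisation of time, so $A$
captures the *ordering* of channel fluctuations while ignoring when, and
how fast, each cycle happens.  For a pair of sinusoids
$a\sin(t + \varphi_i)$, $b\sin(t + \varphi_j)$ traversed over $n$ periods,

$$
A_{ij} = n\pi\, a b \, \sin(\varphi_i - \varphi_j),
$$

which the test suite verifies against dense quadrature to $10^{-3}$
relative error.

The path must be closed for the area to be well defined: per channel we
subtract the linear ramp connecting first and last samples, then the
mean (`center_and_close()`).  Discretely, `lead_matrix()` uses the
shoelace formula with wraparound, which is exact for the
piecewise-linear interpolation of the samples — the natural quadrature
for sampled data, since any smooth quadrature differs only at
$O(\Delta t^2)$.

A real antisymmetric matrix has purely imaginary eigenvalues in pairs
$\pm i\mu$.  The eigenvector of the leading $+i\mu$ assigns each channel
a complex number: its modulus is the channel's **cyclic strength**, its
argument the channel's **phase** in the common cycle.  Two ambiguities
are intrinsic and propagate to every consumer: a global rotation (we fix
it by rotating the largest-modulus component to argument zero) and a
global sign — the direction of the cycle is not identifiable from $A$
alone, so phases are compared by `circular_rmse()`, which considers both
orientations.

When the signal mixes two harmonics, the second harmonic lives in a
different eigenspace: its channels collapse towards the origin of the
leading eigenvector and the second eigenvector pair is needed to resolve
them.  `spectral_decomposition()` therefore retains two pairs by
default.

## What the synthetic generator emulates — and what it does not

The cohort generator stands in for a resting-state study whose raw data
are not publicly deposited: 15 control-like and 32 patient-like
subjects, 33 channels × 300 samples per run, 2 sessions × 2 runs.  The
phase model is hierarchical:

* group template: evenly spaced phases $2\pi k/m$;
* subject template: group template + persistent $N(0, 0.5^2)$ offset per
  channel (the "fingerprint");
* run phases: subject template + run-level jitter, sd 0.1 rad for the
  control-like group and 0.6 rad for the patient-like group by default.

Channels are unit-amplitude sinusoids (10 cycles per run, a rate in the
infra-slow range when read at a 2-s sampling interval) plus white
Gaussian noise at a signal-to-noise *power* ratio of 20.  Amplitudes are
deliberately equal across groups: any group difference must come from
the consistency of the phase ordering, which is the premise under test.
Where the motivating study reports no value (amplitudes, cycle count,
noise colour), these defaults were chosen once as plausible for
infra-slow BOLD fluctuations and are not revisited.

Passing tests on this generator show that the estimators recover planted
ordering structure under additive white noise and phase jitter.  They do
*not* show robustness to features of real fMRI the generator omits:
hemodynamic convolution, scanner drift and physiological noise (which
are neither white nor stationary), spatial correlation between regions,
amplitude heterogeneity, or head motion.  Results on real data depend on
preprocessing choices outside this package's scope.

## Estimation and inference stages

**Fingerprinting.** Cross-session subject identification trains a 1-NN
classifier (cosine metric) on one session's run vectors and tests on the
other, in both directions, groups pooled; each subject can be correctly
identified up to four times.  Features are raw 528-dimensional
upper-triangle vectorisations, no reduction.  Distance ties break to the
lowest subject index (ties occur on degenerate synthetic data).

**Selection.** Univariate Wilks' lambda $\Lambda = SS_W / SS_T$ ranks
pairs; it is a monotone transform of the one-way $F$ statistic, which a
test verifies against `stats::aov`.  Stability selection redraws 1,000
random halves — *subject-level and group-stratified*, so runs of one
subject never straddle a subset boundary and both groups stay
represented; descriptions of such procedures rarely specify the sampling
unit, and this is our resolution of that ambiguity.  A caution verified empirically during development: counts
under the null are far more concentrated than a binomial
$(n_{\text{trials}}, k/p)$ model suggests, because overlapping halves
make trials strongly dependent — stability counts should be compared
between features, not against a binomial reference.

**Classification.** Subject-level half splits (all runs of a subject on
one side) prevent identity leakage; the option to balance classes
subsamples the majority group's training subjects.  Feature modes:
PCA-10 fitted on the training half only; whole-data Wilks top-20, which
reuses test data during selection and therefore *double dips* — the
implementation emits a warning and the mode exists only to document the
inflation; and the stability-selected top-10 pairs.  Classifiers: linear
and degree-2 polynomial SVM (`e1071`, default cost, feature scaling on),
LDA/QDA (`MASS`; QDA retries with a small ridge on singular class
covariances), and PLS-DA implemented as NIPALS PLS1 regression on ±1
class coding with decision threshold 0, cross-checked against
`mixOmics::pls`.  The requested 20 latent components are capped at the
feature count, since selected-pair modes supply only 10–20 features.
Confusion matrices are row-normalised percentages (rows = true class)
averaged over 100 Monte Carlo splits, and the overall accuracy is the
class-size-weighted mean of the diagonal — the convention that
reproduces the published overall accuracies from their per-class rates
(e.g. 26.73/80.63% with sizes 15/32 gives 63.43%).

A calibration subtlety: on *one fixed* null cohort, re-splitting yields
mean accuracy systematically below 50% (train and test group means of a
finite sample are negatively correlated — the "anti-learning" effect).
Calibration at 50% is therefore asserted over fresh null cohorts per
trial; the fixed-cohort pessimism is real behaviour, not a bug, and the
majority-class bias of unbalanced null training is asserted separately.

**Graphs.** For the selected pairs, each subject votes once per pair
(sign of the run-averaged entry of the max-normalised lead matrix;
exact-zero votes are dropped and logged).  Edges point in the majority
direction with the vote proportion as weight; layers follow the
longest-path rule (a node appears as soon as all predecessors have).
Majority directions can be cyclic; cycles are broken by repeatedly
dropping the lowest-weight edge inside a strongly connected component —
deterministic, and logged edge by edge.  Normalisation by the maximum
absolute entry is one of two documented options (Frobenius scaling would
only change edge strengths, not directions or votes).

## Numerical choices and degenerate inputs

* Antisymmetry is enforced exactly (`(A - t(A))/2`) after the shoelace
  sum, so invariance tests can assert equality to machine precision.
* A numerically zero lead matrix yields `defined = FALSE` strengths and
  an error from phase recovery, rather than arbitrary phases.
* Eigenvalue ties break by first occurrence in the decomposition output;
  PCA loading signs are fixed by making the largest-magnitude
  coefficient positive.
* Constant features make Wilks' lambda undefined: scalar calls error,
  vectorised ranking returns `NA` and excludes the pair from top-$k$
  sets for that trial.
* Warps are validated (strictly increasing, fixing 0 and 1) and applied
  to the analytic signal rather than by resampling, so reparameterisation
  tests carry no interpolation error.

## Problem sizes

The bundled analyses use the study-sized cohort (47 subjects × 4 runs of
33 × 300) for fingerprinting, selection (1,000 stability trials) and
classification (100 Monte Carlo splits per protocol); the calibration
study uses 100 fresh 16-subject null cohorts of 16 channels × 200
samples per classifier. These sizes keep every stage comfortably
reproducible on a single CPU while leaving the statistical assertions
well-powered.

## Known limitations

* Only second-order iterated integrals are computed; the higher
  signature, and streaming computation, are out of scope.
* The two-group univariate Wilks criterion is implemented; multivariate
  Wilks' lambda is not.
* No multiplicity correction is applied to lambda values (the selection
  procedure it reproduces applied none).
* The generator's group contrast is purely phase-ordering variability;
  amplitude- or topology-based contrasts are not modelled.
* Plot rendering of the published figures is out of scope; all stages
  emit data tables instead.
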