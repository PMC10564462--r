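---
title: "Cross-validated MANOVA decoding: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-validated MANOVA decoding: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cvmanova)
```

# The problem

In a near-threshold detection experiment, a participant judges on every trial
whether a weak signal is present ("yes"/"no"), and reports the choice with a
left- or right-hand response under a mapping that changes from trial to
trial. The neural questions this package addresses are: how much information
multichannel recordings carry about each task variable (stimulus, choice,
response, mapping, task context, confidence) at each time point; whether two
variables, two time points, or two contexts share a common multivariate
pattern; where in a source space that information resides; and whether the
trial-by-trial strength of the choice signal behaves like a signal-detection
decision variable.

The estimator has to work in a design where the variables are correlated by
construction — accuracy is fixed once stimulus and choice are known, and
response is fixed once choice and mapping are known — so naive decoders
trained on one variable can be driven by another. The remedy used throughout
is a factorial condition design: every occupied combination of binary
variables is a *unique condition*, models are fit per condition, and each
variable is read out through a main-effect contrast that is balanced over
all other included variables.

# Pattern distinctness

Let $Y$ be trials $\times$ channels data at one time point, $X$ the trials
$\times$ q condition indicator matrix, and $B = X^{+} Y$ the per-condition
mean patterns. A contrast $c$ over conditions (entries $+1/q_{+}$ and
$-1/q_{-}$ on the two level groups, zero elsewhere) turns $B$ into the
pattern difference $\delta = B{}'c$ between the two level-averaged means.

Within an $n$-fold cross-validation, with $B_{tr}$ from the training folds
and $B_{te}$ from the held-out fold, pattern distinctness is

$$
D \;=\; \frac{\sqrt{\kappa_{tr}\,\kappa_{te}}}{n_{te}}\;
\delta_{tr}' \,\hat\Sigma^{-1}\, \delta_{te},
\qquad
\kappa = \frac{c' (X_{te}'X_{te})\, c}{(c'c)^2},
$$

where $n_{te}$ is the number of test-fold trials. For
$c_{tr} = c_{te} = c$ this is algebraically identical to the trace form
$\operatorname{tr}\!\big(B_{tr}' P_c\, X_{te}'X_{te}\, P_c\, B_{te}
\hat\Sigma^{-1}\big)/n_{te}$ with $P_c = c(c'c)^{-1}c'$, the standard
cross-validated MANOVA statistic; the package's test suite verifies the
identity by brute-force evaluation. Because training and test halves are
independent, $E[D] = 0$ whenever no true pattern difference exists, so $D$
is signed and unclipped — negative estimates are part of the null
distribution and must not be truncated.

Writing the statistic through the scalar product of the two
contrast-of-means patterns, rather than through condition-space projectors
on both sides, is what makes *cross*-decoding well defined: with two
different contrasts (two variables, two time points, or two condition
subsets on the two sides) the projector product vanishes identically for
orthogonal contrasts in a balanced design, while the pattern-space product
measures exactly the quantity of interest,
$\delta_{A}' \hat\Sigma^{-1} \delta_{B}$. The geometric-mean weight
$\sqrt{\kappa_{tr}\kappa_{te}}$ makes the two readings coincide in the
within-variable case and gives the expected-cross-decoding identity below
its exact form. Asymmetric requests are computed in both direction
assignments (train on A / test on B and vice versa) and averaged.

## Noise normalization

$\hat\Sigma^{-1}$ is estimated per training fold from a baseline time point
(default $-0.5$ s relative to the first cue): residuals $\Xi$ after removing
condition means give $S = \Xi'\Xi$, shrunk as
$S_\lambda = (1-\lambda) S + \lambda\,(\operatorname{tr} S / p)\,I$ with
$\lambda = 0.05$, and scaled as
$\hat\Sigma^{-1} = (f_E - p - 1)\, S_\lambda^{-1}$ with
$f_E = n_{tr} - \operatorname{rank}(X)$. The $(f_E - p - 1)$ factor is the
inverse-Wishart correction that makes the whitened statistic unbiased; it
requires $f_E > p + 1$, and every analysis therefore needs at least
$N + K + 1$ trials (N channels, K model variables). Shrinking towards
$(\operatorname{tr} S/p) I$ rather than raw $I$ keeps the estimator
invariant to global rescaling of the data; exact invariance under arbitrary
invertible channel maps holds at $\lambda = 0$ (the shrinkage target is not
affine-equivariant), which is how the property is tested.

## Folds and seeds

The number of folds equals the lowest trial count over unique conditions,
and each condition's trials are spread as evenly as possible over folds, so
training and test sets always contain every condition — this is what lets
the estimator absorb the unavoidable imbalance of behavior-dependent
variables without discarding trials. Because the partition is random, every
analysis is repeated over several seeded partitions (10 by default) and
averaged before any further processing.

## Expected cross-decoding

If two contexts share one pattern and differ only in signal-to-noise ratio,
cross-decoding is expected to reach
$E_{12} = \sqrt{|D_1 D_2|}\,\mathrm{sign}(D_1)\,\mathrm{sign}(D_2)$; the
absolute value under the root with the sign product outside is the
continuous extension to (null-range) negative inputs. Empirical
cross-decoding significantly *below* $E_{12}$ indicates partially distinct
patterns; the group test is a one-tailed cluster permutation on the
per-subject difference.

## Smoothing

Decoding time courses are smoothed with a unit-sum Hanning kernel of 0.5 s
full width at half maximum; time–time generalization matrices with a
separable 2-D kernel of 0.1 s FWHM. At the edges the kernel is renormalized
over its valid support, so constants pass through unchanged. Smoothing is
applied after seed averaging and before group statistics.

# Group inference

Cluster-based sign-permutation tests: per time point (or time pair), an
across-subject one-sample t-test is thresholded at $\alpha = 0.05$ for the
requested tail; contiguous suprathreshold samples (4-connected components on
2-D grids) form clusters whose mass is the summed t value. Each subject's
whole time course is multiplied by a random sign in each of $n_{perm}$
permutations, the maximal cluster mass is recorded, and observed clusters
receive $p = (1 + \#\{\text{perm max} \ge \text{mass}\})/(1 + n_{perm})$.
The +1 correction guarantees validity; p-values have resolution
$1/(n_{perm}+1)$ and are invariant to global scaling. Cluster mass (rather
than extent) and the 4-neighborhood are the dominant conventions for this
test family; both are fixed choices here. Window analyses
(`ttest_window()`) average each subject's statistic over a stated window
and apply a one- or two-tailed t-test.

# Searchlight mapping

Each source (three dipole-direction channels) is decoded together with its
immediate neighbors, and the resulting $D$ is divided by the square root of
the searchlight's channel count, which equates the null sampling scale of
neighborhoods of different size (the dimension count; it does not, and is
not meant to, correct small-sample noise-precision variance, so
neighborhoods should stay well below the trial count). Sources are averaged
with their mirror homolog across hemispheres first, then within four region
groups (occipital, temporal, central, frontal). Spatial structure is
summarized by correlating, per subject, the information map at each time
point with a reference distribution (e.g., another variable's map averaged
over its characteristic window) across sources.

The packaged geometry is synthetic: a Fibonacci lattice on a spherical
shell with neighborhoods of 1.5 lattice spacings, region labels by angular
sector and hemispheres by the sagittal plane. It preserves what the
analysis actually consumes — adjacency, group labels, laterality — and
nothing anatomical; any real parcellation can be supplied through the same
`source_geometry` structure.

# Single-trial readout and geometry

The choice axis of a training fold is the whitened contrast of training
betas, $\hat\Sigma^{-1} (B_{tr}'c)$; projecting a held-out trial onto it
gives the linear statistic whose train–test product averages to $D$, which
keeps single-trial and aggregate readouts internally consistent. Projections
are strictly out-of-fold. The sign of the projection predicts the stimulus
class; under the SDT generator this predictability is at chance before
stimulus onset and rises after it, although choice information itself can
precede onset (via bias and sequential terms).

For the placement of the four choice $\times$ accuracy cells on the choice
axis, a model trained on all choices is tested on three cell pairs (correct
yes vs correct no, incorrect yes vs incorrect no, correct yes vs incorrect
no). Because the training axis is common to all pairs, the cross statistic
is *linear* in the separation along the axis, so the signed $D$ values are
used directly as pairwise distances in a least-squares 1-D embedding
(taking $\sqrt{D}$ there would be inconsistent for signed cross terms;
the cell ordering, which is the scientific claim, is invariant to this
monotone choice). Positions are normalized so correct-no sits at $-1$ and
correct-yes at $+1$.

Two-variable representational geometry is reconstructed from decoding
values alone: vector lengths $\sqrt{D_v}$ and the angle
$\arccos\!\big(D_{cross}/\sqrt{D_1 D_2}\big)$ with the cosine clipped to
$[-1, 1]$; identical representations give $0°$, orthogonal ones $90°$.
Angles are only defined for positive within-variable $D$.

# Behavioral model and meta-d′

Hit and false-alarm rates use a $1/(2N)$ boundary correction before the
quantile transform; $d' = z(H) - z(FA)$ and $c = -(z(H)+z(FA))/2$ (the
relative criterion $c' = c/d'$ is reported alongside, since printed
criteria in the literature are ambiguous between the two). Meta-d′ is the
maximum-likelihood sensitivity of an equal-variance SDT observer whose
confidence ratings, conditional on stimulus and choice, reproduce the
observed type-2 counts, with the type-1 criterion held at its fitted
relative position and one type-2 criterion per response side. The fit first
profiles the type-2 criteria at meta-d′ = d′ (the ideal-observer identity,
which the optimum can therefore never fall below at the start) and then
optimizes all three parameters by Nelder–Mead; zero count cells are padded
with 1/4 trial.

# The synthetic generator

`simulate_subject()` emulates the study conditions the estimators assume:

* **Design**: two task contexts (mapping cued before or after the
  stimulus), balanced stimulus and mapping, deterministic response and
  accuracy, two runs, an optional lagged choice/response; occupied
  combinations of up to five independent binary variables give at most 32
  unique conditions.
* **Behavior**: an equal-variance SDT decision variable
  $DV = \text{bias} + d_{gen}\cdot 1[\text{signal}] + w_{seq}\cdot
  \text{prev} + \varepsilon$, choice by threshold, confidence by
  $|DV - c|$ exceeding a cutoff. Defaults ($d_{gen} = 1.35$, unbiased
  criterion, bias SD 0.3, magnitude-variable sequential weight 0.15,
  confidence cutoff 0.8) give roughly 74% correct, a balanced
  choice-to-hand split, and more high-confidence reports on correct than
  on error trials. The sequential term defaults to magnitude-variable
  (positive attraction with trial-varying strength) because only the
  variability of the prior, not its sign, is constrained by the behavioral
  phenomena being emulated; a signed mode is available.
* **Neural data**: each variable contributes a unit channel pattern times a
  temporal envelope (ramp/plateau profiles aligned to cue at 0 s, stimulus
  at 1.25–3.25 s, response from 5 s) times the trial's level ($\pm 1/2$);
  the choice pattern is additionally scaled by
  $1 + g\,|DV - c|$, which is what produces the confidence/accuracy
  ordering of choice information and the cell ordering on the choice axis.
  Pattern pairs can be given exact angles (Gram–Schmidt plus rotation), so
  shared ($0°$) and orthogonal ($90°$) context representations are exactly
  realizable. Noise is Gaussian with exponentially decaying channel
  covariance (`rho = 0.3`), which makes the whitening step consequential.
  Sequential bias enters the DV only, not the patterns, so previous-choice
  controls can be tested as confound exclusions.

What the generator does *not* emulate: realistic forward models or sensor
geometry, oscillatory dynamics, artifacts, non-Gaussian noise, temporal
autocorrelation of the noise, or drift in behavior. Passing tests therefore
certify the estimators' statistical properties (unbiasedness, confound
immunity, calibration, recovery of planted structure) — not performance on
real recordings.

A caveat on single draws: with correlated noise, two patterns that are
orthogonal in channel space are generally not orthogonal in the
$\hat\Sigma^{-1}$ metric, so a single subject's cross-decoding between
"orthogonal" patterns fluctuates around zero without being zero. All
orthogonality claims are therefore group-level claims, and the simulated
subjects draw independent pattern banks.

# Numerical and scale choices

* Contrast scaling $\pm 1/q_{\pm}$ makes $c'B$ a difference of
  level-averaged means; $D$ is invariant to contrast rescaling.
* Degenerate inputs fail loudly and specifically: empty conditions name the
  condition, zero-variance normalization cells name run/channel/time,
  insufficient trials state the $N + K + 1$ bound, searchlight failures
  name the source.
* Baseline precision is estimated per training fold (never from test
  trials); the projection axis applies $\hat\Sigma^{-1}$ exactly once.
* Tests and the acceptance script run on deliberately small problem sizes —
  sessions of 128–512 trials, 6–96 channels, a 20 Hz time axis, hundreds of
  replicate simulations, 200–500 permutations — chosen so the full suite
  exercises every estimator end-to-end at Monte-Carlo precision adequate
  for the properties being checked. Null-mean checks use 3.3-sigma
  Monte-Carlo intervals to control the familywise error over the many
  simultaneous cells being tested.
* `simulate_valid_subject()` redraws a session (advancing the seed) when a
  rare behavioral condition ends up with fewer than two trials, mirroring
  the exclusion of under-sampled participants in the emulated design.

# Known limitations

* Contrasts are binary; multi-level factors and continuous covariates are
  out of scope.
* The meta-d′ fit is the equal-variance model with a single confidence
  level split; response-conditional and hierarchical variants are not
  implemented.
* The 1-D placement uses three cell pairs; with exactly four cells the
  embedding is identified only up to the anchors, which is why positions
  are reported normalized.
* File I/O uses plain-text containers (JSON + CSV) with the fixed column
  set of the condition table; binary scientific containers are not written
  by this package.
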