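---
title: "Models and methods behind offdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind offdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(offdyn)
```

`offdyn` analyses transient population OFF responses — the activity
transients that follow stimulus termination — under two competing
generative accounts, and provides the linear-network theory, estimators,
controls and synthetic data needed to tell them apart. This vignette is
the package's own account of the science: the models and their
assumptions, the parameters that matter, what the generator emulates, and
the numerical choices made where the design was genuinely open.

## The network model and its amplification theory

The population state $r(t) \in \mathbb{R}^N$ (activity relative to
baseline) obeys the autonomous linear rate equation

$$\tau \dot r = -r + J r, \qquad r(0) = r_0,$$

with the time constant $\tau$ fixed to one (a data-time scale factor is
carried separately; see *Time units* below). Each stimulus enters only
through its offset state $r_0$; no external input acts afterwards. The
solution is the propagator applied to the initial state,
$r(t) = e^{t(J - I)} r_0$, computed by `propagate()`.

**Amplification.** The instantaneous growth rate of the distance from
baseline is $\tfrac{d}{dt}\log\lVert r\rVert = r^\top (J_S - I) r /
\lVert r\rVert^2$ with $J_S = (J + J^\top)/2$. Its maximum over unit
states is $\lambda_{\max}(J_S) - 1$, so some initial state is transiently
amplified **iff** $\lambda_{\max}(J_S) > 1$ (`amplification_criterion()`),
while stability requires all eigenvalues of $J$ to have real part below
one. Normal matrices ($JJ^\top = J^\top J$) satisfy
$\lambda_{\max}(J_S) = \max \mathrm{Re}\,\lambda(J) < 1$ and can only
decay; non-normality is necessary but not sufficient.

**Low-rank structure.** For $J = UV^\top$ with unit-norm left patterns
(the canonical SVD factorization used by `low_rank_connectivity()`),
trajectories stay within the span of $r_0$ and the right patterns, and the
$R \times R$ overlap matrix $V^\top U$ carries the nonzero spectrum of
$J$. The nonzero eigenvalues of $J_S$ solve a rank-$2R$ implicit
condition, implemented in `lowrank_sym_eigs()` through the equivalent
$2R \times 2R$ block eigenproblem and used as an independent cross-check
of the dense eigensolver. For a unit-rank network the criterion reduces to
$\lVert u \rVert > 2 / (\cos\theta + 1)$, with stability
$\cos\theta < 1/\lVert u\rVert$ (`unit_rank_conditions()`).

**Rotational channels.** The building block of the structured
connectivities is the rank-2 channel
$J_2 = \Delta_1 v^{(2)} v^{(1)\top} - \Delta_2 v^{(1)} v^{(2)\top}$ on an
orthonormal pair, with purely imaginary eigenvalues $\pm i\omega$,
$\omega = \sqrt{\Delta_1\Delta_2}$: always stable, amplified iff
$|\Delta_2 - \Delta_1| > 2$. `closed_form_trajectory()` evaluates the
analytic solution for superpositions of mutually orthogonal channels plus
a decaying component orthogonal to all channel planes; its exact agreement
with matrix-exponential propagation is the central oracle equivalence in
the test suite. Conditions on the initial state
(`initial_state_condition()`) use the numerically computed peak time
rather than the asymptotic quarter-period rule $\omega t^* \approx \pi/2$,
which is only accurate for $\Delta_2 \gg \Delta_1$; the numerical peak is
exact in all regimes. Initial and peak states decorrelate as
$\Delta_2/\Delta_1$ grows — the signature separating rotational network
dynamics from single-cell decay, where the peak is the initial state.

## The single-cell model

`fit_single_cell()` implements
$r_i^{(s)}(t) = r_{0,i}^{(s)} L_i(t)$: one temporal filter per neuron,
shared across stimuli, scaled by a per-stimulus firing-rate range (the
filter's dynamic range $|\max_t - \min_t|$ is normalized to one, folding
any scale into the ranges). Filters are expanded on `n_basis = 10`
Gaussian bumps of width 35 ms; responses are divided by their dynamic
range and the stimulus-independent coefficients solved by least squares.
Bump centers are spaced uniformly over the analysis window (a standard
choice; the count, not the placement, controls resolution). To avoid
dividing by near-zero ranges, only the most responsive neurons are fitted;
the cutoff (top 50% by largest range across stimuli, `keep_frac`) is a
configurable convention, since responsiveness thresholds are inherently
dataset specific.

## Fitting the network model

`build_design()` stacks trial-averaged responses over time and stimuli,
estimates velocities by forward differences
$\dot X(t_i) = (X(t_{i+1}) - X(t_i))/(t_{i+1} - t_i)$ aligned with the
left time point, and reduces dimensionality by PCA (default: 100
components or the count reaching 90% of the variance, whichever is
smaller; recovery-oriented analyses pass `var_threshold = 1` to fix the
count by `n_pc` alone). Ridge regression solves
$\hat J = I + (X_\lambda^\top X_\lambda)^{-1} X_\lambda^\top
\dot X_\lambda$ on the augmented design; reduced-rank ridge projects the
ridge solution on the leading right singular vectors of
$X_\lambda \hat J_\lambda$, the exact solution of the rank-constrained
problem. Cross-validation partitions each stimulus's rows into K = 10
contiguous temporal chunks; the rank is chosen where the CV score
saturates (smallest rank reaching 95% of the plateau — the saturation
level is a convention, exposed as `plateau_frac`) and the penalty
maximizes the CV score at that rank.

Three numerical choices deserve emphasis:

- **Projection without centering the coordinates.** The PCA basis is
  computed from data centered over times and stimuli (the standard
  variance convention), but activity is projected *uncentered*, with the
  mean direction appended to the basis. The dynamics have their fixed
  point at baseline zero; centering the coordinates introduces an affine
  offset ($\dot y = Ay + Am$) that an intercept-free linear regression
  cannot represent, which measurably caps single-stimulus fits.
- **Discrete-map prediction.** The forward-difference regression
  estimates the one-step flow map $(P_{\Delta t} - I)/\Delta t$, not the
  continuous generator. `predict_and_score()` therefore chains the fitted
  map across the grid by default (exact for noiseless data at any
  sampling rate); exponentiating the fitted generator instead
  (`discrete = FALSE`) compounds an $O(|\lambda|\Delta t)$ phase error at
  31.5 Hz sampling. For spectra, `connectivity_spectrum()` inverts the
  same discretization per eigenvalue,
  $\lambda_J = 1 + \log(1 + \Delta t(\mu - 1))/\Delta t$, valid while
  $|\mathrm{Im}\,\lambda\,\Delta t| < \pi$.
- **Degenerate ranks under shared frequencies.** When all channels share
  one $\omega$ (the homogeneous simulation regime), every coefficient
  function lies in the span of $\{e^{-t}\cos\omega t, e^{-t}\sin\omega t,
  e^{-t}\}$, so a single-stimulus trajectory is *exactly*
  three-dimensional regardless of the ambient dimension, and rank
  selection can saturate below the nominal connectivity rank. Analyses
  that need identifiable per-channel structure use heterogeneous
  $\Delta$'s or match the component count `k` to the generated signal
  rank.

## Geometry and controls

`cumulative_variance()` implements the variance curves (centered over
times and stimuli). `cvpca_spectrum()` estimates stimulus-related variance
from the covariance between the responses of distinct trials, averaged
over ordered trial pairs: noise independent across trials cancels in
expectation, unlike naive PCA which adds it to every component. The
estimator retains a small downward bias on components whose
signal-to-noise ratio is low (training-trial principal directions rotate
away from weak signal directions), so unbiasedness claims apply to the
top components.

`subspace_overlap()` is the cosine of the smallest principal angle:
$\sigma_{\max}(Q_1^\top Q_2)$ on the top-K principal components of each
response (K = 5 by convention; the prose notion of the "largest angle
between any two vectors" of two subspaces corresponds to this largest
singular value, which is what is implemented). Two controls assess
significance: permuting stimulus labels across trials (addresses the
possibility that low overlaps arise from high ambient dimensionality;
lower-tail permutation p-value) and split-half resampling (addresses
trial-to-trial variability: cross-stimulus overlaps from 10-trial
averages are compared by t-test with within-stimulus overlaps between two
disjoint 10-trial halves, taking the conservative maximum of the two
per-stimulus p-values and claiming significance only where the
cross-stimulus mean is below both within-stimulus means).

## Transient channels

`fit_channels()` fits the reduced-rank model to each stimulus
independently (one shared PC basis; the variance cutoff is disabled there
because truncating below the dynamics' dimensionality entangles the
per-stimulus fits), factorizes each fitted connectivity canonically, and
`connectivity_overlap()` measures principal-angle cosines between the
orthonormalized right-pattern spans. `sum_channels_test()` compares the
goodness of fit of the jointly fitted connectivity with the sum of the
per-stimulus channels and with controls in which the entries of the sum
are permuted uniformly at random (the natural unstructured permutation,
seeded and repeated).

## Single-trial variability

With trial-to-trial noise only in the initial condition,
$C(t) = s^2 P_t P_t^\top$: variance grows along the amplified direction
(the trial-averaged state at its norm peak, `amplified_direction()`) but
stays of order one along random directions, and destroying cross-neuron
correlations by per-neuron trial-label shuffling collapses the effect. A
single-cell mechanism yields a diagonal covariance
$s^2 L_i^2(t)\,\delta_{ij}$ at every time, so shuffling changes nothing —
the discriminating prediction. `va_contrast()` quantifies this via
$\Delta VA = VA(\text{ampl}) - VA(\text{rand})$ over 50 subsamples of 90%
of the cells, with random directions drawn uniformly on the sphere and
averaged (20 per subsample; resampled per subsample, logged via the run
seed). The primary p-value is an exact one-sided permutation test: the
real $\Delta VA$ is ranked among the $\Delta VA$ of independent
trial-label shuffles, which are exchangeable with the data under the
diagonal-covariance null. A t-test of real against shuffle-averaged
$\Delta VA$ across subsamples is also reported, but subsamples of one
dataset are strongly dependent and that test is anticonservative —
empirically it rejects almost always under both mechanisms, which is why
it is not the primary decision statistic. Across stimuli, a Wilcoxon
signed-rank test pools the per-stimulus contrasts.

## Decoding

`loo_accuracy()` classifies stimulus pairs per 50 ms bin with the
nearest-class-mean rule $w = c_1 - c_2$, $b = (c_1 + c_2)/2$, sign of
$w^\top(x - b)$ (the difference form written with a vector offset is
implemented as this nearest-mean rule, the only dimensionally consistent
reading), under leave-one-out cross-validation; ties are broken at random
under the run seed. Chance levels shuffle labels independently per bin;
the summary is reported over time by default, with an across-shuffle
variant exposed, since either convention is defensible.

## Surrogate controls

`marginal_stats()` removes marginal means iteratively until all three
marginal sums vanish (tolerance $10^{-10}$, at most 100 sweeps) and
accumulates the marginal covariances across times, dimensions and
stimuli. `generate_surrogates()` draws Gaussian tensors whose noise has
Kronecker-separable covariance built from the eigendecompositions of the
constrained marginals; unconstrained axes receive isotropic factors with
trace matched to the data (the maximum-entropy choice given no
constraint), and the per-axis spectra are normalized so that every
constrained marginal covariance is matched in expectation and the total
variance is preserved. The three families T, TK and TKC constrain
progressively more marginals. This Kronecker-eigenbasis construction is
one valid choice satisfying the stated moment constraints; output
manifests label it as such, and the contract — constraint satisfaction —
is asserted empirically in the tests rather than by appeal to a
particular solver.

## The synthetic-data generator

`generate_network_dataset()` emulates the statistical structure of the
pooled recordings: 16 ramping-sound stimuli (`enumerate_stimulus_set()`
reproduces the direction x frequency x duration x modulation design), 20
trials, 31.5 Hz frames over a −50…+300 ms OFF window (≈11 native frames;
an optional resampled grid, default 35 points, supports finer velocity
estimation — both grids are first-class since the original temporal
resolution of the OFF analyses is ambiguous), 13 sessions of 180 ± 72
neurons rescaled to the population size, and a connectivity of 20
mutually orthogonal rank-2 rotational channels with $\Delta_1 = 1$,
$\Delta_2 = 7$ on 1000 units. Stimuli are represented purely by their
offset states (ON-period dynamics are out of scope by the models' own
assumption): each stimulus starts on its channel's amplified input
direction $v^{(2)}$, stimulus clusters mix a shared and a private
amplified direction so that all pairwise within-cluster cosines equal the
configured value, and per-trial initial states add isotropic Gaussian
noise with `init_noise_sd = 0.1` by default (a ~10% perturbation of the
unit-norm state, a realistic regime for trial-averaged calcium data;
observation noise defaults to zero because the models place noise only in
the initial condition). Time is mapped to the data clock through a 100 ms
network time constant, which places the rotational peak
($\omega t^* \approx \pi/2$ model units $\approx$ 60 ms data time) inside
the OFF window, matching where cortical OFF responses peak.

`generate_single_cell_dataset()` draws per-neuron filters as random
mixtures of Gaussian bumps (normalized to unit range) and nonnegative
per-stimulus ranges with configurable across-stimulus correlation —
ranges are magnitudes, which is what makes the shared-filter
normalization well posed. Trials perturb the ranges, so the trial
covariance is diagonal by construction.

What the generator does **not** emulate: calcium indicator dynamics and
deconvolution artifacts, non-Gaussian and activity-dependent noise,
ON-period transients, and session-to-session gain differences. Passing
tests on generated data therefore validate the estimators and the
discriminating logic under the models' own assumptions, not the
biological preprocessing chain.

## Problem sizes and determinism

The test suite exercises the full pipeline at desk scale: populations of
40–300 neurons for module tests, one 1000-unit / 16-stimulus / 20-trial
simulation subsampled to 200 neurons for the structure-recovery check,
200-repeat spectrum calibrations and 100-null calibration loops for the
controls. These sizes were chosen so that each claim is tested at the
smallest scale where its effect is unambiguous. All stochastic stages are
seeded; `run_pipeline()` derives per-stage substreams from one master
seed and logs them, so every output is reproducible from the
configuration alone.

## Known limitations

- The analytic channel formulas assume exactly orthonormal channel bases;
  `rotational_channel_bank()` enforces this within $10^{-8}$ and
  degenerate ($\omega = 0$) channels fall back to dense propagation.
- Spectrum recovery by `connectivity_spectrum()` assumes
  $|\mathrm{Im}\,\lambda\,\Delta t| < \pi$ (no frequency aliasing on the
  sampling grid).
- The split-half control tests distinguishability, not orthogonality:
  strongly correlated but distinct stimuli are legitimately flagged as
  different.
- cvPCA is unbiased only where signal dominates the per-trial noise along
  the corresponding component; tail components are shrunk.
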