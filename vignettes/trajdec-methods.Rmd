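---
title: "Methods: simulated transfer learning for EEG trajectory decoding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulated transfer learning for EEG trajectory decoding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

In a pursuit tracking task a participant attempts to move their hand so a
cursor follows a moving on-screen target (the "snake") while low-frequency
EEG is recorded. A continuous decoder maps the EEG to the 2-D target
kinematics — horizontal and vertical position and velocity, extended with
the non-directional distance `d = sqrt(p_hor^2 + p_ver^2)` and speed
`s = sqrt(v_hor^2 + v_ver^2)`. The scientific question `trajdec` addresses
is *transfer*: can a decoder trained on other participants (or earlier
sessions) decode a new participant or session above chance, and how do four
model-update strategies compare? Because suitable public recordings do not
exist, the package ships a synthetic study generator with a known
source-to-kinematics coupling, so every claim is testable against ground
truth.

## Generative model of the synthetic studies

Sensor data follow the linear EEG forward model `X = G J + n`:

* **Lead field `G`** (`gen_leadfield()`): electrodes on the upper unit
  sphere, free-orientation sources on an interior shell (radius ≤ 0.9),
  dipole-like gain `(r - s)_axis / |r - s|^3`. Sources are partitioned into
  28 contiguous patches named after the central medial regions commonly
  used for movement decoding (cuneus, paracentral lobule, pre-/postcentral
  gyri, superior parietal lobule, precuneus, superior frontal and occipital
  gyri, split per hemisphere). This is deliberately *not* an anatomical
  head model; it reproduces the qualitative distance fall-off and ROI
  structure that the source-imaging stage needs.
* **Coupled sources**: inside the coupling ROIs (default: paracentral
  lobule, precuneus, cuneus, both hemispheres) the source activity is a
  linear read-out `B · lagged(kinematics)` of the snake at lags 0, −150 and
  −300 ms. `B` is shared across participants, drawn independently per
  participant, or rotated per session — the knob that decides whether
  transfer can succeed.
* **Background**: all other sources carry independent unit-variance
  Gaussian noise with a `1/f` power spectrum between `1/duration` and
  45 Hz. It is synthesized in the frequency domain and mixed through `G`
  spectrally, which is distributionally identical to per-source time-domain
  synthesis but an order of magnitude cheaper.
* **Sensor noise**: white, scaled so the realized SNR against the noiseless
  `G J` matches the requested value (default 10 dB).
* **Snake** (`gen_snake()`): per dimension a sum of 12 random-phase
  sinusoids with frequencies drawn in 0.1–1 Hz and snapped to the block's
  Fourier grid, so the trajectory is periodic over the block and the
  analytic velocity is exact on the sampling grid.

Desk-scale defaults: 8 participants × 3 sessions × 3 blocks (labelled 0%,
50%, 100% feedback), 32 channels at 200 Hz, 500 source locations, 5 trials
of 24 s per block (trials are contiguous and equal length; the 24 s default
makes a 120 s block an integer number of trials). Paper-scale sizes (60
channels, 5000 locations, 10 participants) are plain configuration.

**Coupling strength.** The coupled activity is scaled to 0.25 of the
background's unit standard deviation. This was calibrated once, during
generator design: with coupling ≈ background, the kinematic subspace
dominates the sensors so strongly that even a decoder trained on *other*
participants' couplings reads it back out, and the generalized model lands
at chance level instead of below it; at 0.25 the movement-related signal
sits well below the ongoing background — the realistic EEG regime — and the
study reproduces the qualitative transfer phenomenon (generalized below
chance with participant-specific couplings, individual models above it,
generalized above chance with shared couplings) robustly across seeds.

What the generator does **not** emulate: eye and movement artifacts (the
corresponding correction stages of real pipelines are out of scope),
anatomical variability between participants (all share one synthetic head),
non-stationarities within a block, and the closed feedback loop (the 50%
and 100% labels are evaluation segments only). Passing tests therefore show
algorithmic correctness and the stated qualitative regime on this model
family — not performance on real EEG.

## Signal conditioning

`filter_chain()` applies zero-phase (forward–backward) 4th-order
Butterworth filters — 0.18 Hz high-pass at 200 Hz, 3 Hz low-pass at
100 Hz — around polyphase resamplings 200 → 100 → 20 Hz, then
`common_average_reference()`. Zero-phase filtering keeps the
feature–kinematics pairing free of group delay. The forward–backward pass
doubles the nominal filter order; the 0.18 Hz recursion at a normalized
cutoff of 1.8e-3 is numerically delicate in transfer-function form and
limits linearity round-off to about 2e-8 of the input scale, which the
tests assert explicitly. `lag_expand()` embeds each feature with lags 0 to
−6 samples (0 to −300 ms at 20 Hz) *per trial*, dropping the first 6
samples of every trial rather than padding, and returns the retained
column indices so the kinematics are subset identically. Indexing is
0-based half-open throughout the trial bookkeeping.

## Source imaging

`sloreta_kernel()` builds the minimum-norm kernel
`T = G'(G G' + alpha C)^{-1}` and standardizes it per location with the
3 × 3 orientation block of the resolution matrix `S_j = T_j G_j`, returning
rows `S_j^{-1/2} T_j` (symmetric inverse square root, eigenvalue floor
1e-12). `alpha` defaults to the SNR-style heuristic
`alpha · trace(C) / trace(G G') = 0.1`; the noise covariance comes from
`estimate_noise_covariance()` (sample covariance plus diagonal loading
`0.01 · trace/P`). The defining structural property — zero localization
error for a noiseless single source as `alpha → 0` — is what the tests pin
down; numeric identity with any external solver is not claimed.
`build_scouting_matrix()` averages sources within each ROI per orientation
(`1/R_i` weights), giving 84 representative signals; after lag expansion
the source-space decoder sees 588 features and the 32-channel sensor-space
decoder 224.

## The decoder cascade

**Recursive exponentially weighted PLS.** The covariance recursion keeps
only `C_yy ← λ C_yy + Y Yᵀ`, `C_yz ← λ C_yz + Y Zᵀ` plus running weighted
sums; λ discounts once per batch and λ = 1 (the default everywhere) makes
the state an additive sufficient statistic — pooled models and
cross-validation folds are formed by adding/subtracting states. Fitting
(`rewpls_fit()`) centers the state with its running means and runs the
covariance-only kernel PLS: per component the weight is the dominant left
singular vector of the deflated cross-covariance, orthogonalized against
previous loadings; the regression map is assembled from the
orthogonalized weights and response loadings. The λ = 1 path is *exactly*
equivalent to batch PLS on the concatenated raw data (asserted to 1e-8
against an independent X-deflation implementation, and to ordinary least
squares at full rank). Centering via running means is a deliberate choice:
the raw recursion accumulates uncentered inner products, and centering at
fit time is what makes the batch equivalence exact.

**Component selection.** `select_components()` builds the 10-fold
cross-validated curve of the mean Pearson correlation of the four linear
kinematics versus component count (contiguous folds; fold states by state
subtraction) and picks the knee: the point of maximal perpendicular
distance to the chord joining the curve's endpoints, ties to the smallest
count, constant curves to 1 with a warning. `A_max` defaults to 50.

**Square-root UKF.** The filter state is the 6-dim extended kinematics; the
transition is a fitted AR(1), the observation maps the state to the PLS
latent scores (`E = W Y`), both by least squares on centered data with
residual noise covariances. The filter propagates the upper Cholesky factor
of the state covariance via QR and rank-1 updates (C++/Armadillo core),
with an eigenvalue-floored re-factorization fallback that is counted and
warned about. Sigma-point parameters default to `alpha = 1e-3, beta = 2,
kappa = 0`. On a linear-Gaussian system the filter coincides with a
conventional Kalman filter to 1e-6 over thousands of steps; the unscented
machinery exists because distance and speed make the state's relation to
the linear kinematics non-linear. Decoded distance and speed are recomputed
from the filtered positions and velocities so the output is always
self-consistent.

**Process-noise calibration.** The latent features carry strong
autocorrelated non-kinematic content, so the observation noise is far from
white and the raw AR-residual process noise makes the filter bandwidth too
narrow — the output lags and the cascade *loses* velocity correlation
relative to raw PLS predictions. `srukf()` therefore calibrates a single
process-noise scale on the training pair (grid 1…64 in powers of two,
maximizing the mean filtered correlation of the linear kinematics over at
most 4000 training samples). This is the usual noise tuning of Kalman-type
decoders, deterministic, and uses training data only. Chance-level refits
reuse the matched model's scale, exactly as they reuse its component count.

## Update strategies

`train_lopo()` pools the 0% blocks of session 1 of all other participants
(λ = 1) and fits the cascade with a knee-selected component count.
`run_strategy()` then simulates the online sequence: every 0% block is
decoded with the model carried in from before it, after which the model is
updated — never (Gen), by cumulative extension of the LOPO pool with the
participant's own 0% blocks (GenC), from the current session's 0% block
alone (Ind), or from all own 0% blocks so far (IndC, whose session-1 model
coincides with Ind1). Both cascade stages are refit from the cumulative
pool at every update and the component count is re-selected. A 3-session
design yields 9 unique models (Gen, GenC1–3, Ind1–3, IndC2–3); causality —
no block decoded by a model that saw it or anything later — is asserted by
test.

## Evaluation

Metrics are the Pearson correlation and the decoding SNR
`10 log10(var(x)/MSE(x, y))`, with variance and MSE both normalized by
`1/n` so that predicting the constant mean of the truth gives exactly 0 dB;
the truth is always the first argument. Group-level summaries use absolute
correlations.

**Chance levels.** `chance_threshold()` permutes the assignment of whole
kinematic trials to feature trials (equal-length trials required), retrains
the full cascade per shuffle, applies it to the matched evaluation blocks,
and takes per kinematic the median |r| over blocks as the repeat's
statistic. Because the features are untouched, only the cross-covariance
and response sums change per shuffle — the expensive feature
autocovariance is computed once. The participant threshold is the upper
permutation quantile: the `ceiling(p(n+1))`-th order statistic of the `n`
shuffle statistics, under which an exchangeable draw falls with probability
`~p` for any `n` — with the default 95th percentile and 20 repeats the
expected coverage is 20/21 ≈ 0.952, and the Monte-Carlo calibration
(`chance_calibration()`) reproduces 95% ± 3% over 200 independent null
replicates. The group threshold is the median across participants.
Per-shuffle knee re-selection is intentionally skipped (the matched model's
component count and noise scale are reused) to bound runtime.

**Comparisons.** `compare_strategies()` groups kinematics into position,
velocity and non-linear, runs two-tailed paired Wilcoxon signed-rank tests
over every pair of strategy × feature-space conditions (via
`stats::wilcox.test`, exact for small n without ties; all-zero difference
sets report NaN), and adjusts p-values by Benjamini–Hochberg within the
family of all pairwise comparisons of one metric and kinematic group.

## Decoding patterns

`decoding_pattern()` applies the forward-model transform
`A = (1/g) Σ_Y W Σ_Z^{-1/2}` to the decoder's feature-to-kinematic map,
with *properly normalized* (1/n) covariances — not the raw training inner
products — and the symmetric matrix inverse square root. The orientation is
chosen so `A` is features × kinematics, the only orientation conformable
with a per-region, per-kinematic pattern; on noiseless linear simulations
with whitened kinematics each pattern column is collinear with the true
forward mixing. `model_gfp()` supplies the normalizer `g`: the median over
permutations of the spatial standard deviation of the trial-averaged
source-projected training data at a random within-trial time point
(equal-length trials required; trial averaging commutes with the linear
projection and is done once). `embed_patterns()` normalizes each pattern by
its maximum absolute entry and embeds the collection in 2-D with an exact
t-SNE (per-point bandwidth by bisection to the target perplexity, default
30 capped at `(n-1)/3`, early exaggeration, momentum descent, fixed seed) —
collections are small, so the quadratic exact algorithm is the right tool.
ROI aggregation of |pattern| conserves the total magnitude and is reported
at lag 0 by convention, with the full lag-resolved pattern retained.

## Reproducibility and problem sizes

Every stochastic stage draws its seed from a single global seed through a
counter-based scheme (`derive_seed()`), so studies regenerate bit-identical
and stages can be re-run in isolation. `run_pipeline()` validates its
configuration (unknown keys rejected) before any computation and writes
metric tables, chance thresholds, comparisons, patterns and a manifest with
an MD5 configuration hash.

The shipped tests and the acceptance script exercise: the algebraic
equivalences (PLS at desk scale 200 × 20 × 6; SR-UKF vs Kalman over 2000
steps), sLORETA localization at 32 channels × 500 locations over 50 random
sources, pattern recovery at 20 × 6, chance calibration with 200 null
replicates of 20 shuffles, and the transfer headline on the full
desk-scale design (8 participants, 120 s blocks; 20 chance shuffles per
participant with the conservative upper permutation quantile). The
shared-coupling positive control uses a single session, which suffices
because it involves only the generalized model, which never updates.

## Known limitations

* The AR(1) transition cannot represent the narrowband snake exactly; the
  calibrated process-noise scale compensates but the filter remains
  mis-specified for strongly oscillatory kinematics.
* The chance statistic aggregates blocks by their median |r| per repeat;
  trial-averaged participant-level correlation is a documented alternative
  that tends to run slightly higher.
* The synthetic head model supports structural properties (localization,
  ROI averaging, pattern recovery), not anatomical claims.
* With a handful of equal-length trials per block the permutation space is
  small; thresholds at 20 shuffles are conservative by construction rather
  than finely resolved.
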