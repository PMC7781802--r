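---
title: "Validating 2D pose streams: models and methods in poseagree"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating 2D pose streams: models and methods in poseagree}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`poseagree` quantifies how well one 2D pose-keypoint stream (the
*candidate*, typically a markerless estimator) agrees with another (the
*reference*, typically a multiview reference system) in terms of the joint
angles a clinician would actually use. This vignette documents the model,
the tunable parameters, the numerical choices, and the design decisions
taken where more than one reasonable convention exists — and what the
synthetic test bed does and does not demonstrate about real data.

## The angle model

Each of the ten registry joints is an ordered landmark triplet (A, B, C)
with B the vertex ([`joint_triplets()`]): shoulders use (hip, shoulder,
elbow), elbows (shoulder, elbow, wrist), hips (shoulder, hip, knee), knees
(hip, knee, ankle), the neck (pelvis, neck, head), and the pelvis (left
knee, pelvis, right knee). The per-frame angle is the **unsigned interior
angle**

$$\theta = \operatorname{atan2}\!\big(|\vec{BA}\times\vec{BC}|,\;
\vec{BA}\cdot\vec{BC}\big) \in [0^\circ, 180^\circ].$$

Decisions taken:

* **Unsigned, not clinical.** No flexion/extension sign convention is
  imposed; every joint yields a single value in [0°, 180°]. This makes the
  angle invariant to translation, rotation, uniform scale, *and reflection*
  of the image — properties the test suite asserts to 1e-9 degrees — at the
  cost of not distinguishing, say, varus from valgus.
* **atan2, not arccos.** The two are mathematically identical but
  `atan2(|cross|, dot)` is numerically stable for near-collinear rays, where
  `acos` of a rounded cosine loses precision. Tests compare the two on
  random triples to 1e-9.
* **Head and pelvis on Body25.** The Body25 convention has no head landmark;
  the nose keypoint stands in for the head, and MidHip for the pelvis. On a
  layout with no pelvis index at all, the pelvis is resolved as the midpoint
  of the two hips. This approximation is the main reason to expect the neck
  angle to behave worst on real estimator output.
* **Degenerate geometry is data, not an error.** A zero-length ray (two
  coincident landmarks) makes that frame's angle *missing*; one bad frame
  can never abort a video. The scalar `interior_angle()` API, by contrast,
  raises a declared error, because a user calling it directly has no
  missingness mask to fall back on.
* **Missingness propagates minimally.** A frame's angle is missing iff one
  of its three landmarks is missing (confidence 0 or coordinates exactly
  (0, 0) on read — the common sentinel convention — or dropout in the
  synthetic generator). Other joints at the same frame are unaffected.
  Confidence values are carried through but never used as weights; no
  published weighting scheme exists for this setting.

## Preprocessing

The pipeline order is **smooth → impute → pair**: smoothing belongs to the
angle-computation stage and imputation to the statistical stage, and pairing
must see complete series.

* **Bartlett smoothing** (`bartlett_smooth()`, window 11 frames ≈ 0.37 s at
  30 fps). Weights are the normalized triangular window (zero endpoints, sum
  1), so constants are preserved exactly and linear trends are preserved
  away from the edges. Edges use reflect padding (mirror about the boundary
  sample, edge not duplicated) so output length equals input length. Missing
  values are excluded from each window and the remaining weights
  renormalized; the missing mask itself is preserved. A length-11 triangular
  filter attenuates white noise variance by Σw² ≈ 0.136 while passing the
  sub-Hz frequencies of human range-of-motion movement nearly unchanged.
* **Moving-average imputation** (`impute_moving_average()`, window 5,
  centered). Each missing value takes the mean of the *observed* values in
  its window (single pass — imputed values never feed later imputations).
  Runs longer than the window are filled by linear interpolation between the
  nearest valid neighbours; leading/trailing gaps take the nearest valid
  value. Window 5 covers the 1–3-frame dropouts a visibility loss typically
  produces without smearing; both windows are pipeline parameters.
  Non-missing values are never altered (asserted property).
* **Pairing** (`pair_angles()`). Equal-rate series are matched on frame
  index. When rates differ (e.g. 25 vs 30 fps sources), the higher-rate
  series is linearly resampled in time onto the lower-rate series' frame
  times, restricted to the overlapping time range — the lower-rate stream
  defines the analysis clock, and linear interpolation at 25–30 fps
  contributes at most |f''|Δt²/8, fractions of a degree for human movement.
  No dynamic time warping or event alignment is attempted: temporal lag is
  *diagnosed* by the cross-correlation stage, never corrected.

## The agreement panel

All statistics act on the paired differences $d_t = c_t - r_t$ pooled per
joint across videos (per-video grouping is kept for the ICC dot plot).

* **Bias** = mean difference; SD with the n−1 denominator; SE = SD/√n;
  95% CI = bias ± 1.96·SE. The normal multiplier is used rather than
  Student-t: at the pair counts this design targets (tens of thousands) the
  two are identical to well below the reported precision, and the normal
  form is what reproduces published worked examples exactly. Note the SE
  assumes independent pairs; smoothed series are serially correlated, so
  the SE is better read as a precision index than a strict standard error
  (see the recovery-tolerance note below).
* **MAE** = mean |d|; **RMSE** = √(mean d²), related to the moments by the
  exact identity RMSE² = bias² + SD²(n−1)/n (`rmse_from_moments()`, asserted
  on every computed panel to 1e-9).
* **MAD**: reported panels in this field rarely say which deviation they
  mean. The default here is the *median absolute deviation about the median*
  (no consistency constant) — a robust scale estimate consistent with
  published panels where MAD < MAE by a wide margin (under normality the
  mean absolute deviation about the mean is ≈ 0.8 SD, which those panels
  contradict). `mad_type = "mean"` switches to the mean absolute deviation
  about the mean.
* **sMAPE** = 100 · mean( |c−r| / ((|c|+|r|)/2) ), the half-sum-denominator
  form bounded at 200%, with a 0/0 summand defined as 0. Unlike MAPE it
  cannot blow up near zero-valued angles.
* **ICC(A,2)** (`icc_a2()`): McGraw & Wong's two-way, absolute-agreement,
  average-measures coefficient on the n×2 matrix of paired frames,
  $$ICC(A,k) = \frac{MS_R - MS_E}{MS_R + (MS_C - MS_E)/n}, \quad k = 2.$$
  Absolute agreement matters: a constant offset between candidate and
  reference strictly lowers it (asserted property), which a consistency ICC
  would ignore. The 95% CI is the McGraw & Wong F-based interval for single
  measures stepped up by the Spearman–Brown relation; the implementation
  was cross-checked against an independent ANOVA-based oracle (to 1e-10 on
  random matrices) and an external implementation during development.
  Classification follows Fleiss: < 0.40 poor, [0.40, 0.75) fair to good,
  ≥ 0.75 excellent — boundaries assigned upward, documented because 0.40 and
  0.75 are otherwise ambiguous. Zero between-subject variance (constant
  frames) makes the ICC undefined and is reported as a per-group error
  without aborting other groups.
* **Box plots** use the linear-interpolation quantile rule (R type 7, the
  common statistical-software default — outlier counts depend on this
  choice); whiskers end at the most extreme observations within 1.5 × IQR of
  the quartiles, and everything beyond is listed as an outlier.

## Time-series diagnostics

* **Stationarity** (`adf_test()`): augmented Dickey–Fuller regression with a
  constant and no trend (range-of-motion angle series have no drift term to
  model), lag order chosen by AIC on a common sample up to the Schwert
  ceiling ⌊12(n/100)^¼⌋, p-values interpolated from the standard
  Dickey–Fuller τ tables for the constant case and clipped to [0.01, 0.99].
  Two numerical points: regressors are standardized (t-ratios are invariant)
  so the normal-equations lag search can detect collinearity by reciprocal
  condition number, and the search stops at the largest well-conditioned
  order — a noise-free sum of k sinusoids satisfies an exact order-2k
  recurrence, which would otherwise make high augmentation orders singular.
  The test is applied to candidate, reference, *and* difference series
  (reported separately); under perfect agreement the difference is constant
  and its row carries a declared degeneracy error rather than a p-value.
* **Cross-correlation** (`cross_correlation()`): both series are
  mean-centered and the CCF uses the full-series n-denominator
  normalization, so the lag-0 value equals the Pearson correlation of the
  pairs (asserted to 1e-12). **Positive lag means the candidate trails the
  reference** (candidate[t] tracks reference[t − lag]); the convention is
  stated because published tables rarely define the sign. Multi-video input
  is pooled per joint as the pair-count-weighted mean of per-video CCFs —
  concatenating videos would manufacture spurious cross-video lag terms.
  The significance band is ±1.96/√n. Default maximum lag:
  round(min(10·log10(n), n/4)). Ties at the maximum break toward the
  smallest |lag|. One caveat worth knowing: the n-denominator convention
  tapers the CCF by (n−|h|)/n, which biases the argmax toward 0 by ~1/n per
  lag; for *narrowband* motion whose per-lag decorrelation is of the same
  order (very slow movement, short videos) the detected lag can sit one
  frame inside the true one. Broadband movement or a few thousand frames
  make recovery exact, which is how the recovery experiments are set up.

## The synthetic study

`generate_paired_dataset()` emulates the *structure* of a markerless-capture
validation study: by default 10 videos of 145 s at 30 fps for both streams
(≈ 43,500 paired frames per joint), a reference stream in the 15-landmark
layout and a candidate stream in the Body25 layout.

Nine joint angles (shoulders, elbows, hips, knees, neck) are driven directly
by sum-of-two-sinusoid trajectories — baseline + amp₁ sin(2πf₁t + φ₁) +
amp₂ sin(2πf₂t + φ₂), frequencies drawn per video in 0.10–0.35 Hz and
0.45–0.90 Hz, phases uniform, all below the Nyquist rate and with amplitudes
validated to keep every angle inside (0°, 180°). A pelvis-rooted kinematic
chain realizes each driven angle *exactly* (each child segment's direction is
the parent ray rotated by the target angle), so extracted angles equal the
returned ground truth to floating-point accuracy — the closed-form oracle
behind many tests. The tenth angle, the pelvis, is geometrically determined
by the two legs; its ground truth is computed from the noise-free chain. A
slow 4° trunk sway keeps the whole skeleton moving.

The candidate stream is degraded by a deliberately simple model —
i.i.d. Gaussian pixel noise on every landmark, Bernoulli dropout (flagged
missing), sparse 80-px outliers in random directions, an optional integer
frame lag, and an optional constant angle bias applied after extraction.
Defaults (7 px noise, 1% dropout, 0.2% outliers) were **calibrated once** so
that the default study's pooled ICCs land in 0.95–0.99, the range a
well-performing 2D estimator achieves against a reference system, with the
per-joint movement amplitudes balanced so every joint sits inside the band
(average-measures ICC ≈ σ²ₛ/(σ²ₛ + σ²_d/4) with σₛ the signal SD and σ_d the
difference SD guided the balancing; measured values 0.96–0.985). A pleasing
emergent property: Gaussian *keypoint* noise induces a small negative *angle*
bias through the nonlinearity of the angle map, largest at the neck with its
short head segment — the same joint that dominates bias in real validation
studies — so the generator reproduces estimator-like bias without modeling
any estimator.

What the generator does **not** emulate: occlusion structure (dropout is
independent across landmarks and frames, real losses are correlated and
pose-dependent), estimator-specific failure modes (left/right swaps,
person-detection failures), perspective and camera motion, soft-tissue or
marker artifacts, and non-stationary movement repertoires. Passing the
synthetic study therefore demonstrates that the *statistical pipeline* is
correct and recovers known ground truth — it does not certify any particular
estimator.

## Tolerances and problem sizes in the test suite

* Exact identities (round trips, truth-vs-extracted angles, similarity
  invariance) are asserted at 1e-6 to 1e-12 as appropriate; oracle
  comparisons (ANOVA ICC, quantiles, convolution weights) at 1e-10 to 1e-12.
* The bias-recovery experiment injects 2.0° into the right shoulder at
  moderate noise (2 px) and checks the recovered bias within **±0.25° per
  seed** and within 3× the empirical replicate SE on the 20-seed mean.
  A ±3·SE/pair check would be mis-specified here: smoothing makes paired
  differences serially correlated, so SD/√n understates the sampling SD of
  the mean by a factor of ~2, while the absolute quarter-degree band is both
  stricter in practical terms and honest about the dependence.
* Lag recovery uses 60–90 s single-video studies with the second sinusoid
  pinned at 0.8 Hz (see the CCF taper caveat above); recovery is then exact
  for lags in −5..5 across seeds.
* Recovery and band experiments run on scaled studies (1–2 videos of
  30–90 s); the calibrated ICC band and the noise-free identity are also
  exercised at the full default size (10 videos × 145 s). These sizes are
  the package's chosen test conditions; all of the statistics concerned are
  n-consistent, and the full-size runs confirm the scaled results.

## Known limitations

* 2D projected angles are viewpoint-dependent; nothing here lifts to 3D or
  decomposes into anatomical planes.
* The ICC confidence interval assumes exchangeable, serially independent
  subjects; on smoothed frame series it is best read as an optimistic
  precision summary (this affects the interval, not the estimate).
* The ADF p-value is table-interpolated and clipped to [0.01, 0.99]; it is a
  decision device at α = 0.05, not a precise tail probability.
* Imputation quality degrades for gaps much longer than the window (it
  reverts to linear interpolation) and at series edges (nearest-value fill).
* `pair_angles()` assumes a shared clock up to frame rate; it cannot detect
  or fix a variable offset — the CCF stage diagnoses constant lags only.
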