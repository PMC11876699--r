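---
title: "Quantifying microtubule dynamics, polyglutamylation and Elongator binding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying microtubule dynamics, polyglutamylation and Elongator binding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtquant)
```

# Scope

`mtquant` quantifies the in vitro TIRF microscopy assays used to study how
the Elongator complex (its Elp123 and Elp456 subcomplexes) interacts with
dynamic microtubules and free tubulin:

1. rigid drift registration of time-lapse movies by cross-correlation;
2. kymograph tip tracking, growth-event segmentation, growth speeds
   (slopes) and lifetimes (onset of growth to the last frame before a
   catastrophe);
3. the lifetime statistic: gamma maximum-likelihood fit of the lifetime
   distribution, the lifetime at half cumulative distribution (the fitted
   median), and its bootstrap interquartile-range error;
4. polyglutamylation scoring of snapshot images: 2-px linescans,
   edge-of-linescan background subtraction, field-of-view (FOV) averaging
   and normalization to the seed channel;
5. mass-action 1:1 binding: the quadratic depletion isotherm, occupancy
   predictions between affinity variants, and dissociation-constant (Kd)
   fitting from two-fold dilution titrations.

Because the raw assays are imaging data, the package ships a first-class
synthetic-data generator that renders event tables, kymographs, multichannel
FOV images, drifting movies and titration curves with known ground truth, so
every pipeline stage can be validated end to end by parameter recovery.

# The dynamic-instability model and its simulator

Microtubules grow from stabilized GMPCPP seeds at both ends: a fast plus end
and a slow minus end. Each end alternates growth episodes at a constant
speed $v$ with abrupt catastrophes. The waiting time to catastrophe (the
growth *lifetime*) is modelled as gamma distributed,
$\tau \sim \Gamma(k, \theta)$, the standard choice for the multi-step,
non-exponential statistics of GTP-cap loss.

Simulator defaults (`dynamics_params()`), all overridable:

| parameter | default | meaning |
|---|---|---|
| `v_plus` | 1.002 µm/min | plus-end growth speed (buffer control) |
| `v_minus` | 0.348 µm/min | minus-end growth speed (buffer control) |
| `lifetime_shape` | 3 | gamma shape $k$ |
| `lifetime_scale` | 75.77 s | gamma scale $\theta$, set so the median is 202.61 s |
| `shrink_speed` | `Inf` | collapse back to the seed within one frame |
| `regrow_delay` | 20 s | pause at the seed before re-nucleation |

The gamma *shape* is not identifiable from the recovery targets used here
(they depend only on the distribution's median), so $k = 3$ is an explicit
modelling choice giving realistically peaked, non-exponential catastrophe
statistics. Shrinkage is instantaneous because all downstream measurements
use growth segments only. Events still growing when the movie ends are
flagged censored and the generator guarantees per-seed bookkeeping:
censored + uncensored events = nucleation episodes.

Imaging (`imaging_params()`) emulates a 100x TIRF rig with an sCMOS camera:
0.107 µm/px, 2 s frame interval, Gaussian PSF with $\sigma$ = 1.3 px,
constant background (100 counts) and Gaussian noise (sd 8 counts by
default; Poisson available). Rendering is the exact convolution of each
line segment with the PSF (an erf profile along the axis and a Gaussian
across it), which makes the pixel sum of an isolated filament exactly
`density x length x gain` and keeps every image affine in gain and
background — both properties are asserted in the test suite.

# Kymograph analysis

**Tip localization.** For each frame and each side of the seed the tip is
the farthest half-maximum crossing of the smoothed intensity profile beyond
the seed, linearly interpolated to subpixel. The half-maximum level is half
of the kymograph's robust plateau amplitude (median of per-frame maxima over
frames with clear signal) above a per-frame baseline taken from the
outermost pixels. A fixed, plateau-derived level has two virtues: for an
edge blurred by a symmetric PSF the crossing sits exactly at the true tip,
and the measurement is invariant to constant offsets and to uniform
intensity scaling. Frames whose own maximum falls below 75% of the plateau
(extensions shorter than a few PSF widths) are flagged `"low"`; frames with
no signal beyond the seed are `"none"` and sit at the seed edge.

**Event segmentation.** Growth is registered when the tip exceeds the seed
edge by 3 px; a catastrophe when the tip regresses by more than 3 px within
one frame interval or returns to the seed edge. The 3-px threshold is a
robustness device, not a definition of onset: after detection the onset is
refined backwards to the frame at which the tip actually left the seed edge,
so lifetimes are not biased by the threshold. The catastrophe time is the
last frame before the collapse. Events still growing at the last frame are
censored.

**Speeds and lifetimes.** The growth speed is the ordinary least-squares
slope of tip position versus time over the event, converted to µm/min.
Whole-event OLS (rather than frame-to-frame differences) averages over
transient growth irregularities; the residual sd is reported per event so
irregular events can be audited. Only full-amplitude (`"ok"`) frames enter
the fit: while the extension is shorter than a few PSF widths the
half-maximum crossing localizes short, and including those frames steepens
the slope (a ~2–7% bias in early experiments; with the filter the
estimator mean is within 2 SEM of truth at n = 300 events). Events with
fewer than 3 usable frames are dropped with a warning and counted.
Lifetimes are reported for uncensored events only; the censored count is
always carried alongside so the exclusion is visible. Polarity is assigned
per seed by mean speed (faster side = plus end), ties broken toward the
side with more events and then lexicographically (flagged ambiguous);
single-sided seeds are `"unknown"`, never guessed.

# The lifetime statistic

The lifetime sample is summarised by the gamma fit's median rather than the
raw mean, following the cumulative-distribution fitting approach for
catastrophe statistics:

1. `fit_gamma_mle()` — shape from
   $\log k - \psi(k) = \log \bar{x} - \overline{\log x}$ by Newton
   iteration (method-of-moments-style initialisation, relative tolerance
   $10^{-12}$), then $\hat\theta = \bar{x}/\hat{k}$. Samples that are
   degenerate (all equal, or containing non-positive values) are rejected
   with explicit errors. Shapes beyond $10^8$ are accepted as converged:
   there the distribution is effectively deterministic and digamma
   cancellation limits attainable precision.
2. `half_cumulative_lifetime()` — the time where the fitted cumulative
   distribution equals 0.5, by inverting the regularized incomplete gamma
   function (`qgamma`) to $10^{-9}$. For exponential data this reduces to
   $\theta \ln 2$, which the tests verify to $10^{-6}$ relative.
3. `bootstrap_lifetime_error()` — 10,000 resamples with replacement at the
   observed sample size, each refit through steps 1–2; the reported error
   is the 75th − 25th percentile range of the bootstrapped medians, with
   percentiles by linear interpolation (type-7), stated because IQR
   conventions differ. Resamples that fail to fit are skipped and counted;
   more than 1% failures is a hard error rather than a silent retry. The
   resampling is vectorised (one index matrix, one vectorised Newton), so
   $B = 10^4$ at $n = 300$ takes well under a second.

The likelihood is not censoring-aware: censored events are excluded before
fitting, which biases the lifetime distribution slightly short when long
events run into the end of the movie. The censored count is always reported
so this is visible; a censoring-aware likelihood is a known limitation, not
an oversight.

# Polyglutamylation scoring

Each microtubule is traced with a 2-px-wide linescan sampled at 1-px
arclength steps (perpendicular offsets of ±0.5 px, bilinear interpolation).
The per-microtubule value is the mean over the on-microtubule span minus
the background, where the background is the mean of the 5 outermost samples
at both ends of the trace — the trace deliberately extends beyond the
polymer so those edges are signal-free. Traces whose edges are *not*
signal-free (edge mean above the on-span mean) are excluded with a recorded
reason, and n totals always reconcile. The FOV statistic is

$$\text{normalized} = 100 \times
  \frac{\langle \text{per-MT antibody mean} \rangle_{\text{FOV}}}
       {\langle \text{seed intensity} \rangle_{\text{FOV}}},$$

with the seed intensity measured over seed masks after subtracting the
median of the non-mask pixels. The factor 100 is a reporting convention
chosen so that typical synthetic calibrations (seed means ≈ 175 counts)
land on a convenient 10–25 scale; every comparison made with the statistic
is a ratio, so the constant is neutral. The condition mean over FOVs equals
the mean of FOV means by construction (averaging per FOV first, then across
FOVs — preserved exactly).

Two numerical details matter at the percent level. First, the on-span is
inset 3 px from the polymer tips so the partial PSF roll-off at the ends
does not dilute the mean. Second, reading the pixel grid by bilinear
interpolation convolves the profile with a tent kernel of variance 1/6 px²
(direction-independent), so `expected_linescan_value()` predicts the
measurement with an effective perpendicular sd of
$\sqrt{\sigma_{\text{PSF}}^2 + 1/6}$; without this term the prediction runs
~4% hot. Remaining systematics (crossing microtubules, discretisation) stay
within a few percent and are covered by the recovery tolerances.

`per_seed_total_signal()` implements the coarser whole-FOV metric: the
channel total minus (mean of a signal-free region × pixel count), divided
by the seed count. The signal-free region is user-supplied; no default
region is guessed.

# Drift registration

Pairwise shifts between successive frames come from the FFT
cross-correlation peak of mean-subtracted, Hann-tapered frames
(the taper suppresses wraparound artefacts), refined to subpixel by
quadratic interpolation of the peak and its neighbours, then accumulated
relative to frame 1. Correction translates every channel by the negated
cumulative shift with bilinear interpolation, filling uncovered edges with
the frame median. Flat (zero-variance) frames are an error, not a (0, 0)
shift. The contract is translation equivariance and idempotence
(re-estimating on a corrected movie gives ≈ 0); synthetic round trips keep
residual drift below 0.1 px/frame. Rotation and scale are out of scope.

# Binding analysis

For 1:1 binding $R + L \rightleftharpoons RL$ with totals comparable to
$K_d$, free ≈ total fails and the exact (quadratic depletion) root is
required:

$$[RL] = \tfrac{1}{2}\left(b - \sqrt{b^2 - 4 R_t L_t}\right),
  \quad b = R_t + L_t + K_d,$$

evaluated as $2 R_t L_t / (b + \sqrt{b^2 - 4 R_t L_t})$ for numerical
stability when $K_d \gg R_t L_t$. `percent_reduction()` turns this into the
occupancy prediction between two affinity variants at fixed totals; at
50 nM / 100 nM totals, moving from a 15.5 nM to a 67.1 nM dissociation
constant removes about a third of the complex:

```{r occupancy}
percent_reduction(15.5e-9, 67.1e-9, R_total = 50e-9, L_total = 100e-9)
```

One Elp456 copy per Elp123 is assumed for this prediction (the
preferentially occupied site); the algebra itself is agnostic and can be
applied per site if a two-site extension is needed.

`fit_kd()` fits titration curves
$s(L_t) = s_{\text{free}} + (s_{\text{bound}} - s_{\text{free}})
\cdot f_{\text{bound}}(L_t)$ by Levenberg–Marquardt with $K_d$
parameterised in log space — the affinities of interest span nanomolar to
tens of micromolar, and the log parameterisation respects positivity across
that range. Initialisation is from the half-maximal-response concentration.
Fits that do not converge, or whose $\hat{K}_d$ escapes far outside the
sampled concentration range, are flagged invalid rather than returned
silently. No Hill coefficient is fitted (plain 1:1). For the synthetic
titrations the dilution series must actually bracket the isotherm: for
nanomolar affinities the generator uses 24 two-fold dilutions from a
2.5 µM top (a 84 nM top leaves the bound plateau unsampled and makes
$K_d$ and $s_{\text{bound}}$ jointly unidentifiable under noise); the
micromolar tubulin case uses 16 dilutions from 200 µM. The labeled species
is constant at 50 nM and noise is 5% of the dynamic range unless stated.

# What the synthetic data does and does not emulate

The generator reproduces: straight filaments elongating from bright seeds
at constant per-end speeds, gamma-distributed catastrophes, censoring at
the movie end, Gaussian-PSF rendering with realistic pixel size and frame
interval, background and Gaussian/Poisson noise, rigid (sub)pixel drift,
per-microtubule antibody densities with log-normal variability, and
titrations under the exact depletion isotherm with additive noise.

It does **not** emulate: curved or bundled microtubules, rescue events,
finite shrinkage speeds, photobleaching, uneven illumination, camera
fixed-pattern noise, stage jitter beyond rigid translation, antibody
binding kinetics, or competition between ligands. Passing recovery tests
therefore demonstrates correctness of the measurement chain under the
stated model, not robustness to every artefact of real data — the usual
division of labour between unit-level validation and instrument controls.

# Problem sizes and reproducibility

All randomness flows through explicit integer seeds; identical seeds give
bit-identical event tables and titrations. The test-suite and the
acceptance analyses use: ≥300 plus-end and ≥130 minus-end growth events
per speed condition; n = 300 lifetimes with B = 10,000 bootstrap
resamples; 100 simulated titrations per affinity; 9 FOVs of ~70
microtubules per condition (1024×1024 px). These sizes mirror the scale of
the corresponding wet-lab datasets (hundreds of events, hundreds of
microtubules over 6–9 FOVs) while keeping a full run to a few minutes on
one CPU.

# Known limitations

- Lifetimes from the kymograph pipeline inherit a small negative bias
  (~one detection delay at the given growth speed) because onsets can only
  be refined back to the first frame with signal above the plateau's
  half-maximum; this is visible in, and tolerated by, the distribution
  consistency checks, and is irrelevant to the lifetime statistic itself,
  which is fed event tables directly.
- The gamma likelihood ignores censoring (see above).
- Tip tracking assumes one growing extension per seed side; crossing or
  overlapping filaments are flagged by the generator but not disentangled
  by the tracker.
- The normalized-intensity constant (×100) and the seed-mask convention
  (pixels within 1.5 px of the seed segment) are package conventions;
  only ratios of the statistic are meaningful across analyses.
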