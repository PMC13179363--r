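---
title: "Estimating within- and cross-frequency cortico-kinematic coupling with xfcacoh"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating within- and cross-frequency cortico-kinematic coupling with xfcacoh}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xfcacoh)
```

## The problem

During rhythmic movement, cortical activity phase-locks to the movement
kinematics — at the movement frequency, at its harmonics, and across
frequencies, where a faster cortical rhythm follows an integer multiple of a
slower peripheral one. Detecting such coupling from dense-montage EEG is hard
for two reasons: volume conduction spreads every cortical source over many
electrodes, so the informative linear combination of channels is unknown; and
a cross-frequency relation cannot be measured by ordinary coherence, which
compares signals at a common frequency.

`xfcacoh` addresses both. The multivariate part is canonical coherence: find
the real channel weights that make the projected EEG maximally coherent with
the peripheral signal at a chosen frequency bin. The cross-frequency part is
frequency warping: deform the slow peripheral signal so that its phase runs
`r` times faster while its amplitude envelope is untouched, then apply the
same coherence maximization at the fast bin.

## Model and estimation

### Cross-spectra

All estimation happens on Welch-averaged cross-spectral matrices. Signals are
cut into segments (default 1 s, 50% overlap, Hann taper, per-segment mean
removal), Fourier transformed with the `e^{-j2πft}` convention, and outer
products averaged into the blocks `C_AA` (EEG × EEG), `C_BB` and `C_AB`. With
1 s segments the bin spacing is 1 Hz, so the study frequencies 3, 6 and 9 Hz
fall on exact bins. The convention fixes the phase sign: a peripheral signal
lagging the EEG at frequency f yields a positive `Arg(C_AB)` at that bin; the
package asserts this with an analytic two-sinusoid case.

### Canonical coherence

At one bin the coupling strength of projections α (EEG) and β (periphery) is

$$L(\alpha,\beta) = \frac{|\alpha^\top C_{AB} \beta|^2}
  {(\alpha^\top C_{AA}\, \alpha)(\beta^\top C_{BB}\, \beta)},$$

with α, β restricted to real coefficients (instantaneous mixing assumption).
`maximize_cacoh()` alternates three closed-form updates: with the phase
rotation φ fixed, `α ∝ Re(C_AA)⁻¹ Re(C_AB e^{-jφ}) β`; symmetrically for β;
then `φ = arg(αᵀ C_AB β)`. The phase parameter represents the optimal per-bin
delay of the projected pair. Each sweep is non-decreasing in L — this is
asserted at every iterate, so a violation aborts rather than silently
degrades — and the best of 10 seeded random restarts is kept. Reported
strength is √L, on the same [0, 1] scale as ordinary coherence magnitude;
the squared value is stored alongside.

The channel weights themselves are not interpretable topographies. The
spatial pattern is obtained by mapping the filter through the real part of
the within-space cross-spectrum, `p = Re(C_AA) α`; its polarity is fixed by
making the largest-magnitude entry positive, and filters are normalized to
unit projected power (`αᵀ Re(C_AA) α = 1`).

A univariate peripheral signal makes β a scalar, and the problem then has a
closed-form solution through a two-dimensional eigenvalue problem. The
package deliberately does not use that shortcut as its estimation path — the
alternating solver is the method under test — but the eigen solution serves
as an independent oracle in the test suite, alongside an exhaustive
grid-search oracle for two-channel instances.

### Frequency warping

For an `f_q : f_r` interaction with `f_r = r f_q` (the package fixes `q = 1`;
non-integer ratios are out of scope), the peripheral signal is band-filtered
around `f_q`, its analytic representation `s(t) = x(t) + jH{x(t)}` computed
by FFT, and the warped surrogate `Re{a(t) e^{j r φ(t)}}` constructed from the
unwrapped phase. Unwrapping before multiplication avoids 2π-discontinuity
artifacts. `xf_ckc()` is then `ckc()` between the EEG and the warped signal
at the `f_r` bin. With `r = 1` the warp is the identity operation and
`xf_ckc()` uses the peripheral signal as-is, so the cross-frequency path
reduces exactly to the within-frequency one.

### When filtering is skipped

Narrow-band filtering exists to isolate the band whose phase is to be read.
Re-filtering a signal that is *already* isolated at the target band — the
warp output, or an oscillator produced by the very same filter — does not
remove any out-of-band energy; it only reshapes the in-band spectral weights
(the 4-pole Butterworth is 3 dB down at the band edges per pass), which
perturbs the instantaneous phase and caps the measurable synchronization of
a perfectly locked warped copy at about 0.95–0.96 regardless of filter
order. `band_filter()` and `warp_frequency()` therefore tag their outputs
with the band they occupy, and `cross_freq_sync()` / `warp_frequency()` skip
the filtering step when the input already carries a matching tag. Raw,
untagged inputs (real recordings) are always filtered. With this rule a
warped copy measures k_sync ≥ 0.99 against its source, as it should by
construction.

### Synchronization index

`sync_index()` implements the circular mean statistic
`k_sync = |N⁻¹ Σ e^{j(qφ_r − rφ_q)}|`. It is invariant to global phase
offsets, symmetric under swapping the inputs together with (q, r), equals 1
exactly under constant phase difference, and scales as `√π/2/√N` under
independence. `cross_freq_sync()` wraps it with the filtering + Hilbert +
edge-exclusion pipeline; peripheral self-coupling (e.g. 3:6 within an
accelerometer component) is the same function applied to `(x, x)`.

## Tunable parameters

| Parameter | Default | Meaning / rationale |
|---|---|---|
| `segment_len_s` | 1 s | Welch segment; 1 Hz resolution puts 3/6/9 Hz on exact bins |
| `overlap_frac` | 0.5 | standard bias/variance trade-off with Hann taper |
| `half_bw_hz` | f/3 | constant relative bandwidth: 1 Hz at 3 Hz, 2 Hz at 6 Hz, 3 Hz at 9 Hz |
| `n_restarts` | 10 | random initializations of the alternating solver |
| `tol` | 1e-8 | relative objective-change convergence threshold |
| `gamma` | 1e-4 | shrinkage `(1−γ)C + γ(tr/P)I` of `Re(C_AA)`, `Re(C_BB)`; stabilizes 61-channel inversion |
| `n_perm` | 199 | permutations; the 95th percentile is the 190th order statistic |
| `epoch_len_s` | 1 s | epoch length for trial permutation when no task blocks are given |
| `lag_ms` | 20 | brain lag behind periphery in simulations (10 samples at 500 Hz) |
| `snr_peripheral` | 10 | variance ratio of summed oscillators to white noise |
| `snr_brain` | grid 0.5…0.01 | per-component projected-variance / background-variance ratio |

## Numerical choices

* **Filter order.** The band-pass is a 4th-order (4-pole) Butterworth
  transfer function applied forward and backward (zero phase). A
  higher-order band-pass in transfer-function form is numerically unstable at
  the method's own operating point (a 2–4 Hz band at 500 Hz sampling places
  all poles near `z = 1`; instability verified directly), while the 4-pole
  design applied twice already attenuates 9 Hz by ~48 dB relative to a 3 Hz
  passband — comfortably beyond the 40 dB the narrow-band analyses need.
* **Edge handling.** Filtering reflect-pads the signal by three filter time
  constants; all phase-based indices additionally discard 2 s per end
  (tagged in an `edge_s` attribute).
* **Degenerate inputs.** A zero signal has amplitude 0 and, by convention,
  phase 0. A zero between-space block yields coherence 0 with the initial
  filters. Patterns orthogonal to the averaging reference keep their polarity
  with a warning. Ties in `nearest_bin()` break toward the lower frequency.
* **Regularized vs raw matrices.** The solver iterates on shrinkage-
  regularized matrices; final coherence, normalization and patterns are
  reported on the raw (unregularized) matrices and clamped to [0, 1].
* **Permutation p-values** default to the add-one estimator
  `(1 + #{null ≥ obs})/(1 + n_perm)`, which cannot be exactly zero; the plain
  proportion is available via `p_method = "plain"`. The 95th percentile uses
  the nearest-rank method, which is bit-reproducible across platforms.
* **Permutation efficiency.** Shuffling peripheral epochs leaves the EEG
  untouched, so the null re-runs cache the EEG-side per-segment spectra and
  the Cholesky factor of `Re(C_AA)` at the bin of interest, and recompute the
  peripheral side (including re-filtering and re-warping for cross-frequency
  interactions) in full for every draw. The cached path is arithmetically
  identical to the full pipeline restricted to the bin; the test suite
  asserts agreement to ~1e-9.

## The simulation framework

`assemble_scenario()` generates the three study designs:

* **S1** — three *independent* narrow-band Gaussian oscillators at 3, 6, 9 Hz
  with variance ratios 1 : 1/2 : 1/4 compose the peripheral signal (plus
  white noise at total SNR 10). Five cortical sources: within-frequency
  copies of each oscillator (3:3, 6:6, 9:9) and warped copies of the 3 Hz
  oscillator at 6 and 9 Hz (3:6, 3:9), each on its own topography.
* **S2** — the 6 and 9 Hz peripheral components are *warped copies* of the
  3 Hz oscillator, making the peripheral signal non-sinusoidal with genuine
  3:6 and 3:9 coupling. Three cortical sources: the two warped components
  plus an independent 6 Hz oscillator that no analysis should be able to
  localize.
* **S3** — as S2, with the two coupled sources sharing one topography.

All cortical sources are delayed 20 ms behind the periphery, projected
through the leadfield, and scaled so that the mean-over-channels variance of
each projected component over that of the 1/f background equals `snr_brain`
exactly (the ratio is enforced by construction and re-measured in tests, not
assumed). The background sums 500 independent pink-noise dipoles with random
unit topographies. Oscillator bandwidth is ±1 Hz at 3 Hz, scaled
proportionally at 6 and 9 Hz. Peripheral noise is scaled so the realized
oscillator-sum-to-noise variance ratio is exactly 10.

**The synthetic leadfield.** An anatomically realistic three-shell forward
model would require head-geometry data this package deliberately does not
depend on. `synthetic_leadfield()` replaces it with pseudo-dipolar
topographies — differences of two spatial Gaussians at nearby random
locations on a 61-electrode spherical-cap layout, unit-normalized, resampled
until pairwise |cosine| < 0.8 between distinct sources. This preserves the
properties the method actually exercises (smooth, overlapping, full-rank
mixing with distinguishable truth patterns) but not scalp physics: absolute
coherence levels and failure thresholds measured here cannot be read as
quantitative predictions for real EEG. `assemble_scenario(leadfield = ...)`
accepts a user-supplied forward matrix to restore realism.

Two counts are deliberately configurable because the study design admits
both readings: repetitions per SNR default to 10 (the permutation analysis
count) and may be raised to 100; the SNR grid has the six listed values
(0.5, 0.25, 0.1, 0.05, 0.025, 0.01).

## What the validation shows — and what it does not

The test suite validates, at desk scale (sizes chosen to keep the full run in
minutes on one CPU): generator fidelity (power ratios, peripheral SNR, lag,
re-measured from generated data, with the peripheral SNR check averaged over
ten 120 s realizations); optimizer-vs-oracle agreement on a 50-instance
random battery; exact reductions (single-channel = Welch coherence, identity
warp = within-frequency fit); pattern recovery on S1 at 120 s with median
recovery error below 0.15 (3:3) and 0.25 (3:6, 3:9) at SNR 0.5 and mean
error non-increasing in SNR over {0.5, 0.1, 0.01}; the uncoupled 6 Hz source
remaining at chance-level recovery at every SNR (S2/S3, 60 s, three
repetitions per condition); 5%-level calibration of the permutation test
over 200 null datasets (30 s, 10-channel backgrounds); and the
shared-generator diagnostic — on an S2 bundle whose 6 Hz cortical source
*is* the warped peripheral, the 6:6 and 3:6 analyses agree spatially
(k_sim > 0.95) and dynamically (projected-source k_sync > 0.9).

Passing these tests shows the estimator is correct and calibrated *under the
generator's assumptions*: Gaussian narrow-band sources, instantaneous linear
mixing, stationary noise, a known integer frequency ratio. Real recordings
violate several of these (artifacts, nonstationarity, imperfect tapping
rhythm, unknown SNR), so empirical significance should always come from the
built-in permutation tests on the data at hand, not from simulation
thresholds.

## Known limitations

* Only the first canonical pair is extracted; deflation for further pairs is
  not implemented.
* The optimal delay is modeled as a per-bin phase rotation; a broadband
  time-lag parameterization is a possible alternative interpretation and is
  not implemented.
* `q` is fixed to 1 in the analysis surface (integer harmonic ratios only);
  the synchronization core accepts general (q, r) for testability.
* No artifact cleaning: the real-data workflow assumes pre-cleaned EEG.
* No source localization of patterns; patterns live in channel space.
* The warping integer `r` must be chosen a priori; data-driven discovery of
  coupling ratios is future work.
* Warping is not compositional: warping by `r` twice is not the same
  operation as warping by `r²` (each pass re-extracts an envelope), and no
  such equivalence is claimed or tested.
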