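# xfcacoh

Within- and cross-frequency cortico-kinematic coherence for multichannel
electrophysiology.

Cortico-kinematic coherence (CKC) measures coupling between cortical activity
(EEG/MEG) and movement kinematics (typically accelerometry), a non-invasive
marker of sensorimotor integration. Conventional CKC is bivariate and
within-frequency; it misses both the spatially distributed nature of cortical
sources and cross-frequency interactions in which a faster cortical rhythm
locks to an integer multiple of a slower peripheral one. `xfcacoh` provides a
multivariate estimator for both cases, aimed at motor-neuroscience
researchers working with dense-montage EEG and peripheral kinematic
recordings.

## Method

**Canonical coherence (caCOH).** Given per-bin cross-spectral matrices
C_AA (EEG), C_BB (periphery) and C_AB (between the spaces), find real
projection vectors α, β maximizing

    L(α, β) = |αᵀ C_AB β|² / ((αᵀ C_AA α)(βᵀ C_BB β))

The reported coupling strength is √L ∈ [0, 1]. Optimization alternates
closed-form updates of α, β and a per-bin phase φ = arg(αᵀ C_AB β) that
absorbs the optimal delay of the projected pair; the objective is provably
non-decreasing per sweep, and the best of several random restarts is kept.
The interpretable topography is the spatial **pattern** p = Re(C_AA) α, not
the filter itself. With a univariate peripheral signal only the EEG-side
filter is free.

**Cross-frequency extension (XF-caCOH).** For an f_q : f_r interaction with
f_r = r·f_q (integer r), the peripheral signal is band-filtered around f_q,
its analytic amplitude a(t) and phase φ(t) are extracted via the Hilbert
transform, and a frequency-warped surrogate

    b_r(t) = Re{ a(t) · exp(j r φ(t)) }

is built, which keeps the amplitude envelope while shifting the dominant
frequency to r·f_q. caCOH applied between the EEG and the warped signal at
the f_r bin then quantifies cross-frequency phase coupling.

**Supporting machinery.** n:m phase-synchronization index
k_sync = |mean exp(j(q·φ_r − r·φ_q))|; pattern recovery error
RError = 1 − |p_origᵀp_rec| / (‖p_orig‖‖p_rec‖) and its complement k_sim;
polarity-aligned pattern averaging; epoch-permutation significance tests
(95th-percentile criterion); a full simulation framework with narrow-band
Gaussian oscillators, a synthetic pseudo-dipolar leadfield, and 1/f dipole
background noise at controlled brain SNR.

## Worked example

Simulate a 61-channel recording with five coupled sources and recover the
3:6 Hz cross-frequency interaction:

```r
library(xfcacoh)

scenario <- simulation_scenario("S1", snr_brain = 0.25, duration_s = 120,
                                fs = 250, seed = 7)
bundle <- assemble_scenario(scenario)

fit <- ckc(bundle$eeg, bundle$peripheral, f = 3, seed = 1)
summary(fit)
#> <cacoh_fit> ckc 3:3 Hz
#>   coherence 0.9924 at bin 3 Hz (239 Welch segments)
#>   phi = -0.375 rad, converged: TRUE, restarts: 10
#>   strongest pattern channels:
#>     E08      +0.6275
#>     E19      +0.5831
#>     ...

xf <- xf_ckc(bundle$eeg, bundle$peripheral, coupling_spec(3, r = 2), seed = 1)
xf
#> <cacoh_fit> xf_ckc 3:6 Hz
#>   coherence 0.9571 at bin 6 Hz (239 Welch segments)
recovery_error(bundle$truth_patterns[["3:6"]], xf)
#> [1] 0.001

pt <- coupling_significance(bundle$eeg, bundle$peripheral,
                            coupling_spec(3, r = 2), n_perm = 199, seed = 2)
pt
#> <perm_null> coherence: observed 0.9571, null 95th pct 0.4419, p = 0.005 (199 permutations)
```

The within-frequency fit reaches coherence 0.99 at the 3 Hz bin and its
pattern concentrates on the channels nearest the simulated source. The
cross-frequency fit at the 6 Hz bin recovers the warped-source topography
almost perfectly (recovery error 0.001) and its strength far exceeds the
epoch-permutation null, so the 3:6 Hz coupling is significant.

The methods vignette (`vignettes/xf-cacoh-methods.Rmd`) documents the model,
the generator, all tunable parameters and the package's numerical choices.

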