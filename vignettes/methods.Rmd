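---
title: "Measurement model and estimator choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measurement model and estimator choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardioratio)
```

This vignette documents the forward model behind the synthetic heart, the
estimators used by the analysis pipeline, and the conventions and known
limitations a user should be aware of when interpreting results.

## 1. The forward model

### Calcium dynamics

Each chamber's free-calcium trace is a baseline (`ca_diastolic`) plus a
train of transients. A single transient is the difference-of-exponentials
kernel

$$k(t) = \frac{e^{-t/\tau_d} - e^{-t/\tau_r}}{\max_s\,(e^{-s/\tau_d} - e^{-s/\tau_r})}, \qquad t \ge 0,$$

normalised so its peak is 1 and scaled so the peak calcium equals
`ca_systolic`. The kernel is causal and unimodal with its maximum at the
closed-form time $t_{pk} = \frac{\tau_r \tau_d}{\tau_d - \tau_r}
\log(\tau_d / \tau_r)$.

Atrial events fire periodically at `heart_rate`; ventricular events follow
each *conducted* atrial event after `av_delay`. `conduction_ratio = n`
conducts every n-th atrial beat (2:1, 3:1 block); `conduction_ratio = Inf`
conducts none (complete block, silent ventricle).

### Sensor models

Fractional sensor occupancy follows a Hill equation,
$\theta = \mathrm{ca}^{h} / (K_d^{h} + \mathrm{ca}^{h})$.

* **FRET ratio**: the numerator (acceptor) channel scales as
  $1 + D\,\theta$ and the denominator (donor) as $1 - \tfrac{D}{1+D}\theta$,
  so the true ratio rises with calcium while total intensity is roughly
  conserved.
* **Reference-fused**: only the numerator channel is calcium-dependent;
  the denominator is a constant reference fluorophore translated with the
  same tissue.
* **Aequorin**: the instantaneous consumption rate constant is
  $k(\mathrm{ca}) = k_0\,\theta$; the remaining photoprotein pool decays as
  $P_{t+1} = P_t\,e^{-k\Delta t}$ and the expected photon count in a frame
  is $P_t (1 - e^{-k\Delta t})\cdot$`photon_scale`.

### Geometry and rendering

Chambers are ellipses whose axes contract by `contraction_fraction`
(linear scale chosen so the *area* loss equals the configured fractional
area change) in phase with the ventricular transient. Rendering draws
per-channel intensities over a `background_level` offset and adds Poisson
photon noise plus Gaussian read noise; ground truth (true ratio traces,
per-frame chamber masks, event times) is returned alongside the movie.

## 2. Ratio pipeline

`compute_ratio_movie` subtracts the (known or estimated) background from
both channels, then ratios pixel-wise. A pixel/frame is **invalid** when
the denominator is non-positive or the ratio falls outside
`[min_displayed/4, max_displayed*4]`; invalid pixels are `NA` in the
ratio stack and excluded from all downstream averages. Background
subtraction matters: without it, non-tissue pixels ratio to approximately
1 (background over background) and dilute the ROI mean toward 1 instead
of being excluded as invalid.

`roi_weighted_ratio` averages valid in-ROI pixels with weights
$w = (I_{num} + I_{den})/2$, so dim, noise-dominated pixels contribute
little. This is the estimator verified against brute-force loops in the
acceptance suite.

Channel misalignment is estimated by `estimate_pixel_shift` (integer
shift maximising normalised cross-correlation, ties broken toward zero
shift) and applied with `apply_shift`, which NA-fills and shrinks the
valid field rather than wrapping.

## 3. Kinetics

### Peak detection and the noise floor

Traces are smoothed with a Savitzky–Golay filter (default window 7,
order 3). Candidate peaks are local maxima passing a topographic
prominence threshold: prominence must exceed
`prominence_fraction` × robust amplitude **and** an absolute floor
`min_amplitude`. A refractory period suppresses double-counting of
secondary humps.

The absolute floor exists because relative thresholds fail on quiescent
traces (a silent ventricle in complete block): with no true peaks, the
"amplitude" is pure noise and any relative cut passes noise excursions.
When calling `segment_cycles` on an **already-smoothed** trace, note that
naive successive-difference noise estimates are biased low (smoothing
correlates neighbours; for SG(7,3) the lag-1 autocorrelation is ≈ 0.74).
The workflow therefore estimates the raw noise SD from the smoothing
*residual*, corrected for the filter's variance shrinkage, and passes a
multiple of it as `min_amplitude`.

### Cycle and frequency conventions

With $p$ detected peaks, `n_cycles` $= p - 1$ (complete peak-to-peak
cycles). Frequency is reported two ways: count-based
(peaks / duration × 60, exact for clean rhythms) and interval-based
(60 / median inter-peak interval). Systolic is the mean of per-cycle
maxima, diastolic the mean of inter-peak minima, amplitude their
difference.

### Known limitation: decay-tail bias in diastolic ratio

Measured diastolic is the mean of inter-beat *minima*. At high heart
rates relative to $\tau_d$ the transient has not fully decayed before the
next beat, so measured diastole sits above true baseline — and the bias is
*rate-dependent* (a 150 min⁻¹ heart inflates more than a 110 min⁻¹ one).
Between-group diastolic comparisons at different rates therefore compare
baseline *plus* a rate-dependent offset; small true baseline differences
can be masked or exaggerated. This is a property of the minima estimator,
not of the ratio pipeline.

### AV-block classification

`detect_av_block` classifies from the ratio of median inter-peak
intervals (ventricular / atrial): within tolerance of an integer
$n \ge 2$ → "n:1"; ≈ 1 → "none"; a silent ventricle → "irregular"
(complete block); anything else → "irregular". Interval ratios are robust
where raw event-count ratios are not: 9 atrial vs 4 ventricular peaks in
a window gives a count ratio of 2.25 for a true 2:1 rhythm. The count
ratio is still reported as `conduction_ratio_estimate`.

## 4. Morphometry

`fractional_area_change(ed, es)` is $(A_{ED} - A_{ES}) / A_{ED}$, exact
by construction. `frame_select_extremes` segments the area trace into
cycles and averages per-cycle maxima (end-diastolic) and minima
(end-systolic); without detectable cycles it falls back to global
extremes and flags `no_cycle`. Areas come from pixel counts
(`mask_area_trace`, `roi_area$raster_area`) or the shoelace formula for
polygon ROIs.

## 5. Aequorin quantification

Raw counts are background-subtracted and converted to a rate
(`rlu_to_rate`), then `consumption_transform` computes, per frame,
$L/L_{max}$ where $L_{max}$ is the remaining (discounted) photon budget —
total emission minus emission consumed so far. Identities that hold
exactly: $L_{consumed} + L_{max} = L_{total}$ at every frame, and
invariance of $L/L_{max}$ under any positive detector gain. Under
constant calcium, $L/L_{max}$ per unit time equals
$(1 - e^{-k\Delta t})/\Delta t$, a constant — but only frames with a
non-exhausted pool are informative; the final frames, where $L_{max}$
approaches zero, are reported but numerically unstable, which is why
`time_averaged_ca_proxy` takes an explicit window.

## 6. Statistics

`normality_gate` runs Shapiro–Wilk on every group; all pass → parametric
(Student t; one-way ANOVA with Tukey all-pairs or Dunnett
versus-control), any fail → nonparametric (Mann–Whitney;
Kruskal–Wallis with tie-corrected, Bonferroni-adjusted Dunn post-hoc).
Chi-square for count tables uses no continuity correction by default.
Parametric significance codes use `*` families, nonparametric `x`
families, so a table row shows which branch was taken. Type-I error of
every test is verified at 2000 null replicates in the acceptance suite.

## 7. Reproducibility

`run_experiment` derives one seed per larva from the run seed
(`seed + 7919 * index`, overridable per group), wraps every stochastic
stage in `withr::with_seed`, and writes an output bundle whose
`manifest.yaml` carries MD5 hashes of every CSV. Reruns of the same
configuration are bit-for-bit identical.

```{r determinism}
cfg <- run_config(groups = list(g = list(scenario = "control", n = 2)),
                  seed = 1L)
identical(run_experiment(cfg)$metrics, run_experiment(cfg)$metrics)
```
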