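---
title: "From single-channel traces to growth-rescue classification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From single-channel traces to growth-rescue classification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chanscreen)
```

`chanscreen` implements a complete analysis chain for small K⁺ channels
studied by planar-lipid-bilayer recording and yeast complementation: from raw
single-channel current traces to functional parameters (unitary conductance
*g*, open probability *P*~O~, time-averaged current), and from there to the
correlation and classification of those parameters against the growth rescue
of a K⁺-uptake-deficient yeast strain. Because such studies rarely deposit
raw traces, the package also ships a synthetic-data generator that emulates
every relevant feature of the acquisition chain, so the whole pipeline is
testable end to end against known ground truth.

This vignette documents the models, the tunable parameters and their
defaults, the numerical choices, and the limits of what the synthetic data
can demonstrate.

## The gating model

A channel variant is described by `gating_model()`: two independent two-state
gates in series, so the pore conducts only when both are open.

* A **slow gate** produces the burst structure that an idealization
  detector resolves. Its stationary open fraction is what "open probability"
  means operationally.
* A **fast flicker gate** can switch far above the recording bandwidth. The
  anti-aliasing filter then averages over flicker, which lowers the *apparent*
  open-channel amplitude *i*~meas~ below the true one *i*~true~ without
  affecting the detected burst structure much. This reproduces the
  experimentally observed divergence between *i*~meas~ and *i*~true~ at
  hyperpolarized voltages.

Two gates are the minimal scheme that reproduces both a voltage-dependent
*P*~O~(V) and *i*~meas~(V) < *i*~true~(V); nothing in the downstream analysis
depends on this scheme being the true kinetic mechanism.

Every rate constant follows a Boltzmann voltage dependence,
$k(V) = k_0\,e^{zVF/RT}$, with the temperature fixed at 25 °C
($RT/F = 25.69$ mV). The conducting level is Ohmic,
$i_\mathrm{true}(V) = g\,(V - E_\mathrm{rev})/1000$ pA with *g* in pS and
voltages in mV; $E_\mathrm{rev} = 0$ in the symmetric 100 mM KCl condition
all defaults assume.

Gate trajectories are alternating exponential dwells
(`sample_dwells()`), with the initial state drawn from the gate's stationary
distribution to avoid burn-in bias. The overlay of the two gates is the
returned `dwell_sequence`, whose empirical conducting fraction is retained as
ground truth for detector validation.

### Preset configurations

`preset_wt()` fixes the slow gate through two anchors — stationary open
fraction 0.034 at −160 mV and 0.005 at +160 mV — which determine the rate
ratio at 0 mV (75.2) and the charge difference (δz = 0.156, split evenly
between opening and closing). The closing rate at 0 mV (47 s⁻¹, mean open
dwell ≈ 20–35 ms across the window) is a free timescale choice: dwell-time
constants are not constrained by the published values this package targets,
so the defaults were chosen once to keep open events well above the filter
rise time at every protocol voltage while leaving low-*P*~O~ records
replicate-hungry, as they are in practice.

The default flicker gate (40000/800 s⁻¹ at 0 mV, z = ±0.25) leaves the
channel effectively unfiltered at positive voltages (p~fast~ > 0.99 above
+40 mV) and reduces the apparent amplitude to ≈ 0.77 of *i*~true~ at
−140 mV. Three mutant-like presets modify one functional axis each:
`preset_high_po()` (open fraction 0.4 at negative voltages),
`preset_low_po()` (voltage-independent 0.005), and `preset_low_g()`
(conductance 4.3-fold below WT, voltage dependence inverted).
`preset_panel()` assembles a 20-genotype panel spanning those ranges.

## Acquisition physics

`render_trace()` synthesizes the current at `fs × oversample_factor`
(default 5 kHz × 10), adds white Gaussian noise scaled by
$\sqrt{\mathrm{oversample}}$, applies the causal Bessel low-pass, and
decimates to `fs`. Oversampling before filtering is essential: it lets
sub-sample flicker shape the apparent amplitude exactly as an analog filter
acting before digitization would. The default noise (0.25 pA at the output
rate, ≈ 0.16 pA rms after the 1 kHz filter) puts the weakest amplitude used
in conductance fitting (+20 mV) at a signal-to-noise ratio above 13.

The filter is a true Bessel design: the analog prototype poles are the roots
of the reverse Bessel polynomial, rescaled so the −3 dB point sits at the
cutoff, then converted by prewarped bilinear transform. The R `signal`
package supplies the bilinear transform but no Bessel prototype, so the
prototype is computed in the package and pinned in the tests against an
independent filter-design oracle (coefficients to 1e−10, −3 dB gain at the
cutoff within 2%, step-response overshoot below 1%). DC gain is normalized
to exactly 1. Note the overshoot property holds at the oversampled rate
where the filter operates; a 1 kHz 4-pole filter designed directly at 5 kHz
would overshoot several percent from bilinear warping.

## Idealization

`estimate_baseline()` takes the closed level from the mode of the amplitude
distribution (coarse kernel-density peak, refined by averaging samples
within 2.5 noise sd of it) — valid because these channels are mostly closed —
and the noise sd from the median absolute deviation of first differences
divided by √2. The MAD estimator ignores open-level excursions; on
filter-correlated noise it underestimates the post-filter sd by a known
factor, which only makes the detector marginally more sensitive and is shared
consistently between threshold and detectability checks.

`hinkley_detect()` implements a higher-order Hinkley jump detector. With the
sample normalized to $z = (x - \mathrm{base})/(\mathrm{target} -
\mathrm{base})$, the order-1 statistic is the classic clipped cumulative sum
$g_1 \leftarrow \max(0, g_1 + z - \tfrac12)$, and each higher order
accumulates the one below, all resetting when $g_1$ touches zero. Jumps are
placed at the most recent zero of $g_1$, after which the detector re-arms
toward the other level.

The threshold calibration is the package's own: with normalized noise
$\sigma_n = \sigma/|\Delta\mathrm{level}|$, the minimum reliably detectable
dwell is taken as $d^\* = \max(1, \lceil(2\lambda\sigma_n)^2\rceil)$ samples
(the dwell whose integrated evidence exceeds λ noise standard deviations),
and the order-*p* statistic fires at the value it would reach $d^\*$ samples
after a clean jump, $h = \tfrac12\binom{d^\*+p-1}{p}$. This reduces to
exact single-sample detection on noiseless traces, and makes event counts
monotone non-increasing in λ. Defaults *p* = 4 and λ = 6 follow the
published practice for brief-event detection at 5 kHz; both are open
parameters of `detector_config()` because reports of such analyses rarely
state them.

Numerical details and degenerate inputs:

* Idealization is two-pass: a first pass with an open-level guess (the
  extreme of a filter-width running mean, or a user hint), then a re-estimate
  of the open level from edge-trimmed detected open segments, then a final
  pass.
* Events shorter than the dead time (0.4/f~c~, the filter rise time) are
  merged into their neighbours rather than reported.
* A trace whose level separation is below λσ (e.g. a flat record) returns a
  single closed event spanning the record, flagged `undetectable`, so
  *P*~O~ = 0 is well defined while the amplitude is missing — exactly what
  the i/V assembly expects.
* Amplitudes are duration-weighted means of open-event samples with
  `edge_margin` (two filter rise times) trimmed at each boundary. Flicker is
  deliberately **not** deconvolved: the package reports the *measured*
  amplitude, and recovers *i*~true~ only by positive-limb extrapolation.

## Channel parameters

`build_relations()` aggregates per-recording (voltage, *i*~meas~, *P*~O~)
into mean ± sample sd relations; missing amplitudes drop out of the i/V but
keep their *P*~O~. `fit_conductance()` fits an ordinary least-squares line
with free intercept — the intercept absorbs baseline offsets, and only the
slope is the conductance. The default fit range is 0…+100 mV; both 0…+100
and 0…+160 mV are in common use for this channel family, so the range is a
recorded argument rather than a constant. `true_current_at()` evaluates the
fitted line at −140 mV; `po_at()` is an exact protocol lookup and refuses to
interpolate. The global `mean_po()` is unweighted across voltages because
per-voltage recording durations vary. Activity products
(`i × P_O`) are formed exactly from their factors.

## Growth model and the hidden expression variable

`simulate_growth()` drives a logistic OD600 curve
$\mathrm{OD}(t) = K/(1 + (K/\mathrm{OD}_0 - 1)e^{-rt})$ whose rate saturates
with activity through a Michaelis term,
$r = r_0 + (r_\mathrm{max} - r_0)\,A/(A + K_A)$, where
$A = f_\mathrm{expr}\,|i \cdot P_O|$ and $f_\mathrm{expr}$ is the hidden
per-genotype expression factor (channels per membrane area). OD noise is
multiplicative log-normal, since optical densities are positive with roughly
proportional errors.

Defaults ($K$ = 1.0, OD₀ = 0.1, $r_\mathrm{max}$ = 0.12 h⁻¹, $K_A$ = 2 pA,
noise sd 0.05) were chosen once so that 48-hour fold changes remain
*discriminative* across the panel's activity range (0.02–6.5 pA): with all
expression factors equal and this map, the Pearson correlation between
|activity| and 48-h fold change is ≈ 0.96. This is the property the
decorrelation demonstration needs as its baseline. The trade-off is that the
simulated WT grows more slowly relative to the OD ceiling than a real
rescued culture, which typically saturates within two days; a steeper map
would mimic that curve but flatten the panel into an uninformative
step-function readout.

The headline demonstration then follows as a property, not a number: drawing
expression factors from a log-normal with increasing spread (sdlog 0 → 4,
mean fixed at 1) decorrelates per-channel activity from growth rescue, with
the median Pearson r falling from ≈ 0.96 through ≈ 0.85 (sdlog 1) to below
0.3 at sdlog 4. This reproduces, in a controlled setting, why growth rescue
alone cannot rank channel variants when membrane expression varies — while
`classify_vs_wt()` shows that coarse better/worse-than-WT calls survive much
longer than quantitative correlation.

## Statistics

Mutant-vs-WT comparisons use the classical equal-variance two-tailed
Student's t-test (`ttest_vs_wt()`; Welch's correction behind a flag), with
significance at p < 0.05 and deliberately no multiple-testing correction
across a panel, matching standard practice in this assay literature (a user
can apply `p.adjust()` downstream). Correlations are Pearson
product-moment (`pearson_r()`), which errors on zero-variance input rather
than returning 0. `multilinear_r2()` regresses growth on current, *P*~O~
and their product with an intercept — without one, R² is not comparable
across software — and errors informatively on rank-deficient designs.
Classification ties with the WT reference are excluded with a warning; the
WT sits on both dividing lines by construction and is never classified.

## Problem sizes and what the tests show

The validation suite runs the full pipeline at desk scale: 30 s records for
conductance fitting (five positive voltages, ten seeds), 120 s records for
open-probability recovery at the voltage extremes, 300 s for the rare-event
low-*P*~O~ variant, and a 20-genotype panel at 10 s per voltage for the
bundled demo. These sizes keep every check inside a few minutes while
leaving the statistical structure of the problem intact: low-*P*~O~ records
are genuinely replicate-hungry, and the recovered medians carry realistic
sampling spread.

What passing tests do show: the detector recovers *P*~O~ within 15% of
generator truth across *P*~O~ 0.005–0.4 and generator SNR 5–10; conductance
fits land within a few percent; the flicker limit
$i_\mathrm{meas} \to i_\mathrm{true}\,k_o/(k_o+k_c)$ holds within 5–7%;
and the growth demonstrations behave as described above. What they do not
show: real bilayer traces contain baseline drift, capacitive transients,
multi-channel insertions and substates, none of which the generator
emulates; the detector has no missed-event correction, no multi-level
idealization and no dwell-time likelihood fitting, so rate constants (as
opposed to occupancies) should not be inferred from its event tables.

## Reproducing the recovery numbers

`scripts/acceptance.R` (repository root) re-runs the six headline
recoveries — WT conductance, WT open probabilities at ±160 mV, the
high- and low-*P*~O~ mutant values, and the WT/low-g conductance ratio —
from scratch at the sizes above and writes them as JSON; see the README for
the exact invocation.
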