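---
title: "Models and methods behind slicephys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind slicephys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slicephys)
```

slicephys re-implements, as tested reusable code, the analysis chain of a
hippocampal slice-physiology study: passive membrane and excitability
measures from whole-cell recordings, detection and decomposition of
synaptic currents, quantification of synaptic puncta and glial morphology
in fluorescence images, Sholl and spine morphometrics, and the statistical
procedures that tie the measurements together. Every stage can be exercised
on synthetic data with known ground truth, so the package is testable
end-to-end without any experimental recordings. This vignette explains the
models, the defaults and the numerical choices.

## Conventions and containers

Time is in ms, current in pA, voltage in mV, distances in µm, charges in
fC (1 pA·ms = 1 fC). Inward (excitatory) currents are negative-going in
raw traces; magnitudes are reported positive downstream. Traces live in a
`sweep_trace()` (samples + sampling rate in kHz + labeled epochs), images
in an `image_stack()` (per-channel 3-D arrays + pixel sizes), and
reconstructions in a `morph_tree()` (SWC-style node table).

## The synthetic-data generator

The generator (`sim_config()` plus the `simulate_*()` family) defines the
study conditions under which the pipeline is validated. Its defaults are
fixed, not tuned per test:

* **Digitization** 20 kHz, the standard rate for whole-cell recordings of
  this kind.
* **Quantal AMPA kernel**: bi-exponential, rise 0.5 ms, decay 5 ms, peak
  20 pA. With 4 pA Gaussian baseline noise this puts the peak/noise ratio
  at 5, a realistic regime for CA1 miniature events.
* **NMDA kernel**: rise 5 ms, decay 80 ms, peak 5 pA. The time constants
  are typical CA1 values and are chosen so that the current 22–27 ms after
  the AMPA peak is almost purely NMDA-mediated — the premise of the
  single-event late-window measurement.
* **Event process**: Poisson at 2 Hz with a 2 ms refractory floor between
  planted events (configurable), so single-event analyses stay well posed.
  In spontaneous-event mode each event is the linear sum of
  k = 1 + Poisson(1) quantal kernels (release-site multiplicity); in
  miniature mode k = 1.
* **Membrane**: two-compartment cell with Rs 10 MΩ, Rm 150–190 MΩ,
  Cm 200 pF, rest −70 mV, threshold −50 mV.

Determinism: each `simulate_*()` call seeds R's RNG from the config seed,
so a seed plus a config reproduces every output bit-for-bit.

The amplitude convention deserves a note. The raw bi-exponential
`A (e^{-t/τd} − e^{-t/τr})` has integral `A(τd − τr)` but a peak smaller
than `A`. By default the generator rescales kernels so `amp` is the event
*peak* (the physiological convention); `normalize_peak = FALSE` exposes
the raw multiplier, for which the charge closed form holds exactly. Both
conventions have analytic helpers (`biexp_charge()`,
`biexp_window_mean()`) used as oracles in the tests.

What the generator does *not* emulate: dendritic filtering and cable
attenuation, correlated (1/f) noise, series-resistance artifacts, receptor
desensitization, realistic optics (point-spread functions) and anisotropic
voxels, and tissue-background autofluorescence structure. Tests passing on
this generator therefore demonstrate correctness of the analysis
algorithms under their stated assumptions, not robustness to every
pathology of real data.

## Passive membrane test

The response of a voltage-clamped two-compartment cell to a voltage step V
is an instantaneous capacitive transient `Ip = V/Rs` relaxing with
`τ = Cm·(Rs·Rm)/(Rs+Rm)` to the steady state `Is = V/(Rs+Rm)`.
`measure_membrane_test()` measures the baseline from the 50 ms before the
step, `Is` from the last quarter of the step, `Ip` as the extremal
transient, and τ by mono-exponential least squares from 0.1 ms after the
transient peak to the end of the step (log-linear initialization, then
Levenberg–Marquardt refinement).

Capacitance is reported, by default, with the conventional printed formula
`Cm = τ·(Is+Ip)²/(V·Is)`. This formula is dimensionally consistent but
does **not** agree with the two-compartment identity
`Cm = τ·(1/Rs + 1/Rm)` when `Ip` is measured from the pre-step baseline
(the two conventions differ in how the transient is referenced, and the
printed form is ambiguous on that point). Rather than silently "fix" it,
the package computes the printed form by default and exposes
`cm_method = "two_compartment"`, which recovers the planted capacitance of
the generator exactly. Users comparing absolute capacitances across
software should check which convention their tool uses.

## Excitability

Current steps (−25 to 250 pA, 25 pA increments, 500 ms) are analyzed for
the F–I curve, the rheobase (first step with ≥ 1 spike) and the threshold
voltage: the voltage at the first sample of the first spike's rising phase
where dV/dt exceeds 20 mV/ms, computed with a 3-point central difference
at native sampling and no smoothing (synthetic 20 kHz traces are clean;
the derivative criterion is configurable).

The generator's leaky integrate-and-fire cell needs one numerical care: at
the exact analytic rheobase `(Vth − Vrest)/Rm` the membrane approaches
threshold only asymptotically, so a strict crossing rule would never fire
at that current in finite time. The generator therefore fires when the
voltage comes within 0.01 mV of threshold (configurable). With the default
time constants the analytic-rheobase step then fires within the 500 ms
window, and the measured rheobase equals the analytic value snapped to the
25 pA grid.

## Synaptic event detection

`detect_events_template()` re-implements the classical sliding
scaled-template search: at every lag a bi-exponential template is fit to
the trace with free scale and offset, and the detection criterion is the
fitted scale divided by the SD of the fit residual. Criterion maxima above
threshold (default 4, the conventional value for this detector; the source
analyses do not state one) become events.

Two numerical choices matter:

* **Dead time.** Secondary criterion maxima occur along the decay of a
  single event, so detections must be separated by at least the template
  rise time plus one decay constant (default; configurable). This is a
  stricter default than the bare rise-time lower bound.
* **Overlap recovery.** An unmodeled neighbouring event inside the
  template window inflates the fit residual and can suppress a true
  detection. The detector therefore runs a second pass after subtracting
  the fitted template at every accepted event (`n_passes = 2`), which
  restores near-unity sensitivity at peak/noise 5 without raising the
  false-discovery rate.

Per event, the peak is the extremum of a 1 ms running mean around the raw
extremum relative to a local 2 ms pre-event baseline (matching the
single-event window convention below), the 10–90% rise time is linearly
interpolated, and the decay constant comes from a profiled 1-D nonlinear
least-squares mono-exponential fit starting two rise constants after the
peak — starting at the peak itself would bias τ upward because the rising
exponential has not fully died there. Inhibitory currents are the same
machinery with `sign = +1`; there is no separate code path.

## AMPA/NMDA decomposition

Average events are built from ≥ 50 per-event snippets (the per-cell
averaging convention; source text elsewhere mentions > 100 events —
`min_n` is configurable and the discrepancy is deliberately left visible),
baseline-subtracted and aligned at the detected onset, defined as the last
upward crossing of 10% of the event peak before the peak (taking the last
crossing, not the first, prevents the tail of a preceding event from
masquerading as the onset). The NMDA waveform is the point-wise difference
between the dual-component average and the pharmacologically isolated
AMPA-only average; charges are trapezoidal areas of the magnitude
waveforms from onset to return-to-baseline, capped at 500 ms after onset
(with an 80 ms NMDA decay the cap truncates < 0.2% of the charge).

Single-event analysis measures the AMPA peak as the mean over a 1 ms
window at the peak and the NMDA component as the mean over 22–27 ms after
the peak. Events enter only if the peak magnitude is ≥ 30 pA *and* ≥ 3×
the RMS baseline noise (the two gates encode "at least −30 pA and clearly
above noise"; the factor is configurable), and only if the late window
does not collide with the next event.

Tonic-current analysis reports the mean holding current over 10 s windows
before and after drug application, and the RMS noise as the average SD
over ten automatically selected 100 ms regions per side containing no
detected event within ±20 ms (greedy left-to-right selection; an error
lists the usable count when fewer than ten exist). The source description
of the RMS measurement conflates a mean with an RMS; the package computes
the SD over event-free regions per side and reports the difference, which
is the only reading that yields a noise quantity.

## Imaging

Processing order is fixed as: per-plane 3×3 median filter → maximum
intensity projection → background subtraction → Otsu binarization (the two
image-processing descriptions in the source differ slightly in order; one
order is implemented and each stage is configurable). Background
subtraction is a grayscale top-hat with a flat disc structuring element of
radius 10 px — the standard fast approximation to rolling-ball
subtraction.

Colocalized synapse counting takes the pixel-wise AND of the two
per-channel Otsu masks ("additive mask" could also mean sum-then-threshold,
which is available as `method = "sum"`), labels 8-connected components and
keeps those with area in the inclusive band [0.1, 1.2] µm²; objects
strictly outside are excluded as unlikely synapses. 3-D cell counts use a
single global Otsu threshold and 26-connected components with a minimum
volume; touching cells bridged by a voxel merge into one object (no
watershed; documented limitation). The astrocytic-uptake measure replaces
the commercial surface-rendering step with plain voxel thresholding: the
glial mask comes from a configured manual threshold, and the reported
quantity is puncta voxels inside the mask as a percentage of mask voxels,
optionally normalized to a control group's mean (group-mean normalization
chosen; the baseline statistic is not pinned down by the source).

The ramification index `RI = P / (2√(πA))` compares a mask's
perimeter-to-area ratio with that of an equal-area circle. Perimeter
estimation on rasterized masks is the only subtle part: counting pixel
edges overestimates smooth boundaries by up to 4/π, and straight-edge
Crofton-style estimators underestimate axis-aligned rectangles. The
package measures the sub-pixel 0.5-level marching-squares contour of the
lightly smoothed mask (Gaussian σ = 1 px), which is accurate to ≈ 0.5% on
a rasterized disc and ≈ 1% on a square — both inside the ±0.03 calibration
band the tests enforce.

## Morphometry

Sholl analysis counts exact intersections of parent→child segments with
concentric spheres at 20 µm increments centered on the soma (the root
node; multi-node somas collapse to their centroid). Crossings are the
distinct roots of the segment–sphere quadratic strictly inside the
segment, so a segment that enters and leaves a shell contributes two —
this makes the result identical to a dense-sampling oracle, which the test
suite checks on 50 random trees. Endpoints exactly on a sphere and
tangencies count as no crossing (measure-zero cases, resolved
deterministically). Whether the original analyses used 3-D spheres or 2-D
projections is not stated; 3-D is the default and `mode = "2d"` analyzes
the projection. Spine metrics average per-segment densities and lengths
over the (typically five) annotated 15–20 µm segments, unweighted — not
pooled across spines.

## Statistics

Two-group comparisons route through normality (Shapiro–Wilk *and*
Anderson–Darling, both at α = 0.05; below n = 8 the Anderson–Darling test
is undefined and Shapiro–Wilk alone decides) and a variance F-test: all
pass → Student's t; otherwise Mann–Whitney U. The sequential correction
multiplies the most significant of N p-values by N, the next by N−1, and
so on, capping at 1 — exactly the printed recipe, with no additional
step-down monotonicity enforcement, so a weak p-value can remain below a
strongly corrected neighbour. Two-way ANOVA is the standard fixed-effects
decomposition (`stats::aov`) with Bonferroni-corrected pairwise
comparisons within levels. ANCOVA for the single-event correlation is the
classical common-slope linear model with additive group offsets and a
sequential sum-of-squares test of the group term. Sample-size estimation
searches the smallest n with exact noncentral-t power above target; the
standard design point (effect 50% of control, SD 25%, power 0.8,
α = 0.05) gives n = 6 per group, cross-checked in the tests by a
Monte-Carlo oracle.

Liquid junction potentials use the generalized Henderson equation with a
shipped table of limiting equivalent conductivities (editable via
`mobility_table()`/`solution_composition()`). HEPES enters with its
anionic fraction at the solution pH (pKa 7.5, about one third at pH 7.2);
EGTA, phosphocreatine and the nucleotides enter as divalent anions with
generic large-anion mobilities; QX-314 as a slow monovalent cation.
Activities are approximated by concentrations. Different calculators use
slightly different mobility tables, so agreement with published values is
expected to about ±1.5 mV, not to the decimal.

```{r}
junction_potential_henderson(internal_kgluconate(), acsf_standard())
junction_potential_henderson(internal_kcl(), acsf_standard())
```

## Problem sizes in the test suite

The validation suite runs on deliberately modest problem sizes chosen to
estimate each quantity stably: 60 s traces for detector operating
characteristics (20 seeds), 30 s traces and 15 cells per group for the
multiplicity cohorts, 100 seeded sweeps for noisy membrane-test recovery,
50 random trees for the Sholl oracle, and 128² px image fields. These
sizes give comfortable statistical margins for every asserted bound while
keeping the whole suite fast.

## Known limitations

* Event amplitudes use the 1 ms peak-window convention, which reads
  ≈ 1–2% below the instantaneous peak for a 5 ms-decay event; all
  amplitude comparisons are internally consistent, but absolute values
  differ slightly from an instantaneous-peak convention.
* The detector's template parameters are assumed known (matched to the
  kernel); mismatched templates degrade gracefully but are not optimized.
* No watershed splitting of touching cells; no deconvolution or chromatic
  registration; microglial skeleton-based morphology feature sets are out
  of scope.
* The Henderson computation ignores activity coefficients and treats
  buffers by their dominant ionization only.
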