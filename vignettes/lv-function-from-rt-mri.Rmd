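---
title: "Left-ventricular function from real-time cardiac MRI: models, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Left-ventricular function from real-time cardiac MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rtlv)
```

## The problem

Cine cardiac MRI reconstructs one averaged heartbeat from data gated over
many cycles, which requires breath holding — in anaesthetised non-human
primates that means artificial ventilation with scripted expiratory holds.
Real-time (RT) MRI instead acquires an image every few tens of
milliseconds without gating, so every heartbeat is imaged individually
while the animal is ventilated continuously. The price is that the frames
of each slice arrive unsorted with respect to cardiac and respiratory
phase, and that image contrast and sharpness are lower. This package
implements the downstream analysis: sorting the frames of a segmented
(label-mask) short-axis series into labelled heart cycles, Simpson's-disks
volumetry per respiratory phase, and the agreement statistics used to
compare methods, observers and repeated examinations.

## The ventricle phantom

No reference data sets are distributable for this setting, so the package
ships a synthetic-data generator that is itself first-class, tested code.
It emulates the acquisition conditions the analysis is designed for:

* heart rate 105 beats/min (typical range 79–134 under anaesthesia);
* 13 short-axis slices of 3 mm with a 0.5 mm gap, 0.9 × 0.9 mm pixels,
  210 frames of 37 ms per slice, slices acquired **sequentially** — so each
  slice's frames belong to different heartbeats;
* pressure-controlled ventilation at 8 breaths/min with 10–20% higher
  EDV/ESV during inspiration (defaults: 15% on both).

**Geometry.** The cavity at end-diastole during expiration is a truncated
half-ellipsoid (apex to equatorial base plane) with long semi-axis
$c = 41$ mm; the short semi-axis is derived from the end-diastolic volume
so that $V = \tfrac{2}{3}\pi a^2 c$ matches `edv_exp` exactly. The
myocardium is an incompressible shell of fixed volume whose outer surface
is recomputed from the instantaneous cavity volume; two papillary
cylinders (total volume ≈ 5% of the muscle volume) are attached to the
endocardial wall over the mid 40% of the long axis. Contraction scales the
short axis only, $a(t) = a_{ED}\sqrt{V(t)/V_{ED}}$; the base plane is
aligned with a disk-cell boundary so that the slice stack tiles the cavity
exactly and the midpoint (slice-centre) sampling of the disk areas
integrates the ellipsoid accurately.

**Waveforms.** The cavity volume is

$$V(t) = ESV(t) + \bigl(EDV(t) - ESV(t)\bigr)\, f(\varphi),$$

where $f$ is a cosine-eased contraction over the systolic fraction
(default 0.35 of the cycle) followed by a cosine-eased relaxation, and
$EDV(t), ESV(t)$ are the expiratory values scaled by
$(1 + g\,a(t))$ with the inspiratory gains $g$ and a trapezoidal
respiratory activation $a(t) \in [0,1]$ (cosine-eased ramps of 15% of the
breath each, inspiratory plateau inside an inspiratory fraction of 0.4).
Setting `resp_rate = 0` freezes the lung at expiration (breath-hold
emulation). Optional log-normal beat-to-beat and breath-to-breath period
jitter is available (`hr_jitter`, `resp_jitter`, both default 0, with
their own seed); the defaults are deterministic cycles, since no
physiological variability magnitudes are established for this setting.

**Real-time degradation.** `cine` mode renders crisp labels for the phases
of one averaged cycle at expiration. `rt` mode smooths each compartment's
indicator with a Gaussian kernel and rethresholds it, emulating the softer
boundaries of regularised real-time reconstruction — not the physics. The
smoothing scale is set at the in-plane resolution (σ = 1.2 px): a much
smaller kernel cannot move any pixel across the threshold on a 0.9 mm
grid, i.e. it degrades nothing. The threshold is 0.55 rather than 0.5,
encoding conservative boundary placement under low contrast; this gives
the RT series the systematic mild under-segmentation (EDV ≈ −2%,
ESV ≈ −4%) that RT imaging shows against cine in practice, while staying
well inside the package's own recovery tolerances. The papillary
cross-section shrinks slightly with cavity volume
($r \propto (V/EDV)^{0.1}$): at end-systole the contracted muscle partly
merges with the wall, so less of it protrudes into the blood pool — this
is what makes papillary reassignment affect SV, not only EDV and ESV.
Tissue intensities are constants per compartment; the RT blood intensity
is set 10% lower so the blood/myocardium contrast ratio reproduces the
reduced RT tissue contrast exactly by construction.

**What the phantom does not emulate.** Receive-coil noise and
reconstruction artefacts, through-plane motion, trabeculation, real
papillary anatomy, observer variability in contouring, and arrhythmia.
Passing the phantom tests therefore demonstrates the correctness of the
sorting, volumetry and statistics on idealised segmentations — not
robustness to segmentation error, which in real data dominates the error
budget.

## Sorting

End-diastole is detected at local maxima of the blood-pool area (or
intensity) trace; peaks must exceed a prominence of 25% of the trace's
interquartile range and be separated by at least 0.6 cardiac periods at
the heart-rate hint. Ties go to the earliest frame; detection is invariant
to positive rescaling. End-systole is the minimum between consecutive EDs,
so the last ED of a window has no ES and cycles are bounded by detected
EDs on both sides.

The respiratory trace is normalised by its plateau levels — samples within
5% of the range from either extreme — mapping the expiration plateau to 1
and the inspiration trough to 0, then thresholded at 0.3/0.7 (the
thresholds are configurable; the values are conventional, splitting the
ramp symmetrically). A cycle's respiratory phase is the label shared by
**all** frames from its ED to its ES; mixed or transition-containing
cycles are invalid and excluded from the per-phase averages. The ED→ES
span (rather than ED→next-ED) is used because the volumetry reads exactly
those two frames; full-cycle strictness is available via `span =
"full_cycle"`.

Ground-truth conventions worth noting: the truth tables define the
discrete ED/ES frame as the frame of extremal *sampled* volume near the
continuous event time (ties earliest). Rounding the continuous event time
instead can disagree by one frame with any detector that sees only the
sampled trace, which matters when a cycle's bounding frame sits exactly on
a respiratory-label boundary. Likewise, comparisons against truth restrict
to cycles whose bounding EDs lie strictly inside the acquisition window —
an ED on the window edge cannot be a local maximum of the recorded trace.

## Volumetry

Disk height defaults to slice thickness + gap (the stack then tiles the
covered length contiguously); thickness-only summation is available. The
basal rule is automated as the fraction of blood-boundary pixels
(4-connectivity) adjacent to myocardium, threshold 50%. Areas are averaged
across a slice's valid cycles per phase **before** the disk summation;
because the disk sum is linear in the areas, the alternative order
(per-cycle single-slice volumes, then averaging) is algebraically
identical when the same cycles are used — both are implemented behind the
`averaging` flag and tested for equality. Masses always use the
myocardium label for LVWM and the papillary label for PM, so
LVM = LVWM + PM holds under either `pm_mode`; `pm_mode` reroutes papillary
pixels only for the cavity/wall **areas** that enter EDV/ESV. Heart rate
for CO is supplied, not estimated from the trace, keeping CO
deterministic. Myocardial density is 1.05 g/mL, the standard cardiac-MR
convention.

All frame and slice indices are 1-based, following R convention; slice 1
is the apex and timestamps are mid-acquisition times.

## Agreement statistics

The ICC form is ICC(2,1) — two-way random effects, absolute agreement,
single measures — because test–retest, inter-observer and
method-comparison questions all concern absolute agreement of single
measurements; a consistency form ICC(3,1) is selectable. Limits of
agreement use the fixed 1.96 multiplier without a small-sample t
correction, matching the original Bland–Altman formulation. Percentage
differences take the first-named condition (cine, test, expiration) as the
reference.

## Acquisition arithmetic

The segmented-cine phase count is implemented as
$p = \lfloor (60/HR) / (TR_s \cdot segments) \cdot 2 \rfloor$ — cardiac
cycle over segment-block duration, doubled by view sharing — which yields
35 phases at 105 bpm and 27 at 134 bpm with TR = 6.48 ms and 5 segments,
inside the nominal 25–40 range. The literal one-line formula
$p = 60/(HR \cdot TR) \cdot 2$ is retained behind `literal = TRUE` for
reference; with TR in either ms or s it falls far outside that range, so
the segment-block reading is the package's documented interpretation. At
the lower end of the heart-rate range even this reading exceeds 40; values
outside 25–40 are returned with a warning, never clamped. The RT per-slice
timing is the plain product 210 × 37.57 ms ≈ 7.9 s; protocols typically
report slightly longer wall-clock times per slice because of preparation
cycles, which the arithmetic deliberately excludes.

## Numerical choices and degenerate inputs

* Constant traces are rejected in normalisation, classification and cine
  phase selection (no modulation to work with), as are traces shorter than
  two cardiac periods or eight samples for peak detection.
* Ties in peak detection, ES search and cine phase selection resolve to
  the earliest frame.
* A respiratory phase without valid cycles is reported absent, never as a
  zero row; an empty ROI, an unknown label value, a negative area or a
  missing sidecar field abort with the offending item named.
* The phantom validates that the acquisition geometry covers the ventricle
  apex-to-base with at least one slice margin and that the in-plane FOV
  contains the dilated epicardium.
* All randomness (trace noise, cohort spread, cycle jitter) flows through
  explicit integer seeds; equal seeds give bit-identical outputs, and the
  pipeline's CSV outputs are byte-stable across reruns.

## Problem sizes used in the tests

The full test suite renders the study-condition phantom (13 × 210 frames
at 64 × 64 pixels) once and reuses it; cine comparisons use 30 phases; the
pipeline test runs a 3-subject cohort at 120 frames per slice. These sizes
were chosen so the complete suite exercises every stage end-to-end in
well under a minute while the discretisation error of the default
geometry (≈ 1–2% in volume) remains small against the 5% recovery
tolerances. The statistics oracles use 50 random subject×condition tables
per run.

## Known limitations

* The phantom's contraction is radially uniform with a fixed long axis;
  longitudinal shortening, torsion and regional wall-motion abnormalities
  are out of scope.
* The basal enclosure rule is applied to a representative end-diastolic
  stack per phase (the first valid cycle per slice), not per cycle.
* The RT degradation model operates on label probability maps; it cannot
  produce the contouring ambiguity that drives inter-observer differences
  on real RT images, so agreement statistics on phantom cohorts mainly
  validate the statistical machinery, not realistic effect sizes.
* `phases_per_cycle` encodes one documented interpretation of the
  segmented-cine phase formula; protocols vary, and the literal flag
  exists precisely because the convention is not universal.
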