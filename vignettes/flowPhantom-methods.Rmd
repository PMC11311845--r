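---
title: "flowPhantom: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{flowPhantom: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flowPhantom)
```

flowPhantom is a digital twin of a linear conveyor-belt flow phantom used
to calibrate instruments that measure retinal blood-flow velocity. The
physical device drives a timing belt with a DC motor; a slide carrying a
monolayer of 10 µm polystyrene microspheres (a sparse subset of them
near-IR fluorescent) rides on the belt behind a focusing achromat, so the
beads translate at a known, tunable velocity (0.5–7 mm/s, the retinal
microvascular range) and stand in for moving red blood cells. The package
reproduces, entirely in software, both the phantom physics and the two
velocimetry analyses used to validate such phantoms: streak-slope
velocimetry on scanning-laser-ophthalmoscope (AO-SLO) line-scan
space–time images, and particle tracking on clinical-SLO ICGA-mode frame
videos. Because the simulator knows the ground truth exactly, every
estimator in the package can be validated as a parameter-recovery
exercise.

## Phantom physics

**Motor calibration.** The voltage-to-belt-velocity map is affine in
|V| with a dead zone:

$$v(V) = \mathrm{sign}(V)\,\max\{0,\; g\,|V| + b\}\quad (|V| >
V_{dead}),\qquad v = 0 \ \text{otherwise.}$$

The defaults are fixed by the two printed calibration endpoints of the
physical device, (1.5 V, 0.5 mm/s) and (11 V, 7 mm/s), giving
$g = 6.5/9.5$ mm/s/V and $b = 0.5 - 1.5g$, with a ±0.5 V dead zone (the
motor needs that much to start moving). Whether the real device's line
passes through (±0.5 V, 0) or jumps is not documented; we use the
endpoint line with a hard zero inside the dead zone, which reproduces
both printed endpoints exactly. Motor electrical dynamics, torque and
friction are out of scope; repeatability can be emulated with an optional
multiplicative Gaussian jitter on the instantaneous velocity
(`jitterFraction`, default off, since only the repeatability outcome —
SD below ~5% — is documented, not a noise mechanism).

**Pulley.** ω (deg/s) converts to belt velocity as
$v = \omega \frac{\pi}{180} r$. The stated 12 mm pulley diameter is
internally inconsistent with 2 mm-pitch GT2 kinematics (pitch diameter
12.73 mm), so the model uses a single configurable effective radius,
default 6.0 mm, matching the stated diameter.

**Optics.** The phantom is imaged in air ($n = 1$) through a 20 or 30 mm
achromat; under the paraxial approximation a scan angle θ maps to
lateral distance $f\theta$ (radians) at the focal plane. A guard rejects
|θ| ≥ 10° where the approximation degrades (the line-scan FOV is 1.5°;
the clinical FOV of 15° ≈ 0.26 rad incurs ~1% small-angle error, which we
accept as the instrument itself reports a single scale).

**Bead monolayer.** Bead centers form a homogeneous spatial Poisson
process at the configured density (defaults: ~580 total and ~40
fluorescent beads/mm², the densities measured on the reference slide;
the alternative 1:3 fluorescent:total ratio mentioned for EMA-style
labeling can be configured explicitly). Fluorescence flags are i.i.d.
Bernoulli with probability equal to the density ratio, so both counts
are Poisson. Pure Poisson placement permits physically impossible
overlapping spheres; an optional hard-disk mode places the same
Poisson-drawn count by random sequential adsorption with a minimum
separation (10 µm for touching beads), which is the realistic model of a
drop-cast monolayer and is used when slide images are counted. At ~5%
area fraction the packing is far from jamming, so adsorption never
stalls.

## Line-scan simulator

In line-scan mode the slow scanner is parked and the resonant scanner
(13.6 kHz) re-samples one line; stacking lines gives a space–time image
with time on the vertical axis (line index) and position along the line
on the horizontal axis. Defaults: 512 pixels across a 1.5° FOV
(≈ 1.02 µm/pixel with the 20 mm lens) and 4096 lines (≈ 0.3 s), chosen
so that a 3.82 mm/s bead at a 30° vessel angle leaves a streak tens of
pixels long — measurable but desk-scale. One line is produced per
resonant period; bidirectional interleaving and sinusoidal scan-velocity
distortion are not modeled (the instrument applies a single scale, and
nothing in the validation depends on desinusoiding).

The belt direction makes the vessel angle α with the fast-scan (+x)
axis. A bead at $(x_0, y_0)$ at time 0 is at
$(x_0 + v\cos\alpha\,t,\ y_0 + v\sin\alpha\,t)$ at line time t; the line
(y = 0) samples its blurred profile. A bead is a uniform disk convolved
with a Gaussian PSF; for speed the simulators use a Gaussian with
moment-matched width $\sigma_{\mathrm{eff}}^2 = \sigma_{PSF}^2 + r^2/4$
(the disk's per-axis variance is $r^2/4$), which is accurate whenever the
PSF is not much narrower than the bead, i.e. for all acquisition
geometries here. Slide microscopy images, where a high-NA objective
resolves the disk, instead use the soft-edged disk profile
$\Phi((r - d)/\sigma_{PSF})$. Intensities follow a
Poisson-plus-Gaussian camera model: expected photons
$B + S\cdot\mathrm{profile}$, Poisson shot noise, gain, then additive
read noise, all driven by one explicit seed per call (no global RNG
state leaks; output is bit-identical under a fixed seed).

The analytic streak oracle (`predictStreak()`) provides the geometry the
estimators are tested against: slope $\Delta x/\Delta t = v\cos\alpha$;
dwell $2 r_{\mathrm{eff}} / (v\sin\alpha)$ for α > 0 with
$r_{\mathrm{eff}} = r + 2\sigma_{PSF}$ (the time the blurred profile
intersects the line, set by the velocity component perpendicular to the
line — hence shorter streaks at steeper angles); the FOV transit time at
α = 0; and the full acquisition duration at v = 0.

## Streak velocimetry

The estimator recovers velocity from a space–time image in four steps.

1. **Preprocess.** Subtract the per-column (per-spatial-pixel) median and
   clip at zero. Static structure — slide reflections, fixed pattern,
   and any strictly stationary bead — occupies a column for most of the
   acquisition and is removed; a moving streak survives because it
   visits each column briefly. The exported `preprocessSpaceTime()` also
   normalizes to [0, 1]; the detector works on the unnormalized residual
   so that its foreground gate (4× the background MAD, a ratio) is
   invariant to global intensity scaling.
2. **Sliding ROI with per-streak masking.** A 128 px × 256 line ROI
   slides with 50% overlap. ROIs whose 99th-percentile residual is below
   the gate are skipped (this is what rejects pure-noise images). Within
   an accepted ROI the foreground (> 0.2 of the ROI maximum) is split
   into 8-connected components, and orientation is measured per
   component (up to the 3 brightest, each required to span ≥ 48 lines
   and ≥ 60 pixels). Masking to one connected streak at a time is
   essential: projecting all foreground pixels together lets fragments
   of *different* parallel streaks shear into spurious alignment,
   which at the default streak density produced a heavy-tailed slope
   distribution.
3. **Radon-style orientation.** For a candidate image angle θ
   (tan θ = pixels per line), foreground pixels are projected onto the
   intercept axis $b = x - \tan\theta\, t$ with bilinear (fractional)
   binning, and the concentration of the projection profile,
   $\sum_b p_b^2 - (\sum_b p_b)^2 / n_b$ with $n_b$ the sheared support
   width, is maximized over θ. The search runs on a 2° coarse grid
   within ±15° of the component's intensity-weighted principal-axis
   orientation (a cheap moment estimate that cannot alias), then a
   0.25° fine grid, then parabolic interpolation of the peak — the
   interpolation matters because the secant correction amplifies angular
   quantization at steep vessel angles. Exact ties break toward the
   smaller |slope|. The physical slope is
   $\tan\theta \cdot \mathrm{pitch} / \mathrm{line\ period}$ (mm/s),
   signed, so bidirectional belt motion is handled naturally.
4. **Summarize.** Slopes more than 3 MAD from the ROI-slope median are
   discarded; each surviving slope is corrected by sec α
   (`slopeToVelocity()`, rejecting α ≥ 89° where the correction
   diverges), and the acquisition is summarized by the mean, SD and
   relative SD of per-streak velocities. An empty measurement set yields
   an explicit no-estimate result rather than NaN arithmetic.

Under the default study conditions (580 beads/mm², default noise,
v = 3.82 mm/s, α = 30°) the per-streak relative SD is ~2–4%, within the
< 6% precision reported for the physical phantom on the AO-SLO channel,
and sweep regressions of measured against true velocity give slopes
within ~1% of unity with r² > 0.999. No numeric agreement with any
particular instrument's regression slope is expected — those depend on
the physical motor and optics — only near-unity recovery of the
simulator's own ground truth.

**Vessel-angle behavior.** The sec correction is accurate below ~45°;
above it, shrinking dwell (few tens of lines) and angular amplification
degrade the estimate, mirroring the breakdown observed on real
instruments. `runAngleSweep()` measures this systematically (α = 90° is
recorded as a flagged failure: the correction is undefined). A cubic
response model y(α) can be fitted (`fitAngleModel()`); the
multiplicative correction factor $v_{ref}/y(\alpha)$
(`angleCorrectionFactor()`) is deliberately opt-in and restricted to
40–90°, because it is only validated at the single velocity the model
was fitted at (the packaged reference model uses 3.82 mm/s). The
reference cubic's own value at α = 0 (1.9 mm/s against a 3.82 mm/s
truth) shows it encodes instrument-specific bias, not geometry — another
reason it is not applied by default.

## Frame-video simulator and particle tracking

ICGA-mode videos render only the fluorescent beads: 15° FOV, 768×768
pixels, 15.4 fps, 5 s. The lateral scale defaults to the true
phantom-in-air value ($f\theta$ across the frame, ≈ 6.82 µm/pixel with
the 20 mm lens); an explicit `umPerPixel` can emulate an
instrument-assumed human-eye scale, which is the mechanism behind the
slight underestimation clinical instruments show on a phantom in air.
The bead field is generated over the FOV extended upstream by the total
belt travel, so beads leave downstream while statistically identical
beads enter upstream and the in-FOV density is stationary for the whole
video.

Per-bead fluorescence amplitudes are lognormal (log-SD 1, median 1,
drawn once per video from the seed). This models the wide emission
spread of dye-loaded PLGA microspheres and is scientifically load-bearing:
at 40 fluorescent beads/mm² the mean spacing (~160 µm) is *smaller* than
the per-frame displacement at the top of the velocity range
(377 µm at 5.8 mm/s), and no frame-to-frame assignment — however optimal —
can recover correspondence for identical beads under those conditions
(the globally cheapest matching links each spot to a different,
nearer bead). Real EMA analyses face the same constraint and track only
the sparse, well-resolved bright subset. The tracking pipeline therefore
accepts a `maxSpotsPerFrame` cap (the sweep default keeps the 25
brightest spots per 768² frame, ~1 per mm², restoring spacing ≫
displacement); the brightness heterogeneity makes that subset stable
across frames.

**Detection** is a scale-normalized Laplacian-of-Gaussian blob detector
at σ = diameter/(2√2) — the standard equivalent of a Hessian-based bead
detector at this scale and easier to verify — with strict 8-neighbor
maxima above a robust threshold (median + 10 MAD of the response by
default, hence intensity-scale invariant), non-maximum suppression at
0.75 × diameter, border rejection, and subpixel refinement by the
response-weighted centroid in a 5×5 window.

**Linking** poses each consecutive frame pair as a linear assignment
problem in the standard augmented form: link costs are squared
displacements, hard-gated at `maxLinkDist` (default twice the per-frame
displacement at the 7 mm/s calibration ceiling), and death/birth costs
equal the squared gate, so a link is accepted only when cheaper than a
death plus a birth. The solver is an exact shortest-augmenting-path
assignment solver (compiled, deterministic), verified in the test suite
against exhaustive enumeration on all fixtures with ≤ 6 spots per frame.
Track merging and splitting are not modeled (beads do not merge);
one-frame gap closing is available but off by default.

**Velocity statistics.** Per-track speed is the mean frame-to-frame
displacement (scaled by µm/pixel × fps); the net straight-line speed is
reported alongside. Tracks qualify with ≥ 5 spots, and a straightness
gate (mean-step ≤ 1.2 × net speed) removes zigzag traces caused by
detection flicker between near-coincident beads — under linear flow a
genuine trace has ratio ≈ 1, so the gate is a track-quality filter of
the kind normally applied interactively in tracking GUIs. The video mean
requires ≥ 20 qualifying traces, as in EMA practice; fewer produces a
flagged low-confidence result, never a silent one.

## Calibration workbench

`linearFit()` (ordinary least squares via `lm`, r² against the mean —
not through the origin, which is the standard convention when none is
documented), `repeatabilityPercentSD()`, `runVelocitySweep()` and
`runAngleSweep()` (simulate → estimate → tabulate, three seeded
replicates per condition by default, every per-replicate seed derived
deterministically from one base seed and recorded in the output so any
row can be reproduced bit-exactly), `fitAngleModel()` and
`angleCorrectionFactor()`. Percent errors are signed
(100·(measured − true)/true) with magnitudes tabulated alongside.

## Validation scale and what it shows

The package's validation experiments run at the acquisition geometry of
the study conditions (full-length 0.3 s space–time images; 5 s videos at
15.4 fps) with five velocities × three replicates per sweep and ten
1 mm² regions for slide counting. These sizes give sampling error well
below the tolerances being checked while keeping a full validation run
in minutes on one core.

Synthetic data here emulate: calibrated linear belt motion, Poisson
bead statistics, PSF blur, photon and read noise, streak geometry at
arbitrary vessel angle, stationary bead flux, and sparse-subset
trackability. They deliberately do not emulate: wavefront aberrations
and AO correction, resonant-scan desinusoiding, eye motion, specular
slide reflections (beyond what column-median subtraction would remove),
ICG pharmacokinetics, pulsatile flow, or instrument-specific scaling
errors. Passing tests therefore demonstrate the correctness and
precision of the algorithms under controlled conditions — not that any
physical instrument achieves these numbers, and conversely the printed
instrument-specific regression constants (slopes 1.041/0.9455, residual
SDs ≈ 0.11 mm/s, the empirical cubic shape) are not targets the
simulator should reproduce.

## Numerical and degenerate-input choices

* v = 0: streak dwell is reported as the acquisition duration; the
  frame simulator renders identical frames (up to noise); a strictly
  static bead is treated as background by design.
* α = 90°: `slopeToVelocity()` and the angle sweep flag the failure
  explicitly; nothing returns an unbounded number.
* Constant images: preprocessing warns and returns zeros; detection
  returns an empty measurement table, and `summarizeAcquisition()`
  produces the explicit no-estimate result.
* All RNG flows through per-call seeds (`withr::with_seed`), so no
  function perturbs the caller's RNG state and every artifact is
  reproducible from its recorded seed.
* `Inf` link costs are encoded as a finite big-M before entering the
  assignment solver; ties in the orientation search break toward the
  smaller |slope|.

## Known limitations

Orientation precision at steep vessel angles (α ≳ 60°) is limited by
streak dwell, as on the physical instrument; the cubic correction is
only as good as the single-velocity data it is fitted to. The tracking
pipeline assumes quasi-linear motion when filtering tracks — for
genuinely diffusive particles the straightness gate should be disabled.
The paraxial scale is used at 15°, a ~1% approximation. None of these
affect the package's intended use: validating estimator implementations
against exact ground truth.
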