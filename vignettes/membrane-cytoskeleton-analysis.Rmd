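---
title: "Models and methods: membrane-bound cytoskeletal dynamics on supported lipid bilayers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

SLBdynamics analyses in vitro reconstitution experiments in which divisome
proteins (FtsZ, its membrane anchor FtsA, the cytoplasmic peptide of FtsN)
act on a supported lipid bilayer and are imaged by TIRF microscopy. This
vignette documents the models behind each estimator, the defaults and
their units, the numerical choices, and what the synthetic-data generators
do and do not emulate.

## Image-level statistics

**Pearson colocalization.** `pearsonCC()` is the plain Pearson correlation
over ROI pixels. No intensity threshold is applied: thresholding changes
the null distribution and the raw statistic is what the downstream
comparisons assume. The default analysis ROI for series-level statistics
is the central 80% rectangle (`centralRoi()`): pattern formation near the
chamber edges and illumination fall-off make the image borders
unrepresentative.

**Differential movies and PCC_diff.** Treadmilling means subunits stay
put while the filament end advances; subtracting frames separated by
`lagFrames` (default 1) and clipping negative values isolates the growth
fronts. The subtraction order is chosen so growing ends are positive;
shrinking ends are discarded by the clip. PCC_diff — the per-frame Pearson
correlation between the two channels' differential movies — therefore
measures co-movement of the growing ends ("co-treadmilling") rather than
static overlap. Frames whose differential image has zero variance (static
movies) are skipped and counted rather than propagated as errors.

**Temporal autocorrelation.** The curve anchors at frame 0: value at lag
k·Δt is the correlation between frame 0 and frame k, which directly asks
"how much of the original pattern is left after t seconds". A
frame-pair-averaged variant is available via `averaged = TRUE` for noisy
movies; it trades interpretability for variance. Decay rates come from a
least-squares monoexponential fit y = a·e^(−b·t) + k with the half time
ln(2)/b. A fit whose decay rate is non-positive or has a relative standard
error above 1 is returned flagged (`isConverged() == FALSE`) — a flat
curve has no identifiable decay and silently reporting one would be worse
than refusing.

**Intensity slope.** Ordinary least squares of channel-B on channel-A
pixel intensities estimates the binding capacity of the structure in A for
the protein in B. The default background handling subtracts each channel's
1st percentile, which removes the camera offset without clipping real
structure; `background = "none"` is available when inputs are already
offset-corrected.

**Channel alignment** is assumed done upstream. The package does not
re-implement feature-based stack registration.

## Transient confinement by packing coefficient

For a window of n steps starting at point i the packing coefficient is

$$p_i = \frac{\sum_{j=i}^{i+n-1} (x_{j+1}-x_j)^2 + (y_{j+1}-y_j)^2}{S_i^2},$$

with $S_i$ the convex-hull area of the n+1 points i..i+n. The numerator is
the summed *squared Euclidean* step length: p is a nonnegative "degree of
folding" of the local trajectory, in µm⁻² when coordinates are in µm. (A
variant that subtracts the y-term appears in some printed descriptions of
this statistic; it can go negative and cannot be thresholded as a
confinement measure, so it is treated here as a typographical artifact and
not implemented.) A molecule confined to a region of linear size L has
p ~ (step²·n)/L⁴; with the defaults below, p ≥ 1000 µm⁻² corresponds to
confinement areas of roughly < 50 nm.

Choices and degenerate cases:

* The hull spans points i..i+n inclusive; the window value is assigned to
  the *first* time point of the window (the statistic describes the
  behaviour of the following n steps).
* Default window n = `ceiling(t_thresh / Δt)`, matching the acquisition
  rate: 5 steps at 51 ms, 8 at 32 ms. Larger windows smear short events;
  shorter windows raise the statistical noise of the hull area.
* Collinear windows (hull area < 1e−12 µm²) give p = +Inf and count as
  confined — a degenerate hull is extreme confinement, not missing data.
* Windows spanning a frame gap give NA and break detection runs.

**Event calling.** Maximal runs of consecutive windows with p ≥ p_thresh
(default 1000 µm⁻²) lasting at least `ceiling(t_thresh/Δt)` windows
(t_thresh default 0.25 s) become events; Brownian trajectories mimic
confinement for shorter stretches, and the two thresholds jointly suppress
those false positives (measured false-track rate < 5% at D = 0.2 µm²/s,
51 ms frames). A called event spans every frame covered by its
above-threshold windows, i.e. from the first window's first point to the
last window's last point, duration (run − 1 + n)·Δt. Mean confinement
times are extracted by fitting A·e^(−t/τ) to the histogram of event
durations (bin width: one frame interval); because the exponential is
memoryless, τ is insensitive to the constant edge offset that any
window-based detector imposes on individual durations. With fewer than 10
events τ is reported as unavailable rather than from an unstable fit.

**Validation metric.** `validateAgainstTruth()` matches detected events to
ground-truth trapping intervals by temporal overlap (intervals dilated by
one frame) and reports |mean detected − mean true| duration over matched
events as the headline error. Individual matched pairs carry
opposite-signed systematic offsets — short events are over-extended by the
window floor, long events are trimmed where edge windows dip below
threshold — and an exponential mix of durations largely cancels these at
the mean level, which is why the mean-level comparison is the stable
benchmark quantity. The per-pair mean absolute error (which grows
monotonically with the trapped-state mobility) and the matched
distributions' fitted decay constants are also returned; the latter are
inflated by duration-dependent detectability (longer events are easier to
detect) and are reported for diagnosis, not as the benchmark.

## Residence times under photobleaching

At lapse interval τ_tl with exposure τ_int, a membrane-bound molecule
disappears from one frame to the next with probability
1 − exp(−(k_off·τ_tl + k_b·τ_int)): unbinding acts throughout the
interval, bleaching only while the shutter is open. Observed dwells are
therefore geometric in frames, and `apparentOffRate()` uses the exact
discrete MLE (q̂ = 1/mean(frames), k_eff = −log(1−q̂)/τ_tl), which makes
k_eff·τ_tl an unbiased estimate of k_off·τ_tl + k_b·τ_int. The familiar
continuous shortcut 1/(mean − τ_tl) is the small-q limit and is documented
but not used. Datasets in which every molecule lasted exactly one frame
are unidentifiable and returned flagged.

`bleachCorrectedLifetime()` regresses k_eff·τ_tl on τ_tl across ≥ 3 lapse
intervals: slope = k_off (lifetime = 1/slope), intercept = bleaching
number k_b·τ_int. Of the several ways to phrase "plot lifetimes against
acquisition rate and invert the slope", this linearization is the one in
which the inverse slope *is* the corrected lifetime, which is why it is
the implemented reading. The regression is weighted by the known
per-interval variances of k_eff and parameter uncertainties are propagated
from them rather than estimated from the residual scatter of five points.
A negative slope means the data are bleaching-dominated at the measured
intervals; the result is flagged instead of reporting a negative lifetime.

**MSD diffusion.** Per-track D comes from an OLS fit of the time-averaged
MSD to 4·D·τ + offset, the intercept absorbing localization noise, D
floored at 0. Default maximum lag is 25% of the track (minimum 3 lags);
for long tracks a much smaller fraction is statistically preferable since
long-lag MSD values are strongly correlated. Tracks shorter than 0.4 s are
skipped with the reason recorded — very short tracks produce MSD fits
dominated by noise.

## FRAP decomposition into diffusion and exchange

Normalized to the pre-bleach steady state, the bleach-region profile
f(x, t) obeys

$$\partial_t f = D\,\partial_x^2 f + k_\mathrm{off}\,(1 - f),$$

with zero-flux boundaries at the profile ends (the field of view, not the
bleach window). The exchange term assumes the solution reservoir is large
and unbleached, appropriate for a supported bilayer under a deep solution
bath in TIRF geometry; no immobile fraction is included (nothing in the
residuals of the validation fits demanded one). Pure exchange recovers
every position at the same rate — the profile shape is invariant — while
diffusion flattens the slopes at the bleach-window borders; fitting the
full (x, t) surface therefore separates D from k_off, including the
boundary cases D = 0 and k_off = 0.

Numerics: Crank–Nicolson time stepping with the conservative finite-volume
Neumann Laplacian (the discrete scheme conserves total fluorescence
exactly when k_off = 0); the initial condition is the first post-bleach
profile; frame times are assigned at mid-exposure. The fit is least
squares over all later profiles via Levenberg–Marquardt with lower bounds
at zero, a small multistart over D (10⁻³, 0.03, 0.3 µm²/s) with k_off
initialized from the mean-intensity recovery, and the integrator's
sub-steps are doubled until the fitted parameters move by < 1%. Parameters
ending at the zero bound are flagged in the diagnostics; on profiles
generated with pure exchange the fitted D is statistically
indistinguishable from zero, the quantitative form of the "shape does not
change" criterion.

`extractRecoveryProfile()` turns a movie plus a rectangular bleach ROI
into profiles: mean projection across the ROI's perpendicular extent,
pointwise normalization to the mean pre-bleach profile, optional global
bleach correction by the intensity ratio of a reference ROI to its
pre-bleach level, and optional mirroring about the bleach-window centre
for asymmetric bleaches. The bleach frame is auto-detected from the
largest ROI-intensity drop when not given.

## FRET efficiency

Destroying the acceptor abolishes transfer, so the donor rises from I_pre
to I_post = I_pre/(1 − E); `fretEfficiencyAP()` reports
E = 100·(I_post − I_pre)/I_post from background-subtracted donor means,
after verifying the acceptor actually dropped by ≥ 50%. Equivalently this
is gain/(gain + I_pre) with gain = I_post − I_pre. A literal ratio variant
100·I_post/(I_post + I_pre) — a form that circulates in protocol
descriptions but yields 50% for *no* donor change — is available behind
`literal = TRUE` strictly for reproducing legacy analyses. Raw (unclipped)
values are returned alongside the [0, 100]-clipped estimate. The spectral
estimator is the proximity ratio 100·Fa/(Fd + Fa) at the nearest sampled
wavelengths to the donor (565 nm, Cy3) and acceptor (670 nm, Cy5) emission
peaks; no bleed-through correction beyond background subtraction is
attempted.

## Binding curves and packing geometry

Hill fits use Levenberg–Marquardt with n bounded to [0.2, 10] and the
midpoint parameter positive; starting values are the first/last responses,
n = 1, and the geometric mid-concentration. Responses keep their native
sign (QCM-D frequency shifts are negative on binding), no automatic flip.
Fits at a bound are flagged, and a fitted midpoint outside the measured
concentration range triggers a warning. `fixN = 1` reduces the QCM-D form
to a Langmuir isotherm.

`latticeSpacing()` evaluates the hexagonal-lattice area per molecule,
2/√3 · 1/(6.022·x·0.001) nm² for x in pmol/cm². `maxPacking()` divides the
molecular footprint by the lipid headgroup area (default 0.5 nm²): a
30 nm² footprint occupies 60 lipids, so anchor-lipid saturation is at
100/60 ≈ 1.67% — conventionally printed as 1.66% (two decimals,
truncated); both the exact and the truncated values are returned. Note
that for a ~7 nm² footprint the same arithmetic gives 100/14 ≈ 7.1%, not
the 5% sometimes quoted for small His-tagged controls; the package reports
the formula's result.

## Synthetic data: what is emulated, and what is not

All generators are deterministic given their seed (the caller's RNG state
is restored afterwards).

**Two-state tracks.** Brownian steps with per-axis sd √(2DΔt); free
molecules over a trap zone bind with per-frame probability
1 − exp(−k_bind·Δt); trapped molecules diffuse with the trapped
coefficient, radially reflected at the zone boundary, and unbind with
probability 1 − exp(−k_unbind·Δt). Transitions are evaluated once per
frame — sub-frame switching is invisible to a frame-based detector and is
not modelled. Defaults are the detector's benchmark conditions: 50
molecules per 10 µm field of view, free D 0.2 µm²/s, trapped D
0.002 µm²/s, 51 ms frames, crossing probability 1. Zone geometry is a
package choice: stationary 25 nm disks on a 0.1 µm grid (≈ 20% area
coverage), set once so that ~10 s tracks show order-one trapping events —
comparable to the confined-track fractions seen in the corresponding
experiments — and matching the sub-50 nm confinement scale the detector
targets. Localization noise defaults to 20 nm per axis, a typical TIRF
single-molecule precision. Not emulated: blinking or multi-step
photophysics, 3D motion, camera EM-gain statistics, zone mobility.
Passing validation therefore shows the detector handles the *kinetic*
structure of the data; imaging artefacts beyond Gaussian localization
error are out of scope.

**Dwell times.** Directly generates geometric frame counts from the
disappearance model above — it emulates the statistics of multi-interval
residence-time imaging (0.125–2 s intervals, 50 ms exposure), not the
imaging itself.

**Filament movies.** Straight filaments of fixed length whose front
advances and rear retracts at the treadmilling speed, rendered as line
density, blurred with a Gaussian PSF (σ 0.15 µm on 106 nm pixels),
Poisson shot noise plus Gaussian read noise. Channel 2 mixes a coupling
fraction of the channel-1 density with a homogeneous background of equal
mean — the knob that takes PCC/PCC_diff from ~0 (independent membrane
binding) to ~1 (perfect co-localization). Not emulated: filament bending,
bundling, nucleation/turnover, photobleaching within the movie.

**FRAP profiles / FRET traces / binding curves.** Forward-integrate the
same reaction–diffusion model the fitter uses (so fit-recovery tests are
complemented by closed-form limit tests: the pure-exchange exponential,
mass conservation at k_off = 0, and heat-kernel variance growth 2Dt for a
narrow bleach, which are independent of the integrator); step the donor by
1/(1 − E); evaluate the named Hill form.

## Problem sizes and reproducibility

The validation suite runs the confinement benchmark at 150 tracks × 400
frames per grid cell over the 3 × 3 binding/unbinding grid (≈ 1500
ground-truth events per trapped-D regime), 10⁴ molecules per interval for
dwell-time recovery, 100 random tracks for the packing-coefficient oracle
comparison, and 120-point spatial grids for FRAP — sizes chosen so each
property is measured well inside its tolerance on a single CPU in minutes.
`runPipeline()` writes a manifest (package version, full configuration,
seed, output checksums) with every run; rerunning a config with the same
seed is bit-identical.

## Known limitations

* Tracks are consumed, not produced: detection/linking of spots is
  upstream (e.g. TrackMate), and only its XML/CSV exports are read.
* The confinement detector's duration resolution is bounded below by
  (run + n − 1) frames; events shorter than ~2× t_thresh are
  systematically over-estimated individually (see the validation-metric
  discussion above).
* The FRAP model is 1D; bleach geometries far from a stripe, strong
  immobile fractions, or acquisition photobleaching beyond the
  reference-ROI correction are outside the model.
* MSD-based D is a single-population estimator; state-resolved diffusion
  (e.g. HMM over free/trapped states) is intentionally out of scope, as is
  any MSD-based confinement classification — the packing coefficient
  exists precisely because windowed MSD misses transient confinement.
* Hill fits describe macroscopic isotherms; no viscoelastic QCM-D
  modelling or thermophoresis-specific corrections are attempted.
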