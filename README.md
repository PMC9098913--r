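# SLBdynamics

Quantitative analysis of membrane-bound cytoskeletal dynamics on supported
lipid bilayers (SLBs).

In vitro reconstitutions of the bacterial divisome put fluorescently
labelled FtsZ, its membrane anchor FtsA, and downstream partners such as
the cytoplasmic peptide of FtsN on a planar membrane and watch them by TIRF
microscopy. The biology lives in quantities that have to be extracted from
those movies and from companion bulk assays: how tightly a second protein
follows treadmilling FtsZ filaments, how long single molecules stay on the
membrane once photobleaching is accounted for, whether fluorescence
recovery after photobleaching (FRAP) is driven by lateral diffusion or by
exchange with solution, how strongly proteins self-interact (FRET), and how
densely a His-tagged protein can pack on Tris-NTA lipids. This package
implements that analysis chain as tested, reusable R functions, together
with seeded synthetic-data generators with known ground truth so every
estimator can be validated end to end.

## What it computes

* **Colocalization / co-treadmilling** — Pearson correlation between two
  channels (PCC); the same statistic on *differential* movies
  (PCC_diff), where consecutive frames are subtracted and negative values
  clipped so only growing filament ends remain, max(0, I(t+lag) − I(t));
  temporal autocorrelation of the filament pattern with a monoexponential
  fit y = a·e^(−b·t) + k; pixel-wise intensity-slope regression
  y = k·x + d; and recruitment-rate fits y = a·(1 − e^(−b·t)) + c.
* **Transient confinement** — the packing coefficient of a trajectory
  window, p_i = Σ_{j=i}^{i+n−1} [(x_{j+1}−x_j)² + (y_{j+1}−y_j)²] / S_i²
  with S_i the convex-hull area of points i..i+n; events are maximal runs
  with p ≥ p_thresh (default 1000 µm⁻², ≈ confinement below ~50 nm)
  lasting ≥ t_thresh (default 0.25 s, i.e. 5 frames at 51 ms or 8 frames
  at 32 ms), with event statistics from monoexponential fits to duration
  histograms.
* **Residence times** — per-interval apparent off-rates by discrete
  exponential MLE, then the photobleach correction: regressing
  k_eff·τ_tl on the lapse interval τ_tl gives the true k_off as the slope
  (lifetime = 1/slope) and the bleaching number k_b·τ_int as the
  intercept. Per-track diffusion coefficients come from MSD = 4·D·τ + b.
* **FRAP decomposition** — fits ∂f/∂t = D·∂²f/∂x² + k_off·(1 − f) with
  reflecting boundaries to the full (x, t) recovery profile: pure exchange
  lifts the profile without changing its shape, diffusion flattens the
  bleach-window borders, so D and k_off separate.
* **FRET** — acceptor photobleaching, E = (I_post − I_pre)/I_post from the
  donor gain, and spectral proximity ratio E = Fa/(Fd + Fa) at the
  donor/acceptor emission peaks (565/670 nm for Cy3/Cy5).
* **Binding curves and packing geometry** — Hill fits
  y = S + (E−S)·xⁿ/(kⁿ+xⁿ) (QCM-D) and y = U + (B−U)/(1+(EC50/C)ⁿ) (MST);
  hexagonal lattice spacing y = 2/√3 · 1/(6.022·x·0.001) nm² from a
  surface density x in pmol/cm²; maximum packing from molecular footprint
  vs lipid area.
* **Synthetic data** — seeded generators for two-state (free/trapped)
  tracks with ground-truth trapping intervals, dwell times under
  photobleaching, dual-colour treadmilling filament movies, FRAP profiles,
  FRET traces and binding curves.

## Worked example

```r
library(SLBdynamics)

# Photobleach-corrected residence time from multi-interval imaging
sets <- simulateDwellTracks(dwellSimConfig(
  kOffTrue = 0.05, bleachRate = 4, integrationTime = 0.05,
  lapseIntervals = c(0.125, 0.25, 0.5, 1, 2),
  nMoleculesPerInterval = 5000, seed = 42))
bleachCorrectedLifetime(sets)
#> FitResult [bleach_corrected_lifetime]
#>                  estimate      stderr
#> k_off          0.04994168 0.002503904
#> lifetime      20.02335665 1.003902333
#> bleach_number  0.20003988 0.002126566
#> R-squared: 0.9833
```

The simulated molecules unbind at 0.05 s⁻¹ but also photobleach
(k_b·τ_int = 0.2 per frame), so the raw mean dwell underestimates the
lifetime badly at fast acquisition; the multi-interval regression recovers
the true 20 s lifetime and the bleaching number.

```r
# Transient confinement of a diffusing peptide on filament traps
sim    <- simulateTwoStateTracks(twoStateSimConfig(seed = 42))
tracks <- filterTracks(sim$tracks)                 # drop tracks < 1 s
events <- confinementAnalysis(tracks)              # p >= 1000, >= 0.25 s
confinementStats(events, tracks)
#> events: 51, mean confinement time: 0.52 s, confined fraction: 68%

maxPacking(30)        # 30 nm^2 FtsA footprint on 0.5 nm^2 lipids
#> $lipidsPerMolecule                : 60
#> $saturatingTrisNtaPercent         : 1.666...
#> $saturatingTrisNtaPercentReported : 1.66
```

A pipeline runner (`runPipeline()`, YAML-configured; see
`inst/extdata/demo_config.yaml` and `inst/scripts/run_pipeline.R`) chains
the stages and writes CSV/JSON outputs plus a reproducibility manifest.
The methods vignette (`vignettes/membrane-cytoskeleton-analysis.Rmd`)
documents the models, defaults and their rationale.

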