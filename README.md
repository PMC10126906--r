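# mechanostat

Quantifying bone mechanoregulation from time-lapsed 3D micro-CT images.

Bone continuously adds and removes tissue at its surfaces, and the
mechanostat model holds that this (re)modeling is regulated by the local
mechanical environment: resorption dominates where the tissue is
mechanically under-used, formation where it is over-used, with set-point
thresholds bounding an adapted window in between. Time-lapsed in vivo
micro-CT of trabecular bone (e.g. the loaded mouse caudal vertebra at
10.5 µm resolution), combined with micro-finite-element estimates of the
local mechanical signal, makes this relationship measurable voxel by
voxel. This package implements the full analysis for registered
baseline/follow-up image pairs:

- **Surface (re)modeling velocity (RmV) curves.** Each baseline
  trabecular surface voxel is classified as formation, quiescence or
  resorption by overlaying the two binary images. A taxicab (city-block)
  distance transform of the follow-up image (and of its inverse) measures
  how much bone was added or removed; a gray-dilation projection carries
  the correct layer distances onto the baseline surface, and a
  cluster-wise linear rescaling guarantees that the distances attributed
  to every (re)modeling cluster sum exactly to its voxel volume. Paired
  with a mechanical signal `ms` sampled on the correct side of the
  surface, the signed distances are averaged per signal bin (1% of the
  99th-percentile cap, quiescent voxels entering as zero) and converted
  to µm/day.

- **Mechanostat fits.** Two parametric forms are fitted to RmV curves by
  bounded multi-start least squares. The piecewise-linear mechanostat

  `RmV(ms) = clamp(RVM·(ms − RT), RSL, 0) + clamp(FVM·(ms − FT), 0, FSL)`

  yields resorption/formation saturation levels (RSL, FSL, µm/day),
  velocity moduli (RVM, FVM, µm/day/µε) and thresholds (RT, FT, µε). The
  continuous hyperbola `RmV(ms) = FSL − RmVM/(RmT + ms)` has no flat
  adapted window; its RSL is the fitted value at the lowest observed
  signal and its zero crossing `RmVM/FSL − RmT` is reported alongside.

- **Conditional probabilities and CCR.** Event-conditional probability
  curves over the normalized signal (per-event count normalization, 1%
  bins) and the correct classification rate: the best normalized trace of
  the 3×3 confusion matrix over all two-threshold partitions of the
  signal axis (1/3 = random, 1 = perfect).

- **Mechanical signal fields.** Strain energy density (SED, MPa) from a
  built-in small-grid linear-elastic voxel FE solver (8-node hexahedra,
  homogeneous or density-derived material maps, force rescaling),
  effective strain `sqrt(2U/E)` (µε, bone side), or the norm of the SED
  gradient (MPa/µm, marrow side) as a fluid-flow proxy.

- **Frequency statistics.** Balanced-bootstrap distributions of the
  fitted parameters (every sample appears exactly `n_rep` times across
  replicates) and the logarithmic regression `y = y0 + a·ln f` of
  bootstrap medians on loading frequency, with pseudo-R².

- **Synthetic ground truth.** A generator that grows trabecular-like
  phantoms, assigns a smooth signal field, and advects the surface under
  a *known* mechanostat rule — so every stage of the pipeline is testable
  end to end without any external data.

Voxel volumes are read and written as NIfTI (`.nii`/`.nii.gz`), MetaImage
(`.mha`/`.mhd`) or multi-page TIFF stacks; all tabular results are
tibbles, fitted objects support `tidy()`/`glance()`, and every result
type has an `autoplot()` method.

## Worked example

Generate a synthetic weekly image pair whose surface moves according to a
known mechanostat rule, then run the full analysis:

```r
library(mechanostat)

truth <- mechanostat_truth(
  "piecewise",
  c(RSL = -2, RVM = 0.04, RT = 150, FT = 300, FVM = 0.02, FSL = 2),
  interval_days = 7, voxel_size = 10.5, noise = 0.1)

sample1 <- synth_sample(seed = 1, truth)          # 48^3 phantom, 0-600 ue ramp
result <- run_pair(sample1$baseline, sample1$followup, sample1$mask,
                   sample1$field, config = pair_config(interval_days = 7))

result$ccr
#> <CCR> 0.9097 at t_r = 24.0%, t_f = 60.0% (38 populated bins)
result$fit_piecewise
#> <mechanostat fit: piecewise> rmse 0.07916 um/day over 38 bins
#>      RSL      RVM       RT       FT      FVM      FSL
#>  -2.4671   0.0250 153.4338 296.7117   0.0178   1.8298
```

The CCR of 0.91 says that, with the two fitted thresholds at 24% and 60%
of the signal cap, 91% of the per-bin conditional probability mass falls
in the correct event interval — far above the 0.33 of a random ternary
classifier, as expected for data generated under a strict mechanostat
rule. The piecewise fit recovers the generating thresholds (RT 153 vs
150 µε, FT 297 vs 300 µε) and saturation levels (FSL 1.83 vs 2 µm/day;
the shortfall reflects merged growth fronts, see the methods vignette)
with an RMSE of 0.08 µm/day. `autoplot(result$curve,
fits = list(piecewise = result$fit_piecewise))` overlays the fit on the
curve; `tidy(result$ccr)` and `glance(result$fit_piecewise)` return the
same numbers as tibbles.

Group-level analysis over a study manifest — per-group curves,
balanced-bootstrap parameter distributions and the log-frequency
regression — runs through `run_study()`; a thin command-line front end
with `synth` and `run-pair` subcommands is installed at
`inst/cli/mechanostat-cli.R`.

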