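---
title: "Methods: estimating bone mechanoregulation from time-lapsed voxel images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: estimating bone mechanoregulation from time-lapsed voxel images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mechanostat)
```

## The model

Trabecular bone adapts its architecture to mechanical demand by adding
and removing tissue at its surfaces. The mechanostat picture formalizes
this as a feedback law: the normal velocity of the bone surface is a
function of the local mechanical signal, negative (resorption) at low
signal, zero inside an adapted window, and positive (formation) above
it, saturating on both sides. This package estimates that relationship —
the (re)modeling velocity (RmV) curve, in µm/day — from a pair of
registered, binarized micro-CT images plus a mechanical signal field
computed on the baseline image, and condenses it into parameters with
physical units:

* piecewise-linear form:
  $\mathrm{RmV}(ms) = \mathrm{clamp}(RVM\,(ms-RT),\,RSL,\,0) +
  \mathrm{clamp}(FVM\,(ms-FT),\,0,\,FSL)$,
  with saturation levels $RSL \le 0 \le FSL$ (µm/day), moduli
  $RVM, FVM > 0$ (µm/day per signal unit) and thresholds $RT \le FT$
  (signal units). The function is continuous by construction at its four
  breakpoints.
* hyperbola form: $\mathrm{RmV}(ms) = FSL - RmVM/(RmT + ms)$, which has
  no flat window. $RmT$ here is strictly the curve parameter; the signal
  at which the curve crosses zero is $RmVM/FSL - RmT$ and is reported
  separately, because the two do not coincide in general. $RSL$ for this
  form is defined as the fitted value at the minimum observed signal.

Key assumptions: the two images are registered (registration is outside
the package's scope), the trabecular compartment mask is given, voxels
are isotropic, and the mechanical state of the interval is adequately
described by the baseline field.

## From image pair to surface table

Within the mask, formed voxels are follow-up-and-not-baseline, resorbed
voxels baseline-and-not-follow-up. Baseline surface voxels (those with a
6-neighborhood background contact; out-of-bounds counts as background)
are labeled formation if face-adjacent to a formed cluster, resorption
if themselves resorbed, quiescent otherwise. When a voxel qualifies for
both, resorption wins — the voxel itself changed — and the collision is
counted in the QC report.

Distances come from a taxicab (L1) distance transform, computed exactly
by separable min-plus sweeps: the DT of the follow-up measures formed
thickness, the DT of the inverted follow-up measures resorption depth.
Formation surfaces receive the maximum DT value among their formed
6-neighbors (a gray dilation; this projects the added layer's own
distance onto the surface instead of the surface voxel's value, which
would be one too large). Resorption surfaces read their own DT value.
Because a cluster's projected distances generally do not sum to its
volume (the dilation multiplies surface counts, and L1 distances
overestimate oblique depths), each cluster's distances are rescaled by
`volume / sum(distances)`: after scaling the identity
$\sum d = $ cluster volume holds exactly, and the signed sum over the
whole table equals the net voxel change between the time points. Formed
islands with no surface contact ("orphans") are excluded and reported
rather than smeared over unrelated surfaces. Cluster connectivity is
6-neighbor, matching the neighborhood used everywhere else.

## Mechanical signals

Three voxel fields can drive the analysis, all derived from a
linear-elastic solution: SED $U$ (MPa), effective strain
$\sqrt{2U/E}\times 10^6$ (µε) — the standard SED-derived scalar that
compensates for tissue-modulus differences — and the Euclidean norm of
the central-difference SED gradient (MPa/µm), a proxy for interstitial
fluid flow. SED and effective strain are read on the bone-side surface
voxel itself; the gradient norm is averaged over the voxel's marrow
6-neighbors, since fluid-flow effects act on the marrow side of the
interface (the voxel-to-surface mapping is not uniquely dictated by the
physics; the mean over adjacent marrow voxels is our choice). Because
the downstream statistics normalize the signal by its 99th percentile,
the gradient's unit convention cannot affect probabilities or CCR.

The built-in FE solver meshes every voxel as an 8-node hexahedron with
2×2×2 Gauss quadrature and per-voxel isotropic modulus (homogeneous:
14 800 MPa bone / 2 MPa marrow, ν = 0.3; heterogeneous: a linear
density–modulus map with a 2 MPa floor, slope and intercept being
external calibration inputs with no defaults). Boundary conditions are
either the uniaxial-compression protocol (bottom face fixed, top face
displaced by 1% of the length) or an affine field of uniform uniaxial
strain on all boundary nodes, for which the homogeneous block has the
closed-form solution $U = E\varepsilon^2/2$ used as the solver's
analytic test. The global system is assembled sparsely and solved by
Jacobi-preconditioned conjugate gradients to a relative residual of
1e-8; assembly-plus-CG was preferred over a matrix-free operator because
at desk scale (≤ 64³ voxels) assembly is cheap and keeps the hot loop in
well-tested sparse linear algebra. Solutions scale linearly with the
applied displacement, so fields are rescaled to in-vivo forces by
$k = F_{target}/F_{FE}$ — linear in strain, quadratic in SED; "linear
rescaling" is ambiguous for energy quantities and the quadratic reading
is the physically consistent one.

## Curves, probabilities, fits

The signal axis is capped at the 99th percentile (linear-interpolation
quantile of all surface values; pooled across samples for group curves)
and split into 100 bins of 1%; values above the cap join the top bin.
The distance axis is binned at 1% of the maximum absolute distance, sign
restored (the sign convention for "maximum value observed" is ours); a
raw-distance option exists and is the mode used when testing exact
identities. Per signal bin the curve reports the count-weighted mean
distance — quiescent voxels contributing zeros — times voxel size over
interval days. The curve's abscissa is the observed mean signal of each
bin (falling back to the bin center when empty): with few distinct
signal values per image the nominal center can misplace a point by half
a bin, which measurably biased hyperbola parameter recovery in
validation, while with the observed mean the noise-free recovery on
exact ground-truth tables is exact to machine precision. Group curves
average per-sample curves bin-wise, unweighted, and mask bins backed by
fewer than three samples.

Conditional probabilities first normalize each event's bin counts by the
event's total — removing the large imbalance between quiescence and the
other events — then renormalize per bin, so populated bins sum to one;
empty bins are flagged, not zero-filled, and are excluded from both the
confusion sums and the CCR denominator (so the denominator equals the
number of populated bins). The CCR sweep is exhaustive over all ordered
bin-boundary pairs; finer sweeps cannot change binned sums. Ties resolve
to the smallest thresholds, making the output deterministic.

Both mechanostat fits are unweighted bounded least squares
(Levenberg–Marquardt) over the unmasked bins, with deterministic
multi-start grids over the threshold parameters — six RT values crossed
with three window widths for the piecewise form (FT is parameterized as
RT + ΔFT, ΔFT ≥ 0, so the threshold order constraint always holds), and
eight RmT values for the hyperbola, whose pole is constrained outside
the data range. Bounds are RSL ∈ [−50, 0], FSL ∈ [0, 50] µm/day, moduli
positive, thresholds inside the observed range. Curves that never go
negative (or never positive) flag the corresponding branch as
unidentifiable instead of fabricating parameters. RMSE is reported over
the fitted bins. A count-weighted loss exists behind a flag; the default
follows the convention of weighting each signal bin equally.

## Balanced bootstrap and frequency regression

Group-level parameter uncertainty uses a balanced bootstrap: `n_rep`
copies of the sample-id list are concatenated, permuted with a seeded
generator, and split into `n_rep` groups of the original size, so every
animal appears exactly `n_rep` times overall. Each replicate rebuilds
the group curve from the resampled tables (including the pooled cap and
the ≥ 3-samples bin filter) and refits; medians and IQRs summarize each
parameter, and more than 20% failed refits aborts with diagnostics.
Frequency dependence is `y = y0 + a ln f` by ordinary least squares on
the bootstrap medians of cyclic groups, with pseudo-R² =
1 − SS_res/SS_tot; sham (0 N) and static (0 Hz) groups cannot enter a
logarithmic fit and are rejected with a clear message. All randomness
flows from one study seed through deterministic per-purpose substreams.

## The synthetic generator

`make_phantom()` smooths seeded white noise (σ = 2.5 voxels by default,
about 50 µm structures at 10.5 µm resolution, within the trabecular
range) and keeps the largest 6-connected component at a target BV/TV of
0.25. Because component merges make the fill → BV/TV map jump, the
generator bisects on the monotone largest-component curve and then grows
the component by its highest-intensity adjacent marrow voxels until the
target is hit exactly; bone is kept ≥ 5 voxels from the border while the
analysis mask stops at 2, leaving headroom so advected surfaces are not
clipped. `evolve_mechanostat()` samples the signal per surface voxel
(with the same side conventions as the analysis), converts the
mechanostat velocity to a voxel displacement over the interval, adds
optional Gaussian velocity noise, rounds probabilistically (so the
expected added volume equals the target exactly — whole layers cannot
represent sub-voxel growth otherwise) and applies layers along marrow
face-neighbor directions; advancing fronts that meet merge, and the
collision count is reported. The default study conditions mirror a
weekly murine protocol: 10.5 µm voxels, 7-day interval, a 0–600 µε
effective-strain ramp (SED quadratic in height so the strain is linear),
48³ volumes.

What the phantoms do *not* emulate: plate/rod anisotropy and curvature
feedback of real trabecular bone, registration error, scanner noise and
partial-volume effects, or spatially correlated biological (non-target)
remodeling. Passing recovery tests therefore demonstrates the
correctness of the estimator chain, not robustness to imaging artifacts.
Two known systematic effects are visible even on phantoms and documented
deliberately: merged growth fronts lose a few percent of commanded
formation volume in narrow marrow spaces, and the dilation step spreads
formation labels to adjacent surface voxels; together they bias
recovered FSL low by roughly 8–9% under the default conditions (within
the 10% recovery band the validation suite asserts). Thresholds RT/FT
recover within about one signal bin.

## Numerical choices and degenerate inputs

Gaussian preprocessing uses kernel radius `ceiling(truncate·σ)` with
symmetric reflect padding and an inclusive (≥) threshold — the
comparison convention and padding are documented choices, tested
explicitly. The L1 distance transform treats out-of-bounds as
background, a conservative choice on cropped fields of view. Quantiles
are type-7 (linear interpolation). The FE solver clamps tiny negative
per-element energies (quadrature round-off) to zero. Degenerate inputs
fail loudly: empty masks, all-empty tables, single-populated-bin CCR
(returned but flagged), clusters with zero projected distance, fits with
too few bins, hyperbola poles inside the data range, and unreachable
phantom BV/TV targets all raise explicit errors rather than returning
plausible numbers.

Problem sizes in the shipped validation suite were chosen for a
laptop-class run: oracle equivalences up to 12³, conservation on fifty
28³ pairs, the FE analytic check at 32³, and parameter recovery on two
groups of six 48³ samples with 250 bootstrap replicates; the statistical
conclusions do not depend on these sizes, only the Monte-Carlo
tightness does.

## Limitations

The method yields a single net-velocity curve; it does not separate
formation-only and resorption-only velocity curves, does not track
(re)modeling patches across more than two time points, and cannot
resolve sub-voxel kinetics — the cluster-volume calibration is exactly
the device that makes whole-voxel distances integrate correctly. Image
registration, compartment segmentation and density calibration are
upstream of the package and assumed done.
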