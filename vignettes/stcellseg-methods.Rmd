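---
title: "Models and numerical methods in STCellSeg"
author: "STCellSeg maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerical methods in STCellSeg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

STCellSeg segments moving cells in 2D fluorescence time-lapse sequences
by combining three ingredients: intensity standardization over sliding
three-frame windows, coupled spatio-temporal nonlinear diffusion with
Parzen-density edge detection and watershed delineation, and a
temporally linked Chan-Vese level-set refinement. This vignette explains
each model, the parameters that matter, the numerical choices we made
where the design was genuinely open, and what the synthetic test data do
and do not demonstrate.

## Intensity standardization

PDE stages differentiate intensities, so frame-to-frame brightness
drift directly perturbs them. The standardization model is learned once
per sequence: all pixels are pooled into a 256-bin histogram over the
global range `[G_Min, G_Max]`, giving the cumulative distribution
`F_AF`. A reference background-threshold intensity `I_ref` is fixed and
its cumulative probability `F_AF(I_ref)` recorded. At test time, each
three-frame window builds its own CDF, finds the intensity `I_test`
whose cumulative probability is closest to `F_AF(I_ref)` (the argmin
runs over occupied bins only, i.e. over intensities that actually occur
in the window; ties go to the smallest intensity), and maps every pixel
through two affine transforms,

```
T1(I) = (I_ref - G_Min) / (I_test - L_Min) * (I - G_Min) + G_Min
T2(I) = 255 * (I - G_Min) / (G_Max - G_Min),
```

clipping the result to [0, 255] but keeping it floating point. With
`L_Min = G_Min`, `T1` sends `I_test` exactly to `I_ref`, so the fraction
of window pixels at or below the standardized reference `T2(I_ref)`
equals `F_AF(I_ref)` up to one histogram bin of probability mass — the
property the test suite checks. For the same reason the delineation
stage thresholds region means against `T2(I_ref)`: that is the reference
level on the standardized scale, and it is the same for every window.

Two readings of `I_ref` are supported because they serve different
data:

* `irefMode = "quantile"` (default, quantile 0.8) places `I_ref` in the
  tail of the background intensity distribution. Cells whose mean is
  only slightly above background stay above threshold — the setting to
  use when dim moving cells are the point of the analysis.
* `irefMode = "otsu"` places `I_ref` at the Otsu split of the pooled
  histogram, a global cell/background threshold. On well-contrasted
  data this yields much tighter delineations, because the dim shoulder
  of a nucleus profile is excluded.

`L_Min` is the window minimum by default (`lminMode = "window"`), with
`"global"` available; an explicit `irefValue` overrides both modes.

## Spatio-temporal nonlinear diffusion

Each window is smoothed by three coupled Perona-Malik equations solved
with explicit finite differences. Spatial fluxes use the four-neighbour
differences, each weighted by the diffusivity evaluated at the gradient
magnitude of a neighbouring position; gradients are central differences
on the replicate-padded image, so positions just outside the border
carry zero normal gradient. The diffusivity is the rational,
region-favouring form `g(x) = 1/(1 + x^2/k^2)` by default
(`gForm = "exponential"` selects `exp(-x^2/k^2)`).

Temporal coupling uses the forward/backward frame differences
`PF = I(t-1) - I(t)` and `NF = I(t+1) - I(t)`. The centre frame gains
`lambda_t * (g(|PF|) PF + g(|NF|) NF)`; the neighbour frames receive the
same fluxes scaled by `-2 lambda_t`. Weighting the temporal differences
by the diffusivity of their own magnitude preserves temporal
discontinuities exactly as spatial edges are preserved; a literal
alternative that multiplies the differences by the neighbour frame's
spatial gradient magnitude is available as
`temporalTerm = "literal_gradmag"`.

Parameters, on the standardized 0-255 scale:

| parameter | default | meaning |
|---|---|---|
| `lambdaS` | 0.2 | spatial step; explicit stability needs <= 0.25 |
| `tsRatio` | 1 | temporal-to-spatial step ratio (`lambda_t = tsRatio * lambdaS`) |
| `k` | 15 | conductance: gradients below k diffuse, above k persist |
| `nIter` | 10 | scale steps per window |

A constant window is an exact fixed point; identical frames reduce the
system to frame-wise spatial diffusion; with `k` large and `tsRatio = 0`
many small steps converge to an isotropic Gaussian blur of per-axis
variance `2 * lambdaS * nIter` (the mirror-padded convolution, matching
the zero-flux boundary). The suite verifies each of these limits plus a
literal double-loop substitution of the update equations.

## Parzen edge-occurrence map

Region interiors have unimodal local intensity distributions; windows
straddling an edge are bimodal, and the window mean then falls into the
density valley between the modes. For every pixel we estimate the
Gaussian-kernel Parzen density of its `window x window` neighbourhood
(replicate-padded) and evaluate it at the neighbourhood mean; the edge
index is `1 - f_h(mean) / max f_h(mean)`, a dimensionless value in
[0, 1] comparable across frames. Defaults: `window = 7`, bandwidth
`h = 8` on the 0-255 scale. The bandwidth controls whether bimodality is
resolved at all — too small and noise ripples the estimate, too large
and the valley disappears — so it is a per-dataset setting, like the
diffusion parameters. The index is exactly invariant to adding a
constant to the frame.

## Watershed delineation and classification

The edge map is a topographic surface: valleys are homogeneous areas,
ridges are discontinuities. We invert it and flood from the regional
minima (EBImage's watershed, with the optional `hMinima` tolerance
merging minima shallower than the given depth); every pixel is assigned
to a basin, and labels are made contiguous. Basins are classified by
the threshold rule mean > `T2(I_ref)`. With `useLikelihoods` (default
on), Gaussian class-conditional models over region area and mean
intensity act as a MAP filter on the threshold candidates: a factor
modeled in both classes enters as a density comparison, while a factor
modeled in only one class acts as a |z| > 3 veto on that class — this is
how one-pixel specks or giant artifacts are rejected when only
cell-class priors are configured. When no explicit class parameters are
given and at least `minSelfEstimate = 3` candidate regions exist, both
classes are fitted from the current partition (cells from candidates,
background from the rest). Adjacent (8-connected) cell basins merge
into one instance each; merging never splits a region, so the instance
count is bounded by the number of foreground basins.

## Chan-Vese level sets with temporal linking

The two-phase piecewise-constant energy

```
F(phi, c1, c2) = mu * length{phi = 0} + nu * area{phi >= 0}
               + lambda1 * int_{phi>=0} (I - c1)^2
               + lambda2 * int_{phi<0}  (I - c2)^2
```

is minimized by gradient descent with the regularized Heaviside
`H_eps(z) = (1 + (2/pi) atan(z/eps))/2` and Dirac
`delta_eps(z) = eps/(pi (eps^2 + z^2))`, `eps = 1`. `c1`/`c2` are the
Heaviside-weighted means inside/outside; a phase holding less than half
a pixel of Heaviside mass is treated as empty and its mean falls back
to the global image mean (flagged on the energy result). All level-set
work happens on frames rescaled to [0, 1]; the defaults `mu = 0.05`,
`nu = 0`, `lambda1 = lambda2 = 1`, `dt = 5`, `tol = 1e-4`,
`maxIter = 500` are calibrated to that scale. We chose `mu = 0.05`
after observing that stronger length penalties visibly round off and
can swallow nuclei of radius ~10 px at this image scale.

Numerical choices that required decisions:

* **Backtracking line search.** Each iteration proposes the step
  `dt * [delta_eps(phi) * (mu*curvature - nu - lambda1 (I-c1)^2 +
  lambda2 (I-c2)^2)]` and halves `dt` until the energy does not
  increase. The energy trace is therefore nonincreasing by
  construction, and divergence cannot occur; if no step size descends,
  the state is a discrete local minimum and the run stops.
* **Initial-field normalization.** `cvEvolve` first replaces its
  initial field by the signed Euclidean distance of its mask (zero set
  preserved). A field carried through earlier evolutions steepens
  enormously at the interface, and since updates scale with
  `delta_eps(phi)`, a steep interface freezes: on a moving-disk
  sequence the linked contour stalls by the fourth frame without this
  normalization and tracks exactly with it.
* **Energy-guarded redistancing.** Every `reinitEvery = 20` iterations
  (and on a stalled step) the field is rebuilt as a signed distance if
  and only if that does not raise the energy, keeping the descent
  monotone while maintaining conditioning during long runs.
* **Convergence.** Relative energy change below `tol` for five
  consecutive iterations, a stalled line search, or `maxIter`.
  `i_final` is recorded and, per the temporal linking rule
  `phi_{n+1}(.; 0) = phi_n(.; i_final)`, the final field of each frame
  seeds the next frame bit-exactly.
* **Cold-start initialization.** The pipeline default is
  `initMode = "intensity"` (`phi0` = image minus its Otsu level). The
  classical checkerboard start is available, but on sparse fluorescence
  scenes it begins with `c1 = c2`, the fitting forces vanish, and the
  relative-energy stopping rule halts the run before the phase symmetry
  breaks.

## The joint method

`segmentSequence(method = "stdiff_tcv")` runs the motion chain
(standardize, diffuse, edge map, watershed, classify) on every frame
whose index is divisible by `kModulo` and converts the instance mask to
a signed field (`reinitOnHandoff` redistances it); other frames inherit
the previous frame's converged field. Every frame is then refined by a
bounded Chan-Vese descent (`refineMaxIter = 60` by default). Two
deliberate asymmetries versus the free-running baselines:

* **Bounded refinement.** The global two-phase energy always prefers
  expelling a region whose mean is nearer the background mean, so an
  unbounded descent would re-lose exactly the low-intensity moving
  cells the motion stage recovered. A bounded budget polishes
  boundaries (where forces are large) without giving the energy time to
  erode a dim cell's interior (where forces are small).
* **Refinement area pressure.** On a Gaussian-profile nucleus the
  symmetric equilibrium rests where `(I-c1)^2 = (I-c2)^2`, i.e. at
  `(c1+c2)/2` — well below the half-maximum level that defines the
  visible nucleus boundary. The refinement therefore accepts its own
  area weight `refineNu` (fixture value 0.2 on the [0, 1] scale): the
  contour then rests where `(I-c2)^2 - (I-c1)^2 = nu`, higher on the
  intensity shoulder. A constant pressure cannot expel a bright core,
  unlike an inflated `lambda1`, which turns nuclei into annuli as soon
  as `lambda1 (peak-c1)^2` exceeds `(peak-c2)^2`.

`kModulo` defaults to 5, limiting the cost of the motion chain while
catching mitoses and entering cells within five frames. The bundled
fixture configurations use `kModulo = 1`: at 2-4 px/frame displacement a
carried contour lags a moving blob on its shallow intensity shoulder,
and re-seeding every frame removes the lag.

## The synthetic sequence generator

`generateSequence()` emulates fluorescently labelled nuclei: elliptical
Gaussian blobs (half-maximum semi-axis 8-13 px, aspect 0.7-1, truncated
at 3 sigma) on a darker background, drifting at a fixed heading with
reflection at the frame margins, with optional mitosis (a blob splits
into two diverging daughters), delayed entry, and additive Gaussian (or
Poisson) noise added last. Ground-truth masks are the noiseless
supports above half-maximum. When `targetSnrDb` is set, blob amplitudes
are rescaled analytically so the measured mean-intensity ratio —
including the contribution of sub-half-maximum blob tails to the
background mean — hits the target; the suite verifies closure within
0.5 dB. When `minSeparation` is set, starts and headings are
rejection-sampled so blobs never touch, which keeps ground-truth
instances distinct.

The named fixtures freeze the study conditions used throughout the
tests: `clean_two_blob` (two cells, 10 frames at 128x128, SNR 20 dB,
2 px/frame, seed 42), `dim_mover` (a bright slow cell plus a dim cell at
4 px/frame whose mean sits below the global cell/background split but
above the background tail — the region-competition failure mode),
`crowded` (12 touching cells) and `mitosis` (one split at frame 5).
`fixtureSegConfig()` records the per-dataset parameter estimates
(reference-threshold mode, `refineNu`, `kModulo`), mirroring the
practice of estimating motion and bandwidth parameters per sequence.

What passing on these fixtures does **not** show: real fluorescence
data have structured noise, uneven illumination, photobleaching, point
spread blur, and cells that deform; blob profiles here are ideal
Gaussians with half-maximum ground truth, so absolute Dice values do
not transfer to microscope data. What the fixtures do establish is the
relative behaviour the method is built on — motion detection recovers
dim moving cells that intensity-only segmentation drops, and level-set
refinement tightens motion masks rather than degrading them.

## Problem sizes and runtime

The test suite and the acceptance script run 128x128, 10-frame
sequences (about one second per frame for the full joint method), 64x64
single-frame grids for the diffusion and level-set properties, and 5x5
grids for the literal finite-difference oracle. These sizes were chosen
to exercise every code path with comfortably measurable effect sizes.

## Known limitations

* Instance separation relies on watershed basins plus adjacency
  merging; touching cells of similar intensity merge into one instance
  (no marker-controlled splitting), as the `crowded` fixture shows.
* No tracking: instance labels are not linked across frames.
* Single-channel 2D only; Poisson noise is supported by the simulator
  but SNR targeting assumes the additive model.
* The diffusion scheme is explicit; very large conductance values with
  `lambdaS` near the stability bound can overshoot local extrema in
  pathological configurations, although the suite's extremum-principle
  checks pass at the defaults.
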