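---
title: "Imaging two-phase aeration by fuzzy-classified impedance tomography"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Imaging two-phase aeration by fuzzy-classified impedance tomography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(feit)
library(dplyr)
```

## The measurement and the model

An aerated emulsion — whipped cream is the motivating system — is a two-phase
medium: an oil-in-water (O/W) phase that conducts at roughly $10^{-1}$ S/m,
and air bubbles that are practically insulating. A ring of $n = 8$ electrodes
on the vessel wall drives a small current (0.1 mA) between each adjacent
electrode pair while the voltage is read on every other adjacent pair; for
$n$ electrodes this *adjacent protocol* yields $N = n(n-3)$ four-terminal
measurements (40 here). From each such frame the package reconstructs an
absolute conductivity image and converts it to a probabilistic air-bubble
map, whose spatial mean tracks air incorporation over an agitation run.

The forward model is the quasi-static conduction equation
$\nabla\cdot(\sigma\nabla\varphi) = 0$ on the 2-D cross-section at electrode
height, with Neumann data: uniform current density $I/S$ over the driven
electrode arcs (the *gap* electrode model — no contact impedance) and zero
flux on the wall. We discretize with piecewise-linear triangular elements and
piecewise-constant conductivity; the potential gauge is fixed by a zero-mean
constraint (a grounded reference node gives identical four-terminal voltages,
which a test verifies to $10^{-10}$).

Two modeling choices deserve note:

* **2-D cross-section.** The vessel is imaged in the electrode plane;
  reconstructed conductivities are per-unit-depth equivalents. The 2-D
  Laplacian is scale-free in length, so coordinates stay in mm.
* **Electrode voltage readout.** The gap model has no unique electrode
  potential, so a readout convention is needed. We use the *current-weighted*
  mean of the electrode's nodal potentials — the same boundary weights that
  inject the current. With matched injection and readout weights the discrete
  system is exactly reciprocal (swapping drive and measurement pairs
  reproduces the voltage to machine precision), a property the plain
  arithmetic nodal mean loses at the $10^{-3}$ level through electrode-end
  effects. The two conventions differ only by those end effects on a uniform
  boundary mesh.

The sensitivity (Jacobian) of measurement $V$ to the conductivity of element
$i$ is the adjoint integral
$\partial V/\partial\sigma_i = -(1/I)\int_{\Omega_i}
\nabla V_\Phi\cdot\nabla V_\Psi\, d\Omega$, with $V_\Phi$ the drive-pair and
$V_\Psi$ the measurement-pair potential. With P1 elements and per-element
$\sigma$ this integral is exact — it equals the exact derivative of the
discrete forward map, which is why the finite-difference comparison in the
test suite agrees to $\sim 10^{-4}$.

## Mesh generation

The disk is meshed by a structured polar triangulation: concentric rings
sharing one angular grid, a fan at the center, and consistent quad-diagonal
splitting. The angular node count is rounded to a multiple of the electrode
count, making the mesh exactly symmetric under rotation by one electrode
pitch (tests exploit this for symmetry checks), and is refined until every
electrode arc (default 10°, configurable — the physical electrode width is
not critical to the method) contains at least one full boundary edge.
Electrode 1 is centered on the $+y$ axis; electrodes number counter-clockwise.
Total mesh area converges to $\pi r^2$ from below as the target edge length
shrinks; at the default resolution it is within 0.5%. The structured family
trades element-quality uniformity near the center for determinism and exact
rotational symmetry, which we value more here than optimal aspect ratios.

## Absolute reconstruction

The inverse problem is solved by Gauss-Newton iteration with identity
Tikhonov regularization,
$$\sigma^{(k+1)} = \sigma^{(k)} +
  \left(J^{(k)\top}J^{(k)} + \lambda I\right)^{-1} J^{(k)\top}
  \left({}^{\mathrm{exp}}V - {}^{\mathrm{sim}}V^{(k)}\right),$$
with $J$ recomputed at every iterate (the non-linear variant). Defaults:
at most 20 iterations, stop when the residual norm changes by less than
$10^{-3}$ (relative), conductivity clamped at a floor of $10^{-6}$ S/m after
each step. Divergence (three consecutive residual increases) flags the result
and returns the best iterate. The starting image is the *homogeneous best
fit*: because homogeneous voltages scale as $1/\sigma$, one reference solve
gives the closed-form scalar
$\sigma_0 = \sigma_{\mathrm{ref}}\,(V_{\mathrm{ref}}\cdot V_{\mathrm{exp}})/
(V_{\mathrm{exp}}\cdot V_{\mathrm{exp}})$; this anchors the image in physical
units of S/m (reconstructing data simulated at $\sigma$ and $10\sigma$ gives
images in ratio 10).

**Regularization strength.** Candidate $\lambda$ values live on a grid
expressed relative to $\mathrm{mean\,diag}(J^\top J)$, spanning $10^{-6}$ to
$10^{2}$, so the grid is mesh-resolution independent. For each candidate the
linearized step is computed through the SVD of $J$ (algebraically the ridge
normal-equation solution, stable at any $\lambda$) and the point
$(\log\lVert J\delta - \Delta V\rVert, \log\lVert\delta\rVert)$ recorded; the
selected $\lambda$ is the point of maximum discrete Menger curvature — the
L-curve corner — held fixed for subsequent iterations (optionally reselected
each iteration). Two numerical guards matter in practice:

* candidates below the smallest resolvable singular value produce
  near-coincident curve points whose discrete curvature is spurious, so
  points closer than 2% of the curve's bounding-box diagonal are thinned
  before the corner search;
* when the curve has no convex corner at all (every curvature non-positive),
  which happens when the 40-vector of residuals is fittable to numerical
  precision — common for noise-free synthetic data, since the Jacobian of the
  adjacent protocol has rank 20 — the selection falls back to a mid-grid
  default ($10^{-2}$ relative) instead of returning an arbitrary point of a
  featureless curve.

**What the update can and cannot do.** The adjacent 8-electrode protocol
measures 40 voltages of which reciprocity leaves 20 independent; every
Gauss-Newton step therefore lives in a 20-dimensional subspace of image
space. The uniform image direction is *not* in that subspace (its orthogonal
complement component has magnitude ~1 on the default mesh), so a uniform
offset in the starting image can never be fully corrected — which is exactly
why the homogeneous best-fit initialization matters: it removes the uniform
error before iteration begins. For the same reason, data whose only misfit is
the discretization discrepancy between a finer simulation mesh and the
reconstruction mesh gets partially fitted into a low-amplitude image ripple
(about 8–17% peak-to-peak across the mesh pairings we test, with the mean
within 2% of truth); this is a structural property of limited-electrode
tomography with an identity regularizer, not an implementation artifact.

When a whole run is reconstructed, each frame keeps the $\lambda$ of its own
first-iteration L-curve (`lambda_scope = "per_frame"`); sharing the run
median (`"run_median"`) is available but measured worse for saturation-time
recovery, because the optimal regularization genuinely differs between the
nearly homogeneous early frames and the high-contrast peak frames.

## Fuzzy phase classification

Per-element conductivities of *all* frames of a run are pooled into one
two-cluster fuzzy c-means problem — pooling preserves the temporal dimension
of the mean membership, since all frames share one pair of centroids. The
alternating updates are the membership-weighted centroid mean (exponent $h$)
and the distance-ratio membership rule (exponent $2/(h-1)$), iterated until
the loss changes by less than $10^{-8}$ relative (cap 500). Defaults and
conventions:

* $h = 2$, the canonical fuzzy-clustering choice; exposed in `fcm_config()`.
  $h \to 1^+$ approaches nearest-centroid hard assignment (tested at 1.05);
  the membership exponent is undefined at $h = 1$ exactly, so the package
  requires $h > 1$.
* Centroids initialize at the pooled minimum and maximum — deterministic, no
  seed, and the ordering convention (cluster 2 = air = low conductivity) is
  enforced on output regardless of internal order.
* A value exactly equal to a centroid takes membership 1 there (the update is
  singular at that point); exact midpoints give 0.5/0.5.
* Distance is the absolute difference of scalar conductivities (1-D feature).

One behavior worth understanding: membership in the air cluster peaks at the
air *centroid*, not at the lowest conductivity. With extremes initialization
the converged air centroid sits above the pooled minimum, so a frame whose
conductivity lies below the centroid can score marginally lower $u_2$ than
one at the centroid. Near the saturation point this compresses differences
between frames — the peak mean membership approaches 1 for every run, which
is also what makes the peak *time* robust while making fine rank distinctions
between near-peak frames hard (see limitations).

## Aeration metrics

The spatial mean membership is area-weighted,
$\langle u_2\rangle = \sum_i u_{2,i}A_i / \sum_i A_i$, over the whole sensor
area and over two circular sampling regions of diameter 20 mm: area 1 at the
vessel center, area 2 near the wall on the electrode-1 radius, centered at
$r = R - d/2$ so the circle is tangent to the wall (maximal wall proximity
without clipping). Region membership is centroid-in-circle — deterministic,
with discretization error bounded by the element size. The saturation time
$t_s$ is the argmax of the series, ties broken toward the earliest time
(first attainment of saturation). Overrun, min-max normalization (which
preserves the argmax, so $t_s$ is normalization-invariant) and the microscopy
area ratio $S_{\mathrm{air}}/S_{\mathrm{all}}$ complete the summaries;
replicate spread is reported as mean absolute deviation.

## The synthetic agitation generator

The generator emulates the three aeration stages: no air before agitation, a
monotone rise of bubble content to the critical saturation point, then a
monotone fall as bubbles are expelled. Per frame, circular bubbles with radii
uniform in 3–8 mm (configurable; deliberately mesoscale — the tomograph
cannot resolve microscopic bubbles, so the phantom mimics bulk dispersion)
are placed by rejection sampling, mutually non-overlapping and fully inside
the vessel, until the programmed area fraction is met; the final bubble is
shrunk to land on the target. Bubble conductivity defaults to the solver
floor $10^{-6}$ S/m rather than the physical $10^{-15}$ S/m of air: the
$10^{-1}$ vs $10^{-6}$ contrast is already far beyond reconstruction
resolution, and the smaller value only degrades the forward conditioning.
Measurement noise is additive, zero-mean Gaussian with standard deviation
proportional to each pattern's voltage (default 1%). One run seed derives
per-frame sub-seeds by a fixed arithmetic rule, so a run is bit-reproducible.

The default fraction profile rises linearly from 0 to the programmed peak
(0.45 at frame 6 of 10 by default — peak fractions near 0.45 correspond to
overruns around 80–100%, the realistic whipping range) and then descends
through the *midpoints* of the rise grid. The midpoint descent makes all ten
per-frame fractions pairwise distinct with equal spacing, so rank-based
comparisons between recovered and programmed aeration are well-defined; a
plain linear descent can accidentally program two frames with essentially
equal fractions, making such comparisons meaningless.

Simulation meshes are always finer than reconstruction meshes (default
~1100 vs ~530 elements; at least 2× in every shipped end-to-end test) so that
recovered results are never an inverse-crime artifact.

## What passing tests do and do not show

The synthetic runs exercise the full chain — protocol, forward solve, noise,
absolute reconstruction, pooled classification, metrics — under known ground
truth, and the saturation time of the programmed profile is recovered at 1%
noise in the shipped demo conditions. They do *not* emulate several features
of real aerated emulsions: continuous sub-resolution microbubble dispersion
(the phantom uses discrete mesoscale circles), electrode contact impedance,
3-D current spreading, temperature drift, or conductivity changes of the O/W
phase itself during whipping. Quantitative agreement on real vessels would
additionally depend on electrode calibration that the gap model idealizes
away.

A quantified limitation: the per-frame mean membership is not perfectly
rank-faithful to the true bubble *area fraction*. Impedance tomography's
sensitivity is boundary-weighted, so the apparent air content of a frame
depends on where its bubbles happen to sit; across seeds we measure Spearman
correlations of 0.95–0.99 (occasionally 1.0) between noiseless
$\langle u_2\rangle$ and the realized fraction on 10-frame runs, with
inversions concentrated among near-peak frames where the pooled memberships
saturate. The saturation *time* is much more robust than the full ranking,
and that is the quantity the method is designed to deliver.

## Numerical choices at a glance

| Quantity | Default | Where |
|---|---|---|
| Electrode arc | 10° | `build_disk_mesh()` |
| Injected current | 0.1 mA (10 kHz metadata) | `adjacent_protocol()` |
| GN iterations / tolerance | 20 / $10^{-3}$ | `recon_config()` |
| $\lambda$ grid (relative) | $10^{-6}..10^{2}$, L-curve corner | `recon_config()` |
| Conductivity floor | $10^{-6}$ S/m | `recon_config()` |
| Fuzziness $h$ | 2 | `fcm_config()` |
| FCM tolerance / cap | $10^{-8}$ / 500 | `fcm_config()` |
| Bubble radii | 3–8 mm | `simulate_agitation_run()` |
| Noise | 1% of \|V\| per pattern | `feit_config()` |
| Sim / recon mesh edges | 4.5 / 6.5 mm | `feit_config()` |

## A complete run

```{r demo, eval = FALSE}
res <- feit_run_all(feit_config(seed = 1))
dplyr::filter(res$analysis$t_s, quantity == "u2_all") # t_s = 300 s (frame 6)
plot_aeration_series(res$analysis$metrics)
plot_membership(res$meshes$recon,
                dplyr::filter(tidy(res$analysis$classification),
                              time_s == 300)$u2)
```
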