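# feit

Fuzzy phase classification implemented in electrical impedance tomography
(fEIT) for imaging two-phase air/emulsion dispersion — e.g. air-bubble
incorporation in whipping cream during agitation — from multi-electrode
boundary voltages, with a full synthetic phantom and agitation-run simulator
so every stage can be exercised without laboratory hardware.

## The problem and the method

A cylindrical vessel (diameter 84 mm) carries a ring of 8 electrodes. A
0.1 mA current is driven between each adjacent electrode pair and the voltage
is measured on every other adjacent pair (the *adjacent method*), giving
`N = n(n-3) = 40` four-terminal measurements per time point. The oil-in-water
(O/W) emulsion phase conducts at roughly `1e-1` S/m while air is practically
non-conducting (`~1e-15` S/m), so the conductivity image separates the two
phases. The pipeline has four stages:

1. **Forward model.** The quasi-static potential solves
   `div(sigma grad phi) = 0` on a triangulated cross-section with Neumann
   boundary conditions `sigma dphi/dn = I/S` on the driven electrode arcs
   (gap model) and zero flux on the wall. Piecewise-linear finite elements,
   piecewise-constant conductivity; the sensitivity of measurement `V` to
   element conductivity `sigma_i` is the adjoint integral
   `dV/dsigma_i = -(1/I) * int_{Omega_i} grad(V_drive) . grad(V_meas) dOmega`,
   exact in this discretization.
2. **Non-linear absolute reconstruction.** Gauss-Newton iteration
   `sigma^(k+1) = sigma^(k) + (J'J + lambda I)^(-1) J' (V_exp - V_sim^(k))`
   with the Jacobian `J` recomputed at every iterate, Tikhonov weight
   `lambda` selected by the L-curve corner, and a homogeneous best-fit
   initial image that pins the absolute scale in S/m.
3. **Fuzzy phase classification.** The pooled conductivity values of all
   frames of a run are clustered into two fuzzy classes by the alternating
   updates `mu_j = sum_i u_ji^h sigma_i / sum_i u_ji^h` and
   `u_ji = 1 / sum_l (|sigma_i - mu_j| / |sigma_i - mu_l|)^(2/(h-1))`
   until the loss `zeta = sum_j sum_i u_ji^h |sigma_i - mu_j|^2` converges.
   The low-conductivity cluster is the air-bubble class; `u_2` is the
   per-element air membership.
4. **Aeration metrics.** The area-weighted mean
   `<u2> = sum_i u_{2,i} A_i / sum_i A_i` (globally and over two circular
   20 mm sampling areas), its peak time `t_s` (the critical saturation point
   of air incorporation), the overrun `OR = (m0 - m_nt)/m_nt * 100` [%], the
   min-max normalization `(x - min)/(max - min)`, and the microscopy area
   ratio `S_air / S_all`.

The synthetic module generates ground-truthed agitation runs: a programmed
bubble-area-fraction profile that rises to a saturation peak and falls again,
seeded non-overlapping circular bubbles per frame, forward simulation on a
fine mesh, and optional proportional Gaussian measurement noise.
Reconstruction always happens on a coarser mesh than simulation, so tests
never commit the inverse crime.

## Worked example

```r
library(feit)
library(dplyr)

# simulate -> reconstruct -> classify -> analyze, all defaults:
# 84 mm vessel, 8 electrodes, 10 frames at 60 s, saturation programmed at
# frame 6 (t = 300 s), peak bubble fraction 0.45, 1% measurement noise
res <- feit_run_all(feit_config(seed = 1))

filter(res$analysis$metrics, quantity == "u2_all")
#>    time_s  value
#>  1      0 0.0187
#>  2     60 0.2546
#>  3    120 0.4662
#>  4    180 0.8234
#>  5    240 0.9084
#>  6    300 0.9619   <- peak: the critical saturation point
#>  7    360 0.9326
#>  8    420 0.7577
#>  9    480 0.5174
#> 10    540 0.3894

filter(res$analysis$t_s, quantity == "u2_all")
#>   quantity   t_s  peak
#>   u2_all     300 0.962
```

The mean air-bubble membership `<u2>_All` rises as air is incorporated,
peaks at the programmed saturation frame (`t_s = 300` s, frame 6), and falls
as bubbles are expelled — the three-stage aeration narrative the method is
built to image. `plot_membership(mesh, u2)` renders any frame with the
two-phase convention (O/W black, air white), and
`plot_aeration_series(res$analysis$metrics)` draws the `<u2>` series for the
whole sensor area and both sampling regions.

A thin command-line front end ships in `inst/cli/feit`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/feit", package = "feit"))')" \
  run-all --out demo_run
```

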