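# solvbox

Diagnostics for a deceptively simple question in explicit-solvent molecular
dynamics: **is the periodic water box big enough for the solvent to behave
like bulk water?**

For large, partly hydrophobic solutes (the hemoglobin tetramer is the
canonical case) an undersized box suppresses the hydrophobic stabilization
of the native quaternary state, and the simulation undergoes structural
transitions that the real molecule does not. The tell-tale observables are
measurable from the trajectory itself:

1. **Water self-diffusion.** From the Einstein relation
   `D = lim (1/6) d⟨|r(t) − r(0)|²⟩/dt`, with the Yeh–Hummer finite-size
   correction `D0 = D_PBC + kB·T·ξ/(6π·η·L)` (ξ = 2.837297 for a cubic
   lattice). In an adequate box the hydration water diffuses like bulk
   water of the same model (corrected TIP3P reference:
   5.95×10⁻⁵ cm²/s).
2. **Hydrogen-bond network.** The average number of water–water H-bonds
   per molecule under donor–acceptor distance cutoffs (2.8 / 3.0 / 3.3 Å =
   strong / medium / weak), its interval running averages, the drop at each
   structural transition, and its fluctuation, which should shrink as
   1/√N_water.
3. **Structural stability.** Cα RMSD against reference structures (Kabsch
   superposition), residue-pair distances (e.g. His146β1–His146β2), salt
   bridge contacts, and change-point detection (penalized binary
   segmentation) on those series.

Supporting analyses: radial distribution functions, Chandler-style solvent
density profiles around a solute, region water counts and their
distributions, diffusion-vs-box-size scaling fits, and the linear
extrapolation of first-transition times against D. Seeded synthetic
generators (Brownian water, ideal gas, H-bond lattices, layered hydration
shells, piecewise-constant transition traces) provide fixtures with exactly
known ground truth, so every stage is testable without trajectory data.

## Worked example

```r
library(solvbox)

# Water-like box: 1000 particles at bulk density diffusing at the corrected
# TIP3P bulk value, 400 ps
water <- gen_brownian_water(N = 1000, L = 31, D = 5.95e-5, dt = 1,
                            n_frames = 400, seed = 11)
est <- fit_diffusion(compute_msd(water, origin_stride = 4))
est
#> <sbx_diffusion> D_pbc = 5.959e-05 +- 3.6e-07 cm^2/s (fit 20-100 ps, L = 31 A)
finite_size_correct(est)
#> <sbx_diffusion> D_pbc = 5.959e-05 +- 3.6e-07 cm^2/s (fit 20-100 ps, L = 31 A)
#>   D0 (corrected) = 6.582e-05 cm^2/s

# A structural distance trace with transitions planted at 140 and 530 ns
trace <- gen_transition_trace(c(140, 530), levels = c(30.9, 25.9, 20.9),
                              sigma = 0.5, dt_ns = 0.5, T_ns = 1000, seed = 7)
detect_transitions(trace)
#> <sbx_transitions> 2 change point(s) at 139.5, 529.5 ns

# Combined verdict
report <- assess_box(water, structural_series = trace,
                     config = solvbox_config(msd_origin_stride = 4,
                                             hbond_stride = 20))
report
#> <sbx_report> box-size adequacy
#>   diffusion : PASS  (D = 5.959e-05 cm^2/s, 100.2% of bulk ref)
#>   H-bonds   : PASS  (mean 3.750 /molecule, fluctuation 0.0990, 1.6x ideal)
#>   stability : FAIL  (2 transition(s) detected)
#>   verdict   : NOT ADEQUATE
```

Reading the output: the fitted diffusion coefficient recovers the
generator's bulk value to 0.2 % (the box passes bulk-likeness at the
default 2 % tolerance); the H-bond fluctuation sits at 1.6× the
statistical-mechanics expectation for this particle count (below the 3×
threshold); but the distance trace contains two detected quaternary-style
transitions, so the box is judged not adequate — exactly the failure mode
an undersized solvent box produces.

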