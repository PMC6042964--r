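---
title: "Solvent-box adequacy diagnostics: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Solvent-box adequacy diagnostics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(solvbox)
```

## The problem

Explicit-solvent molecular dynamics wraps a protein in a periodic box of
water. The folk rule — a few water layers between protein and boundary — is
not always enough: for large, partly hydrophobic solutes such as the
hemoglobin tetramer, the hydration water in an undersized box stops behaving
like bulk water, and solvent-mediated stabilization (the hydrophobic effect)
is not reproduced. The observable symptoms are (i) a depressed water
self-diffusion coefficient relative to the bulk value of the water model,
(ii) fewer water–water hydrogen bonds per molecule with larger fluctuations,
and (iii) spurious large-scale structural transitions of the solute.
`solvbox` packages these three diagnostics, the hydration-structure profiles
that explain them, and a combined adequacy verdict.

## Diffusion: MSD, Einstein relation, finite-size correction

The self-diffusion coefficient is estimated from the mean-squared
displacement via the Einstein relation

$$ D = \lim_{t\to\infty} \frac{1}{6}\,
   \frac{\partial}{\partial t}\langle |r(t)-r(0)|^2 \rangle . $$

`compute_msd()` averages over all selected particles and all time origins
(optionally thinned with `origin_stride`, which changes only the sampling,
not the estimator). It refuses wrapped coordinates: box wrapping introduces
spurious L-sized jumps into displacements. `fit_diffusion()` takes the
least-squares slope over a fit window and divides by 6. The window default
is the central **10–50 % of the available lags**: short lags are excluded
because real MSD curves have a non-diffusive short-time regime, long lags
because the origin average there has few effectively independent samples.
The window is exposed (`t_min`, `t_max`) and the error bar is the absolute
difference between fits on the two halves of the window — a deliberately
simple, assumption-free spread estimate.

Under periodic boundary conditions, hydrodynamic self-interaction with the
periodic images depresses D. `finite_size_correct()` applies the standard
cubic-lattice correction

$$ D_0 = D_\mathrm{PBC} + \frac{k_B T\,\xi}{6\pi\eta L},
   \qquad \xi = 2.837297 , $$

which is linear in $1/L$ (equivalently $N^{-1/3}$ at fixed density).
Defaults: $T = 298$ K, $\eta = 3.21\times10^{-4}$ Pa s (the standard TIP3P
shear viscosity at 298 K). The bulk reference used for "bulk-likeness"
comparisons defaults to $5.95\times10^{-5}$ cm²/s, the finite-size-corrected
bulk TIP3P value; it is a configuration constant, not re-derived, because
published formulations of the correction arithmetic for that number are
ambiguous about which L enters. `scaling_fit()` fits D against $1/L$ across
box sizes, and `extrapolate_transition_time()` fits the empirically linear
relation between D and the time of the first structural transition.

## Hydrogen-bond statistics

`find_hbonds()` counts water–water bonds by the donor–acceptor (O–O)
distance criterion at the conventional cutoffs 2.8 Å (strong), 3.0 Å
(medium) and 3.3 Å (weak). No angular term is applied by default: the
criterion must work on oxygen-only coordinates, and the distance-only
definition is the one the diagnostics are calibrated to. An optional
donor-H⋯acceptor angle filter is available when hydrogens are present. The
search uses a cell list (cells no smaller than the cutoff, 13
forward-neighbour scan) and is exactly equivalent to the all-pairs scan;
the equivalence is asserted in the test suite. A cutoff above L/2 is an
error because the minimum-image convention becomes ambiguous there.

Per-molecule averages credit each bond to both partners
(`2 × pairs / N`); the pairs-counted-once convention is selectable and
halves the absolute level without affecting drops or fluctuation trends.
`interval_statistics()` computes running averages between supplied interval
boundaries (the lifetimes of structural states) plus the per-transition mean
drops.

The adequacy criterion for fluctuations is scale-aware: the standard
deviation of the per-frame bonds-per-molecule series is compared against
`factor × sqrt(mean / N_water)`, the statistical-mechanics expectation for
uncorrelated molecular counts, which shrinks as $1/\sqrt{N}$ with box size.
An absolute threshold cannot serve boxes of 10³ and 10⁵ waters at once; the
default factor of 3 is heuristic and marked as such.

## Structural metrics and transition detection

`kabsch_rmsd()` computes the optimal proper rigid superposition by SVD,
rejecting reflections by construction; structures are paired on the
(chain, residue number) intersection of their Cα atoms, dropping mismatches.
A quaternion-eigenvector oracle and an independent superposition routine
cross-check it in the tests. `residue_pair_distance()` deliberately does
*not* apply the minimum image: intra-protein pairs (e.g. the two terminal
His146 Cα atoms of the β chains, whose separation distinguishes the tense
from the relaxed quaternary state) stay together when the protein's centre
of mass is restrained, and wrapping would fold genuine large-amplitude
motion back into the box.

`detect_transitions()` commits to penalized binary segmentation on the
squared-error cost — transitions in the published traces were identified by
eye, so the package needed a reproducible rule. Defaults: penalty
$3\hat\sigma^2\log n$ (BIC-like) with $\hat\sigma$ estimated robustly from
the median absolute successive difference divided by $\sqrt2$ (so plateau
jumps do not inflate the noise estimate), and a minimum segment of 10
samples. Both are exposed. The reported change-point time is the last
sample of the left segment; with a sampling interval of 0.1 ns this places
a planted 140 ns step at 139.9 ns, well inside the ±5 ns recovery
tolerance used in the tests.

## Hydration structure

`radial_distribution()` normalizes the minimum-image distance histogram by
the ideal-gas shell expectation $4\pi r^2\,\mathrm{d}r\,\rho$; bins are the
standard `[k·dr, (k+1)·dr)` grid with centers at half-integers, so a shell
planted exactly at a bin boundary reports within half a bin of its true
radius. `density_profile()` measures water density versus distance from the
solute surface: distance to the solute centre of geometry minus an
effective radius R (default: the 99 %-coverage radius of the solute atoms,
because "the radius" of a protein is otherwise undefined; override with an
explicit R), normalized by the bulk density taken from the outermost 10 %
of valid distances (valid means $R + r \le L/2$). If no bulk region exists
the profile is returned unnormalized with a warning rather than silently
misnormalized. Default bin widths are 0.1 Å for residue-scale g(r) and
0.5 Å for protein-scale profiles. Region water counts
(`count_waters_in_region()`) take explicit sphere or cylinder geometry —
published "central cylinder" counts do not fully specify the geometry, so
none is inferred.

## The synthetic generators

The generators are statistical stand-ins with exactly known ground truth,
not water models: no forces, no hydrogens, no thermostat.

* `gen_brownian_water()`: independent Gaussian walks with per-step
  per-dimension variance $2D\,\mathrm{d}t$ (units: 1 cm²/s = 10⁴ Å²/ps,
  fixed in one place). MSD-based estimators must recover D exactly in
  expectation.
* `gen_ideal_gas()`: uniform points; the flat-g(r) oracle.
* `gen_hbond_lattice()`: fully periodic simple-cubic lattice — exactly 6
  nearest neighbours per site, the hand-countable H-bond fixture.
* `gen_layered_solute()`: delta-function hydration shells at known radii
  plus uniform background excluded from `max(radii) + 1` Å.
* `gen_transition_trace()`: piecewise-constant means with i.i.d. Gaussian
  noise. Real structural traces are autocorrelated; i.i.d. is the minimal
  testable choice, so detector performance on these fixtures bounds, rather
  than predicts, performance on correlated data.

Every generator takes an explicit seed, is bit-reproducible, and records
its ground truth in the returned object's metadata so tests never re-derive
truth from the fixture.

What passing these tests shows — and does not show. Recovery on the
fixtures validates the estimators' correctness and calibration under known
conditions. It does not validate force fields, sampling adequacy of real
MD, or the behaviour of correlated noise; on real trajectories the
diagnostics remain advisory.

## The adequacy report

`assess_box()` runs the three criteria and returns per-stage metrics,
flags, and a verdict that is a pure function of the recorded metrics and
thresholds: bulk-likeness of D (default tolerance 2 %, matching the known
1–2 % shift that physiological ions alone produce), the scale-aware
H-bond fluctuation criterion, and absence of detected transitions. The
Yeh–Hummer correction is applied to the fitted D only when
`apply_correction = TRUE`: synthetic Brownian particles have no
hydrodynamic self-interaction, so for fixtures the uncorrected D is the
right comparand, while real MD water should enable it. A stage that errors
is reported and leaves the verdict at "not adequate" — a partial report
never claims adequacy. The report is advisory: it states whether the three
observable criteria hold, not that the simulated state is thermodynamically
stable.

## Problem sizes and numerical choices

The test suite and the bundled analysis script run on desk-scale problems
chosen to keep the full suite in the low minutes while leaving comfortable
statistical margins: Brownian-water recovery uses 1000 particles × 1000
frames (the estimator's seed-to-seed spread there is ≈1.4 %, against a 2 %
tolerance, and its 20-seed mean is unbiased to ≈0.1 %); change-point
recovery uses 10 000-sample traces with plateaus 10 noise-σ apart;
hydration fixtures use a few hundred points per shell. Degenerate inputs
fail loudly by design: wrapped coordinates into MSD, cutoffs or ranges
beyond L/2, empty selections, non-cubic boxes, overlapping shells, and
zero-volume regions are all errors rather than silent zeros.

## Known limitations

* Cubic boxes only; non-cubic input is rejected.
* Trajectory I/O is plain-text multi-frame XYZ (with a `box=L dt=dt`
  comment convention); binary formats (DCD/XTC) are out of scope.
* H-bond detection is distance-only by default; lifetimes and kinetics are
  not computed.
* Binary segmentation is greedy; for closely spaced transitions under heavy
  noise an exact dynamic-programming search could differ.
* The β-chain identifiers used to address His146 are configuration, not
  inference: deposited structures vary in chain naming.
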