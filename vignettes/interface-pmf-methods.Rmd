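---
title: "Methods: free-energy and orientation analysis at a slab-water interface"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: free-energy and orientation analysis at a slab-water interface}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slabpmf)
```

This vignette is the package's own account of the methods it implements:
the models, the numerical choices, what the synthetic-data generator does
and does not emulate, and the design decisions taken where more than one
reasonable convention exists. Every empirical statement below is one that
the test suite or the analysis scripts actually compute.

## The physical setting

A single solute molecule (the motivating case is an anionic perfluoroalkyl
surfactant such as PFOA or PFOS at infinite dilution) approaches a polymer
slab — polyethylene in the motivating case — immersed in water. The
quantities of interest are:

* the potential of mean force (PMF) along the slab-solute separation,
  reconstructed from umbrella-sampling windows;
* the position of the slab-water interface (Gibbs dividing surface, GDS),
  used to re-reference the reaction coordinate;
* the orientational order of the solute relative to the local polymer
  chain director near the interface;
* the solute's internal conformational change, as backbone RMSD.

## Umbrella sampling and WHAM

Each window `i` restrains the raw reaction coordinate ξ′ with a harmonic
bias w_i(ξ′) = k/2 (ξ′ − ξ_i′)². The default force constant is
41.84 kJ mol⁻¹ Å⁻² (10 kcal mol⁻¹ Å⁻²; `bias_spec()` accepts kcal units
with the explicit 4.184 conversion) and the default temperature 300 K
with k_B = 0.0083144621 kJ mol⁻¹ K⁻¹.

`wham_solve()` iterates the standard self-consistent equations on binned
counts, starting from f_i = 0, until max |Δf_i| < tol·k_BT
(default tol = 10⁻⁶, cap 10⁵ iterations; non-convergence is an error that
reports the residual rather than a silent result). Bins with zero total
counts are excluded from the normalization and reported as `NA`, never
interpolated.

Two numerical choices deserve justification:

**Bin width (default 0.1 Å).** The biased stationary distribution in a
window has width σ = √(k_BT/k) ≈ 0.24 Å at the default force constant.
Bins must resolve that width; 0.1 Å ≈ σ/2 does, while still leaving
hundreds of counts per bin at the sample sizes used here.

**Bias discretization (default `"average"`).** The discretized WHAM
equations need a per-bin Boltzmann factor of the bias. Evaluating the
bias at the bin center (the common midpoint rule, available as
`bias_quadrature = "midpoint"`) is biased when the bias energy varies by
more than k_BT across a bin — at k = 41.84 and 0.2 Å bins the variation
reaches several k_BT a few bins away from the window center, and the
resulting reconstruction carries a systematic ripple of several tenths of
a kJ mol⁻¹ (visible as a non-flat reconstruction of a flat profile). The
default therefore uses the analytic bin average of exp(−w/k_BT), a
Gaussian integral evaluated as an erf difference, which is exact for the
bias factor at any bin width. Neither quadrature is exact once the
*unknown* profile also varies strongly within a bin, which is the second
reason the default bins are fine rather than coarse: at 0.1 Å both
quadratures agree and both recover a 5 k_BT double well with RMSE ≈ 0.3
kJ mol⁻¹ under the test suite's sampling (25 windows × 5·10⁴ samples).

**Plateau zeroing.** Following standard practice for interfacial PMFs,
the zero is fixed by fitting a constant (the arithmetic mean) to the PMF
over the bulk-solvent plateau and subtracting it everywhere
(`zero_by_plateau()`). The plateau range defaults to the last 20% of
defined bins and should be overridden whenever the window layout makes
that heuristic wrong; the subtracted constant and range are recorded in
the profile's `zero_reference`.

**Replicas.** Statistical uncertainty is the per-bin sample standard
deviation across independent replicas (`combine_replicas()`), matching
the "independent simulations per window" design rather than a bootstrap.
Replicas must be zeroed before combination so they share a reference
state; combining unzeroed replicas is refused.

## Synthetic window data

`sample_window()` draws from exp(−[A(ξ)+w(ξ)]/k_BT) by Metropolis Monte
Carlo: only the stationary distribution matters to WHAM, so Monte Carlo
replaces restrained MD. The base profile is tabulated on a 0.005 Å grid
and linearly interpolated inside the compiled kernel; proposals outside
the domain are rejected (an infinite wall). The proposal step is tuned
during burn-in to a 30–50% acceptance rate; burn-in defaults to 10% of
the requested samples and is exposed as a parameter, since equilibration
discard rules are a matter of protocol rather than of the estimator.
A decorrelation stride (`thin`, default 10 Metropolis steps per retained
sample) keeps retained samples close to independent, so closed-form
checks of means and variances at 3 standard errors are meaningful.

The sampler is validated against closed forms: a harmonic bias on a flat
profile gives a Gaussian with variance k_BT/k; adding a harmonic profile
of stiffness a shifts the mean to kξ_c/(a+k) and the variance to
k_BT/(a+k) (completing the square); with no bias a bounded flat profile
gives uniform counts within a multinomial envelope.

A practical note on window layout: adjacent windows must overlap for the
self-consistent iteration to be well conditioned. `window_overlap()`
reports the overlap coefficient Σ min(p, q) per adjacent pair; layouts
whose spacing is many σ converge impractically slowly and give
random-walk drift in the relative f_i. The test suite uses 25 windows
over 20 Å at the default force constant (spacing ≈ 0.83 Å ≈ 3.4 σ,
overlap ≈ 0.07), which is the sparsest layout that behaved well.

## Interface fits and the Gibbs dividing surface

`density_profile()` bins wrapped coordinates along the chosen axis and
converts to g cm⁻³ with Avogadro's number; mass density (not number
density) is used because interfacial studies report bulk densities in
g cm⁻³. The box cross-section is taken per frame, assuming a
fixed-volume (NVT-like) ensemble, which is the ensemble that preserves
interfacial area.

The slab model shares a single ρ_b and width D across its two edges; the
solvent model likewise. Fits use Levenberg–Marquardt (`minpack.lm`),
with starting values from the half-maximum crossings of the profile, and
refuse flat profiles. Fit idempotence (refitting a fitted curve) holds
to 10⁻⁸, and parameters on exact model data are recovered to 10⁻⁴
relative; with 1% multiplicative noise, to 2%.

The GDS is the root of ρ_slab(z) − ρ_w(z) near each interface, located
by a coarse bracketing scan followed by Brent's method (tolerance
10⁻⁶ Å). When several crossings fall in a bracket the one nearest the
interfacial midpoint is taken; absence of a sign change (e.g. solvent
denser than the slab everywhere) is an explicit error.

`rereference()` maps ξ′ to the signed distance ξ from the *nearest*
surface, negative toward the slab interior. Ties at the exact midplane
resolve to the upper surface. Note a consequence of "nearest": ξ is
invariant (not negated) under reflection of the whole system through the
slab midplane; it is negated by reflection about a single surface.

## Orientation analysis

The solute director (`solute_vector()`) averages the normalized
1,3-vectors x_{k+1} − x_{k−1} over interior backbone beads and
normalizes; with the backbone listed tail-to-head, it points toward the
headgroup. For a carboxylate-headed solute the headgroup carbon is
excluded from the backbone list by the caller; a sulfonate headgroup
contributes no carbon at all, so all tail carbons enter and the sulfur
never does.

The local chain director (`slab_vector()`) accumulates the 1,3-vectors
of slab fragments selected by `select_cylinder()`: a fragment belongs to
the cylinder when its *central* bead lies within the radius (13 Å
default, minimum image in xy) and axial range (18 Å above the slab COM
up to the nearest GDS). Membership by the central atom is the simplest
convention that avoids double-counting partial fragments. Because chain
ends are chemically indistinguishable, each fragment vector's sign is
arbitrary; the implementation flips each vector when its dot product
with the running resultant is negative (the first vector, and the final
resultant, are flipped to non-negative z; an exactly horizontal
resultant deterministically flips to +z). Literal maximization of the
resultant magnitude over all 2ⁿ sign choices is exponential; the greedy
rule is used instead, and the test suite retains the exact enumeration
as an oracle for n ≤ 15, where the greedy magnitude never exceeds the
optimum, reaches at least 75% of it on random vector sets, and equals it
on near-aligned sets — the physical regime of stretched chains near an
interface.

S_v is computed per frame from θ = ∠(v₁, v₂) and ensemble-averaged
within ξ-bins as (3⟨cos²θ⟩ − 1)/2 (averaging cos²θ first or per-frame
S_v is the same affine transform either way). Confidence intervals are
t-intervals across replica means, or across contiguous block means
(5 blocks) when only one replica exists; bins with no frames are `NA`.

## Backbone RMSD

`kabsch_align()` is the SVD superposition with the determinant
correction that forbids reflections — a mirror image keeps a positive
RMSD, as the rotation-grid oracle in the tests confirms. Superposition
is unweighted (equal atom masses): nothing in the backbone-restricted
analysis motivates mass weighting. The printed definition of RMSD as a
mean of deviations is implemented as the standard root of the mean
*squared* Euclidean deviation, since the unsquared form is dimensionally
inconsistent. `backbone_rmsd(align = FALSE)` exposes the raw deviation
(e.g. d/√N for a single displaced atom); the default aligns first, and
alignment can only reduce the value. The reference "extended
conformation" is the all-anti zigzag built by `make_oriented_chain()`.

## The slab generator: what it emulates, and what it does not

`make_interface_system()` builds bead systems whose ensemble densities
follow the two tanh models exactly up to sampling noise:

* **Solvent** beads are single sites with z drawn by inverse-CDF
  sampling from the solvent model — the generated density *is* the
  model.
* **Slab chains** run along +z; each chain's lower and upper end are
  drawn from logistic distributions centred at h₁ and h₂ with scale D/4,
  whose survival/CDF are exactly the tanh edge factors. The resulting
  density is the product of the two edge sigmoids, which differs from
  the difference-of-tanh form only by terms of order e^(−4(h₂−h₁)/D) —
  negligible for any slab thicker than a few D. Beads sit at cell
  centers along the span so the smeared edge is unbiased. A consequence
  is that bead counts per chain vary; the interface shape, not the
  chain length, is the controlled quantity.
* **Chain orientation** defaults to +z with a 5° Gaussian tilt jitter —
  a crystalline-slab-like degree of alignment; set it to 0 for exact
  alignment. The jitter is frozen within a realization, so ensemble
  averages of the chain director need several independent realizations
  (`make_interface_trajectory()` jitters positions, not chain tilts).
* **The solute** is placed with its COM at a prescribed signed distance
  ξ₀ from the upper GDS (computed analytically from the generating
  parameters and carried in the `"generating"` attribute) and a
  prescribed tilt θ₀, in extended or noise-perturbed conformation. Its
  beads carry charge −1/n so the molecule is a net −1 anion;
  `correct_net_charge()` is the utility that enforces such a target
  exactly after any rounding.

Default bulk densities (0.93 and 1.04 g cm⁻³) and bead masses (14, 18,
50 g mol⁻¹) are those of a semicrystalline high-density polyethylene
slab in water with a CF₂-like solute. What the generator does **not**
emulate: real chain conformational statistics (no torsional ensemble,
no folding), solvent structure (no hydrogen-bond network, no layering
beyond the imposed profile), electrostatics, and any coupling between
solute position and slab structure. Passing tests therefore validate
the *analysis operators* — that WHAM inverts known biased sampling, that
fits invert known density shapes, that directors recover constructed
orientations — not the physics of any particular polymer-water system.

## Problem sizes and runtime envelope

The test suite and analysis scripts run at desk scale by choice:
25-window WHAM recovery uses 5·10⁴ samples per window; interface
round-trips use ensembles of 6–8 boxes of ≈ 8000 beads; orientation
ensembles pool 6 realizations × 3 frames. The whole suite completes in
well under a minute on one core; the compiled Metropolis kernel makes
the sampling cost negligible relative to the WHAM iteration.

## Known limitations

* The fixed-point WHAM iteration converges slowly for badly overlapping
  window layouts; the package reports rather than repairs this (no
  adaptive reweighting, no MBAR).
* One-dimensional reaction coordinates only; no autocorrelation-based
  inefficiency weighting (the synthetic sampler's `thin` makes samples
  near-independent, which real MD data are not).
* The greedy director flip rule is a heuristic; its exactness guarantee
  is empirical and restricted to near-aligned fragment sets.
* The LAMMPS-dump reader handles the common `id/mol/type/x·xs·xu/q/mass`
  column vocabulary, not every dialect.
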