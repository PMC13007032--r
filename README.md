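# slabpmf

Free-energy and orientation analysis for umbrella-sampling studies of a
single solute (e.g. an anionic perfluoroalkyl surfactant) crossing a
polymer slab-water interface. The package implements the full
post-processing chain that such a study needs, and a synthetic-data
generator with known ground truth so that every stage can be validated
end to end without running molecular dynamics.

## What it computes

**PMF by WHAM.** Umbrella windows restrain the reaction coordinate
ξ′ (the z-distance between the slab and solute centers of mass) with
harmonic biases w_i(ξ′) = k/2 (ξ′ − ξ_i′)². The unbiased potential of
mean force is reconstructed from the per-window histograms by the
weighted histogram analysis method, i.e. the self-consistent equations

    P_j = Σ_i n_ij / Σ_i n_i exp[(f_i − w_i(ξ_j)) / k_B T]
    f_i = −k_B T ln Σ_j P_j exp[−w_i(ξ_j) / k_B T]

iterated to a tolerance on max |Δf_i|, with the Boltzmann factor of the
bias averaged analytically over each bin. The PMF is zeroed on the
bulk-solvent plateau, and independent replicas give a per-bin standard
deviation.

**Gibbs dividing surfaces.** Mass-density profiles of the slab and the
solvent along z are fitted with hyperbolic-tangent models,

    ρ_slab(z) = ρ_b/2 · tanh[2(z−h₁)/D₁] − ρ_b/2 · tanh[2(z−h₂)/D₁]
    ρ_w(z)    = ρ_b,w − ρ_b,w/2 · tanh[2(z−h₃)/D₂] + ρ_b,w/2 · tanh[2(z−h₄)/D₂]

and the Gibbs dividing surface at each interface is the root of
ρ_slab(z) = ρ_w(z). The reaction coordinate is then re-referenced to
ξ, the signed distance to the nearest surface (negative toward the slab
interior).

**Orientational order parameter.** The solute director v₁ is the
normalized mean of the 1,3-backbone vectors; the local chain director
v₂ accumulates the 1,3-vectors of slab-chain fragments inside a
cylinder (radius 13 Å, from 18 Å above the slab COM up to the
interface) with a sign-flip convention that prevents cancellation from
chain folding and keeps v₂ within 90° of +z. The order parameter is

    S_v = (3 ⟨cos²θ⟩ − 1) / 2,   θ = ∠(v₁, v₂)

(1 = parallel, −0.5 = perpendicular, 0 = isotropic), binned along ξ
with t-based confidence intervals.

**Backbone RMSD.** Kabsch superposition (SVD with reflection
correction) followed by the root-mean-square deviation over the
backbone subset, against an extended reference conformation.

**Synthetic ground truth.** Biased reaction-coordinate series are drawn
by Metropolis Monte Carlo from analytic free-energy profiles; slab +
solvent bead systems are built with exactly prescribed tanh density
shapes, chain orientation statistics and solute placement/tilt.

## Worked example

The `analysis/` directory is a four-stage narrative workflow; outputs go
to `results/`.

```sh
Rscript analysis/01_simulate_windows.R   # biased window series + overlap check
Rscript analysis/02_wham_pmf.R           # WHAM -> plateau zeroing -> replicas
Rscript analysis/03_interface_gds.R      # density fits + Gibbs surfaces
Rscript analysis/04_orientation_rmsd.R   # S_v(xi) profile + backbone RMSD
```

Stage 2 reconstructs a ground-truth profile with a −26.5 kJ/mol minimum
at ξ = −4.7 Å and prints:

```
recovered PMF minimum: -25.67 +/- 0.35 kJ/mol at xi = -4.65 A
generating truth:      -26.13 kJ/mol at xi = -4.65 A
RMSE vs truth over defined bins (after plateau zeroing): 0.207 kJ/mol
```

(the "truth" line is the generating curve averaged to the same 0.1 Å
bins, which is why it differs slightly from the −26.5 point minimum).
Stage 3 recovers the generating interface parameters and surfaces:

```
slab fit:    rho_b 0.934 g/cm^3 (true 0.93), h = [-20.05, 19.99] (true [-20, 20]), D 3.08 (true 3)
solvent fit: rho_b 1.040 g/cm^3 (true 1.04), h = [-20.98, 20.99] (true [-21, 21]), D 3.07 (true 3)
Gibbs surfaces: z = -20.454 / 20.429 A (constructed truth -20.437 / 20.437)
```

and stage 4 shows that a solute built with a 30° tilt over z-aligned
chains yields binned S_v values straddling the analytic value
(3 cos²30° − 1)/2 = 0.625.

A single-call variant of the same chain is available as
`run_pipeline(config)`, where `config` is a YAML file or named list
(seed, temperature, window layout, slab geometry, cylinder spec); it
writes the same TSV/YAML artifacts plus a seeded, config-hashed run log.

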