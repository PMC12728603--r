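# kbsolv

Solvation thermodynamics of macromolecular solutes in mixed solvents, for
structural and computational biophysicists studying how osmolytes (urea,
TMAO, ...) shift protein folding equilibria. Starting from particle
configurations of a solute in a two-component solvent (water `w` +
cosolvent `c`), `kbsolv` computes:

- **minimum-distance distribution functions** (MDDFs),
  `MDDF(r) = n_s(r) / n_s*(r)` — solvent density as a function of the
  minimum distance between any solvent-molecule atom and any solute atom,
  normalized by a numerically generated ideal reference that accounts for
  the shapes of both solute and solvent, with per-atom / per-residue /
  backbone–side-chain decompositions and differential density maps between
  conformational states;
- **distance-resolved Kirkwood–Buff integrals**,
  `G_ps(R) = (1/rho_s) [N_ps(R) − N*_ps(R)]`, in Å³/molecule and L/mol;
- **preferential interaction parameters**,
  `Gamma_pc ≈ rho_c [G_pc(R) − G_pw(R)]`, with block-averaged errors, and
  the **Wyman linkage shift** `dGamma = Gamma^U − Gamma^N` between states;
- **transfer free energies** by numerical integration of
  `dmu_p/dm_c = −Gamma_pc (R T M_p/M_c)(1/m_c + d ln(gamma_c)/dm_c)`
  from pure water to each cosolvent concentration, and their U−N
  differences (the cosolvent effect on the folding free energy);
- **Shrake–Rupley SASA** on a deterministic spiral lattice, with additive
  transfer-model **m-value estimates** from per-group areas and
  user-supplied coefficient tables;
- **ensemble metrics**: fraction of native contacts Q (20% distance
  tolerance), Kabsch RMSD, representative-structure selection, Boltzmann
  population free energies;
- a **synthetic-configuration generator** with analytically known g(r),
  densities and `Gamma_true`, so every stage of the pipeline can be
  validated against ground truth.

I/O: fixed-column PDB, multi-frame extended XYZ with a `Lattice` key,
delimited result tables (1e-12 round-trip), YAML run configurations, and a
JSON manifest with content hashes for reproducible end-to-end runs
(`run_solvation()`, `run_transfer()`).

## Worked example

Plant a known cosolvent enhancement around a point solute, then recover it
with the full pipeline:

```r
library(kbsolv)

rho_c <- molar_to_density(0.5)            # 0.5 mol/L in molecules/A^3
spec <- generator_spec(
  species = list(
    species_spec("w", molar_to_density(5.55)),
    species_spec("c", rho_c, profile_gaussian_bump(3, 5, 1),
                 molar_mass = 60.06)),
  box = 50, n_frames = 50, seed = 1)
run <- generate_frames(spec)
run$truth
#>   G_w = 0 +/- 0 A^3/molecule
#>   G_c = 2443 +/- 56.1 A^3/molecule
#>   Gamma_true = 0.7356 +/- 0.0169

mddf_w <- accumulate_mddf(run$frames, "w", bin_width = 0.25, cutoff = 12, seed = 1)
mddf_c <- accumulate_mddf(run$frames, "c", bin_width = 0.25, cutoff = 12, seed = 2)
kbi_profile(mddf_c)
#> kbi_profile: species 'c', 50 frames
#>   plateau G = 2298 A^3/molecule (1.384 L/mol) +/- 334 over R in [7.00, 12.00] A

gamma_pc(kbi_profile(mddf_c), kbi_profile(mddf_w))
#> Gamma_pc = 0.7155 +/- 0.131 (molecules), R = 12.00 A, rho_c = 0.491 mol/L
```

The generator planted an excess of `Gamma_true = 0.736` cosolvent
molecules in the solute's domain; the estimator recovers `0.72 ± 0.13`.
The cosolvent KBI plateau (`+2298` Å³/molecule, i.e. `+1.38` L/mol) is the
excess volume the cosolvent occupies around the solute relative to an
ideal distribution. From a Γ series over concentrations, the transfer free
energy and the 2:1-population free-energy difference follow:

```r
gam <- data.frame(m = seq(0.1, 1, 0.1))
gam$gamma <- 0.7155 * gam$m / 0.5          # Gamma roughly linear in m_c
transfer_free_energy(gam, activity_ideal(), 300, M_p = 7000, M_c = 60.06,
                     state = "N")
#> transfer_curve 'N': T = 300 K, printed convention
#>   dmu_tr(1) = -99.426 kcal/mol

boltzmann_dg(2, 1, 300)
#> [1] -0.4132275
```

A favorable Γ (accumulation) gives a negative transfer free energy — the
cosolvent stabilizes that conformation — and states populated 2:1 at 300 K
are separated by roughly −0.4 kcal/mol.

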