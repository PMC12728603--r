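---
title: "Solvation thermodynamics from minimum-distance distributions"
author: "kbsolv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Solvation thermodynamics from minimum-distance distributions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kbsolv)
```

## The model

How a small cosolvent (an osmolyte such as urea or TMAO) shifts a protein's
folding equilibrium can be understood through its solvation thermodynamics.
`kbsolv` implements that chain of analysis for particle configurations of a
solute in a two-component solvent (water `w` + cosolvent `c`), using the
minimum-distance formulation of Kirkwood–Buff solvation theory.

**Minimum-distance distribution functions (MDDFs).** For solutes of complex,
irregular shape, a radial distribution function about a single center is
uninformative. Instead, for every solvent molecule we record the minimum
distance $r$ between any of its atoms and any solute atom, and form

$$\mathrm{MDDF}(r) = \frac{n_s(r)}{n_s^*(r)},$$

the density of solvent molecules at minimum distance $r$ relative to an
*ideal* (non-interacting) reference $n_s^*$. Because the minimum-distance
coordinate depends on the shapes of both solute and solvent, the reference
cannot be written in closed form; it is generated numerically by re-placing
the frame's own molecules at uniform random positions with uniform random
orientations (uniform unit quaternions, position assigned to the molecule's
first atom). Hydrogens participate by default — the short-distance peaks
near 1.75–1.9 Å that identify hydrogen bonding only appear when they do —
with a heavy-atom-only option.

**Kirkwood–Buff integrals (KBIs).** In a finite subvolume bounded by the
minimum distance $R$,

$$G_{ps}(R) = \frac{1}{\rho_s}\left[N_{ps}(R) - N_{ps}^*(R)\right],$$

where $N_{ps}$ and $N_{ps}^*$ are the cumulative real and ideal counts
within $R$ and $\rho_s$ is the solvent's bulk number density. $G_{ps}$ is
the excess volume occupied by species $s$ around the solute; its plateau at
large $R$ is the KBI.

**Preferential interaction parameters.** In the infinitely dilute solute
limit,

$$\Gamma_{pc} \approx \rho_c\left[G_{pc}(R) - G_{pw}(R)\right],$$

the excess number of cosolvent molecules in the solute's domain relative to
bulk composition: $\Gamma_{pc} > 0$ means accumulation (urea-like),
$\Gamma_{pc} < 0$ exclusion / preferential hydration (TMAO-like).

**Wyman linkage.** For two conformational states $U$ and $N$,
$\partial \ln K / \partial \ln a_c = \Gamma^U_{pc} - \Gamma^N_{pc} =
\Delta\Gamma_{pc}$: a positive $\Delta\Gamma$ means raising the cosolvent
concentration favors the denatured state.

**Transfer free energies.** The absolute concentration dependence follows
from integrating the chemical potential from pure water:

$$\Delta\mu_{p,tr}(m_c) = \int_0^{m_c}
  \frac{\partial\mu_p}{\partial m_c}\,dm_c, \qquad
  \frac{\partial\mu_p}{\partial m_c} =
  -\Gamma_{pc}\,\frac{R T M_p}{M_c}
  \left(\frac{1}{m_c} + \frac{\partial\ln\gamma_c}{\partial m_c}\right).$$

`transfer_free_energy()` implements the integrand exactly as printed,
including the $M_p/M_c$ factor; because the dimensional status of that
factor differs between conventions in the literature, a
`convention = "molal"` switch drops it (Lin–Timasheff molal convention).
The difference $\delta\Delta\mu^{U-N}_{p,tr}$ between two states closes the
Tanford transfer cycle: it equals the cosolvent-induced change of the
folding free energy.

Complementing the configurational route, `shrake_rupley()` +
`mvalue_additive()` give the classical additive transfer-model estimate:
per-group solvent-accessible areas times experimental group transfer free
energies, at 1 mol/L by convention. Finally, `fraction_native_contacts()`,
`kabsch_rmsd()`, `representative_structure()` and `boltzmann_dg()` supply
the ensemble bookkeeping used when comparing folding states.

## Numerical choices

**Units.** Coordinates Å, energies kcal/mol, temperatures K. KBIs are
reported both as Å³/molecule and L/mol (factor $6.02214076\times10^{-4}$);
$R = 1.987204\times10^{-3}$ kcal mol⁻¹ K⁻¹. Boxes are orthorhombic only —
triclinic input is rejected explicitly. Indices are 1-based throughout, as
everywhere in R; file serials are carried as labels only.

**Histograms.** Bins are half-open and left-closed, $[iw, (i+1)w)$; a
distance exactly at the cutoff is excluded. Defaults: bin width 0.05 Å
(resolving hydrogen-bond peak positions), cutoff 20 Å. Bins whose ideal
count is zero (inside the solute's excluded volume) have an undefined
ratio; they are reported as 0 and flagged in the `undefined` mask.

**Ideal reference.** Regenerated per frame so box-volume fluctuations are
respected, with `oversample` placements per real molecule (default 10);
the reference is scaled by `1/oversample` so real and ideal histograms
represent the same number of molecules. Doubling the oversample must change
the MDDF by less than the real-count sampling error — this convergence
property is part of the test suite.

**Bulk density.** $\rho_s$ defaults to a bulk estimator: molecules with
minimum distance beyond `d_bulk` (default 10 Å) divided by the
corresponding ideal-reference volume fraction. Plain $N/V$ is biased in
small boxes when the solute perturbs an appreciable volume fraction; the
bulk estimator is not. $N/V$ remains available (`rho = "nv"`), and a known
density can be supplied directly.

**Plateau detection.** The KBI is reported as the mean of $G(R)$ over the
final 5 Å window of the grid (configurable), with a flatness diagnostic
comparing the window's range against its block-averaged standard error.
The window must be large enough to encompass the solution region perturbed
by the solute; inspect `flat_ok` when in doubt.

**Uncertainties.** Block averaging over frames, 5 blocks by default. With
few frames the block estimate of the SE is itself noisy; for sharper error
bars over long frame sets, raise `n_blocks` (the validation runs use 20).

**Transfer integration.** $\Gamma(m)$ is interpolated piecewise-linearly
through the supplied series with the anchor $\Gamma(0)=0$. The anchor is
physically forced — $\Gamma \approx \rho_c[G_{pc}-G_{pw}] \to 0$ as
$\rho_c \to 0$ — and removes the $1/m_c$ singularity of the integrand,
whose $m \to 0$ limit is evaluated from the anchor slope. Integration is
trapezoidal on a refined grid (default 1000 nodes); for $\Gamma$ linear in
$m$ with ideal activity the quadrature is exact to rounding. Activity
tables are differentiated by central differences at interior nodes.

**Tie-breaks.** When two atom pairs realize exactly the same minimum
distance, the lowest (solute atom, solvent atom) index pair wins. This is
deterministic and matches the brute-force oracle used in the tests bit for
bit.

**SASA.** Shrake–Rupley point sampling on a deterministic golden-section
spiral (no random numbers, so areas are reproducible bit-for-bit),
default 960 points per atom, probe 1.4 Å, Bondi-style radii shipped as an
editable data file. An isolated atom's area is exact by construction;
two-sphere occlusion converges to the spherical-cap closed form within 1%
at 4000 points. Which radii and probe an external SASA tool used must be
matched by the caller when comparing; our defaults are recorded in the
result object.

**Native contacts.** $Q$ counts a contact as formed when the Cα–Cα
distance does not exceed the native distance by more than 20%
(`d <= 1.2 * d_native`). We read the criterion as an upper bound only — a
compressed contact still counts as formed. Contact *lists* are inputs
(pair list + native distance); deriving candidate pairs from structure
chemistry is out of scope, though `contact_map_from_native()` fills native
distances for a supplied pair list.

**Representative structures.** All members are superposed on the first
member, averaged coordinate-wise, and the member with minimum Kabsch RMSD
to that average is returned. A single alignment pass is used — no
iterative re-averaging — and ties go to the lowest index.

## What the synthetic generator emulates — and what it does not

`generate_frames()` produces configurations whose solvation structure is
known exactly: per species, molecules are proposed as a Poisson process of
intensity $\rho_s V g_{\max}$, placed uniformly with uniform random
orientations, and accepted with probability $g(r_{\min})/g_{\max}$. Because
rejection targets the *minimum-distance* coordinate — exactly the
coordinate the MDDF estimator measures — generator and estimator form a
closed verification loop: the far-field density is $\rho_s$ by
construction, and the planted profile $g(r)$ is the ground truth the
pipeline must recover. `ground_truth()` integrates $(g-1)$ against the
minimum-distance volume element by Monte-Carlo quadrature and reports the
quadrature error alongside.

Default conditions mimic the study regime at desk scale: cosolvent near
0.5 mol/L, and water at 55.5 mol/L scaled down tenfold so frames stay
small; analyses needing realistic water counts (the hard-sphere
excluded-volume check) raise the density per run. Validation problem
sizes: 200 frames in 40 Å boxes for the normalization and excluded-volume
checks, and 20 replicas of 25 frames in 50 Å boxes for the
preferential-interaction recovery — sizes at which the recovery bands
(3 standard errors) are a few tenths of a molecule.

What the generator deliberately does *not* emulate: real water structure
(no hydrogen-bond network, no orientational correlations), solvent–solvent
correlations of any kind, force-field energetics, or conformational
dynamics of the solute. Passing the recovery tests therefore certifies the
*estimators* — histogramming, ideal-reference normalization, KBI and
$\Gamma$ algebra, error propagation — not the physics of any particular
solvent model. Estimates on real trajectories inherit whatever sampling
limitations those trajectories have.

A known finite-box property worth keeping in mind: the ideal reference
represents the frame's own molecule count spread over the whole box, so the
finite-subvolume $G(R)$ underestimates the infinite-dilution KBI by a
factor $\approx (1 - V_{md}(R)/V)$. With the validation box sizes this is a
few percent and well inside the quoted errors, but for small boxes or very
large solutes it matters; the bulk-density estimator mitigates the density
part of the effect, not the reference-count part.

## Design choices where the design was open

- **Species in input files.** Nothing in common trajectory formats marks
  which atoms belong to which solvent species. Our extended-XYZ convention
  carries `Solute=n` and `Species="label:n_molecules:atoms_per_molecule[:molar_mass]"`
  in the comment line; a sidecar species partition can be supplied instead.
  Molecules are fixed contiguous atom blocks — no connectivity inference.
- **Ideal-reference oversampling.** No canonical value exists; we default
  to 10 placements per molecule and expose it, and the tests verify that
  doubling it is statistically neutral.
- **Activity data.** Only the ideal model ($\gamma_c \equiv 1$) ships;
  measured activity tables are data the user supplies as two-column text.
- **Transfer-model coefficients.** These are experimental data with several
  published scales (urea and TMAO variants differ in their coefficients);
  the package ships a template plus a clearly synthetic test table, never
  asserted published values.
- **Backbone atom names.** The backbone/side-chain split defaults to
  {N, CA, C, O, H, HA, HA2, HA3, HN, OXT} (glycine HA2/HA3 backbone) and is
  overridable.
- **Orchestration.** The pipeline is file-mediated: `run_solvation()` and
  `run_transfer()` read a plain YAML/list configuration, write delimited
  tables (readable to 1e-12 round-trip) and a JSON manifest with content
  hashes and the seed, so any run can be reproduced and checked
  byte-for-byte.

## Limitations

- Orthorhombic minimum image only; no triclinic cells.
- The finite-subvolume KBI carries the $O(V_{md}/V)$ box-size effect noted
  above; no closed-system finite-size corrections beyond the bulk-density
  estimator are applied.
- $\gamma_c$ is never computed from simulation; transfer free energies are
  only as good as the supplied activity model.
- SASA derivatives and power-diagram (analytic) areas are out of scope, as
  are hydrogen-bond geometric criteria, secondary-structure assignment and
  landscape clustering.
- `read_pdb()` implements the fixed-column dialect with strict coordinate
  fields and rejects insertion codes rather than guessing.

## A minimal worked loop

```{r example, eval = FALSE}
## plant a cosolvent enhancement, then recover it
rho_c <- molar_to_density(0.5)
spec <- generator_spec(
  species = list(
    species_spec("w", molar_to_density(5.55)),
    species_spec("c", rho_c, profile_gaussian_bump(3, 5, 1),
                 molar_mass = 60.06)),
  box = 50, n_frames = 50, seed = 1)
run <- generate_frames(spec)
run$truth                      # analytic G_w, G_c, Gamma_true

mddf_w <- accumulate_mddf(run$frames, "w", bin_width = 0.25, cutoff = 12)
mddf_c <- accumulate_mddf(run$frames, "c", bin_width = 0.25, cutoff = 12)
gamma_pc(kbi_profile(mddf_c), kbi_profile(mddf_w))
```
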