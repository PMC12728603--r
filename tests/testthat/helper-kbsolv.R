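## Shared fixtures and independent oracles, all built in code.

## Brute-force double-loop minimum-distance oracle (independent of the
## package's vectorized engine; first-strictly-smaller wins, scanning solvent
## atoms within a molecule and solute atoms in index order, which realizes
## the lowest-(solute, solvent)-index tie-break for exact ties).
brute_min_events <- function(S, A, apm, box) {
  nm <- nrow(A) / apm
  out <- data.frame(molecule = integer(nm), r = numeric(nm),
                    solute_atom = integer(nm), solvent_atom = integer(nm))
  for (m in seq_len(nm)) {
    best <- Inf; bi <- NA_integer_; bj <- NA_integer_
    for (i in seq_len(nrow(S))) {
      for (k in seq_len(apm)) {
        j <- (m - 1L) * apm + k
        dx <- S[i, 1] - A[j, 1]; dx <- dx - box[1] * round(dx / box[1])
        dy <- S[i, 2] - A[j, 2]; dy <- dy - box[2] * round(dy / box[2])
        dz <- S[i, 3] - A[j, 3]; dz <- dz - box[3] * round(dz / box[3])
        d2 <- dx * dx + dy * dy + dz * dz
        if (d2 < best) { best <- d2; bi <- i; bj <- j }
      }
    }
    out$molecule[m] <- m; out$r[m] <- sqrt(best)
    out$solute_atom[m] <- bi; out$solvent_atom[m] <- bj
  }
  out
}

random_frame <- function(n_solute, n_mol, apm, box, seed) {
  set.seed(seed)
  S <- cbind(runif(n_solute, 0, box[1]), runif(n_solute, 0, box[2]),
             runif(n_solute, 0, box[3]))
  A <- cbind(runif(n_mol * apm, 0, box[1]), runif(n_mol * apm, 0, box[2]),
             runif(n_mol * apm, 0, box[3]))
  list(S = S, A = A,
       frame = suppressWarnings(configuration(
         S, list(solvent_species("c", A, apm)), box)))
}

## toy two-residue peptide with explicit names/elements (geometry is
## schematic; used for SASA partitioning and m-value fixtures)
toy_dipeptide <- function() {
  atom_records(
    serial = 1:10,
    name = c("N", "CA", "C", "O", "CB",   "N", "CA", "C", "O", "CB"),
    resname = c(rep("ALA", 5), rep("SER", 5)),
    resid = c(rep(1L, 5), rep(2L, 5)),
    chain = "A",
    x = c(0.0, 1.5, 2.2, 2.0, 1.9, 3.5, 5.0, 5.7, 5.5, 5.4),
    y = c(0.0, 0.2, 1.4, 2.5, -1.0, 1.3, 1.5, 2.7, 3.8, 0.2),
    z = c(0.0, 0.1, 0.0, 0.2, 0.5, 0.1, 0.0, 0.3, 0.1, -0.9),
    element = c("N", "C", "C", "O", "C", "N", "C", "C", "O", "C")
  )
}

## uniform-solvent generator spec around a point solute (ideal gas)
ideal_gas_spec <- function(n_frames, seed, box = 40,
                           rho_w = molar_to_density(5.55),
                           rho_c = molar_to_density(0.5)) {
  generator_spec(
    species = list(species_spec("w", rho_w),
                   species_spec("c", rho_c, molar_mass = 60.06)),
    box = box, n_frames = n_frames, seed = seed)
}

## spherical-cap closed form: accessible area of sphere 1 (expanded radius
## R1) occluded by sphere 2 (expanded radius R2) at center distance d
two_sphere_cap_area <- function(R1, R2, d) {
  x1 <- (d^2 + R1^2 - R2^2) / (2 * d)
  4 * pi * R1^2 - 2 * pi * R1 * (R1 - x1)
}
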