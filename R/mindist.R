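## Minimum-distance engine: for every solvent molecule, the minimum distance
## between any of its atoms and any solute atom, under the orthorhombic
## minimum-image convention.

## squared minimum-image distance matrix between rows of a (n x 3) and b (m x 3)
.pbc_d2 <- function(a, b, box) {
  dx <- outer(a[, 1], b[, 1], "-"); dx <- dx - box[1] * round(dx / box[1])
  dy <- outer(a[, 2], b[, 2], "-"); dy <- dy - box[2] * round(dy / box[2])
  dz <- outer(a[, 3], b[, 3], "-"); dz <- dz - box[3] * round(dz / box[3])
  dx * dx + dy * dy + dz * dz
}

## core: events for solvent atom matrix `solv` grouped by `mol` (sorted),
## against solute matrix `solute`. Tie-break: lowest (solute_atom, solvent_atom).
.min_events <- function(solute, solv, mol, box) {
  d2 <- .pbc_d2(solute, solv, box)
  if (nrow(solute) == 1L) {
    pam <- d2[1L, ]
    arg <- rep.int(1L, ncol(d2))
  } else {
    pam <- do.call(pmin, lapply(seq_len(nrow(d2)), function(i) d2[i, ]))
    arg <- max.col(-t(d2), ties.method = "first")
  }
  atom <- seq_along(pam)
  o <- order(mol, pam, arg, atom)
  first <- o[!duplicated(mol[o])]
  data.frame(molecule = mol[first], r = sqrt(pam[first]),
             solute_atom = arg[first], solvent_atom = atom[first])
}

.get_species <- function(frame, species) {
  sp <- frame$solvent[[species]]
  if (is.null(sp)) stop(sprintf("species '%s' not present in frame", species))
  sp
}

.heavy_mask <- function(elements, n) {
  if (is.null(elements)) rep(TRUE, n) else toupper(elements) != "H"
}

#' Minimum solute-solvent distances for one frame
#'
#' For each solvent molecule of the requested species, finds the minimum
#' distance between any of its atoms and any solute atom under the
#' minimum-image convention, together with the atom pair realizing it.
#' Ties are broken by the lowest (solute atom, solvent atom) index pair.
#'
#' @param frame a \code{\link{configuration}}.
#' @param species species label, e.g. \code{"w"} or \code{"c"}.
#' @param heavy_only if TRUE, hydrogens are excluded on both sides (requires
#'   element information; by default all atoms participate).
#' @return data.frame with one row per molecule: \code{molecule}, \code{r}
#'   (Angstrom), \code{solute_atom}, \code{solvent_atom} (1-based indices
#'   into the frame's solute and the species' atom list).
#' @export
min_distances <- function(frame, species, heavy_only = FALSE) {
  sp <- .get_species(frame, species)
  if (sp$n_molecules == 0L) stop(sprintf("empty species '%s'", species))
  ext <- apply(frame$solute, 2, function(v) diff(range(v)))
  if (any(ext > frame$box / 2))
    warning("solute extent exceeds half the box in at least one dimension; minimum image may be ambiguous")
  solute <- frame$solute
  s_idx <- seq_len(nrow(solute))
  if (heavy_only && !is.null(frame$solute_atoms)) {
    keep <- .heavy_mask(frame$solute_atoms$element, nrow(solute))
    solute <- solute[keep, , drop = FALSE]; s_idx <- s_idx[keep]
  }
  apm <- sp$atoms_per_molecule
  mol <- rep(seq_len(sp$n_molecules), each = apm)
  solv <- sp$coords
  a_idx <- seq_len(nrow(solv))
  if (heavy_only && !is.null(sp$elements)) {
    keep <- .heavy_mask(rep_len(sp$elements, nrow(solv)), nrow(solv))
    solv <- solv[keep, , drop = FALSE]; mol <- mol[keep]; a_idx <- a_idx[keep]
  }
  ev <- .min_events(solute, solv, mol, frame$box)
  ev$solute_atom <- s_idx[ev$solute_atom]
  ev$solvent_atom <- a_idx[ev$solvent_atom]
  ev
}

## uniform random rotation matrices are applied via unit quaternions:
## rotate rows of v (n x 3) by quaternions q (n x 4, normalized, w x y z)
.quat_rotate <- function(v, q) {
  w <- q[, 1]; u <- q[, 2:4, drop = FALSE]
  ## t = 2 u x v ; v' = v + w t + u x t
  t1 <- 2 * (u[, 2] * v[, 3] - u[, 3] * v[, 2])
  t2 <- 2 * (u[, 3] * v[, 1] - u[, 1] * v[, 3])
  t3 <- 2 * (u[, 1] * v[, 2] - u[, 2] * v[, 1])
  cbind(v[, 1] + w * t1 + u[, 2] * t3 - u[, 3] * t2,
        v[, 2] + w * t2 + u[, 3] * t1 - u[, 1] * t3,
        v[, 3] + w * t3 + u[, 1] * t2 - u[, 2] * t1)
}

#' Ideal-reference minimum distances
#'
#' Generates the numerically sampled ideal (non-interacting) reference for
#' the minimum-distance distribution: molecule conformations are drawn with
#' replacement from the frame's real molecules of the species, given a
#' uniform random rotation (uniform unit quaternion) and a uniform random
#' position of their first atom in the box, and the minimum distance of each
#' placement to the solute is recorded. The reference thereby accounts for
#' the shapes of both solute and solvent.
#'
#' @param frame a \code{\link{configuration}}.
#' @param species species label.
#' @param oversample number of placements per real molecule (>= 1).
#' @param seed integer seed; the same seed reproduces the event list exactly.
#' @return data.frame as in \code{\link{min_distances}}, with
#'   \code{oversample * n_molecules} rows; \code{solvent_atom} indexes atoms
#'   within the placed molecules.
#' @export
ideal_min_distances <- function(frame, species, oversample = 10L, seed = 1L) {
  sp <- .get_species(frame, species)
  if (sp$n_molecules == 0L) stop(sprintf("empty species '%s'", species))
  oversample <- as.integer(oversample)
  if (oversample < 1L) stop("oversample must be >= 1")
  n_mol <- sp$n_molecules; apm <- sp$atoms_per_molecule
  m <- oversample * n_mol
  box <- frame$box
  with_seed(seed, {
    pick <- sample.int(n_mol, m, replace = TRUE)
    pos <- cbind(stats::runif(m, 0, box[1]), stats::runif(m, 0, box[2]),
                 stats::runif(m, 0, box[3]))
    if (apm > 1L) {
      q <- matrix(stats::rnorm(4L * m), m, 4L)
      q <- q / sqrt(rowSums(q * q))
      first <- (pick - 1L) * apm + 1L
      coords <- matrix(0, m * apm, 3L)
      coords[seq.int(1L, by = apm, length.out = m), ] <- pos
      for (k in 2:apm) {
        rel <- sp$coords[first + (k - 1L), , drop = FALSE] -
          sp$coords[first, , drop = FALSE]
        rel <- rel - rep(box, each = m) * round(rel / rep(box, each = m))
        coords[seq.int(k, by = apm, length.out = m), ] <- pos + .quat_rotate(rel, q)
      }
    } else {
      coords <- pos
    }
  })
  mol <- rep(seq_len(m), each = apm)
  .min_events(frame$solute, coords, mol, box)
}
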