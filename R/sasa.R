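## Shrake-Rupley solvent-accessible surface areas and additive
## transfer-model m-value estimates.

#' Deterministic golden-section spiral point set on the unit sphere
#'
#' @param n number of points.
#' @return n x 3 matrix of unit vectors.
#' @keywords internal
golden_spiral <- function(n) {
  k <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * k / n)
  theta <- pi * (1 + sqrt(5)) * k
  cbind(cos(theta) * sin(phi), sin(theta) * sin(phi), cos(phi))
}

#' Load the default van der Waals radii table
#'
#' Bondi-style radii shipped as a data file
#' (\code{inst/extdata/vdw_radii.csv}); users may supply their own table.
#'
#' @return named numeric vector of radii (Angstrom) keyed by element symbol.
#' @export
default_vdw_radii <- function() {
  path <- system.file("extdata", "vdw_radii.csv", package = "kbsolv")
  df <- read_result_table(path)
  stats::setNames(df$radius, df$element)
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Places a deterministic golden-spiral lattice of \code{n_points} points on
#' the solvent-expanded sphere of every atom (radius \code{r_i + probe});
#' a point is accessible when it lies outside every neighboring atom's
#' expanded sphere. The per-atom area is
#' \code{4*pi*(r_i+probe)^2 * accessible/n_points}. With no random number
#' use, results are reproducible bit-for-bit.
#'
#' @param atoms an \code{atom_records} table.
#' @param probe probe radius, Angstrom (water: 1.4).
#' @param n_points points per atom (default 960).
#' @param radii named numeric vector of van der Waals radii by element;
#'   defaults to the shipped Bondi-style table.
#' @return object of class \code{sasa_result}: the atom table with an
#'   \code{area} column (A^2), \code{total} (A^2), \code{total_nm2},
#'   and the parameters used.
#' @export
shrake_rupley <- function(atoms, probe = 1.4, n_points = 960L, radii = NULL) {
  if (is.null(radii)) radii <- default_vdw_radii()
  if (n_points < 1L) stop("n_points must be >= 1")
  el <- atoms$element
  unknown <- !(el %in% names(radii))
  if (any(unknown))
    stop(sprintf("radii lookup error: no radius for element '%s' (atom %d, name '%s')",
                 el[which(unknown)[1]], which(unknown)[1],
                 atoms$name[which(unknown)[1]]))
  r <- unname(radii[el])
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  n <- nrow(xyz)
  pts <- golden_spiral(as.integer(n_points))
  area <- numeric(n)
  for (i in seq_len(n)) {
    ri <- r[i] + probe
    d2 <- colSums((t(xyz) - xyz[i, ])^2)
    nb <- which(d2 < (r[i] + r + 2 * probe)^2 & seq_len(n) != i)
    p <- pts * ri
    p <- sweep(p, 2, xyz[i, ], "+")
    acc <- rep(TRUE, nrow(p))
    for (j in nb) {
      rj <- r[j] + probe
      dj2 <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
        (p[, 3] - xyz[j, 3])^2
      acc <- acc & dj2 > rj * rj
      if (!any(acc)) break
    }
    area[i] <- 4 * pi * ri * ri * sum(acc) / n_points
  }
  out <- as.data.frame(atoms)
  out$radius <- r
  out$area <- area
  structure(list(atoms = out, total = sum(area), total_nm2 = sum(area) / 100,
                 probe = probe, n_points = as.integer(n_points),
                 radii_id = attr(radii, "id") %||% "bondi-default"),
            class = "sasa_result")
}

#' @export
print.sasa_result <- function(x, ...) {
  cat(sprintf("sasa_result: %d atoms, total %.2f A^2 (%.3f nm^2); probe %.2f A, %d points/atom\n",
              nrow(x$atoms), x$total, x$total_nm2, x$probe, x$n_points))
  invisible(x)
}

#' @export
as.data.frame.sasa_result <- function(x, ...) {
  df <- x$atoms
  attr(df, "units") <- c(area = "A^2")
  df
}

#' Partition SASA into per-residue backbone and side-chain areas
#'
#' Every atom is assigned to exactly one class by membership of its name in
#' the backbone set (glycine HA2/HA3 are backbone by default); all other
#' names are side chain.
#'
#' @param result a \code{sasa_result}.
#' @param backbone_atom_names atom names counted as backbone.
#' @return data.frame with one row per residue: \code{resid},
#'   \code{resname}, \code{backbone}, \code{sidechain}, \code{total} (A^2).
#' @export
partition_sasa <- function(result, backbone_atom_names = BACKBONE_ATOM_NAMES) {
  at <- result$atoms
  bb <- at$name %in% backbone_atom_names
  key <- paste(at$chain, at$resid)
  res <- unique(data.frame(key = key, resid = at$resid, resname = at$resname,
                           stringsAsFactors = FALSE))
  agg <- function(mask) {
    v <- tapply(at$area[mask], key[mask], sum)
    out <- stats::setNames(rep(0, nrow(res)), res$key)
    out[names(v)] <- v
    unname(out)
  }
  data.frame(resid = res$resid, resname = res$resname,
             backbone = agg(bb), sidechain = agg(!bb),
             total = agg(bb) + agg(!bb))
}

#' Read a transfer-model coefficient table
#'
#' Coefficient tables are data, not package constants: delimited text with
#' columns \code{group} (\code{"backbone"} or a residue type), \code{dg}
#' (group transfer free energy at 1 mol/L, cal/mol per reference unit) and
#' \code{a_ref} (reference area, A^2). '#' header lines may carry a
#' provenance string.
#'
#' @param path path to the table.
#' @return data.frame of class \code{coefficient_table}.
#' @export
read_coefficient_table <- function(path) {
  df <- read_result_table(path)
  coefficient_table(df$group, df$dg, df$a_ref,
                    provenance = paste(attr(df, "header"), collapse = "; "))
}

#' Construct a coefficient table
#'
#' @param group group labels (\code{"backbone"} plus residue types).
#' @param dg transfer free energies at 1 mol/L, cal/mol per reference unit.
#' @param a_ref reference areas, A^2 (> 0).
#' @param provenance free-text provenance string.
#' @return data.frame of class \code{coefficient_table}.
#' @export
coefficient_table <- function(group, dg, a_ref, provenance = "") {
  if (any(a_ref <= 0)) stop("reference areas must be > 0")
  df <- data.frame(group = as.character(group), dg = as.numeric(dg),
                   a_ref = as.numeric(a_ref), stringsAsFactors = FALSE)
  attr(df, "provenance") <- provenance
  class(df) <- c("coefficient_table", "data.frame")
  df
}

#' Additive transfer-model m-value estimate from SASAs
#'
#' For each state, \code{dmu_tr = sum_k (A_k / A_ref_k) * dg_k} over the
#' backbone group and the per-residue-type side-chain groups, converted
#' cal -> kcal; the m-value is \code{dmu^U - dmu^N}, by convention at
#' 1 mol/L cosolvent.
#'
#' @param sasa_N,sasa_U \code{sasa_result} objects for the native and
#'   denatured conformations (same residue composition).
#' @param coeffs a \code{\link{coefficient_table}} covering the backbone and
#'   every residue type present.
#' @param backbone_atom_names atom names counted as backbone.
#' @return object of class \code{mvalue_estimate}: \code{dmu_N},
#'   \code{dmu_U}, \code{mvalue} (kcal/mol/M), and the backbone/side-chain
#'   contributions (their sum equals the total exactly).
#' @export
mvalue_additive <- function(sasa_N, sasa_U, coeffs,
                            backbone_atom_names = BACKBONE_ATOM_NAMES) {
  pn <- partition_sasa(sasa_N, backbone_atom_names)
  pu <- partition_sasa(sasa_U, backbone_atom_names)
  if (nrow(pn) != nrow(pu) || !identical(sort(pn$resname), sort(pu$resname)))
    stop(sprintf("composition mismatch between states: N has {%s}, U has {%s}",
                 paste(sort(unique(pn$resname)), collapse = ","),
                 paste(sort(unique(pu$resname)), collapse = ",")))
  types <- unique(pn$resname)
  missing <- setdiff(c("backbone", types), coeffs$group)
  if (length(missing) > 0)
    stop(sprintf("coefficient table does not cover: %s",
                 paste(missing, collapse = ", ")))
  row <- function(g) coeffs[match(g, coeffs$group), ]
  state_dmu <- function(p) {
    bbr <- row("backbone")
    bb <- sum(p$backbone) / bbr$a_ref * bbr$dg / 1000
    sc <- 0
    for (ty in types) {
      r <- row(ty)
      sc <- sc + sum(p$sidechain[p$resname == ty]) / r$a_ref * r$dg / 1000
    }
    c(backbone = bb, sidechain = sc, total = bb + sc)
  }
  dn <- state_dmu(pn); du <- state_dmu(pu)
  d_bb <- du[["backbone"]] - dn[["backbone"]]
  d_sc <- du[["sidechain"]] - dn[["sidechain"]]
  structure(list(dmu_N = dn[["total"]], dmu_U = du[["total"]],
                 mvalue = d_bb + d_sc,   # additive by construction
                 backbone = d_bb, sidechain = d_sc,
                 per_state = rbind(N = dn, U = du)),
            class = "mvalue_estimate")
}

#' @export
print.mvalue_estimate <- function(x, ...) {
  cat(sprintf("m-value = %.4g kcal/mol/M (backbone %.4g + side chain %.4g)\n",
              x$mvalue, x$backbone, x$sidechain))
  cat(sprintf("  dmu_tr at 1 mol/L: N = %.4g, U = %.4g kcal/mol\n",
              x$dmu_N, x$dmu_U))
  invisible(x)
}
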