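## Minimum-distance distribution functions: accumulate real and ideal
## minimum-distance histograms over frames and normalize real/ideal.

#' Accumulate a minimum-distance distribution function over frames
#'
#' For each frame the real minimum-distance histogram is computed with
#' \code{\link{min_distances}} and the ideal (non-interacting) reference with
#' \code{\link{ideal_min_distances}}, scaled by \code{1/oversample} so both
#' represent the same number of molecules. The MDDF is the per-bin ratio of
#' the frame-averaged real to ideal counts. Bins are half-open,
#' left-closed \code{[i*w, (i+1)*w)}; a distance exactly at the cutoff is
#' excluded. The ideal reference is regenerated per frame so box-volume
#' fluctuations are respected.
#'
#' The bulk number density is estimated from molecules with minimum distance
#' beyond \code{d_bulk}, divided by the corresponding ideal-reference volume
#' fraction; when that region is empty the total N/V density is used.
#'
#' @param frames list of \code{\link{configuration}} objects.
#' @param species species label.
#' @param bin_width histogram bin width, Angstrom.
#' @param cutoff largest distance histogrammed, Angstrom. Should not exceed
#'   half the smallest box length (warning otherwise).
#' @param oversample ideal-reference placements per real molecule.
#' @param seed integer seed for the ideal reference (per-frame streams are
#'   derived from it).
#' @param d_bulk distance beyond which molecules are considered bulk,
#'   Angstrom.
#' @param heavy_only passed to the distance engine.
#' @return an object of class \code{mddf_result}; see Details for fields.
#'
#' @details Fields include \code{r} (bin midpoints), \code{real}/\code{ideal}
#' (mean counts per frame per bin), \code{mddf}, \code{undefined} (mask of
#' bins with zero ideal count, reported as 0), cumulative counts
#' \code{cum_real}/\code{cum_ideal} on the bin-edge grid \code{R},
#' per-solute-atom count attribution \code{contributions}, per-frame count
#' matrices, and the bulk density estimates \code{rho_bulk} / \code{rho_nv}
#' (molecules/A^3).
#' @export
accumulate_mddf <- function(frames, species, bin_width = 0.05, cutoff = 20,
                            oversample = 10L, seed = 1L, d_bulk = 10,
                            heavy_only = FALSE) {
  if (inherits(frames, "configuration")) frames <- list(frames)
  nf <- length(frames)
  if (nf == 0L) stop("empty input: no frames")
  min_box <- min(vapply(frames, function(f) min(f$box), numeric(1)))
  if (cutoff > min_box / 2)
    warning("cutoff exceeds half the smallest box length; long-range bins are unreliable")
  nb <- as.integer(round(cutoff / bin_width))
  n_solute <- nrow(frames[[1]]$solute)
  per_real <- matrix(0, nf, nb)
  per_ideal <- matrix(0, nf, nb)
  contrib <- matrix(0, n_solute, nb)
  n_bulk <- numeric(nf); f_bulk <- numeric(nf)
  n_mol <- numeric(nf); vol <- numeric(nf)
  molar_mass <- frames[[1]]$solvent[[species]]$molar_mass
  for (f in seq_len(nf)) {
    fr <- frames[[f]]
    ev <- min_distances(fr, species, heavy_only = heavy_only)
    bin <- floor(ev$r / bin_width) + 1
    keep <- bin >= 1 & bin <= nb
    per_real[f, ] <- tabulate(bin[keep], nb)
    idx <- (bin[keep] - 1L) * n_solute + ev$solute_atom[keep]
    contrib <- contrib + matrix(tabulate(idx, n_solute * nb), n_solute, nb)
    iv <- ideal_min_distances(fr, species, oversample = oversample,
                              seed = (as.numeric(seed) + 97 * f) %% .Machine$integer.max)
    ibin <- floor(iv$r / bin_width) + 1
    ikeep <- ibin >= 1 & ibin <= nb
    per_ideal[f, ] <- tabulate(ibin[ikeep], nb) / oversample
    n_bulk[f] <- sum(ev$r > d_bulk)
    f_bulk[f] <- mean(iv$r > d_bulk)
    n_mol[f] <- nrow(ev)
    vol[f] <- prod(fr$box)
  }
  real <- colMeans(per_real)
  ideal <- colMeans(per_ideal)
  undefined <- ideal == 0
  mddf <- ifelse(undefined, 0, real / ifelse(undefined, 1, ideal))
  rho_nv <- mean(n_mol) / mean(vol)
  denom <- mean(f_bulk * vol)
  rho_bulk <- if (denom > 0 && mean(n_bulk) > 0) mean(n_bulk) / denom else rho_nv
  structure(list(
    species = species, bin_width = bin_width, cutoff = cutoff,
    edges = seq(0, nb * bin_width, by = bin_width),
    r = (seq_len(nb) - 0.5) * bin_width,
    R = seq_len(nb) * bin_width,
    real = real, ideal = ideal, mddf = mddf, undefined = undefined,
    cum_real = cumsum(real), cum_ideal = cumsum(ideal),
    per_frame_real = per_real, per_frame_ideal = per_ideal,
    contributions = contrib / nf,
    n_frames = nf, n_molecules = mean(n_mol), volume = mean(vol),
    rho_bulk = rho_bulk, rho_nv = rho_nv, d_bulk = d_bulk,
    oversample = oversample, seed = seed, molar_mass = molar_mass
  ), class = "mddf_result")
}

#' @export
print.mddf_result <- function(x, ...) {
  cat(sprintf("mddf_result: species '%s', %d frames, %d bins of %.3g A (cutoff %.3g A)\n",
              x$species, x$n_frames, length(x$r), x$bin_width, x$cutoff))
  cat(sprintf("  mean molecules/frame %.1f; bulk density %.4g molecules/A^3 (%.3g mol/L)\n",
              x$n_molecules, x$rho_bulk, density_to_molar(x$rho_bulk)))
  invisible(x)
}

#' @export
as.data.frame.mddf_result <- function(x, ...) {
  df <- data.frame(r = x$r, mddf = x$mddf, real = x$real, ideal = x$ideal,
                   R = x$R, cum_real = x$cum_real, cum_ideal = x$cum_ideal,
                   undefined = as.integer(x$undefined))
  attr(df, "units") <- c(r = "A", mddf = "dimensionless", real = "counts/frame",
                         ideal = "counts/frame", R = "A",
                         cum_real = "counts/frame", cum_ideal = "counts/frame",
                         undefined = "flag")
  df
}

#' Per-frame standard error of the MDDF, per bin
#'
#' Empirical frame-to-frame standard error of the mean real count divided by
#' the mean ideal count.
#'
#' @param x an \code{mddf_result}.
#' @return numeric vector, one SE per bin (NA where the ideal count is zero).
#' @export
mddf_se <- function(x) {
  se_counts <- apply(x$per_frame_real, 2, stats::sd) / sqrt(x$n_frames)
  ifelse(x$undefined, NA_real_, se_counts / ifelse(x$undefined, 1, x$ideal))
}

#' Decompose an MDDF into solute-group contributions
#'
#' Each minimum-distance event is attributed to the group of the solute atom
#' that realizes it. Group contributions are reported on the same
#' normalization as the total MDDF (raw counts divided by the total ideal
#' counts), so they sum to the total bin-by-bin.
#'
#' @param result an \code{mddf_result}.
#' @param partition character (or factor) vector of group labels, one per
#'   solute atom, in solute atom order.
#' @return an object of class \code{mddf_decomposition} with matrices
#'   \code{counts} and \code{normalized} (groups x bins).
#' @export
decompose_mddf <- function(result, partition) {
  n_solute <- nrow(result$contributions)
  partition <- as.character(partition)
  if (length(partition) != n_solute || anyNA(partition))
    stop(sprintf("partition error: partition must map all %d solute atoms to groups",
                 n_solute))
  groups <- unique(partition)
  counts <- do.call(rbind, lapply(groups, function(g)
    colSums(result$contributions[partition == g, , drop = FALSE])))
  rownames(counts) <- groups
  norm <- sweep(counts, 2, ifelse(result$undefined, 1, result$ideal), "/")
  norm[, result$undefined] <- 0
  structure(list(groups = groups, counts = counts, normalized = norm,
                 r = result$r, bin_width = result$bin_width,
                 species = result$species, total_real = result$real,
                 total_mddf = result$mddf),
            class = "mddf_decomposition")
}

#' @export
print.mddf_decomposition <- function(x, ...) {
  cat(sprintf("mddf_decomposition: %d groups x %d bins (species '%s')\n",
              length(x$groups), length(x$r), x$species))
  invisible(x)
}

#' @export
as.data.frame.mddf_decomposition <- function(x, ...) {
  df <- data.frame(r = x$r, t(x$normalized), check.names = FALSE)
  attr(df, "units") <- c(r = "A", rep("dimensionless", length(x$groups)))
  df
}

#' Group solute atoms by residue
#'
#' @param atoms an \code{atom_records} table.
#' @return character vector of labels \code{"<resname><resid>"}, one per atom.
#' @export
partition_by_residue <- function(atoms) {
  sprintf("%s%d", atoms$resname, atoms$resid)
}

#' Split solute atoms into backbone and side chain
#'
#' @param atoms an \code{atom_records} table.
#' @param backbone_atom_names atom names counted as backbone (glycine
#'   HA2/HA3 are backbone by default).
#' @return character vector with values \code{"backbone"} or
#'   \code{"sidechain"}, one per atom.
#' @export
partition_backbone <- function(atoms, backbone_atom_names = BACKBONE_ATOM_NAMES) {
  ifelse(atoms$name %in% backbone_atom_names, "backbone", "sidechain")
}

#' Differential solvent-density map between two states
#'
#' Signed per-group, per-bin difference of normalized MDDF contributions
#' between two conformational states (A minus B), with a per-group summary
#' obtained by integrating over a caller-chosen distance window.
#'
#' @param a,b \code{mddf_decomposition} objects for states A and B, on the
#'   same bin grid and species, with the same group set.
#' @param window length-2 numeric distance window (Angstrom) for the
#'   per-group summary integral; defaults to the whole grid.
#' @return object of class \code{density_map} with matrix \code{delta}
#'   (groups x bins) and vector \code{summary} (the window integral, A).
#' @export
differential_density_map <- function(a, b, window = NULL) {
  if (length(a$r) != length(b$r) || any(abs(a$r - b$r) > 1e-12) ||
      a$species != b$species)
    stop("incompatibility error: decompositions have different bin grids or species")
  if (!identical(sort(a$groups), sort(b$groups)))
    stop("incompatibility error: group sets differ between states")
  bb <- b$normalized[a$groups, , drop = FALSE]
  delta <- a$normalized - bb
  if (is.null(window)) window <- range(a$r)
  sel <- a$r >= window[1] & a$r <= window[2]
  summary <- rowSums(delta[, sel, drop = FALSE]) * a$bin_width
  structure(list(groups = a$groups, delta = delta, summary = summary,
                 r = a$r, window = window, species = a$species),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  cat(sprintf("density_map: %d groups x %d bins, summary window [%.2f, %.2f] A\n",
              length(x$groups), length(x$r), x$window[1], x$window[2]))
  top <- order(abs(x$summary), decreasing = TRUE)[seq_len(min(3, length(x$summary)))]
  cat("  largest |summary|:", paste(sprintf("%s (%.4g)", x$groups[top],
                                            x$summary[top]), collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.density_map <- function(x, ...) {
  df <- data.frame(r = x$r, t(x$delta), check.names = FALSE)
  attr(df, "units") <- c(r = "A", rep("dimensionless", length(x$groups)))
  df
}
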