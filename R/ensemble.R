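## Conformational-ensemble metrics: fraction of native contacts, Kabsch
## superposition RMSD, representative-structure selection and Boltzmann
## population free energies.

#' Construct a native contact map
#'
#' Contact maps are inputs to this package (pair lists with native Ca-Ca
#' distances); this constructor validates them. Use
#' \code{\link{contact_map_from_native}} to fill distances from a native
#' structure.
#'
#' @param i,j 1-based residue indices, \code{i < j}.
#' @param d_native native Ca-Ca distances, Angstrom.
#' @param min_seq_sep minimum sequence separation \code{|i - j|} (default 3).
#' @return data.frame of class \code{contact_map}.
#' @export
contact_map <- function(i, j, d_native, min_seq_sep = 3L) {
  i <- as.integer(i); j <- as.integer(j)
  swap <- i > j
  tmp <- i[swap]; i[swap] <- j[swap]; j[swap] <- tmp
  if (any(duplicated(paste(i, j)))) stop("duplicate contact pairs")
  if (any(j - i < min_seq_sep))
    stop(sprintf("contacts with |i - j| < %d are excluded", min_seq_sep))
  df <- data.frame(i = i, j = j, d_native = as.numeric(d_native))
  class(df) <- c("contact_map", "data.frame")
  df
}

#' Fill native distances for a pair list from a native structure
#'
#' @param ca n x 3 matrix of native Ca coordinates (row = residue).
#' @param pairs data.frame or matrix with columns \code{i}, \code{j}.
#' @param min_seq_sep minimum sequence separation.
#' @return a \code{\link{contact_map}}.
#' @export
contact_map_from_native <- function(ca, pairs, min_seq_sep = 3L) {
  ca <- as.matrix(ca)
  i <- pairs[, 1]; j <- pairs[, 2]
  d <- sqrt(rowSums((ca[i, , drop = FALSE] - ca[j, , drop = FALSE])^2))
  contact_map(i, j, d, min_seq_sep = min_seq_sep)
}

#' Read a three-column contact-map file
#'
#' @param path delimited text with columns \code{i}, \code{j},
#'   \code{d_native} (Angstrom).
#' @param min_seq_sep minimum sequence separation.
#' @return a \code{\link{contact_map}}.
#' @export
read_contact_map <- function(path, min_seq_sep = 3L) {
  df <- read_result_table(path)
  contact_map(df[[1]], df[[2]], df[[3]], min_seq_sep = min_seq_sep)
}

#' Fraction of native contacts Q
#'
#' A native contact is counted as formed when the Ca-Ca distance in the
#' query structure does not exceed the native distance by more than the
#' tolerance: \code{d <= (1 + tolerance) * d_native}.
#'
#' @param ca n x 3 matrix of Ca coordinates (row = residue index).
#' @param map a \code{\link{contact_map}}.
#' @param tolerance fractional tolerance (default 0.20).
#' @return Q in [0, 1].
#' @export
fraction_native_contacts <- function(ca, map, tolerance = 0.20) {
  if (nrow(map) == 0) stop("empty contact map")
  ca <- as.matrix(ca)
  if (max(map$j) > nrow(ca))
    stop("structure does not cover all contact-map residues")
  d <- sqrt(rowSums((ca[map$i, , drop = FALSE] - ca[map$j, , drop = FALSE])^2))
  mean(d <= (1 + tolerance) * map$d_native)
}

## optimal proper rotation (Kabsch, SVD with determinant correction)
.kabsch_fit <- function(a, b) {
  ac <- sweep(a, 2, colMeans(a)); bc <- sweep(b, 2, colMeans(b))
  s <- svd(crossprod(ac, bc))
  d <- sign(det(s$u) * det(s$v))
  rot <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  list(rot = rot, a_centered = ac, b_centered = bc)
}

#' Minimal RMSD under optimal rigid superposition (Kabsch)
#'
#' @param a,b n x 3 coordinate matrices with matching atom order, n >= 3.
#' @return RMSD in Angstrom after the optimal proper rotation and
#'   translation of \code{a} onto \code{b}.
#' @export
kabsch_rmsd <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!identical(dim(a), dim(b))) stop("coordinate size mismatch")
  if (nrow(a) < 3) stop("need at least 3 atoms")
  f <- .kabsch_fit(a, b)
  diff <- f$a_centered %*% f$rot - f$b_centered
  sqrt(sum(diff * diff) / nrow(a))
}

#' Superpose one structure onto another
#'
#' @param a structure to move (n x 3).
#' @param b reference structure (n x 3).
#' @return \code{a} after the optimal rigid superposition onto \code{b}.
#' @export
kabsch_superpose <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  f <- .kabsch_fit(a, b)
  sweep(f$a_centered %*% f$rot, 2, colMeans(b), "+")
}

#' Most representative member of an ensemble
#'
#' All members are superposed onto the first, the coordinate-wise average
#' structure is formed, and the member with minimum Kabsch RMSD to that
#' average is returned (ties: lowest index). A single alignment pass is
#' used, with no iterative mean refinement.
#'
#' @param members list of n x 3 coordinate matrices.
#' @return index of the most representative member.
#' @export
representative_structure <- function(members) {
  if (length(members) == 0) stop("empty ensemble")
  if (length(members) == 1) return(1L)
  aligned <- lapply(members, kabsch_superpose, b = members[[1]])
  avg <- Reduce(`+`, aligned) / length(aligned)
  rmsds <- vapply(aligned, kabsch_rmsd, numeric(1), b = avg)
  which.min(rmsds)
}

#' Free energy difference from Boltzmann populations
#'
#' \code{dG = -R T ln(p_a / p_b)}: a state twice as populated as another at
#' 300 K lies roughly 0.4 kcal/mol lower in free energy.
#'
#' @param p_a,p_b populations (counts or probabilities, > 0).
#' @param temperature temperature, K.
#' @return free energy difference a relative to b, kcal/mol.
#' @export
boltzmann_dg <- function(p_a, p_b, temperature = 300) {
  if (p_a <= 0 || p_b <= 0) stop("populations must be > 0")
  if (temperature <= 0) stop("temperature must be > 0")
  -R_GAS_KCAL * temperature * log(p_a / p_b)
}
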