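## Kirkwood-Buff solvation thermodynamics: distance-resolved KBIs,
## preferential interaction parameters, Wyman linkage shifts and transfer
## free energies.

#' Distance-resolved Kirkwood-Buff integral from an MDDF
#'
#' Computes \code{G_ps(R) = (1/rho_s) * [N_ps(R) - N*_ps(R)]} on the
#' bin-edge grid, where \code{N_ps(R)} and \code{N*_ps(R)} are the
#' cumulative real and ideal minimum-distance counts within \code{R}. The
#' plateau value is the mean of \code{G(R)} over the final
#' \code{plateau_window} Angstrom, with a flatness diagnostic.
#'
#' @param result an \code{\link{accumulate_mddf}} result.
#' @param rho \code{"bulk"} (default) for the bulk-density estimator,
#'   \code{"nv"} for total N/V, or a numeric density in molecules/A^3.
#' @param plateau_window width of the terminal averaging window, Angstrom.
#' @param n_blocks number of frame blocks for the plateau standard error.
#' @return object of class \code{kbi_profile}: grids \code{R}, \code{G}
#'   (A^3/molecule) and \code{G_Lmol} (L/mol), the density used, the plateau
#'   estimate with standard error, and per-frame profiles for downstream
#'   block averaging.
#' @export
kbi_profile <- function(result, rho = "bulk", plateau_window = 5,
                        n_blocks = 5L) {
  rho_s <- if (is.numeric(rho)) rho
           else switch(match.arg(rho, c("bulk", "nv")),
                       bulk = result$rho_bulk, nv = result$rho_nv)
  if (!is.finite(rho_s) || rho_s <= 0)
    stop("invalid density: rho_s must be a positive finite number")
  R <- result$R
  cum_real_f <- t(apply(result$per_frame_real, 1, cumsum))
  cum_ideal_f <- t(apply(result$per_frame_ideal, 1, cumsum))
  G_f <- (cum_real_f - cum_ideal_f) / rho_s
  G <- colMeans(G_f)
  sel <- R >= result$cutoff - plateau_window
  if (!any(sel)) stop("plateau window lies outside the R grid")
  plateau <- mean(G[sel])
  blocks <- .block_index(result$n_frames, n_blocks)
  bvals <- vapply(split(seq_len(result$n_frames), blocks), function(ix)
    mean(colMeans(G_f[ix, , drop = FALSE])[sel]), numeric(1))
  se <- if (length(bvals) > 1) stats::sd(bvals) / sqrt(length(bvals)) else NA_real_
  flat <- diff(range(G[sel]))
  structure(list(
    species = result$species, R = R, G = G,
    G_Lmol = G * A3_PER_MOLECULE_TO_L_PER_MOL,
    rho = rho_s, rho_molar = density_to_molar(rho_s),
    plateau = plateau, plateau_Lmol = plateau * A3_PER_MOLECULE_TO_L_PER_MOL,
    plateau_se = se, plateau_window = c(result$cutoff - plateau_window, result$cutoff),
    flatness = flat, flat_ok = is.na(se) || flat <= 3 * se * sqrt(length(bvals)),
    per_frame_G = G_f, n_frames = result$n_frames,
    molar_mass = result$molar_mass
  ), class = "kbi_profile")
}

.block_index <- function(n, n_blocks) {
  n_blocks <- max(1L, min(as.integer(n_blocks), n))
  as.integer(cut(seq_len(n), n_blocks, labels = FALSE))
}

#' @export
print.kbi_profile <- function(x, ...) {
  cat(sprintf("kbi_profile: species '%s', %d frames\n", x$species, x$n_frames))
  cat(sprintf("  plateau G = %.4g A^3/molecule (%.4g L/mol) +/- %.3g over R in [%.2f, %.2f] A\n",
              x$plateau, x$plateau_Lmol, x$plateau_se,
              x$plateau_window[1], x$plateau_window[2]))
  invisible(x)
}

#' @export
as.data.frame.kbi_profile <- function(x, ...) {
  df <- data.frame(R = x$R, G = x$G, G_Lmol = x$G_Lmol)
  attr(df, "units") <- c(R = "A", G = "A^3/molecule", G_Lmol = "L/mol")
  df
}

#' Preferential interaction parameter from two KBI profiles
#'
#' In the infinitely dilute solute limit,
#' \code{Gamma_pc = rho_c * [G_pc(R) - G_pw(R)]}. The uncertainty is
#' obtained by block averaging over frames and propagated through the
#' difference.
#'
#' @param pc \code{kbi_profile} for the cosolvent.
#' @param pw \code{kbi_profile} for water, on the same R grid.
#' @param R evaluation radius in Angstrom; \code{NULL} (default) averages
#'   over the cosolvent profile's plateau window.
#' @param n_blocks number of frame blocks for the standard error.
#' @return object of class \code{gamma_estimate} with fields \code{gamma},
#'   \code{se}, \code{R}, \code{rho_c} (molecules/A^3).
#' @export
gamma_pc <- function(pc, pw, R = NULL, n_blocks = 5L) {
  if (length(pc$R) != length(pw$R) || any(abs(pc$R - pw$R) > 1e-9))
    stop("incompatibility error: KBI profiles are on different R grids")
  if (is.null(R)) {
    sel <- pc$R >= pc$plateau_window[1] & pc$R <= pc$plateau_window[2]
    R_rep <- pc$plateau_window[2]
  } else {
    if (R < min(pc$R) - 1e-9 || R > max(pc$R) + 1e-9)
      stop("R outside the profile grid")
    sel <- which.min(abs(pc$R - R))
    R_rep <- pc$R[sel]
  }
  gamma <- pc$rho * (mean(pc$G[sel]) - mean(pw$G[sel]))
  nf <- pc$n_frames
  if (nf != pw$n_frames)
    stop("incompatibility error: profiles built from different frame counts")
  blocks <- .block_index(nf, n_blocks)
  bvals <- vapply(split(seq_len(nf), blocks), function(ix)
    pc$rho * (mean(colMeans(pc$per_frame_G[ix, , drop = FALSE])[sel]) -
              mean(colMeans(pw$per_frame_G[ix, , drop = FALSE])[sel])),
    numeric(1))
  se <- if (length(bvals) > 1) stats::sd(bvals) / sqrt(length(bvals)) else NA_real_
  structure(list(gamma = gamma, se = se, R = R_rep, rho_c = pc$rho,
                 rho_c_molar = pc$rho_molar, species = pc$species),
            class = "gamma_estimate")
}

#' @export
print.gamma_estimate <- function(x, ...) {
  cat(sprintf("Gamma_pc = %.4g +/- %.3g (molecules), R = %.2f A, rho_c = %.3g mol/L\n",
              x$gamma, x$se, x$R, x$rho_c_molar))
  invisible(x)
}

#' Wyman-linkage shift between two conformational states
#'
#' \code{dGamma = Gamma^U - Gamma^N}; by the Wyman linkage relation this
#' equals the derivative of the log denaturation equilibrium constant with
#' respect to the log cosolvent activity, so a positive value means the
#' cosolvent favors the denatured state.
#'
#' @param gamma_U,gamma_N \code{gamma_estimate} objects (or lists with
#'   \code{gamma} and \code{se}).
#' @return list with \code{delta_gamma}, \code{se} (quadrature sum), and an
#'   \code{interpretation} string.
#' @export
wyman_delta <- function(gamma_U, gamma_N) {
  dg <- gamma_U$gamma - gamma_N$gamma
  se <- sqrt((gamma_U$se %||% 0)^2 + (gamma_N$se %||% 0)^2)
  interp <- if (dg > 0) "positive: cosolvent favors the denatured state (U)"
            else if (dg < 0) "negative: cosolvent favors the native state (N)"
            else "zero: no preferential linkage"
  structure(list(delta_gamma = dg, se = se, interpretation = interp),
            class = "wyman_delta")
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || all(is.na(a))) b else a

#' @export
print.wyman_delta <- function(x, ...) {
  cat(sprintf("dGamma_pc = %.4g +/- %.3g; %s\n", x$delta_gamma, x$se,
              x$interpretation))
  invisible(x)
}

## ---- activity models ----------------------------------------------------

#' Ideal cosolvent activity model (gamma_c = 1)
#'
#' @return an \code{activity_model} whose activity-coefficient derivative is
#'   identically zero.
#' @export
activity_ideal <- function() {
  structure(list(type = "ideal",
                 lngamma = function(m) rep(0, length(m)),
                 dlngamma_dm = function(m) rep(0, length(m))),
            class = "activity_model")
}

#' Tabulated cosolvent activity model
#'
#' @param m concentrations (strictly increasing, mol/kg or mol/L as
#'   configured by the caller; the pipeline only requires consistency with
#'   the Gamma series).
#' @param lngamma log activity coefficients at \code{m}.
#' @return an \code{activity_model}; the derivative d ln(gamma)/dm is formed
#'   by central differences at interior nodes (one-sided at the ends) and
#'   interpolated linearly.
#' @export
activity_table <- function(m, lngamma) {
  if (length(m) < 2 || any(diff(m) <= 0))
    stop("activity table concentrations must be strictly increasing")
  if (any(!is.finite(lngamma))) stop("activity table ln(gamma) must be finite")
  n <- length(m)
  d <- numeric(n)
  d[1] <- (lngamma[2] - lngamma[1]) / (m[2] - m[1])
  d[n] <- (lngamma[n] - lngamma[n - 1]) / (m[n] - m[n - 1])
  if (n > 2) {
    i <- 2:(n - 1)
    d[i] <- (lngamma[i + 1] - lngamma[i - 1]) / (m[i + 1] - m[i - 1])
  }
  if (any(!is.finite(d))) stop("activity derivative is not finite")
  structure(list(type = "table", m = m, lng = lngamma, d = d,
                 lngamma = function(x) stats::approx(m, lngamma, x, rule = 2)$y,
                 dlngamma_dm = function(x) stats::approx(m, d, x, rule = 2)$y),
            class = "activity_model")
}

#' Read a two-column activity table
#'
#' @param path delimited text file with columns \code{m} and \code{lngamma}
#'   ('#' comment lines allowed).
#' @return an \code{activity_model}.
#' @export
read_activity_table <- function(path) {
  df <- read_result_table(path)
  activity_table(df[[1]], df[[2]])
}

## ---- transfer free energies ---------------------------------------------

#' Transfer free energy of one conformational state
#'
#' Integrates the concentration dependence of the state's chemical
#' potential from pure water to each cosolvent concentration:
#' \deqn{\Delta\mu_{p,tr}(m) = \int_0^{m} \partial\mu_p/\partial m_c \, dm_c}
#' with the integrand
#' \deqn{\partial\mu_p/\partial m_c = -\Gamma_{pc} (R T M_p/M_c)
#'       (1/m_c + \partial\ln\gamma_c/\partial m_c).}
#' \code{Gamma(m)} is interpolated piecewise-linearly through the supplied
#' series with the physically forced anchor \code{Gamma(0) = 0} (which also
#' removes the 1/m singularity), and the integral is evaluated by the
#' trapezoidal rule on a refined grid.
#'
#' @param gammas data.frame with columns \code{m} (> 0, strictly
#'   increasing) and \code{gamma}; an optional \code{se} column is carried
#'   through.
#' @param activity an \code{\link{activity_ideal}} or
#'   \code{\link{activity_table}} model.
#' @param temperature temperature in K.
#' @param M_p,M_c molar masses of the solute and cosolvent, g/mol.
#' @param n_nodes number of trapezoid nodes on \code{[0, max(m)]}.
#' @param convention \code{"printed"} keeps the \code{M_p/M_c} factor of the
#'   integrand as printed; \code{"molal"} selects the Lin-Timasheff molal
#'   convention (factor 1).
#' @param state state label carried into the result.
#' @return object of class \code{transfer_curve}: data.frame \code{curve}
#'   with \code{m}, \code{integrand} (kcal/mol per concentration unit) and
#'   \code{dmu} (kcal/mol), plus metadata. \code{dmu[m = 0]} is exactly 0.
#' @export
transfer_free_energy <- function(gammas, activity = activity_ideal(),
                                 temperature = 300, M_p, M_c,
                                 n_nodes = 1000L, convention = c("printed", "molal"),
                                 state = "state") {
  convention <- match.arg(convention)
  m <- gammas$m; g <- gammas$gamma
  if (length(m) < 2) stop("need Gamma at >= 2 concentrations")
  if (any(m <= 0)) stop("invalid concentration grid: m = 0 is implicit (anchor Gamma(0) = 0)")
  if (any(diff(m) <= 0)) stop("invalid concentration grid: must be strictly increasing")
  fac <- if (convention == "printed") M_p / M_c else 1
  grid <- seq(0, max(m), length.out = as.integer(n_nodes))
  gam <- stats::approx(c(0, m), c(0, g), xout = grid)$y
  gam_over_m <- c(g[1] / m[1], gam[-1] / grid[-1])
  integrand <- -R_GAS_KCAL * temperature * fac *
    (gam_over_m + gam * activity$dlngamma_dm(grid))
  h <- diff(grid)
  dmu <- c(0, cumsum(h * (integrand[-1] + integrand[-length(integrand)]) / 2))
  structure(list(curve = data.frame(m = grid, integrand = integrand, dmu = dmu),
                 input = gammas, temperature = temperature,
                 M_p = M_p, M_c = M_c, convention = convention, state = state),
            class = "transfer_curve")
}

#' @export
print.transfer_curve <- function(x, ...) {
  n <- nrow(x$curve)
  cat(sprintf("transfer_curve '%s': T = %g K, %s convention\n",
              x$state, x$temperature, x$convention))
  cat(sprintf("  dmu_tr(%.3g) = %.5g kcal/mol\n", x$curve$m[n], x$curve$dmu[n]))
  invisible(x)
}

#' @export
as.data.frame.transfer_curve <- function(x, ...) {
  df <- x$curve
  attr(df, "units") <- c(m = "mol/L (or mol/kg)", integrand = "kcal/mol per unit m",
                         dmu = "kcal/mol")
  df
}

#' Evaluate a transfer curve at given concentrations
#'
#' @param x a \code{transfer_curve}.
#' @param m concentrations.
#' @return interpolated \code{dmu} values, kcal/mol.
#' @export
transfer_at <- function(x, m) {
  stats::approx(x$curve$m, x$curve$dmu, xout = m)$y
}

#' Difference of transfer free energies between two states
#'
#' \code{ddmu(m) = dmu_U(m) - dmu_N(m)}; a negative value means the
#' cosolvent favors unfolding at that concentration (it lowers the unfolded
#' state's transfer cost relative to the native state's).
#'
#' @param curve_U,curve_N \code{transfer_curve} objects on the same
#'   temperature and concentration grid.
#' @return data.frame with columns \code{m} and \code{ddmu} (kcal/mol).
#' @export
delta_transfer <- function(curve_U, curve_N) {
  if (curve_U$temperature != curve_N$temperature)
    stop("incompatibility error: different temperatures")
  if (nrow(curve_U$curve) != nrow(curve_N$curve) ||
      any(abs(curve_U$curve$m - curve_N$curve$m) > 1e-12))
    stop("incompatibility error: different concentration grids")
  df <- data.frame(m = curve_U$curve$m,
                   ddmu = curve_U$curve$dmu - curve_N$curve$dmu)
  attr(df, "units") <- c(m = "mol/L (or mol/kg)", ddmu = "kcal/mol")
  df
}
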