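## End-to-end orchestration: frames -> MDDF -> KBI -> Gamma (-> transfer),
## driven by a run configuration (R list or YAML file), with a
## machine-readable manifest for provenance.

.default_config <- list(
  bin_width = 0.05, cutoff = 20, oversample = 10L, seed = 1L,
  d_bulk = 10, plateau_window = 5, n_blocks = 5L,
  temperature = 300, activity = "ideal", rho = "bulk"
)

#' Validate a run configuration
#'
#' @param config named list or path to a YAML file. Recognized fields:
#'   \code{frames} (extended-XYZ path), \code{species} (sidecar partition,
#'   see \code{\link{read_xyz_frames}}), \code{box}, \code{n_solute},
#'   \code{water}/\code{cosolvent} (species labels, default "w"/"c"),
#'   \code{bin_width}, \code{cutoff}, \code{oversample}, \code{seed},
#'   \code{d_bulk}, \code{plateau_window}, \code{n_blocks},
#'   \code{temperature}, \code{activity} ("ideal" or a table path),
#'   \code{output_dir}.
#' @return the completed configuration list.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(.default_config, config)
  cfg$water <- cfg$water %||% "w"
  cfg$cosolvent <- cfg$cosolvent %||% "c"
  if (is.null(cfg$output_dir)) stop("validation error: output_dir is required")
  if (!is.null(cfg$frames) && !file.exists(cfg$frames))
    stop(sprintf("validation error: frames file not found: %s", cfg$frames))
  if (is.character(cfg$activity) && cfg$activity != "ideal" &&
      !file.exists(cfg$activity))
    stop(sprintf("validation error: activity table not found: %s", cfg$activity))
  cfg
}

.manifest <- function(dir, files, cfg, extra = list()) {
  paths <- file.path(dir, files)
  man <- c(list(
    package = "kbsolv",
    version = as.character(utils::packageVersion("kbsolv")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = cfg$seed,
    parameters = cfg[c("bin_width", "cutoff", "oversample", "d_bulk",
                       "plateau_window", "n_blocks", "temperature")],
    outputs = lapply(seq_along(files), function(i)
      list(file = files[[i]], md5 = unname(tools::md5sum(paths[[i]]))))
  ), extra)
  jsonlite::write_json(man, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  man
}

#' Run the solvation pipeline end to end
#'
#' Reads (or accepts) frames, accumulates MDDFs for water and cosolvent,
#' computes distance-resolved KBIs and the preferential interaction
#' parameter, and writes all tables plus a manifest (inputs, parameters,
#' seed, software version, output hashes) to the output directory.
#'
#' @param config see \code{\link{validate_config}}.
#' @param frames optional list of \code{\link{configuration}} objects; when
#'   supplied, \code{config$frames} is not read.
#' @return invisibly, a list with the in-memory results
#'   (\code{mddf_w}, \code{mddf_c}, \code{kbi_w}, \code{kbi_c},
#'   \code{gamma}) and the manifest.
#' @export
run_solvation <- function(config, frames = NULL) {
  cfg <- validate_config(config)
  if (is.null(frames)) {
    if (is.null(cfg$frames)) stop("validation error: no frames supplied")
    frames <- read_xyz_frames(cfg$frames, species = cfg$species,
                              box = cfg$box, n_solute = cfg$n_solute)
  }
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  res <- list()
  for (lab in c(w = cfg$water, c = cfg$cosolvent)) {
    res[[paste0("mddf_", lab)]] <- accumulate_mddf(
      frames, lab, bin_width = cfg$bin_width, cutoff = cfg$cutoff,
      oversample = cfg$oversample, seed = cfg$seed, d_bulk = cfg$d_bulk)
    res[[paste0("kbi_", lab)]] <- kbi_profile(
      res[[paste0("mddf_", lab)]], rho = cfg$rho,
      plateau_window = cfg$plateau_window, n_blocks = cfg$n_blocks)
  }
  res$gamma <- gamma_pc(res[[paste0("kbi_", cfg$cosolvent)]],
                        res[[paste0("kbi_", cfg$water)]],
                        n_blocks = cfg$n_blocks)
  files <- character(0)
  for (lab in c(cfg$water, cfg$cosolvent)) {
    f1 <- sprintf("mddf_%s.csv", lab); f2 <- sprintf("kbi_%s.csv", lab)
    write_table(res[[paste0("mddf_", lab)]], file.path(cfg$output_dir, f1),
                meta = c(species = lab, seed = cfg$seed,
                         bin_width = cfg$bin_width, cutoff = cfg$cutoff,
                         oversample = cfg$oversample))
    write_table(res[[paste0("kbi_", lab)]], file.path(cfg$output_dir, f2),
                meta = c(species = lab, seed = cfg$seed,
                         rho_molecules_per_A3 = res[[paste0("kbi_", lab)]]$rho))
    files <- c(files, f1, f2)
  }
  gdf <- data.frame(gamma = res$gamma$gamma, se = res$gamma$se,
                    R = res$gamma$R, rho_c = res$gamma$rho_c)
  attr(gdf, "units") <- c(gamma = "molecules", se = "molecules", R = "A",
                          rho_c = "molecules/A^3")
  write_table(gdf, file.path(cfg$output_dir, "gamma.csv"),
              meta = c(seed = cfg$seed))
  files <- c(files, "gamma.csv")
  res$manifest <- .manifest(cfg$output_dir, files, cfg,
                            extra = list(n_frames = length(frames)))
  invisible(res)
}

#' Transfer free energies for two or more states
#'
#' Takes per-state Gamma series (files written by \code{\link{write_table}}
#' or data.frames with columns \code{m}, \code{gamma}), integrates each
#' into a transfer curve, and writes per-state curves plus pairwise
#' difference tables relative to the state tagged \code{native_label}.
#'
#' @param gamma_series named list (names = state labels) of file paths or
#'   data.frames; all states must share the concentration grid.
#' @param M_p,M_c molar masses, g/mol.
#' @param activity an activity model or \code{"ideal"} or a table path.
#' @param temperature temperature, K.
#' @param output_dir output directory.
#' @param native_label label of the reference (native) state.
#' @param n_nodes trapezoid nodes.
#' @param convention integrand convention, see
#'   \code{\link{transfer_free_energy}}.
#' @return invisibly, list of \code{transfer_curve}s, the difference
#'   data.frames, and the manifest.
#' @export
run_transfer <- function(gamma_series, M_p, M_c, activity = "ideal",
                         temperature = 300, output_dir,
                         native_label = "N", n_nodes = 1000L,
                         convention = "printed") {
  if (length(gamma_series) < 2)
    stop("need >= 2 states: the folding difference is undefined for one state")
  if (!(native_label %in% names(gamma_series)))
    stop(sprintf("no state labelled '%s' among: %s", native_label,
                 paste(names(gamma_series), collapse = ", ")))
  if (is.character(activity))
    activity <- if (identical(activity, "ideal")) activity_ideal()
                else read_activity_table(activity)
  series <- lapply(gamma_series, function(g)
    if (is.character(g)) read_result_table(g) else g)
  grids <- lapply(series, `[[`, "m")
  for (g in grids[-1])
    if (length(g) != length(grids[[1]]) || any(abs(g - grids[[1]]) > 1e-9))
      stop("incompatibility error: states have different concentration grids")
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  curves <- lapply(names(series), function(st)
    transfer_free_energy(series[[st]], activity, temperature, M_p, M_c,
                         n_nodes = n_nodes, convention = convention, state = st))
  names(curves) <- names(series)
  files <- character(0)
  for (st in names(curves)) {
    f <- sprintf("transfer_%s.csv", st)
    write_table(curves[[st]], file.path(output_dir, f),
                meta = c(state = st, temperature = temperature,
                         convention = convention))
    files <- c(files, f)
  }
  deltas <- list()
  for (st in setdiff(names(curves), native_label)) {
    d <- delta_transfer(curves[[st]], curves[[native_label]])
    f <- sprintf("delta_transfer_%s_minus_%s.csv", st, native_label)
    write_table(d, file.path(output_dir, f),
                meta = c(states = sprintf("%s - %s", st, native_label)))
    deltas[[st]] <- d
    files <- c(files, f)
  }
  cfg <- utils::modifyList(.default_config,
                           list(temperature = temperature, seed = NA))
  man <- .manifest(output_dir, files, cfg,
                   extra = list(states = names(curves),
                                native = native_label,
                                M_p = M_p, M_c = M_c))
  invisible(list(curves = curves, deltas = deltas, manifest = man))
}
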