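# Experiment drivers: the package's standard computational experiments at
# full or scaled-down size.  All randomness flows from the single seed in
# the configuration; configs are copied into output directories so every
# experiment is reproducible from its output alone.

#' Noise-amplification sweep over uniformly-spaced radial arrays
#'
#' Evaluates the figure-of-merit q of radial reference arrays for every
#' combination of sensor count N and helmet radius R, on the 2D surface grid
#' of the matching radius.  Arrays with fewer sensors than basis components
#' are evaluated with the minimum-norm pseudoinverse (flagged in the output).
#'
#' @param n_sensors Integer vector of sensor counts N.
#' @param radii Numeric vector of helmet radii R, metres.
#' @param config Experiment configuration (see
#'   \code{\link{read_experiment_config}}); basis cutoffs and grid size are
#'   taken from it.
#' @return data.frame with columns N, R, q, mean_amp, rank_deficient; written
#'   to \code{radial_sweep.tsv} in \code{config$output_dir} when set.
#' @export
run_radial_sweep <- function(n_sensors = c(120L, 240L), radii = 0.15,
                             config = read_experiment_config()) {
  spec <- multipole_spec(config$l_internal, config$l_external)
  rows <- list()
  for (R in radii) {
    surf <- helmet_surface(R, config$cylinder_height, config$opening_angle)
    grid <- sampling_grid(surf, n_points = config$grid_points)
    gf <- grid_field_matrix(grid, spec)
    for (N in n_sensors) {
      fom <- suppressWarnings(
        figure_of_merit(radial_array(surf, N), spec, grid, grid_fields = gf))
      rows[[length(rows) + 1L]] <-
        data.frame(N = N, R = R, q = fom$q, mean_amp = fom$mean_amp,
                   rank_deficient = fom$rank_deficient)
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(out, file.path(config$output_dir, "radial_sweep.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  out
}

#' Run a full sensor-array optimization experiment
#'
#' Builds the sampling volume and grid from the configuration, initializes
#' with a uniformly-spaced radial array (on the surface of
#' \code{initial_radius}; for 3D volumes the default is the outer surface),
#' runs the annealing optimizer, and evaluates the channel capacity of the
#' initial and final arrays.  When \code{config$output_dir} is set, writes
#' the trajectory log, sensor-array snapshots, the final array and a copy of
#' the configuration.
#'
#' @param config Experiment configuration list.
#' @param optimizer Optional \code{\link{optimizer_config}}; by default
#'   built from the configuration's iteration/evaluation budgets and seed.
#' @return List with \code{trajectory}, \code{initial_q}, \code{final_q},
#'   \code{initial_capacity}, \code{final_capacity}.
#' @export
run_optimization_experiment <- function(config = read_experiment_config(),
                                        optimizer = NULL) {
  volume <- config_volume(config)
  grid <- config_grid(config, volume)
  spec <- multipole_spec(config$l_internal, config$l_external)
  r_init <- config$initial_radius
  if (is.null(r_init))
    r_init <- if (inherits(volume, "helmet_shell3d")) volume$outer_radius
              else volume$radius
  init_surface <- helmet_surface(r_init, config$cylinder_height,
                                 config$opening_angle)
  initial <- radial_array(init_surface, config$m)
  if (is.null(optimizer))
    optimizer <- optimizer_config(iterations = config$iterations,
                                  max_cost_evaluations =
                                    config$max_cost_evaluations,
                                  seed = config$seed)
  traj <- optimize_array(initial, volume, spec, grid, optimizer)
  ens <- sample_dipole_ensemble(config$n_dipoles, config$source_radius,
                                config$total_rms_moment, config$seed)
  cap0 <- channel_capacity(leadfield(initial, ens), ens$sigma_diag,
                           config$noise_sd)
  cap1 <- channel_capacity(leadfield(traj$final, ens), ens$sigma_diag,
                           config$noise_sd)
  if (!is.null(config$output_dir)) {
    out <- config$output_dir
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    write_trajectory(traj, file.path(out, "trajectory.tsv"))
    for (nm in names(traj$snapshots))
      write_sensor_array(traj$snapshots[[nm]],
                         file.path(out, sprintf("array_eval%s.tsv", nm)),
                         comment = sprintf("snapshot at cost evaluation %s",
                                           nm))
    write_sensor_array(traj$final, file.path(out, "array_final.tsv"),
                       comment = sprintf("final array, q = %.6g", traj$final_q))
    cfg <- config
    cfg$output_dir <- NULL
    yaml::write_yaml(cfg, file.path(out, "config.yaml"))
  }
  list(trajectory = traj, initial_q = traj$initial_q,
       final_q = traj$final_q, initial_capacity = cap0,
       final_capacity = cap1)
}

#' Evaluate a sensor array
#'
#' One-stop report for an array (object or file): figure-of-merit, mean
#' amplification, numerical rank of the measurement matrix, channel
#' capacity under the default dipole model, and the orientation histogram.
#'
#' @param array A \code{\link{sensor_array}} or the path of a sensor-array
#'   file.
#' @param config Experiment configuration controlling the volume, basis,
#'   grid and capacity model.
#' @return List of class \code{array_report} with fields \code{q},
#'   \code{mean_amp}, \code{rank}, \code{n_components}, \code{capacity},
#'   \code{orientation_hist}, \code{m}.
#' @export
evaluate_array <- function(array, config = read_experiment_config()) {
  if (is.character(array)) array <- read_sensor_array(array)
  volume <- config_volume(config)
  grid <- config_grid(config, volume)
  spec <- multipole_spec(config$l_internal, config$l_external)
  fom <- suppressWarnings(figure_of_merit(array, spec, grid))
  cap <- array_capacity(array, n_dipoles = config$n_dipoles,
                        source_radius = config$source_radius,
                        total_rms_moment = config$total_rms_moment,
                        noise_sd = config$noise_sd, seed = config$seed)
  structure(list(q = fom$q, mean_amp = fom$mean_amp, rank = fom$rank,
                 n_components = spec$n_components, capacity = cap,
                 orientation_hist = orientation_diagnostics(array),
                 m = array$m),
            class = "array_report")
}

#' @export
print.array_report <- function(x, ...) {
  cat(sprintf("Array report (%d sensors)\n", x$m))
  cat(sprintf("  q (max noise amplification): %.6g\n", x$q))
  cat(sprintf("  mean noise amplification:    %.6g\n", x$mean_amp))
  cat(sprintf("  rank(S): %d of %d components\n", x$rank, x$n_components))
  cat(sprintf("  channel capacity: %.4g bits per sample\n", x$capacity))
  invisible(x)
}
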