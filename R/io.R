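# Sensor-array files and experiment configuration.

#' Read a sensor-array file
#'
#' Tab-separated text, one sensor per line with columns
#' \code{x y z ex ey ez} (position in metres, unit orientation); lines
#' starting with \code{#} are comments.  Orientations are normalized on
#' read; rows whose orientation norm deviates from 1 by more than 1e-3 are
#' rejected.
#'
#' @param path File path.
#' @return A \code{\link{sensor_array}}.
#' @export
read_sensor_array <- function(path) {
  lines <- readLines(path)
  rows <- list()
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (ln == "" || startsWith(ln, "#")) next
    fields <- strsplit(ln, "[\t ]+")[[1]]
    vals <- suppressWarnings(as.numeric(fields))
    if (length(vals) < 6L || anyNA(vals[1:6]))
      stop(sprintf("parse error in '%s' at line %d: expected 6 numeric %s",
                   path, i, "columns x y z ex ey ez"), call. = FALSE)
    rows[[length(rows) + 1L]] <- vals[1:6]
  }
  if (!length(rows)) stop("no sensors found in '", path, "'", call. = FALSE)
  m <- do.call(rbind, rows)
  sensor_array(m[, 1:3, drop = FALSE], m[, 4:6, drop = FALSE],
               norm_tol = 1e-3)
}

#' Write a sensor-array file
#'
#' @param array A \code{\link{sensor_array}}.
#' @param path Output path.
#' @param comment Optional comment line(s) written as \code{#} headers.
#' @export
write_sensor_array <- function(array, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste("#", comment), con)
  writeLines("# x\ty\tz\tex\tey\tez", con)
  df <- cbind(array$positions, array$orientations)
  utils::write.table(format(df, digits = 17, scientific = TRUE,
                            trim = TRUE),
                     con, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read an experiment configuration
#'
#' Flat key-value YAML; unknown keys are an error so typos fail loudly.
#' Defaults (applied for missing keys) follow the package's standard study
#' conditions: internal cutoff 10, external cutoff 3, helmet radius 0.15 m,
#' shell radii 0.15-0.25 m, 1000-point 2D / 5x500-point 3D grids, 1000
#' annealing iterations, 1e7 cost evaluations, 1000 dipoles in a 0.07 m
#' ball with RSS moment 2e-8 A m, sensor noise 1e-14 T.
#'
#' @param path YAML file path, or NULL for pure defaults.
#' @param overrides Named list overriding file values.
#' @return Named list of configuration values.
#' @export
read_experiment_config <- function(path = NULL, overrides = list()) {
  defaults <- list(
    volume = "2d",             # "2d" or "3d"
    radius = 0.15,             # 2D surface radius, m
    inner_radius = 0.15, outer_radius = 0.25,
    cylinder_height = 0.15, opening_angle = pi / 2,
    m = 240L,                  # number of sensors
    l_internal = 10L, l_external = 3L,
    grid_points = 1000L, grid_shells = 5L, grid_points_per_shell = 500L,
    iterations = 1000L, max_cost_evaluations = 1e7,
    initial_radius = NULL,     # radial-initialization radius (3D: outer)
    n_dipoles = 1000L, source_radius = 0.07,
    total_rms_moment = 2e-8, noise_sd = 1e-14,
    seed = 1L, output_dir = NULL)
  vals <- if (is.null(path)) list() else yaml::read_yaml(path)
  unknown <- setdiff(c(names(vals), names(overrides)), names(defaults))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg <- utils::modifyList(defaults, vals)
  utils::modifyList(cfg, overrides)
}

config_volume <- function(cfg) {
  if (identical(cfg$volume, "3d"))
    helmet_shell3d(cfg$inner_radius, cfg$outer_radius,
                   cfg$cylinder_height, cfg$opening_angle)
  else
    helmet_surface(cfg$radius, cfg$cylinder_height, cfg$opening_angle)
}

config_grid <- function(cfg, volume = config_volume(cfg)) {
  sampling_grid(volume, n_points = cfg$grid_points,
                n_shells = cfg$grid_shells,
                points_per_shell = cfg$grid_points_per_shell)
}
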