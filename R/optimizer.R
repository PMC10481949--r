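# Sensor-array optimization: minimize the noise-amplification figure-of-merit
# q over sensor positions and orientations inside a sampling volume.
#
# The array is encoded as a box-bounded continuous parameter vector (so a
# generic annealer can search it): per sensor a cumulative-area coordinate u
# and a scaled azimuth v on the helmet surface (v excludes the face-opening
# sector by construction), for 3D shells a radial coordinate t in [0,1]
# mapping inner -> outer surface, and two orientation angles.  Every point of
# the bounds box decodes to an admissible array, so the search can never
# leave the sampling volume.

# admissible area of the helmet surface of radius R (opening excluded)
adm_area <- function(R, h, gam) 2 * pi * R^2 + (2 * pi - gam) * R * h

decode_positions <- function(volume, u, v, t = NULL) {
  if (inherits(volume, "helmet_shell3d")) {
    R <- volume$inner_radius + t * (volume$outer_radius - volume$inner_radius)
    h <- volume$cylinder_height; gam <- volume$opening_angle
  } else {
    R <- rep(volume$radius, length(u))
    h <- volume$cylinder_height; gam <- volume$opening_angle
  }
  a_hemi <- 2 * pi * R^2
  a <- u * adm_area(R, h, gam)
  hemi <- a <= a_hemi
  ct <- 1 - pmin(a, a_hemi) / a_hemi
  st <- sqrt(pmax(0, 1 - ct^2))
  d <- pmax(0, a - a_hemi) / ((2 * pi - gam) * R)
  phi <- ifelse(hemi, 2 * pi * v, gam / 2 + (2 * pi - gam) * v)
  cbind(ifelse(hemi, R * st * cos(phi), R * cos(phi)),
        ifelse(hemi, R * st * sin(phi), R * sin(phi)),
        ifelse(hemi, R * ct, -d))
}

#' Encode a sensor array as a bounded parameter vector
#'
#' Inverse of \code{\link{decode_array}}: positions map to (u, v) surface
#' coordinates (cumulative-area fraction and scaled azimuth), plus a radial
#' coordinate t for 3D shells; orientations map to (polar, azimuth) angles.
#' The parameter vector has length 4m (surface) or 5m (shell), grouped per
#' sensor, and the returned bounds box covers exactly the admissible set.
#'
#' @param array A \code{\link{sensor_array}} with all sensors inside
#'   \code{volume}.
#' @param volume A \code{helmet_surface} or \code{helmet_shell3d}.
#' @return List with \code{par}, \code{lower}, \code{upper}.
#' @export
encode_array <- function(array, volume) {
  stopifnot(inherits(array, "sensor_array"))
  p <- array$positions
  if (!all(volume_contains(volume, p, tol = 1e-6)))
    stop("all sensors must lie inside the sampling volume", call. = FALSE)
  shell <- inherits(volume, "helmet_shell3d")
  h <- volume$cylinder_height; gam <- volume$opening_angle
  m <- array$m
  z <- p[, 3]; rho <- sqrt(p[, 1]^2 + p[, 2]^2)
  # equator points belong to the hemisphere chart (the decode boundary
  # a <= a_hemi maps them there, and the face opening does not apply)
  hemi <- z >= -1e-12
  R <- ifelse(hemi, sqrt(rowSums(p^2)), rho)
  t <- if (shell) {
    pmin(1, pmax(0, (R - volume$inner_radius) /
                   (volume$outer_radius - volume$inner_radius)))
  } else NULL
  A <- adm_area(R, h, gam)
  a <- ifelse(hemi, 2 * pi * R^2 * (1 - z / R), 2 * pi * R^2 - z * (2 * pi - gam) * R)
  u <- pmin(1, pmax(0, a / A))
  phi <- atan2(p[, 2], p[, 1]) %% (2 * pi)
  v <- ifelse(hemi, phi / (2 * pi),
              pmin(1, pmax(0, (phi - gam / 2) / (2 * pi - gam))))
  e <- array$orientations
  psi <- acos(pmin(1, pmax(-1, e[, 3])))
  chi <- atan2(e[, 2], e[, 1]) %% (2 * pi)
  per <- if (shell) 5L else 4L
  par <- numeric(per * m)
  lower <- numeric(per * m); upper <- numeric(per * m)
  for (i in seq_len(m)) {
    o <- (i - 1L) * per
    blk <- if (shell) c(u[i], v[i], t[i], psi[i], chi[i])
           else c(u[i], v[i], psi[i], chi[i])
    par[o + seq_len(per)] <- blk
    lower[o + seq_len(per)] <- 0
    upper[o + seq_len(per)] <- if (shell) c(1, 1, 1, pi, 2 * pi)
                               else c(1, 1, pi, 2 * pi)
  }
  list(par = par, lower = lower, upper = upper)
}

#' Decode a parameter vector into a sensor array
#'
#' @param par Parameter vector as produced by \code{\link{encode_array}}.
#' @param volume The sampling volume the encoding refers to.
#' @return A \code{\link{sensor_array}}; all sensors inside \code{volume} by
#'   construction, orientations exactly unit.
#' @export
decode_array <- function(par, volume) {
  shell <- inherits(volume, "helmet_shell3d")
  per <- if (shell) 5L else 4L
  if (length(par) %% per != 0L)
    stop("parameter vector length must be a multiple of ", per, call. = FALSE)
  m <- length(par) %/% per
  blk <- matrix(par, nrow = per)
  u <- blk[1L, ]; v <- blk[2L, ]
  t <- if (shell) blk[3L, ] else NULL
  psi <- blk[per - 1L, ]; chi <- blk[per, ]
  pos <- decode_positions(volume, u, v, t)
  ori <- cbind(sin(psi) * cos(chi), sin(psi) * sin(chi), cos(psi))
  sensor_array(pos, ori, norm_tol = 1e-9)
}

#' Optimizer configuration
#'
#' @param iterations Maximum number of global annealing iterations; each
#'   iteration is a block of \code{evals_per_iteration} cost evaluations at
#'   one temperature stage.
#' @param max_cost_evaluations Hard cap on cost-function calls.
#' @param evals_per_iteration Proposals per iteration; default scales with
#'   the parameter dimension (2 per coordinate, at least 50).
#' @param temp Initial annealing temperature on the log-q scale.
#' @param step_hi,step_lo Initial and final proposal step, as a fraction of
#'   each coordinate's range (geometric decay over the run).
#' @param jump_prob Probability that a proposal redraws the chosen sensor
#'   uniformly over the admissible set instead of taking a local step
#'   (long-range moves in the spirit of fast-annealing visiting
#'   distributions).
#' @param polish Run a box-constrained local search (L-BFGS-B on log q) from
#'   the best annealed configuration, mirroring dual annealing's local-search
#'   stage.
#' @param polish_budget Maximum cost evaluations the local search may spend
#'   (it is cut off mid-run once exhausted).
#' @param polish_maxit Iteration cap for the local search.
#' @param checkpoint_every Record an array snapshot every this many cost
#'   evaluations (plus the initial and final arrays).
#' @param seed Integer seed controlling all randomness of the run.
#' @return List of class \code{optimizer_config}.
#' @export
optimizer_config <- function(iterations = 1000L,
                             max_cost_evaluations = 1e7,
                             evals_per_iteration = NULL,
                             temp = 1.0,
                             step_hi = 0.6, step_lo = 0.02,
                             jump_prob = 0.1,
                             polish = TRUE, polish_budget = 5000L,
                             polish_maxit = 100L,
                             checkpoint_every = 10000L,
                             seed = 1L) {
  stopifnot(iterations >= 0, max_cost_evaluations > 0, temp > 0,
            step_hi > 0, step_lo > 0, polish_budget >= 0)
  structure(list(iterations = as.integer(iterations),
                 max_cost_evaluations = max_cost_evaluations,
                 evals_per_iteration = evals_per_iteration,
                 temp = temp, step_hi = step_hi, step_lo = step_lo,
                 jump_prob = jump_prob,
                 polish = polish, polish_budget = as.integer(polish_budget),
                 polish_maxit = as.integer(polish_maxit),
                 checkpoint_every = as.integer(checkpoint_every),
                 seed = as.integer(seed)),
            class = "optimizer_config")
}

#' Cost of a parameter vector
#'
#' \code{q} of the decoded array, evaluated with
#' \code{\link{figure_of_merit}}.  Out-of-bounds coordinates are clamped to
#' the bounds (with a warning), since annealers may propose boundary values.
#'
#' @param par Parameter vector (see \code{\link{encode_array}}).
#' @param volume,spec,grid The sampling volume, basis and evaluation grid.
#' @param grid_fields Optional precomputed grid field matrix.
#' @return The scalar figure-of-merit q (nonnegative).
#' @export
array_cost <- function(par, volume, spec, grid, grid_fields = NULL) {
  b <- param_bounds(volume, length(par))
  if (any(par < b$lower - 1e-12) || any(par > b$upper + 1e-12)) {
    warning("parameters outside bounds were clamped", call. = FALSE)
    par <- pmin(pmax(par, b$lower), b$upper)
  }
  fom <- figure_of_merit(decode_array(par, volume), spec, grid,
                         grid_fields = grid_fields)
  fom$q
}

# bounds box for a parameter vector of given length over a volume
param_bounds <- function(volume, n_par) {
  per <- if (inherits(volume, "helmet_shell3d")) 5L else 4L
  if (n_par %% per != 0L)
    stop("parameter vector length must be a multiple of ", per, call. = FALSE)
  m <- n_par %/% per
  hi <- if (per == 5L) c(1, 1, 1, pi, 2 * pi) else c(1, 1, pi, 2 * pi)
  list(lower = numeric(n_par), upper = rep(hi, m))
}

#' Optimize a sensor array by simulated annealing
#'
#' Minimizes the figure-of-merit q over sensor positions and orientations
#' inside the sampling volume.  The annealing engine is
#' \code{stats::optim(method = "SANN")} (Belisle's Metropolis annealer with
#' logarithmic cooling), driven on the log-q scale with a bespoke bounded
#' proposal kernel that perturbs one randomly chosen sensor at a time with a
#' step size decaying geometrically from \code{step_hi} to \code{step_lo}
#' over the run; a box-constrained local search from the best configuration
#' finishes the run (as in dual annealing's local-search stage).
#'
#' @param initial Initial \code{\link{sensor_array}} (all sensors inside
#'   \code{volume}).
#' @param volume Sampling volume.
#' @param spec Multipole basis.
#' @param grid Evaluation grid (a \code{\link{sampling_grid}} of
#'   \code{volume}).
#' @param config An \code{\link{optimizer_config}}.
#' @return An object of class \code{opt_trajectory}: \code{log} data frame
#'   (iteration, n_cost_evals, best_q, mean_amp), \code{snapshots} list of
#'   arrays, \code{initial}/\code{final} arrays with their q values, and the
#'   seed.  Best-q along the log is non-increasing.
#' @export
optimize_array <- function(initial, volume, spec, grid,
                           config = optimizer_config()) {
  stopifnot(inherits(initial, "sensor_array"),
            inherits(config, "optimizer_config"))
  enc <- encode_array(initial, volume)  # errors if initial is infeasible
  if (initial$m * 3 < spec$n_components)
    warning("fewer measurements than basis components is strongly ",
            "discouraged (m < n)", call. = FALSE)
  d <- length(enc$par)
  per <- d %/% initial$m
  tmax <- if (is.null(config$evals_per_iteration)) max(50L, 2L * d)
          else as.integer(config$evals_per_iteration)
  total <- min(config$iterations * tmax, config$max_cost_evaluations)
  gf <- grid_field_matrix(grid, spec)

  env <- new.env()
  env$t <- 0L
  env$best_par <- enc$par
  fom0 <- figure_of_merit(initial, spec, grid, grid_fields = gf)
  env$best_q <- fom0$q
  env$best_mean <- fom0$mean_amp
  env$rows <- list(data.frame(iteration = 0L, n_cost_evals = 0L,
                              best_q = fom0$q, mean_amp = fom0$mean_amp))
  env$snapshots <- list(`0` = initial)
  env$clamped <- 0L
  env$rank_def <- 0L

  env$cap <- Inf
  fn <- function(par) {
    if (env$t >= env$cap)
      stop(structure(class = c("megarray_budget", "error", "condition"),
                     list(message = "cost-evaluation budget exhausted",
                          call = NULL)))
    out <- par < enc$lower | par > enc$upper
    if (any(out)) {
      env$clamped <- env$clamped + 1L
      par <- pmin(pmax(par, enc$lower), enc$upper)
    }
    fom <- suppressWarnings(
      figure_of_merit(decode_array(par, volume), spec, grid,
                      grid_fields = gf))
    if (fom$rank_deficient) env$rank_def <- env$rank_def + 1L
    env$t <- env$t + 1L
    if (fom$q < env$best_q) {
      env$best_q <- fom$q
      env$best_mean <- fom$mean_amp
      env$best_par <- par
    }
    if (env$t %% tmax == 0L) {
      it <- env$t %/% tmax
      env$rows[[length(env$rows) + 1L]] <-
        data.frame(iteration = it, n_cost_evals = env$t,
                   best_q = env$best_q, mean_amp = env$best_mean)
    }
    if (env$t %% config$checkpoint_every == 0L)
      env$snapshots[[as.character(env$t)]] <- decode_array(env$best_par, volume)
    log(fom$q)
  }

  # proposal kernel: perturb every coordinate of one randomly chosen sensor,
  # with Gaussian steps scaled by the cooling fraction; azimuthal coordinates
  # wrap, the rest reflect at the bounds
  wrap_cols <- if (per == 5L) c(2L, 5L) else c(2L, 4L)
  propose <- function(par, ...) {
    frac <- env$t / max(total, 1L)
    s <- config$step_hi * (config$step_lo / config$step_hi)^frac
    i <- sample.int(initial$m, 1L)
    o <- (i - 1L) * per
    idx <- o + seq_len(per)
    w <- enc$upper[idx] - enc$lower[idx]
    if (stats::runif(1) < config$jump_prob) {
      par[idx] <- enc$lower[idx] + stats::runif(per) * w
      return(par)
    }
    par[idx] <- par[idx] + stats::rnorm(per, sd = s * w)
    for (k in seq_len(per)) {
      j <- idx[k]
      if (k %in% wrap_cols) {
        par[j] <- enc$lower[j] +
          (par[j] - enc$lower[j]) %% (enc$upper[j] - enc$lower[j])
      } else {
        # reflect into the box
        span <- enc$upper[j] - enc$lower[j]
        x <- (par[j] - enc$lower[j]) %% (2 * span)
        par[j] <- enc$lower[j] + ifelse(x > span, 2 * span - x, x)
      }
    }
    par
  }

  set.seed(config$seed)
  if (total > 0L && config$iterations > 0L) {
    env$cap <- total
    tryCatch(
      stats::optim(enc$par, fn, gr = propose, method = "SANN",
                   control = list(maxit = total, temp = config$temp,
                                  tmax = tmax)),
      megarray_budget = function(e) NULL)
    if (config$polish && env$t < config$max_cost_evaluations) {
      env$cap <- min(config$max_cost_evaluations,
                     env$t + config$polish_budget)
      tryCatch(
        stats::optim(env$best_par, fn, method = "L-BFGS-B",
                     lower = enc$lower, upper = enc$upper,
                     control = list(maxit = config$polish_maxit)),
        error = function(e) NULL)
      it <- env$rows[[length(env$rows)]]$iteration
      env$rows[[length(env$rows) + 1L]] <-
        data.frame(iteration = it + 1L, n_cost_evals = env$t,
                   best_q = env$best_q, mean_amp = env$best_mean)
    }
  }

  final <- decode_array(env$best_par, volume)
  env$snapshots[[as.character(env$t)]] <- final
  structure(list(log = do.call(rbind, env$rows),
                 snapshots = env$snapshots,
                 initial = initial, initial_q = fom0$q,
                 final = final, final_q = env$best_q,
                 final_mean_amp = env$best_mean,
                 n_cost_evals = env$t,
                 n_clamped = env$clamped,
                 n_rank_deficient = env$rank_def,
                 seed = config$seed,
                 config = config),
            class = "opt_trajectory")
}

#' @export
print.opt_trajectory <- function(x, ...) {
  cat(sprintf(
    "Annealing run: %d cost evaluations, q %.4g -> %.4g (seed %d)\n",
    x$n_cost_evals, x$initial_q, x$final_q, x$seed))
  invisible(x)
}

#' Sensor-orientation diagnostics
#'
#' Histogram of the angles between each sensor's orientation and the outward
#' spherical radial direction (position unit vector from the origin).
#'
#' @param array A \code{\link{sensor_array}}.
#' @param n_bins Number of equal-width bins on [0, pi].
#' @return List with \code{angles} (radians, in [0, pi]), \code{breaks} and
#'   \code{counts} (summing to m).
#' @export
orientation_diagnostics <- function(array, n_bins = 18L) {
  rhat <- array$positions / sqrt(rowSums(array$positions^2))
  cosang <- rowSums(rhat * array$orientations)
  ang <- acos(pmin(1, pmax(-1, cosang)))
  breaks <- seq(0, pi, length.out = n_bins + 1L)
  counts <- as.integer(table(cut(ang, breaks, include.lowest = TRUE)))
  list(angles = ang, breaks = breaks, counts = counts)
}

#' Write a trajectory log to a delimited file
#'
#' @param trajectory An \code{opt_trajectory}.
#' @param path Output path (tab-separated columns iteration, n_cost_evals,
#'   best_q, mean_amp).
#' @export
write_trajectory <- function(trajectory, path) {
  utils::write.table(trajectory$log, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
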