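# Channel information capacity of a sensor array.
#
# Independent validation metric: random current dipoles inside a spherical
# volume conductor drive the array through the closed-form spherical-model
# lead field (Sarvas solution); the capacity is the Shannon capacity of the
# orthogonal channels defined by the eigen-decomposition of L Sigma L^T
# against i.i.d. sensor noise of variance sigma^2.

MU0 <- 4e-7 * pi  # vacuum permeability, T m / A

#' Random current-dipole ensemble
#'
#' Dipole locations uniform in a ball of radius \code{source_radius} about
#' the origin (radius drawn by the inverse-CDF rule r = R u^(1/3)), moments
#' uniform on the unit sphere.  The amplitude covariance is diagonal with
#' equal per-dipole variance \code{total_rms_moment^2 / count}, so the
#' root-sum-squared moment across the ensemble equals
#' \code{total_rms_moment}.
#'
#' @param count Number of dipoles (default 1000).
#' @param source_radius Ball radius, metres (default 0.07).
#' @param total_rms_moment Root-sum-squared dipole moment, A m (default
#'   2e-8).
#' @param seed Integer seed; the ensemble is reproducible for a fixed seed.
#' @return An object of class \code{dipole_ensemble}: \code{positions} and
#'   \code{orientations} (count-by-3), \code{sigma_diag} (per-dipole
#'   amplitude variances, (A m)^2), and the generating parameters.
#' @export
sample_dipole_ensemble <- function(count = 1000L, source_radius = 0.07,
                                   total_rms_moment = 2e-8, seed = 1L) {
  count <- as.integer(count)
  stopifnot(count >= 1L, source_radius > 0, total_rms_moment >= 0)
  set.seed(as.integer(seed))
  u <- stats::runif(count)
  r <- source_radius * u^(1 / 3)
  dir <- matrix(stats::rnorm(3L * count), ncol = 3L)
  dir <- dir / sqrt(rowSums(dir^2))
  ori <- matrix(stats::rnorm(3L * count), ncol = 3L)
  ori <- ori / sqrt(rowSums(ori^2))
  structure(list(positions = r * dir,
                 orientations = ori,
                 sigma_diag = rep(total_rms_moment^2 / count, count),
                 source_radius = source_radius,
                 total_rms_moment = total_rms_moment,
                 seed = as.integer(seed)),
            class = "dipole_ensemble")
}

#' @export
print.dipole_ensemble <- function(x, ...) {
  cat(sprintf(
    "Dipole ensemble: %d dipoles in a %.3g m ball, RSS moment %.3g A m\n",
    nrow(x$positions), x$source_radius, x$total_rms_moment))
  invisible(x)
}

#' Magnetic field of a current dipole in a spherical conductor
#'
#' Closed-form (Sarvas) solution for the field outside a spherically
#' symmetric volume conductor centred at the origin, projected onto a sensor
#' orientation.  Radial dipoles (moment parallel to the position vector) are
#' magnetically silent and give exactly zero.
#'
#' @param position Dipole location, metres (inside the conductor).
#' @param moment Dipole moment vector, A m.
#' @param sensor_position Field point, metres; must be farther from the
#'   origin than the dipole.
#' @param sensor_orientation Unit vector; the measured field component.
#' @return Scalar field component in tesla.
#' @export
dipole_lead <- function(position, moment, sensor_position,
                        sensor_orientation) {
  r0 <- as.numeric(position); Q <- as.numeric(moment)
  r <- as.numeric(sensor_position); e <- as.numeric(sensor_orientation)
  if (sqrt(sum(r^2)) <= sqrt(sum(r0^2)))
    stop("sensor must be farther from the conductor centre than the dipole",
         call. = FALSE)
  if (sum(r0^2) == 0) {
    warning("dipole at the conductor centre has an ambiguous radial ",
            "direction; returning zero field", call. = FALSE)
    return(0)
  }
  a_vec <- r - r0
  a <- sqrt(sum(a_vec^2)); rn <- sqrt(sum(r^2))
  F_ <- a * (rn * a + rn^2 - sum(r0 * r))
  gradF <- (a^2 / rn + sum(a_vec * r) / a + 2 * a + 2 * rn) * r -
    (a + 2 * rn + sum(a_vec * r) / a) * r0
  Qxr0 <- c(Q[2] * r0[3] - Q[3] * r0[2],
            Q[3] * r0[1] - Q[1] * r0[3],
            Q[1] * r0[2] - Q[2] * r0[1])
  B <- MU0 / (4 * pi * F_^2) * (F_ * Qxr0 - sum(Qxr0 * r) * gradF)
  sum(B * e)
}

# scalar magnetic potential of the spherical-conductor dipole field
# (B = -mu0 grad U outside the conductor); used as a test oracle
dipole_potential <- function(position, moment, r) {
  r0 <- as.numeric(position); Q <- as.numeric(moment); r <- as.numeric(r)
  a_vec <- r - r0
  a <- sqrt(sum(a_vec^2)); rn <- sqrt(sum(r^2))
  F_ <- a * (rn * a + rn^2 - sum(r0 * r))
  Qxr0 <- c(Q[2] * r0[3] - Q[3] * r0[2],
            Q[3] * r0[1] - Q[1] * r0[3],
            Q[1] * r0[2] - Q[2] * r0[1])
  -sum(Qxr0 * r) / (4 * pi * F_)
}

#' Lead-field matrix of an array for a dipole ensemble
#'
#' Entry (i, j) is the field (tesla) at sensor i per unit moment (1 A m) of
#' dipole j along its orientation.
#'
#' @param array A \code{\link{sensor_array}}; every sensor must lie outside
#'   the ensemble's source ball.
#' @param ensemble A \code{\link{sample_dipole_ensemble}} result.
#' @return m-by-p numeric matrix of class \code{lead_field}.
#' @export
leadfield <- function(array, ensemble) {
  stopifnot(inherits(array, "sensor_array"),
            inherits(ensemble, "dipole_ensemble"))
  sens_r <- sqrt(rowSums(array$positions^2))
  if (any(sens_r <= ensemble$source_radius))
    stop("all sensors must be outside the source ball", call. = FALSE)
  m <- array$m; p <- nrow(ensemble$positions)
  L <- matrix(0, m, p)
  for (j in seq_len(p)) {
    r0 <- ensemble$positions[j, ]
    Q <- ensemble$orientations[j, ]  # unit moment
    rr <- sqrt(sum(r0^2))
    if (rr == 0) next  # centre dipole: ambiguous radial direction, silent
    Qxr0 <- c(Q[2] * r0[3] - Q[3] * r0[2],
              Q[3] * r0[1] - Q[1] * r0[3],
              Q[1] * r0[2] - Q[2] * r0[1])
    rp <- array$positions
    a_vec <- sweep(rp, 2L, r0)
    a <- sqrt(rowSums(a_vec^2)); rn <- sqrt(rowSums(rp^2))
    r0_dot_r <- as.numeric(rp %*% r0)
    avr <- rowSums(a_vec * rp)
    F_ <- a * (rn * a + rn^2 - r0_dot_r)
    c1 <- a^2 / rn + avr / a + 2 * a + 2 * rn
    c2 <- a + 2 * rn + avr / a
    Qxr0_dot_r <- as.numeric(rp %*% Qxr0)
    # B_i = mu0/(4 pi F^2) (F Qxr0 - (Qxr0 . r) (c1 r - c2 r0))
    Bx <- F_ * Qxr0[1] - Qxr0_dot_r * (c1 * rp[, 1] - c2 * r0[1])
    By <- F_ * Qxr0[2] - Qxr0_dot_r * (c1 * rp[, 2] - c2 * r0[2])
    Bz <- F_ * Qxr0[3] - Qxr0_dot_r * (c1 * rp[, 3] - c2 * r0[3])
    scale <- MU0 / (4 * pi * F_^2)
    L[, j] <- scale * (Bx * array$orientations[, 1] +
                         By * array$orientations[, 2] +
                         Bz * array$orientations[, 3])
  }
  class(L) <- c("lead_field", class(L))
  L
}

#' Shannon channel information capacity
#'
#' \eqn{I = 1/2 \sum_i \log_2(\lambda_i / \sigma^2 + 1)} where
#' \eqn{\lambda_i} are the eigenvalues of the signal covariance
#' \eqn{L \Sigma L^T} and \eqn{\sigma} the sensor noise sd.
#'
#' @param L m-by-p lead-field matrix.
#' @param Sigma Source amplitude covariance: p-by-p positive-semidefinite
#'   matrix, or a length-p vector of diagonal variances, or a single scalar.
#' @param noise_sd Sensor noise standard deviation sigma, tesla (> 0).
#' @return Capacity in bits per sample.
#' @export
channel_capacity <- function(L, Sigma, noise_sd = 1e-14) {
  stopifnot(noise_sd > 0)
  L <- unclass(L)
  p <- ncol(L)
  if (is.matrix(Sigma)) {
    if (max(abs(Sigma - t(Sigma))) > 1e-12 * max(abs(Sigma), 1))
      stop("Sigma must be symmetric positive semidefinite", call. = FALSE)
    ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-10 * max(abs(ev), 1))
      stop("Sigma must be positive semidefinite", call. = FALSE)
    C <- L %*% Sigma %*% t(L)
  } else {
    s <- if (length(Sigma) == 1L) rep(as.numeric(Sigma), p) else as.numeric(Sigma)
    if (length(s) != p) stop("diagonal Sigma has wrong length", call. = FALSE)
    if (any(s < 0)) stop("Sigma must be positive semidefinite", call. = FALSE)
    C <- tcrossprod(L * rep(s, each = nrow(L)), L)
  }
  lam <- eigen((C + t(C)) / 2, symmetric = TRUE, only.values = TRUE)$values
  neg_tol <- 1e-12 * max(abs(lam), .Machine$double.xmin)
  if (min(lam) < -neg_tol)
    stop("signal covariance has a significantly negative eigenvalue",
         call. = FALSE)
  lam <- pmax(lam, 0)
  0.5 * sum(log2(lam / noise_sd^2 + 1))
}

#' Capacity of an array under the default random-dipole source model
#'
#' Convenience wrapper: builds (or reuses) a dipole ensemble and returns
#' \code{\link{channel_capacity}} of the array's lead field.
#'
#' @param array A \code{\link{sensor_array}}.
#' @param ensemble Optional \code{dipole_ensemble}; built from the remaining
#'   arguments when NULL.
#' @param n_dipoles,source_radius,total_rms_moment,seed Ensemble parameters
#'   (see \code{\link{sample_dipole_ensemble}}).
#' @param noise_sd Sensor noise sd, tesla.
#' @return Capacity in bits per sample.
#' @export
array_capacity <- function(array, ensemble = NULL, n_dipoles = 1000L,
                           source_radius = 0.07, total_rms_moment = 2e-8,
                           noise_sd = 1e-14, seed = 1L) {
  if (is.null(ensemble))
    ensemble <- sample_dipole_ensemble(n_dipoles, source_radius,
                                       total_rms_moment, seed)
  channel_capacity(leadfield(array, ensemble), ensemble$sigma_diag, noise_sd)
}
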