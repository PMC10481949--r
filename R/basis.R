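# Vector-spherical-harmonic (multipole) magnetic-field basis.
#
# Source-free magnetic fields in a shell free of currents can be written as
# gradients of harmonic scalar potentials.  The internal ("alpha") part uses
# potentials proportional to r^-(l+1) Y_lm and models fields of sources below
# the sensor shell (the brain); the external ("beta") part uses r^l Y_lm and
# models far-away interference sources.  This is the signal-space-separation
# (SSS) field model.
#
# Normalization convention (fixed, documented, part of the public contract):
# orthonormal real spherical harmonics built on associated Legendre functions
# that include the Condon-Shortley phase (as returned by pracma::legendre),
# with unit leading coefficients in the potentials:
#   internal potential V_lm(r) = r^-(l+1) * Y_lm(theta, phi)
#   external potential V_lm(r) = r^l     * Y_lm(theta, phi)
#   B_lm(r) = -grad V_lm(r)
# Y_lm real: m > 0 -> sqrt(2) N_lm P_l^m(cos th) cos(m phi),
#            m = 0 ->         N_l0 P_l^0(cos th),
#            m < 0 -> sqrt(2) N_l|m| P_l^|m|(cos th) sin(|m| phi),
# N_lm = sqrt((2l+1)/(4 pi) (l-|m|)!/(l+|m|)!).
# The noise-amplification metric is provably invariant under any fixed
# per-component rescaling of this convention (see noise_metric tests).

#' Multipole basis specification
#'
#' Defines a truncated vector-spherical-harmonics (VSH) expansion of the
#' magnetic field: internal (neuronal) components up to degree
#' \code{l_max_internal} and external (interference) components up to degree
#' \code{l_max_external}, expanded about \code{origin}.
#'
#' @param l_max_internal Internal degree cutoff (integer >= 1).
#' @param l_max_external External degree cutoff (integer >= 0; 0 disables the
#'   external model).
#' @param origin Expansion origin, metres (length-3 numeric).
#' @return An object of class \code{multipole_spec} with fields
#'   \code{l_max_internal}, \code{l_max_external}, \code{origin} and the
#'   derived component count \code{n_components}.
#' @examples
#' spec <- multipole_spec(10, 3)
#' spec$n_components   # 135
#' @export
multipole_spec <- function(l_max_internal, l_max_external = 0L,
                           origin = c(0, 0, 0)) {
  l_max_internal <- as.integer(l_max_internal)
  l_max_external <- as.integer(l_max_external)
  if (length(l_max_internal) != 1L || is.na(l_max_internal) ||
      l_max_internal < 1L)
    stop("'l_max_internal' must be a single integer >= 1", call. = FALSE)
  if (length(l_max_external) != 1L || is.na(l_max_external) ||
      l_max_external < 0L)
    stop("'l_max_external' must be a single integer >= 0", call. = FALSE)
  origin <- as.numeric(origin)
  if (length(origin) != 3L || anyNA(origin))
    stop("'origin' must be a numeric 3-vector", call. = FALSE)
  structure(
    list(l_max_internal = l_max_internal,
         l_max_external = l_max_external,
         origin = origin,
         n_components = component_count(l_max_internal, l_max_external)),
    class = "multipole_spec")
}

#' @export
print.multipole_spec <- function(x, ...) {
  cat("Multipole (VSH) basis: internal L =", x$l_max_internal,
      "| external L =", x$l_max_external,
      "| n =", x$n_components, "components\n")
  cat("  origin:", paste(signif(x$origin, 4), collapse = ", "), "m\n")
  invisible(x)
}

#' Number of components in a truncated VSH expansion
#'
#' The internal part contributes \eqn{L_a(L_a+2)} components (degrees
#' \eqn{1..L_a}, orders \eqn{-l..l}) and the external part \eqn{L_b(L_b+2)}.
#'
#' @param l_max_internal,l_max_external Degree cutoffs; alternatively pass a
#'   \code{multipole_spec} as the first argument.
#' @return Integer component count.
#' @examples
#' component_count(10, 3)  # 135
#' @export
component_count <- function(l_max_internal, l_max_external = 0L) {
  if (inherits(l_max_internal, "multipole_spec"))
    return(l_max_internal$n_components)
  la <- as.integer(l_max_internal); lb <- as.integer(l_max_external)
  if (is.na(la) || la < 1L) stop("internal cutoff must be >= 1", call. = FALSE)
  if (is.na(lb) || lb < 0L) stop("external cutoff must be >= 0", call. = FALSE)
  la * (la + 2L) + lb * (lb + 2L)
}

#' Canonical component ordering of the basis
#'
#' All internal components first (degree l ascending, order m ascending within
#' each degree), then all external components likewise.  This ordering defines
#' the columns of the measurement matrix S and of every coefficient vector.
#'
#' @param spec A \code{multipole_spec}.
#' @return A data.frame with columns \code{part} ("internal"/"external"),
#'   \code{l}, \code{m} and \code{column}.
#' @export
basis_index <- function(spec) {
  stopifnot(inherits(spec, "multipole_spec"))
  blocks <- list()
  for (part in c("internal", "external")) {
    lmax <- if (part == "internal") spec$l_max_internal else spec$l_max_external
    if (lmax >= 1L)
      for (l in seq_len(lmax))
        blocks[[length(blocks) + 1L]] <-
          data.frame(part = part, l = l, m = seq.int(-l, l))
  }
  out <- do.call(rbind, blocks)
  out$column <- seq_len(nrow(out))
  out
}

#' Selector matrices for internal/external coefficients
#'
#' Diagonal 0/1 matrices picking the internal (alpha) or external (beta)
#' block of a coefficient vector; \code{I_alpha + I_beta = I} and
#' \code{I_alpha I_beta = 0}.
#'
#' @param spec A \code{multipole_spec}.
#' @param part \code{"internal"} or \code{"external"}.
#' @return An n-by-n diagonal matrix.
#' @export
selector_matrix <- function(spec, part = c("internal", "external")) {
  part <- match.arg(part)
  diag(as.numeric(basis_index(spec)$part == part))
}

# logical mask of internal components in canonical order
internal_mask <- function(spec) {
  n_int <- spec$l_max_internal * (spec$l_max_internal + 2L)
  seq_len(spec$n_components) <= n_int
}

# Evaluate all basis fields at a set of points.
#
# points: k x 3 matrix (metres). Returns an array of dim c(3, n, k):
# arr[, j, i] is the Cartesian field of component j at point i.
# Points on (or within ~1e-10 rad of) the polar axis are displaced off the
# axis by clamping the polar angle, which keeps the spherical-gradient
# formulas finite; the displacement is far below any physical scale used here.
basis_field_array <- function(points, spec) {
  stopifnot(inherits(spec, "multipole_spec"))
  points <- rbind(points)  # tolerate a single 3-vector
  if (ncol(points) != 3L) stop("'points' must be k x 3", call. = FALSE)
  k <- nrow(points)
  rel <- sweep(points, 2L, spec$origin)
  r <- sqrt(rowSums(rel^2))
  if (any(r < 1e-300))
    stop("basis fields are singular at the expansion origin", call. = FALSE)
  theta <- acos(pmin(1, pmax(-1, rel[, 3] / r)))
  eps_pole <- 1e-10
  theta <- pmin(pmax(theta, eps_pole), pi - eps_pole)
  phi <- atan2(rel[, 2], rel[, 1])
  ct <- cos(theta); st <- sin(theta)
  cp <- cos(phi);   sp <- sin(phi)

  # spherical unit vectors at each point (k x 3 each)
  rhat <- cbind(st * cp, st * sp, ct)
  that <- cbind(ct * cp, ct * sp, -st)
  phat <- cbind(-sp, cp, 0)

  idx <- basis_index(spec)
  arr <- array(0, dim = c(3L, spec$n_components, k))
  lmax <- max(spec$l_max_internal, spec$l_max_external)

  # associated Legendre P_l^m(cos theta) for all l, m (Condon-Shortley phase)
  P <- vector("list", lmax)
  for (l in seq_len(lmax)) P[[l]] <- rbind(pracma::legendre(l, ct))
  P0 <- rbind(rep(1, k))  # degree 0

  for (j in seq_len(spec$n_components)) {
    part <- idx$part[j]; l <- idx$l[j]; m <- idx$m[j]
    am <- abs(m)
    Plm <- P[[l]][am + 1L, ]
    Plm_prev <- if (l == 1L) {
      if (am == 0L) P0[1L, ] else rep(0, k)
    } else if (am > l - 1L) rep(0, k) else P[[l - 1L]][am + 1L, ]
    Nlm <- sqrt((2 * l + 1) / (4 * pi) *
                  exp(lgamma(l - am + 1) - lgamma(l + am + 1)))
    if (am > 0L) Nlm <- Nlm * sqrt(2)
    trig  <- if (m > 0L) cos(m * phi) else if (m < 0L) sin(am * phi) else rep(1, k)
    # d(trig)/dphi
    dtrig <- if (m > 0L) -m * sin(m * phi) else if (m < 0L) am * cos(am * phi)
             else rep(0, k)
    # dP_l^m(cos th)/dtheta = (l ct P_l^m - (l+m) P_{l-1}^m) / st
    dPdth <- (l * ct * Plm - (l + am) * Plm_prev) / st
    Y <- Nlm * Plm * trig
    dYdth <- Nlm * dPdth * trig
    dYdph_over_st <- Nlm * Plm * dtrig / st
    if (part == "internal") {
      rf <- r^(-(l + 2))
      Br <- (l + 1) * rf * Y
      Bt <- -rf * dYdth
      Bp <- -rf * dYdph_over_st
    } else {
      rf <- r^(l - 1)
      Br <- -l * rf * Y
      Bt <- -rf * dYdth
      Bp <- -rf * dYdph_over_st
    }
    arr[, j, ] <- t(Br * rhat + Bt * that + Bp * phat)
  }
  arr
}

#' Evaluate one basis field component
#'
#' Cartesian magnetic field (per unit coefficient) of a single internal or
#' external VSH component at point \code{r}.
#'
#' @param spec A \code{multipole_spec}.
#' @param column Column index in the canonical ordering (see
#'   \code{\link{basis_index}}), or alternatively give \code{part}, \code{l},
#'   \code{m}.
#' @param r Evaluation point, metres (length-3).
#' @param part,l,m Component identification used when \code{column} is NULL.
#' @return Length-3 numeric field vector.
#' @export
basis_field <- function(spec, r, column = NULL, part = NULL, l = NULL, m = NULL) {
  if (is.null(column)) {
    idx <- basis_index(spec)
    column <- idx$column[idx$part == part & idx$l == l & idx$m == m]
    if (length(column) != 1L) stop("component not found in basis", call. = FALSE)
  }
  basis_field_array(rbind(as.numeric(r)), spec)[, column, 1L]
}

#' Interpolation row vector s(r, e)
#'
#' Row of basis-field projections for a (virtual) sensor at location \code{r}
#' with unit orientation \code{e}: entry j equals \code{e . B_j(r)}.
#'
#' @param r Location, metres (length-3).
#' @param e Unit orientation (length-3; must be unit norm within 1e-9).
#' @param spec A \code{multipole_spec}.
#' @return Numeric vector of length \code{spec$n_components}.
#' @export
basis_row <- function(r, e, spec) {
  e <- as.numeric(e)
  if (abs(sqrt(sum(e^2)) - 1) > 1e-9)
    stop("orientation 'e' must be a unit vector (|norm - 1| <= 1e-9)",
         call. = FALSE)
  arr <- basis_field_array(rbind(as.numeric(r)), spec)
  as.numeric(e %*% arr[, , 1L])
}

#' Measurement matrix S of a sensor array
#'
#' Row i is the basis row of sensor i: the array's linear response
#' \code{phi = S x} to a coefficient vector \code{x}.
#'
#' @param array A \code{\link{sensor_array}}.
#' @param spec A \code{multipole_spec}.
#' @return An m-by-n numeric matrix.
#' @export
basis_matrix <- function(array, spec) {
  stopifnot(inherits(array, "sensor_array"))
  arr <- basis_field_array(array$positions, spec)
  m <- nrow(array$positions)
  S <- matrix(0, m, spec$n_components)
  for (i in seq_len(m)) S[i, ] <- array$orientations[i, ] %*% arr[, , i]
  S
}

#' Field of a coefficient vector
#'
#' Evaluates \code{B(r) = sum_j x_j B_j(r)} for coefficients \code{x} in the
#' canonical component ordering.
#'
#' @param x Numeric coefficient vector of length \code{spec$n_components}.
#' @param r Evaluation point, metres.
#' @param spec A \code{multipole_spec}.
#' @return Length-3 Cartesian field vector.
#' @export
field_at <- function(x, r, spec) {
  x <- as.numeric(x)
  if (length(x) != spec$n_components)
    stop("coefficient vector has wrong length", call. = FALSE)
  arr <- basis_field_array(rbind(as.numeric(r)), spec)
  as.numeric(arr[, , 1L] %*% x)
}

# scalar potential of one component (used by finite-difference test oracles)
basis_potential <- function(spec, r, column) {
  idx <- basis_index(spec)
  part <- idx$part[column]; l <- idx$l[column]; m <- idx$m[column]
  rel <- as.numeric(r) - spec$origin
  rr <- sqrt(sum(rel^2))
  theta <- acos(pmin(1, pmax(-1, rel[3] / rr)))
  phi <- atan2(rel[2], rel[1])
  am <- abs(m)
  Plm <- pracma::legendre(l, cos(theta))[am + 1L]
  Nlm <- sqrt((2 * l + 1) / (4 * pi) *
                exp(lgamma(l - am + 1) - lgamma(l + am + 1)))
  if (am > 0L) Nlm <- Nlm * sqrt(2)
  trig <- if (m > 0L) cos(m * phi) else if (m < 0L) sin(am * phi) else 1
  Y <- Nlm * Plm * trig
  if (part == "internal") rr^(-(l + 1)) * Y else rr^l * Y
}
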