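# Helmet-shaped sampling volumes and quasi-uniform point sets.
#
# Coordinate conventions (shared by the whole package): right-handed
# Cartesian axes with the origin at the helmet's sphere centre, +z up through
# the hemisphere apex, +x through the face opening; polar angle theta from
# +z, azimuth phi from +x.  SI units throughout.

#' Helmet surface (2D sampling volume)
#'
#' A hemisphere of radius \code{radius} (z >= 0) joined to a cylindrical band
#' of the same radius extending down to \code{-cylinder_height}, with an
#' azimuthal opening sector of width \code{opening_angle} (centred on +x)
#' removed from the band for the face.
#'
#' @param radius Sphere/cylinder radius R, metres.
#' @param cylinder_height Height of the band below the equator, metres.
#' @param opening_angle Azimuthal width of the face opening, radians.
#' @return An object of class \code{helmet_surface}.
#' @export
helmet_surface <- function(radius = 0.15, cylinder_height = 0.15,
                           opening_angle = pi / 2) {
  stopifnot(radius > 0, cylinder_height >= 0,
            opening_angle >= 0, opening_angle <= 2 * pi)
  structure(list(radius = radius, cylinder_height = cylinder_height,
                 opening_angle = opening_angle),
            class = c("helmet_surface", "sampling_volume"))
}

#' Helmet shell (3D sampling volume)
#'
#' The closed region between two helmet surfaces of radii
#' \code{inner_radius} and \code{outer_radius} sharing the same cylinder
#' height and face opening.
#'
#' @param inner_radius,outer_radius Shell radii, metres.
#' @param cylinder_height Height of the band below the equator, metres.
#' @param opening_angle Azimuthal width of the face opening, radians.
#' @return An object of class \code{helmet_shell3d}.
#' @export
helmet_shell3d <- function(inner_radius = 0.15, outer_radius = 0.25,
                           cylinder_height = 0.15, opening_angle = pi / 2) {
  stopifnot(inner_radius > 0, outer_radius > inner_radius,
            cylinder_height >= 0, opening_angle >= 0, opening_angle <= 2 * pi)
  structure(list(inner_radius = inner_radius, outer_radius = outer_radius,
                 cylinder_height = cylinder_height,
                 opening_angle = opening_angle),
            class = c("helmet_shell3d", "sampling_volume"))
}

#' @export
print.helmet_surface <- function(x, ...) {
  cat(sprintf("Helmet surface: R = %g m, band height %g m, opening %.3g rad\n",
              x$radius, x$cylinder_height, x$opening_angle))
  invisible(x)
}

#' @export
print.helmet_shell3d <- function(x, ...) {
  cat(sprintf(
    "Helmet shell: radii [%g, %g] m, band height %g m, opening %.3g rad\n",
    x$inner_radius, x$outer_radius, x$cylinder_height, x$opening_angle))
  invisible(x)
}

# TRUE when azimuth phi falls in the face-opening sector (centred on +x)
in_opening <- function(phi, opening_angle) {
  d <- abs(((phi + pi) %% (2 * pi)) - pi)  # wrapped distance to phi = 0
  d < opening_angle / 2 - 1e-12
}

#' Membership test for sampling volumes
#'
#' @param volume A \code{helmet_surface} or \code{helmet_shell3d}.
#' @param p Point, metres (length-3), or a k-by-3 matrix of points.
#' @param tol Boundary tolerance, metres: points within \code{tol} of the
#'   admissible set count as inside.
#' @return Logical (vector for a matrix of points).
#' @export
volume_contains <- function(volume, p, tol = 1e-9) UseMethod("volume_contains")

#' @export
volume_contains.helmet_surface <- function(volume, p, tol = 1e-9) {
  p <- rbind(p)
  r <- sqrt(rowSums(p^2))
  rho <- sqrt(p[, 1]^2 + p[, 2]^2)
  phi <- atan2(p[, 2], p[, 1])
  on_hemi <- abs(r - volume$radius) <= tol & p[, 3] >= -tol
  on_band <- abs(rho - volume$radius) <= tol &
    p[, 3] <= tol & p[, 3] >= -volume$cylinder_height - tol &
    !in_opening(phi, volume$opening_angle)
  on_hemi | on_band
}

#' @export
volume_contains.helmet_shell3d <- function(volume, p, tol = 1e-9) {
  p <- rbind(p)
  r <- sqrt(rowSums(p^2))
  rho <- sqrt(p[, 1]^2 + p[, 2]^2)
  phi <- atan2(p[, 2], p[, 1])
  in_hemi <- r >= volume$inner_radius - tol & r <= volume$outer_radius + tol &
    p[, 3] >= -tol
  in_band <- rho >= volume$inner_radius - tol &
    rho <= volume$outer_radius + tol &
    p[, 3] <= tol & p[, 3] >= -volume$cylinder_height - tol &
    !in_opening(phi, volume$opening_angle)
  in_hemi | in_band
}

#' Area of a helmet surface
#'
#' Closed form: hemisphere \eqn{2 \pi R^2} plus band
#' \eqn{(2\pi - \gamma) R h} with the opening sector removed.
#'
#' @param surface A \code{helmet_surface}.
#' @return Area in square metres.
#' @examples
#' surface_area(helmet_surface())  # ~0.247 m^2
#' @export
surface_area <- function(surface) {
  stopifnot(inherits(surface, "helmet_surface"))
  2 * pi * surface$radius^2 +
    (2 * pi - surface$opening_angle) * surface$radius * surface$cylinder_height
}

# Map cumulative area a (measured from the apex over the FULL surface of
# revolution, opening included) to a point on the meridian at azimuth phi.
helmet_point_full <- function(surface, a, phi) {
  R <- surface$radius
  a_hemi <- 2 * pi * R^2
  hemi <- a <= a_hemi
  ct <- 1 - pmin(a, a_hemi) / a_hemi  # hemisphere: a = 2 pi R^2 (1 - cos th)
  st <- sqrt(pmax(0, 1 - ct^2))
  d <- pmax(0, a - a_hemi) / (2 * pi * R)  # band depth below equator
  x <- ifelse(hemi, R * st * cos(phi), R * cos(phi))
  y <- ifelse(hemi, R * st * sin(phi), R * sin(phi))
  z <- ifelse(hemi, R * ct, -d)
  cbind(x, y, z)
}

#' Quasi-uniform spiral point set on a helmet surface
#'
#' Lays a single generalized (golden-angle) spiral over the helmet treated as
#' a surface of revolution parameterized by cumulative area, then rejects
#' candidates whose azimuth falls in the band's face opening, iteratively
#' raising the candidate count until exactly \code{count} points survive.
#' Deterministic for fixed inputs.
#'
#' @param surface A \code{helmet_surface}.
#' @param count Number of points (>= 4).
#' @return A \code{count}-by-3 matrix of points on the surface.
#' @export
spiral_points <- function(surface, count) {
  count <- as.integer(count)
  if (is.na(count) || count < 4L) stop("'count' must be >= 4", call. = FALSE)
  R <- surface$radius; h <- surface$cylinder_height
  gam <- surface$opening_angle
  a_full <- 2 * pi * R^2 + 2 * pi * R * h
  a_adm  <- surface_area(surface)
  ga <- pi * (3 - sqrt(5))  # golden angle

  gen <- function(M) {
    k <- seq_len(M)
    a <- (k - 0.5) / M * a_full
    phi <- (k * ga) %% (2 * pi)
    band <- a > 2 * pi * R^2
    keep <- !(band & in_opening(phi, gam))
    helmet_point_full(surface, a[keep], phi[keep])
  }

  m0 <- max(count, floor(count * a_full / a_adm) - 5L)
  for (M in m0:(m0 + 4L * count + 100L)) {
    pts <- gen(M)
    if (nrow(pts) == count) return(unname(pts))
    if (nrow(pts) > count) break
  }
  # candidate counts jump past an exact hit: drop the trailing extras from
  # the smallest overshooting set (still deterministic)
  unname(pts[seq_len(count), , drop = FALSE])
}

#' Outward surface normal of a helmet surface
#'
#' Radial from the origin on the hemisphere; radial from the cylinder axis on
#' the band.  The two agree on the equator seam.
#'
#' @param surface A \code{helmet_surface}.
#' @param p Point on the surface (within 1e-6 m), or k-by-3 matrix.
#' @return Unit normal(s); k-by-3 matrix for matrix input, else length-3.
#' @export
surface_normal <- function(surface, p) {
  single <- is.null(dim(p))
  p <- rbind(p)
  if (!all(volume_contains(surface, p, tol = 1e-6)))
    stop("point is not on the helmet surface (tolerance 1e-6 m)",
         call. = FALSE)
  hemi <- p[, 3] > 1e-9
  n <- p
  n[!hemi, 3] <- 0
  n <- n / sqrt(rowSums(n^2))
  if (single) as.numeric(n) else unname(n)
}

#' Sensor array
#'
#' An ordered set of point magnetometers, each with a position (metres) and a
#' unit orientation along which it measures the field.
#'
#' @param positions m-by-3 numeric matrix, metres.
#' @param orientations m-by-3 numeric matrix; rows are normalized, and rows
#'   whose norm deviates from 1 by more than \code{norm_tol} are rejected.
#' @param norm_tol Maximum allowed deviation of orientation norms from 1
#'   before normalization.
#' @return An object of class \code{sensor_array} with fields
#'   \code{positions}, \code{orientations} and \code{m}.
#' @export
sensor_array <- function(positions, orientations, norm_tol = 1e-3) {
  positions <- rbind(positions); orientations <- rbind(orientations)
  if (ncol(positions) != 3L || ncol(orientations) != 3L ||
      nrow(positions) != nrow(orientations) || nrow(positions) < 1L)
    stop("positions and orientations must be matching m x 3 matrices (m >= 1)",
         call. = FALSE)
  if (anyNA(positions) || anyNA(orientations))
    stop("sensor coordinates must be finite", call. = FALSE)
  nrm <- sqrt(rowSums(orientations^2))
  bad <- which(abs(nrm - 1) > norm_tol)
  if (length(bad))
    stop("orientation norm deviates from 1 by more than ", norm_tol,
         " for sensor(s) ", paste(bad, collapse = ", "), call. = FALSE)
  structure(list(positions = unname(positions),
                 orientations = unname(orientations / nrm),
                 m = nrow(positions)),
            class = "sensor_array")
}

#' @export
print.sensor_array <- function(x, ...) {
  cat("Sensor array with", x$m, "point sensors\n")
  invisible(x)
}

#' Uniformly-spaced radial array
#'
#' \code{count} sensors quasi-uniformly spread over a helmet surface, each
#' oriented along the outward surface normal: the reference non-optimized
#' array design.
#'
#' @param surface A \code{helmet_surface}.
#' @param count Number of sensors N.
#' @return A \code{\link{sensor_array}}.
#' @export
radial_array <- function(surface, count) {
  pts <- spiral_points(surface, count)
  sensor_array(pts, surface_normal(surface, pts))
}

#' Discretization grid of a sampling volume
#'
#' For a 2D surface: \code{n_points} spiral points on the surface (default
#' 1000).  For a 3D shell: \code{n_shells} concentric helmet surfaces with
#' radii evenly spaced over [inner, outer] (endpoints included), each carrying
#' \code{points_per_shell} spiral points (defaults 5 x 500 = 2500).
#'
#' @param volume A \code{helmet_surface} or \code{helmet_shell3d}.
#' @param n_points Points for the 2D grid.
#' @param n_shells,points_per_shell 3D grid discretization.
#' @return An object of class \code{sampling_grid} with a \code{points}
#'   matrix and density metadata.
#' @export
sampling_grid <- function(volume, n_points = 1000L, n_shells = 5L,
                          points_per_shell = 500L) {
  if (inherits(volume, "helmet_surface")) {
    pts <- spiral_points(volume, n_points)
    meta <- list(type = "surface", n_points = n_points,
                 area_per_point = surface_area(volume) / n_points)
  } else if (inherits(volume, "helmet_shell3d")) {
    radii <- seq(volume$inner_radius, volume$outer_radius,
                 length.out = n_shells)
    pts <- do.call(rbind, lapply(radii, function(R)
      spiral_points(helmet_surface(R, volume$cylinder_height,
                                   volume$opening_angle),
                    points_per_shell)))
    meta <- list(type = "shell3d", n_shells = n_shells,
                 points_per_shell = points_per_shell, shell_radii = radii)
  } else stop("unsupported volume type", call. = FALSE)
  structure(list(points = pts, volume = volume, meta = meta),
            class = "sampling_grid")
}

#' @export
print.sampling_grid <- function(x, ...) {
  cat("Sampling grid:", nrow(x$points), "points (", x$meta$type, ")\n")
  invisible(x)
}
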