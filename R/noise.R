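# Interpolation-noise propagation and the figure-of-merit q.
#
# With measurements phi_hat = S x + noise (i.i.d. Gaussian, sd sigma), the
# neuronal field component at any (r, e) is estimated by the virtual sensor
#   phi_a(r, e) = s_{r,e} I_a S^+ phi_hat,
# where S^+ is the Moore-Penrose pseudoinverse and I_a selects the internal
# coefficients.  The estimate's noise sd is ||s_{r,e} I_a S^+|| sigma; the
# ratio to sigma is the noise amplification, and its maximum over the
# sampling volume and all orientations is the scalar figure-of-merit q.

# SVD-based Moore-Penrose pseudoinverse with relative singular-value cutoff
# max(m, n) * eps * sigma_max (minimum-norm solution when rank deficient).
#
# The raw VSH columns of S span ~10 orders of magnitude (internal components
# scale as r^-(l+2), external as r^(l-1)), which would make a plain relative
# cutoff discard genuinely informative components.  The pseudoinverse is
# therefore computed on a column-equilibrated copy S D^-1 (D = column norms)
# and mapped back as S^+ = D^-1 (S D^-1)^+; for full column rank this equals
# the Moore-Penrose inverse exactly (the same per-component diagonal
# rescaling invariance that makes q independent of the basis normalization),
# and the rank decision becomes scale-invariant.
# Rank is decided on the equilibrated spectrum (cutoff above).  For full
# column rank the pseudoinverse is computed from the equilibrated
# factorization (mathematically identical, numerically accurate); when rank
# deficient, the minimum-norm pseudoinverse is computed in the raw basis
# convention, retaining the top-rank singular triplets, which matches what
# reference SSS pipelines produce for underdetermined arrays.
mp_pinv <- function(S) {
  d_col <- sqrt(colSums(S^2))
  d_col[d_col == 0] <- 1
  Se <- sweep(S, 2L, d_col, "/")
  sv <- svd(Se)
  tol <- max(dim(S)) * .Machine$double.eps * sv$d[1]
  rank <- sum(sv$d > tol)
  if (rank == 0L) stop("degenerate (all-zero) measurement matrix",
                       call. = FALSE)
  if (rank == ncol(S)) {
    pinv <- (sv$v %*% (t(sv$u) / sv$d)) / d_col
  } else {
    svr <- svd(S)
    k <- seq_len(rank)
    pinv <- svr$v[, k, drop = FALSE] %*%
      (t(svr$u[, k, drop = FALSE]) / svr$d[k])
  }
  list(pinv = pinv, rank = rank)
}

#' Internal-coefficient interpolation operator
#'
#' Returns \code{I_a S^+}: the n-by-m operator mapping measurements to
#' estimated internal (neuronal) coefficients; rows belonging to external
#' components are identically zero.  The pseudoinverse is SVD-based with
#' relative cutoff \code{max(m,n) * eps * sigma_max}; rank-deficient matrices
#' yield the minimum-norm solution and the numerical rank is attached as
#' attribute \code{"rank"}.
#'
#' @param S m-by-n measurement matrix (see \code{\link{basis_matrix}}).
#' @param spec The \code{multipole_spec} whose ordering defines S's columns.
#' @return n-by-m matrix with attribute \code{"rank"}.
#' @export
interpolation_operator <- function(S, spec) {
  stopifnot(ncol(S) == spec$n_components)
  pi_ <- mp_pinv(S)
  P <- pi_$pinv
  P[!internal_mask(spec), ] <- 0
  attr(P, "rank") <- pi_$rank
  P
}

#' Virtual-sensor estimate of the neuronal field component
#'
#' Estimates the internal-field reading a sensor at (\code{r}, \code{e})
#' would produce, from the actual array's (noisy) measurements.  Exact when
#' the measurements are noise-free, the field lies in the internal basis and
#' S has full column rank.
#'
#' @param measurement Length-m numeric measurement vector (tesla).
#' @param r Virtual sensor location, metres.
#' @param e Virtual sensor unit orientation.
#' @param S m-by-n measurement matrix of the real array.
#' @param spec The \code{multipole_spec}.
#' @param operator Optional precomputed \code{\link{interpolation_operator}}.
#' @return Scalar estimate, tesla.
#' @export
virtual_sensor <- function(measurement, r, e, S, spec, operator = NULL) {
  measurement <- as.numeric(measurement)
  if (length(measurement) != nrow(S))
    stop("measurement length does not match the number of sensors",
         call. = FALSE)
  if (is.null(operator)) operator <- interpolation_operator(S, spec)
  as.numeric(basis_row(r, e, spec) %*% (operator %*% measurement))
}

#' Noise amplification at a location-orientation pair
#'
#' \code{||s_{r,e} I_a S^+||}: the factor by which i.i.d. sensor noise of sd
#' sigma is amplified in the virtual-sensor estimate at (\code{r}, \code{e}).
#' Independent of sigma itself.
#'
#' @inheritParams virtual_sensor
#' @return Nonnegative scalar.
#' @export
noise_amp_at <- function(r, e, S, spec, operator = NULL) {
  if (is.null(operator)) operator <- interpolation_operator(S, spec)
  sqrt(sum(as.numeric(basis_row(r, e, spec) %*% operator)^2))
}

#' Worst-case noise amplification at a point
#'
#' Maximum of \code{\link{noise_amp_at}} over all unit orientations,
#' computed exactly as the largest singular value of \code{F(r) I_a S^+},
#' where the rows of the 3-by-n matrix \code{F(r)} are the Cartesian
#' components of the basis fields at \code{r}.
#'
#' @inheritParams virtual_sensor
#' @return Nonnegative scalar.
#' @export
max_noise_amp_at_point <- function(r, S, spec, operator = NULL) {
  if (is.null(operator)) operator <- interpolation_operator(S, spec)
  Fr <- basis_field_array(rbind(as.numeric(r)), spec)[, , 1L]
  svd(Fr %*% operator, nu = 0, nv = 0)$d[1]
}

# Largest eigenvalue of symmetric 3x3 matrices, vectorized over rows of the
# six unique entries (a11, a22, a33, a12, a13, a23). Trigonometric closed form.
max_eig_sym3 <- function(a11, a22, a33, a12, a13, a23) {
  q <- (a11 + a22 + a33) / 3
  p2 <- (a11 - q)^2 + (a22 - q)^2 + (a33 - q)^2 +
    2 * (a12^2 + a13^2 + a23^2)
  p <- sqrt(pmax(p2, 0) / 6)
  b11 <- a11 - q; b22 <- a22 - q; b33 <- a33 - q
  detB <- b11 * (b22 * b33 - a23^2) - a12 * (a12 * b33 - a23 * a13) +
    a13 * (a12 * a23 - b22 * a13)
  r <- ifelse(p > 0, detB / (2 * p^3), 0)
  r <- pmin(1, pmax(-1, r))
  lam <- q + 2 * p * cos(acos(r) / 3)
  ifelse(p2 <= 0, q, lam)
}

# Precompute the stacked grid basis-field matrix (3G x n); reusable across
# arrays because it depends only on the grid and the basis.
grid_field_matrix <- function(grid, spec) {
  arr <- basis_field_array(grid$points, spec)       # 3 x n x G
  G <- dim(arr)[3]
  m <- matrix(aperm(arr, c(1, 3, 2)), nrow = 3L * G,
              ncol = spec$n_components)
  m
}

#' Noise-amplification field and figure-of-merit q
#'
#' Evaluates the worst-case (over orientation) noise amplification at every
#' grid point of the sampling volume; \code{q} is the maximum over the grid
#' and \code{mean_amp} the arithmetic mean of the per-point worst cases.
#'
#' @param array A \code{\link{sensor_array}}.
#' @param spec A \code{\link{multipole_spec}}.
#' @param grid A \code{\link{sampling_grid}}.
#' @param grid_fields Optional precomputed \code{grid_field_matrix(grid,
#'   spec)} to reuse across repeated evaluations (the grid fields do not
#'   depend on the array).
#' @param S Optional precomputed measurement matrix.
#' @return An object of class \code{noise_amp_field}: list with
#'   \code{per_point_amp}, \code{q}, \code{mean_amp}, \code{rank},
#'   \code{rank_deficient}, \code{m} and the grid.
#' @export
figure_of_merit <- function(array, spec, grid, grid_fields = NULL, S = NULL) {
  stopifnot(inherits(grid, "sampling_grid"))
  if (is.null(S)) S <- basis_matrix(array, spec)
  P <- interpolation_operator(S, spec)
  rank <- attr(P, "rank")
  if (rank < spec$n_components)
    warning(sprintf(
      "measurement matrix is rank deficient (rank %d < n = %d); ",
      rank, spec$n_components),
      "q computed with the minimum-norm pseudoinverse", call. = FALSE)
  if (is.null(grid_fields)) grid_fields <- grid_field_matrix(grid, spec)
  G <- nrow(grid$points)
  A <- grid_fields %*% P                          # (3G) x m
  i1 <- seq(1L, 3L * G, by = 3L)
  A1 <- A[i1, , drop = FALSE]
  A2 <- A[i1 + 1L, , drop = FALSE]
  A3 <- A[i1 + 2L, , drop = FALSE]
  amp <- sqrt(pmax(0, max_eig_sym3(
    rowSums(A1 * A1), rowSums(A2 * A2), rowSums(A3 * A3),
    rowSums(A1 * A2), rowSums(A1 * A3), rowSums(A2 * A3))))
  structure(list(per_point_amp = amp,
                 q = max(amp),
                 mean_amp = mean(amp),
                 rank = rank,
                 rank_deficient = rank < spec$n_components,
                 m = nrow(S),
                 spec = spec,
                 grid = grid),
            class = "noise_amp_field")
}

#' @export
print.noise_amp_field <- function(x, ...) {
  cat(sprintf(
    "Noise amplification over %d grid points: q = %.4g, mean = %.4g%s\n",
    length(x$per_point_amp), x$q, x$mean_amp,
    if (x$rank_deficient) sprintf(" [rank deficient: %d]", x$rank) else ""))
  invisible(x)
}

#' Export a noise-amplification map
#'
#' Writes a tab-separated table (x, y, z, amp) with a header recording the
#' basis cutoffs, sensor count and the q / mean summaries.
#'
#' @param field A \code{noise_amp_field} from \code{\link{figure_of_merit}}.
#' @param path Output file path.
#' @export
write_noise_map <- function(field, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(
    "# L_internal=%d L_external=%d m=%d q=%.10g mean_amp=%.10g",
    field$spec$l_max_internal, field$spec$l_max_external, field$m,
    field$q, field$mean_amp), con)
  writeLines("x\ty\tz\tamp", con)
  df <- cbind(field$grid$points, field$per_point_amp)
  utils::write.table(df, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
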