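# Shared fixtures: everything is generated in code, no stored data.

# random admissible array on a sampling volume, via the optimizer's
# parameterization (uniform in the bounded parameter box)
random_array <- function(m, volume = helmet_surface()) {
  per <- if (inherits(volume, "helmet_shell3d")) 5L else 4L
  hi <- if (per == 5L) c(1, 1, 1, pi, 2 * pi) else c(1, 1, pi, 2 * pi)
  par <- as.numeric(t(matrix(stats::runif(per * m), ncol = per) %*% diag(hi)))
  decode_array(par, volume)
}

# random unit 3-vector(s)
random_unit <- function(k = 1L) {
  v <- matrix(stats::rnorm(3L * k), ncol = 3L)
  v <- v / sqrt(rowSums(v^2))
  if (k == 1L) as.numeric(v) else v
}

# quasi-uniform unit directions (Fibonacci sphere) for brute-force
# orientation maximization oracles
fibonacci_directions <- function(n) {
  k <- seq_len(n)
  z <- 1 - (2 * k - 1) / n
  st <- sqrt(pmax(0, 1 - z^2))
  phi <- k * pi * (3 - sqrt(5))
  cbind(st * cos(phi), st * sin(phi), z)
}

# small default fixtures used across files
small_spec <- function() multipole_spec(3, 1)   # n = 18
small_surface <- function() helmet_surface()
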