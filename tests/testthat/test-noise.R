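# Pseudoinverse interpolation, noise amplification and the figure-of-merit.

test_that("interpolation operator: orthogonal S inverts, external rows vanish", {
  spec <- multipole_spec(2, 0)           # n = 8, all-internal selector
  n <- spec$n_components
  Q <- qr.Q(qr(matrix(rnorm(n * n), n)))  # random orthogonal
  P <- interpolation_operator(Q, spec)
  expect_equal(unname(P), t(Q), tolerance = 1e-12, ignore_attr = TRUE)

  spec2 <- multipole_spec(2, 1)           # 8 internal + 3 external
  set.seed(31)
  S <- matrix(rnorm(20 * spec2$n_components), 20)
  P2 <- interpolation_operator(S, spec2)
  expect_equal(P2[9:11, ], matrix(0, 3, 20))
  # pseudoinverse identity on the internal block
  Ia <- selector_matrix(spec2, "internal")
  expect_equal(P2 %*% S, Ia %*% MASS::ginv(S) %*% S, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_lt(max(abs(P2 %*% S - Ia)), 1e-10)
  expect_error(interpolation_operator(matrix(0, 4, spec2$n_components),
                                      spec2), "degenerate")
})

test_that("virtual sensors reproduce internal fields exactly and reject external ones", {
  spec <- multipole_spec(5, 2)           # n = 43
  set.seed(32)
  surf <- helmet_surface()
  arr <- random_array(80, surf)
  S <- basis_matrix(arr, spec)
  op <- interpolation_operator(S, spec)
  n_int <- 5 * 7
  x_int <- numeric(spec$n_components); x_int[1:n_int] <- rnorm(n_int)
  phi <- as.numeric(S %*% x_int)
  for (trial in 1:20) {
    probe <- random_array(1, surf)
    r <- probe$positions[1, ]; e <- probe$orientations[1, ]
    truth <- sum(e * field_at(x_int, r, spec))
    est <- virtual_sensor(phi, r, e, S, spec, operator = op)
    expect_equal(est, truth, tolerance = 1e-8)
  }
  # purely external field: estimate vanishes relative to the measurement
  x_ext <- numeric(spec$n_components)
  x_ext[(n_int + 1):spec$n_components] <- rnorm(spec$n_components - n_int)
  phi_ext <- as.numeric(S %*% x_ext)
  probe <- random_array(1, surf)
  est_ext <- virtual_sensor(phi_ext, probe$positions[1, ],
                            probe$orientations[1, ], S, spec, operator = op)
  # scale by the field magnitude at the probe for a meaningful relative bound
  ref <- sqrt(sum(field_at(x_ext, probe$positions[1, ], spec)^2))
  expect_lt(abs(est_ext) / ref, 1e-8)
  expect_equal(virtual_sensor(numeric(80), probe$positions[1, ],
                              probe$orientations[1, ], S, spec), 0)
  expect_error(virtual_sensor(numeric(7), probe$positions[1, ],
                              probe$orientations[1, ], S, spec), "length")
})

test_that("interpolation noise scales linearly with sensor noise", {
  spec <- multipole_spec(3, 1)
  set.seed(33)
  surf <- helmet_surface()
  arr <- random_array(40, surf)
  S <- basis_matrix(arr, spec)
  op <- interpolation_operator(S, spec)
  probe <- random_array(1, surf)
  r <- probe$positions[1, ]; e <- probe$orientations[1, ]
  amp <- noise_amp_at(r, e, S, spec, operator = op)
  n_mc <- 20000L
  for (sigma in c(1, 7)) {
    noise <- matrix(rnorm(n_mc * arr$m, sd = sigma), n_mc)
    w <- as.numeric(basis_row(r, e, spec) %*% op)
    est <- noise %*% w
    expect_equal(sd(est) / sigma, amp, tolerance = 0.03)
  }
})

test_that("hat-matrix bound: full-identity selector at sensor locations", {
  # with no external components the selector is the identity, and the
  # amplification at a sensor's own (r, e) is sqrt(H_ii) <= 1 for m > n
  spec <- multipole_spec(3, 0)
  set.seed(34)
  arr <- random_array(30, helmet_surface())
  S <- basis_matrix(arr, spec)
  op <- interpolation_operator(S, spec)
  H <- S %*% op
  for (i in c(1L, 10L, 25L)) {
    amp <- noise_amp_at(arr$positions[i, ], arr$orientations[i, ], S, spec,
                        operator = op)
    expect_equal(amp, sqrt(H[i, i]), tolerance = 1e-8)
    expect_lte(amp, 1 + 1e-10)
  }
})

test_that("orientation maximization: spectral norm dominates and matches brute force", {
  spec <- multipole_spec(4, 2)
  set.seed(35)
  surf <- helmet_surface()
  arr <- random_array(50, surf)
  S <- basis_matrix(arr, spec)
  op <- interpolation_operator(S, spec)
  dirs <- fibonacci_directions(10000L)
  for (trial in 1:5) {
    r <- random_array(1, surf)$positions[1, ]
    mx <- max_noise_amp_at_point(r, S, spec, operator = op)
    for (k in 1:5)
      expect_gte(mx, noise_amp_at(r, random_unit(), S, spec, operator = op))
    w <- megarray:::basis_field_array(rbind(r), spec)[, , 1] %*% op
    brute <- max(sqrt(rowSums((dirs %*% w)^2)))
    expect_equal(mx, brute, tolerance = 1e-3)
  }
})

test_that("q is invariant to per-component basis rescaling at full rank", {
  spec <- multipole_spec(4, 2)
  set.seed(36)
  surf <- helmet_surface()
  arr <- random_array(60, surf)
  grid <- sampling_grid(surf, n_points = 200L)
  gf <- megarray:::grid_field_matrix(grid, spec)
  S <- basis_matrix(arr, spec)
  q0 <- figure_of_merit(arr, spec, grid, grid_fields = gf, S = S)$q
  D <- 10^runif(spec$n_components, -3, 3)
  q1 <- figure_of_merit(arr, spec, grid,
                        grid_fields = gf %*% diag(D),
                        S = S %*% diag(D))$q
  expect_equal(q1, q0, tolerance = 1e-10)
})

test_that("figure_of_merit: permutation invariance and summary consistency", {
  spec <- multipole_spec(3, 1)
  set.seed(37)
  surf <- helmet_surface()
  arr <- random_array(30, surf)
  grid <- sampling_grid(surf, n_points = 150L)
  fom <- figure_of_merit(arr, spec, grid)
  expect_equal(fom$q, max(fom$per_point_amp))
  expect_equal(fom$mean_amp, mean(fom$per_point_amp))
  expect_lte(fom$mean_amp, fom$q)
  # permuting grid points leaves q and the mean unchanged
  perm <- sample.int(nrow(grid$points))
  gridp <- grid; gridp$points <- grid$points[perm, ]
  fomp <- figure_of_merit(arr, spec, gridp)
  expect_equal(fomp$q, fom$q, tolerance = 1e-12)
  expect_equal(fomp$mean_amp, fom$mean_amp, tolerance = 1e-12)
  # sensor relabeling leaves q unchanged
  sperm <- sample.int(arr$m)
  arrp <- sensor_array(arr$positions[sperm, ], arr$orientations[sperm, ])
  expect_equal(figure_of_merit(arrp, spec, grid)$q, fom$q, tolerance = 1e-10)
  # vectorized per-point amplification agrees with the single-point spectral
  # computation
  op <- interpolation_operator(basis_matrix(arr, spec), spec)
  for (i in c(1L, 77L)) {
    expect_equal(fom$per_point_amp[i],
                 max_noise_amp_at_point(grid$points[i, ], NULL, spec,
                                        operator = op),
                 tolerance = 1e-10)
  }
})

test_that("adding sensors never increases the amplification field", {
  spec <- multipole_spec(3, 1)
  set.seed(38)
  surf <- helmet_surface()
  base <- random_array(25, surf)          # m > n = 18, full rank
  extra <- random_array(5, surf)
  grown <- sensor_array(rbind(base$positions, extra$positions),
                        rbind(base$orientations, extra$orientations))
  grid <- sampling_grid(surf, n_points = 150L)
  f1 <- figure_of_merit(base, spec, grid)
  f2 <- figure_of_merit(grown, spec, grid)
  expect_true(all(f2$per_point_amp <= f1$per_point_amp * (1 + 1e-9)))
  expect_lte(f2$q, f1$q * (1 + 1e-9))
})

test_that("rank-deficient arrays are flagged and use the minimum-norm inverse", {
  spec <- multipole_spec(10, 3)
  surf <- helmet_surface()
  grid <- sampling_grid(surf, n_points = 200L)
  expect_warning(f <- figure_of_merit(radial_array(surf, 120), spec, grid),
                 "rank deficient")
  expect_true(f$rank_deficient)
  expect_identical(f$rank, 120L)
})

test_that("q grows with the internal cutoff for a fixed radial array", {
  surf <- helmet_surface()
  grid <- sampling_grid(surf)
  arr <- radial_array(surf, 240)
  qs <- vapply(c(6L, 8L, 10L), function(la) {
    spec <- multipole_spec(la, 3)
    figure_of_merit(arr, spec, grid)$q
  }, numeric(1))
  expect_true(all(diff(qs) >= 0))
})

test_that("noise maps round-trip through the text export", {
  spec <- multipole_spec(2, 1)
  surf <- helmet_surface()
  grid <- sampling_grid(surf, n_points = 50L)
  set.seed(39)
  fom <- figure_of_merit(random_array(20, surf), spec, grid)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_noise_map(fom, path)
  lines <- readLines(path)
  expect_match(lines[1], "q=")
  tab <- read.table(path, skip = 2)
  expect_equal(nrow(tab), 50L)
  expect_equal(tab[[4]], fom$per_point_amp, tolerance = 1e-9)
})
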