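# VSH field-model basis: counts, ordering, field values, matrix assembly.

test_that("component count follows La(La+2) + Lb(Lb+2)", {
  expect_identical(component_count(10, 3), 135L)
  expect_identical(component_count(1, 1), 6L)
  expect_identical(component_count(2, 0), 8L)
  expect_identical(multipole_spec(10, 3)$n_components, 135L)
  expect_identical(nrow(basis_index(multipole_spec(10, 3))), 135L)
  expect_error(component_count(0, 3), "internal")
  expect_error(multipole_spec(2, -1), "external")
})

test_that("canonical ordering is internal-first, l then m ascending", {
  idx <- basis_index(multipole_spec(3, 2))
  expect_identical(idx$column, seq_len(nrow(idx)))
  n_int <- 3 * 5
  expect_true(all(idx$part[seq_len(n_int)] == "internal"))
  expect_true(all(idx$part[-seq_len(n_int)] == "external"))
  # within each (part, l) block, orders run -l..l
  for (l in 1:3) {
    blk <- idx[idx$part == "internal" & idx$l == l, ]
    expect_identical(blk$m, seq.int(-l, l))
  }
  expect_false(is.unsorted(idx$l[seq_len(n_int)]))
})

test_that("selector matrices are complementary orthogonal projectors", {
  spec <- multipole_spec(4, 2)
  Ia <- selector_matrix(spec, "internal")
  Ib <- selector_matrix(spec, "external")
  expect_equal(Ia + Ib, diag(spec$n_components))
  expect_equal(Ia %*% Ib, matrix(0, spec$n_components, spec$n_components))
  x <- rnorm(spec$n_components)
  expect_equal(as.numeric(Ia %*% x + Ib %*% x), x)
})

test_that("basis fields scale along rays per their degree", {
  spec <- multipole_spec(6, 3)
  idx <- basis_index(spec)
  r0 <- c(0.05, 0.11, 0.13)
  for (col in c(1L, 20L, 48L, 49L, 60L, 63L)) {
    b1 <- basis_field(spec, r0, column = col)
    b2 <- basis_field(spec, 2 * r0, column = col)
    l <- idx$l[col]
    expected <- if (idx$part[col] == "internal") 2^(-(l + 2)) else 2^(l - 1)
    expect_equal(sqrt(sum(b2^2) / sum(b1^2)), expected, tolerance = 1e-12)
  }
})

test_that("fields are the negative gradients of their scalar potentials", {
  spec <- multipole_spec(10, 3)
  set.seed(11)
  for (trial in 1:15) {
    col <- sample.int(135L, 1L)
    r <- random_unit() * runif(1, 0.08, 0.3)
    B <- basis_field(spec, r, column = col)
    h <- 1e-6
    g <- vapply(1:3, function(k) {
      dr <- numeric(3); dr[k] <- h
      (megarray:::basis_potential(spec, r + dr, col) -
         megarray:::basis_potential(spec, r - dr, col)) / (2 * h)
    }, numeric(1))
    expect_lt(sqrt(sum((B + g)^2)) / sqrt(sum(B^2)), 1e-6)
  }
})

test_that("every basis field is divergence- and curl-free", {
  spec <- multipole_spec(5, 3)
  set.seed(12)
  h <- 1e-6
  for (trial in 1:10) {
    col <- sample.int(spec$n_components, 1L)
    r <- random_unit() * runif(1, 0.1, 0.25)
    # Jacobian by central differences
    J <- matrix(0, 3, 3)
    for (k in 1:3) {
      dr <- numeric(3); dr[k] <- h
      J[, k] <- (basis_field(spec, r + dr, column = col) -
                   basis_field(spec, r - dr, column = col)) / (2 * h)
    }
    # degree-1 external components have constant fields (J = 0), so the
    # normalization includes the field magnitude over a 1 cm length scale
    B <- basis_field(spec, r, column = col)
    scale <- max(sqrt(sum(J^2)), sqrt(sum(B^2)) / 0.01)
    expect_lt(abs(J[1, 1] + J[2, 2] + J[3, 3]) / scale, 1e-4)
    curl <- c(J[3, 2] - J[2, 3], J[1, 3] - J[3, 1], J[2, 1] - J[1, 2])
    expect_lt(sqrt(sum(curl^2)) / scale, 1e-4)
  }
})

test_that("basis_row projects the per-component fields and is linear in e", {
  spec <- small_spec()
  set.seed(13)
  r <- c(0.05, -0.1, 0.12)
  e <- random_unit()
  row <- basis_row(r, e, spec)
  manual <- vapply(seq_len(spec$n_components), function(j)
    sum(e * basis_field(spec, r, column = j)), numeric(1))
  expect_equal(row, manual, tolerance = 1e-12)
  # linearity of the unnormalized directional functional
  u <- random_unit(); v <- random_unit()
  Fr <- megarray:::basis_field_array(rbind(r), spec)[, , 1]
  lhs <- as.numeric((0.3 * u + 0.5 * v) %*% Fr)
  rhs <- 0.3 * as.numeric(u %*% Fr) + 0.5 * as.numeric(v %*% Fr)
  expect_equal(lhs, rhs, tolerance = 1e-12)
  expect_error(basis_row(r, c(1, 1, 0), spec), "unit")
  expect_error(basis_field(spec, c(0, 0, 0), column = 1), "origin")
})

test_that("basis_matrix stacks sensor rows; duplicate sensors duplicate rows", {
  spec <- small_spec()
  set.seed(14)
  arr1 <- random_array(1)
  S1 <- basis_matrix(arr1, spec)
  expect_equal(dim(S1), c(1L, spec$n_components))
  expect_equal(S1[1, ],
               basis_row(arr1$positions[1, ], arr1$orientations[1, ], spec))
  arr2 <- sensor_array(arr1$positions[c(1, 1), ], arr1$orientations[c(1, 1), ])
  S2 <- basis_matrix(arr2, spec)
  expect_equal(S2[1, ], S2[2, ])
})

test_that("240-sensor radial array gives a full-rank 240 x 135 matrix", {
  spec <- multipole_spec(10, 3)
  S <- basis_matrix(radial_array(helmet_surface(), 240), spec)
  expect_equal(dim(S), c(240L, 135L))
  # scale-invariant numerical rank: equilibrate columns, cutoff max(dim)*eps
  Se <- sweep(S, 2, sqrt(colSums(S^2)), "/")
  d <- svd(Se, nu = 0, nv = 0)$d
  expect_identical(sum(d > max(dim(S)) * .Machine$double.eps * d[1]), 135L)
})

test_that("field_at is the coefficient-weighted sum of component fields", {
  spec <- small_spec()
  set.seed(15)
  r <- c(-0.04, 0.09, 0.14)
  expect_equal(field_at(numeric(spec$n_components), r, spec), c(0, 0, 0))
  x1 <- numeric(spec$n_components); x1[7] <- 2.5
  expect_equal(field_at(x1, r, spec),
               2.5 * basis_field(spec, r, column = 7), tolerance = 1e-12)
  x <- rnorm(spec$n_components)
  e <- random_unit()
  expect_equal(sum(e * field_at(x, r, spec)),
               sum(basis_row(r, e, spec) * x), tolerance = 1e-12)
})
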