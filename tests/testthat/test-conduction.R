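test_that("tensor_from_fibers: completeness, canonical frames, errors", {
  # equal velocities with any orthonormal frame give v^2 * Id
  th <- 0.77
  f <- c(cos(th), sin(th)); s <- c(-sin(th), cos(th))
  M <- tensor_from_fibers(f, s, vf = 0.5, vs = 0.5)
  expect_equal(tensor_eval(M, c(0.3, 0.9)),
               cbind(m11 = 0.25, m12 = 0, m22 = 0.25), tolerance = 1e-14)
  # canonical 3D axes with the physiological velocities
  M3 <- tensor_from_fibers(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                           vf = 0.6, vs = 0.4, vn = 0.2)
  expect_equal(tensor_eval(M3, NULL), diag(c(0.36, 0.16, 0.04)),
               tolerance = 1e-14)
  expect_error(tensor_from_fibers(c(1, 0), c(0.3, 1), vf = 1, vs = 0.5),
               "orthonormal")
  expect_error(tensor_from_fibers(c(1, 0), c(0, 1), vf = 0.4, vs = 0.6),
               "vf >= vs")
})

test_that("tensor_from_fibers eigenvalues are the squared velocities", {
  set.seed(11)
  for (rep in 1:100) {
    th <- runif(1, 0, 2 * pi)
    f <- c(cos(th), sin(th)); s <- c(-sin(th), cos(th))
    vf <- runif(1, 0.5, 1); vs <- runif(1, 0.1, vf)
    M <- tensor_eval(tensor_from_fibers(f, s, vf = vf, vs = vs), c(0, 0))
    ev <- eigen(matrix(c(M[1], M[2], M[2], M[3]), 2), symmetric = TRUE)$values
    expect_equal(sort(ev), sort(c(vf^2, vs^2)), tolerance = 1e-12)
    # ellipticity: M v . v >= vs^2 |v|^2
    v <- runif(2, -1, 1)
    quad <- M[1] * v[1]^2 + 2 * M[2] * v[1] * v[2] + M[3] * v[2]^2
    expect_gte(quad, vs^2 * sum(v^2) - 1e-12)
  }
})

test_that("benchmark tensor values and ellipticity", {
  M <- benchmark2d_tensor()
  expect_equal(as.numeric(tensor_eval(M, c(0, 0))), c(1.1, 0, 1.1))
  expect_equal(as.numeric(tensor_eval(M, c(0.5, 0.5))), c(2.1, 0, 2.1))
  # minimum eigenvalue over the closed square is 1.1 (sin >= 0 on [0,1])
  g <- as.matrix(expand.grid(seq(0, 1, length.out = 41),
                             seq(0, 1, length.out = 41)))
  expect_equal(tensor_ellipticity(M, g), 1.1, tolerance = 1e-12)
})

test_that("directional Jacobian: hand values and FD oracle", {
  M <- benchmark2d_tensor()
  expect_equal(directional_jacobian(M, c(1, 0), c(0.5, 0.5)),
               matrix(0, 2, 2), tolerance = 1e-12)
  expect_equal(directional_jacobian(M, c(1, 0), c(0, 0)),
               matrix(c(pi, 0, 0, 0), 2, 2), tolerance = 1e-12)
  expect_equal(directional_jacobian(constant_tensor(diag(c(2, 3))),
                                    c(0.4, -1), c(0.2, 0.8)),
               matrix(0, 2, 2))
  # central finite differences of the columns of M
  set.seed(3)
  dd <- 1e-6
  for (rep in 1:100) {
    p <- runif(2, 0.05, 0.95); v <- runif(2, -1, 1)
    fdm <- matrix(0, 2, 2)
    for (k in 1:2) {
      for (b in 1:2) {
        pp <- p; pm <- p
        pp[b] <- pp[b] + dd; pm[b] <- pm[b] - dd
        colp <- tensor_eval(M, pp); colm <- tensor_eval(M, pm)
        full_p <- matrix(c(colp[1], colp[2], colp[2], colp[3]), 2)
        full_m <- matrix(c(colm[1], colm[2], colm[2], colm[3]), 2)
        fdm[, b] <- fdm[, b] + (full_p[, k] - full_m[, k]) / (2 * dd) * v[k]
      }
    }
    expect_equal(directional_jacobian(M, v, p), fdm, tolerance = 1e-6)
  }
  expect_error(directional_jacobian(per_cell_tensor(cbind(1, 0, 1)),
                                    c(1, 0), c(0, 0)), "Jacobian")
})

test_that("per-element tensors are cell-indexed and reject mismatch", {
  mesh <- unit_square_mesh(3)
  vals <- cbind(rep(1.5, nrow(mesh$cells)), 0.1, 0.9)
  M <- per_cell_tensor(vals)
  expect_false(M$has_jacobian)
  expect_equal(unname(eikloc:::tensor_on_cells(M, mesh)), unname(vals))
  expect_error(eikloc:::tensor_on_cells(per_cell_tensor(vals[-1, ]), mesh),
               "cells")
  expect_error(tensor_eval(M, c(0.5, 0.5)), "cell")
})

test_that("per-element frames build the expected per-cell tensor", {
  mesh <- unit_square_mesh(2)
  nc <- nrow(mesh$cells)
  th <- seq(0, pi / 3, length.out = nc)
  M <- tensor_from_fibers(cbind(cos(th), sin(th)), cbind(-sin(th), cos(th)),
                          vf = 0.6, vs = 0.4)
  vals <- eikloc:::tensor_on_cells(M, mesh)
  for (c in c(1L, nc)) {
    R <- matrix(c(cos(th[c]), sin(th[c]), -sin(th[c]), cos(th[c])), 2)
    full <- R %*% diag(c(0.36, 0.16)) %*% t(R)
    expect_equal(as.numeric(vals[c, ]), c(full[1, 1], full[1, 2], full[2, 2]),
                 tolerance = 1e-14)
  }
})
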