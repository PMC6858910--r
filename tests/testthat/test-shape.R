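# helper: full pipeline up to the perturbation field on a small benchmark
shape_pipeline <- function(n = 32, include_S0 = NULL) {
  bp <- small_benchmark(n)
  obs <- reference_observation(bp$problem, bp$truth)
  src <- source_set(bp$init_midpoints, bp$radii)
  st <- solve_newton(bp$problem, src)
  phi <- solve_adjoint(bp$problem, src, st$T, obs)
  den <- assemble_density(bp$problem, st$T, phi, src,
                          include_S0 = include_S0)
  list(bp = bp, obs = obs, src = src, st = st, phi = phi, den = den)
}

test_that("S1 density matches the hand-evaluated single-cell case", {
  # single cell, M = Id, eps = 1, grad T = (1,0), grad phi = (0,1), phi = 1:
  # S1 = Id*0 - [(1,0)(x)(0,1) + (0,1)(x)(1,0)] - 2 (1,0)(x)(1,0)
  #    = [[-2, -1], [-1, 0]]
  tri <- eik_mesh(rbind(c(0, 0), c(1, 0), c(0, 1)), rbind(1:3),
                  markers = list(GammaN = rbind(c(1, 2), c(2, 3), c(3, 1)),
                                 GammaO = rbind(c(1, 2))))
  prob <- eik_problem(tri, constant_tensor(diag(2)), solver_params(eps = 1))
  Tf <- tri$vertices[, 1]          # grad T = (1,0)
  phi <- tri$vertices[, 2] + 1     # grad phi = (0,1), vertex mean = 4/3
  # make phi have cell average exactly 1
  phi <- phi - 1 / 3
  den <- assemble_density(prob, Tf, phi, integer(0), include_S0 = FALSE)
  expect_equal(as.numeric(den$S1), c(-2, -1, -1, 0), tolerance = 1e-14)
})

test_that("density vanishes with phi and S0 vanishes for constant M", {
  pl <- shape_pipeline(16)
  den0 <- assemble_density(pl$bp$problem, pl$st$T, numeric(length(pl$st$T)),
                           pl$src)
  expect_equal(max(abs(den0$S1)), 0)
  expect_equal(max(abs(den0$S0)), 0)
  mesh <- pl$bp$problem$mesh
  prob_const <- eik_problem(mesh, constant_tensor(diag(c(1.5, 0.7))),
                            solver_params())
  stc <- solve_newton(prob_const, pl$src)
  phic <- solve_adjoint(prob_const, pl$src, stc$T, pl$obs)
  denc <- assemble_density(prob_const, stc$T, phic, pl$src,
                           include_S0 = TRUE)
  expect_equal(max(abs(denc$S0)), 0)
  expect_error(assemble_density(
    eik_problem(mesh, per_cell_tensor(cbind(rep(1, nrow(mesh$cells)), 0, 1)),
                solver_params()),
    stc$T, phic, pl$src, include_S0 = TRUE), "Jacobian")
})

test_that("shape_derivative is linear and vanishes at h = 0", {
  pl <- shape_pipeline(16)
  mesh <- pl$bp$problem$mesh
  nv <- nrow(mesh$vertices)
  expect_equal(shape_derivative(pl$bp$problem, pl$den, matrix(0, nv, 2)), 0)
  set.seed(21)
  h1 <- matrix(rnorm(2 * nv), ncol = 2)
  h2 <- matrix(rnorm(2 * nv), ncol = 2)
  d1 <- shape_derivative(pl$bp$problem, pl$den, h1)
  d2 <- shape_derivative(pl$bp$problem, pl$den, h2)
  d12 <- shape_derivative(pl$bp$problem, pl$den, 2.5 * h1 - 0.7 * h2)
  expect_equal(d12, 2.5 * d1 - 0.7 * d2, tolerance = 1e-12)
})

test_that("perturbation field: zero density, descent, duality identity", {
  pl <- shape_pipeline(32)
  den0 <- pl$den
  den0$S1[] <- 0
  if (!is.null(den0$S0)) den0$S0[] <- 0
  p0 <- solve_perturbation(pl$bp$problem, den0)
  expect_equal(max(abs(p0$h)), 0)
  pert <- solve_perturbation(pl$bp$problem, pl$den)
  expect_lt(pert$DJh, 0)
  # duality: DJ.h from the volume expression equals -h^T K_S h from the
  # smoother, evaluated through two independent code paths
  DJh <- shape_derivative(pl$bp$problem, pl$den, pert$h)
  expect_lt(abs(DJh - pert$DJh), 1e-8 * abs(DJh))
  # h vanishes on the outer boundary
  bnd <- boundary_vertices(pl$bp$problem$mesh, "GammaN")
  expect_equal(max(abs(pert$h[bnd, ])), 0)
})

test_that("average_over_sources: constants, linear fields, decoupling", {
  mesh <- unit_square_mesh(16)
  nv <- nrow(mesh$vertices)
  src <- source_set(rbind(c(0.3, 0.3), c(0.72, 0.68)), 0.11)
  hc <- cbind(rep(0.4, nv), rep(-1.2, nv))
  expect_equal(average_over_sources(mesh, hc, src),
               rbind(c(0.4, -1.2), c(0.4, -1.2)))
  # h = (x, y) and a grid-symmetric ball: average is the midpoint
  src_sym <- source_set(rbind(c(0.5, 0.5)), 0.13)
  hxy <- mesh$vertices
  expect_equal(average_over_sources(mesh, hxy, src_sym), rbind(c(0.5, 0.5)),
               tolerance = 1e-12)
  # per-source averages depend only on that source's ball
  h2 <- hc
  dn <- dirichlet_nodes(mesh, src)
  h2[dn$per_source[[2]], ] <- 99
  expect_equal(average_over_sources(mesh, h2, src)[1, ], c(0.4, -1.2))
})

test_that("diagnostic split reconstructs DJ.h and vanishes degenerately", {
  pl <- shape_pipeline(32)
  pert <- solve_perturbation(pl$bp$problem, pl$den)
  ds <- diagnostic_split(pl$bp$problem, pl$st$T, pl$phi, pert$h, pl$den)
  DJh <- shape_derivative(pl$bp$problem, pl$den, pert$h)
  expect_lt(abs(ds$signed_sum - DJh), 1e-10 * abs(DJh))
  expect_true(all(ds$values >= 0))
  nv <- nrow(pl$bp$problem$mesh$vertices)
  ds0 <- diagnostic_split(pl$bp$problem, pl$st$T, pl$phi, matrix(0, nv, 2),
                          pl$den)
  expect_equal(unname(ds0$values), rep(0, 6))
  dsphi0 <- diagnostic_split(pl$bp$problem, pl$st$T, numeric(nv), pert$h,
                             pl$den)
  expect_equal(unname(dsphi0$values), rep(0, 6))
})

test_that("translation bump is rigid on the core and compactly supported", {
  mesh <- unit_square_mesh(24)
  h <- translation_bump(mesh, c(0.4, 0.5), c(1, -2), 0.15, 0.3)
  v <- mesh$vertices
  rho <- sqrt((v[, 1] - 0.4)^2 + (v[, 2] - 0.5)^2)
  core <- rho <= 0.15
  expect_true(all(h[core, 1] == 1 & h[core, 2] == -2))
  expect_equal(max(abs(h[rho >= 0.3, ])), 0)
  expect_error(translation_bump(mesh, c(0.4, 0.5), c(1, 0), 0.3, 0.2), "R2")
})

test_that("finite-difference gradient check passes on a small benchmark", {
  bp <- small_benchmark(48)
  obs <- reference_observation(bp$problem, bp$truth)
  src <- source_set(bp$init_midpoints, bp$radii)
  gc <- gradient_check(bp$problem, src, obs,
                       directions = list(c(1, 0), c(0, 1)))
  expect_true(all(gc$rel_err_scaled <= 0.08))
  expect_identical(nrow(gc), 4L)
})
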