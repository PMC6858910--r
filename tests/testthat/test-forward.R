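# thin-strip reduction: with M = Id, f = 1, g = 0, source wall at x = 0 and
# Neumann on the long sides, w solves -eps^2 w'' + w = -1, w(0) = 0,
# w'(1) = 0, so w = -1 + cosh((1-x)/eps)/cosh(1/eps) and
# T = -eps log(cosh((1-x)/eps)/cosh(1/eps)).
strip_problem <- function(nx, eps = 0.1) {
  mesh <- rect_mesh(nx, 1, 1, 1 / nx)
  list(problem = eik_problem(mesh, constant_tensor(diag(2)),
                             solver_params(eps = eps)),
       dirichlet = which(mesh$vertices[, 1] < 1e-12),
       x = mesh$vertices[, 1])
}
strip_exact <- function(x, eps) -eps * log(cosh((1 - x) / eps) / cosh(1 / eps))

test_that("thin-strip closed form is reproduced by both solvers", {
  sp <- strip_problem(256)
  Tex <- strip_exact(sp$x, 0.1)
  hc <- solve_hopf_cole(sp$problem, sp$dirichlet)
  expect_lt(max(abs(hc$T - Tex)), 1e-3)
  wex <- -1 + cosh((1 - sp$x) / 0.1) / cosh(1 / 0.1)
  expect_lt(max(abs(hc$w - wex)), 1e-3)
  nw <- solve_newton(sp$problem, sp$dirichlet)
  expect_lt(max(abs(nw$T - Tex)), 1e-3)
  expect_true(nw$converged)
})

test_that("maximum-principle bounds hold on benchmark solves", {
  bp <- small_benchmark(32)
  hc <- solve_hopf_cole(bp$problem, bp$truth)
  expect_gt(min(hc$w), -1)
  expect_lte(max(hc$w), 1e-10)
  expect_gte(min(hc$T), -1e-10)
  expect_equal(max(abs(hc$T[hc$dirichlet])), 0)
  nw <- solve_newton(bp$problem, bp$truth)
  expect_gte(min(nw$T), -1e-10)
  expect_equal(max(abs(nw$T[nw$dirichlet])), 0)
})

test_that("Newton agrees with Hopf-Cole at discretization level, O(h^2)", {
  errs <- sapply(c(16, 32, 64), function(n) {
    bp <- small_benchmark(n)
    max(abs(solve_newton(bp$problem, bp$truth)$T -
            solve_hopf_cole(bp$problem, bp$truth)$T))
  })
  expect_lt(errs[3], 1e-3)
  # the two independent discretizations differ at O(h^2): each refinement
  # shrinks the gap by ~4
  expect_gt(errs[1] / errs[2], 2.5)
  expect_gt(errs[2] / errs[3], 2.5)
})

test_that("Newton fixed point and cold/warm start consistency", {
  bp <- small_benchmark(16)
  nw <- solve_newton(bp$problem, bp$truth)
  again <- solve_newton(bp$problem, bp$truth, initial = nw$T)
  expect_length(again$newton_history, 1L)  # already below tolerance
  expect_equal(again$T, nw$T)
  cold <- solve_newton(bp$problem, bp$truth, initial = "zero")
  expect_lt(max(abs(cold$T - nw$T)), 1e-8)
})

test_that("vanishing eps drives the strip toward the distance function", {
  # T -> x (the distance function over sqrt(M), M = 1); the deviation is the
  # O(eps) boundary-layer offset ~ eps log 2 plus O(h).  (For eps much
  # smaller, w + 1 = exp(-T/eps) underflows: the Hopf-Cole route is limited
  # to moderate eps, which the Newton path shares via its initialization.)
  errs <- sapply(c(0.2, 0.1, 0.05), function(eps) {
    sp <- strip_problem(512, eps = eps)
    max(abs(solve_hopf_cole(sp$problem, sp$dirichlet)$T - sp$x))
  })
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 0.05)
})

test_that("adjoint: zero data residual, linearity, Dirichlet nodes", {
  bp <- small_benchmark(24)
  nw <- solve_newton(bp$problem, bp$truth)
  onodes <- boundary_vertices(bp$problem$mesh, "GammaO")
  z <- nw$T
  phi0 <- solve_adjoint(bp$problem, bp$truth, nw$T, z)
  expect_lt(max(abs(phi0)), 1e-12)
  z1 <- nw$T; z1[onodes] <- z1[onodes] - 0.05 * sin(5 * z1[onodes]) - 0.02
  phi1 <- solve_adjoint(bp$problem, bp$truth, nw$T, z1)
  # scaling the misfit by c scales phi by c exactly (same linear system)
  z2 <- nw$T + 3 * (z1 - nw$T)
  phi2 <- solve_adjoint(bp$problem, bp$truth, nw$T, z2)
  expect_equal(phi2, 3 * phi1, tolerance = 1e-6)
  expect_equal(max(abs(phi1[nw$dirichlet])), 0)
})

test_that("solver parameter validation", {
  expect_error(solver_params(eps = 0), "positive")
  expect_error(solver_params(f = -1), "positive")
  expect_error(solver_params(g = -0.1), "non-negative")
  expect_error(solve_hopf_cole(small_benchmark(8)$problem, integer(0)),
               "empty Dirichlet")
})
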