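test_that("stiffness: hand-assembled local matrix, kernel, symmetry", {
  # single right triangle with unit legs
  tri <- eik_mesh(rbind(c(0, 0), c(1, 0), c(0, 1)), rbind(1:3),
                  markers = list(GammaN = rbind(c(1, 2), c(2, 3), c(3, 1))))
  K <- as.matrix(assemble_stiffness(tri, constant_tensor(diag(2))))
  expect_equal(K, rbind(c(1, -0.5, -0.5), c(-0.5, 0.5, 0),
                        c(-0.5, 0, 0.5)), tolerance = 1e-14)
  mesh <- wiggled_mesh(6)
  Kb <- assemble_stiffness(mesh, benchmark2d_tensor())
  ones <- rep(1, nrow(mesh$vertices))
  expect_lt(max(abs(Kb %*% ones)), 1e-12)            # constants in kernel
  expect_lt(max(abs(Kb - Matrix::t(Kb))), 1e-12)     # symmetry
  # positive semidefinite with kernel exactly the constants
  ev <- eigen(as.matrix(Kb), symmetric = TRUE, only.values = TRUE)$values
  expect_gt(sort(ev)[2], 1e-10)
  expect_lt(abs(sort(ev)[1]), 1e-12)
  expect_error(assemble_stiffness(mesh, NULL, scale = -1), "positive")
})

test_that("assembled forms agree entrywise with slow quadrature oracles", {
  mesh <- wiggled_mesh(5)  # 50 cells
  Mfun <- function(x) matrix(c(sin(pi * x[1]) + 1.1, 0, 0,
                               sin(pi * x[2]) + 1.1), 2)
  K <- as.matrix(assemble_stiffness(mesh, benchmark2d_tensor(), scale = 0.1))
  expect_equal(K, slow_stiffness(mesh, Mfun, scale = 0.1), tolerance = 1e-12)
  set.seed(5)
  b <- matrix(runif(2 * nrow(mesh$cells), -1, 1), ncol = 2)
  C <- as.matrix(assemble_convection(mesh, b))
  expect_equal(C, slow_convection(mesh, b), tolerance = 1e-12)
  B <- as.matrix(assemble_boundary_mass(mesh, "GammaO"))
  expect_equal(B, slow_boundary_mass(mesh, "GammaO"), tolerance = 1e-12)
  Mm <- as.matrix(assemble_mass(mesh))
  expect_equal(sum(Mm), sum(mesh$area), tolerance = 1e-12)  # int 1 = |U|
})

test_that("convection: zero field, column sums, derivative consistency", {
  mesh <- unit_square_mesh(2)
  expect_equal(max(abs(assemble_convection(
    mesh, matrix(0, nrow(mesh$cells), 2)))), 0)
  set.seed(8)
  b <- matrix(runif(2 * nrow(mesh$cells), -1, 1), ncol = 2)
  C <- assemble_convection(mesh, b)
  # row i sums over j to int (b . grad psi_i): partition of unity
  rs <- Matrix::rowSums(C)
  hand <- numeric(nrow(mesh$vertices))
  for (c in seq_len(nrow(mesh$cells))) {
    for (a in 1:3) {
      g <- c(mesh$gx[c, a], mesh$gy[c, a])
      hand[mesh$cells[c, a]] <- hand[mesh$cells[c, a]] +
        sum(b[c, ] * g) * mesh$area[c]
    }
  }
  expect_equal(as.numeric(rs), hand, tolerance = 1e-13)
  # for T = x, M = Id: b = 2 grad T = (2,0); matrix = 2 x the x-derivative
  # convection matrix from the independent quadrature loop
  b2 <- cbind(rep(2, nrow(mesh$cells)), 0)
  expect_equal(as.matrix(assemble_convection(mesh, b2)),
               2 * slow_convection(mesh, cbind(rep(1, nrow(mesh$cells)), 0)),
               tolerance = 1e-13)
  expect_error(assemble_convection(mesh, b[-1, , drop = FALSE]), "per cell")
})

test_that("boundary mass: facet blocks, perimeter, interior rows", {
  for (n in c(1L, 3L, 16L, 64L)) {
    B <- assemble_boundary_mass(unit_square_mesh(n), "GammaN")
    expect_equal(sum(B), 4, tolerance = 1e-12)
  }
  mesh <- unit_square_mesh(4)
  B <- assemble_boundary_mass(mesh, "GammaO")
  L <- 1 / 4
  fac <- boundary_facets(mesh, "GammaO")
  i <- fac$v1[1]; j <- fac$v2[1]
  expect_equal(B[i, j], L / 6, tolerance = 1e-14)
  interior <- which(mesh$vertices[, 1] > 0 & mesh$vertices[, 1] < 1 &
                    mesh$vertices[, 2] > 0 & mesh$vertices[, 2] < 1)
  expect_equal(sum(abs(B[interior, ])), 0)
})

test_that("elementwise gradient reproduces linear fields exactly", {
  mesh <- wiggled_mesh(7)
  v <- mesh$vertices
  expect_equal(max(abs(elementwise_gradient(mesh, rep(3.2, nrow(v))))), 0)
  gx <- elementwise_gradient(mesh, v[, 1])
  expect_equal(gx, cbind(rep(1, nrow(mesh$cells)), 0), tolerance = 1e-12)
  g <- elementwise_gradient(mesh, v[, 1] + 2 * v[, 2])
  expect_equal(g, cbind(rep(1, nrow(mesh$cells)), 2), tolerance = 1e-12)
})

test_that("Dirichlet elimination: exact linear solution, idempotence", {
  mesh <- unit_square_mesh(8)
  v <- mesh$vertices
  K <- assemble_stiffness(mesh, constant_tensor(diag(2)))
  left <- which(v[, 1] == 0); right <- which(v[, 1] == 1)
  sys <- apply_dirichlet(K, numeric(nrow(v)), c(left, right),
                         c(rep(0, length(left)), rep(1, length(right))))
  u <- solve_system(sys, "chol")
  expect_equal(u, v[, 1], tolerance = 1e-12)  # harmonic u = x exactly P1
  # idempotence: re-applying the same constraints changes nothing
  K2 <- sys$K_ff
  sys2 <- apply_dirichlet(K, numeric(nrow(v)), c(left, right, left),
                          c(rep(0, length(left)), rep(1, length(right)),
                            rep(0, length(left))))
  expect_equal(as.matrix(sys2$K_ff), as.matrix(K2))
  # constraining every node needs no solve
  all_sys <- apply_dirichlet(K, numeric(nrow(v)), seq_len(nrow(v)),
                             v[, 2])
  expect_equal(solve_system(all_sys), v[, 2])
  expect_error(apply_dirichlet(K, numeric(nrow(v)), c(1, 1), c(0, 1)),
               "conflicting")
})

test_that("boundary misfit: zero case, constant offset, quadrature oracle", {
  mesh <- wiggled_mesh(6)
  v <- mesh$vertices
  Tf <- sin(v[, 1]) + v[, 2]^2
  expect_equal(boundary_misfit(mesh, Tf, Tf), 0)
  # T - z constant c on the whole boundary: J = c^2/2 * |GammaO| = 2 c^2
  expect_equal(boundary_misfit(mesh, Tf + 0.3, Tf), 0.5 * 0.3^2 * 4,
               tolerance = 1e-12)
  set.seed(9)
  z <- Tf + runif(length(Tf), -0.2, 0.2)
  B_slow <- slow_boundary_mass(mesh, "GammaO")
  r <- numeric(length(Tf))
  onodes <- boundary_vertices(mesh, "GammaO")
  r[onodes] <- (Tf - z)[onodes]
  expect_equal(boundary_misfit(mesh, Tf, z),
               0.5 * sum(r * (B_slow %*% r)), tolerance = 1e-12)
})
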