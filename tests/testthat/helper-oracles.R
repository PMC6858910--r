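# Independent slow-path oracles used across the suite.  These deliberately
# use dense per-element loops and explicit quadrature, sharing no code with
# the vectorized assembly in the package.

# wiggled structured mesh: interior vertices perturbed, valid for amp < 0.5
wiggled_mesh <- function(n, amp = 0.2, seed = 42) {
  set.seed(seed)
  m <- unit_square_mesh(n)
  v <- m$vertices
  interior <- v[, 1] > 0 & v[, 1] < 1 & v[, 2] > 0 & v[, 2] < 1
  v[interior, ] <- v[interior, ] +
    matrix(runif(2 * sum(interior), -amp / n, amp / n), ncol = 2)
  eik_mesh(v, m$cells, m$markers)
}

# 3-point (edge midpoint) quadrature over one triangle
tri_quad <- function(p1, p2, p3, f) {
  A <- abs((p2[1] - p1[1]) * (p3[2] - p1[2]) -
           (p3[1] - p1[1]) * (p2[2] - p1[2])) / 2
  q <- list((p1 + p2) / 2, (p2 + p3) / 2, (p3 + p1) / 2)
  A / 3 * sum(vapply(q, f, numeric(1)))
}

# P1 basis value / gradient helpers on a triangle
p1_basis <- function(p1, p2, p3) {
  Tm <- cbind(p2 - p1, p3 - p1)
  list(
    value = function(a, x) {
      lam <- solve(Tm, x - p1)
      c(1 - sum(lam), lam)[a]
    },
    grad = function(a) {
      G <- solve(t(Tm), diag(2))  # columns: grad lambda_2, grad lambda_3
      if (a == 1) -G[, 1] - G[, 2] else G[, a - 1]
    })
}

# slow entrywise assembly of int (M grad psi_j).grad psi_i with M a function
slow_stiffness <- function(mesh, Mfun, scale = 1) {
  nv <- nrow(mesh$vertices)
  K <- matrix(0, nv, nv)
  for (c in seq_len(nrow(mesh$cells))) {
    id <- mesh$cells[c, ]
    p1 <- mesh$vertices[id[1], ]; p2 <- mesh$vertices[id[2], ]
    p3 <- mesh$vertices[id[3], ]
    bas <- p1_basis(p1, p2, p3)
    for (a in 1:3) for (b in 1:3) {
      ga <- bas$grad(a); gb <- bas$grad(b)
      K[id[a], id[b]] <- K[id[a], id[b]] +
        scale * tri_quad(p1, p2, p3, function(x)
          sum(ga * (Mfun(x) %*% gb)))
    }
  }
  K
}

# slow assembly of int (b . grad psi_i) psi_j with b constant per cell
slow_convection <- function(mesh, bcell) {
  nv <- nrow(mesh$vertices)
  C <- matrix(0, nv, nv)
  for (c in seq_len(nrow(mesh$cells))) {
    id <- mesh$cells[c, ]
    p1 <- mesh$vertices[id[1], ]; p2 <- mesh$vertices[id[2], ]
    p3 <- mesh$vertices[id[3], ]
    bas <- p1_basis(p1, p2, p3)
    for (a in 1:3) for (b in 1:3) {
      ga <- bas$grad(a)
      C[id[a], id[b]] <- C[id[a], id[b]] +
        tri_quad(p1, p2, p3, function(x)
          sum(bcell[c, ] * ga) * bas$value(b, x))
    }
  }
  C
}

# slow boundary mass by 2-point Gauss per facet
slow_boundary_mass <- function(mesh, marker) {
  nv <- nrow(mesh$vertices)
  B <- matrix(0, nv, nv)
  fac <- boundary_facets(mesh, marker)
  gp <- (1 + c(-1, 1) / sqrt(3)) / 2   # Gauss points on [0,1]
  for (r in seq_len(nrow(fac))) {
    i <- fac$v1[r]; j <- fac$v2[r]; L <- fac$len[r]
    for (g in gp) {
      w <- L / 2
      psi <- c(1 - g, g)
      idx <- c(i, j)
      for (a in 1:2) for (b in 1:2)
        B[idx[a], idx[b]] <- B[idx[a], idx[b]] + w * psi[a] * psi[b]
    }
  }
  B
}

# small benchmark-style problem shared by several tests
small_benchmark <- function(n = 32) benchmark2d_problem(n)
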