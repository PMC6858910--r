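## ---------------------------------------------------------------------------
## P1 finite-element assembly on triangles.
##
## All operators are assembled over the full hold-all mesh of U; the source
## balls enter only through Dirichlet elimination of their node sets.
## Quadrature: degree-2 (edge-midpoint) rule for coefficient averaging in
## domain forms, closed-form blocks for P1 x P1 integrands, two-node exact
## blocks on boundary facets.
## ---------------------------------------------------------------------------

triplet_matrix <- function(i, j, x, nv) {
  Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(nv, nv))
}

#' Assemble the anisotropic stiffness matrix
#'
#' Entry \eqn{(i,j) = scale \int_U (M \nabla\psi_j) \cdot \nabla\psi_i \, dx}.
#' Symmetric for symmetric \eqn{M}; constants lie in its kernel.
#'
#' @param mesh an \code{eik_mesh}.
#' @param M an \code{eik_tensor}, or \code{NULL} for the identity tensor.
#' @param scale positive scalar multiplier (e.g. \eqn{\varepsilon}).
#' @param cell_weight optional per-cell scalar weight multiplying \eqn{M}.
#' @return sparse matrix (V x V).
#' @export
assemble_stiffness <- function(mesh, M = NULL, scale = 1, cell_weight = NULL) {
  if (scale <= 0) stop("scale must be positive")
  nv <- nrow(mesh$vertices)
  nc <- nrow(mesh$cells)
  if (is.null(M)) {
    Mc <- cbind(rep(1, nc), 0, 1)
  } else {
    Mc <- tensor_on_cells(M, mesh)
  }
  if (!is.null(cell_weight)) Mc <- Mc * cell_weight
  ii <- jj <- xx <- vector("list", 9L)
  k <- 0L
  for (a in 1:3) for (b in 1:3) {
    k <- k + 1L
    val <- mesh$area * scale *
      (Mc[, 1L] * mesh$gx[, a] * mesh$gx[, b] +
       Mc[, 2L] * (mesh$gx[, a] * mesh$gy[, b] +
                   mesh$gy[, a] * mesh$gx[, b]) +
       Mc[, 3L] * mesh$gy[, a] * mesh$gy[, b])
    ii[[k]] <- mesh$cells[, a]; jj[[k]] <- mesh$cells[, b]; xx[[k]] <- val
  }
  triplet_matrix(unlist(ii), unlist(jj), unlist(xx), nv)
}

#' Assemble the convection matrix
#'
#' Entry \eqn{(i,j) = \int_U (b \cdot \nabla\psi_i) \, \psi_j \, dx} for a
#' per-cell-constant vector field \eqn{b} (exact integration).  The Newton
#' system uses the transpose of this matrix (gradient on the trial slot); the
#' adjoint system uses it as is.
#'
#' @param mesh an \code{eik_mesh}.
#' @param b per-cell vectors (C x 2 matrix).
#' @return sparse matrix (V x V).
#' @export
assemble_convection <- function(mesh, b) {
  b <- as.matrix(b)
  if (nrow(b) != nrow(mesh$cells) || ncol(b) != 2L)
    stop("b must supply one 2-vector per cell")
  nv <- nrow(mesh$vertices)
  ii <- jj <- xx <- vector("list", 9L)
  k <- 0L
  for (a in 1:3) {
    bg <- (b[, 1L] * mesh$gx[, a] + b[, 2L] * mesh$gy[, a]) * mesh$area / 3
    for (bb in 1:3) {
      k <- k + 1L
      ii[[k]] <- mesh$cells[, a]; jj[[k]] <- mesh$cells[, bb]; xx[[k]] <- bg
    }
  }
  triplet_matrix(unlist(ii), unlist(jj), unlist(xx), nv)
}

#' Assemble the domain mass matrix
#'
#' Entry \eqn{(i,j) = \int_U c \, \psi_i \psi_j \, dx} with \eqn{c} constant
#' per cell (default 1); exact P1 blocks.
#'
#' @param mesh an \code{eik_mesh}.
#' @param coeff scalar or per-cell coefficient.
#' @return sparse matrix (V x V).
#' @export
assemble_mass <- function(mesh, coeff = 1) {
  nv <- nrow(mesh$vertices)
  w <- mesh$area * coeff / 12
  ii <- jj <- xx <- vector("list", 9L)
  k <- 0L
  for (a in 1:3) for (b in 1:3) {
    k <- k + 1L
    ii[[k]] <- mesh$cells[, a]; jj[[k]] <- mesh$cells[, b]
    xx[[k]] <- w * (if (a == b) 2 else 1)
  }
  triplet_matrix(unlist(ii), unlist(jj), unlist(xx), nv)
}

#' Assemble the boundary mass matrix on a marked boundary
#'
#' Entry \eqn{(i,j) = \int_{\Gamma_{marker}} \psi_i \psi_j \, ds}; a facet of
#' length L contributes the exact 1D P1 block \code{[[L/3, L/6], [L/6, L/3]]}.
#'
#' @param mesh an \code{eik_mesh}.
#' @param marker boundary marker label.
#' @return sparse matrix (V x V), nonzero only at marked-boundary vertices.
#' @export
assemble_boundary_mass <- function(mesh, marker) {
  fac <- boundary_facets(mesh, marker)
  nv <- nrow(mesh$vertices)
  L <- fac$len
  triplet_matrix(c(fac$v1, fac$v2, fac$v1, fac$v2),
                 c(fac$v1, fac$v2, fac$v2, fac$v1),
                 c(L / 3, L / 3, L / 6, L / 6), nv)
}

## load vector: \int_U f psi_i dx for f constant per cell (or scalar)
domain_load <- function(mesh, f = 1) {
  nv <- nrow(mesh$vertices)
  w <- mesh$area * f / 3
  out <- numeric(nv)
  for (a in 1:3) {
    acc <- tapply(w, mesh$cells[, a], sum)
    out[as.integer(names(acc))] <- out[as.integer(names(acc))] + acc
  }
  out
}

## load vector: \int_{Gamma_marker} g psi_i ds for g constant per facet
boundary_load <- function(mesh, marker, g = 1) {
  fac <- boundary_facets(mesh, marker)
  nv <- nrow(mesh$vertices)
  out <- numeric(nv)
  w <- fac$len * g / 2
  for (col in c("v1", "v2")) {
    acc <- tapply(w, fac[[col]], sum)
    out[as.integer(names(acc))] <- out[as.integer(names(acc))] + acc
  }
  out
}

#' Element-wise gradient of a P1 field
#'
#' @param mesh an \code{eik_mesh}.
#' @param u nodal values (length V).
#' @return C x 2 matrix; the exact (per-cell-constant) gradient of the P1
#'   interpolant.
#' @export
elementwise_gradient <- function(mesh, u) {
  if (length(u) != nrow(mesh$vertices)) stop("u must be a nodal field")
  u1 <- u[mesh$cells[, 1L]]; u2 <- u[mesh$cells[, 2L]]; u3 <- u[mesh$cells[, 3L]]
  cbind(mesh$gx[, 1L] * u1 + mesh$gx[, 2L] * u2 + mesh$gx[, 3L] * u3,
        mesh$gy[, 1L] * u1 + mesh$gy[, 2L] * u2 + mesh$gy[, 3L] * u3)
}

## per-cell vertex average of a nodal field
cell_mean <- function(mesh, u) {
  (u[mesh$cells[, 1L]] + u[mesh$cells[, 2L]] + u[mesh$cells[, 3L]]) / 3
}

#' Impose Dirichlet values by symmetric elimination
#'
#' Moves the constrained columns to the right-hand side and restricts the
#' system to the free nodes; the returned object can be solved with
#' \code{\link{solve_system}} and re-applied idempotently.
#'
#' @param K sparse system matrix (V x V).
#' @param rhs right-hand-side vector (length V).
#' @param nodes constrained vertex indices.
#' @param values prescribed values (recycled).
#' @return list with the reduced matrix \code{K_ff}, reduced right-hand side
#'   \code{rhs_f}, \code{free} and \code{nodes}/\code{values}.
#' @export
apply_dirichlet <- function(K, rhs, nodes, values = 0) {
  nv <- nrow(K)
  if (length(nodes) == 0L)
    return(list(K_ff = K, rhs_f = rhs, free = seq_len(nv),
                nodes = integer(0), values = numeric(0)))
  if (min(nodes) < 1L || max(nodes) > nv) stop("constrained node out of range")
  values <- rep_len(values, length(nodes))
  dup <- duplicated(nodes)
  if (any(dup)) {
    first <- match(nodes[dup], nodes)
    if (any(abs(values[dup] - values[first]) > 0))
      stop("duplicate constrained node with conflicting values")
    nodes <- nodes[!dup]; values <- values[!dup]
  }
  free <- setdiff(seq_len(nv), nodes)
  rhs_f <- rhs[free]
  if (any(values != 0))
    rhs_f <- rhs_f - as.numeric(K[free, nodes, drop = FALSE] %*% values)
  list(K_ff = K[free, free, drop = FALSE], rhs_f = rhs_f, free = free,
       nodes = nodes, values = values)
}

#' Solve a Dirichlet-constrained system
#'
#' @param sys result of \code{\link{apply_dirichlet}}.
#' @param solver \code{"lu"} (general sparse LU) or \code{"chol"} (sparse
#'   Cholesky; the matrix must be symmetric positive definite).
#' @return full-length solution vector with the prescribed values at the
#'   constrained nodes.
#' @export
solve_system <- function(sys, solver = c("lu", "chol")) {
  solver <- match.arg(solver)
  nv <- length(sys$free) + length(sys$nodes)
  out <- numeric(nv)
  out[sys$nodes] <- sys$values
  if (length(sys$free)) {
    xf <- if (solver == "chol") {
      ch <- Matrix::Cholesky(Matrix::forceSymmetric(sys$K_ff), LDL = FALSE)
      as.numeric(Matrix::solve(ch, sys$rhs_f))
    } else {
      as.numeric(Matrix::solve(sys$K_ff, sys$rhs_f))
    }
    out[sys$free] <- xf
  }
  out
}

#' Boundary misfit functional
#'
#' \eqn{J = \frac12 \int_{\Gamma_O} (T - z)^2 \, ds}, evaluated exactly for
#' P1 traces via the boundary mass matrix.
#'
#' @param mesh an \code{eik_mesh}.
#' @param T nodal activation-time field (length V).
#' @param obs an observation object (see \code{\link{reference_observation}})
#'   or a full-length nodal vector giving z on the observatory vertices.
#' @param B_O optional precomputed \code{GammaO} boundary mass matrix.
#' @return scalar misfit value (>= 0).
#' @export
boundary_misfit <- function(mesh, T, obs, B_O = NULL) {
  if (is.null(B_O)) B_O <- assemble_boundary_mass(mesh, "GammaO")
  r <- numeric(nrow(mesh$vertices))
  if (inherits(obs, "eik_obs")) {
    if (anyNA(obs$z)) stop("observation is missing values on GammaO nodes")
    r[obs$nodes] <- T[obs$nodes] - obs$z
  } else {
    nodes <- boundary_vertices(mesh, "GammaO")
    if (anyNA(obs[nodes])) stop("z missing on a GammaO vertex")
    r[nodes] <- T[nodes] - obs[nodes]
  }
  0.5 * sum(r * as.numeric(B_O %*% r))
}
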