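## ---------------------------------------------------------------------------
## Squared-conduction-velocity tensor fields M(x).
##
## Two modes:
##  * analytic  - M given by vectorized functions of the coordinates, with an
##                optional directional Jacobian (needed by the S0 density);
##  * per_cell  - one constant symmetric tensor per mesh cell (the element-
##                wise representation; no Jacobian, S0 disabled).
## Symmetric 2x2 tensors are packed as (m11, m12, m22).
## ---------------------------------------------------------------------------

new_eik_tensor <- function(type, d, eval_fun = NULL, dirjac = NULL,
                           per_cell = NULL, label = type) {
  structure(list(type = type, d = d, eval_fun = eval_fun, dirjac = dirjac,
                 per_cell = per_cell, label = label,
                 has_jacobian = !is.null(dirjac)),
            class = "eik_tensor")
}

#' @export
print.eik_tensor <- function(x, ...) {
  cat(sprintf("<eik_tensor> %s (d = %d, jacobian: %s)\n", x$label, x$d,
              if (x$has_jacobian) "yes" else "no"))
  invisible(x)
}

#' Spatially constant conduction tensor
#'
#' @param M symmetric positive-definite d x d matrix (units: squared
#'   velocity).
#' @return an \code{eik_tensor} with an (identically zero) directional
#'   Jacobian.
#' @export
constant_tensor <- function(M) {
  M <- as.matrix(M)
  if (max(abs(M - t(M))) > 1e-12 * max(1, max(abs(M))))
    stop("M must be symmetric")
  d <- nrow(M)
  if (d == 2L) {
    ef <- function(x, y) cbind(m11 = rep(M[1, 1], length(x)),
                               m12 = rep(M[1, 2], length(x)),
                               m22 = rep(M[2, 2], length(x)))
    dj <- function(P, V) matrix(0, nrow(rbind(P)), 4L)
    new_eik_tensor("analytic", 2L, ef, dj, label = "constant")
  } else {
    t <- new_eik_tensor("constant3", d, label = "constant")
    t$matrix <- M
    t
  }
}

#' Anisotropic benchmark tensor on the unit square
#'
#' The diagonal tensor \eqn{M = diag(\sin(\pi x) + 1.1, \sin(\pi y) + 1.1)}
#' used by the 2D unit-square benchmark, with its analytic directional
#' Jacobian.
#'
#' @return an \code{eik_tensor}.
#' @export
benchmark2d_tensor <- function() {
  ef <- function(x, y) cbind(m11 = sin(pi * x) + 1.1,
                             m12 = rep(0, length(x)),
                             m22 = sin(pi * y) + 1.1)
  ## DM_1 = [[pi cos(pi x), 0], [0, 0]], DM_2 = [[0, 0], [0, pi cos(pi y)]]
  ## => M_V = DM_1 V1 + DM_2 V2 = diag(pi cos(pi x) V1, pi cos(pi y) V2)
  dj <- function(P, V) {
    P <- rbind(P); V <- rbind(V)
    cbind(pi * cos(pi * P[, 1L]) * V[, 1L], 0, 0,
          pi * cos(pi * P[, 2L]) * V[, 2L])
  }
  new_eik_tensor("analytic", 2L, ef, dj, label = "benchmark2d")
}

#' Analytic tensor field from vectorized component functions
#'
#' @param eval_fun function of coordinate vectors \code{(x, y)} returning an
#'   n x 3 matrix of packed components \code{(m11, m12, m22)}.
#' @param dirjac optional directional Jacobian: function of point matrix
#'   \code{P} (n x 2) and vector matrix \code{V} (n x 2) returning the n
#'   matrices \eqn{M_V = \sum_k DM_k V_k} packed row-wise as
#'   \code{(m[1,1], m[1,2], m[2,1], m[2,2])}.
#' @param label display label.
#' @return an \code{eik_tensor}.
#' @export
analytic_tensor <- function(eval_fun, dirjac = NULL, label = "analytic") {
  new_eik_tensor("analytic", 2L, eval_fun, dirjac, label = label)
}

#' Per-element constant tensor field
#'
#' @param values C x 3 matrix of packed components \code{(m11, m12, m22)},
#'   one row per mesh cell.
#' @return an \code{eik_tensor} without Jacobian (the S0 density is disabled
#'   in this mode).
#' @export
per_cell_tensor <- function(values) {
  values <- as.matrix(values)
  if (ncol(values) != 3L) stop("values must have columns (m11, m12, m22)")
  new_eik_tensor("per_cell", 2L, per_cell = values, label = "per_cell")
}

#' Conduction tensor from fiber/sheet(/normal) frames
#'
#' Builds \eqn{M = v_f^2 f f^* + v_s^2 s s^* (+ v_n^2 n n^*)} from an
#' orthonormal frame and per-direction conduction velocities.  Vectors may be
#' single frame vectors (constant field) or per-element matrices (one row per
#' cell, giving a per-element tensor).
#'
#' @param f,s fiber and sheet unit direction(s); \code{n} the sheet normal
#'   (3D only).
#' @param vf,vs,vn conduction velocities with \code{vf >= vs >= vn > 0}
#'   (\code{vn} ignored in 2D).
#' @param n sheet-normal direction(s), 3D only.
#' @param tol orthonormality tolerance.
#' @return an \code{eik_tensor}; constant in 2D/3D for single vectors,
#'   per-element in 2D for row-wise input.
#' @export
tensor_from_fibers <- function(f, s, n = NULL, vf, vs, vn = NULL,
                               tol = 1e-8) {
  fm <- rbind(f); sm <- rbind(s)
  d <- ncol(fm)
  vels <- c(vf, vs, if (d == 3L) vn)
  if (any(is.na(vels)) || any(vels <= 0) || is.unsorted(rev(vels)))
    stop("velocities must satisfy vf >= vs ", if (d == 3L) ">= vn ", "> 0")
  nm <- if (d == 3L) rbind(n) else NULL
  chk <- function(a, b) max(abs(rowSums(a * b)))
  nrm <- function(a) max(abs(rowSums(a * a) - 1))
  bad <- max(nrm(fm), nrm(sm), chk(fm, sm),
             if (d == 3L) c(nrm(nm), chk(fm, nm), chk(sm, nm)) else 0)
  if (bad > tol) stop("frame is not orthonormal (deviation ", format(bad),
                      " > tol)")
  if (nrow(fm) == 1L) {
    M <- vf^2 * crossprod(fm) + vs^2 * crossprod(sm) +
      (if (d == 3L) vn^2 * crossprod(nm) else 0)
    constant_tensor(as.matrix(M))
  } else {
    if (d != 2L) stop("per-element frames are supported in 2D only")
    m11 <- vf^2 * fm[, 1L]^2 + vs^2 * sm[, 1L]^2
    m12 <- vf^2 * fm[, 1L] * fm[, 2L] + vs^2 * sm[, 1L] * sm[, 2L]
    m22 <- vf^2 * fm[, 2L]^2 + vs^2 * sm[, 2L]^2
    per_cell_tensor(cbind(m11, m12, m22))
  }
}

#' Evaluate a tensor field at points
#'
#' @param M an \code{eik_tensor} (analytic or constant).
#' @param P point matrix (n x d) or a single point.
#' @return for 2D fields an n x 3 matrix of packed \code{(m11, m12, m22)};
#'   for a constant 3D tensor the 3 x 3 matrix itself.
#' @export
tensor_eval <- function(M, P) {
  if (M$type == "constant3") return(M$matrix)
  if (M$type == "per_cell")
    stop("per-element tensors are indexed by cell, not by point")
  P <- rbind(P)
  M$eval_fun(P[, 1L], P[, 2L])
}

## packed per-cell tensor values, averaged with the degree-2 edge-midpoint
## rule for analytic fields (exact for per-cell-constant M)
tensor_on_cells <- function(M, mesh) {
  if (M$type == "per_cell") {
    if (nrow(M$per_cell) != nrow(mesh$cells))
      stop("per-element tensor has ", nrow(M$per_cell),
           " rows but the mesh has ", nrow(mesh$cells), " cells")
    return(M$per_cell)
  }
  if (M$type != "analytic") stop("tensor mode unsupported on a 2D mesh")
  acc <- 0
  for (q in 1:3)
    acc <- acc + M$eval_fun(mesh$qx[, q], mesh$qy[, q])
  acc / 3
}

#' Directional Jacobian of a tensor field
#'
#' Returns \eqn{M_v = \sum_k DM_k v_k}, where \eqn{DM_k} is the Jacobian of
#' the k-th column of \eqn{M}; the object appearing in the S0 shape-gradient
#' density.
#'
#' @param M an \code{eik_tensor} with Jacobian.
#' @param v direction vector (length 2).
#' @param point evaluation point (length 2).
#' @return 2 x 2 matrix.
#' @export
directional_jacobian <- function(M, v, point) {
  if (!isTRUE(M$has_jacobian))
    stop("tensor has no directional Jacobian; disable S0")
  r <- M$dirjac(rbind(as.numeric(point)), rbind(as.numeric(v)))
  matrix(r[1L, ], 2L, 2L, byrow = TRUE)
}

#' Sampled ellipticity constant of a tensor field
#'
#' @param M an \code{eik_tensor}.
#' @param P sample points (n x 2), or a mesh whose cell centroids are used.
#' @return the minimum sampled eigenvalue.
#' @export
tensor_ellipticity <- function(M, P) {
  if (is(P, "eik_mesh")) {
    vals <- tensor_on_cells(M, P)
  } else {
    vals <- tensor_eval(M, P)
  }
  tr <- vals[, 1L] + vals[, 3L]
  det <- vals[, 1L] * vals[, 3L] - vals[, 2L]^2
  lmin <- tr / 2 - sqrt(pmax(0, tr^2 / 4 - det))
  min(lmin)
}
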