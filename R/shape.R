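## ---------------------------------------------------------------------------
## Volume-expression shape derivative
##     DJ(Omega, Gamma) h = int_Omega  S1 : Dh + S0 . h  dx
## with densities
##     S1 = Id (eps M gT . gphi + (|gT|_M^2 - f) phi)
##          - eps (gT (x) M gphi + gphi (x) M gT) - 2 (gT (x) M gT) phi
##     S0 = eps M*_{gT} gphi + M*_{gT} gT phi,
## the perturbation field h from the H1(U) smoother
##     int_U Dh : Dv + h . v = -int_Omega S1 : Dv + S0 . v,  h = 0 on dU,
## and the per-source midpoint shifts obtained by averaging h over each ball.
## ---------------------------------------------------------------------------

## per-cell M gT products, shared by densities and diagnostics
density_ingredients <- function(problem, T, phi) {
  mesh <- problem$mesh
  gT <- elementwise_gradient(mesh, T)
  gp <- elementwise_gradient(mesh, phi)
  Mc <- problem$Mc
  MgT <- cbind(Mc[, 1L] * gT[, 1L] + Mc[, 2L] * gT[, 2L],
               Mc[, 2L] * gT[, 1L] + Mc[, 3L] * gT[, 2L])
  Mgp <- cbind(Mc[, 1L] * gp[, 1L] + Mc[, 2L] * gp[, 2L],
               Mc[, 2L] * gp[, 1L] + Mc[, 3L] * gp[, 2L])
  list(gT = gT, gp = gp, MgT = MgT, Mgp = Mgp,
       q = gT[, 1L] * MgT[, 1L] + gT[, 2L] * MgT[, 2L],     # |gT|_M^2
       cross = gT[, 1L] * Mgp[, 1L] + gT[, 2L] * Mgp[, 2L], # M gT . gphi
       pbar = cell_mean(mesh, phi))
}

#' Assemble the shape-derivative densities S1 and S0
#'
#' Evaluates the per-cell densities of the volume expression of the shape
#' derivative, with \eqn{\nabla T}, \eqn{\nabla\varphi} element-wise
#' constant and \eqn{\varphi} taken as the cell-vertex average.  Cells whose
#' vertices all lie outside the source node set form the discrete
#' \eqn{\Omega} over which the densities are integrated.
#'
#' @param problem an \code{eik_problem}.
#' @param T converged state field.
#' @param phi adjoint field.
#' @param sources an \code{eik_sources} or Dirichlet vertex indices (defines
#'   the discrete \eqn{\Omega}).
#' @param include_S0 include the S0 density (requires a tensor Jacobian);
#'   default: automatic (on for analytic tensors with Jacobian).
#' @return list of class \code{eik_density}: \code{S1} (C x 4, row-major
#'   2x2), \code{S0} (C x 2 or NULL), logical cell mask \code{in_omega}.
#' @export
assemble_density <- function(problem, T, phi, sources,
                             include_S0 = NULL) {
  mesh <- problem$mesh
  p <- problem$params
  if (is.null(include_S0)) include_S0 <- isTRUE(problem$M$has_jacobian)
  if (include_S0 && !isTRUE(problem$M$has_jacobian))
    stop("include_S0 requires a tensor with directional Jacobian")
  ing <- density_ingredients(problem, T, phi)
  scal <- p$eps * ing$cross + (ing$q - p$f) * ing$pbar
  S1 <- cbind(
    scal - p$eps * (ing$gT[, 1L] * ing$Mgp[, 1L] +
                    ing$gp[, 1L] * ing$MgT[, 1L]) -
      2 * ing$gT[, 1L] * ing$MgT[, 1L] * ing$pbar,
    -p$eps * (ing$gT[, 1L] * ing$Mgp[, 2L] + ing$gp[, 1L] * ing$MgT[, 2L]) -
      2 * ing$gT[, 1L] * ing$MgT[, 2L] * ing$pbar,
    -p$eps * (ing$gT[, 2L] * ing$Mgp[, 1L] + ing$gp[, 2L] * ing$MgT[, 1L]) -
      2 * ing$gT[, 2L] * ing$MgT[, 1L] * ing$pbar,
    scal - p$eps * (ing$gT[, 2L] * ing$Mgp[, 2L] +
                    ing$gp[, 2L] * ing$MgT[, 2L]) -
      2 * ing$gT[, 2L] * ing$MgT[, 2L] * ing$pbar)
  S0 <- NULL
  if (include_S0) {
    Mv <- problem$M$dirjac(mesh$centroid, ing$gT)  # M_{gT}, rows (11,12,21,22)
    tgp <- cbind(Mv[, 1L] * ing$gp[, 1L] + Mv[, 3L] * ing$gp[, 2L],
                 Mv[, 2L] * ing$gp[, 1L] + Mv[, 4L] * ing$gp[, 2L])
    tgT <- cbind(Mv[, 1L] * ing$gT[, 1L] + Mv[, 3L] * ing$gT[, 2L],
                 Mv[, 2L] * ing$gT[, 1L] + Mv[, 4L] * ing$gT[, 2L])
    S0 <- p$eps * tgp + tgT * ing$pbar
  }
  nodes <- resolve_dirichlet(problem, sources)
  isdir <- logical(nrow(mesh$vertices))
  isdir[nodes] <- TRUE
  in_omega <- !(isdir[mesh$cells[, 1L]] | isdir[mesh$cells[, 2L]] |
                isdir[mesh$cells[, 3L]])
  structure(list(S1 = S1, S0 = S0, in_omega = in_omega,
                 include_S0 = include_S0),
            class = "eik_density")
}

## per-cell Dh (C x 4, rows (d1/dx, d1/dy, d2/dx, d2/dy)) and cell means
field_cell_data <- function(mesh, h) {
  g1 <- elementwise_gradient(mesh, h[, 1L])
  g2 <- elementwise_gradient(mesh, h[, 2L])
  list(Dh = cbind(g1, g2),
       hbar = cbind(cell_mean(mesh, h[, 1L]), cell_mean(mesh, h[, 2L])))
}

#' Evaluate the shape derivative in a direction
#'
#' \eqn{DJ(\Omega,\Gamma) h = \int_\Omega S_1 : Dh + S_0 \cdot h \, dx},
#' summed over the discrete \eqn{\Omega} cells; linear in \code{h}.
#'
#' @param problem an \code{eik_problem}.
#' @param density an \code{eik_density}.
#' @param h nodal vector field (V x 2).
#' @return scalar directional shape derivative.
#' @export
shape_derivative <- function(problem, density, h) {
  mesh <- problem$mesh
  fc <- field_cell_data(mesh, h)
  contr <- density$S1[, 1L] * fc$Dh[, 1L] + density$S1[, 2L] * fc$Dh[, 2L] +
           density$S1[, 3L] * fc$Dh[, 3L] + density$S1[, 4L] * fc$Dh[, 4L]
  if (!is.null(density$S0))
    contr <- contr + density$S0[, 1L] * fc$hbar[, 1L] +
             density$S0[, 2L] * fc$hbar[, 2L]
  sum((mesh$area * contr)[density$in_omega])
}

## cached Cholesky of the scalar H1(U) operator restricted to interior nodes
perturbation_operator <- function(problem) {
  cache <- problem$cache
  if (is.null(cache$KS)) {
    mesh <- problem$mesh
    KS <- assemble_stiffness(mesh, NULL, 1) + assemble_mass(mesh)
    bnd <- boundary_vertices(mesh, "GammaN")
    interior <- setdiff(seq_len(nrow(mesh$vertices)), bnd)
    cache$KS_ff <- KS[interior, interior, drop = FALSE]
    cache$KS_chol <- Matrix::Cholesky(Matrix::forceSymmetric(cache$KS_ff),
                                      LDL = FALSE)
    cache$KS_interior <- interior
    cache$KS <- TRUE
  }
  cache
}

#' Solve for the smoothed perturbation field
#'
#' Each component of \eqn{h} solves the \eqn{H^1(U)} problem
#' \eqn{\int_U Dh : Dv + h \cdot v = -\int_\Omega S_1 : Dv + S_0 \cdot v}
#' with \eqn{h = 0} on the vertices of \eqn{\partial U}; by construction
#' \eqn{DJ \cdot h = -\|h\|_{H^1}^2 \le 0}, so \eqn{h} is a descent
#' direction.  The SPD operator is factorized once per problem and reused.
#'
#' @param problem an \code{eik_problem}.
#' @param density an \code{eik_density}.
#' @return list of class \code{eik_perturbation}: nodal field \code{h}
#'   (V x 2) and \code{DJh} (the duality value \eqn{-\|h\|_{H^1}^2}).
#' @export
solve_perturbation <- function(problem, density) {
  mesh <- problem$mesh
  op <- perturbation_operator(problem)
  nv <- nrow(mesh$vertices)
  area <- mesh$area * density$in_omega  # zero outside discrete Omega
  h <- matrix(0, nv, 2L)
  hKh <- 0
  for (comp in 1:2) {
    w1 <- area * density$S1[, 2L * comp - 1L]
    w2 <- area * density$S1[, 2L * comp]
    w0 <- if (!is.null(density$S0)) area * density$S0[, comp] / 3 else 0
    rhs <- numeric(nv)
    for (a in 1:3) {
      contrib <- w1 * mesh$gx[, a] + w2 * mesh$gy[, a] + w0
      acc <- tapply(contrib, mesh$cells[, a], sum)
      idx <- as.integer(names(acc))
      rhs[idx] <- rhs[idx] + acc
    }
    rf <- -rhs[op$KS_interior]
    xf <- as.numeric(Matrix::solve(op$KS_chol, rf))
    h[op$KS_interior, comp] <- xf
    hKh <- hKh + sum(xf * as.numeric(op$KS_ff %*% xf))
  }
  structure(list(h = h, DJh = -hKh), class = "eik_perturbation")
}

#' Average the perturbation field over each source ball
#'
#' @param mesh an \code{eik_mesh}.
#' @param h nodal vector field (V x 2).
#' @param sources an \code{eik_sources}.
#' @return N x 2 matrix of per-source mean displacements.
#' @export
average_over_sources <- function(mesh, h, sources) {
  dn <- dirichlet_nodes(mesh, sources)
  t(vapply(dn$per_source, function(idx)
    colMeans(h[idx, , drop = FALSE]), numeric(2L)))
}

#' Diagnostic split of the shape derivative
#'
#' The six absolute-valued integrals \eqn{S_{11}, S_{12}, S_{13}, S_{14},
#' S_{01}, S_{02}} that partition \eqn{DJ \cdot h} by density term; their
#' signed sum reconstructs \eqn{DJ \cdot h} exactly.
#'
#' @param problem an \code{eik_problem}.
#' @param T,phi state and adjoint fields.
#' @param h nodal perturbation field (V x 2).
#' @param density an \code{eik_density} (supplies the \eqn{\Omega} mask and
#'   the S0 switch).
#' @return named list: \code{values} (six absolute integrals) and
#'   \code{signed_sum} (equals \eqn{DJ \cdot h}).
#' @export
diagnostic_split <- function(problem, T, phi, h, density) {
  mesh <- problem$mesh
  p <- problem$params
  ing <- density_ingredients(problem, T, phi)
  fc <- field_cell_data(mesh, h)
  area <- mesh$area * density$in_omega
  trDh <- fc$Dh[, 1L] + fc$Dh[, 4L]
  s11 <- p$eps * sum(area * ing$cross * trDh)
  s12 <- sum(area * (ing$q - p$f) * ing$pbar * trDh)
  outer_contr <- function(u, v) # (u (x) v) : Dh  per cell
    u[, 1L] * v[, 1L] * fc$Dh[, 1L] + u[, 1L] * v[, 2L] * fc$Dh[, 2L] +
    u[, 2L] * v[, 1L] * fc$Dh[, 3L] + u[, 2L] * v[, 2L] * fc$Dh[, 4L]
  s13 <- p$eps * sum(area * (outer_contr(ing$gT, ing$Mgp) +
                             outer_contr(ing$gp, ing$MgT)))
  s14 <- 2 * sum(area * outer_contr(ing$gT, ing$MgT) * ing$pbar)
  s01 <- s02 <- 0
  if (!is.null(density$S0)) {
    Mv <- problem$M$dirjac(mesh$centroid, ing$gT)
    tgp <- cbind(Mv[, 1L] * ing$gp[, 1L] + Mv[, 3L] * ing$gp[, 2L],
                 Mv[, 2L] * ing$gp[, 1L] + Mv[, 4L] * ing$gp[, 2L])
    tgT <- cbind(Mv[, 1L] * ing$gT[, 1L] + Mv[, 3L] * ing$gT[, 2L],
                 Mv[, 2L] * ing$gT[, 1L] + Mv[, 4L] * ing$gT[, 2L])
    s01 <- p$eps * sum(area * (tgp[, 1L] * fc$hbar[, 1L] +
                               tgp[, 2L] * fc$hbar[, 2L]))
    s02 <- sum(area * ing$pbar * (tgT[, 1L] * fc$hbar[, 1L] +
                                  tgT[, 2L] * fc$hbar[, 2L]))
  }
  list(values = c(S11 = abs(s11), S12 = abs(s12), S13 = abs(s13),
                  S14 = abs(s14), S01 = abs(s01), S02 = abs(s02)),
       signed_sum = s11 + s12 - s13 - s14 + s01 + s02)
}

#' Rigid-translation bump field around one source
#'
#' Builds a nodal vector field equal to a constant vector \code{v} on a
#' neighborhood of source \code{i} (radius \code{R1}), decaying smoothly to
#' zero at radius \code{R2}; used by the finite-difference gradient check,
#' where moving source \code{i} by \eqn{t v} realizes the deformation
#' \eqn{x + t h(x)} exactly on the ball.
#'
#' @param mesh an \code{eik_mesh}.
#' @param center source midpoint (length 2).
#' @param v translation vector (length 2).
#' @param R1 radius of the rigid core (must exceed the source radius).
#' @param R2 support radius (\code{R2 > R1}).
#' @return nodal field (V x 2).
#' @export
translation_bump <- function(mesh, center, v, R1, R2) {
  if (R2 <= R1) stop("R2 must exceed R1")
  rho <- sqrt((mesh$vertices[, 1L] - center[1L])^2 +
              (mesh$vertices[, 2L] - center[2L])^2)
  s <- pmin(pmax((rho - R1) / (R2 - R1), 0), 1)
  chi <- 1 - (3 * s^2 - 2 * s^3)  # cubic smoothstep cutoff
  cbind(chi * v[1L], chi * v[2L])
}

#' Finite-difference check of the shape derivative
#'
#' Compares \eqn{DJ \cdot h} (via the assembled densities) against a
#' finite-difference slope of the misfit under rigid translations of each
#' source.  Because the sources are represented logically, the discrete
#' misfit is piecewise constant in the midpoints at sub-vertex-spacing
#' scales; the slope is therefore estimated by a least-squares secant fit
#' over a symmetric window of a few mesh edge lengths, which averages the
#' staircase.  Two error measures are reported: the per-direction relative
#' error, and the same error normalized by the per-source gradient scale
#' (the largest probed \eqn{|DJ \cdot h|}), which is the well-conditioned
#' measure when a probe direction is nearly orthogonal to the gradient.
#'
#' @param problem an \code{eik_problem}.
#' @param sources current \code{eik_sources}.
#' @param obs observation data.
#' @param directions list of unit 2-vectors (default: 3 directions spread
#'   120 degrees apart).
#' @param window half-width of the finite-difference window, in mesh mean
#'   edge lengths.
#' @param n_samples secant samples per side of the window.
#' @param R1,R2 bump radii (defaults: source radius + 2 mesh edges, and
#'   2.5 x R1 capped away from the outer boundary and the other sources so
#'   the field keeps compact support in U).
#' @param include_S0 passed to \code{\link{assemble_density}}.
#' @return data.frame with one row per (source, direction): \code{DJh},
#'   \code{fd}, \code{rel_err}, \code{rel_err_scaled}.
#' @export
gradient_check <- function(problem, sources, obs, directions = NULL,
                           window = 2, n_samples = 4L, R1 = NULL, R2 = NULL,
                           include_S0 = NULL) {
  if (is.null(directions))
    directions <- lapply(c(0, 2 * pi / 3, 4 * pi / 3) + 0.3,
                         function(a) c(cos(a), sin(a)))
  mesh <- problem$mesh
  state <- solve_newton(problem, sources)
  J0 <- boundary_misfit(mesh, state$T, obs, problem$B_O)
  phi <- solve_adjoint(problem, sources, state$T, obs)
  density <- assemble_density(problem, state$T, phi, sources,
                              include_S0 = include_S0)
  lo <- apply(mesh$vertices, 2L, min)
  hi <- apply(mesh$vertices, 2L, max)
  ts0 <- window * problem$h_mean *
    setdiff(seq(-1, 1, length.out = 2L * n_samples + 1L), 0)
  rows <- list()
  for (i in seq_len(sources$n)) {
    ci <- sources$midpoints[i, ]
    r1 <- if (is.null(R1)) sources$radii[i] + 2 * problem$h_mean else R1
    gap <- min(c(ci - lo, hi - ci))
    others <- if (sources$n > 1L)
      sqrt(rowSums((sources$midpoints[-i, , drop = FALSE] -
                    rep(ci, each = sources$n - 1L))^2)) -
        sources$radii[-i] else Inf
    r2 <- if (is.null(R2)) min(2.5 * r1, gap * 0.95, min(others) * 0.95)
          else R2
    src_rows <- list()
    for (v in directions) {
      hfield <- translation_bump(mesh, ci, v, r1, r2)
      DJh <- shape_derivative(problem, density, hfield)
      Js <- vapply(ts0, function(t) {
        pert <- sources
        pert$midpoints[i, ] <- ci + t * v
        Tp <- solve_newton(problem, pert, initial = state$T)$T
        boundary_misfit(mesh, Tp, obs, problem$B_O)
      }, numeric(1L))
      tt <- c(ts0, 0); JJ <- c(Js, J0)
      fd <- sum((tt - mean(tt)) * (JJ - mean(JJ))) / sum((tt - mean(tt))^2)
      src_rows[[length(src_rows) + 1L]] <- data.frame(
        source = i, vx = v[1L], vy = v[2L], DJh = DJh, fd = fd)
    }
    sr <- do.call(rbind, src_rows)
    scale_i <- max(abs(sr$DJh))
    sr$rel_err <- abs(sr$fd - sr$DJh) / pmax(abs(sr$DJh), 1e-300)
    sr$rel_err_scaled <- abs(sr$fd - sr$DJh) / scale_i
    rows[[length(rows) + 1L]] <- sr
  }
  do.call(rbind, rows)
}
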