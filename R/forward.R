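## ---------------------------------------------------------------------------
## The viscous Eikonal state equation
##     -eps div(M grad T) + |grad T|_M^2 = f   in Omega,
##     T = 0 on the source boundary,  -eps M grad T . n = g on Gamma_N,
## solved either through the Hopf-Cole substitution T = -eps log(w + 1)
## (a single SPD linear solve) or by Newton's method on the nonlinear P1
## system, plus the adjoint (linearized-transposed) equation.
## ---------------------------------------------------------------------------

#' Solver parameters for the state problem
#'
#' @param eps viscosity/diffusion parameter \eqn{\varepsilon > 0} (time
#'   units; 0.1 for the dimensionless 2D benchmark, 80 ms for physiological
#'   geometries).
#' @param f constant source density (default 1).
#' @param g constant non-negative Neumann flux on \code{GammaN} (default 0).
#' @param newton_tol Euclidean norm of the free-node residual at which the
#'   Newton iteration stops.
#' @param newton_max_iter maximum Newton iterations.
#' @param linear_rel_tol relative residual tolerance of the linear solves
#'   inside Newton.
#' @param linear_abs_tol absolute residual tolerance of the adjoint and
#'   perturbation solves.
#' @return a list of class \code{eik_params}.
#' @export
solver_params <- function(eps = 0.1, f = 1, g = 0, newton_tol = 1e-10,
                          newton_max_iter = 30L, linear_rel_tol = 1e-4,
                          linear_abs_tol = 1e-8) {
  if (eps <= 0) stop("eps must be positive")
  if (f <= 0) stop("f must be positive")
  if (g < 0) stop("g must be non-negative")
  if (newton_tol <= 0 || linear_rel_tol <= 0 || linear_abs_tol <= 0)
    stop("tolerances must be positive")
  structure(list(eps = eps, f = f, g = g, newton_tol = newton_tol,
                 newton_max_iter = as.integer(newton_max_iter),
                 linear_rel_tol = linear_rel_tol,
                 linear_abs_tol = linear_abs_tol),
            class = "eik_params")
}

#' Precompute the assembly context of a forward problem
#'
#' Bundles the mesh, conduction tensor and solver parameters with every
#' iterate-independent discrete operator (stiffness, mass, boundary mass,
#' load vectors, per-cell tensor values), so repeated solves during the
#' localization loop reuse them.
#'
#' @param mesh an \code{eik_mesh}.
#' @param M an \code{eik_tensor}.
#' @param params an \code{eik_params}.
#' @return a list of class \code{eik_problem}.
#' @export
eik_problem <- function(mesh, M, params = solver_params()) {
  Mc <- tensor_on_cells(M, mesh)
  alpha <- tensor_ellipticity(M, mesh)
  if (alpha <= 0)
    warning("conduction tensor is not elliptic on sampled cells (min eig ",
            format(alpha), ")")
  K1 <- assemble_stiffness(mesh, M, scale = 1)
  mass <- assemble_mass(mesh)
  B_N <- assemble_boundary_mass(mesh, "GammaN")
  B_O <- if (!is.null(mesh$markers$GammaO))
    assemble_boundary_mass(mesh, "GammaO") else B_N
  structure(list(mesh = mesh, M = M, params = params, Mc = Mc,
                 alpha = alpha, K1 = K1, mass = mass, B_N = B_N, B_O = B_O,
                 load_f = domain_load(mesh, 1),
                 load_g = boundary_load(mesh, "GammaN", 1),
                 h_mean = mesh_size(mesh)[["mean"]],
                 cache = new.env(parent = emptyenv())),
            class = "eik_problem")
}

#' @export
print.eik_problem <- function(x, ...) {
  cat(sprintf(
    "<eik_problem> %d vertices, eps = %g, f = %g, g = %g, M = %s\n",
    nrow(x$mesh$vertices), x$params$eps, x$params$f, x$params$g, x$M$label))
  invisible(x)
}

## resolve a sources/dirichlet specification to a node index vector
resolve_dirichlet <- function(problem, sources) {
  if (inherits(sources, "eik_sources"))
    dirichlet_nodes(problem$mesh, sources)$all
  else as.integer(sources)
}

new_state <- function(T, w = NULL, history = NULL, converged = TRUE,
                      dirichlet = integer(0), method = "hopf_cole") {
  structure(list(T = T, w = w, newton_history = history,
                 converged = converged, dirichlet = dirichlet,
                 method = method),
            class = "eik_state")
}

#' @export
print.eik_state <- function(x, ...) {
  cat(sprintf("<eik_state> %s, converged: %s, max T = %g\n", x$method,
              x$converged, max(x$T)))
  invisible(x)
}

#' Solve the state equation through the Hopf-Cole transformation
#'
#' Solves the linear SPD problem in \eqn{w} (stiffness \eqn{\varepsilon^2 M}
#' plus mass weighted by \eqn{f} plus Robin term \eqn{g} on \code{GammaN},
#' load \eqn{-f} and \eqn{-g}), with \eqn{w = 0} on the source nodes, and
#' returns \eqn{T = -\varepsilon \log(w + 1)}.  The maximum principle bounds
#' \eqn{-1 < w \le 0} are verified on the discrete solution.
#'
#' @param problem an \code{eik_problem}.
#' @param sources an \code{eik_sources}, or directly a vector of Dirichlet
#'   vertex indices.
#' @return an \code{eik_state} carrying both \code{T} and \code{w}.
#' @export
solve_hopf_cole <- function(problem, sources) {
  p <- problem$params
  nodes <- resolve_dirichlet(problem, sources)
  if (length(nodes) == 0L) stop("empty Dirichlet node set")
  K <- p$eps^2 * problem$K1 + p$f * problem$mass
  if (p$g != 0) K <- K + p$g * problem$B_N
  rhs <- -p$f * problem$load_f - p$g * problem$load_g
  sys <- apply_dirichlet(K, rhs, nodes, 0)
  w <- solve_system(sys, solver = "chol")
  wmin <- min(w)
  if (wmin <= -1)
    stop("Hopf-Cole failure: nodal w reaches ", format(wmin),
         " <= -1; transformation undefined")
  if (max(w) > 1e-10)
    warning("Hopf-Cole maximum-principle violation: max w = ",
            format(max(w)))
  T <- -p$eps * log(w + 1)
  new_state(T, w = w, dirichlet = nodes, method = "hopf_cole")
}

## discrete residual of the state equation: r_i = e(T, psi_i)
state_residual <- function(problem, T) {
  p <- problem$params
  mesh <- problem$mesh
  gT <- elementwise_gradient(mesh, T)
  MgT1 <- problem$Mc[, 1L] * gT[, 1L] + problem$Mc[, 2L] * gT[, 2L]
  MgT2 <- problem$Mc[, 2L] * gT[, 1L] + problem$Mc[, 3L] * gT[, 2L]
  q <- gT[, 1L] * MgT1 + gT[, 2L] * MgT2   # |grad T|_M^2 per cell
  r <- p$eps * as.numeric(problem$K1 %*% T)
  w <- (q - p$f) * mesh$area / 3
  for (a in 1:3) {
    acc <- tapply(w, mesh$cells[, a], sum)
    idx <- as.integer(names(acc))
    r[idx] <- r[idx] + acc
  }
  r - p$g * problem$load_g
}

## convection field b = 2 M grad T per cell, and its matrix C with
## C[i,j] = int (b . grad psi_i) psi_j
newton_convection <- function(problem, T) {
  gT <- elementwise_gradient(problem$mesh, T)
  b <- cbind(2 * (problem$Mc[, 1L] * gT[, 1L] + problem$Mc[, 2L] * gT[, 2L]),
             2 * (problem$Mc[, 2L] * gT[, 1L] + problem$Mc[, 3L] * gT[, 2L]))
  assemble_convection(problem$mesh, b)
}

#' Solve the state equation by Newton's method
#'
#' Newton iteration on the discrete nonlinear P1 system; by default it is
#' warm-started from the Hopf-Cole solution (an excellent globalizer), a
#' cold start from \eqn{T = 0} or any supplied field is also possible.
#' Inner linear systems are solved to relative tolerance
#' \code{linear_rel_tol} by preconditioned BiCGSTAB with a direct-LU
#' fallback.
#'
#' @param problem an \code{eik_problem}.
#' @param sources an \code{eik_sources} or Dirichlet vertex indices.
#' @param initial optional initial nodal field, or \code{"hopf_cole"}
#'   (default) / \code{"zero"}.
#' @param precond optional preassembled gauge preconditioner (internal use).
#' @return an \code{eik_state} with the converged \code{T} and the Newton
#'   residual-norm history.
#' @export
solve_newton <- function(problem, sources, initial = "hopf_cole",
                         precond = NULL) {
  p <- problem$params
  nodes <- resolve_dirichlet(problem, sources)
  if (length(nodes) == 0L) stop("empty Dirichlet node set")
  nv <- nrow(problem$mesh$vertices)
  free <- setdiff(seq_len(nv), nodes)
  if (is.character(initial)) {
    initial <- match.arg(initial, c("hopf_cole", "zero"))
    T <- if (initial == "zero") numeric(nv)
         else solve_hopf_cole(problem, nodes)$T
  } else {
    T <- as.numeric(initial)
    T[nodes] <- 0
  }
  if (is.null(precond) || !identical(precond$free, free))
    precond <- make_gauge_precond(problem$mesh, problem$M, p$eps, T, free)
  history <- numeric(0)
  converged <- FALSE
  for (it in seq_len(p$newton_max_iter + 1L)) {
    r <- state_residual(problem, T)[free]
    rn <- sqrt(sum(r^2))
    history <- c(history, rn)
    if (rn <= p$newton_tol) { converged <- TRUE; break }
    if (it > p$newton_max_iter) break
    C <- newton_convection(problem, T)
    KN <- p$eps * problem$K1 + Matrix::t(C)
    KNf <- KN[free, free, drop = FALSE]
    tol <- max(p$linear_rel_tol * rn, 1e-14)
    dT <- solve_convdiff(KNf, -r, precond, mode = "N", tol = tol)
    T[free] <- T[free] + as.numeric(dT)
  }
  if (!converged) {
    err <- simpleError(sprintf(
      "Newton failed to converge in %d iterations (last residual %g)",
      p$newton_max_iter, history[length(history)]))
    err$history <- history
    stop(err)
  }
  if (min(T) < -1e-10)
    warning("state solution violates T >= 0: min T = ", format(min(T)))
  new_state(T, history = history, converged = converged, dirichlet = nodes,
            method = "newton")
}

#' Solve the adjoint state equation
#'
#' Solves \eqn{K_A \varphi = f_A} with \eqn{K_A} the transpose of the Newton
#' system matrix at \code{T} (stiffness plus transposed convection with
#' drift \eqn{2 M \nabla T}), right-hand side
#' \eqn{f_A = -B_O (T - z)} (the sign that makes the assembled shape
#' gradient a descent direction), and \eqn{\varphi = 0} on the source nodes.
#'
#' @param problem an \code{eik_problem}.
#' @param sources an \code{eik_sources} or Dirichlet vertex indices.
#' @param T converged nodal state field.
#' @param obs observation object or full-length nodal vector of \eqn{z}.
#' @param precond optional preassembled gauge preconditioner.
#' @return nodal adjoint field \eqn{\varphi} (length V).
#' @export
solve_adjoint <- function(problem, sources, T, obs, precond = NULL) {
  p <- problem$params
  nodes <- resolve_dirichlet(problem, sources)
  nv <- nrow(problem$mesh$vertices)
  free <- setdiff(seq_len(nv), nodes)
  r <- numeric(nv)
  if (inherits(obs, "eik_obs")) {
    r[obs$nodes] <- T[obs$nodes] - obs$z
  } else {
    onodes <- boundary_vertices(problem$mesh, "GammaO")
    r[onodes] <- T[onodes] - obs[onodes]
  }
  fA <- -as.numeric(problem$B_O %*% r)
  C <- newton_convection(problem, T)
  KA <- p$eps * problem$K1 + C
  KAf <- KA[free, free, drop = FALSE]
  if (is.null(precond) || !identical(precond$free, free))
    precond <- make_gauge_precond(problem$mesh, problem$M, p$eps, T, free)
  phi <- numeric(nv)
  phi[free] <- solve_convdiff(KAf, fA[free], precond, mode = "A",
                              tol = p$linear_abs_tol)
  phi
}
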