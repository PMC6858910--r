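## ---------------------------------------------------------------------------
## Source localization: the outer gradient loop.  Each iteration solves the
## state, adjoint and perturbation problems, averages h over the source
## balls, moves the midpoints by lambda_i h_i (capped at step length ell),
## and accepts/backtracks on the misfit J.  The mesh is never touched; only
## the logical source positions (hence their Dirichlet node sets) change.
## ---------------------------------------------------------------------------

#' Configuration of the localization loop
#'
#' @param ell step-length cap on \eqn{\|\lambda_i h_i\|}; default 2 mesh
#'   mean edge lengths (resolved at run time), the middle of the recommended
#'   1-3 edge-length range.
#' @param theta step-scale growth factor applied to \eqn{\lambda_i} after an
#'   accepted step (> 1).
#' @param alpha_bt backtracking shrink factor in (0, 1).
#' @param tol_rel stop when \eqn{J^k / J^0 \le} \code{tol_rel}.
#' @param tol_abs stop immediately when \eqn{J^k \le} \code{tol_abs}
#'   (guards the already-converged start).
#' @param max_iter maximum outer iterations.
#' @param max_backtracks consecutive rejected steps before giving up.
#' @param stagnation_fraction stop when every \eqn{\|\lambda_i h_i\|} falls
#'   below this fraction of the mean edge length; the default 0.01 lets the
#'   midpoints settle well below the mesh size before declaring stagnation.
#' @param include_S0 include the S0 density (default: automatic).
#' @param diagnostics record the six-way diagnostic split each iteration.
#' @param verbose print one line per iteration.
#' @return list of class \code{eik_config}.
#' @export
localization_config <- function(ell = NULL, theta = 1.5, alpha_bt = 0.5,
                                tol_rel = 1e-8, tol_abs = 1e-14,
                                max_iter = 200L, max_backtracks = 10L,
                                stagnation_fraction = 0.01,
                                include_S0 = NULL, diagnostics = FALSE,
                                verbose = FALSE) {
  if (!is.null(ell) && ell <= 0) stop("ell must be positive")
  if (theta <= 1) stop("theta must exceed 1")
  if (alpha_bt <= 0 || alpha_bt >= 1) stop("alpha_bt must lie in (0,1)")
  structure(list(ell = ell, theta = theta, alpha_bt = alpha_bt,
                 tol_rel = tol_rel, tol_abs = tol_abs,
                 max_iter = as.integer(max_iter),
                 max_backtracks = as.integer(max_backtracks),
                 stagnation_fraction = stagnation_fraction,
                 include_S0 = include_S0, diagnostics = diagnostics,
                 verbose = verbose),
            class = "eik_config")
}

#' Move source midpoints along the averaged perturbation field
#'
#' Displaces each midpoint by \eqn{\lambda_i h_i}, reducing \eqn{\lambda_i}
#' whenever \eqn{\|\lambda_i h_i\| > \ell} so the cap is met exactly, and
#' halving any step that would leave the domain bounding box (error after 30
#' halvings).
#'
#' @param midpoints N x 2 matrix.
#' @param h_avg N x 2 per-source averaged field.
#' @param lambda per-source step scales.
#' @param ell step cap.
#' @param bbox 2 x 2 matrix (rows: lower/upper corner) of the domain, or
#'   NULL to skip the inside test.
#' @return list: \code{midpoints}, clipped \code{lambda}, displacement
#'   matrix \code{disp}.
#' @export
step_midpoints <- function(midpoints, h_avg, lambda, ell, bbox = NULL) {
  n <- nrow(midpoints)
  disp <- h_avg * lambda
  for (i in seq_len(n)) {
    nrm <- sqrt(sum(disp[i, ]^2))
    if (nrm > ell) {
      lambda[i] <- lambda[i] * ell / nrm
      disp[i, ] <- disp[i, ] * ell / nrm
    }
    if (!is.null(bbox)) {
      cand <- midpoints[i, ] + disp[i, ]
      halvings <- 0L
      while (any(cand <= bbox[1L, ] | cand >= bbox[2L, ])) {
        disp[i, ] <- disp[i, ] / 2
        cand <- midpoints[i, ] + disp[i, ]
        halvings <- halvings + 1L
        if (halvings > 30L)
          stop("cannot keep source ", i, " inside the domain")
      }
    }
  }
  list(midpoints = midpoints + disp, lambda = lambda, disp = disp)
}

#' Backtracking decision rule
#'
#' Accepted steps (candidate J not above the current J) scale every
#' \eqn{\lambda_i} up by \eqn{\theta}; rejected steps shrink them by
#' \eqn{\alpha_{bt}} and restore the midpoints.
#'
#' @param J_current,candidate_J misfit before/after the trial step.
#' @param lambda per-source step scales.
#' @param theta,alpha_bt growth/shrink factors.
#' @return list: logical \code{accept}, updated \code{lambda}.
#' @export
backtrack_update <- function(J_current, candidate_J, lambda, theta,
                             alpha_bt) {
  if (candidate_J <= J_current)
    list(accept = TRUE, lambda = lambda * theta)
  else
    list(accept = FALSE, lambda = lambda * alpha_bt)
}

#' Run the source-localization algorithm
#'
#' The outer loop of the inverse method: starting from the initial
#' midpoints, repeatedly solve state/adjoint/perturbation problems, shift
#' the midpoints, and accept or backtrack on the misfit.  Accepted-step
#' \eqn{J^k} is non-increasing by construction.
#'
#' @param mesh an \code{eik_mesh} (or an \code{eik_problem}, which is then
#'   used directly and \code{M}/\code{params} ignored).
#' @param M an \code{eik_tensor}.
#' @param params an \code{eik_params}.
#' @param obs observation data (\code{eik_obs} or nodal vector).
#' @param init_midpoints N x 2 matrix of starting midpoints.
#' @param radii source radii.
#' @param config an \code{eik_config}.
#' @param truth optional N x 2 matrix of reference midpoints; enables the
#'   distance history \eqn{d_i^k}.
#' @return object of class \code{eik_locresult}: final \code{midpoints},
#'   \code{trajectory} (list of N x 2 matrices, entry k+1 = iterate k),
#'   \code{J_history}, \code{d_history}, per-iteration \code{step_norms},
#'   \code{lambda}, \code{status}, optional \code{diagnostics}.
#' @export
run_localization <- function(mesh, M = NULL, params = solver_params(), obs,
                             init_midpoints, radii,
                             config = localization_config(), truth = NULL) {
  problem <- if (inherits(mesh, "eik_problem")) mesh
             else eik_problem(mesh, M, params)
  mesh <- problem$mesh
  p <- problem$params
  ell <- if (is.null(config$ell)) 2 * problem$h_mean else config$ell
  bbox <- rbind(apply(mesh$vertices, 2L, min), apply(mesh$vertices, 2L, max))
  nv <- nrow(mesh$vertices)

  sources <- source_set(init_midpoints, radii)
  n <- sources$n
  state <- solve_newton(problem, sources)
  J <- boundary_misfit(mesh, state$T, obs, problem$B_O)
  J0 <- J
  dist_to <- function(mp) if (is.null(truth)) rep(NA_real_, n)
    else sqrt(rowSums((mp - truth)^2))

  trajectory <- list(sources$midpoints)
  J_history <- J
  d_history <- list(dist_to(sources$midpoints))
  step_log <- list()
  diag_log <- list()
  lambda <- rep(NA_real_, n)
  status <- "max_iter"
  consec_rejects <- 0L

  if (J0 <= config$tol_abs) {
    status <- "tol_reached"
  } else {
    for (k in seq_len(config$max_iter)) {
      free <- setdiff(seq_len(nv), resolve_dirichlet(problem, sources))
      precond <- make_gauge_precond(mesh, problem$M, p$eps, state$T, free)
      phi <- solve_adjoint(problem, sources, state$T, obs, precond = precond)
      density <- assemble_density(problem, state$T, phi, sources,
                                  include_S0 = config$include_S0)
      pert <- solve_perturbation(problem, density)
      if (pert$DJh > abs(pert$DJh) * 1e-8)
        warning("shape derivative is not a descent value: DJh = ",
                format(pert$DJh))
      h_avg <- average_over_sources(mesh, pert$h, sources)
      if (k == 1L) {
        hn <- sqrt(rowSums(h_avg^2))
        lambda <- ell / pmax(hn, 1e-14)
      }
      if (isTRUE(config$diagnostics)) {
        ds <- diagnostic_split(problem, state$T, phi, pert$h, density)
        diag_log[[k]] <- c(iter = k, ds$values, DJh = pert$DJh,
                           signed_sum = ds$signed_sum)
      }

      accepted <- FALSE
      for (bt in 0:config$max_backtracks) {
        st <- step_midpoints(sources$midpoints, h_avg, lambda, ell, bbox)
        cand <- sources
        cand$midpoints <- st$midpoints
        cand_state <- solve_newton(problem, cand, initial = state$T,
                                   precond = precond)
        Jc <- boundary_misfit(mesh, cand_state$T, obs, problem$B_O)
        upd <- backtrack_update(J, Jc, st$lambda, config$theta,
                                config$alpha_bt)
        if (upd$accept) {
          sources <- cand
          state <- cand_state
          J <- Jc
          lambda <- upd$lambda
          step_norms <- sqrt(rowSums(st$disp^2))
          accepted <- TRUE
          consec_rejects <- 0L
          break
        }
        lambda <- upd$lambda
        consec_rejects <- consec_rejects + 1L
        if (consec_rejects >= config$max_backtracks) break
      }
      if (!accepted) { status <- "backtrack_exhausted"; break }

      trajectory[[length(trajectory) + 1L]] <- sources$midpoints
      J_history <- c(J_history, J)
      d_history[[length(d_history) + 1L]] <- dist_to(sources$midpoints)
      step_log[[length(step_log) + 1L]] <- step_norms
      if (isTRUE(config$verbose))
        cat(sprintf("iter %3d  J/J0 = %.3e  max step = %.3e  max d = %.3e\n",
                    k, J / J0, max(step_norms),
                    suppressWarnings(max(dist_to(sources$midpoints)))))
      if (J / J0 <= config$tol_rel || J <= config$tol_abs) {
        status <- "tol_reached"; break
      }
      if (all(step_norms < config$stagnation_fraction * problem$h_mean)) {
        status <- "stagnated"; break
      }
    }
  }

  structure(list(midpoints = sources$midpoints, radii = sources$radii,
                 trajectory = trajectory, J_history = J_history,
                 d_history = do.call(rbind, d_history),
                 step_norms = if (length(step_log)) do.call(rbind, step_log)
                              else NULL,
                 lambda = lambda, status = status, J0 = J0, J = J,
                 n_iter = length(trajectory) - 1L,
                 diagnostics = if (length(diag_log))
                   as.data.frame(do.call(rbind, diag_log)) else NULL,
                 final_state = state),
            class = "eik_locresult")
}

#' @export
print.eik_locresult <- function(x, ...) {
  cat(sprintf("<eik_locresult> %d iterations, status: %s\n", x$n_iter,
              x$status))
  cat(sprintf("  J/J0 = %.3e\n", x$J / x$J0))
  d <- x$d_history[nrow(x$d_history), ]
  if (!anyNA(d))
    cat(sprintf("  final distances d_i: %s\n",
                paste(format(d, digits = 3), collapse = ", ")))
  invisible(x)
}
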