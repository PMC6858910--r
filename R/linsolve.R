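## ---------------------------------------------------------------------------
## Linear solvers.
##
## The SPD systems (Hopf-Cole, perturbation smoother) are solved by sparse
## Cholesky with factor caching.  The nonsymmetric convection-diffusion
## systems (Newton step, adjoint) are solved by BiCGSTAB preconditioned with
## the gauge-transformed SPD operator
##     K~ = eps * stiffness(exp(-2T/eps) M),
## which symmetrizes the drift 2 M grad(T) exactly at the continuous level.
## If the iteration does not reach its tolerance a direct sparse LU solve is
## used instead, so the solver contract (relative 1e-4 for Newton steps,
## absolute 1e-8 elsewhere) always holds.
## ---------------------------------------------------------------------------

## BiCGSTAB for Ax = b with left preconditioner psolve(r) ~ A^{-1} r.
## Stops when ||b - Ax||_2 <= tol (unpreconditioned residual).
bicgstab <- function(A, b, psolve, x0 = NULL, tol, maxit = 300L) {
  n <- length(b)
  x <- if (is.null(x0)) numeric(n) else x0
  r <- b - as.numeric(A %*% x)
  if (sqrt(sum(r^2)) <= tol)
    return(list(x = x, converged = TRUE, iter = 0L, resid = sqrt(sum(r^2))))
  r0 <- r
  rho <- alpha <- omega <- 1
  v <- p <- numeric(n)
  for (it in seq_len(maxit)) {
    rho1 <- sum(r0 * r)
    if (abs(rho1) < 1e-300) break
    beta <- (rho1 / rho) * (alpha / omega)
    rho <- rho1
    p <- r + beta * (p - omega * v)
    phat <- psolve(p)
    v <- as.numeric(A %*% phat)
    alpha <- rho / sum(r0 * v)
    s <- r - alpha * v
    if (sqrt(sum(s^2)) <= tol) {
      x <- x + alpha * phat
      return(list(x = x, converged = TRUE, iter = it,
                  resid = sqrt(sum(s^2))))
    }
    shat <- psolve(s)
    t <- as.numeric(A %*% shat)
    omega <- sum(t * s) / sum(t * t)
    x <- x + alpha * phat + omega * shat
    r <- s - omega * t
    rn <- sqrt(sum(r^2))
    if (rn <= tol)
      return(list(x = x, converged = TRUE, iter = it, resid = rn))
    if (!is.finite(rn)) break
  }
  list(x = x, converged = FALSE, iter = maxit, resid = sqrt(sum(r^2)))
}

## Gauge preconditioner for the convection-diffusion pair
##   K_N = eps K(M) + C(2 M grad T)^T   (Newton: gradient on trial slot)
##   K_A = t(K_N)                       (adjoint)
## Returns cholesky factor of the reduced K~ plus the nodal weight D.
make_gauge_precond <- function(mesh, M, eps, Tfield, free) {
  Tc <- pmax(cell_mean(mesh, Tfield), 0)
  wcell <- exp(-2 * Tc / eps)
  Kt <- assemble_stiffness(mesh, M, scale = eps, cell_weight = wcell)
  Ktf <- Kt[free, free, drop = FALSE]
  ## tiny diagonal shift guards the pure-Neumann limit (empty Dirichlet set
  ## never occurs in practice, but keeps the factorization safe)
  ch <- Matrix::Cholesky(Matrix::forceSymmetric(Ktf), LDL = FALSE,
                         Imult = 1e-12)
  Dn <- exp(-2 * pmax(Tfield[free], 0) / eps)
  list(chol = ch, D = Dn, free = free)
}

## Solve the reduced system A x = b (A = K_N or K_A restricted to free
## nodes).  mode "N": preconditioner z = K~^{-1}(D r); mode "A" (transpose
## operator): z = D K~^{-1} r.
solve_convdiff <- function(A, b, precond = NULL, mode = c("N", "A"),
                           tol, x0 = NULL, maxit = 250L) {
  mode <- match.arg(mode)
  if (!is.null(precond)) {
    psolve <- if (mode == "N") {
      function(r) as.numeric(Matrix::solve(precond$chol, precond$D * r))
    } else {
      function(r) precond$D * as.numeric(Matrix::solve(precond$chol, r))
    }
    res <- bicgstab(A, b, psolve, x0 = x0, tol = tol, maxit = maxit)
    if (res$converged) {
      attr(res$x, "solver") <- c(method = "bicgstab", iter = res$iter)
      return(res$x)
    }
  }
  x <- as.numeric(Matrix::solve(A, b))
  attr(x, "solver") <- c(method = "lu", iter = NA)
  x
}
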