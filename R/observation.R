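## ---------------------------------------------------------------------------
## Observed activation maps z on the observatory boundary Gamma_O:
## noise-free reference traces (case RI) and degraded data obtained by
## subsampling at uniformly spaced boundary points, adding zero-average
## uniform noise scaled by the domain-mean activation time, and
## inverse-distance (Shepard) interpolation back onto the Gamma_O vertices
## (cases II for xi = 0 and PI for xi > 0).
## ---------------------------------------------------------------------------

new_obs <- function(nodes, z, coords, case, m = NA_integer_, xi = NA_real_,
                    seed = NA_integer_, mean_T = NA_real_) {
  structure(list(nodes = nodes, z = z, coords = coords, case = case,
                 m = m, xi = xi, seed = seed, mean_T = mean_T),
            class = "eik_obs")
}

#' @export
print.eik_obs <- function(x, ...) {
  cat(sprintf("<eik_obs> case %s, %d GammaO vertices", x$case,
              length(x$nodes)))
  if (!is.na(x$m)) cat(sprintf(", m = %d samples, xi = %g", x$m, x$xi))
  cat("\n")
  invisible(x)
}

#' Noise-free reference observation (case RI)
#'
#' Solves the state equation for the true sources and restricts the
#' activation-time field to the \code{GammaO} vertices.
#'
#' @param problem an \code{eik_problem} (or an \code{eik_mesh}, with
#'   \code{M} and \code{params} supplied).
#' @param true_sources an \code{eik_sources}.
#' @param M,params used only when \code{problem} is a mesh.
#' @return an \code{eik_obs} tagged \code{"RI"}; carries the domain-mean
#'   reference activation time needed by \code{\link{degrade_observation}}.
#' @export
reference_observation <- function(problem, true_sources, M = NULL,
                                  params = solver_params()) {
  if (inherits(problem, "eik_mesh")) problem <- eik_problem(problem, M, params)
  mesh <- problem$mesh
  state <- solve_newton(problem, true_sources)
  nodes <- boundary_vertices(mesh, "GammaO")
  ## domain mean of T^r over the discrete Omega (cells outside the sources)
  dn <- resolve_dirichlet(problem, true_sources)
  isdir <- logical(nrow(mesh$vertices)); isdir[dn] <- TRUE
  in_omega <- !(isdir[mesh$cells[, 1L]] | isdir[mesh$cells[, 2L]] |
                isdir[mesh$cells[, 3L]])
  Tc <- cell_mean(mesh, state$T)
  mean_T <- sum((mesh$area * Tc)[in_omega]) / sum(mesh$area[in_omega])
  obs <- new_obs(nodes, state$T[nodes], mesh$vertices[nodes, , drop = FALSE],
                 case = "RI", mean_T = mean_T)
  attr(obs, "T_full") <- state$T
  attr(obs, "loop") <- boundary_loop(mesh, "GammaO")
  attr(obs, "mesh_vertices") <- mesh$vertices
  obs
}

#' Degrade a reference observation (cases II and PI)
#'
#' Reproduces the observation-degradation pipeline dimension-agnostically on
#' the boundary polyline: (1) place \code{m} sample points uniformly spaced
#' in arclength along \code{GammaO}; (2) read the nearest-vertex trace value
#' at each; (3) add independent uniform noise
#' \eqn{\xi_i \in [-\xi/2, \xi/2]} scaled by the domain-mean reference
#' activation time; (4) interpolate back onto every \code{GammaO} vertex by
#' inverse-distance (Shepard) weighting, exact at sample hits.
#'
#' @param obs a reference observation from
#'   \code{\link{reference_observation}}.
#' @param m number of sample points (clipped with a warning at the number of
#'   \code{GammaO} vertices).
#' @param xi noise level (0 gives case II, > 0 case PI).
#' @param seed RNG seed for the noise draw (unused when \code{xi = 0}).
#' @param idw_power Shepard weight exponent.
#' @return an \code{eik_obs}.
#' @export
degrade_observation <- function(obs, m, xi = 0, seed = 1L, idw_power = 2) {
  if (!inherits(obs, "eik_obs") || obs$case != "RI")
    stop("degrade_observation expects a reference (RI) observation")
  if (m < 2) stop("m must be at least 2")
  if (xi < 0) stop("xi must be non-negative")
  loop <- attr(obs, "loop")
  verts <- attr(obs, "mesh_vertices")
  if (m > length(loop)) {
    warning("m exceeds the number of GammaO vertices; clipped to ",
            length(loop))
    m <- length(loop)
  }
  pts <- verts[loop, , drop = FALSE]
  seg <- sqrt(rowSums((rbind(pts[-1L, , drop = FALSE], pts[1L, ,
                             drop = FALSE]) - pts)^2))
  cum <- c(0, cumsum(seg))           # arclength at loop vertices, closed
  total <- cum[length(cum)]
  s_pos <- (seq_len(m) - 1L) * total / m
  ## coordinates of the arclength-uniform sample points on the polyline
  si <- findInterval(s_pos, cum, rightmost.closed = TRUE)
  frac <- (s_pos - cum[si]) / seg[si]
  nxt <- c(seq_along(loop)[-1L], 1L)
  scoord <- pts[si, , drop = FALSE] +
    frac * (pts[nxt[si], , drop = FALSE] - pts[si, , drop = FALSE])
  ## nearest GammaO vertex value at each sample point
  tvals <- numeric(m)
  Tfull <- attr(obs, "T_full")
  for (k in seq_len(m)) {
    d2 <- (obs$coords[, 1L] - scoord[k, 1L])^2 +
          (obs$coords[, 2L] - scoord[k, 2L])^2
    tvals[k] <- Tfull[obs$nodes[which.min(d2)]]
  }
  if (xi > 0) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv()) else NULL
    set.seed(as.integer(seed))
    noise <- runif(m, -xi / 2, xi / 2)
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    tvals <- tvals + noise * obs$mean_T
  }
  ## Shepard interpolation back onto all GammaO vertices
  z <- numeric(length(obs$nodes))
  for (k in seq_along(obs$nodes)) {
    d <- sqrt((scoord[, 1L] - obs$coords[k, 1L])^2 +
              (scoord[, 2L] - obs$coords[k, 2L])^2)
    hit <- which(d < 1e-12)
    if (length(hit)) {
      z[k] <- tvals[hit[1L]]
    } else {
      w <- 1 / d^idw_power
      z[k] <- sum(w * tvals) / sum(w)
    }
  }
  new_obs(obs$nodes, z, obs$coords,
          case = if (xi == 0) "II" else "PI",
          m = as.integer(m), xi = xi,
          seed = if (xi > 0) as.integer(seed) else NA_integer_,
          mean_T = obs$mean_T)
}

#' Write an observation table to CSV
#'
#' Columns: vertex id, coordinates, z.
#'
#' @param obs an \code{eik_obs}.
#' @param path output path.
#' @export
write_observation_csv <- function(obs, path) {
  utils::write.csv(data.frame(vertex = obs$nodes, x = obs$coords[, 1L],
                              y = obs$coords[, 2L], z = obs$z),
                   path, row.names = FALSE)
  invisible(path)
}
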