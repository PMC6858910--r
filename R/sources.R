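## ---------------------------------------------------------------------------
## Activation sources: balls omega_i = B_{r_i}(x_i) represented logically.
## The mesh is never deformed; moving a source only changes which vertices
## fall inside its ball (the Dirichlet node set where T = 0).
## ---------------------------------------------------------------------------

#' Define a set of activation sources
#'
#' Each source is a ball \eqn{B_{r_i}(x_i)}; activation starts simultaneously
#' on all of them, so the activation time is held at zero on every mesh
#' vertex inside a ball.
#'
#' @param midpoints numeric matrix, one row per source (2 columns).
#' @param radii positive radii, recycled to the number of sources.
#' @return an object of class \code{eik_sources}.
#' @export
source_set <- function(midpoints, radii) {
  midpoints <- rbind(midpoints)
  storage.mode(midpoints) <- "double"
  n <- nrow(midpoints)
  radii <- rep_len(as.numeric(radii), n)
  if (any(radii <= 0)) stop("all source radii must be positive")
  structure(list(midpoints = midpoints, radii = radii, n = n),
            class = "eik_sources")
}

#' @export
print.eik_sources <- function(x, ...) {
  cat(sprintf("<eik_sources> %d source(s)\n", x$n))
  for (i in seq_len(x$n))
    cat(sprintf("  x_%d = (%s), r = %g\n", i,
                paste(format(x$midpoints[i, ]), collapse = ", "), x$radii[i]))
  invisible(x)
}

#' Dirichlet node sets of the source balls
#'
#' Returns the mesh vertices inside the closed ball of each source.  A ball
#' that contains no vertex is assigned its single nearest vertex (with a
#' warning) so that the state problem keeps a nonempty Dirichlet set.
#'
#' @param mesh an \code{eik_mesh}.
#' @param sources an \code{eik_sources}.
#' @return list with \code{per_source} (list of integer vectors) and
#'   \code{all} (sorted union).
#' @export
dirichlet_nodes <- function(mesh, sources) {
  v <- mesh$vertices
  per <- vector("list", sources$n)
  for (i in seq_len(sources$n)) {
    d2 <- (v[, 1L] - sources$midpoints[i, 1L])^2 +
          (v[, 2L] - sources$midpoints[i, 2L])^2
    idx <- which(d2 <= sources$radii[i]^2)
    if (length(idx) == 0L) {
      idx <- which.min(d2)
      warning(sprintf(
        "source %d ball contains no vertex; snapped to nearest vertex %d", i,
        idx))
    }
    per[[i]] <- idx
  }
  list(per_source = per, all = sort(unique(unlist(per))))
}
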