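#' @importFrom Matrix sparseMatrix Cholesky forceSymmetric t crossprod Diagonal
#' @importFrom methods as is
#' @importFrom stats runif setNames
NULL

## ---------------------------------------------------------------------------
## Simplicial meshes of the hold-all domain U
##
## A mesh is a plain list of class "eik_mesh":
##   vertices  V x 2 matrix of coordinates
##   cells     C x 3 integer matrix (counter-clockwise orientation)
##   markers   named list: marker label -> E x 2 matrix of boundary edges
##   dim       spatial dimension (2)
## plus cached per-cell geometry (areas, P1 basis gradients, centroids,
## edge-midpoint quadrature points) so that assembly never recomputes it.
## ---------------------------------------------------------------------------

#' Construct a triangular mesh
#'
#' Builds the internal mesh representation from raw vertex/cell/boundary
#' arrays, enforcing counter-clockwise cell orientation and precomputing the
#' per-cell quantities (signed areas, P1 basis gradients, centroids and
#' degree-2 quadrature points) used by all assembly routines.
#'
#' @param vertices numeric matrix, one row per vertex (2 columns).
#' @param cells integer matrix, one row per triangle (3 vertex indices,
#'   1-based).
#' @param markers named list mapping a boundary marker label (e.g.
#'   \code{"GammaN"}, \code{"GammaO"}) to a two-column matrix of boundary-edge
#'   vertex indices.  Marked edges must be edges of exactly one cell.
#' @return an object of class \code{eik_mesh}.
#' @export
eik_mesh <- function(vertices, cells, markers = list()) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  cells <- as.matrix(cells)
  storage.mode(cells) <- "integer"
  dimnames(vertices) <- dimnames(cells) <- NULL
  if (ncol(vertices) != 2L) stop("only 2-dimensional meshes are supported")
  if (ncol(cells) != 3L) stop("cells must be vertex triples")
  if (min(cells) < 1L || max(cells) > nrow(vertices))
    stop("cell vertex index out of range")

  x <- matrix(vertices[cells, 1L], ncol = 3L)
  y <- matrix(vertices[cells, 2L], ncol = 3L)
  twoA <- (x[, 2L] - x[, 1L]) * (y[, 3L] - y[, 1L]) -
          (x[, 3L] - x[, 1L]) * (y[, 2L] - y[, 1L])
  flip <- twoA < 0
  if (any(flip)) { # enforce counter-clockwise orientation
    cells[flip, 2:3] <- cells[flip, 3:2]
    x <- matrix(vertices[cells, 1L], ncol = 3L)
    y <- matrix(vertices[cells, 2L], ncol = 3L)
    twoA <- abs(twoA)
  }
  if (any(twoA <= 0)) stop("degenerate cell (zero area) encountered")
  area <- twoA / 2

  ## P1 basis gradients: grad psi_k = (b_k, c_k) / (2A)
  gx <- cbind(y[, 2L] - y[, 3L], y[, 3L] - y[, 1L], y[, 1L] - y[, 2L]) / twoA
  gy <- cbind(x[, 3L] - x[, 2L], x[, 1L] - x[, 3L], x[, 2L] - x[, 1L]) / twoA
  centroid <- cbind(rowMeans(x), rowMeans(y))
  ## degree-2 quadrature: edge midpoints, weights 1/3
  qx <- cbind((x[, 1L] + x[, 2L]) / 2, (x[, 2L] + x[, 3L]) / 2,
              (x[, 3L] + x[, 1L]) / 2)
  qy <- cbind((y[, 1L] + y[, 2L]) / 2, (y[, 2L] + y[, 3L]) / 2,
              (y[, 3L] + y[, 1L]) / 2)

  markers <- lapply(markers, function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "integer"
    if (ncol(m) != 2L) stop("boundary edges must be vertex pairs")
    m
  })

  structure(list(vertices = vertices, cells = cells, markers = markers,
                 dim = 2L, area = area, gx = gx, gy = gy,
                 centroid = centroid, qx = qx, qy = qy),
            class = "eik_mesh")
}

#' @export
print.eik_mesh <- function(x, ...) {
  cat(sprintf("<eik_mesh> %d vertices, %d triangles, markers: %s\n",
              nrow(x$vertices), nrow(x$cells),
              paste(names(x$markers), collapse = ", ")))
  invisible(x)
}

#' Structured triangulation of a rectangle
#'
#' Triangulates \eqn{(0,L_x) \times (0,L_y)} with \code{nx} by \code{ny}
#' square (or rectangular) cells, each split along the lower-left to
#' upper-right diagonal.  All four sides carry both the \code{GammaN}
#' (Neumann) and \code{GammaO} (observatory) markers.
#'
#' @param nx,ny number of cells per side.
#' @param Lx,Ly side lengths.
#' @return an \code{eik_mesh} with \code{(nx+1)(ny+1)} vertices and
#'   \code{2 nx ny} triangles.
#' @export
rect_mesh <- function(nx, ny, Lx = 1, Ly = 1) {
  if (length(nx) != 1L || nx < 1 || nx != round(nx))
    stop("nx must be a positive integer")
  if (length(ny) != 1L || ny < 1 || ny != round(ny))
    stop("ny must be a positive integer")
  nx <- as.integer(nx); ny <- as.integer(ny)
  xs <- seq(0, Lx, length.out = nx + 1L)
  ys <- seq(0, Ly, length.out = ny + 1L)
  vertices <- cbind(rep(xs, times = ny + 1L), rep(ys, each = nx + 1L))
  vid <- function(i, j) (j - 1L) * (nx + 1L) + i  # i in 1..nx+1, j in 1..ny+1
  i <- rep(seq_len(nx), times = ny)
  j <- rep(seq_len(ny), each = nx)
  ll <- vid(i, j); lr <- vid(i + 1L, j)
  ul <- vid(i, j + 1L); ur <- vid(i + 1L, j + 1L)
  ## split along ll -> ur diagonal
  cells <- rbind(cbind(ll, lr, ur), cbind(ll, ur, ul))
  bottom <- cbind(vid(seq_len(nx), 1L), vid(seq_len(nx) + 1L, 1L))
  top    <- cbind(vid(seq_len(nx), ny + 1L), vid(seq_len(nx) + 1L, ny + 1L))
  left   <- cbind(vid(1L, seq_len(ny)), vid(1L, seq_len(ny) + 1L))
  right  <- cbind(vid(nx + 1L, seq_len(ny)), vid(nx + 1L, seq_len(ny) + 1L))
  bnd <- rbind(bottom, right, top, left)
  eik_mesh(vertices, cells, markers = list(GammaN = bnd, GammaO = bnd))
}

#' Structured triangulation of the unit square
#'
#' @param n_cells cells per side; the mesh has \code{(n_cells+1)^2} vertices
#'   and \code{2 n_cells^2} triangles.
#' @return an \code{eik_mesh}.
#' @export
unit_square_mesh <- function(n_cells) rect_mesh(n_cells, n_cells, 1, 1)

## unique undirected edges of the mesh, as a 2-column matrix
mesh_edges <- function(mesh) {
  cells <- mesh$cells
  e <- rbind(cells[, c(1L, 2L)], cells[, c(2L, 3L)], cells[, c(3L, 1L)])
  e <- cbind(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
  unique(e)
}

#' Mesh resolution
#'
#' @param mesh an \code{eik_mesh}.
#' @return named numeric vector with the minimum and mean length over the
#'   unique mesh edges.
#' @export
mesh_size <- function(mesh) {
  e <- mesh_edges(mesh)
  d <- sqrt(rowSums((mesh$vertices[e[, 1L], , drop = FALSE] -
                     mesh$vertices[e[, 2L], , drop = FALSE])^2))
  c(min = min(d), mean = mean(d))
}

#' Marked boundary facets with outward normals
#'
#' @param mesh an \code{eik_mesh}.
#' @param marker boundary marker label.
#' @return data.frame with vertex indices \code{v1}, \code{v2}, outward unit
#'   normal components \code{nx}, \code{ny} and facet length \code{len}.
#' @export
boundary_facets <- function(mesh, marker) {
  edges <- mesh$markers[[marker]]
  if (is.null(edges)) stop("unknown boundary marker: ", marker)
  p1 <- mesh$vertices[edges[, 1L], , drop = FALSE]
  p2 <- mesh$vertices[edges[, 2L], , drop = FALSE]
  tvec <- p2 - p1
  len <- sqrt(rowSums(tvec^2))
  nx <- tvec[, 2L] / len
  ny <- -tvec[, 1L] / len
  ## orient outward: the normal must point away from the owning cell's
  ## opposite vertex
  own <- edge_owner_cell(mesh, edges)
  opp <- integer(nrow(edges))
  for (k in 1:3) {
    cand <- mesh$cells[own, k]
    use <- cand != edges[, 1L] & cand != edges[, 2L]
    opp[use] <- cand[use]
  }
  mid <- (p1 + p2) / 2
  toopp <- mesh$vertices[opp, , drop = FALSE] - mid
  flip <- (nx * toopp[, 1L] + ny * toopp[, 2L]) > 0
  nx[flip] <- -nx[flip]; ny[flip] <- -ny[flip]
  data.frame(v1 = edges[, 1L], v2 = edges[, 2L], nx = nx, ny = ny, len = len)
}

## for each (boundary) edge, the index of a cell containing it
edge_owner_cell <- function(mesh, edges) {
  cells <- mesh$cells
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  all_e <- c(key(cells[, 1L], cells[, 2L]), key(cells[, 2L], cells[, 3L]),
             key(cells[, 3L], cells[, 1L]))
  owner <- rep(seq_len(nrow(cells)), 3L)
  m <- match(key(edges[, 1L], edges[, 2L]), all_e)
  if (anyNA(m)) stop("marked edge is not an edge of any cell")
  owner[m]
}

#' Vertices lying on a marked boundary
#'
#' @param mesh an \code{eik_mesh}.
#' @param marker boundary marker label.
#' @return sorted integer vector of vertex indices.
#' @export
boundary_vertices <- function(mesh, marker) {
  edges <- mesh$markers[[marker]]
  if (is.null(edges)) stop("unknown boundary marker: ", marker)
  sort(unique(as.vector(edges)))
}

## Ordered closed loop of vertices along a marked boundary (assumes the
## marked edge set forms a single cycle, as on the benchmark geometries).
boundary_loop <- function(mesh, marker) {
  edges <- mesh$markers[[marker]]
  if (is.null(edges)) stop("unknown boundary marker: ", marker)
  verts <- sort(unique(as.vector(edges)))
  adj <- vector("list", length(verts))
  names(adj) <- as.character(verts)
  for (r in seq_len(nrow(edges))) {
    a <- as.character(edges[r, 1L]); b <- as.character(edges[r, 2L])
    adj[[a]] <- c(adj[[a]], edges[r, 2L])
    adj[[b]] <- c(adj[[b]], edges[r, 1L])
  }
  if (any(lengths(adj) != 2L))
    stop("marked boundary is not a single closed loop")
  start <- verts[1L]
  loop <- integer(length(verts))
  loop[1L] <- start
  prev <- -1L
  cur <- start
  for (k in seq_len(length(verts) - 1L)) {
    nb <- adj[[as.character(cur)]]
    nxt <- if (nb[1L] == prev) nb[2L] else nb[1L]
    loop[k + 1L] <- nxt
    prev <- cur
    cur <- nxt
  }
  loop
}

## ---------------------------------------------------------------------------
## Plain-text mesh exchange format
## ---------------------------------------------------------------------------

#' Write a mesh to a plain-text file
#'
#' Sections: \code{$vertices} (one coordinate pair per line),
#' \code{$cells} (one vertex-index triple per line) and one
#' \code{$marker <label>} section per boundary marker (one edge per line).
#' Indices are written 1-based.
#'
#' @param mesh an \code{eik_mesh}.
#' @param path output file path.
#' @export
write_mesh_text <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("$vertices", con)
  utils::write.table(format(mesh$vertices, digits = 17, trim = TRUE), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  writeLines("$cells", con)
  utils::write.table(mesh$cells, con, row.names = FALSE, col.names = FALSE)
  for (nm in names(mesh$markers)) {
    writeLines(paste("$marker", nm), con)
    utils::write.table(mesh$markers[[nm]], con, row.names = FALSE,
                       col.names = FALSE)
  }
  invisible(path)
}

#' Read a mesh written by \code{write_mesh_text}
#'
#' @param path input file path.
#' @return an \code{eik_mesh}.
#' @export
read_mesh_text <- function(path) {
  lines <- readLines(path)
  sec <- grep("^\\$", lines)
  if (length(sec) < 2L) stop("malformed mesh file")
  secname <- sub("^\\$", "", lines[sec])
  bounds <- c(sec, length(lines) + 1L)
  blocks <- lapply(seq_along(sec), function(k) {
    body <- lines[(sec[k] + 1L):(bounds[k + 1L] - 1L)]
    body <- body[nzchar(trimws(body))]
    do.call(rbind, lapply(strsplit(trimws(body), "[[:space:]]+"), as.numeric))
  })
  names(blocks) <- secname
  markers <- list()
  for (k in seq_along(secname)) {
    if (startsWith(secname[k], "marker ")) {
      markers[[sub("^marker ", "", secname[k])]] <- blocks[[k]]
    }
  }
  eik_mesh(blocks[["vertices"]], blocks[["cells"]], markers)
}
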