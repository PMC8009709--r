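#' Triangle mesh
#'
#' A minimal surface-mesh container: an `n x 3` numeric matrix of vertex
#' coordinates (millimetres) and an `m x 3` integer matrix of 1-based vertex
#' indices, one row per triangular facet. All geometry in the package flows
#' through this class.
#'
#' @param vertices numeric matrix with 3 columns, one row per vertex (mm).
#' @param faces integer matrix with 3 columns, one row per triangle; 1-based
#'   indices into `vertices`. Indices within a row must be distinct.
#' @return an object of class `triangle_mesh` with elements `vertices` and
#'   `faces`.
#' @examples
#' m <- triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
#'                    rbind(c(1L, 2L, 3L)))
#' n_vertices(m)
#' @export
triangle_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("'vertices' must have 3 columns")
  if (ncol(faces) != 3L) stop("'faces' must have 3 columns")
  if (nrow(vertices) == 0L || nrow(faces) == 0L) {
    stop("empty mesh: need at least one vertex and one face")
  }
  if (any(!is.finite(vertices))) stop("non-finite vertex coordinates")
  if (any(faces < 1L) || any(faces > nrow(vertices))) {
    stop("face indices out of range")
  }
  if (any(faces[, 1L] == faces[, 2L] | faces[, 2L] == faces[, 3L] |
            faces[, 1L] == faces[, 3L])) {
    stop("degenerate face: repeated vertex index within a face")
  }
  dimnames(vertices) <- NULL
  dimnames(faces) <- NULL
  structure(list(vertices = vertices, faces = faces), class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  rng <- apply(x$vertices, 2L, range)
  cat(sprintf("triangle_mesh: %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  cat(sprintf("  bbox x [%.3f, %.3f] y [%.3f, %.3f] z [%.3f, %.3f] mm\n",
              rng[1L, 1L], rng[2L, 1L], rng[1L, 2L], rng[2L, 2L],
              rng[1L, 3L], rng[2L, 3L]))
  invisible(x)
}

#' Number of vertices / faces
#' @param mesh a [triangle_mesh()].
#' @return integer count.
#' @export
n_vertices <- function(mesh) nrow(mesh$vertices)

#' @rdname n_vertices
#' @export
n_faces <- function(mesh) nrow(mesh$faces)

#' Merge coincident vertices
#'
#' Welds vertices closer than `tol` (as produced by STL facet soup or by
#' patch-wise mesh assembly) and drops faces that become degenerate. Merging
#' uses two shifted uniform grids joined by union-find, so a pair of points
#' within `tol/2` can never be split by an unlucky grid boundary.
#'
#' @param mesh a [triangle_mesh()].
#' @param tol weld tolerance in mm (default `1e-6`).
#' @return a `triangle_mesh` with duplicates merged.
#' @export
weld_vertices <- function(mesh, tol = 1e-6) {
  v <- mesh$vertices
  n <- nrow(v)
  key1 <- paste(round(v[, 1L] / tol), round(v[, 2L] / tol),
                round(v[, 3L] / tol))
  key2 <- paste(round(v[, 1L] / tol + 0.5), round(v[, 2L] / tol + 0.5),
                round(v[, 3L] / tol + 0.5))
  g1 <- match(key1, key1)
  g2 <- match(key2, key2)
  # propagate component minima over the two groupings to a fixpoint
  parent <- seq_len(n)
  repeat {
    prev <- parent
    m1 <- stats::ave(parent, g1, FUN = min)
    m2 <- stats::ave(parent, g2, FUN = min)
    parent <- pmin(parent, m1, m2)
    parent <- parent[parent]
    if (identical(parent, prev)) break
  }
  root <- parent
  keep <- sort(unique(root))
  remap <- integer(n)
  remap[keep] <- seq_along(keep)
  new_faces <- matrix(remap[root[mesh$faces]], ncol = 3L)
  ok <- new_faces[, 1L] != new_faces[, 2L] &
    new_faces[, 2L] != new_faces[, 3L] &
    new_faces[, 1L] != new_faces[, 3L]
  triangle_mesh(v[keep, , drop = FALSE], new_faces[ok, , drop = FALSE])
}

#' Per-face unit normals and areas
#'
#' Normals follow the right-hand rule on the stored winding order; for a
#' consistently oriented closed mesh generated by this package they point
#' outward.
#'
#' @param mesh a [triangle_mesh()].
#' @return list with `normals` (m x 3 unit rows; zero rows for degenerate
#'   faces) and `areas` (length m, mm^2).
#' @export
face_normals <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  e1 <- v[f[, 2L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  e2 <- v[f[, 3L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  cr <- cbind(e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L],
              e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L],
              e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L])
  len <- sqrt(rowSums(cr^2))
  nrm <- cr / ifelse(len > 0, len, 1)
  list(normals = nrm, areas = len / 2)
}

#' Per-vertex unit normals
#'
#' Area-weighted average of incident face normals (the weighting implied by
#' summing unnormalised face cross products), renormalised.
#'
#' @param mesh a [triangle_mesh()].
#' @return n x 3 matrix of unit normals.
#' @export
vertex_normals <- function(mesh) {
  fn <- face_normals(mesh)
  w <- fn$normals * fn$areas
  idx <- as.vector(mesh$faces)
  acc <- rowsum(rbind(w, w, w), idx)
  out <- matrix(0, nrow(mesh$vertices), 3L)
  out[as.integer(rownames(acc)), ] <- acc
  len <- sqrt(rowSums(out^2))
  out / ifelse(len > 0, len, 1)
}

#' Signed enclosed volume
#'
#' Divergence-theorem volume of a closed, consistently oriented mesh;
#' positive when normals point outward.
#'
#' @param mesh a [triangle_mesh()].
#' @return volume in mm^3.
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1L], , drop = FALSE]
  b <- v[f[, 2L], , drop = FALSE]
  c3 <- v[f[, 3L], , drop = FALSE]
  det3 <- a[, 1L] * (b[, 2L] * c3[, 3L] - b[, 3L] * c3[, 2L]) -
    a[, 2L] * (b[, 1L] * c3[, 3L] - b[, 3L] * c3[, 1L]) +
    a[, 3L] * (b[, 1L] * c3[, 2L] - b[, 2L] * c3[, 1L])
  sum(det3) / 6
}

#' Watertightness and orientation checks
#'
#' A mesh is watertight when every undirected edge is shared by exactly two
#' faces; it is consistently oriented when each such edge is traversed once
#' in each direction.
#'
#' @param mesh a [triangle_mesh()].
#' @return logical scalar.
#' @export
is_watertight <- function(mesh) {
  e <- .directed_edges(mesh)
  key <- paste(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
  all(tabulate(match(key, unique(key))) == 2L)
}

#' @rdname is_watertight
#' @export
is_consistently_oriented <- function(mesh) {
  e <- .directed_edges(mesh)
  key <- paste(e[, 1L], e[, 2L])
  if (anyDuplicated(key) > 0L) return(FALSE)
  rev_key <- paste(e[, 2L], e[, 1L])
  all(rev_key %in% key)
}

.directed_edges <- function(mesh) {
  f <- mesh$faces
  rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(3L, 1L)])
}

#' All unique edge lengths
#' @param mesh a [triangle_mesh()].
#' @return numeric vector of undirected edge lengths (mm).
#' @export
edge_lengths <- function(mesh) {
  e <- .directed_edges(mesh)
  key <- paste(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
  e <- e[!duplicated(key), , drop = FALSE]
  d <- mesh$vertices[e[, 1L], , drop = FALSE] -
    mesh$vertices[e[, 2L], , drop = FALSE]
  sqrt(rowSums(d^2))
}
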