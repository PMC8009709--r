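# Region segmentation of an integration-model mesh.
#
# Labels are decided on a Laplacian-smoothed copy of the mesh (normals of a
# noisy scan are too jittery to threshold directly); the labels are then
# transferred back by vertex index, so downstream fits always see the
# original coordinates.

# median dihedral jitter across mesh edges: ~0 for a clean tessellation,
# tens of degrees for a noisy scan
.normal_roughness <- function(mesh) {
  fn <- face_normals(mesh)$normals
  e <- .directed_edges(mesh)
  fid <- rep(seq_len(nrow(mesh$faces)), 3L)
  key <- paste(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
  o <- order(key)
  ks <- key[o]
  adj <- which(ks[-1L] == ks[-length(ks)])
  if (length(adj) == 0L) return(0)
  pick <- unique(as.integer(seq(1L, length(adj),
                                length.out = min(20000L, length(adj)))))
  f1 <- fid[o[adj[pick]]]
  f2 <- fid[o[adj[pick] + 1L]]
  d <- pmin(1, pmax(-1, rowSums(fn[f1, , drop = FALSE] *
                                  fn[f2, , drop = FALSE])))
  stats::median(acos(d)) * 180 / pi
}

.smooth_copy <- function(mesh, iterations = NULL, lambda = 0.5) {
  if (is.null(iterations)) {
    # clean tessellations need no smoothing; noisy ones get more with noise
    rough <- .normal_roughness(mesh)
    iterations <- if (rough < 2) 0L else as.integer(pmin(12, 4 + rough / 3))
  }
  if (iterations == 0L) return(mesh)
  e <- .directed_edges(mesh)
  key <- paste(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
  e <- e[!duplicated(key), , drop = FALSE]
  n <- nrow(mesh$vertices)
  A <- Matrix::sparseMatrix(i = c(e[, 1L], e[, 2L]), j = c(e[, 2L], e[, 1L]),
                            x = 1, dims = c(n, n))
  deg <- pmax(Matrix::rowSums(A), 1)
  v <- mesh$vertices
  for (i in seq_len(iterations)) {
    v <- v + lambda * (as.matrix(A %*% v) / deg - v)
  }
  triangle_mesh(v, mesh$faces)
}

# dominant planar-cluster axis: the line direction shared by the large
# parallel planar regions (base disk, shoulder annulus, ditch floor)
.detect_axis <- function(fn) {
  areas <- fn$areas
  nrm <- fn$normals
  nf <- length(areas)
  # deterministic even subsamples keep every patch proportionally represented
  score_set <- unique(as.integer(seq(1L, nf, length.out = min(20000L, nf))))
  cand <- unique(as.integer(seq(1L, nf, length.out = min(500L, nf))))
  M <- abs(nrm[cand, , drop = FALSE] %*% t(nrm[score_set, , drop = FALSE]))
  sc <- as.numeric((M > cos(10 * pi / 180)) %*% areas[score_set])
  best <- nrm[cand[which.max(sc)], ]
  # refine: principal direction of the orientation tensor of the cluster
  sel <- abs(as.numeric(nrm %*% best)) > cos(10 * pi / 180)
  w <- areas[sel]
  Ncl <- nrm[sel, , drop = FALSE]
  ev <- eigen(crossprod(Ncl * w, Ncl), symmetric = TRUE)
  ax <- ev$vectors[, 1L]
  ax * sign(sum(ax * best))
}

# 1-D clustering of face heights by gap splitting; returns cluster id per face
.height_clusters <- function(t, gap) {
  o <- order(t)
  ts <- t[o]
  brk <- which(diff(ts) > gap)
  id <- integer(length(t))
  id[o] <- findInterval(seq_along(ts), brk + 0.5) + 1L
  id
}

#' Segment an integration-model mesh into fit regions
#'
#' Classifies vertices into the disjoint regions needed by the metrology
#' stage: `base` plane, `shoulder` annulus, `lower_wall`, `upper_wall`,
#' `occlusal` (the cone or flat cap) and `ditch` (channel walls and floor).
#' Faces are classified on a smoothed copy by the angle of their normal to
#' the model axis (within 15 degrees of the axis: planar/axial; within 15
#' degrees of perpendicular: wall; otherwise slanted) combined with height
#' bands along the axis; each vertex is assigned to the region with the
#' largest incident face area.
#'
#' @param mesh a [triangle_mesh()] in any rigid pose.
#' @param axis_hint optional length-3 approximate axis direction; when
#'   `NULL` the axis is detected from the dominant planar clusters.
#' @return object of class `mesh_regions`: named list of integer vertex
#'   index vectors, with attributes `axis` (unit, pointing from base to
#'   occlusal side), `center` (a point near the axis on the base plane),
#'   `heights` (named: base, shoulder, top) and `ditch_frame` (list with
#'   the channel cross directions and half width, or `NULL`).
#' @export
segment_regions <- function(mesh, axis_hint = NULL) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  sm <- .smooth_copy(mesh)
  fn <- face_normals(sm)
  areas <- fn$areas
  nrm <- fn$normals
  fc <- (sm$vertices[sm$faces[, 1L], , drop = FALSE] +
           sm$vertices[sm$faces[, 2L], , drop = FALSE] +
           sm$vertices[sm$faces[, 3L], , drop = FALSE]) / 3

  ax <- if (is.null(axis_hint)) .detect_axis(fn) else
    axis_hint / sqrt(sum(axis_hint^2))

  ca <- as.numeric(nrm %*% ax)                 # cos(angle to axis), signed
  axial <- abs(ca) > cos(15 * pi / 180)
  radial <- abs(ca) < sin(15 * pi / 180)
  t_all <- as.numeric(fc %*% ax)
  rng <- diff(range(t_all))
  gap <- 0.04 * rng

  if (!any(axial)) stop("segmentation failed: no axial (planar) region found")
  cl <- .height_clusters(t_all[axial], gap)
  cl_area <- tapply(areas[axial], cl, sum)
  base_cl <- as.integer(names(which.max(cl_area)))
  base_faces <- which(axial)[cl == base_cl]
  # orient the axis so the base faces look away from the model (-axis)
  flip <- sign(sum(ca[base_faces] * areas[base_faces]))
  if (flip > 0) {
    ax <- -ax
    ca <- -ca
    t_all <- -t_all
  }
  pl_base <- fit_plane(sm$vertices[unique(as.vector(sm$faces[base_faces, ])), ,
                                   drop = FALSE])
  if (pl_base$residual > 0.01 * rng) {
    stop("segmentation failed: base region is not planar")
  }
  t_base <- sum(colMeans(fc[base_faces, , drop = FALSE]) * ax)
  center <- colMeans(fc[base_faces, , drop = FALSE])

  # shoulder: the lowest substantial upward-facing planar band above base
  up <- which(ca > cos(15 * pi / 180))
  up <- setdiff(up, base_faces)
  if (length(up) == 0L) stop("segmentation failed: shoulder region not found")
  clu <- .height_clusters(t_all[up], gap)
  aru <- tapply(areas[up], clu, sum)
  big <- as.integer(names(aru)[aru >= 0.2 * max(aru)])
  t_by_cl <- tapply(t_all[up], clu, stats::median)
  shoulder_cl <- big[which.min(t_by_cl[as.character(big)])]
  shoulder_faces <- up[clu == shoulder_cl]
  t_shoulder <- stats::median(t_all[shoulder_faces])
  above_shoulder <- setdiff(up[t_all[up] > t_shoulder + gap], shoulder_faces)

  # walls: perpendicular faces, split at shoulder height; above the
  # shoulder, distinguish the cylinder wall (normal radial) from ditch walls
  wall <- which(radial)
  lower_wall_faces <- wall[t_all[wall] < t_shoulder]
  wall_up <- wall[t_all[wall] >= t_shoulder]
  if (length(lower_wall_faces) == 0L) {
    stop("segmentation failed: lower lateral wall not found")
  }
  # azimuthal alignment: unit horizontal normal component against the
  # outward radial direction (1 on the cylinder wall, ~h/r on ditch walls)
  horiz <- fc - matrix(center, nrow(fc), 3L, byrow = TRUE)
  horiz <- horiz - outer(as.numeric(horiz %*% ax), ax)
  r_face <- sqrt(rowSums(horiz^2))
  n_h <- nrm - outer(ca, ax)
  n_h_len <- sqrt(rowSums(n_h^2))
  azim <- rowSums(n_h * horiz) / (pmax(n_h_len, 1e-12) * pmax(r_face, 1e-12))

  upper_wall_faces <- wall_up[azim[wall_up] > cos(30 * pi / 180)]
  ditch_wall_faces <- wall_up[azim[wall_up] < 0.5]
  if (length(upper_wall_faces) == 0L) {
    stop("segmentation failed: upper lateral wall not found")
  }
  R1_est <- stats::median(r_face[upper_wall_faces])

  # ditch frame from the 4-fold direction of the channel-wall normals
  ditch_frame <- NULL
  if (length(ditch_wall_faces) >= 8L) {
    hn <- n_h[ditch_wall_faces, , drop = FALSE] /
      pmax(n_h_len[ditch_wall_faces], 1e-12)
    fr <- .axis_frame(ax)
    phi <- atan2(as.numeric(hn %*% fr$e2), as.numeric(hn %*% fr$e1))
    w4 <- areas[ditch_wall_faces]
    phi0 <- atan2(sum(w4 * sin(4 * phi)), sum(w4 * cos(4 * phi))) / 4
    d1 <- cos(phi0) * fr$e1 + sin(phi0) * fr$e2
    d2 <- -sin(phi0) * fr$e1 + cos(phi0) * fr$e2
    wp <- fc[ditch_wall_faces, , drop = FALSE] -
      matrix(center, length(ditch_wall_faces), 3L, byrow = TRUE)
    half_w <- stats::median(pmin(abs(as.numeric(wp %*% d1)),
                                 abs(as.numeric(wp %*% d2))))
    half_w <- min(half_w, 0.45 * R1_est)
    ditch_frame <- list(d1 = d1, d2 = d2, half_width = half_w)
  }

  in_cross <- function(faces) {
    if (is.null(ditch_frame) || length(faces) == 0L) {
      return(rep(FALSE, length(faces)))
    }
    p <- fc[faces, , drop = FALSE] - matrix(center, length(faces), 3L,
                                            byrow = TRUE)
    lim <- 1.25 * ditch_frame$half_width
    abs(as.numeric(p %*% ditch_frame$d1)) < lim |
      abs(as.numeric(p %*% ditch_frame$d2)) < lim
  }

  # occlusal surface: slanted upward faces above the shoulder and inside
  # the rim radius (keeps smoothing-rounded rim/wall fuzz out), plus any
  # flat cap band, minus everything inside the ditch cross
  slanted <- which(!axial & !radial & ca > 0)
  t_top <- max(t_all)
  margin <- t_shoulder + 0.3 * (t_top - t_shoulder)
  occl_slant <- slanted[t_all[slanted] > margin &
                          r_face[slanted] < 0.93 * R1_est]
  occl_flat <- above_shoulder[!in_cross(above_shoulder)]
  floor_faces <- above_shoulder[in_cross(above_shoulder)]
  occl_faces <- c(occl_slant[!in_cross(occl_slant)], occl_flat)
  if (length(occl_faces) == 0L) {
    stop("segmentation failed: occlusal surface not found")
  }
  ditch_faces <- c(ditch_wall_faces, floor_faces)

  # vertex labels: region with the largest incident face area wins
  classes <- list(base = base_faces, shoulder = shoulder_faces,
                  lower_wall = lower_wall_faces,
                  upper_wall = upper_wall_faces,
                  occlusal = occl_faces, ditch = ditch_faces)
  nv <- nrow(mesh$vertices)
  best_area <- matrix(0, nv, length(classes))
  for (k in seq_along(classes)) {
    f <- classes[[k]]
    if (length(f) == 0L) next
    idx <- as.vector(mesh$faces[f, , drop = FALSE])
    acc <- rowsum(rep(areas[f], 3L), idx)
    best_area[as.integer(rownames(acc)), k] <- acc
  }
  lab <- max.col(best_area, ties.method = "first")
  lab[rowSums(best_area) == 0] <- 0L
  regions <- lapply(seq_along(classes), function(k) which(lab == k))
  names(regions) <- names(classes)

  structure(regions, class = "mesh_regions",
            axis = ax, center = center,
            heights = c(base = t_base, shoulder = t_shoulder, top = t_top),
            ditch_frame = ditch_frame)
}

#' @export
print.mesh_regions <- function(x, ...) {
  cat("mesh_regions:",
      paste(sprintf("%s=%d", names(x), lengths(x)), collapse = " "), "\n")
  invisible(x)
}
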