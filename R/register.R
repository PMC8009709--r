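#' Closest points on a reference mesh
#'
#' Exact nearest point on the reference surface (point-to-triangle, through
#' a uniform spatial grid) for each query point.
#'
#' @param points n x 3 matrix of query points.
#' @param reference a [triangle_mesh()].
#' @return list with `distance` (unsigned, mm), `face` (index of nearest
#'   triangle) and `point` (n x 3 nearest surface points).
#' @export
closest_points <- function(points, reference) {
  stopifnot(inherits(reference, "triangle_mesh"))
  points <- as.matrix(points)
  res <- cpp_closest_points(points, reference$vertices, reference$faces)
  list(distance = sqrt(res$dist2), face = res$face, point = res$point)
}

#' Iterative closest point rigid registration
#'
#' Registers `test` onto `reference` by alternating exact nearest-surface
#' correspondences (test vertices to reference triangles) with the
#' closed-form SVD (Kabsch/Umeyama) rigid update. Optionally the worst
#' `trim_fraction` of correspondences is discarded each iteration (trimmed
#' ICP). Iterations stop when the relative change in correspondence RMS
#' falls below `tol` or after `max_iter` iterations; with trimming fixed the
#' correspondence RMS is non-increasing across iterations.
#'
#' @param test,reference [triangle_mesh()] objects.
#' @param trim_fraction fraction in `[0, 0.5)` of worst matches dropped.
#' @param tol relative RMS-change convergence tolerance.
#' @param max_iter maximum number of iterations (both stages combined).
#' @param method `"hybrid"` (default) runs point-to-point SVD updates until
#'   the RMS stalls, then polishes with linearised point-to-plane
#'   Gauss-Newton steps (much faster final convergence on smooth, nearly
#'   axisymmetric surfaces); `"point"` is pure point-to-point, whose
#'   correspondence RMS is non-increasing at fixed trimming.
#' @param max_points cap on the number of test vertices used (an evenly
#'   spaced deterministic subset); `Inf` uses all.
#' @return list with `transform` (a [rigid_transform()] mapping `test` into
#'   the reference frame), `converged` (logical), `rms` (final
#'   correspondence RMS, mm) and `rms_trace` (per-iteration RMS).
#'   Non-convergence is reported through `converged = FALSE`, never as an
#'   error.
#' @export
icp_register <- function(test, reference, trim_fraction = 0, tol = 1e-8,
                         max_iter = 200L, method = c("hybrid", "point"),
                         max_points = 5000L) {
  stopifnot(inherits(test, "triangle_mesh"),
            inherits(reference, "triangle_mesh"))
  method <- match.arg(method)
  if (trim_fraction < 0 || trim_fraction >= 0.5) {
    stop("trim_fraction must be in [0, 0.5)")
  }
  p0 <- test$vertices
  if (nrow(p0) > max_points) {
    p0 <- p0[unique(as.integer(seq(1L, nrow(p0), length.out = max_points))), ,
             drop = FALSE]
  }
  ref_n <- face_normals(reference)$normals
  tr <- rigid_transform()
  rms_prev <- Inf
  rms_trace <- numeric(0L)
  converged <- FALSE
  n_keep <- max(3L, as.integer(floor(nrow(p0) * (1 - trim_fraction))))
  stage <- "point"
  # the closed-form stage decays geometrically (a few % per iteration) once
  # only the azimuthal error remains; treat that as the stall signature
  stall_tol <- if (method == "hybrid") max(tol, 0.02) else tol

  for (it in seq_len(max_iter)) {
    p <- apply_transform(p0, tr)
    cp <- closest_points(p, reference)
    keep <- seq_len(nrow(p))
    if (n_keep < nrow(p)) {
      keep <- order(cp$distance)[seq_len(n_keep)]
    }
    rms <- sqrt(mean(cp$distance[keep]^2))
    rms_trace <- c(rms_trace, rms)
    if (rms < 1e-9) {             # already coincident to numeric precision
      converged <- TRUE
      break
    }
    rel <- abs(rms_prev - rms) / max(rms, .Machine$double.eps)
    if (is.finite(rms_prev) && (rel <= tol || rms < 1e-12)) {
      if (stage == "plane" || method == "point") {
        converged <- TRUE
        break
      }
    }
    if (stage == "point" && method == "hybrid" && is.finite(rms_prev) &&
          rel <= stall_tol && it >= 10L) {
      stage <- "plane"
    }
    rms_prev <- rms
    src <- p[keep, , drop = FALSE]
    dst <- cp$point[keep, , drop = FALSE]
    if (stage == "point") {
      # closed-form Kabsch/Umeyama update
      mu_s <- colMeans(src)
      mu_d <- colMeans(dst)
      H <- crossprod(sweep(src, 2L, mu_s), sweep(dst, 2L, mu_d))
      sv <- svd(H)
      d <- sign(det(sv$v %*% t(sv$u)))
      Rk <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
      tk <- mu_d - as.numeric(Rk %*% mu_s)
      upd <- rigid_transform(Rk, tk)
    } else {
      # linearised point-to-plane Gauss-Newton step, with the rotation
      # capped to the linearisation's validity range and a backtracking
      # line search on the correspondence RMS
      nn <- ref_n[cp$face[keep], , drop = FALSE]
      b <- -rowSums((src - dst) * nn)
      cxn <- cbind(src[, 2L] * nn[, 3L] - src[, 3L] * nn[, 2L],
                   src[, 3L] * nn[, 1L] - src[, 1L] * nn[, 3L],
                   src[, 1L] * nn[, 2L] - src[, 2L] * nn[, 1L])
      A <- cbind(cxn, nn)
      sol <- tryCatch(solve(crossprod(A), crossprod(A, b)),
                      error = function(e) NULL)
      if (is.null(sol)) break
      w <- sol[1:3]
      tk <- sol[4:6]
      ang <- sqrt(sum(w^2))
      if (ang > 0.2) {            # cap the step at ~11 degrees
        w <- w * (0.2 / ang)
        tk <- tk * (0.2 / ang)
        ang <- 0.2
      }
      s <- 1
      accepted <- FALSE
      for (half in 1:6) {
        ws <- w * s
        angs <- sqrt(sum(ws^2))
        Rk <- if (angs > 0) rotation_about(ws / angs, angs * 180 / pi) else
          diag(3)
        tr_try <- compose_transform(rigid_transform(Rk, tk * s), tr)
        cp_try <- closest_points(apply_transform(p0, tr_try), reference)
        d_try <- sort(cp_try$distance)[seq_len(n_keep)]
        if (sqrt(mean(d_try^2)) < rms) {
          tr <- tr_try
          accepted <- TRUE
          break
        }
        s <- s / 2
      }
      if (!accepted) {
        converged <- TRUE      # no descent direction left at this scale
        break
      }
      next
    }
    tr <- compose_transform(upd, tr)
  }
  list(transform = tr, converged = converged,
       rms = rms_trace[length(rms_trace)],
       iterations = length(rms_trace), rms_trace = rms_trace)
}

#' Signed deviation of a registered scan from the reference
#'
#' For every test vertex, the signed nearest distance to the reference
#' surface: positive when the vertex lies on the outward-normal side of its
#' nearest reference triangle (the scan sits outside the reference), negative
#' inside. `test` is assumed already registered.
#'
#' @param test,reference [triangle_mesh()] objects.
#' @return object of class `deviation_field`: list with `signed_distance`
#'   (mm), `points` (the test vertices), `face` (nearest reference triangle)
#'   and `sign_convention = "outward-positive"`.
#' @export
deviation_map <- function(test, reference) {
  stopifnot(inherits(test, "triangle_mesh"),
            inherits(reference, "triangle_mesh"))
  cp <- closest_points(test$vertices, reference)
  fn <- face_normals(reference)$normals
  d <- test$vertices - cp$point
  s <- rowSums(d * fn[cp$face, , drop = FALSE])
  structure(list(signed_distance = ifelse(s >= 0, 1, -1) * cp$distance,
                 points = test$vertices, face = cp$face,
                 sign_convention = "outward-positive"),
            class = "deviation_field")
}

#' @export
print.deviation_field <- function(x, ...) {
  cat(sprintf("deviation_field: %d samples, RMS %.4f mm, range [%.4f, %.4f]\n",
              length(x$signed_distance), rms_deviation(x),
              min(x$signed_distance), max(x$signed_distance)))
  invisible(x)
}

#' RMS of a deviation field
#'
#' Root of the mean squared signed surface distance over all samples (the
#' per-point "3D fitting" RMS with divisor equal to the sample count).
#'
#' @param field a [deviation_map()] result, or a numeric vector of signed
#'   distances.
#' @return RMS in mm.
#' @export
rms_deviation <- function(field) {
  d <- if (inherits(field, "deviation_field")) field$signed_distance else field
  if (length(d) == 0L) stop("empty deviation field")
  sqrt(mean(d^2))
}

#' Replicate-form RMS of an index
#'
#' The per-replicate reading of the study's RMS formula: the reference value
#' `rR` against the measured value of each of the `n` replicate scans,
#' `sqrt(sum((rR - rA_i)^2) / n)`.
#'
#' @param reference_value scalar reference value `rR`.
#' @param replicate_values numeric vector of per-replicate measurements
#'   `rA` (length >= 2).
#' @return RMS in the units of the index.
#' @examples
#' replicate_rms(10, c(9, 11))   # 1
#' @export
replicate_rms <- function(reference_value, replicate_values) {
  if (length(replicate_values) < 2L) stop("need at least 2 replicate values")
  sqrt(mean((reference_value - replicate_values)^2))
}
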