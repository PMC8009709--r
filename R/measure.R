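#' Measure the six design indices of a scanned model
#'
#' Recovers `(R1, R2, L1, L2, L3, theta)` from a mesh in any rigid pose by
#' least-squares primitive fitting on the segmented regions:
#' the lower lateral wall is fitted as a (possibly drafted) surface of
#' revolution whose axis becomes the measurement axis, with `R2` evaluated
#' at the base-plane height; `R1` comes from a cylinder fit of the upper
#' wall; base and shoulder planes are fitted by total least squares and the
#' occlusal cone by orthogonal-distance least squares (ditch vertices are
#' excluded by segmentation, residual outliers by trimmed refits). Heights
#' are distances between the fitted planes measured along the axis; the
#' occlusal rim sits where the fitted cone meets the upper cylinder, so
#' `L3 = L1 + L2` holds by construction of the rim. All six indices are
#' functions of fitted primitives only and hence invariant under rigid
#' repositioning of the mesh.
#'
#' @param mesh a [triangle_mesh()] containing the canonical model features.
#' @param axis_hint optional approximate axis direction (see
#'   [segment_regions()]).
#' @return object of class `index_measurement`: named list with the six
#'   indices (mm / degrees), `residuals` (per-fit RMS orthogonal distance,
#'   mm), `region_sizes` (vertex counts) and `cone_degenerate` (logical).
#' @examples
#' \donttest{
#' m <- generate_model(model_spec(segments = 96, outer_draft = 0))
#' measure_indices(m)
#' }
#' @export
measure_indices <- function(mesh, axis_hint = NULL) {
  reg <- segment_regions(mesh, axis_hint = axis_hint)
  ax0 <- attr(reg, "axis")
  v <- mesh$vertices

  # measurement axis from the tallest revolved surface (the base wall)
  low <- .robust_fit(v[reg$lower_wall, , drop = FALSE],
                     function(p) .fit_revolved_wall(p, ax0, taper = TRUE),
                     .cyl_resid)
  ax <- low$axis * sign(sum(low$axis * ax0))   # keep pointing occlusally
  c0 <- low$center

  plane_t <- function(pl) {
    # intersection of the fitted plane with the measurement axis line
    (pl$offset - sum(pl$normal * c0)) / sum(pl$normal * ax)
  }
  base <- .robust_fit(v[reg$base, , drop = FALSE],
                      function(p) fit_plane(p), .plane_resid)
  shoulder <- .robust_fit(v[reg$shoulder, , drop = FALSE],
                          function(p) fit_plane(p), .plane_resid)
  t_base <- plane_t(base)
  t_shoulder <- plane_t(shoulder)

  upper <- .robust_fit(v[reg$upper_wall, , drop = FALSE],
                       function(p) fit_cylinder(p, ax), .cyl_resid)
  R1 <- upper$radius
  # R2 at the base height (exact for a drafted wall, reduces to the
  # cylinder radius when the taper is zero)
  R2 <- low$radius + low$taper * t_base

  cone <- .robust_fit(v[reg$occlusal, , drop = FALSE],
                      function(p) fit_cone(p, ax), .cone_resid)
  if (cone$degenerate) {
    theta <- 0
    t_rim <- sum((cone$apex - c0) * ax)        # flat-cap plane height
  } else {
    theta <- cone$theta
    t_apex <- sum((cone$apex - c0) * ax)
    t_rim <- t_apex - R1 * tan(theta * pi / 180)
  }

  out <- list(R1 = R1, R2 = R2,
              L1 = t_rim - t_shoulder,
              L2 = t_shoulder - t_base,
              L3 = t_rim - t_base,
              theta = theta,
              residuals = c(base = base$residual,
                            shoulder = shoulder$residual,
                            lower_wall = low$residual,
                            upper_wall = upper$residual,
                            occlusal = cone$residual),
              region_sizes = lengths(unclass(reg)),
              cone_degenerate = cone$degenerate)
  class(out) <- "index_measurement"
  out
}

#' @export
print.index_measurement <- function(x, ...) {
  cat(sprintf(
    "index_measurement: R1=%.4f R2=%.4f L1=%.4f L2=%.4f L3=%.4f mm, theta=%.4f deg\n",
    x$R1, x$R2, x$L1, x$L2, x$L3, x$theta))
  cat("  fit residuals (mm): ",
      paste(sprintf("%s=%.2g", names(x$residuals), x$residuals),
            collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Indices as a one-row data frame
#' @param x an `index_measurement`.
#' @param ... unused.
#' @return data.frame with columns R1, R2, L1, L2, L3, theta.
#' @export
as.data.frame.index_measurement <- function(x, ...) {
  data.frame(R1 = x$R1, R2 = x$R2, L1 = x$L1, L2 = x$L2, L3 = x$L3,
             theta = x$theta)
}
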