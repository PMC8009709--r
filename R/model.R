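#' Design specification of the integration model
#'
#' The single-tooth integration model is an axisymmetric two-tier solid,
#' described by the six indices reported for the physical standard: base
#' cylinder radius `R2` and height `L2`, coaxial upper cylinder radius `R1`
#' and height `L1`, total height `L3 = L1 + L2`, and the inclination `theta`
#' of the conical occlusal cap above the rim plane. Two perpendicular
#' rectangular ditches crossing at the axis mimic a prepared MOD cavity;
#' they are auxiliary features, not indices. An optional outward-wall draft
#' tilts the base wall inwards so the solid has no axial undercut.
#'
#' @param R1 upper cylinder radius, mm.
#' @param R2 base cylinder radius (at the base plane), mm; must exceed `R1`.
#' @param L1 upper-tier height (shoulder plane to occlusal rim), mm.
#' @param L2 base-tier height (base plane to shoulder plane), mm.
#' @param L3 total height, mm; must equal `L1 + L2` (stored redundantly and
#'   validated; the measurement stage still measures it directly).
#' @param theta occlusal cap inclination above the shoulder-parallel plane,
#'   degrees in `[0, 90)`.
#' @param ditch_width full ditch width, mm; `0` disables the ditches.
#' @param ditch_depth ditch floor depth below the occlusal rim plane, mm;
#'   must stay above the shoulder (`ditch_depth < L1`); `0` disables.
#' @param outer_draft inward inclination of the base wall, degrees (>= 0);
#'   `R2` is defined at the base plane.
#' @param segments angular tessellation count around the axis.
#' @return an object of class `model_spec`.
#' @examples
#' spec <- model_spec()              # the theoretical design values
#' spec$R1
#' @export
model_spec <- function(R1 = 3, R2 = 5, L1 = 2, L2 = 8, L3 = L1 + L2,
                       theta = 23, ditch_width = 1.5, ditch_depth = 1,
                       outer_draft = 2, segments = 128L) {
  chk <- function(ok, msg) if (!ok) stop("model_spec invariant violated: ", msg)
  chk(is.finite(R1) && is.finite(R2) && R1 > 0 && R1 < R2, "R1 < R2 (both > 0)")
  chk(L1 > 0 && L2 > 0, "L1 > 0 and L2 > 0")
  chk(abs(L3 - (L1 + L2)) < 1e-9, "L3 = L1 + L2")
  chk(theta >= 0 && theta < 90, "0 <= theta < 90")
  chk(ditch_width >= 0 && ditch_width < 2 * R1, "ditch_width < 2*R1")
  chk(ditch_depth >= 0 && ditch_depth < L1, "ditch_depth < L1")
  chk(outer_draft >= 0, "outer_draft >= 0 (no axial undercut)")
  r2_top <- R2 - L2 * tan(outer_draft * pi / 180)
  chk(r2_top > R1, "base wall with draft must stay wider than R1 at the shoulder")
  chk(segments >= 16, "segments >= 16")
  structure(list(R1 = R1, R2 = R2, L1 = L1, L2 = L2, L3 = L3, theta = theta,
                 ditch_width = ditch_width, ditch_depth = ditch_depth,
                 outer_draft = outer_draft, segments = as.integer(segments)),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf(
    "model_spec: R1=%.3f R2=%.3f L1=%.3f L2=%.3f L3=%.3f theta=%.3f deg\n",
    x$R1, x$R2, x$L1, x$L2, x$L3, x$theta))
  cat(sprintf("  ditch %.2f x %.2f mm, draft %.2f deg, %d segments\n",
              x$ditch_width, x$ditch_depth, x$outer_draft, x$segments))
  invisible(x)
}

#' The six design indices of a spec as a named vector
#' @param spec a [model_spec()].
#' @return named numeric vector `(R1, R2, L1, L2, L3, theta)`.
#' @export
spec_indices <- function(spec) {
  c(R1 = spec$R1, R2 = spec$R2, L1 = spec$L1, L2 = spec$L2, L3 = spec$L3,
    theta = spec$theta)
}

# --- mesh assembly helpers ---------------------------------------------------

# triangulate a structured grid of vertex indices; rows advance first
# (wrapping if wrap_rows), cols second; flip reverses every winding
.grid_faces <- function(idx, wrap_rows = FALSE, flip = FALSE) {
  nr <- nrow(idx); nc <- ncol(idx)
  i <- seq_len(if (wrap_rows) nr else nr - 1L)
  ip <- if (wrap_rows) c(seq_len(nr)[-1L], 1L) else seq_len(nr)[-1L]
  j <- seq_len(nc - 1L)
  a <- as.vector(idx[i, j, drop = FALSE])
  b <- as.vector(idx[ip, j, drop = FALSE])
  cc <- as.vector(idx[ip, j + 1L, drop = FALSE])
  d <- as.vector(idx[i, j + 1L, drop = FALSE])
  f <- rbind(cbind(a, b, cc), cbind(a, cc, d))
  if (flip) f <- f[, c(1L, 3L, 2L)]
  f
}

.mesh_builder <- function() {
  env <- new.env(parent = emptyenv())
  env$verts <- vector("list", 0L)
  env$faces <- vector("list", 0L)
  env$n <- 0L
  env
}

.add_patch <- function(bld, pts, dim_rc, wrap_rows = FALSE, flip = FALSE) {
  idx <- matrix(bld$n + seq_len(nrow(pts)), nrow = dim_rc[1L], ncol = dim_rc[2L])
  bld$verts[[length(bld$verts) + 1L]] <- pts
  bld$faces[[length(bld$faces) + 1L]] <- .grid_faces(idx, wrap_rows, flip)
  bld$n <- bld$n + nrow(pts)
  invisible(bld)
}

# points of a surface-of-revolution patch: profile (r_k, z_k) swept over phi;
# vertex order: rows = phi (fastest), cols = profile station
.revolve_pts <- function(phi, r, z) {
  np <- length(phi)
  cs <- cos(phi); sn <- sin(phi)
  cbind(rep(r, each = np) * cs, rep(r, each = np) * sn, rep(z, each = np))
}

# exact quarter-turn rotation matrices (entries 0/±1) acting on xy
.quadrant_rot <- list(
  matrix(c(1, 0, 0, 1), 2L),
  matrix(c(0, 1, -1, 0), 2L),
  matrix(c(-1, 0, 0, -1), 2L),
  matrix(c(0, -1, 1, 0), 2L)
)

.rotate_xy <- function(pts, q) {
  Q <- .quadrant_rot[[q]]
  cbind(pts[, 1L] * Q[1L, 1L] + pts[, 2L] * Q[1L, 2L],
        pts[, 1L] * Q[2L, 1L] + pts[, 2L] * Q[2L, 2L],
        pts[, 3L])
}

# --- generator ---------------------------------------------------------------

#' Generate the integration model mesh
#'
#' Builds a watertight, consistently outward-oriented triangle mesh of the
#' canonical geometry: base plane at `z = 0`, drafted base wall up to the
#' shoulder plane at `z = L2`, upper cylinder wall to the occlusal rim at
#' `z = L3`, and a conical occlusal cap rising at `theta` towards the axis
#' (apex at `z = L3 + R1 tan(theta)`). When the ditches are enabled, two
#' perpendicular flat-floored channels of the given width are cut to
#' `ditch_depth` below the rim plane, crossing at the axis and opening
#' through the upper wall; with equal ditches the model is symmetric under a
#' quarter turn about its axis.
#'
#' @param spec a [model_spec()].
#' @return a [triangle_mesh()] (welded at `1e-6` mm).
#' @examples
#' m <- generate_model(model_spec(segments = 48, ditch_width = 0,
#'                                ditch_depth = 0))
#' is_watertight(m)
#' @export
generate_model <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  R1 <- spec$R1; R2 <- spec$R2
  L2 <- spec$L2; L3 <- spec$L3
  th <- spec$theta * pi / 180
  draft <- spec$outer_draft * pi / 180
  r2_top <- R2 - L2 * tan(draft)
  z_apex <- L3 + R1 * tan(th)
  ditch <- spec$ditch_width > 0 && spec$ditch_depth > 0
  h <- spec$ditch_width / 2
  zf <- L3 - spec$ditch_depth

  n <- spec$segments
  edge <- 2 * pi * R2 / n        # target chord length at the widest circle
  row_edge <- 2 * edge           # coarser target across profile stations
  nseg <- function(len, minimum = 2L) {
    max(minimum, min(96L, as.integer(ceiling(len / row_edge))))
  }

  # angular grid: per quadrant a ditch sector [-psi, psi] and a corner
  # sector [psi, pi/2 - psi]; without ditches a uniform grid
  if (ditch) {
    psi <- asin(h / R1)
    m_d <- max(2L, as.integer(round(2 * psi * R1 / edge)))
    m_c <- max(4L, 2L * as.integer(ceiling((pi / 2 - 2 * psi) * R1 / edge / 2)))
    m_f <- m_c %/% 2L
    phi_d <- seq(-psi, psi, length.out = m_d + 1L)
    phi_c <- seq(psi, pi / 2 - psi, length.out = m_c + 1L)
    pattern <- c(phi_d[-(m_d + 1L)], phi_c[-(m_c + 1L)])
  } else {
    n4 <- 4L * as.integer(ceiling(n / 4))
    pattern <- seq(0, pi / 2, length.out = n4 / 4L + 1L)[-(n4 / 4L + 1L)]
  }
  phi <- c(pattern, pattern + pi / 2, pattern + pi, pattern + 3 * pi / 2)

  bld <- .mesh_builder()
  np <- length(phi)

  # base disk (z = 0), normal -z: cols = radius outward
  r_base <- seq(0, R2, length.out = nseg(R2) + 1L)
  .add_patch(bld, .revolve_pts(phi, r_base, rep(0, length(r_base))),
             c(np, length(r_base)), wrap_rows = TRUE)

  # base (lower) wall with draft: cols = z upward
  z_low <- seq(0, L2, length.out = nseg(L2) + 1L)
  r_low <- R2 - z_low * tan(draft)
  r_low[length(r_low)] <- r2_top
  .add_patch(bld, .revolve_pts(phi, r_low, z_low),
             c(np, length(z_low)), wrap_rows = TRUE)

  # shoulder annulus (z = L2), normal +z: cols = radius inward
  r_sh <- seq(r2_top, R1, length.out = nseg(r2_top - R1) + 1L)
  .add_patch(bld, .revolve_pts(phi, r_sh, rep(L2, length(r_sh))),
             c(np, length(r_sh)), wrap_rows = TRUE)

  cone_z <- function(r) z_apex - r * tan(th)

  if (!ditch) {
    # upper wall L2 -> L3, then full conical cap (collapses to a flat fan
    # when theta = 0); the r = 0 ring welds into a single apex vertex
    z_up <- seq(L2, L3, length.out = nseg(L3 - L2) + 1L)
    .add_patch(bld, .revolve_pts(phi, rep(R1, length(z_up)), z_up),
               c(np, length(z_up)), wrap_rows = TRUE)
    r_cap <- seq(R1, 0, length.out = nseg(R1 / cos(th)) + 1L)
    .add_patch(bld, .revolve_pts(phi, r_cap, cone_z(r_cap)),
               c(np, length(r_cap)), wrap_rows = TRUE)
  } else {
    x_end <- R1 * cos(psi)       # chord endpoint on the rim circle
    frac <- seq(0, 1, length.out = m_f + 1L)
    chord_x <- h + frac * (x_end - h)

    # upper wall, full ring from L2 to the ditch floor level zf
    z_up1 <- seq(L2, zf, length.out = nseg(zf - L2) + 1L)
    .add_patch(bld, .revolve_pts(phi, rep(R1, length(z_up1)), z_up1),
               c(np, length(z_up1)), wrap_rows = TRUE)

    # upper wall, corner sectors only, from zf to the rim L3
    z_up2 <- seq(zf, L3, length.out = nseg(L3 - zf) + 1L)
    nz2 <- length(z_up2)
    for (q in 1:4) {
      ang <- phi_c + (q - 1) * pi / 2
      .add_patch(bld, .revolve_pts(ang, rep(R1, nz2), z_up2),
                 c(length(ang), nz2))
    }

    # occlusal corner cone patches: transfinite blend between the inner
    # chord polyline and the rim arc (region is convex); built in quadrant
    # 1 and copied by exact quarter turns
    inner <- rbind(cbind(rev(chord_x), h), cbind(h, chord_x[-1L]))
    arc <- cbind(R1 * cos(phi_c), R1 * sin(phi_c))
    nv <- nseg(R1 - h * sqrt(2))
    s <- seq(0, 1, length.out = nv + 1L)
    corner_xy <- do.call(rbind, lapply(s, function(si) {
      inner * (1 - si) + arc * si
    }))
    corner <- cbind(corner_xy,
                    cone_z(sqrt(corner_xy[, 1L]^2 + corner_xy[, 2L]^2)))
    for (q in 1:4) {
      .add_patch(bld, .rotate_xy(corner, q), c(m_c + 1L, nv + 1L),
                 flip = TRUE)
    }

    # ditch side walls of quadrant-1 corner (then rotated): vertical quads
    # from the floor zf up to the local cone surface
    z_top <- cone_z(sqrt(chord_x^2 + h^2))
    nw <- nz2 - 1L   # outer wall column must share rows with the rim band
    sw <- seq(0, 1, length.out = nw + 1L)
    wall_y <- do.call(rbind, lapply(sw, function(si) {
      cbind(chord_x, h, zf + si * (z_top - zf))
    }))
    wall_x <- do.call(rbind, lapply(sw, function(si) {
      cbind(h, rev(chord_x), zf + si * (rev(z_top) - zf))
    }))
    for (q in 1:4) {
      .add_patch(bld, .rotate_xy(wall_y, q), c(m_f + 1L, nw + 1L))
      .add_patch(bld, .rotate_xy(wall_x, q), c(m_f + 1L, nw + 1L))
    }

    # ditch floor: centre square plus four arc-ended arms at z = zf
    yk <- R1 * sin(phi_d)                 # -h .. h, symmetric
    sq <- cbind(rep(yk, times = m_d + 1L), rep(yk, each = m_d + 1L), zf)
    .add_patch(bld, sq, c(m_d + 1L, m_d + 1L))
    xout <- R1 * cos(phi_d)
    # rows = x (fastest), cols = y: one block of x stations per y row
    arm_pts <- do.call(rbind, lapply(seq_along(phi_d), function(k) {
      cbind(h + frac * (xout[k] - h), yk[k], zf)
    }))
    for (q in 1:4) {
      .add_patch(bld, .rotate_xy(arm_pts, q), c(m_f + 1L, m_d + 1L))
    }
  }

  mesh <- triangle_mesh(do.call(rbind, bld$verts), do.call(rbind, bld$faces))
  mesh <- weld_vertices(mesh, tol = 1e-6)
  if (mesh_volume(mesh) < 0) mesh$faces <- mesh$faces[, c(1L, 3L, 2L)]
  mesh
}

#' Gold-standard reference
#'
#' The digital stand-in for the coordinate-measuring-machine calibrated
#' reference: a high-tessellation mesh of the model plus the six reference
#' index values `rR` used by the trueness/precision/RMS formulas. By default
#' the reference values are the design indices of `spec`; a CMM-calibrated
#' run may substitute measured means via `reference_values`.
#'
#' @param spec a [model_spec()].
#' @param segments tessellation for the reference mesh (default 512).
#' @param reference_values optional named numeric of length 6 overriding
#'   `(R1, R2, L1, L2, L3, theta)`.
#' @return object of class `gold_standard`: list with `mesh`,
#'   `reference_values`, `spec`.
#' @export
gold_standard <- function(spec, segments = 512L, reference_values = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  spec$segments <- as.integer(segments)
  vals <- spec_indices(spec)
  if (!is.null(reference_values)) {
    if (length(reference_values) != 6L) {
      stop("reference_values must have 6 elements (R1, R2, L1, L2, L3, theta)")
    }
    if (!is.null(names(reference_values))) {
      vals[names(reference_values)] <- reference_values
    } else {
      vals[] <- reference_values
    }
  }
  structure(list(mesh = generate_model(spec), reference_values = vals,
                 spec = spec),
            class = "gold_standard")
}

#' @export
print.gold_standard <- function(x, ...) {
  cat("gold_standard reference\n  values: ",
      paste(sprintf("%s=%.3f", names(x$reference_values),
                    x$reference_values), collapse = " "), "\n", sep = "")
  print(x$mesh)
  invisible(x)
}

# --- flat key=value config ---------------------------------------------------

#' Read / write a model spec as a flat key=value file
#' @param spec a [model_spec()].
#' @param path file path.
#' @return `read_model_spec` returns a [model_spec()]; `write_model_spec`
#'   returns `path` invisibly.
#' @export
write_model_spec <- function(spec, path) {
  writeLines(sprintf("%s=%.10g", names(unclass(spec)),
                     as.numeric(unclass(spec))), path)
  invisible(path)
}

#' @rdname write_model_spec
#' @export
read_model_spec <- function(path) {
  kv <- read.dcf.kv(path)
  do.call(model_spec, as.list(kv))
}

# parse "key=value" lines into a named numeric vector
read.dcf.kv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  parts <- strsplit(lines, "=", fixed = TRUE)
  vals <- vapply(parts, function(p) as.numeric(trimws(p[2L])), numeric(1L))
  names(vals) <- vapply(parts, function(p) trimws(p[1L]), character(1L))
  vals
}
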