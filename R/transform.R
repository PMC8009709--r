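#' Rigid transform
#'
#' A proper rigid motion of 3-space: `x -> R x + t` with `R` a rotation
#' matrix (orthonormal, determinant +1) and `t` a translation in mm.
#'
#' @param rotation 3 x 3 rotation matrix.
#' @param translation length-3 numeric translation (mm).
#' @param tol orthonormality tolerance for validation.
#' @return object of class `rigid_transform` with elements `R` and `t`.
#' @examples
#' tr <- rigid_transform(diag(3), c(1, 0, 0))
#' invert_transform(tr)$t
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0),
                            tol = 1e-8) {
  rotation <- unname(as.matrix(rotation))
  translation <- as.numeric(translation)
  if (!all(dim(rotation) == c(3L, 3L)) || length(translation) != 3L) {
    stop("rotation must be 3x3 and translation length 3")
  }
  if (max(abs(crossprod(rotation) - diag(3))) > tol) {
    stop("rotation matrix is not orthonormal")
  }
  if (det(rotation) < 0) stop("rotation matrix has negative determinant")
  structure(list(R = rotation, t = translation), class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("rigid_transform: angle %.4f deg, |t| = %.4f mm\n",
              rotation_angle(x), sqrt(sum(x$t^2))))
  invisible(x)
}

#' Compose two rigid transforms
#'
#' `compose_transform(a, b)` is the transform applying `b` first, then `a`.
#'
#' @param a,b [rigid_transform()] objects.
#' @return a `rigid_transform`.
#' @export
compose_transform <- function(a, b) {
  rigid_transform(a$R %*% b$R, as.numeric(a$R %*% b$t) + a$t)
}

#' Invert a rigid transform
#' @param x a [rigid_transform()].
#' @return the inverse `rigid_transform`.
#' @export
invert_transform <- function(x) {
  rigid_transform(t(x$R), as.numeric(-t(x$R) %*% x$t))
}

#' Rotation angle of a rigid transform
#' @param x a [rigid_transform()].
#' @return rotation angle in degrees, in `[0, 180]`.
#' @export
rotation_angle <- function(x) {
  ctheta <- (sum(diag(x$R)) - 1) / 2
  acos(min(1, max(-1, ctheta))) * 180 / pi
}

#' Axis-angle rotation matrix
#' @param axis length-3 direction (normalised internally).
#' @param angle rotation angle in degrees.
#' @return 3 x 3 rotation matrix (Rodrigues formula).
#' @export
rotation_about <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  th <- angle * pi / 180
  K <- matrix(c(0, a[3L], -a[2L], -a[3L], 0, a[1L], a[2L], -a[1L], 0), 3L, 3L)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Random rigid transform
#'
#' Rotation by an angle uniform on `[0, max_angle]` about a uniformly random
#' axis, plus a translation uniform in the ball of radius `max_translation`.
#' Draws from the current RNG stream.
#'
#' @param max_angle maximum rotation angle, degrees.
#' @param max_translation maximum translation norm, mm.
#' @return a [rigid_transform()].
#' @export
random_rigid_transform <- function(max_angle, max_translation) {
  ax <- stats::rnorm(3L)
  ax <- ax / sqrt(sum(ax^2))
  ang <- stats::runif(1L, 0, max_angle)
  tdir <- stats::rnorm(3L)
  tdir <- tdir / sqrt(sum(tdir^2))
  tlen <- max_translation * stats::runif(1L)^(1 / 3)
  rigid_transform(rotation_about(ax, ang), tdir * tlen)
}

#' Apply a rigid transform
#'
#' @param x a [triangle_mesh()] or an `n x 3` point matrix.
#' @param transform a [rigid_transform()].
#' @return object of the same type with transformed coordinates; pairwise
#'   distances are preserved to numerical precision.
#' @export
apply_transform <- function(x, transform) {
  if (!inherits(transform, "rigid_transform")) {
    transform <- do.call(rigid_transform, transform)
  }
  if (inherits(x, "triangle_mesh")) {
    v <- x$vertices %*% t(transform$R)
    v <- sweep(v, 2L, transform$t, "+")
    return(triangle_mesh(v, x$faces))
  }
  p <- as.matrix(x)
  sweep(p %*% t(transform$R), 2L, transform$t, "+")
}
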