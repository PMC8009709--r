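#' Total least squares plane fit
#'
#' The plane minimising the sum of squared orthogonal distances: its normal
#' is the smallest principal direction of the centred covariance, the plane
#' passes through the centroid.
#'
#' @param points n x 3 matrix, n >= 3, not all collinear.
#' @return list with `normal` (unit), `offset` (`normal . x = offset` on the
#'   plane, mm) and `residual` (RMS orthogonal distance, mm).
#' @export
fit_plane <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 3L) stop("plane fit needs at least 3 points")
  ctr <- colMeans(points)
  cc <- sweep(points, 2L, ctr)
  ev <- eigen(crossprod(cc) / nrow(points), symmetric = TRUE)
  if (ev$values[2L] < 1e-12 * max(ev$values[1L], 1e-300)) {
    stop("degenerate (collinear) point set: plane fit is rank deficient")
  }
  normal <- ev$vectors[, 3L]
  res <- as.numeric(cc %*% normal)
  list(normal = normal, offset = sum(normal * ctr),
       residual = sqrt(mean(res^2)))
}

.plane_resid <- function(fit, points) {
  as.numeric(as.matrix(points) %*% fit$normal) - fit$offset
}

# orthonormal complement of a unit vector
.axis_frame <- function(a) {
  a <- a / sqrt(sum(a^2))
  ref <- if (abs(a[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * a) * a
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(a[2L] * e1[3L] - a[3L] * e1[2L],
          a[3L] * e1[1L] - a[1L] * e1[3L],
          a[1L] * e1[2L] - a[2L] * e1[1L])
  list(a = a, e1 = e1, e2 = e2)
}

# distance of points to the line (c0 + t a), plus the height t
.axis_dist <- function(points, a, c0) {
  q <- sweep(points, 2L, c0)
  t <- as.numeric(q %*% a)
  hq <- q - outer(t, a)
  list(d = sqrt(rowSums(hq^2)), t = t)
}

# shared engine: least-squares surface of revolution with linear radius
# profile r(t) = r0 + k t; `taper = FALSE` pins k = 0 (a true cylinder).
.fit_revolved_wall <- function(points, axis_init, taper, max_iter = 100L) {
  points <- as.matrix(points)
  if (nrow(points) < 6L) stop("cylinder fit needs at least 6 points")
  fr <- .axis_frame(axis_init)
  ctr <- colMeans(points)
  resid_fn <- function(par) {
    a <- fr$a + par[1L] * fr$e1 + par[2L] * fr$e2
    a <- a / sqrt(sum(a^2))
    c0 <- ctr + par[3L] * fr$e1 + par[4L] * fr$e2
    ad <- .axis_dist(points, a, c0)
    if (taper) {
      fitv <- stats::lm.fit(cbind(1, ad$t), ad$d)$fitted.values
      ad$d - fitv
    } else {
      ad$d - mean(ad$d)
    }
  }
  fit <- minpack.lm::nls.lm(
    par = c(0, 0, 0, 0), fn = resid_fn,
    control = minpack.lm::nls.lm.control(maxiter = max_iter, ftol = 1e-15,
                                         ptol = 1e-15))
  if (fit$info == 5L) {
    stop(sprintf("cylinder fit did not converge in %d iterations (residual %.3g mm)",
                 max_iter, sqrt(mean(fit$fvec^2))))
  }
  par <- fit$par
  a <- fr$a + par[1L] * fr$e1 + par[2L] * fr$e2
  a <- a / sqrt(sum(a^2))
  c0 <- ctr + par[3L] * fr$e1 + par[4L] * fr$e2
  ad <- .axis_dist(points, a, c0)
  if (taper) {
    cf <- stats::lm.fit(cbind(1, ad$t), ad$d)$coefficients
    r0 <- cf[[1L]]; k <- cf[[2L]]
  } else {
    r0 <- mean(ad$d); k <- 0
  }
  res <- ad$d - (r0 + k * ad$t)
  list(axis = a, center = c0, radius = r0, taper = k,
       residual = sqrt(mean(res^2)))
}

#' Least squares cylinder fit
#'
#' Nonlinear least squares over axis direction and position, minimising
#' `sum((distance-to-axis - r)^2)`; the radius is profiled out analytically
#' at each step. Initialisation requires `axis_init` within about 45 degrees
#' of the true axis.
#'
#' @param points n x 3 matrix, n >= 6.
#' @param axis_init length-3 initial axis direction.
#' @return list with `axis` (unit), `center` (a point on the axis), `radius`
#'   (mm) and `residual` (RMS of `distance - radius`, mm).
#' @export
fit_cylinder <- function(points, axis_init) {
  fit <- .fit_revolved_wall(points, axis_init, taper = FALSE)
  fit[c("axis", "center", "radius", "residual")]
}

.cyl_resid <- function(fit, points) {
  ad <- .axis_dist(as.matrix(points), fit$axis, fit$center)
  ad$d - (fit$radius + if (is.null(fit$taper)) 0 else fit$taper * ad$t)
}

#' Least squares cone fit
#'
#' Fits a right circular cone by Levenberg-Marquardt over apex, axis
#' direction and half-angle, minimising orthogonal distances
#' `rho cos(gamma) - h sin(gamma)` (zero on the surface). The reported
#' surface inclination is `theta = 90 - gamma` degrees, i.e. the angle of
#' the lateral surface above the plane perpendicular to the axis. Nearly
#' flat data (initial inclination below `flat_tol` degrees) falls back to a
#' plane fit and reports `theta = 0` with `degenerate = TRUE`.
#'
#' @param points n x 3 matrix, n >= 7.
#' @param axis_init length-3 initial axis direction, pointing from the cone
#'   opening towards the apex.
#' @param flat_tol degeneracy threshold on the initial inclination, degrees.
#' @return list with `apex` (3-vector), `axis` (unit, towards the apex),
#'   `theta` (degrees), `half_angle` (degrees, `90 - theta`), `residual`
#'   (RMS orthogonal distance, mm) and `degenerate` (logical).
#' @export
fit_cone <- function(points, axis_init, flat_tol = 0.5) {
  points <- as.matrix(points)
  if (nrow(points) < 7L) stop("cone fit needs at least 7 points")
  fr <- .axis_frame(axis_init)
  ctr <- colMeans(points)
  ad0 <- .axis_dist(points, fr$a, ctr)
  sl <- stats::lm.fit(cbind(1, ad0$d), ad0$t)$coefficients
  theta0 <- atan(-sl[[2L]])          # t = t_apex - rho tan(theta)
  if (abs(theta0) < flat_tol * pi / 180) {
    pl <- fit_plane(points)
    nrm <- pl$normal * sign(sum(pl$normal * fr$a))
    apex <- ctr + (pl$offset - sum(pl$normal * ctr)) / sum(pl$normal * nrm) * nrm
    return(list(apex = apex, axis = fr$a, theta = 0, half_angle = 90,
                residual = pl$residual, degenerate = TRUE))
  }
  apex0 <- ctr + fr$a * sl[[1L]]     # regression height at rho = 0
  gamma0 <- pi / 2 - abs(theta0)
  resid_fn <- function(par) {
    a <- fr$a + par[4L] * fr$e1 + par[5L] * fr$e2
    a <- a / sqrt(sum(a^2))
    apex <- par[1:3]
    q <- sweep(points, 2L, apex)
    h <- -as.numeric(q %*% a)          # depth below apex along the axis
    rho <- sqrt(pmax(rowSums(q^2) - h^2, 0))
    rho * cos(par[6L]) - h * sin(par[6L])
  }
  fit <- minpack.lm::nls.lm(
    par = c(apex0, 0, 0, gamma0), fn = resid_fn,
    control = minpack.lm::nls.lm.control(maxiter = 500L, ftol = 1e-15,
                                         ptol = 1e-15))
  if (fit$info == 5L) {
    stop(sprintf("cone fit did not converge (residual %.3g mm)",
                 sqrt(mean(fit$fvec^2))))
  }
  a <- fr$a + fit$par[4L] * fr$e1 + fit$par[5L] * fr$e2
  a <- a / sqrt(sum(a^2))
  gamma <- fit$par[6L]
  theta <- 90 - gamma * 180 / pi
  list(apex = fit$par[1:3], axis = a, theta = theta,
       half_angle = gamma * 180 / pi,
       residual = sqrt(mean(fit$fvec^2)), degenerate = FALSE)
}

.cone_resid <- function(fit, points) {
  points <- as.matrix(points)
  if (isTRUE(fit$degenerate)) {
    return(as.numeric(points %*% fit$axis) - sum(fit$axis * fit$apex))
  }
  q <- sweep(points, 2L, fit$apex)
  h <- -as.numeric(q %*% fit$axis)
  rho <- sqrt(pmax(rowSums(q^2) - h^2, 0))
  g <- fit$half_angle * pi / 180
  rho * cos(g) - h * sin(g)
}

# iterated trimmed refit: robust to a minority of mislabelled points while
# remaining exact (machine precision) on clean data
.robust_fit <- function(points, fit_fun, resid_fun, rounds = 4L, k = 4) {
  points <- as.matrix(points)
  idx <- seq_len(nrow(points))
  fit <- fit_fun(points)
  for (r in seq_len(rounds)) {
    res <- abs(resid_fun(fit, points))
    s <- max(stats::median(res) * 1.4826, 1e-9)
    keep <- which(res < k * s)
    if (length(keep) < 8L || length(keep) == length(idx)) break
    refit <- tryCatch(fit_fun(points[keep, , drop = FALSE]),
                      error = function(e) NULL)
    if (is.null(refit)) break     # keep the last successful fit
    fit <- refit
    idx <- keep
  }
  fit$n_used <- length(idx)
  fit
}
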