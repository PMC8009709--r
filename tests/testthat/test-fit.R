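test_that("plane fit is exact on planar data and order invariant", {
  set.seed(3)
  pts <- cbind(runif(40, -2, 2), runif(40, -2, 2), 5)
  f <- fit_plane(pts)
  expect_equal(abs(f$normal[3]), 1, tolerance = 1e-12)
  expect_equal(f$offset * sign(f$normal[3]), 5, tolerance = 1e-12)
  expect_equal(f$residual, 0, tolerance = 1e-12)
  f2 <- fit_plane(pts[sample(40), ])
  expect_equal(abs(sum(f$normal * f2$normal)), 1, tolerance = 1e-12)
  expect_error(fit_plane(cbind(1:9, 2 * (1:9), 3 * (1:9))), "collinear")
})

test_that("plane fit residual matches a brute-force numeric oracle", {
  pts <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
               c(0.5, 0.5, 0.1))
  f <- fit_plane(pts)
  # oracle: direct minimisation of RMS orthogonal distance over (angles, d)
  obj <- function(par) {
    n <- c(sin(par[1]) * cos(par[2]), sin(par[1]) * sin(par[2]), cos(par[1]))
    sqrt(mean((pts %*% n - par[3])^2))
  }
  o <- stats::optim(c(0.01, 0.01, 0), obj, method = "Nelder-Mead",
                    control = list(reltol = 1e-14, maxit = 5000))
  expect_equal(f$residual, o$value, tolerance = 1e-6)
})

test_that("cylinder fit recovers exact tessellated radii", {
  ang <- seq(0, 2 * pi, length.out = 181)[-181]
  for (r_true in c(3, 5)) {
    pts <- do.call(rbind, lapply(seq(0, 8, by = 0.5), function(z) {
      cbind(r_true * cos(ang), r_true * sin(ang), z)
    }))
    f <- fit_cylinder(pts, axis_init = c(0.2, -0.1, 1))
    expect_equal(f$radius, r_true, tolerance = 1e-9)
    expect_lt(f$residual, 1e-9)
    expect_equal(abs(f$axis[3]), 1, tolerance = 1e-9)
  }
})

test_that("cylinder fit is consistent under radial noise", {
  set.seed(17)
  n <- 5000
  ang <- runif(n, 0, 2 * pi)
  z <- runif(n, 0, 8)
  r <- 3 + rnorm(n, sd = 0.01)
  pts <- cbind(r * cos(ang), r * sin(ang), z)
  f <- fit_cylinder(pts, axis_init = c(0, 0, 1))
  expect_equal(f$radius, 3, tolerance = 1e-3)
})

test_that("cone fit recovers the surface inclination exactly", {
  ang <- seq(0, 2 * pi, length.out = 121)[-121]
  th <- 23 * pi / 180
  pts <- do.call(rbind, lapply(seq(0.8, 3, by = 0.2), function(r) {
    cbind(r * cos(ang), r * sin(ang), 11.273 - r * tan(th))
  }))
  f <- fit_cone(pts, axis_init = c(0, 0, 1))
  expect_false(f$degenerate)
  expect_equal(f$theta, 23, tolerance = 1e-6)
  expect_lt(f$residual, 1e-9)
  expect_equal(f$apex, c(0, 0, 11.273), tolerance = 1e-6)
})

test_that("cone fit flags flat caps and is rigid-transform invariant", {
  ang <- seq(0, 2 * pi, length.out = 61)[-61]
  flat <- do.call(rbind, lapply(c(1, 2, 3), function(r) {
    cbind(r * cos(ang), r * sin(ang), 10)
  }))
  f <- fit_cone(flat, axis_init = c(0, 0, 1))
  expect_true(f$degenerate)
  expect_equal(f$theta, 0)

  th <- 30 * pi / 180
  pts <- do.call(rbind, lapply(seq(0.5, 3, by = 0.25), function(r) {
    cbind(r * cos(ang), r * sin(ang), 12 - r * tan(th))
  }))
  set.seed(5)
  tr <- random_rigid_transform(40, 10)
  f1 <- fit_cone(pts, axis_init = c(0, 0, 1))
  f2 <- fit_cone(apply_transform(pts, tr),
                 axis_init = as.numeric(tr$R %*% c(0, 0, 1)))
  expect_equal(f2$theta, f1$theta, tolerance = 1e-6)
})
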