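test_that("registering a mesh onto itself returns the identity", {
  m <- generate_model(model_spec(segments = 48L))
  fit <- icp_register(m, m)
  expect_true(fit$converged)
  expect_lt(fit$rms, 1e-9)
  expect_lt(rotation_angle(fit$transform), 1e-9)
  expect_lt(sqrt(sum(fit$transform$t^2)), 1e-9)
})

test_that("icp recovers a known rigid transform on the noise-free model", {
  m <- generate_model(model_spec(segments = 64L, outer_draft = 0))
  set.seed(21)
  for (i in 1:2) {
    tr <- random_rigid_transform(20, 3)
    fit <- icp_register(apply_transform(m, tr), m, tol = 1e-12)
    rec <- compose_transform(fit$transform, tr)   # identity if recovered
    expect_lt(rotation_angle(rec) * pi / 180, 1e-6)
    expect_lt(sqrt(sum(rec$t^2)), 1e-6)
    expect_lt(fit$rms, 1e-6)
  }
})

test_that("pure point-to-point iterations never increase correspondence RMS", {
  m <- generate_model(model_spec(segments = 48L))
  set.seed(4)
  tr <- random_rigid_transform(15, 2)
  fit <- icp_register(apply_transform(m, tr), m, method = "point",
                      max_iter = 60L, tol = 0)
  expect_true(all(diff(fit$rms_trace) <= 1e-12))
})

test_that("deviation maps are zero for identical meshes and signed for offsets", {
  m <- generate_model(model_spec(segments = 32L))
  d0 <- deviation_map(m, m)
  expect_true(all(abs(d0$signed_distance) < 1e-12))
  expect_equal(rms_deviation(d0), 0)
  ref <- make_plane_patch(0, 4)
  above <- apply_transform(make_plane_patch(0, 4),
                           rigid_transform(diag(3), c(0, 0, 0.2)))
  dv <- deviation_map(above, ref)
  expect_equal(unname(dv$signed_distance), rep(0.2, 4), tolerance = 1e-12)
  expect_equal(rms_deviation(dv), 0.2, tolerance = 1e-12)
  below <- apply_transform(ref, rigid_transform(diag(3), c(0, 0, -0.3)))
  expect_true(all(deviation_map(below, ref)$signed_distance < 0))
})

test_that("closest-point distances match the brute-force oracle", {
  set.seed(8)
  mesh <- make_plane_patch(0, 2)
  mesh <- triangle_mesh(rbind(mesh$vertices, c(1, 1, 1)),
                        rbind(mesh$faces, c(2L, 4L, 5L), c(4L, 3L, 5L)))
  expect_lte(n_vertices(mesh), 50L)
  pts <- cbind(runif(25, -1, 3), runif(25, -1, 3), runif(25, -1, 2))
  fast <- closest_points(pts, mesh)$distance
  slow <- brute_force_distance(pts, mesh)
  expect_equal(fast, slow, tolerance = 1e-9)
})

test_that("rms is invariant under a joint rigid transform of both meshes", {
  m <- generate_model(model_spec(segments = 32L))
  s <- simulate_scan(m, scanner_profile("n", noise_sigma = 0.05,
                                        base_seed = 3L), 1)
  r1 <- rms_deviation(deviation_map(s, m))
  set.seed(13)
  tr <- random_rigid_transform(50, 10)
  r2 <- rms_deviation(deviation_map(apply_transform(s, tr),
                                    apply_transform(m, tr)))
  expect_equal(r1, r2, tolerance = 1e-9)
})

test_that("replicate-form RMS follows the per-replicate formula", {
  expect_equal(replicate_rms(10, c(9, 11)), 1)
  expect_equal(replicate_rms(3, rep(3, 30)), 0)
  set.seed(30)
  rA <- rnorm(30, 3, 0.2)
  expect_equal(replicate_rms(3, rA), sqrt(sum((3 - rA)^2) / 30),
               tolerance = 1e-12)
  expect_error(replicate_rms(3, 2.9), "at least 2")
})
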