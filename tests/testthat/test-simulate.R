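ref48 <- generate_model(model_spec(segments = 48L))

test_that("null profile is the identity and replicates are deterministic", {
  null <- scanner_profile("null")
  s <- simulate_scan(ref48, null, 1)
  expect_identical(s$vertices, ref48$vertices)
  expect_identical(s$faces, ref48$faces)
  p <- scanner_profile("p", noise_sigma = 0.05, drift_amplitude = 0.02,
                       pose_rotation_max = 5, pose_translation_max = 2,
                       sample_fraction = 0.9, base_seed = 123L)
  a <- simulate_scan(ref48, p, 7)
  b <- simulate_scan(ref48, p, 7)
  expect_identical(a$vertices, b$vertices)
  expect_identical(a$faces, b$faces)
  # different replicates differ
  expect_false(identical(simulate_scan(ref48, p, 8)$vertices, a$vertices))
})

test_that("simulation leaves the caller's RNG stream untouched", {
  set.seed(99)
  before <- .Random.seed
  invisible(simulate_scan(ref48, scanner_profile("p", noise_sigma = 0.1), 1))
  expect_identical(.Random.seed, before)
})

test_that("normal noise displaces vertices by sigma in RMS", {
  ref <- generate_model(model_spec(segments = 256L))
  expect_gt(n_vertices(ref), 1e4)
  p <- scanner_profile("n", noise_sigma = 0.05, base_seed = 11L)
  s <- simulate_scan(ref, p, 1)
  disp <- sqrt(mean(rowSums((s$vertices - ref$vertices)^2)))
  expect_equal(disp, 0.05, tolerance = 0.05)   # within 5 %
})

test_that("group RMS deviation increases with noise sigma", {
  rms <- vapply(c(0.01, 0.05, 0.10), function(sg) {
    p <- scanner_profile("g", noise_sigma = sg, base_seed = 500L)
    mean(vapply(1:2, function(k) {
      rms_deviation(deviation_map(simulate_scan(ref48, p, k), ref48))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(rms) > 0))
})

test_that("a study writes systematically named STL files per profile", {
  profs <- list(scanner_profile("sysA", noise_sigma = 0.02, base_seed = 1L),
                scanner_profile("sysB", noise_sigma = 0.05, base_seed = 2L))
  out <- withr::local_tempdir()
  study <- simulate_study(ref48, profs, n_replicates = 3, out_dir = out)
  expect_named(study, c("sysA", "sysB"))
  expect_length(attr(study, "files"), 6L)
  expect_true(file.exists(file.path(out, "sysB", "scan_003.stl")))
  back <- read_stl(file.path(out, "sysA", "scan_001.stl"))
  expect_equal(n_faces(back), n_faces(study$sysA[[1]]))
  expect_error(simulate_study(ref48, profs[c(1, 1)], 2), "duplicate")
})

test_that("profiles survive the flat config round trip", {
  p <- scanner_profile("ios", noise_sigma = 0.033, drift_amplitude = 0.02,
                       drift_scale = 7, sample_fraction = 0.85,
                       base_seed = 42L)
  path <- withr::local_tempfile(fileext = ".cfg")
  write_scanner_profile(p, path)
  expect_equal(read_scanner_profile(path), p)
})

test_that("decimation below 4 faces is rejected", {
  tiny <- triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0),
                              c(0, 0, 1)),
                        rbind(c(1L, 2L, 3L), c(2L, 4L, 3L), c(1L, 2L, 5L),
                              c(2L, 4L, 5L), c(4L, 3L, 5L), c(3L, 1L, 5L)))
  p <- scanner_profile("d", sample_fraction = 0.3, base_seed = 1L)
  expect_error(simulate_scan(tiny, p, 1), "below 4 faces")
})
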