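test_that("segmentation finds all six regions on a clean model", {
  m <- generate_model(model_spec(segments = 96L))
  reg <- segment_regions(m)
  expect_named(reg, c("base", "shoulder", "lower_wall", "upper_wall",
                      "occlusal", "ditch"))
  expect_true(all(lengths(reg) > 0))
  # regions are disjoint
  all_idx <- unlist(reg)
  expect_equal(anyDuplicated(all_idx), 0L)
  # base vertices sit at the bottom, occlusal at the top of the axis
  ax <- attr(reg, "axis")
  t <- as.numeric(m$vertices %*% ax)
  expect_lt(max(t[reg$base]), min(t[reg$occlusal]))
})

test_that("segmentation is invariant under rotation with a correct hint", {
  m <- generate_model(model_spec(segments = 64L))
  reg0 <- segment_regions(m, axis_hint = c(0, 0, 1))
  Rz <- rotation_about(c(1, 2, 0), 30)
  m2 <- apply_transform(m, rigid_transform(Rz))
  reg1 <- segment_regions(m2, axis_hint = as.numeric(Rz %*% c(0, 0, 1)))
  expect_equal(lengths(reg1), lengths(reg0))
})

test_that("segmentation rejects a sphere (no planar base)", {
  expect_error(segment_regions(make_sphere()), "segmentation failed")
})

test_that("indices are recovered across the design grid", {
  for (sp in list(model_spec(R1 = 2, theta = 30, outer_draft = 0,
                             segments = 96L),
                  model_spec(R1 = 4, theta = 0, outer_draft = 2,
                             segments = 96L),
                  model_spec(theta = 15, outer_draft = 2, segments = 96L))) {
    mi <- measure_indices(generate_model(sp))
    got <- unlist(as.data.frame(mi))
    expect_lt(max(abs(got[1:5] - spec_indices(sp)[1:5])), 0.005)
    expect_lt(abs(got[["theta"]] - sp$theta), 0.05)
  }
})

test_that("flat-capped model reports the cone degeneracy", {
  mi <- measure_indices(generate_model(model_spec(theta = 0, segments = 96L)))
  expect_true(mi$cone_degenerate)
  expect_equal(mi$theta, 0)
})

test_that("indices are pose invariant", {
  m <- generate_model(model_spec(segments = 96L))
  base <- unlist(as.data.frame(measure_indices(m)))
  set.seed(19)
  tr <- random_rigid_transform(120, 15)
  posed <- unlist(as.data.frame(measure_indices(apply_transform(m, tr))))
  expect_equal(posed, base, tolerance = 1e-6)
})

test_that("fit residuals on clean meshes stay below the chord error", {
  sp <- model_spec(segments = 128L)
  mi <- measure_indices(generate_model(sp))
  chord <- sp$R2 * (1 - cos(pi / sp$segments))
  expect_true(all(mi$residuals < chord))
})

test_that("index SD across replicates grows with the noise level", {
  ref <- generate_model(model_spec(segments = 128L))
  sds <- sapply(c(0.01, 0.05), function(sg) {
    p <- scanner_profile("n", noise_sigma = sg, base_seed = 800L)
    vals <- t(vapply(1:4, function(k) {
      unlist(as.data.frame(measure_indices(simulate_scan(ref, p, k))))
    }, numeric(6L)))
    apply(vals, 2, sd)
  })
  expect_true(all(sds[, 2] > sds[, 1]))
})
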