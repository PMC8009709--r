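test_that("model_spec enforces the design invariants by name", {
  expect_error(model_spec(R1 = 5, R2 = 3), "R1 < R2")
  expect_error(model_spec(L1 = 0), "L1 > 0")
  expect_error(model_spec(L3 = 11), "L3 = L1 \\+ L2")
  expect_error(model_spec(theta = 90), "theta")
  expect_error(model_spec(ditch_width = 7), "ditch_width")
  expect_error(model_spec(ditch_depth = 2.5), "ditch_depth")
  expect_error(model_spec(outer_draft = -1), "outer_draft")
  expect_error(model_spec(outer_draft = 15), "draft")
})

test_that("generated models are watertight and consistently oriented", {
  for (sp in list(model_spec(segments = 48L),
                  model_spec(segments = 48L, outer_draft = 0),
                  model_spec(R1 = 2, theta = 30, segments = 48L),
                  model_spec(R1 = 4, theta = 0, segments = 48L),
                  model_spec(segments = 48L, ditch_width = 0,
                             ditch_depth = 0))) {
    m <- generate_model(sp)
    expect_true(is_watertight(m))
    expect_true(is_consistently_oriented(m))
    expect_gt(mesh_volume(m), 0)
    # no undercut: nothing sticks out beyond the base circle
    expect_lte(max(sqrt(rowSums(m$vertices[, 1:2]^2))), sp$R2 + 1e-9)
  }
})

test_that("flat-capped ditchless model has max height exactly L3", {
  m <- generate_model(model_spec(theta = 0, ditch_width = 0, ditch_depth = 0,
                                 outer_draft = 0, segments = 64L))
  expect_equal(max(m$vertices[, 3]), 10)
})

test_that("volume of the flat two-tier cylinder converges with tessellation", {
  exact <- pi * (5^2 * 8 + 3^2 * 2)
  errs <- vapply(c(64L, 128L, 256L), function(s) {
    abs(mesh_volume(generate_model(model_spec(
      theta = 0, ditch_width = 0, ditch_depth = 0, outer_draft = 0,
      segments = s))) - exact)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3] / exact, 1e-3)
})

test_that("model with equal ditches is symmetric under a quarter turn", {
  m <- generate_model(model_spec(segments = 64L))
  r <- apply_transform(m, rigid_transform(rotation_about(c(0, 0, 1), 90)))
  merged <- weld_vertices(
    triangle_mesh(rbind(m$vertices, r$vertices),
                  rbind(m$faces, r$faces + nrow(m$vertices))), tol = 1e-6)
  # every rotated vertex welds onto an original one
  expect_equal(n_vertices(merged), n_vertices(m))
})

test_that("gold standard carries design or substituted reference values", {
  gs <- gold_standard(model_spec(), segments = 48L)
  expect_equal(unname(gs$reference_values),
               c(3, 5, 2, 8, 10, 23))
  cmm <- c(R1 = 3.003, R2 = 5.044, L1 = 2.029, L2 = 7.914, L3 = 9.942,
           theta = 23.199)
  gs2 <- gold_standard(model_spec(), segments = 48L, reference_values = cmm)
  expect_equal(gs2$reference_values, cmm)
  expect_true(is_watertight(gs2$mesh))
})

test_that("model spec survives the flat config round trip", {
  sp <- model_spec(R1 = 2.5, theta = 17, segments = 96L)
  path <- withr::local_tempfile(fileext = ".cfg")
  write_model_spec(sp, path)
  expect_equal(read_model_spec(path), sp)
})
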