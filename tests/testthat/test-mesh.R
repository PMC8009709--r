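test_that("triangle_mesh validates its invariants", {
  expect_error(triangle_mesh(matrix(0, 0, 3), rbind(1:3)), "empty")
  expect_error(triangle_mesh(diag(3), rbind(c(1, 1, 2))), "degenerate")
  expect_error(triangle_mesh(diag(3), rbind(c(1, 2, 4))), "out of range")
  v <- diag(3); v[1, 1] <- NA
  expect_error(triangle_mesh(v, rbind(1:3)), "non-finite")
})

test_that("welding merges coincident vertices and drops collapsed faces", {
  # two triangles sharing an edge, written as a 6-vertex soup
  soup <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
                c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  m <- weld_vertices(triangle_mesh(soup, rbind(1:3, 4:6)))
  expect_equal(n_vertices(m), 4L)
  expect_equal(n_faces(m), 2L)
  # near-coincident points across a rounding boundary still merge
  soup2 <- rbind(soup, soup[1, ] + 1e-9)
  m2 <- weld_vertices(triangle_mesh(soup2, rbind(1:3, 4:6, c(7L, 2L, 3L))))
  expect_equal(n_vertices(m2), 4L)
})

test_that("rigid transforms compose, invert and preserve edge lengths", {
  set.seed(11)
  tr <- random_rigid_transform(60, 10)
  m <- generate_model(model_spec(segments = 32L))
  m2 <- apply_transform(m, tr)
  expect_equal(edge_lengths(m2), edge_lengths(m), tolerance = 1e-9)
  back <- apply_transform(m2, invert_transform(tr))
  expect_lt(max(abs(back$vertices - m$vertices)), 1e-9)
  # identity and pure translation
  expect_identical(apply_transform(m, rigid_transform())$vertices, m$vertices)
  sh <- apply_transform(m, rigid_transform(diag(3), c(1, 0, 0)))
  expect_equal(sh$vertices[, 1], m$vertices[, 1] + 1)
  expect_equal(sh$vertices[, 2:3], m$vertices[, 2:3])
  # composition closure
  tr2 <- random_rigid_transform(30, 2)
  comp <- compose_transform(tr2, tr)
  expect_equal(apply_transform(apply_transform(m, tr), tr2)$vertices,
               apply_transform(m, comp)$vertices, tolerance = 1e-12)
  expect_error(rigid_transform(matrix(1, 3, 3)), "orthonormal")
})

test_that("vertex normals of a flat patch point along +z", {
  p <- make_plane_patch()
  vn <- vertex_normals(p)
  expect_equal(vn, matrix(rep(c(0, 0, 1), each = 4), 4), tolerance = 1e-12)
})
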