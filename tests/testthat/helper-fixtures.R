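# shared fixtures, built in code at test time

# lat-long tessellated sphere (no planar regions at all)
make_sphere <- function(radius = 3, n_lat = 16L, n_lon = 32L) {
  lat <- seq(-pi / 2, pi / 2, length.out = n_lat + 1L)
  lon <- seq(0, 2 * pi, length.out = n_lon + 1L)[-(n_lon + 1L)]
  pts <- do.call(rbind, lapply(lat, function(la) {
    cbind(radius * cos(la) * cos(lon), radius * cos(la) * sin(lon),
          radius * sin(la))
  }))
  idx <- matrix(seq_len(nrow(pts)), nrow = n_lon)
  faces <- NULL
  for (j in seq_len(n_lat)) {
    i <- seq_len(n_lon)
    ip <- c(i[-1L], 1L)
    a <- idx[i, j]; b <- idx[ip, j]; cc <- idx[ip, j + 1L]; d <- idx[i, j + 1L]
    faces <- rbind(faces, cbind(a, b, cc), cbind(a, cc, d))
  }
  weld_vertices(triangle_mesh(pts, faces))
}

# two-triangle square patch in the z = z0 plane, normals +z
make_plane_patch <- function(z0 = 0, size = 1) {
  triangle_mesh(rbind(c(0, 0, z0), c(size, 0, z0), c(0, size, z0),
                      c(size, size, z0)),
                rbind(c(1L, 2L, 3L), c(2L, 4L, 3L)))
}

# hand-written ASCII STL of the unit cube (12 facets, 8 distinct corners)
write_cube_ascii_stl <- function(path) {
  v <- expand.grid(x = 0:1, y = 0:1, z = 0:1)
  quads <- list(c(1, 2, 4, 3), c(5, 7, 8, 6), c(1, 5, 6, 2), c(3, 4, 8, 7),
                c(1, 3, 7, 5), c(2, 6, 8, 4))
  lines <- "solid cube"
  for (q in quads) {
    for (tri in list(q[c(1, 2, 3)], q[c(1, 3, 4)])) {
      lines <- c(lines, "  facet normal 0 0 0", "    outer loop",
                 sprintf("      vertex %g %g %g", v[tri, 1], v[tri, 2],
                         v[tri, 3]),
                 "    endloop", "  endfacet")
    }
  }
  writeLines(c(lines, "endsolid cube"), path)
  path
}

# brute-force unsigned point-to-mesh distance (all-triangle minimisation)
brute_force_distance <- function(points, mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  closest_tri <- function(p, a, b, cc) {
    # minimise |a + s ab + t ac - p| over the triangle domain by dense
    # barycentric grid refinement (independent of the C++ region walk)
    ab <- b - a; ac <- cc - a
    best <- Inf
    s_lo <- 0; s_hi <- 1; t_lo <- 0; t_hi <- 1
    for (pass in 1:12) {
      s <- seq(s_lo, s_hi, length.out = 21)
      t <- seq(t_lo, t_hi, length.out = 21)
      g <- expand.grid(s = s, t = t)
      # project points beyond the hypotenuse back onto it so the s + t = 1
      # boundary stays reachable through every refinement pass
      over <- g$s + g$t > 1
      g$s[over] <- g$s[over] / (g$s[over] + g$t[over])
      g$t[over] <- 1 - g$s[over]
      q <- cbind(a[1] + g$s * ab[1] + g$t * ac[1],
                 a[2] + g$s * ab[2] + g$t * ac[2],
                 a[3] + g$s * ab[3] + g$t * ac[3])
      d2 <- (q[, 1] - p[1])^2 + (q[, 2] - p[2])^2 + (q[, 3] - p[3])^2
      k <- which.min(d2)
      best <- sqrt(d2[k])
      ds <- (s_hi - s_lo) / 20; dt <- (t_hi - t_lo) / 20
      s_lo <- max(0, g$s[k] - ds); s_hi <- min(1, g$s[k] + ds)
      t_lo <- max(0, g$t[k] - dt); t_hi <- min(1, g$t[k] + dt)
    }
    best
  }
  vapply(seq_len(nrow(points)), function(i) {
    min(vapply(seq_len(nrow(f)), function(j) {
      closest_tri(points[i, ], v[f[j, 1], ], v[f[j, 2], ], v[f[j, 3], ])
    }, numeric(1)))
  }, numeric(1))
}
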