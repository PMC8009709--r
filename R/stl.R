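#' Read an STL file
#'
#' Reads binary or ASCII STL (auto-detected) into a [triangle_mesh()].
#' STL stores an unindexed triangle soup, so coincident facet corners are
#' welded on input; the face count equals the facet count in the file.
#'
#' @param path path to an STL file.
#' @param weld_tol weld tolerance in mm passed to [weld_vertices()].
#' @return a [triangle_mesh()].
#' @export
read_stl <- function(path, weld_tol = 1e-6) {
  size <- file.info(path)$size
  if (is.na(size) || size == 0) stop("empty or unreadable STL file: ", path)
  head_raw <- readBin(path, "raw", n = min(size, 512L))
  txt <- rawToChar(head_raw[head_raw != as.raw(0L)])
  ascii <- grepl("^\\s*solid", txt, useBytes = TRUE) &&
    grepl("facet", txt, useBytes = TRUE)
  tri <- if (ascii) .read_stl_ascii(path) else .read_stl_binary(path, size)
  nf <- nrow(tri) / 3L
  mesh <- triangle_mesh(tri, matrix(seq_len(3L * nf), ncol = 3L, byrow = TRUE))
  weld_vertices(mesh, tol = weld_tol)
}

.read_stl_binary <- function(path, size) {
  if (size < 84) {
    stop(sprintf("malformed binary STL '%s': %d bytes, need at least 84",
                 path, size))
  }
  con <- file(path, "rb")
  on.exit(close(con))
  invisible(readBin(con, "raw", n = 80L))
  count <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  expected <- 84 + 50 * count
  if (expected != size) {
    stop(sprintf(
      "malformed binary STL '%s': facet count %d implies %d bytes, file has %d (records start at byte offset 84)",
      path, count, expected, size))
  }
  if (count == 0L) stop("binary STL contains zero facets: ", path)
  rec <- matrix(readBin(con, "raw", n = 50L * count), nrow = 50L)
  coords <- readBin(as.vector(rec[1:48, ]), "numeric", n = 12L * count,
                    size = 4L, endian = "little")
  m <- matrix(coords, nrow = 12L)          # nx ny nz v1 v2 v3 per column
  tri <- matrix(as.vector(m[4:12, ]), ncol = 3L, byrow = TRUE)
  if (any(!is.finite(tri))) stop("non-finite coordinates in binary STL: ", path)
  tri
}

.read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vl) == 0L || length(vl) %% 3L != 0L) {
    stop(sprintf("malformed ASCII STL '%s': %d vertex lines (not a positive multiple of 3)",
                 path, length(vl)))
  }
  nums <- scan(text = sub("^\\s*vertex\\s+", "", vl), quiet = TRUE)
  if (length(nums) != 3L * length(vl)) {
    stop("malformed ASCII STL vertex line in ", path)
  }
  matrix(nums, ncol = 3L, byrow = TRUE)
}

#' Write an STL file
#'
#' Binary mode writes the standard little-endian layout: 80-byte header,
#' uint32 facet count, then one 50-byte record per facet (normal, three
#' vertices as float32, attribute byte count 0). Coordinates are therefore
#' stored in single precision in either mode.
#'
#' @param mesh a [triangle_mesh()].
#' @param path output path.
#' @param mode `"binary"` (default) or `"ascii"`.
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path, mode = c("binary", "ascii")) {
  mode <- match.arg(mode)
  stopifnot(inherits(mesh, "triangle_mesh"))
  fn <- face_normals(mesh)$normals
  v <- mesh$vertices
  f <- mesh$faces
  if (mode == "binary") {
    con <- file(path, "wb")
    on.exit(close(con))
    header <- charToRaw(sprintf("%-80s", "scanmetry binary STL"))[1:80]
    writeBin(header, con)
    writeBin(as.integer(nrow(f)), con, size = 4L, endian = "little")
    per_facet <- cbind(fn, v[f[, 1L], , drop = FALSE],
                       v[f[, 2L], , drop = FALSE], v[f[, 3L], , drop = FALSE])
    floats <- writeBin(as.vector(t(per_facet)), raw(), size = 4L,
                       endian = "little")
    rec <- matrix(raw(1L), nrow = 50L, ncol = nrow(f))
    rec[1:48, ] <- matrix(floats, nrow = 48L)
    writeBin(as.vector(rec), con)
  } else {
    out <- character(7L * nrow(f) + 2L)
    out[1L] <- "solid scanmetry"
    base <- 1L + 7L * (seq_len(nrow(f)) - 1L)
    out[base + 1L] <- sprintf("  facet normal %.9e %.9e %.9e",
                              fn[, 1L], fn[, 2L], fn[, 3L])
    out[base + 2L] <- "    outer loop"
    for (k in 1:3) {          # vertex lines of the facet loop
      vk <- v[f[, k], , drop = FALSE]
      out[base + 2L + k] <- sprintf("      vertex %.9e %.9e %.9e",
                                    vk[, 1L], vk[, 2L], vk[, 3L])
    }
    out[base + 6L] <- "    endloop"
    out[base + 7L] <- "  endfacet"
    out[length(out)] <- "endsolid scanmetry"
    writeLines(out, path)
  }
  invisible(path)
}
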