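#' Scanner error profile
#'
#' A stochastic stand-in for one scan system. A simulated scan perturbs the
#' reference mesh with, in order: (1) a smooth low-frequency drift field
#' displacing vertices along their normals (emulating accumulated stitching
#' error), (2) i.i.d. Gaussian noise along the normals (optical depth
#' error), (3) a random rigid pose, and (4) random face decimation.
#'
#' @param name label for the simulated system; used in reports/file names.
#' @param noise_sigma SD of the per-vertex Gaussian normal displacement, mm.
#' @param drift_amplitude RMS amplitude of the smooth drift field, mm.
#' @param drift_scale spatial correlation length of the drift, mm (> 0).
#' @param pose_rotation_max maximum random pose rotation, degrees.
#' @param pose_translation_max maximum random pose translation, mm.
#' @param sample_fraction fraction of faces retained after decimation,
#'   in `(0, 1]`.
#' @param base_seed integer seed; replicate `k` uses `base_seed + k`.
#' @return object of class `scanner_profile`.
#' @export
scanner_profile <- function(name, noise_sigma = 0, drift_amplitude = 0,
                            drift_scale = 10, pose_rotation_max = 0,
                            pose_translation_max = 0, sample_fraction = 1,
                            base_seed = 1L) {
  stopifnot(noise_sigma >= 0, drift_amplitude >= 0, drift_scale > 0,
            pose_rotation_max >= 0, pose_translation_max >= 0,
            sample_fraction > 0, sample_fraction <= 1)
  structure(list(name = as.character(name), noise_sigma = noise_sigma,
                 drift_amplitude = drift_amplitude, drift_scale = drift_scale,
                 pose_rotation_max = pose_rotation_max,
                 pose_translation_max = pose_translation_max,
                 sample_fraction = sample_fraction,
                 base_seed = as.integer(base_seed)),
            class = "scanner_profile")
}

#' @export
print.scanner_profile <- function(x, ...) {
  cat(sprintf(
    "scanner_profile '%s': sigma=%.3f mm, drift=%.3f mm (scale %.1f mm), pose %.1f deg / %.1f mm, keep %.0f%% faces, base_seed %d\n",
    x$name, x$noise_sigma, x$drift_amplitude, x$drift_scale,
    x$pose_rotation_max, x$pose_translation_max, 100 * x$sample_fraction,
    x$base_seed))
  invisible(x)
}

#' Default study profiles
#'
#' Three simulated systems — two handheld intraoral-scanner analogues and a
#' noisier extraoral analogue — whose error magnitudes are chosen to yield
#' surface RMS values of a few tens of micrometres, the order observed for
#' commercial scan systems on machined steel models.
#'
#' @param base_seed integer; profile k uses `base_seed + 1000 * k`.
#' @return list of three [scanner_profile()] objects.
#' @export
default_profiles <- function(base_seed = 1L) {
  list(
    scanner_profile("iosA", noise_sigma = 0.025, drift_amplitude = 0.012,
                    drift_scale = 8, pose_rotation_max = 5,
                    pose_translation_max = 2, sample_fraction = 0.9,
                    base_seed = base_seed + 1000L),
    scanner_profile("iosB", noise_sigma = 0.035, drift_amplitude = 0.020,
                    drift_scale = 8, pose_rotation_max = 5,
                    pose_translation_max = 2, sample_fraction = 0.9,
                    base_seed = base_seed + 2000L),
    scanner_profile("labC", noise_sigma = 0.045, drift_amplitude = 0.028,
                    drift_scale = 10, pose_rotation_max = 5,
                    pose_translation_max = 2, sample_fraction = 0.9,
                    base_seed = base_seed + 3000L)
  )
}

# low-order polynomial drift basis on coordinates scaled by the correlation
# length; returns an n x K matrix with roughly unit-RMS columns
.drift_basis <- function(v, scale) {
  ctr <- colMeans(v)
  x <- (v[, 1L] - ctr[1L]) / scale
  y <- (v[, 2L] - ctr[2L]) / scale
  z <- (v[, 3L] - ctr[3L]) / scale
  B <- cbind(1, x, y, z, x * y, x * z, y * z, x^2 - mean(x^2),
             y^2 - mean(y^2), z^2 - mean(z^2))
  rms <- sqrt(colMeans(B^2))
  sweep(B, 2L, ifelse(rms > 0, rms, 1), "/")
}

#' Simulate one scan
#'
#' Deterministic given `(profile$base_seed, replicate)`: the RNG is seeded
#' with `base_seed + replicate`, so re-running yields bitwise-identical
#' output; the caller's RNG state is left untouched.
#'
#' @param reference a [triangle_mesh()] (the gold-standard mesh).
#' @param profile a [scanner_profile()].
#' @param replicate replicate number (>= 0).
#' @return a [triangle_mesh()] simulated scan.
#' @export
simulate_scan <- function(reference, profile, replicate = 0L) {
  stopifnot(inherits(reference, "triangle_mesh"),
            inherits(profile, "scanner_profile"), replicate >= 0)
  .with_seed(profile$base_seed + as.integer(replicate), {
    v <- reference$vertices
    f <- reference$faces
    nrm <- vertex_normals(reference)
    # (1) smooth stitching drift along normals
    if (profile$drift_amplitude > 0) {
      B <- .drift_basis(v, profile$drift_scale)
      coef <- rnorm(ncol(B)) / sqrt(ncol(B))
      v <- v + nrm * (profile$drift_amplitude * as.numeric(B %*% coef))
    }
    # (2) i.i.d. Gaussian depth noise along normals
    if (profile$noise_sigma > 0) {
      v <- v + nrm * rnorm(nrow(v), sd = profile$noise_sigma)
    }
    # (3) random rigid pose
    if (profile$pose_rotation_max > 0 || profile$pose_translation_max > 0) {
      tr <- random_rigid_transform(profile$pose_rotation_max,
                                   profile$pose_translation_max)
      v <- apply_transform(v, tr)
    }
    # (4) random face decimation
    if (profile$sample_fraction < 1) {
      m_keep <- as.integer(round(nrow(f) * profile$sample_fraction))
      if (m_keep < 4L) {
        stop("sample_fraction decimates the mesh below 4 faces")
      }
      f <- f[sort(sample.int(nrow(f), m_keep)), , drop = FALSE]
      used <- sort(unique(as.vector(f)))
      remap <- integer(nrow(v))
      remap[used] <- seq_along(used)
      v <- v[used, , drop = FALSE]
      f <- matrix(remap[f], ncol = 3L)
    }
    triangle_mesh(v, f)
  })
}

#' Simulate a full study
#'
#' `n_replicates` scans for each scanner profile, optionally written to
#' `<out_dir>/<profile name>/scan_###.stl` as binary STL.
#'
#' @param reference a [triangle_mesh()].
#' @param profiles list of [scanner_profile()] objects with distinct names.
#' @param n_replicates replicates per profile (>= 2).
#' @param out_dir optional output directory for STL files.
#' @return named list (one element per profile) of lists of
#'   [triangle_mesh()] scans, invisibly carrying a `files` attribute when
#'   written to disk.
#' @export
simulate_study <- function(reference, profiles, n_replicates, out_dir = NULL) {
  stopifnot(n_replicates >= 2)
  nms <- vapply(profiles, function(p) p$name, character(1L))
  if (anyDuplicated(nms) > 0L) stop("duplicate profile names: ",
                                    paste(nms[duplicated(nms)], collapse = ", "))
  out <- vector("list", length(profiles))
  names(out) <- nms
  files <- character(0L)
  for (i in seq_along(profiles)) {
    scans <- lapply(seq_len(n_replicates), function(k) {
      simulate_scan(reference, profiles[[i]], replicate = k)
    })
    if (!is.null(out_dir)) {
      dir.create(file.path(out_dir, nms[i]), recursive = TRUE,
                 showWarnings = FALSE)
      for (k in seq_len(n_replicates)) {
        path <- file.path(out_dir, nms[i], sprintf("scan_%03d.stl", k))
        write_stl(scans[[k]], path, mode = "binary")
        files <- c(files, path)
      }
    }
    out[[i]] <- scans
  }
  attr(out, "files") <- files
  out
}

#' Read / write scanner profiles as a flat key=value file
#'
#' One profile per file; numeric fields plus `name`.
#'
#' @param profile a [scanner_profile()].
#' @param path file path.
#' @return `read_scanner_profile` returns a [scanner_profile()].
#' @export
write_scanner_profile <- function(profile, path) {
  u <- unclass(profile)
  writeLines(c(sprintf("name=%s", u$name),
               sprintf("%s=%.10g", setdiff(names(u), "name"),
                       as.numeric(u[setdiff(names(u), "name")]))), path)
  invisible(path)
}

#' @rdname write_scanner_profile
#' @export
read_scanner_profile <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "=", fixed = TRUE)
  keys <- vapply(parts, function(p) trimws(p[1L]), character(1L))
  vals <- vapply(parts, function(p) trimws(p[2L]), character(1L))
  args <- as.list(as.numeric(vals[keys != "name"]))
  names(args) <- keys[keys != "name"]
  args$name <- vals[keys == "name"]
  do.call(scanner_profile, args)
}
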