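#' Trueness of a measurement (scaled relative deviation)
#'
#' `(rR - rA) / rR * 1000`: the signed deviation of a measured value from
#' the reference value, relative to the reference and scaled by 10^3
#' (dimensionless). Positive when the scan under-reads the reference.
#'
#' @param reference_value reference (gold standard) value `rR`, nonzero.
#' @param measured_value measured value(s) `rA`; vectorised.
#' @return trueness, dimensionless x 10^3.
#' @examples
#' trueness(8, 7.914)    # 10.75
#' trueness(2, 2.029)    # -14.5
#' @export
trueness <- function(reference_value, measured_value) {
  if (any(reference_value == 0)) stop("reference value must be nonzero")
  (reference_value - measured_value) / reference_value * 1e3
}

#' Precision of replicate measurements (scaled SD)
#'
#' `sd(rA) / rR * 1000`: the sample standard deviation (n-1 denominator) of
#' replicate measurements relative to the reference value, scaled by 10^3.
#'
#' @param reference_value reference value `rR`, nonzero.
#' @param replicate_values numeric vector of replicate measurements
#'   (length >= 2).
#' @return precision, dimensionless x 10^3 (>= 0).
#' @export
precision <- function(reference_value, replicate_values) {
  if (any(reference_value == 0)) stop("reference value must be nonzero")
  if (length(replicate_values) < 2L) stop("need at least 2 replicates")
  stats::sd(replicate_values) / reference_value * 1e3
}

# tie-corrected Kruskal-Wallis H from pooled ranks and group sizes
.kw_h <- function(ranks, grp, n) {
  Rj <- tapply(ranks, grp, sum)
  nj <- tabulate(grp)
  H <- 12 / (n * (n + 1)) * sum(Rj^2 / nj[nj > 0]) - 3 * (n + 1)
  ties <- table(ranks)
  C <- 1 - sum(ties^3 - ties) / (n^3 - n)
  if (C <= 0) return(0)
  H / C
}

#' Kruskal-Wallis rank test
#'
#' Tie-corrected Kruskal-Wallis H with the chi-square approximation
#' (`df = groups - 1`), plus an exact permutation p value (full enumeration
#' of group assignments) when the pooled sample is small.
#'
#' @param groups list of two or more numeric vectors.
#' @param exact_max_n largest pooled size for which the exact permutation p
#'   is also computed (default 10; set 0 to disable).
#' @return list with `H`, `df`, `p_value` (chi-square), `p_exact` (exact
#'   permutation p, or `NA` when not computed) and `n`.
#' @export
kruskal_wallis <- function(groups, exact_max_n = 10L) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  sizes <- lengths(groups)
  if (any(sizes < 1L)) stop("every group needs at least one value")
  x <- unlist(groups, use.names = FALSE)
  n <- length(x)
  if (n < 3L) stop("need at least 3 values in total")
  grp <- rep(seq_along(groups), sizes)
  r <- rank(x)
  H <- .kw_h(r, grp, n)
  df <- length(groups) - 1L
  p <- stats::pchisq(H, df, lower.tail = FALSE)
  if (all(x == x[1L])) {
    H <- 0
    p <- 1
  }
  p_exact <- NA_real_
  if (n <= exact_max_n) {
    perms <- .group_assignments(sizes)
    Hs <- vapply(perms, function(g) .kw_h(r, g, n), numeric(1L))
    p_exact <- mean(Hs >= H - 1e-12)
  }
  list(H = H, df = df, p_value = p, p_exact = p_exact, n = n)
}

# all distinct assignments of n = sum(sizes) items to groups of the given
# sizes (multiset permutations via recursive combinations)
.group_assignments <- function(sizes) {
  n <- sum(sizes)
  build <- function(avail, k) {
    if (k == length(sizes)) {
      g <- integer(n)
      g[avail] <- k
      return(list(g))
    }
    picks <- utils::combn(avail, sizes[k], simplify = FALSE)
    out <- list()
    for (p in picks) {
      rest <- build(setdiff(avail, p), k + 1L)
      out <- c(out, lapply(rest, function(g) {
        g[p] <- k
        g
      }))
    }
    out
  }
  build(seq_len(n), 1L)
}

#' Confidence interval for a mean RMS
#'
#' Student-t confidence interval on the mean of replicate RMS values.
#'
#' @param rms_values numeric vector of per-replicate RMS values (>= 2).
#' @param level confidence level in (0, 1), default 0.95.
#' @return named numeric `c(lower, mean, upper)`.
#' @export
rms_confidence_interval <- function(rms_values, level = 0.95) {
  n <- length(rms_values)
  if (n < 2L) stop("need at least 2 RMS values")
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  m <- mean(rms_values)
  half <- stats::qt(1 - (1 - level) / 2, df = n - 1L) *
    stats::sd(rms_values) / sqrt(n)
  c(lower = m - half, mean = m, upper = m + half)
}

#' Evaluate a full accuracy study
#'
#' Assembles the study report: per system and index, trueness (mean +/- SD
#' of per-replicate values), precision, and the replicate-form index RMS;
#' per system, surface RMS summaries with a t confidence interval; and
#' Kruskal-Wallis comparisons across systems for every index and for the
#' surface RMS. Raw p values are reported (no multiplicity correction) and
#' flagged at both conventional thresholds.
#'
#' @param gold a [gold_standard()] (its `reference_values` are `rR`).
#' @param measurements named list (one element per system) of data frames
#'   with columns `R1, R2, L1, L2, L3, theta`, one row per replicate scan.
#' @param rms_values named list (same names) of numeric vectors of surface
#'   RMS values (mm), one per replicate.
#' @param level confidence level for the RMS interval.
#' @param alpha significance threshold used for the `significant` flag.
#' @return object of class `accuracy_report` with data frames `trueness`,
#'   `precision`, `index_rms`, `surface_rms` and `kruskal_wallis`.
#' @export
evaluate_study <- function(gold, measurements, rms_values, level = 0.95,
                           alpha = 0.05) {
  stopifnot(inherits(gold, "gold_standard"))
  systems <- names(measurements)
  if (is.null(systems) || any(!nzchar(systems))) {
    stop("'measurements' must be a named list (one element per system)")
  }
  if (!setequal(systems, names(rms_values))) {
    stop("system labels of 'measurements' and 'rms_values' differ")
  }
  idx_names <- c("R1", "R2", "L1", "L2", "L3", "theta")
  rR <- gold$reference_values[idx_names]

  rows_tru <- list()
  rows_pre <- list()
  rows_rms <- list()
  for (s in systems) {
    m <- measurements[[s]]
    if (!all(idx_names %in% names(m))) {
      stop("measurements for system '", s, "' lack index columns")
    }
    tru <- vapply(idx_names, function(k) {
      dv <- trueness(rR[[k]], m[[k]])
      c(mean(dv), stats::sd(dv))
    }, numeric(2L))
    pre <- vapply(idx_names, function(k) precision(rR[[k]], m[[k]]),
                  numeric(1L))
    rrm <- vapply(idx_names, function(k) replicate_rms(rR[[k]], m[[k]]),
                  numeric(1L))
    rows_tru[[s]] <- data.frame(system = s, index = idx_names,
                                mean = tru[1L, ], sd = tru[2L, ],
                                n = nrow(m), row.names = NULL)
    rows_pre[[s]] <- data.frame(system = s, index = idx_names,
                                precision = pre, n = nrow(m),
                                row.names = NULL)
    rows_rms[[s]] <- data.frame(system = s, index = idx_names,
                                rms = rrm, n = nrow(m), row.names = NULL)
  }

  surf <- do.call(rbind, lapply(systems, function(s) {
    r <- rms_values[[s]]
    ci <- rms_confidence_interval(r, level)
    data.frame(system = s, n = length(r), mean = mean(r), sd = stats::sd(r),
               ci_lower = ci[["lower"]], ci_upper = ci[["upper"]],
               row.names = NULL)
  }))

  kw <- do.call(rbind, lapply(c(idx_names, "surface_rms"), function(k) {
    if (length(systems) < 2L) {
      return(data.frame(comparison = k, H = NA_real_, df = NA_integer_,
                        p_value = NA_real_, sig_0.05 = NA, sig_0.01 = NA,
                        row.names = NULL))
    }
    gl <- if (k == "surface_rms") rms_values[systems] else
      lapply(measurements[systems], function(m) m[[k]])
    res <- kruskal_wallis(gl)
    data.frame(comparison = k, H = res$H, df = res$df, p_value = res$p_value,
               sig_0.05 = res$p_value < 0.05, sig_0.01 = res$p_value < 0.01,
               row.names = NULL)
  }))

  structure(list(trueness = do.call(rbind, rows_tru),
                 precision = do.call(rbind, rows_pre),
                 index_rms = do.call(rbind, rows_rms),
                 surface_rms = surf,
                 kruskal_wallis = kw,
                 reference_values = rR,
                 alpha = alpha,
                 note = "raw p values; no multiple-testing correction applied"),
            class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat("accuracy_report\n\nTrueness (x10^3, mean +/- SD per system and index):\n")
  tw <- stats::reshape(transform(x$trueness,
                                 cell = sprintf("%.2f +/- %.2f", mean, sd),
                                 mean = NULL, sd = NULL, n = NULL),
                       idvar = "system", timevar = "index",
                       direction = "wide")
  names(tw) <- sub("^cell\\.", "", names(tw))
  print(tw, row.names = FALSE)
  cat("\nPrecision (x10^3):\n")
  pw <- stats::reshape(x$precision[, c("system", "index", "precision")],
                       idvar = "system", timevar = "index",
                       direction = "wide")
  names(pw) <- sub("^precision\\.", "", names(pw))
  print(pw, row.names = FALSE, digits = 4)
  cat("\nSurface RMS (mm):\n")
  print(x$surface_rms, row.names = FALSE, digits = 4)
  cat("\nKruskal-Wallis across systems:\n")
  print(x$kruskal_wallis, row.names = FALSE, digits = 4)
  cat("\nNote:", x$note, "\n")
  invisible(x)
}
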