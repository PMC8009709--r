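test_that("trueness follows the scaled relative-deviation formula", {
  expect_equal(trueness(3.003, 3.003), 0)
  expect_equal(trueness(8, 7.914), 10.75)
  expect_equal(trueness(2, 2.029), -14.5)
  expect_error(trueness(0, 1), "nonzero")
  # scale invariance
  expect_equal(trueness(5 * 2, 4.9 * 2), trueness(5, 4.9))
})

test_that("precision is the scaled replicate SD", {
  expect_equal(precision(3, rep(2.9, 10)), 0)
  # replicate pair constructed to have SD exactly 0.163
  reps <- 3.003 + c(-1, 1) * 0.163 / sqrt(2)
  expect_equal(sd(reps), 0.163)
  expect_equal(precision(3.003, reps), 0.163 / 3.003 * 1e3, tolerance = 1e-12)
  expect_equal(round(precision(3.003, reps), 1), 54.3)
  expect_equal(precision(3.003 * 2, reps * 2), precision(3.003, reps))
  expect_error(precision(3, 2.9), "2 replicates")
})

test_that("kruskal-wallis H and p match the base-R implementation", {
  set.seed(23)
  g <- list(rnorm(8), rnorm(8, 0.5), rnorm(8, 1))
  mine <- kruskal_wallis(g)
  ref <- stats::kruskal.test(unlist(g), rep(1:3, each = 8))
  expect_equal(mine$H, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(mine$df, unname(ref$parameter))
  expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
  # tie correction agrees too
  gt <- list(c(1, 2, 2, 3), c(2, 3, 3, 4), c(4, 4, 5, 5))
  reft <- stats::kruskal.test(unlist(gt), rep(1:3, each = 4))
  expect_equal(kruskal_wallis(gt)$H, unname(reft$statistic),
               tolerance = 1e-12)
})

test_that("exact permutation p is computed for small pooled samples", {
  res <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))
  # fully separated groups: only the 3! block permutations reach max H
  expect_equal(res$p_exact, 6 / choose(9, 3) / choose(6, 3))
  expect_equal(res$H, unname(stats::kruskal.test(
    1:9, rep(1:3, each = 3))$statistic), tolerance = 1e-12)
  # identical data degenerate to H = 0, p = 1
  same <- kruskal_wallis(list(c(1, 1), c(1, 1), c(1, 1)))
  expect_equal(same$H, 0)
  expect_equal(same$p_value, 1)
  # exact p agrees with a Monte-Carlo estimate on a tied case
  g <- list(c(1, 2, 2), c(3, 3, 4), c(5, 5, 6))
  ex <- kruskal_wallis(g)
  set.seed(31)
  x <- unlist(g)
  lab <- rep(1:3, each = 3)
  r <- rank(x)
  hs <- replicate(20000, scanmetry:::.kw_h(r, sample(lab), 9))
  expect_equal(ex$p_exact, mean(hs >= ex$H - 1e-12), tolerance = 0.02)
})

test_that("rms confidence interval matches the closed form", {
  expect_equal(unname(rms_confidence_interval(rep(0.04, 5))),
               c(0.04, 0.04, 0.04))
  ci <- rms_confidence_interval(c(0.03, 0.05))
  half <- qt(0.975, 1) * sd(c(0.03, 0.05)) / sqrt(2)
  expect_equal(unname(ci), c(0.04 - half, 0.04, 0.04 + half))
  # width shrinks as 1/sqrt(n) at fixed SD
  w <- vapply(c(4, 16), function(n) {
    x <- rep(c(0.03, 0.05), n / 2)
    diff(rms_confidence_interval(x)[c(1, 3)])
  }, numeric(1))
  expect_lt(w[2], w[1])
})

test_that("evaluate_study flags nothing for two identical systems", {
  gs <- gold_standard(model_spec(), segments = 48L)
  m <- data.frame(R1 = rnorm(6, 3, 0.01), R2 = rnorm(6, 5, 0.01),
                  L1 = rnorm(6, 2, 0.01), L2 = rnorm(6, 8, 0.01),
                  L3 = rnorm(6, 10, 0.01), theta = rnorm(6, 23, 0.1))
  rep_rms <- runif(6, 0.02, 0.04)
  rep_ <- evaluate_study(gs, list(a = m, b = m),
                         list(a = rep_rms, b = rep_rms))
  expect_true(all(rep_$kruskal_wallis$p_value > 0.99))
  expect_false(any(rep_$kruskal_wallis$sig_0.05))
  a_rows <- rep_$trueness[rep_$trueness$system == "a", -1]
  b_rows <- rep_$trueness[rep_$trueness$system == "b", -1]
  expect_equal(a_rows, b_rows, ignore_attr = TRUE)
  expect_error(evaluate_study(gs, list(a = m), list(b = rep_rms)), "labels")
})

test_that("null-error scans give zero trueness and precision", {
  gs <- gold_standard(model_spec(outer_draft = 0), segments = 128L)
  scans <- lapply(1:2, function(k) {
    simulate_scan(gs$mesh, scanner_profile("null"), k)
  })
  mm <- do.call(rbind, lapply(scans, function(s) {
    as.data.frame(measure_indices(s))
  }))
  rep_ <- evaluate_study(gs, list(null = mm),
                         list(null = c(1e-9, 1e-9)))
  expect_true(all(abs(rep_$trueness$mean) < 1e-4))
  expect_true(all(rep_$precision$precision < 1e-6))
})
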