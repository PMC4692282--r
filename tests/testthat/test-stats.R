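test_that("peak detection recovers sinusoid peaks on the frame grid", {
  tt <- seq(0, 300, by = 3)
  x <- sin(2 * pi * tt / 41)
  pk <- find_peaks(tt, x)
  expect_gt(nrow(pk), 5)
  iv <- diff(pk$time)
  expect_true(all(iv >= 39 & iv <= 42))  # grid quantization of 41 min
  # flat trace has no peaks
  expect_equal(nrow(find_peaks(tt, rep(2, length(tt)))), 0)
})

test_that("smoothing makes detection robust to measurement noise", {
  tt <- seq(0, 300, by = 3)
  clean <- 1 + sin(2 * pi * tt / 41)
  n_clean <- nrow(find_peaks(tt, clean))
  set.seed(301)
  ok <- 0
  for (i in 1:20) {
    noisy <- clean + rnorm(length(tt), sd = 0.1)  # SNR ~ 10
    if (nrow(find_peaks(tt, noisy)) == n_clean) ok <- ok + 1
  }
  expect_gte(ok, 18)
})

test_that("coefficients of variation use the n-1 sample convention", {
  pk <- data.frame(height = c(1, 1, 3, 3),
                   interval = c(NA, 40, 42, 41))
  cv <- amplitude_and_period_cv(pk)
  expect_equal(cv$amplitude_cv, stats::sd(c(1, 1, 3, 3)) / 2)
  expect_equal(round(cv$amplitude_cv, 3), 0.577)
  expect_equal(cv$mean_period, 41)
  expect_error(amplitude_and_period_cv(data.frame(height = 1,
                                                  interval = NA)),
               "at least 2")
})

test_that("all reported statistics are invariant to fluorescence scale", {
  set.seed(302)
  spec <- synthetic_spec("parametric_sine", n_lineages = 3,
                         duration = 120)
  tree <- generate_synthetic(spec)$tree
  s1 <- summary_stats(tree)
  tree2 <- tree
  tree2$frames$fluorescence <- 37.5 * tree2$frames$fluorescence
  s2 <- summary_stats(tree2)
  expect_equal(s2$amplitude_cv, s1$amplitude_cv)
  expect_equal(s2$period_cv, s1$period_cv)
  expect_equal(s2$corr$rho, s1$corr$rho)
})

test_that("sister correlation is 1 for identical and 0 for unrelated twins", {
  set.seed(303)
  identical_pair <- function(k) {
    a <- runif(1, 0.5, 2)
    f <- function(tt) a * (1 + sin(2 * pi * tt / 41))
    list(f, f)
  }
  tree <- caterpillar_tree(20, identical_pair)
  corr <- sister_correlation(tree)
  expect_true(all(abs(corr$rho - 1) < 1e-9))
  expect_true(all(corr$n_pairs == 20))
  set.seed(304)
  noise_pair <- function(k) {
    v1 <- rnorm(10)
    v2 <- rnorm(10)
    list(function(tt) v1[seq_along(tt)], function(tt) v2[seq_along(tt)])
  }
  corr2 <- sister_correlation(caterpillar_tree(60, noise_pair))
  expect_true(all(abs(corr2$rho) < 0.35, na.rm = TRUE))
  expect_lt(mean(abs(corr2$rho)), 0.2)
})

test_that("sister pairs stop contributing once either sister divides", {
  # sisters 2 and 3 divide again at t = 60; frames beyond that belong to
  # the granddaughters, so lags past 30 min have no pairs
  f <- function(t) 1 + sin(2 * pi * t / 41)
  tree <- toy_tree(f, f, t_div = 30, t_end = 60)
  corr <- sister_correlation(tree, max_lag = 45)
  expect_true(all(corr$n_pairs[corr$lag > 30] == 0))
})

test_that("statistic distances follow their closed forms", {
  expect_equal(cv_distance(0.35, 0.47), 0.12)
  lag <- seq(3, 30, by = 3)
  c1 <- structure(data.frame(lag = lag, rho = seq(0.98, 0.5, length = 10),
                             n_pairs = 50),
                  class = c("correlation_function", "data.frame"))
  c2 <- c1
  c2$rho <- c1$rho + 0.1
  expect_equal(corr_distance(c1, c1), 0)
  expect_equal(corr_distance(c2, c1), 0.1 * sqrt(10))
  c3 <- c1
  c3$rho <- NA_real_
  expect_error(corr_distance(c1, c3), "no defined lags")
})

test_that("the KS comparison is calibrated on the null", {
  set.seed(305)
  a <- rnorm(300, 1, 0.47)
  expect_equal(ks_compare(a, a)$statistic, 0)
  pass <- vapply(1:30, function(i)
    ks_compare(rnorm(300, 1, 0.47), rnorm(300, 1, 0.47))$pass, logical(1))
  expect_gte(mean(pass), 0.9)
  # clearly different shapes are flagged
  expect_false(ks_compare(rnorm(400, 1, 0.1),
                          rexp(400))$pass)
})

test_that("pooled and per-lineage variability agree on homogeneous data", {
  set.seed(306)
  spec <- synthetic_spec("parametric_sine", n_lineages = 6,
                         duration = 180)
  pk <- peak_statistics(generate_synthetic(spec)$tree)
  pooled <- amplitude_and_period_cv(pk)$amplitude_cv
  per_lin <- vapply(split(pk, pk$lineage_id), function(d)
    amplitude_and_period_cv(d)$amplitude_cv, numeric(1))
  expect_lt(abs(mean(per_lin) - pooled), 0.1)
})
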