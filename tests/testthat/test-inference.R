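fake_grid <- function(cv_fun, corr_fun, omegas = 1:5 * 10,
                      gammas = seq(0, 0.2, 0.05)) {
  cv <- outer(omegas, gammas, cv_fun)
  co <- outer(omegas, gammas, corr_fun)
  structure(list(omega_values = omegas, gamma_values = gammas,
                 cv_map = cv, corr_map = co, stats = NULL),
            class = "noise_grid")
}

test_that("minimizing contours find exact and refined minima", {
  # quadratic valleys whose floors are straight interior lines; quadratic
  # refinement recovers the off-grid vertex exactly
  g <- fake_grid(function(o, g) (g - (0.05 + 0.001 * o))^2,
                 function(o, g) (g - (0.15 - 0.001 * o))^2)
  ct <- min_contours(g)
  expect_equal(ct$cv_contour$gamma, 0.05 + 0.001 * g$omega_values,
               tolerance = 1e-6)
  expect_equal(ct$corr_contour$gamma, 0.15 - 0.001 * g$omega_values,
               tolerance = 1e-6)
})

test_that("ties take the smallest gamma", {
  g <- fake_grid(function(o, g) rep(1, length(g)),
                 function(o, g) rep(1, length(g)))
  ct <- min_contours(g)
  expect_true(all(ct$cv_contour$gamma == 0))
})

test_that("straight crossing contours intersect where they should", {
  ct <- list(
    cv_contour = data.frame(omega = 1:3, gamma = c(0.2, 0.1, 0.0),
                            value = 0),
    corr_contour = data.frame(omega = 1:3, gamma = c(0.0, 0.1, 0.2),
                              value = 0)
  )
  est <- intersect_contours(ct)
  expect_true(est$intersects)
  expect_equal(est$omega_hat, 2)
  expect_equal(est$gamma_hat, 0.1)
  # parallel contours never intersect
  ct2 <- list(
    cv_contour = data.frame(omega = 1:3, gamma = c(0.3, 0.3, 0.3),
                            value = 0),
    corr_contour = data.frame(omega = 1:3, gamma = c(0.0, 0.0, 0.0),
                              value = 0)
  )
  est2 <- intersect_contours(ct2, gamma_resolution = 0.05)
  expect_false(est2$intersects)
  expect_true(is.na(est2$omega_hat))
})

test_that("the scan recovers the truth from toy reference data", {
  set.seed(501)
  truth_om <- 150
  truth_ga <- 0.15
  make <- function(om, ga, n) {
    pool_trees(lapply(seq_len(n), function(i)
      toy_lineage(toy_params(omega = om, gamma_ext = ga),
                  n_generations = 6, lineage_id = i)))
  }
  reference <- summary_stats(make(truth_om, truth_ga, 25))
  sim_fn <- function(om, ga) summary_stats(make(om, ga, 10))
  grid <- scan_grid(reference, sim_fn, c(50, 150, 450),
                    c(0.05, 0.15, 0.25), base_seed = 77)
  # both maps attain their minimum at (or adjacent to) the truth
  cv_best <- which(grid$cv_map == min(grid$cv_map), arr.ind = TRUE)
  corr_best <- which(grid$corr_map == min(grid$corr_map), arr.ind = TRUE)
  expect_equal(unname(cv_best[1, 2]), 2)    # gamma identified by cv map
  expect_equal(unname(corr_best[1, 1]), 2)  # omega identified by corr map
  # sensitivity asymmetry on the raw statistics: the amplitude CV
  # responds relatively more to gamma than to omega, the correlation
  # function relatively more to omega than to gamma
  s <- grid$stats
  amp_d_om <- abs(s[[3, 2]]$amplitude_cv - s[[1, 2]]$amplitude_cv)
  amp_d_ga <- abs(s[[2, 3]]$amplitude_cv - s[[2, 1]]$amplitude_cv)
  corr_d_om <- corr_distance(s[[3, 2]]$corr, s[[1, 2]]$corr)
  corr_d_ga <- corr_distance(s[[2, 3]]$corr, s[[2, 1]]$corr)
  expect_gt(amp_d_ga / amp_d_om, corr_d_ga / corr_d_om)
})
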