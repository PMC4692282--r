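test_that("only basal production fires from an empty cell", {
  sys <- build_reactions(oscillator_params(), omega = 1)
  expect_length(sys$reactions, 8)
  counts <- c(r = 0, a = 0, g = 0, G = 0)
  a <- vapply(sys$reactions, function(r) r$propensity(counts, 1),
              numeric(1))
  p1 <- sys$params
  basal <- hill_activity(0, 0, p1$f, p1$C_a, p1$C_r) *
    c(p1$alpha_r, p1$alpha_a, p1$alpha_g)
  expect_equal(unname(a[1:3]), unname(basal))
  expect_equal(unname(a[4:8]), rep(0, 5))
  # delayed reactions carry the transcriptional delays
  expect_equal(vapply(sys$reactions, `[[`, numeric(1), "delay"),
               c(p1$tau_r, p1$tau_a, p1$tau_g, 0, 0, 0, 0, 0))
})

test_that("doubling omega doubles molecule numbers", {
  p <- oscillator_params()
  set.seed(101)
  mean_fluor <- vapply(c(1, 2), function(om) {
    m <- 0
    for (s in 1:15) {
      tr <- simulate_cell(p, omega = om, t_end = 300)
      m <- m + mean(tr$fluorescence[tr$time >= 60])
    }
    m / 15
  }, numeric(1))
  expect_equal(mean_fluor[2] / mean_fluor[1], 2, tolerance = 0.15)
})

test_that("a pure death process decays monotonically in expectation", {
  p <- oscillator_params(alpha = 0, gamma_r = 0, gamma_a = 0,
                         gamma_g = 0, gamma_G = 0)
  set.seed(102)
  m <- 0
  for (s in 1:20) {
    tr <- simulate_cell(p, omega = 1, t_end = 60,
                        init_counts = c(0L, 0L, 0L, 200L))
    m <- m + tr$fluorescence
  }
  m <- m / 20
  # only dilution remains once production and proteolysis are off
  expect_equal(m[1], 200 * exp(-p$beta * 3), tolerance = 0.05)
  expect_true(all(diff(m) <= 1e-9))
})

test_that("with zero delay and frozen activity the count is Poisson", {
  # one species, constant birth rate b, first-order death d: stationary
  # distribution is Poisson(b / d)
  b <- 40
  d <- 2
  rx <- list(
    list(propensity = function(n, V = 1, t = 0) b, delta = c(x = 1),
         delay = 0),
    list(propensity = function(n, V = 1, t = 0) d * n[1],
         delta = c(x = -1), delay = 0)
  )
  set.seed(103)
  draws <- vapply(1:400, function(i)
    simulate_reactions(rx, c(x = 20), t_end = 6)$counts, numeric(1))
  expect_equal(mean(draws), b / d, tolerance = 0.05)
  expect_equal(var(draws), b / d, tolerance = 0.2)
  # chi-square goodness of fit against the Poisson pmf
  ks <- suppressWarnings(
    stats::chisq.test(table(cut(draws, c(-1, 14, 17, 20, 23, 26, Inf))),
                      p = diff(stats::ppois(c(-1, 14, 17, 20, 23, 26, Inf),
                                            b / d))))
  expect_gt(ks$p.value, 0.01)
})

test_that("delayed completions appear exactly one delay after initiation", {
  # single delayed production from an empty system with frozen rate:
  # counts at time t equal initiations completed by t - tau, so the count
  # trace is a Poisson process shifted by the delay
  b <- 5
  tau <- 4
  rx <- list(list(propensity = function(n, V = 1, t = 0) b,
                  delta = c(x = 1), delay = tau))
  set.seed(104)
  res <- simulate_reactions(rx, c(x = 0), t_end = 10,
                            record_times = c(2, 3.9, 6, 10))
  # nothing can complete before tau
  expect_equal(res$states[1:2, "x"], c(2, 3.9)*0)
  draws <- vapply(1:200, function(i)
    simulate_reactions(rx, c(x = 0), t_end = 10,
                       record_times = 10)$states[1, "x"], numeric(1))
  expect_equal(mean(draws), b * (10 - tau), tolerance = 0.1)
})

test_that("the compiled kernel and the reference SSA agree in distribution", {
  p <- oscillator_params()
  om <- 0.6
  init <- as.integer(round(limit_cycle_state(p) * om))
  set.seed(105)
  fast <- vapply(1:150, function(i) {
    tr <- simulate_cell(p, omega = om, t_end = 21, init_counts = init)
    tr$fluorescence[7]
  }, numeric(1))
  sys <- build_reactions(p, omega = om)
  slow <- vapply(1:150, function(i) {
    r <- simulate_reactions(sys$reactions,
                            stats::setNames(init, c("r", "a", "g", "G")),
                            t_end = 21, record_times = 21)
    r$states[1, "G"]
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(fast, slow))
  expect_gt(ks$p.value, 0.01)
})

test_that("amplitude variability decreases with the noise scale", {
  set.seed(106)
  tab <- amplitude_cv_vs_omega(c(1, 4), n_sims = 30, t_end = 360)
  expect_lt(tab$amplitude_cv[2], tab$amplitude_cv[1])
  expect_true(all(tab$n_peaks > 20))
})
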