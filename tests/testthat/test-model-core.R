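test_that("zero production and empty history give the zero solution", {
  p <- oscillator_params(alpha = 0)
  traj <- integrate_dde(p, history = c(0, 0, 0, 0), t_end = 50)
  expect_true(all(as.matrix(traj[-1]) == 0))
})

test_that("the fitted parameter set oscillates with a 41-minute period", {
  traj <- integrate_dde(oscillator_params(), t_end = 600)
  expect_true(all(as.matrix(traj[-1]) >= 0))
  per <- oscillation_period(traj)
  expect_gt(per, 39)
  expect_lt(per, 43)
})

test_that("halving the step changes the solution below solver tolerance", {
  # pointwise self-convergence over one cycle; over many cycles the
  # truncation error is amplified through the near-extinct troughs, so
  # the long-run check is on the period
  p <- oscillator_params()
  a <- integrate_dde(p, t_end = 60, dt = 0.005, record_every = 100L)
  b <- integrate_dde(p, t_end = 60, dt = 0.0025, record_every = 200L)
  expect_equal(a$time, b$time)
  expect_lt(max(abs(a$G - b$G)) / max(a$G), 1e-6)
  pa <- oscillation_period(integrate_dde(p, t_end = 500, dt = 0.005))
  pb <- oscillation_period(integrate_dde(p, t_end = 500, dt = 0.0025))
  expect_equal(pa, pb, tolerance = 2e-3)
})

test_that("omega rescaling leaves concentration dynamics invariant", {
  p <- oscillator_params()
  h <- c(r = 0, a = 10, g = 0, G = 0)
  # pointwise over one cycle: the two solutions are the same numbers up to
  # rounding (longer horizons amplify rounding through the near-extinct
  # troughs, where the flow is locally expanding)
  base <- integrate_dde(p, history = h, t_end = 60)
  for (om in c(0.5, 2.5, 3)) {
    sc <- integrate_dde(rescale_params(p, om), history = om * h,
                        t_end = 60)
    expect_lt(max(abs(sc$G - om * base$G)) / max(om * base$G), 1e-9)
    expect_lt(max(abs(sc$r - om * base$r)) / max(om * base$r), 1e-9)
  }
  # over many cycles the invariant quantity is the limit cycle itself:
  # period and amplitude agree to solver tolerance
  long_base <- integrate_dde(p, history = h, t_end = 400)
  long_sc <- integrate_dde(rescale_params(p, 3), history = 3 * h,
                           t_end = 400)
  expect_equal(oscillation_period(long_sc),
               oscillation_period(long_base), tolerance = 5e-3)
  expect_equal(max(long_sc$G[long_sc$time > 250]) / 3,
               max(long_base$G[long_base$time > 250]), tolerance = 1e-2)
})

test_that("perturbed histories relax to the same limit cycle period", {
  p <- oscillator_params()
  per <- vapply(list(c(0, 10, 0, 0), c(1, 14, 2, 1), c(0, 6, 0, 3)),
                function(h) oscillation_period(
                  integrate_dde(p, history = h, t_end = 600)),
                numeric(1))
  expect_lt(diff(range(per)) / mean(per), 0.01)
})

test_that("oscillation segments are normalized and averaged as specified", {
  tt <- seq(-40, 40, by = 1)
  seg <- data.frame(time = tt + 40, value = 3 + 2 * cos(2 * pi * tt / 41))
  # single segment: peak-centered min-max normalization to [0, 1]
  one <- normalize_and_average(list(seg))
  expect_equal(one$time, seq(-33, 33, by = 3))
  expect_equal(max(one$value), 1)
  expect_equal(min(one$value), 0)
  expect_equal(one$value[one$time == 0], 1)
  # two identical copies average to the same curve
  expect_equal(normalize_and_average(list(seg, seg)), one)
  # affine rescaling of the fluorescence leaves the result unchanged
  seg2 <- transform(seg, value = 5 * value + 2)
  expect_equal(normalize_and_average(list(seg2)), one)
  flat <- transform(seg, value = 1)
  expect_error(normalize_and_average(list(flat)), "degenerate")
})

test_that("the fit error is zero at self and scores period mismatch", {
  p <- oscillator_params()
  traj <- integrate_dde(p, t_end = 500)
  per <- oscillation_period(traj)
  seg <- oscnoise:::model_peak_segment(traj)
  G_ref <- normalize_and_average(list(seg))
  e_self <- fit_error(p, G_ref, per)
  expect_lt(e_self, 0.05)
  # a pure period error of a factor 2 contributes (mu - 2 mu)^2 / mu^2 = 1
  e_wrong_per <- fit_error(p, G_ref, per / 2)
  expect_equal(e_wrong_per - e_self, 1, tolerance = 0.05)
})

test_that("gradient descent recovers perturbed parameters", {
  p <- oscillator_params()
  traj <- integrate_dde(p, t_end = 500)
  per <- oscillation_period(traj)
  G_ref <- normalize_and_average(list(oscnoise:::model_peak_segment(traj)))
  # an empty free set returns the starting point with its error
  f0 <- fit_parameters(G_ref, per, p0 = p, free = character(0))
  expect_equal(f0$params, p)
  p0 <- p
  p0$C_r <- p$C_r * 1.2
  p0$alpha <- p$alpha * 1.2
  p0$alpha_r <- 25 * p0$alpha / 4
  p0$alpha_a <- 30 * p0$alpha
  p0$alpha_g <- 60 * p0$alpha
  fit <- fit_parameters(G_ref, per, p0 = p0, free = c("alpha", "C_r"),
                        max_iter = 40)
  expect_lt(fit$error, fit_error(p0, G_ref, per))
  expect_lt(abs(fit$params$C_r - p$C_r) / p$C_r, 0.1)
  expect_lt(abs(fit$params$alpha - p$alpha) / p$alpha, 0.1)
  expect_equal(fit$period, per, tolerance = 0.03)
})
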