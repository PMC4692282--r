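test_that("growth-rate sampling reproduces the measured distribution", {
  cc <- cell_cycle_params()
  expect_equal(sample_growth_rate(cell_cycle_params(Gamma_beta = 0), 5),
               rep(cc$beta0, 5))
  set.seed(201)
  b <- sample_growth_rate(cc, 1e4)
  expect_equal(mean(b), 0.0295, tolerance = 0.01)
  expect_equal(stats::sd(b) / mean(b), 0.099, tolerance = 0.05)
  # symmetry about beta0
  expect_lt(abs(mean(b > cc$beta0) - 0.5), 0.02)
})

test_that("division volumes follow the shifted gamma law", {
  cc <- cell_cycle_params()
  expect_equal(sample_division_volume(cell_cycle_params(k = 0), 3),
               rep(4.5, 3))
  set.seed(202)
  v <- sample_division_volume(cc, 1e4)
  expect_true(all(v > cc$V_base))
  expect_equal(mean(v), cc$V_base + cc$k * cc$theta, tolerance = 0.02)
  expect_equal(mean(v), 7, tolerance = 0.02)
})

test_that("division conserves molecules and the delay queue", {
  cc <- cell_cycle_params()
  noise <- noise_params()
  means <- c(100, 200, 300)
  set.seed(203)
  for (i in 1:25) {
    cell <- list(counts = as.integer(rpois(4, c(40, 150, 300, 500))),
                 queue_time = sort(runif(rpois(1, 20), 100, 106)),
                 V = 7.2, V_max = 7.2,
                 alphas = means * runif(3, 0.8, 1.2))
    cell$queue_species <- sample(0:2, length(cell$queue_time),
                                 replace = TRUE)
    d <- divide(cell, noise, cc, means)
    expect_equal(d[[1]]$counts + d[[2]]$counts, cell$counts)
    expect_equal(sort(c(d[[1]]$queue_time, d[[2]]$queue_time)),
                 cell$queue_time)
    expect_equal(d[[1]]$V, 3.6)
    expect_equal(d[[2]]$V, 3.6)
    # sister rates satisfy the mean constraint exactly
    q <- noise$q
    m <- q * cell$alphas + (1 - q) * means
    expect_equal((d[[1]]$alphas + d[[2]]$alphas) / 2, m)
  }
  expect_error(divide(list(counts = c(1L, 1L, 1L, 1L),
                           queue_time = numeric(0),
                           queue_species = integer(0), V = 5, V_max = 7,
                           alphas = means),
                      noise, cc, means), "below V_max")
})

test_that("deterministic limits of the rate resampling rule hold", {
  means <- c(10, 20, 30)
  cell <- list(counts = c(10L, 10L, 10L, 10L), queue_time = numeric(0),
               queue_species = integer(0), V = 7, V_max = 7,
               alphas = c(14, 18, 33))
  cc <- cell_cycle_params()
  # no variability: both daughters get exactly the reverted mean
  d <- divide(cell, noise_params(1, 0, 0.6), cc, means)
  expect_equal(d[[1]]$alphas, 0.6 * cell$alphas + 0.4 * means)
  expect_equal(d[[2]]$alphas, d[[1]]$alphas)
  # full memory: exactly the mother's rates
  d2 <- divide(cell, noise_params(1, 0, 1), cc, means)
  expect_equal(d2[[1]]$alphas, cell$alphas)
})

test_that("the rate recursion reaches its analytic stationary law", {
  gam <- 0.12
  q <- exp(-log(2) / 5)
  mu <- 50
  set.seed(204)
  p <- mu
  n <- 1e5
  out <- numeric(n)
  for (i in seq_len(n)) {
    p <- (q * p + (1 - q) * mu) * (1 + gam * rnorm(1))
    out[i] <- p
  }
  out <- out[-(1:100)]
  expect_equal(mean(out), mu, tolerance = 0.02)
  expect_equal(stats::sd(out) / mean(out), stationary_rate_cv(gam, q),
               tolerance = 0.05)
  # the burn-in sampler draws from the same law
  draws <- replicate(4000, stationary_rate(mu, gam, q))
  expect_equal(mean(draws), mu, tolerance = 0.02)
  expect_equal(stats::sd(draws) / mean(draws), stationary_rate_cv(gam, q),
               tolerance = 0.1)
})

test_that("a one-generation lineage is a progenitor with two daughters", {
  set.seed(205)
  tree <- simulate_lineage(oscillator_params(), noise_params(0.5, 0),
                           cell_cycle_params(), n_generations = 1)
  expect_s3_class(tree, "lineage_tree")
  expect_equal(nrow(tree$cells), 3)
  expect_equal(sum(is.na(tree$cells$parent_id)), 1)
  expect_setequal(tree$cells$parent_id[!is.na(tree$cells$parent_id)], 1)
  # daughters born when the mother divides
  expect_equal(tree$cells$birth_time[2:3],
               rep(tree$cells$division_time[1], 2))
  validate_lineage_tree(tree)
})

test_that("sister pairs are strongly correlated right after division", {
  set.seed(206)
  tree <- simulate_lineages(6, params = oscillator_params(),
                            noise = noise_params(2.1, 0.12),
                            cc = cell_cycle_params(), n_generations = 5)
  corr <- sister_correlation(tree)
  expect_gt(corr$rho[1], 0.9)
  # correlations decay with time since division
  expect_gt(corr$rho[1], corr$rho[8])
})

test_that("tree validation catches broken structures", {
  cells <- data.frame(lineage_id = 1, cell_id = 1:3,
                      parent_id = c(NA, 1, 9), birth_time = c(0, 30, 30),
                      division_time = c(30, 60, 60))
  frames <- data.frame(lineage_id = 1, cell_id = 1, time = c(3, 6),
                       fluorescence = c(1, 2))
  expect_error(lineage_tree(cells, frames), "orphan parent id\\(s\\) 9")
  cells2 <- transform(cells, parent_id = c(NA, 1, 1),
                      birth_time = c(0, 30, 31))
  expect_error(lineage_tree(cells2, frames), "birth times")
})
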