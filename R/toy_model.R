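#' Parameters of the amplitude-phase toy oscillator
#'
#' A minimal stochastic oscillator in polar coordinates used to validate
#' the noise-inference method end to end: the amplitude `r` relaxes to its
#' set point `r0` at rate `rho` and diffuses with intensity `1/sqrt(Omega)`,
#' while the phase advances at `2 pi / T` (corrected by `r0 / r`) with
#' diffusion `1/(r sqrt(Omega))`.  Extrinsic noise enters as division-time
#' resampling of the set point `r0` with CV `gamma_ext` and memory `q`,
#' exactly as for the production rates of the full model.
#'
#' @param r0_mean Mean amplitude set point, AU (arbitrary; CVs and
#'   correlations do not depend on it).
#' @param rho Relaxation rate of the amplitude (limit-cycle stability),
#'   min^-1.
#' @param period Oscillation period `T`, min.
#' @param omega Intrinsic-noise scale (> 0); at `gamma_ext = 0` the
#'   stationary amplitude variance is `1 / (2 rho omega)`.
#' @param gamma_ext Per-division CV of `r0`.
#' @param q Memory of the `r0` recursion in `[0, 1]`.
#' @param division_interval Time between divisions, min; default
#'   `ln 2 / 0.0295` (the mean generation time implied by the measured
#'   growth rate).
#' @return Object of class `toy_params`.
#' @export
toy_params <- function(r0_mean = 1, rho = 0.1, period = 41, omega = 200,
                       gamma_ext = 0.15, q = exp(-log(2) / 5),
                       division_interval = log(2) / 0.0295) {
  stopifnot(r0_mean > 0, rho > 0, period > 0, omega > 0, gamma_ext >= 0,
            q >= 0, q <= 1, division_interval > 0)
  structure(list(r0_mean = r0_mean, rho = rho, period = period,
                 omega = omega, gamma_ext = gamma_ext, q = q,
                 division_interval = division_interval),
            class = "toy_params")
}

#' Euler-Maruyama simulation of the toy oscillator
#'
#' Integrates the amplitude-phase equations with independent Wiener
#' increments for `r` and `theta` and a reflecting floor
#' `r >= 0.05 r0_mean` (the phase drift is singular at `r = 0`).  The
#' observable is `x(t) = r cos(theta)` sampled on the 3-min frame grid.
#'
#' @param params A [toy_params()] object.
#' @param t_end Duration, min.
#' @param dt Euler-Maruyama step, min (must satisfy `dt <= 0.01 period`
#'   for the convergence checks to hold).
#' @param r_init,theta_init Initial state; default starts on the set point.
#' @param r0 Set point used for this realization; default `r0_mean`.
#' @param frame_dt Frame spacing, min.
#' @return Data frame `(time, x)`; attributes `final` (list with `r`,
#'   `theta`) and `floor_frac` (fraction of steps at the floor; a warning
#'   is raised above 1%).
#' @export
em_simulate <- function(params, t_end = 480, dt = 0.05, r_init = NULL,
                        theta_init = 0, r0 = NULL, frame_dt = 3) {
  stopifnot(inherits(params, "toy_params"))
  if (dt > 0.01 * params$period)
    stop("dt must be at most 1% of the period")
  if (is.null(r0)) r0 <- params$r0_mean
  if (is.null(r_init)) r_init <- r0
  frames <- seq(frame_dt, t_end, by = frame_dt)
  res <- toy_sim_cpp(r_init, theta_init, r0, params$rho, params$period,
                     params$omega, 0.05 * params$r0_mean, 0, t_end, dt,
                     frames)
  if (res$floor_frac > 0.01)
    warning(sprintf(
      "amplitude at the reflecting floor for %.1f%% of steps; intrinsic noise too large for the amplitude-phase approximation",
      100 * res$floor_frac))
  out <- data.frame(time = frames, x = res$x)
  attr(out, "final") <- list(r = res$r, theta = res$theta)
  attr(out, "floor_frac") <- res$floor_frac
  out
}

#' Lineage simulation of the toy oscillator
#'
#' Binary-tree version of [em_simulate()]: cells divide every
#' `division_interval` minutes; both daughters start from the mother's
#' exact `(r, theta)` (all sister divergence comes from `r0` resampling
#' and subsequent intrinsic noise), and each daughter's set point `r0` is
#' resampled by the division-time recursion with the sister-mean
#' constraint ([sister_rates()]).  The progenitor's `r0` is drawn from the
#' stationary law of the recursion.  Produces the same lineage-tree schema
#' as the full model, so all downstream statistics apply unchanged.
#'
#' @param params A [toy_params()] object.
#' @param n_generations Division rounds per branch.
#' @param dt Euler-Maruyama step, min.
#' @param frame_dt Frame spacing, min.
#' @param lineage_id Identifier stored in the output.
#' @return A [lineage_tree()] whose `fluorescence` column holds
#'   `x = r cos(theta)`.
#' @export
toy_lineage <- function(params, n_generations = 7, dt = 0.05, frame_dt = 3,
                        lineage_id = 1L) {
  stopifnot(inherits(params, "toy_params"))
  Td <- params$division_interval
  r0_prog <- stationary_rate(params$r0_mean, params$gamma_ext, params$q)
  stack <- list(list(r = r0_prog, theta = 0, r0 = r0_prog, id = 1L,
                     parent = NA_integer_, birth = 0, gen = 0L))
  horizon <- (n_generations + 1) * Td
  all_frames <- seq(frame_dt, by = frame_dt,
                    length.out = ceiling(horizon / frame_dt))
  cells <- list()
  frames <- list()
  while (length(stack)) {
    item <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    t_div <- item$birth + Td
    fr <- all_frames[all_frames > item$birth + 1e-9 &
                       all_frames <= t_div + 1e-9]
    res <- toy_sim_cpp(item$r, item$theta, item$r0, params$rho,
                       params$period, params$omega,
                       0.05 * params$r0_mean, item$birth, t_div, dt, fr)
    k <- length(cells) + 1L
    cells[[k]] <- data.frame(lineage_id = lineage_id, cell_id = item$id,
                             parent_id = item$parent,
                             birth_time = item$birth,
                             division_time = t_div)
    if (length(fr))
      frames[[k]] <- data.frame(lineage_id = lineage_id,
                                cell_id = item$id, time = fr,
                                fluorescence = res$x)
    if (item$gen < n_generations) {
      r0d <- sister_rates(item$r0, params$r0_mean, params$gamma_ext,
                          params$q)
      for (j in 1:2)
        stack[[length(stack) + 1]] <-
          list(r = res$r, theta = res$theta, r0 = r0d[j],
               id = 2L * item$id + (j - 1L), parent = item$id,
               birth = t_div, gen = item$gen + 1L)
    }
  }
  lineage_tree(do.call(rbind, cells),
               do.call(rbind, frames[!vapply(frames, is.null, logical(1))]),
               frame_dt = frame_dt)
}

#' In-silico recovery experiment for the noise-inference method
#'
#' Generates toy-oscillator lineage data at known noise levels
#' (`true_omega`, `true_gamma`), treats its summary statistics as the
#' "experimental" reference, scans toy simulations over an
#' `(omega, gamma)` grid, and estimates the noise levels by intersecting
#' the minimizing contours of the amplitude-CV distance and the
#' correlation distance.  Recovering the truth validates the entire
#' inference stack without any external data.
#'
#' @param true_omega,true_gamma Ground-truth noise levels.
#' @param omega_values,gamma_values Scan grid (should bracket the truth).
#' @param params Baseline [toy_params()] (noise fields are overridden).
#' @param n_lineages_ref,n_generations_ref Budget for the reference data.
#' @param n_lineages,n_generations Budget per grid cell.
#' @param q Memory used in both reference and scan.
#' @return A `noise_estimate` (see [intersect_contours()]) with the scan
#'   grid attached as attribute `grid` and the reference statistics as
#'   `reference`.
#' @export
toy_recovery_experiment <- function(true_omega = 200, true_gamma = 0.15,
                                    omega_values = c(50, 100, 150, 200,
                                                     300, 450),
                                    gamma_values = c(0.05, 0.1, 0.15,
                                                     0.2, 0.25),
                                    params = toy_params(),
                                    n_lineages_ref = 40,
                                    n_generations_ref = 7,
                                    n_lineages = 15, n_generations = 7) {
  pref <- params
  pref$omega <- true_omega
  pref$gamma_ext <- true_gamma
  ref_tree <- do.call(rbind_trees, lapply(seq_len(n_lineages_ref),
    function(i) toy_lineage(pref, n_generations_ref, lineage_id = i)))
  reference <- summary_stats(ref_tree)
  sim_fn <- function(omega, gamma) {
    pp <- params
    pp$omega <- omega
    pp$gamma_ext <- gamma
    tr <- do.call(rbind_trees, lapply(seq_len(n_lineages),
      function(i) toy_lineage(pp, n_generations, lineage_id = i)))
    summary_stats(tr)
  }
  grid <- scan_grid(reference, sim_fn, omega_values, gamma_values)
  est <- intersect_contours(min_contours(grid))
  attr(est, "grid") <- grid
  attr(est, "reference") <- reference
  est
}

# internal: pool lineage trees (sharing one frame grid)
rbind_trees <- function(...) {
  trees <- list(...)
  lineage_tree(do.call(rbind, lapply(trees, `[[`, "cells")),
               do.call(rbind, lapply(trees, `[[`, "frames")),
               frame_dt = trees[[1]]$frame_dt)
}
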