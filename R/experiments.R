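#' Find the repression threshold giving a target oscillation period
#'
#' Bisection on `C_r` (the LacI concentration needed for half-maximal
#' repression; lowering IPTG lowers `C_r`) until the mean oscillation
#' period of stochastic lineage simulations matches `target_period`.  All
#' other parameters, including the noise levels, are held fixed.  The
#' period is measured on lineage simulations rather than the deterministic
#' model because below `C_r` of about 2.3 the deterministic model loses
#' strict periodicity (quasiperiodic intervals around 33-35 min) while the
#' stochastic mean period continues to decrease smoothly through the
#' 29-min regime observed without IPTG.
#'
#' @param target_period Target mean period, min.
#' @param params Baseline [oscillator_params()].
#' @param noise,cc Noise and cell-cycle parameters used for the period
#'   measurement.
#' @param lower,upper Bisection bracket for `C_r`.
#' @param n_lineages,n_generations Simulation budget per period evaluation.
#' @param tol Stop when the measured period is within `tol` min of target.
#' @param max_iter Maximum bisection steps.
#' @return List with `C_r`, `period`, `params` (the modified set).
#' @export
find_cr_for_period <- function(target_period = 29,
                               params = oscillator_params(),
                               noise = noise_params(),
                               cc = cell_cycle_params(),
                               lower = 0.4, upper = NULL,
                               n_lineages = 10, n_generations = 6,
                               tol = 0.5, max_iter = 12) {
  if (is.null(upper)) upper <- params$C_r
  measure <- function(cr) {
    p <- params
    p$C_r <- cr
    tree <- simulate_lineages(n_lineages, params = p, noise = noise,
                              cc = cc, n_generations = n_generations)
    cv <- amplitude_and_period_cv(peak_statistics(tree))
    cv$mean_period
  }
  lo <- lower
  hi <- upper
  per <- NA_real_
  mid <- (lo + hi) / 2
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    per <- measure(mid)
    if (is.na(per)) stop("no oscillation detected at C_r = ", mid)
    if (abs(per - target_period) <= tol) break
    if (per > target_period) hi <- mid else lo <- mid
  }
  p <- params
  p$C_r <- mid
  list(C_r = mid, period = per, params = p)
}

#' Run a named simulation experiment
#'
#' Reproducible workflows tying the modules together; each experiment
#' corresponds to one of the package's headline analyses.  Given the same
#' `seed` and configuration the outputs are identical.  Budgets default to
#' desk scale (a few minutes each); `full = TRUE` restores
#' publication-scale budgets (hours).
#'
#' Available experiments:
#' \describe{
#'   \item{`single_cell_cv`}{amplitude/period CV of constant-volume
#'     single-cell simulations across intrinsic-noise scales, with the
#'     `c / omega` fit.}
#'   \item{`lineage_cv`}{lineage simulations without parameter variability
#'     at `omega` 0.5 and 1.0: amplitude/period CVs and sister
#'     correlations.}
#'   \item{`noise_scan`}{grid scan of `(omega, gamma)` against a reference
#'     dataset (synthetic full-model data at the fitted noise levels
#'     unless `reference` is supplied) and contour-intersection estimate.}
#'   \item{`fitted_validation`}{lineage simulation at the fitted noise
#'     levels; summary statistics and KS comparison of amplitude
#'     distributions against the reference.}
#'   \item{`iptg_prediction`}{lower `C_r` until the period is 29 min
#'     (0 mM IPTG), then simulate at the fitted noise levels and report
#'     the predicted statistics.}
#'   \item{`memory_ablation`}{the `noise_scan` with lineage memory removed
#'     (`q = 0`); the minimizing contours are expected not to intersect.}
#'   \item{`toy_recovery`}{in-silico validation of the inference method on
#'     the toy oscillator ([toy_recovery_experiment()]).}
#' }
#'
#' @param name Experiment name (see above).
#' @param seed Integer RNG seed; recorded in the manifest.
#' @param out_dir Optional directory; results are written as CSV/JSON plus
#'   a `manifest.json` capturing name, seed, budgets and package version.
#' @param full Use publication-scale budgets.
#' @param reference Optional [summary_stats()] used by the scan /
#'   validation experiments instead of the synthetic reference.
#' @param params,noise,cc Model configuration.
#' @return A list of experiment-specific results (also serialized if
#'   `out_dir` is given).
#' @export
run_experiment <- function(name = c("single_cell_cv", "lineage_cv",
                                    "noise_scan", "fitted_validation",
                                    "iptg_prediction", "memory_ablation",
                                    "toy_recovery"),
                           seed = 1, out_dir = NULL, full = FALSE,
                           reference = NULL,
                           params = oscillator_params(),
                           noise = noise_params(),
                           cc = cell_cycle_params()) {
  name <- match.arg(name)
  set.seed(seed)
  n_lin <- if (full) 200 else 30
  n_gen <- if (full) 8 else 6
  res <- switch(
    name,
    single_cell_cv = {
      tab <- amplitude_cv_vs_omega(c(0.9, 1.5, 2, 3, 4),
                                   n_sims = if (full) 500 else 100,
                                   t_end = 480, params = params)
      list(table = tab, c_fit = attr(tab, "c_fit"))
    },
    lineage_cv = {
      out <- lapply(c(0.5, 1), function(om) {
        tree <- simulate_lineages(n_lin, params = params,
                                  noise = noise_params(om, 0, noise$q),
                                  cc = cc, n_generations = n_gen)
        summary_stats(tree)
      })
      names(out) <- c("omega_0.5", "omega_1")
      out
    },
    noise_scan = {
      if (is.null(reference))
        reference <- synthetic_reference(params, noise, cc, n_lin, n_gen)
      est <- estimate_noise(reference, params = params, cc = cc,
                            q = noise$q,
                            n_lineages = if (full) 50 else 10,
                            n_generations = n_gen,
                            base_seed = seed)
      list(estimate = est, reference = reference)
    },
    fitted_validation = {
      if (is.null(reference))
        reference <- synthetic_reference(params, noise, cc, n_lin, n_gen)
      tree <- simulate_lineages(n_lin, params = params, noise = noise,
                                cc = cc, n_generations = n_gen)
      s <- summary_stats(tree)
      list(stats = s, reference = reference,
           ks = ks_compare(s$amplitudes, reference$amplitudes))
    },
    iptg_prediction = {
      fit <- find_cr_for_period(29, params = params, noise = noise,
                                cc = cc, n_lineages = if (full) 30 else 10,
                                n_generations = n_gen)
      tree <- simulate_lineages(n_lin, params = fit$params, noise = noise,
                                cc = cc, n_generations = n_gen)
      list(C_r = fit$C_r, bisection_period = fit$period,
           stats = summary_stats(tree))
    },
    memory_ablation = {
      if (is.null(reference))
        reference <- synthetic_reference(params, noise, cc, n_lin, n_gen)
      est <- estimate_noise(reference, params = params, cc = cc, q = 0,
                            n_lineages = if (full) 50 else 10,
                            n_generations = n_gen,
                            base_seed = seed)
      list(estimate = est, reference = reference)
    },
    toy_recovery = {
      est <- toy_recovery_experiment(
        n_lineages_ref = if (full) 100 else 30,
        n_lineages = if (full) 40 else 12)
      list(estimate = est)
    })
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    manifest <- list(experiment = name, seed = seed, full = full,
                     package_version =
                       as.character(utils::packageVersion("oscnoise")),
                     timestamp = format(Sys.time(), tz = "UTC"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE)
    jsonlite::write_json(serialize_results(res),
                         file.path(out_dir, "results.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  res
}

# reference statistics from a synthetic full-model dataset at the given
# noise levels (stands in for experimental data, which ships separately)
synthetic_reference <- function(params, noise, cc, n_lineages,
                                n_generations) {
  tree <- simulate_lineages(n_lineages, params = params, noise = noise,
                            cc = cc, n_generations = n_generations)
  summary_stats(tree)
}

# strip non-serializable pieces for the results JSON
serialize_results <- function(x) {
  if (inherits(x, "summary_stats"))
    return(list(amplitude_cv = x$amplitude_cv, period_cv = x$period_cv,
                mean_period = x$mean_period,
                mean_amplitude = x$mean_amplitude, n_peaks = x$n_peaks,
                corr = as.data.frame(unclass(x$corr))))
  if (inherits(x, "noise_estimate"))
    return(list(omega_hat = x$omega_hat, gamma_hat = x$gamma_hat,
                intersects = x$intersects, gap = x$gap,
                cv_contour = x$cv_contour, corr_contour = x$corr_contour))
  if (is.list(x)) return(lapply(x, serialize_results))
  x
}
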