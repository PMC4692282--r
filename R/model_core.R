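#' Integrate the deterministic delay model of the oscillator
#'
#' Solves the four delay differential equations for repressor, activator,
#' immature GFP and mature GFP concentrations with fixed-step RK4 and linear
#' interpolation into the stored solution for the delayed arguments.  The
#' initial history is constant.  For the default parameter set the solution
#' relaxes to a stable limit cycle with a period of about 41 min.
#'
#' @param params An [oscillator_params()] object.
#' @param history Constant pre-history, named or positional vector
#'   `(r, a, g, G)` in molecules cell^-1.  The default puts a pulse of
#'   activator into an otherwise empty cell, which lies in the basin of the
#'   limit cycle and avoids the trivial low-expression state.
#' @param t_end End time, min.
#' @param dt Integration step, min; must be smaller than the shortest
#'   positive delay.
#' @param record_every Keep every `record_every`-th step in the output.
#' @return A data frame with columns `time`, `r`, `a`, `g`, `G`.
#' @examples
#' traj <- integrate_dde(oscillator_params(), t_end = 300)
#' @export
integrate_dde <- function(params, history = c(r = 0, a = 10, g = 0, G = 0),
                          t_end = 500, dt = 0.005, record_every = 20L) {
  stopifnot(inherits(params, "oscillator_params"))
  if (length(history) != 4 || any(history < 0))
    stop("history must be 4 nonnegative concentrations (r, a, g, G)")
  taus <- c(params$tau_r, params$tau_a, params$tau_g)
  pos <- taus[taus > 0]
  if (length(pos) && dt >= min(pos))
    stop("dt must be smaller than the shortest positive delay")
  m <- dde_integrate_cpp(param_vector(params), as.numeric(history), t_end,
                         dt, as.integer(record_every))
  out <- as.data.frame(m)
  names(out) <- c("time", "r", "a", "g", "G")
  out
}

#' Oscillation period of a deterministic trajectory
#'
#' Measures the period as the mean peak-to-peak interval of the chosen
#' variable after discarding an initial transient.
#'
#' @param traj Data frame from [integrate_dde()].
#' @param variable Column to analyse (default mature GFP `"G"`).
#' @param transient Time (min) discarded before measuring.
#' @return Mean period in min, or `NA` if fewer than 3 peaks are found
#'   (no sustained oscillation).
#' @export
oscillation_period <- function(traj, variable = "G", transient = 200) {
  x <- traj[[variable]][traj$time >= transient]
  tt <- traj$time[traj$time >= transient]
  pk <- local_maxima(x)
  rng <- diff(range(x))
  if (rng <= 0) return(NA_real_)
  pk <- pk[x[pk] - min(x) > 0.2 * rng]  # ignore numerical ripples
  if (length(pk) < 3) return(NA_real_)
  mean(diff(tt[pk]))
}

# indices of strict interior local maxima
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
}

#' Peak-centered normalized mean oscillation
#'
#' Implements the double normalization used to compare model and measured
#' oscillation shapes: every segment is centered on its peak, restricted to
#' 33 min before and after the peak (one full trough on each side), min-max
#' normalized to `[0, 1]`, averaged pointwise on the 3-min frame grid, and
#' the average is min-max normalized once more.
#'
#' @param segments A list of data frames with columns `time` and `value`,
#'   each containing a single oscillation peak and spanning at least 67 min.
#' @param grid_dt Output grid spacing, min.
#' @return Data frame with columns `time` (-33..33) and `value` in `[0, 1]`.
#' @export
normalize_and_average <- function(segments, grid_dt = 3) {
  if (!length(segments)) stop("no segments supplied")
  grid <- seq(-33, 33, by = grid_dt)
  norm <- lapply(segments, function(s) {
    if (diff(range(s$time)) < 66)
      stop("each segment must span at least 67 min around its peak")
    ip <- which.max(s$value)
    tt <- s$time - s$time[ip]
    v <- stats::approx(tt, s$value, xout = grid, rule = 2)$y
    rng <- range(v)
    if (rng[2] - rng[1] <= 0)
      stop("degenerate (flat) segment: max equals min")
    (v - rng[1]) / (rng[2] - rng[1])
  })
  avg <- Reduce(`+`, norm) / length(norm)
  avg <- (avg - min(avg)) / (max(avg) - min(avg))
  data.frame(time = grid, value = avg)
}

#' Shape-and-period error of the deterministic model
#'
#' Error function minimized when fitting the deterministic model to the
#' normalized mean oscillation: the sum of squared relative differences
#' between the normalized reference `G(t)` and the model's normalized
#' oscillation on the same peak-centered grid, plus the squared relative
#' period mismatch.  The relative error is undefined at the normalized
#' minimum (reference exactly 0) and ill-conditioned on the near-zero
#' trough floor, so grid points with reference below `zero_tol` are
#' excluded from the shape sum.  Returns `Inf` when the model does not
#' oscillate.
#'
#' @param params Candidate [oscillator_params()].
#' @param G_ref Reference mean oscillation from [normalize_and_average()].
#' @param mu_per Reference mean period, min.
#' @param t_end,dt Integration settings for the candidate model.
#' @param zero_tol Reference values below this fraction of the peak are
#'   left out of the relative-error sum.
#' @return Nonnegative error (dimensionless), `Inf` if non-oscillating.
#' @export
fit_error <- function(params, G_ref, mu_per, t_end = 500, dt = 0.005,
                      zero_tol = 0.01) {
  traj <- try(integrate_dde(params, t_end = t_end, dt = dt), silent = TRUE)
  if (inherits(traj, "try-error")) return(Inf)
  per <- oscillation_period(traj)
  if (is.na(per)) return(Inf)
  seg <- model_peak_segment(traj, transient = 200)
  if (is.null(seg)) return(Inf)
  sim <- normalize_and_average(list(seg), grid_dt = diff(G_ref$time[1:2]))
  keep <- G_ref$value > zero_tol
  shape <- sum((G_ref$value[keep] - sim$value[keep])^2 / G_ref$value[keep]^2)
  shape + (mu_per - per)^2 / mu_per^2
}

# extract one peak-centered segment (+-33 min padded) from a trajectory
model_peak_segment <- function(traj, transient = 200, variable = "G") {
  sel <- traj$time >= transient
  x <- traj[[variable]][sel]
  tt <- traj$time[sel]
  pk <- local_maxima(x)
  rng <- diff(range(x))
  if (rng <= 0) return(NULL)
  pk <- pk[x[pk] - min(x) > 0.2 * rng]
  pk <- pk[tt[pk] - 34 >= tt[1] & tt[pk] + 34 <= tt[length(tt)]]
  if (!length(pk)) return(NULL)
  ip <- pk[ceiling(length(pk) / 2)]
  keep <- tt >= tt[ip] - 34 & tt <= tt[ip] + 34
  data.frame(time = tt[keep], value = x[keep])
}

#' Fit the deterministic model to a reference oscillation
#'
#' Local minimization of [fit_error()] by finite-difference gradient descent
#' in log-parameter space (which keeps all rates positive) with a
#' backtracking line search.  The free set defaults to the eight parameters
#' estimated from data: the per-plasmid production rate `alpha` (which moves
#' the three production rates together), the proteolysis rates, `f`, `R0`,
#' `C_a` and `C_r`.  Delays, the maturation rate and the dilution rate are
#' fixed.
#'
#' @param G_ref Reference mean oscillation ([normalize_and_average()] output).
#' @param mu_per Reference mean period, min.
#' @param p0 Starting [oscillator_params()].
#' @param free Character vector of parameter names to optimize (subset of
#'   `alpha`, `gamma_r`, `gamma_a`, `gamma_g`, `f`, `R0`, `C_a`, `C_r`).
#' @param max_iter Maximum gradient-descent iterations.
#' @param tol Convergence tolerance on the relative error change.
#' @param step0 Initial line-search step in log-parameter space.
#' @param t_end,dt Integration settings used for every error evaluation.
#' @return A list of class `fit_result` with elements `params`, `error`,
#'   `period`, `iterations`, `converged`.
#' @export
fit_parameters <- function(G_ref, mu_per, p0 = oscillator_params(),
                           free = c("alpha", "gamma_r", "gamma_a", "gamma_g",
                                    "f", "R0", "C_a", "C_r"),
                           max_iter = 100, tol = 1e-6, step0 = 0.1,
                           t_end = 500, dt = 0.005) {
  allowed <- c("alpha", "gamma_r", "gamma_a", "gamma_g", "f", "R0",
               "C_a", "C_r")
  if (!all(free %in% allowed))
    stop("free parameters must be a subset of: ",
         paste(allowed, collapse = ", "))
  make_params <- function(logv) {
    vals <- as.list(exp(logv))
    names(vals) <- free
    p <- p0
    for (nm in free) p[[nm]] <- vals[[nm]]
    if ("alpha" %in% free) {  # production rates tied to alpha
      p$alpha_r <- 25 * p$alpha / 4
      p$alpha_a <- 60 * p$alpha / 2
      p$alpha_g <- 60 * p$alpha
    }
    p
  }
  efun <- function(logv) fit_error(make_params(logv), G_ref, mu_per,
                                   t_end = t_end, dt = dt)
  if (!length(free)) {
    e0 <- fit_error(p0, G_ref, mu_per, t_end = t_end, dt = dt)
    traj0 <- integrate_dde(p0, t_end = t_end, dt = dt)
    res <- list(params = p0, error = e0,
                period = oscillation_period(traj0), iterations = 0L,
                converged = TRUE)
    class(res) <- "fit_result"
    return(res)
  }
  lv <- log(unlist(p0[free], use.names = FALSE))
  e <- efun(lv)
  if (!is.finite(e))
    stop("starting parameters do not produce sustained oscillations")
  iter <- 0
  converged <- FALSE
  if (length(free)) {
    h <- 1e-4
    for (iter in seq_len(max_iter)) {
      grad <- vapply(seq_along(lv), function(i) {
        lp <- lv; lp[i] <- lp[i] + h
        ep <- efun(lp)
        if (!is.finite(ep)) ep <- e + 10  # push away from non-oscillating
        (ep - e) / h
      }, numeric(1))
      gn <- sqrt(sum(grad^2))
      if (gn == 0) { converged <- TRUE; break }
      step <- step0
      improved <- FALSE
      while (step > 1e-6) {
        lt <- lv - step * grad / gn
        et <- efun(lt)
        if (is.finite(et) && et < e) {
          improved <- TRUE
          break
        }
        step <- step / 2
      }
      if (!improved) { converged <- TRUE; break }
      rel <- (e - et) / max(e, .Machine$double.eps)
      lv <- lt
      e <- et
      if (rel < tol) { converged <- TRUE; break }
    }
  }
  pfit <- make_params(lv)
  traj <- integrate_dde(pfit, t_end = t_end, dt = dt)
  res <- list(params = pfit, error = e, period = oscillation_period(traj),
              iterations = iter, converged = converged)
  class(res) <- "fit_result"
  res
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Deterministic model fit:\n")
  cat("  error  :", format(x$error, digits = 5), "\n")
  cat("  period :", format(x$period, digits = 4), "min\n")
  cat("  iterations:", x$iterations,
      if (x$converged) "(converged)" else "(max iterations)", "\n")
  invisible(x)
}

#' Write / read a trajectory as two-column CSV
#'
#' @param traj Data frame with a `time` column and one value column.
#' @param path File path.
#' @param value Name of the value column.
#' @return `read_trajectory_csv()` returns a data frame `(time, value)`.
#' @export
write_trajectory_csv <- function(traj, path, value = "value") {
  out <- data.frame(time_min = traj$time, value = traj[[value]])
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  d <- utils::read.csv(path)
  data.frame(time = d$time_min, value = d$value)
}
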