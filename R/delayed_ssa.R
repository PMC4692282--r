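#' Reaction system of the stochastic oscillator
#'
#' Builds the eight reactions of the stochastic model as explicit R objects:
#' three delayed productions (repressor, activator, immature GFP; firing
#' schedules the molecule to appear one transcriptional delay later), four
#' losses combining dilution (in constant-volume mode) with saturated ClpXP
#' proteolysis shared across all tagged proteins, and GFP maturation.
#' Propensities use the volume-scaled form `x -> V R(y / V)`: productions
#' scale with `V` and the Hill / proteolysis terms are evaluated on
#' concentrations `y / V`.  All rate and affinity parameters are pre-scaled
#' by `omega` (see [rescale_params()]).
#'
#' This R-level representation, together with [simulate_reactions()], is the
#' slow reference implementation of the delayed SSA; production lineage
#' simulations use the compiled kernel behind [simulate_cell()] and
#' [simulate_lineage()], which implements the identical system.
#'
#' @param params An [oscillator_params()] object (unscaled).
#' @param omega Intrinsic-noise scale (> 0).
#' @param dilution_in_propensity If `TRUE` (constant-volume single-cell
#'   mode) each loss propensity includes the first-order dilution rate
#'   `beta`; if `FALSE` dilution must come from explicit volume growth.
#' @return List of class `reaction_system`: reactions (each with fields
#'   `name`, `propensity(counts, V, t)`, `delta`, `delay`) plus the scaled
#'   parameter set.
#' @export
build_reactions <- function(params, omega = 1, dilution_in_propensity = TRUE) {
  stopifnot(inherits(params, "oscillator_params"))
  p <- rescale_params(params, omega)
  bl <- if (dilution_in_propensity) p$beta else 0
  species <- c("r", "a", "g", "G")
  hill <- function(counts, V) {
    hill_activity(counts[1] / V, counts[2] / V, p$f, p$C_a, p$C_r)
  }
  dsat <- function(counts, V) 1 / (p$R0 + sum(counts) / V)
  rx <- list()
  prod_rates <- c(r = p$alpha_r, a = p$alpha_a, g = p$alpha_g)
  prod_delay <- c(r = p$tau_r, a = p$tau_a, g = p$tau_g)
  for (i in 1:3) {
    local({
      ii <- i
      delta <- stats::setNames(c(0, 0, 0, 0), species)
      delta[ii] <- 1
      rx[[length(rx) + 1]] <<- list(
        name = paste0("prod_", species[ii]),
        propensity = function(counts, V = 1, t = 0)
          V * prod_rates[[ii]] * hill(counts, V),
        delta = delta, delay = prod_delay[[ii]]
      )
    })
  }
  loss_rates <- c(p$gamma_r, p$gamma_a, p$gamma_g, p$gamma_G)
  for (i in 1:4) {
    local({
      ii <- i
      delta <- stats::setNames(c(0, 0, 0, 0), species)
      delta[ii] <- -1
      rx[[length(rx) + 1]] <<- list(
        name = paste0("loss_", species[ii]),
        propensity = function(counts, V = 1, t = 0)
          counts[ii] * (bl + loss_rates[ii] * dsat(counts, V)),
        delta = delta, delay = 0
      )
    })
  }
  rx[[length(rx) + 1]] <- list(
    name = "maturation",
    propensity = function(counts, V = 1, t = 0) p$lambda_mat * counts[3],
    delta = stats::setNames(c(0, 0, -1, 1), species), delay = 0
  )
  structure(list(reactions = rx, params = p, omega = omega,
                 dilution_in_propensity = dilution_in_propensity),
            class = "reaction_system")
}

#' Reference delayed SSA on an explicit reaction list
#'
#' Plain-R next-reaction-time Gillespie simulation supporting fixed
#' per-reaction delays: firing a delayed reaction schedules its state change
#' on a queue of pending events, and a pending completion that precedes the
#' next tentative reaction time fires first.  Intended as a readable,
#' independent reference for small systems and for validating the compiled
#' lineage kernel; it is far too slow for production runs.
#'
#' @param reactions List of reactions (`propensity`, `delta`, `delay`), e.g.
#'   from [build_reactions()], or hand-built for toy systems.
#' @param counts Named integer vector of initial molecule counts.
#' @param t_end End time.
#' @param V Constant volume passed to propensities.
#' @param record_times Optional times at which to record the state.
#' @return List with `counts` (final), `events` (number fired), and if
#'   `record_times` given a matrix `states` (rows = record times).
#' @export
simulate_reactions <- function(reactions, counts, t_end, V = 1,
                               record_times = NULL) {
  t <- 0
  queue_t <- numeric(0)
  queue_i <- integer(0)
  nrec <- length(record_times)
  states <- if (nrec) matrix(NA_real_, nrec, length(counts),
                             dimnames = list(NULL, names(counts)))
  ri <- 1L
  nev <- 0L
  repeat {
    a <- vapply(reactions, function(r) r$propensity(counts, V, t), numeric(1))
    if (any(a < 0)) stop("negative propensity at t = ", t)
    a0 <- sum(a)
    t_rxn <- if (a0 > 0) t + stats::rexp(1, a0) else Inf
    t_q <- if (length(queue_t)) min(queue_t) else Inf
    t_next <- min(t_rxn, t_q, t_end)
    while (ri <= nrec && record_times[ri] <= t_next) {
      states[ri, ] <- counts
      ri <- ri + 1L
    }
    if (t_next >= t_end) break
    if (t_q <= t_rxn) {
      k <- which.min(queue_t)
      counts <- counts + reactions[[queue_i[k]]]$delta
      queue_t <- queue_t[-k]
      queue_i <- queue_i[-k]
      t <- t_q
    } else {
      j <- sample.int(length(a), 1, prob = a)
      if (reactions[[j]]$delay > 0) {
        queue_t <- c(queue_t, t_rxn + reactions[[j]]$delay)
        queue_i <- c(queue_i, j)
      } else {
        counts <- counts + reactions[[j]]$delta
      }
      t <- t_rxn
    }
    nev <- nev + 1L
    if (any(counts < 0)) stop("negative count produced at t = ", t)
  }
  out <- list(counts = counts, events = nev)
  if (nrec) out$states <- states
  out
}

#' Stochastic single-cell simulation at constant volume
#'
#' Delayed-SSA simulation of one cell with fixed volume `V = 1` and no
#' division; cell growth enters only as first-order dilution at rate
#' `beta`.  This is the configuration used to study pure intrinsic noise.
#' Fluorescence (mature GFP per unit volume) is recorded on the 3-min
#' microscopy frame grid.
#'
#' @param params An [oscillator_params()] object (unscaled).
#' @param omega Intrinsic-noise scale.
#' @param t_end Duration, min.
#' @param init_counts Optional integer counts `(r, a, g, G)`; by default a
#'   point on the deterministic limit cycle scaled to `omega` (see
#'   [limit_cycle_state()]).
#' @param frame_dt Frame spacing, min.
#' @return Data frame `(time, fluorescence)`; attribute `final` holds the
#'   final counts and delay queue.
#' @export
simulate_cell <- function(params, omega = 1, t_end = 480,
                          init_counts = NULL, frame_dt = 3) {
  stopifnot(inherits(params, "oscillator_params"))
  if (t_end <= 0) stop("t_end must be positive")
  if (is.null(init_counts))
    init_counts <- as.integer(round(limit_cycle_state(params) * omega))
  pO <- rescale_params(params, omega)
  frames <- seq(frame_dt, t_end, by = frame_dt)
  res <- ssa_cell_cpp(as.integer(init_counts), numeric(0), integer(0),
                      0, t_end, 1, pO$beta, FALSE, pO$beta,
                      cell_param_vector(pO), frames)
  out <- data.frame(time = frames, fluorescence = res$fluor)
  attr(out, "final") <- res[c("counts", "queue_time", "queue_species")]
  out
}

# vector layout of the per-cell C++ kernel (no beta: passed separately)
cell_param_vector <- function(p) {
  c(p$alpha_r, p$alpha_a, p$alpha_g, p$gamma_r, p$gamma_a, p$gamma_g,
    p$gamma_G, p$R0, p$C_a, p$C_r, p$f, p$tau_r, p$tau_a, p$tau_g,
    p$lambda_mat)
}

# cache of deterministic limit-cycle states keyed by parameter values
.lc_cache <- new.env(parent = emptyenv())

#' Point on the deterministic limit cycle
#'
#' Integrates the deterministic model and returns the concentration state
#' `(r, a, g, G)` at a mature-GFP peak after the transient, used to
#' initialize stochastic simulations near the attractor (multiplied by
#' `omega` and the cell volume to give counts).  Results are cached per
#' parameter set.
#'
#' @param params An [oscillator_params()] object.
#' @param phase `"peak"` or `"trough"` of mature GFP.
#' @return Named numeric vector `(r, a, g, G)`.
#' @export
limit_cycle_state <- function(params, phase = c("peak", "trough")) {
  phase <- match.arg(phase)
  key <- paste(c(phase, format(param_vector(params), digits = 12)),
               collapse = "|")
  hit <- .lc_cache[[key]]
  if (!is.null(hit)) return(hit)
  traj <- integrate_dde(params, t_end = 400, dt = 0.005, record_every = 50L)
  sel <- traj$time >= 250
  x <- traj$G[sel]
  i <- if (phase == "peak") which.max(x) else which.min(x)
  row <- traj[sel, ][i, ]
  st <- c(r = row$r, a = row$a, g = row$g, G = row$G)
  .lc_cache[[key]] <- st
  st
}

#' Amplitude variability versus intrinsic-noise scale
#'
#' Runs `n_sims` constant-volume single-cell simulations per value of
#' `omega` and reports the pooled peak-amplitude CV (and period CV).  The
#' amplitude CV decreases roughly as `c / omega`; the returned attribute
#' `c_fit` is the least-squares coefficient of that fit.
#'
#' @param omegas Intrinsic-noise scales to scan.
#' @param n_sims Simulations per scale (>= 50 recommended).
#' @param t_end Duration of each simulation, min.
#' @param params Oscillator parameters.
#' @param transient Initial span excluded from peak statistics, min.
#' @param min_prominence_frac Peak-detection threshold.
#' @return Data frame `(omega, amplitude_cv, period_cv, n_peaks)`, with
#'   attribute `c_fit`.
#' @export
amplitude_cv_vs_omega <- function(omegas, n_sims = 100, t_end = 480,
                                  params = oscillator_params(),
                                  transient = 60,
                                  min_prominence_frac = 0.2) {
  rows <- lapply(omegas, function(om) {
    heights <- numeric(0)
    intervals <- numeric(0)
    init <- as.integer(round(limit_cycle_state(params) * om))
    for (s in seq_len(n_sims)) {
      tr <- simulate_cell(params, omega = om, t_end = t_end,
                          init_counts = init)
      tr <- tr[tr$time >= transient, ]
      pk <- find_peaks(tr$time, tr$fluorescence,
                       min_prominence_frac = min_prominence_frac)
      if (nrow(pk)) {
        heights <- c(heights, pk$height)
        if (nrow(pk) > 1) intervals <- c(intervals, diff(pk$time))
      }
    }
    if (length(heights) < 20)
      warning("fewer than 20 peaks detected at omega = ", om)
    data.frame(
      omega = om,
      amplitude_cv = stats::sd(heights) / mean(heights),
      period_cv = if (length(intervals) >= 2)
        stats::sd(intervals) / mean(intervals) else NA_real_,
      n_peaks = length(heights)
    )
  })
  out <- do.call(rbind, rows)
  w <- 1 / out$omega
  attr(out, "c_fit") <- sum(out$amplitude_cv * w) / sum(w^2)
  out
}
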