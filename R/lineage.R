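#' Cell-cycle parameters
#'
#' Distributions of the single-cell growth rate and the size required for
#' division, estimated from phase-contrast microscopy: the growth rate is
#' normal, `beta = beta0 (1 + Gamma_beta eta)` with `eta ~ N(0, 1)`, and the
#' division size follows a shifted gamma, `V_max = V_base + Gamma(k, theta)`
#' (mean `V_base + k theta` = 7 um).
#'
#' @param beta0 Mean growth rate, min^-1.
#' @param Gamma_beta CV of the growth rate (dimensionless).
#' @param V_base Shift of the division-size distribution, um.
#' @param k,theta Shape and scale of the gamma part (dimensionless).
#' @param V_unit Cell length (um) corresponding to one unit of the
#'   dimensionless volume that multiplies reaction propensities.  Measured
#'   sizes are in um (cell length) while the molecule-number scale of the
#'   stochastic model is set by the dimensionless product
#'   `omega * V / V_unit`.  The default, half the mean division size
#'   `(V_base + k theta) / 2` = 3.5 um, gives a newborn cell of average
#'   size one propensity volume -- the same convention as the
#'   constant-volume single-cell mode, where a (newborn-sized) cell has
#'   `V = 1` -- so `omega` means the same thing in both modes.  Any other
#'   choice is equivalent to rescaling `omega`.
#' @return Object of class `cell_cycle_params`.
#' @export
cell_cycle_params <- function(beta0 = 0.0295, Gamma_beta = 0.099,
                              V_base = 4.5, k = 2.5, theta = 1,
                              V_unit = (V_base + k * theta) / 2) {
  stopifnot(beta0 > 0, Gamma_beta >= 0, V_base > 0, k >= 0, theta > 0,
            V_unit > 0)
  structure(list(beta0 = beta0, Gamma_beta = Gamma_beta, V_base = V_base,
                 k = k, theta = theta, V_unit = V_unit),
            class = "cell_cycle_params")
}

#' Noise parameters
#'
#' The two inferred noise levels and the heritability of production-rate
#' variability: `omega` scales absolute molecule numbers (intrinsic noise;
#' larger is quieter), `gamma_ext` is the per-division CV of the heritable
#' production rates (extrinsic noise), and `q` in `[0, 1]` is the
#' autoregressive memory of the division-time parameter recursion
#' (`q = exp(-ln 2 / 5)` corresponds to a 5-generation half-life;
#' `q = 0` removes lineage memory, `q = 1` removes mean reversion).
#' Defaults are the values fitted to growth in 2 mM IPTG.
#'
#' @param omega Intrinsic-noise scale, > 0.
#' @param gamma_ext Parameter-variability CV, >= 0.
#' @param q Homeostatic memory in `[0, 1]`.
#' @return Object of class `noise_params`.
#' @export
noise_params <- function(omega = 2.1, gamma_ext = 0.12,
                         q = exp(-log(2) / 5)) {
  stopifnot(omega > 0, gamma_ext >= 0, q >= 0, q <= 1)
  structure(list(omega = omega, gamma_ext = gamma_ext, q = q),
            class = "noise_params")
}

#' Sample a daughter-cell growth rate
#'
#' `beta = beta0 (1 + Gamma_beta eta)`, `eta ~ N(0, 1)`, resampled
#' independently for every daughter cell; nonpositive draws (possible only
#' for unrealistically large `Gamma_beta`) are rejected and redrawn.
#'
#' @param cc A [cell_cycle_params()] object.
#' @param n Number of draws.
#' @return Growth rates, min^-1.
#' @export
sample_growth_rate <- function(cc, n = 1) {
  b <- cc$beta0 * (1 + cc$Gamma_beta * stats::rnorm(n))
  while (any(bad <- b <= 0))
    b[bad] <- cc$beta0 * (1 + cc$Gamma_beta * stats::rnorm(sum(bad)))
  b
}

#' Sample a division volume
#'
#' `V_max = V_base + Gamma(k, theta)`; fixed for a cell until it divides.
#'
#' @param cc A [cell_cycle_params()] object.
#' @param n Number of draws.
#' @return Division volumes, um.
#' @export
sample_division_volume <- function(cc, n = 1) {
  if (cc$k == 0) return(rep(cc$V_base, n))
  cc$V_base + stats::rgamma(n, shape = cc$k, scale = cc$theta)
}

#' Division-time resampling of a heritable production rate
#'
#' The autoregressive recursion applied to each heritable production rate
#' at cell division: the target is `m = q p_mother + (1 - q) p_mean`
#' (mean reversion with memory `q`), and the two sisters receive
#' `p1 = m (1 + Gamma eta)` and `p2 = m (1 - Gamma eta)` with a single
#' `eta ~ N(0, 1)` per parameter per division, so each daughter's rate has
#' per-division CV `Gamma` while the sister pair satisfies the constraint
#' `(p1 + p2) / 2 = m` exactly.  Draws that would produce a nonpositive
#' rate are rejected and redrawn.
#'
#' @param p_mother Mother's value of the rate.
#' @param p_mean Population mean of the rate (homeostatic target).
#' @param gamma_ext Per-division CV.
#' @param q Memory in `[0, 1]`.
#' @return Numeric vector `c(p1, p2)` of sister values.
#' @export
sister_rates <- function(p_mother, p_mean, gamma_ext, q) {
  m <- q * p_mother + (1 - q) * p_mean
  repeat {
    eta <- stats::rnorm(1)
    p <- m * c(1 + gamma_ext * eta, 1 - gamma_ext * eta)
    if (all(p > 0)) return(p)
  }
}

#' Draw a production rate from the stationary distribution
#'
#' Realized by iterating the division-time recursion
#' `p <- (q p + (1 - q) p_mean)(1 + Gamma eta)` for `burnin` steps from the
#' mean, which converges to the stationary law of the parameter process;
#' used to initialize progenitor cells.  The stationary mean is `p_mean`
#' and the stationary variance is
#' `p_mean^2 Gamma^2 (1 + q^2 ...)`, the fixed point of
#' `v' = (q^2 v + p_mean^2)(1 + Gamma^2) - p_mean^2` (see
#' [stationary_rate_cv()]).
#'
#' @param p_mean Population mean.
#' @param gamma_ext Per-division CV.
#' @param q Memory.
#' @param burnin Recursion steps.
#' @return One draw.
#' @export
stationary_rate <- function(p_mean, gamma_ext, q, burnin = 50) {
  p <- p_mean
  for (i in seq_len(burnin)) {
    repeat {
      pn <- (q * p + (1 - q) * p_mean) * (1 + gamma_ext * stats::rnorm(1))
      if (pn > 0) break
    }
    p <- pn
  }
  p
}

#' Analytic stationary CV of the heritable-rate recursion
#'
#' Fixed point of the variance recursion of the division-time resampling
#' rule: `v = (q^2 v + mu^2)(1 + Gamma^2) - mu^2` gives stationary variance
#' `v = mu^2 Gamma^2 / (1 - q^2 (1 + Gamma^2))` and hence stationary CV
#' `Gamma / sqrt(1 - q^2 (1 + Gamma^2))`.  Requires
#' `q^2 (1 + Gamma^2) < 1`, otherwise the variance diverges.
#'
#' @param gamma_ext Per-division CV.
#' @param q Memory.
#' @return Stationary coefficient of variation.
#' @export
stationary_rate_cv <- function(gamma_ext, q) {
  den <- 1 - q^2 * (1 + gamma_ext^2)
  if (den <= 0) return(Inf)
  gamma_ext / sqrt(den)
}

#' Divide a cell into two daughters
#'
#' Implements everything that happens at cell division: the volume is
#' halved; every molecule of every species is assigned to daughter 1 with
#' probability 1/2 (binomial partitioning), daughter 2 receiving the rest;
#' every pending delayed production in the queue is independently assigned
#' to one daughter, keeping its completion time; each daughter draws a
#' fresh growth rate and division volume; and the heritable production
#' rates are resampled per parameter by [sister_rates()].
#'
#' @param cell Cell state: list with `counts` (integer, length 4),
#'   `queue_time`, `queue_species`, `V`, `V_max`, `alphas` (length-3 vector
#'   of the cell's production rates, order r, a, g).
#' @param noise A [noise_params()] object.
#' @param cc A [cell_cycle_params()] object.
#' @param alpha_means Length-3 vector of population-mean production rates.
#' @return List of two daughter cell states (fields as in `cell`, volume
#'   `V / 2`, fresh `beta` and `V_max`).
#' @export
divide <- function(cell, noise, cc, alpha_means) {
  if (cell$V < cell$V_max * (1 - 1e-9))
    stop("division triggered below V_max (V = ", cell$V, ")")
  n1 <- stats::rbinom(4, cell$counts, 0.5)
  n2 <- cell$counts - n1
  nq <- length(cell$queue_time)
  to1 <- if (nq) stats::runif(nq) < 0.5 else logical(0)
  a_pair <- vapply(1:3, function(i)
    sister_rates(cell$alphas[i], alpha_means[i], noise$gamma_ext, noise$q),
    numeric(2))
  mk <- function(counts, qsel, alphas) {
    list(counts = as.integer(counts),
         queue_time = cell$queue_time[qsel],
         queue_species = cell$queue_species[qsel],
         V = cell$V / 2,
         V_max = sample_division_volume(cc),
         beta = sample_growth_rate(cc),
         alphas = alphas)
  }
  list(mk(n1, to1, a_pair[1, ]), mk(n2, !to1, a_pair[2, ]))
}

#' Lineage tree container
#'
#' A branched set of cells with parent links and per-frame fluorescence.
#' `cells` has columns `lineage_id`, `cell_id`, `parent_id` (`NA` for the
#' progenitor), `birth_time`, `division_time` (end of tracking for leaf
#' cells); `frames` has `lineage_id`, `cell_id`, `time`, `fluorescence`.
#'
#' @param cells,frames Data frames as described.
#' @param frame_dt Frame spacing, min.
#' @return Object of class `lineage_tree`.
#' @export
lineage_tree <- function(cells, frames, frame_dt = 3) {
  tr <- structure(list(cells = cells, frames = frames, frame_dt = frame_dt),
                  class = "lineage_tree")
  validate_lineage_tree(tr)
  tr
}

#' Validate the structural invariants of a lineage tree
#'
#' Checks parent-link consistency (every non-`NA` parent exists in the same
#' lineage; exactly one progenitor per lineage; 0 or 2 daughters per cell;
#' daughters born at the parent's division time) and that frame times lie
#' on a uniform grid.  Stops with a message naming the offending ids.
#'
#' @param tree A `lineage_tree`.
#' @return The tree, invisibly.
#' @export
validate_lineage_tree <- function(tree) {
  cells <- tree$cells
  for (lid in unique(cells$lineage_id)) {
    cl <- cells[cells$lineage_id == lid, ]
    roots <- cl$cell_id[is.na(cl$parent_id)]
    if (length(roots) != 1)
      stop("lineage ", lid, " must have exactly one progenitor, found ",
           length(roots))
    orphan <- setdiff(cl$parent_id[!is.na(cl$parent_id)], cl$cell_id)
    if (length(orphan))
      stop("lineage ", lid, ": orphan parent id(s) ",
           paste(orphan, collapse = ", "))
    nd <- table(cl$parent_id[!is.na(cl$parent_id)])
    if (any(nd != 2))
      stop("lineage ", lid, ": cell(s) ",
           paste(names(nd)[nd != 2], collapse = ", "),
           " have a number of daughters other than 2")
    idx <- match(cl$parent_id, cl$cell_id)
    ok <- is.na(idx) | abs(cl$birth_time - cl$division_time[idx]) < 1e-6
    if (!all(ok))
      stop("lineage ", lid, ": daughter birth times do not match parent ",
           "division times for cell(s) ",
           paste(cl$cell_id[!ok], collapse = ", "))
  }
  tm <- sort(unique(tree$frames$time))
  if (length(tm) > 1) {
    dtv <- diff(tm)
    if (any(abs(dtv %% tree$frame_dt) > 1e-6 &
              abs(dtv %% tree$frame_dt - tree$frame_dt) > 1e-6))
      stop("frame times are not on a uniform ", tree$frame_dt, "-min grid")
  }
  invisible(tree)
}

#' @export
print.lineage_tree <- function(x, ...) {
  cat("Lineage tree:", length(unique(x$cells$lineage_id)), "lineage(s),",
      nrow(x$cells), "cells,", nrow(x$frames), "frames (",
      x$frame_dt, "min grid )\n")
  invisible(x)
}

#' Simulate the full lineage of a progenitor cell
#'
#' Delayed stochastic simulation of every branch of a lineage: each cell's
#' volume grows exponentially at its own rate `beta`, molecule dynamics run
#' under the delayed SSA with volume-scaled propensities (dilution arises
#' from growth and halving, not from a first-order loss), and when the
#' volume reaches the cell's division size the cell is replaced by two
#' daughters via [divide()].  Each branch undergoes `n_generations`
#' divisions; the final generation is tracked over its full cycle but does
#' not divide.  Fluorescence is the mature-GFP concentration `G / V` on
#' the 3-min frame grid.
#'
#' The progenitor starts as a newborn cell (volume `V_max / 2`), with
#' production rates drawn from the stationary law of the heritable-rate
#' recursion and molecule counts placed on the deterministic limit cycle
#' (scaled by `omega` and the volume); statistics should discard a short
#' initial transient.
#'
#' @param params [oscillator_params()] (unscaled; `omega` scaling applied
#'   internally).
#' @param noise [noise_params()].
#' @param cc [cell_cycle_params()].
#' @param n_generations Number of division rounds per branch (>= 1).
#' @param frame_dt Frame spacing, min.
#' @param lineage_id Identifier stored in the output tables.
#' @return A [lineage_tree()].
#' @export
simulate_lineage <- function(params, noise = noise_params(),
                             cc = cell_cycle_params(), n_generations = 8,
                             frame_dt = 3, lineage_id = 1L) {
  stopifnot(inherits(params, "oscillator_params"),
            inherits(noise, "noise_params"),
            inherits(cc, "cell_cycle_params"))
  if (n_generations < 1) stop("n_generations must be >= 1")
  pO <- rescale_params(params, noise$omega)
  alpha_means <- c(pO$alpha_r, pO$alpha_a, pO$alpha_g)
  conc0 <- limit_cycle_state(params) * noise$omega
  ndiv <- 2^(n_generations + 1) - 1
  horizon <- (n_generations + 2) * log(2) / (cc$beta0 * (1 - 3 * cc$Gamma_beta))
  all_frames <- seq(frame_dt, by = frame_dt,
                    length.out = ceiling(horizon / frame_dt))

  Vm0 <- sample_division_volume(cc)
  prog <- list(counts = as.integer(round(conc0 * Vm0 / 2 / cc$V_unit)),
               queue_time = numeric(0), queue_species = integer(0),
               V = Vm0 / 2, V_max = Vm0, beta = sample_growth_rate(cc),
               alphas = vapply(alpha_means, stationary_rate,
                               numeric(1), gamma_ext = noise$gamma_ext,
                               q = noise$q))
  stack <- list(list(cell = prog, id = 1L, parent = NA_integer_,
                     birth = 0, gen = 0L))
  cells <- vector("list", ndiv)
  frames <- vector("list", ndiv)
  ci <- 0L
  while (length(stack)) {
    item <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    cell <- item$cell
    t_div <- item$birth + log(cell$V_max / cell$V) / cell$beta
    fr <- all_frames[all_frames > item$birth + 1e-9 &
                       all_frames <= t_div + 1e-9]
    pv <- cell_param_vector(pO)
    pv[1:3] <- cell$alphas
    res <- ssa_cell_cpp(cell$counts, cell$queue_time, cell$queue_species,
                        item$birth, t_div, cell$V / cc$V_unit, cell$beta,
                        TRUE, 0, pv, fr)
    ci <- ci + 1L
    cells[[ci]] <- data.frame(lineage_id = lineage_id, cell_id = item$id,
                              parent_id = item$parent,
                              birth_time = item$birth,
                              division_time = t_div)
    if (length(fr))
      frames[[ci]] <- data.frame(lineage_id = lineage_id,
                                 cell_id = item$id, time = fr,
                                 fluorescence = res$fluor)
    if (item$gen < n_generations) {
      cell$counts <- res$counts
      cell$queue_time <- res$queue_time
      cell$queue_species <- res$queue_species
      cell$V <- cell$V_max
      dtr <- divide(cell, noise, cc, alpha_means)
      for (k in 1:2)
        stack[[length(stack) + 1]] <- list(cell = dtr[[k]],
                                           id = 2L * item$id + (k - 1L),
                                           parent = item$id, birth = t_div,
                                           gen = item$gen + 1L)
    }
  }
  lineage_tree(do.call(rbind, cells[seq_len(ci)]),
               do.call(rbind, frames[!vapply(frames, is.null, logical(1))]),
               frame_dt = frame_dt)
}

#' Simulate and pool several lineages
#'
#' @param n_lineages Number of independent progenitor cells.
#' @param ... Passed to [simulate_lineage()].
#' @return A pooled [lineage_tree()] with `lineage_id` 1..`n_lineages`.
#' @export
simulate_lineages <- function(n_lineages, ...) {
  trees <- lapply(seq_len(n_lineages), function(i)
    simulate_lineage(lineage_id = i, ...))
  lineage_tree(do.call(rbind, lapply(trees, `[[`, "cells")),
               do.call(rbind, lapply(trees, `[[`, "frames")),
               frame_dt = trees[[1]]$frame_dt)
}
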