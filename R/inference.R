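#' Scan simulations over a grid of noise levels
#'
#' For every `(omega, gamma)` cell of the grid, runs the supplied
#' simulator, computes summary statistics, and records two mismatches with
#' the reference: the absolute difference of pooled amplitude CVs and the
#' L2 distance between sister-correlation functions on their shared lag
#' range.  The random seed is set deterministically per cell from
#' `base_seed`, so maps are reproducible and refining one cell does not
#' shift the others.
#'
#' @param reference Reference [summary_stats()] (experimental or
#'   in-silico).
#' @param sim_fn Function `(omega, gamma) -> summary_stats` running the
#'   model at one grid cell.
#' @param omega_values,gamma_values Ascending grid values (>= 3 each
#'   recommended).
#' @param base_seed Integer; per-cell seed is derived from it.
#' @return Object of class `noise_grid`: list with `omega_values`,
#'   `gamma_values`, `cv_map`, `corr_map` (matrices, rows = omega), and
#'   `stats` (list-matrix of the per-cell summary statistics).  Cells
#'   whose simulation fails (e.g. non-oscillating) get `Inf` distances.
#' @export
scan_grid <- function(reference, sim_fn, omega_values, gamma_values,
                      base_seed = NULL) {
  stopifnot(length(omega_values) >= 2, length(gamma_values) >= 1,
            !is.unsorted(omega_values), !is.unsorted(gamma_values))
  no <- length(omega_values)
  ng <- length(gamma_values)
  cv_map <- matrix(Inf, no, ng)
  corr_map <- matrix(Inf, no, ng)
  stats_m <- vector("list", no * ng)
  dim(stats_m) <- c(no, ng)
  for (i in seq_len(no)) {
    for (j in seq_len(ng)) {
      if (!is.null(base_seed))
        set.seed((base_seed + 7919L * i + 104729L * j) %% .Machine$integer.max)
      s <- try(sim_fn(omega_values[i], gamma_values[j]), silent = TRUE)
      if (inherits(s, "try-error")) next
      stats_m[[i, j]] <- s
      cv_map[i, j] <- cv_distance(s$amplitude_cv, reference$amplitude_cv)
      corr_map[i, j] <- corr_distance(s$corr, reference$corr)
    }
  }
  structure(list(omega_values = omega_values, gamma_values = gamma_values,
                 cv_map = cv_map, corr_map = corr_map, stats = stats_m),
            class = "noise_grid")
}

#' @export
print.noise_grid <- function(x, ...) {
  cat("Noise grid:", length(x$omega_values), "omega x",
      length(x$gamma_values), "gamma values\n")
  cat("amplitude-CV distance map:\n")
  m <- round(x$cv_map, 3)
  dimnames(m) <- list(paste0("omega=", x$omega_values),
                      paste0("gamma=", x$gamma_values))
  print(m)
  cat("correlation distance map:\n")
  m2 <- round(x$corr_map, 3)
  dimnames(m2) <- dimnames(m)
  print(m2)
  invisible(x)
}

#' Minimizing contours of a noise grid
#'
#' For each omega value, finds the gamma minimizing each distance map,
#' with one-dimensional quadratic sub-grid refinement through the argmin
#' and its neighbours (the printed noise estimates are not grid values, so
#' sub-grid resolution is needed).  Ties take the smallest gamma; columns
#' that are entirely non-finite are dropped from the contour.
#'
#' @param grid A `noise_grid` from [scan_grid()].
#' @return List with `cv_contour` and `corr_contour`, each a data frame
#'   `(omega, gamma, value)`.
#' @export
min_contours <- function(grid) {
  stopifnot(inherits(grid, "noise_grid"))
  one <- function(map) {
    rows <- lapply(seq_along(grid$omega_values), function(i) {
      v <- map[i, ]
      if (!any(is.finite(v))) return(NULL)
      j <- which(v == min(v, na.rm = TRUE))[1]  # tie -> smallest gamma
      g <- grid$gamma_values
      gj <- g[j]
      vj <- v[j]
      if (j > 1 && j < length(g) && all(is.finite(v[c(j - 1, j + 1)]))) {
        # vertex of the parabola through (g[j-1], g[j], g[j+1])
        refined <- quad_vertex(g[(j - 1):(j + 1)], v[(j - 1):(j + 1)])
        if (is.finite(refined$x) && refined$x >= g[j - 1] &&
              refined$x <= g[j + 1]) {
          gj <- refined$x
          vj <- refined$y
        }
      }
      data.frame(omega = grid$omega_values[i], gamma = gj, value = vj)
    })
    do.call(rbind, rows)
  }
  out <- list(cv_contour = one(grid$cv_map), corr_contour = one(grid$corr_map))
  attr(out, "gamma_spacing") <-
    if (length(grid$gamma_values) > 1)
      stats::median(diff(grid$gamma_values)) else 0.05
  out
}

# vertex of the parabola through three points (x must be distinct)
quad_vertex <- function(x, y) {
  fit <- stats::lm.fit(cbind(1, x, x^2), y)
  a <- fit$coefficients[3]
  b <- fit$coefficients[2]
  if (!is.finite(a) || a <= 0) return(list(x = NA_real_, y = NA_real_))
  xv <- -b / (2 * a)
  list(x = unname(xv),
       y = unname(fit$coefficients[1] + b * xv + a * xv^2))
}

#' Intersect the two minimizing contours
#'
#' Estimates the noise levels as the point where the minimal level set of
#' the amplitude-CV map crosses that of the correlation map.  Each
#' contour point is kept only where its map value is indistinguishable
#' from the map's global minimum (within `level_tol`, the Monte-Carlo
#' noise scale of the maps); a per-column argmin far above the global
#' minimum is not part of the minimal level set and must not fabricate an
#' intersection (this matters at low omega, where intrinsic noise alone
#' can match the amplitude while the correlation fit is poor).  The
#' difference `gamma_cv(omega) - gamma_corr(omega)` is then linearly
#' interpolated in omega; a sign change gives the crossing point.  If the
#' curves never change sign but approach within `gamma_resolution`, the
#' point of closest approach is returned; otherwise the result is flagged
#' as having no intersection (the expected outcome when lineage memory is
#' removed, `q = 0`).
#'
#' @param contours List with `cv_contour` and `corr_contour` from
#'   [min_contours()].
#' @param gamma_resolution Gamma distance under which a closest approach
#'   still counts as an intersection; defaults to 60% of the gamma grid
#'   spacing recorded by [min_contours()], else `0.03`.
#' @param level_tol A contour point is part of the minimal level set if
#'   its map value is within `level_tol` of the map's global minimum.
#' @return Object of class `noise_estimate`: list with `omega_hat`,
#'   `gamma_hat` (both `NA` if no intersection), `intersects` (logical),
#'   `gap` (gamma distance at the estimate), and the two contours.
#' @export
intersect_contours <- function(contours, gamma_resolution = NULL,
                               level_tol = 0.06) {
  cvc <- contours$cv_contour
  coc <- contours$corr_contour
  if (length(intersect(cvc$omega, coc$omega)) < 2)
    stop("contours share fewer than 2 omega values")
  cvc <- cvc[cvc$value <= min(cvc$value) + level_tol, ]
  coc <- coc[coc$value <= min(coc$value) + level_tol, ]
  shared <- intersect(cvc$omega, coc$omega)
  if (length(shared) < 2) {
    # the two minimal level sets barely coexist in omega: there is no
    # simultaneous match of amplitude variability and correlation
    est <- list(omega_hat = NA_real_, gamma_hat = NA_real_,
                intersects = FALSE, gap = Inf,
                cv_contour = contours$cv_contour,
                corr_contour = contours$corr_contour)
    class(est) <- "noise_estimate"
    return(est)
  }
  shared <- sort(shared)
  if (is.null(gamma_resolution)) {
    sp <- attr(contours, "gamma_spacing")
    gamma_resolution <- if (is.null(sp)) 0.03 else 0.6 * sp
  }
  g1 <- cvc$gamma[match(shared, cvc$omega)]
  g2 <- coc$gamma[match(shared, coc$omega)]
  v1 <- cvc$value[match(shared, cvc$omega)]
  v2 <- coc$value[match(shared, coc$omega)]
  d <- g1 - g2
  est <- NULL
  sgn <- sign(d)
  cross <- which(sgn[-1] * sgn[-length(sgn)] <= 0)
  if (length(cross)) {
    # with Monte-Carlo jitter the contours can cross more than once; keep
    # the crossing where both mismatches are smallest
    cand <- lapply(cross, function(k) {
      w <- if (d[k] == d[k + 1]) 0.5 else d[k] / (d[k] - d[k + 1])
      list(omega = shared[k] + w * (shared[k + 1] - shared[k]),
           gamma = g1[k] + w * (g1[k + 1] - g1[k]),
           score = (1 - w) * (v1[k] + v2[k]) + w * (v1[k + 1] + v2[k + 1]))
    })
    best <- cand[[which.min(vapply(cand, `[[`, numeric(1), "score"))]]
    est <- list(omega_hat = best$omega, gamma_hat = best$gamma,
                intersects = TRUE, gap = 0)
  } else {
    k <- which.min(abs(d))
    if (abs(d[k]) <= gamma_resolution) {
      est <- list(omega_hat = shared[k],
                  gamma_hat = (g1[k] + g2[k]) / 2,
                  intersects = TRUE, gap = abs(d[k]))
    } else {
      est <- list(omega_hat = NA_real_, gamma_hat = NA_real_,
                  intersects = FALSE, gap = abs(d[k]))
    }
  }
  est$cv_contour <- cvc
  est$corr_contour <- coc
  class(est) <- "noise_estimate"
  est
}

#' @export
print.noise_estimate <- function(x, ...) {
  if (x$intersects) {
    cat(sprintf(
      "Noise estimate: omega = %.3g, gamma = %.3g (contour gap %.3g)\n",
      x$omega_hat, x$gamma_hat, x$gap))
  } else {
    cat(sprintf(
      "No contour intersection%s: the amplitude and correlation constraints cannot be met simultaneously\n",
      if (is.finite(x$gap))
        sprintf(" (closest gamma gap %.3g)", x$gap) else ""))
  }
  invisible(x)
}

#' Full-model noise inference from reference statistics
#'
#' Scans lineage simulations of the dual-feedback oscillator over an
#' `(omega, gamma)` grid against reference summary statistics and
#' intersects the minimizing contours.  This is the estimator that, given
#' experimental lineage statistics, determines the intrinsic-noise scale
#' and the production-rate variability.
#'
#' @param reference Reference [summary_stats()].
#' @param params [oscillator_params()].
#' @param cc [cell_cycle_params()].
#' @param q Lineage memory of the heritable rates.
#' @param omega_values,gamma_values Scan grid.
#' @param n_lineages,n_generations Simulation budget per grid cell.
#' @param base_seed Per-cell seed base (see [scan_grid()]).
#' @return A `noise_estimate` with attribute `grid`.
#' @export
estimate_noise <- function(reference, params = oscillator_params(),
                           cc = cell_cycle_params(),
                           q = exp(-log(2) / 5),
                           omega_values = c(0.5, 1, 1.5, 2, 2.5, 3),
                           gamma_values = c(0, 0.05, 0.1, 0.15, 0.2),
                           n_lineages = 12, n_generations = 6,
                           base_seed = NULL) {
  sim_fn <- function(omega, gamma) {
    tree <- simulate_lineages(n_lineages, params = params,
                              noise = noise_params(omega, gamma, q),
                              cc = cc, n_generations = n_generations)
    summary_stats(tree)
  }
  grid <- scan_grid(reference, sim_fn, omega_values, gamma_values,
                    base_seed = base_seed)
  est <- intersect_contours(min_contours(grid))
  attr(est, "grid") <- grid
  est
}
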