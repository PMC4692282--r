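#' Detect oscillation peaks in a fluorescence trace
#'
#' Local maxima of the (optionally smoothed) series whose topographic
#' prominence is at least `min_prominence_frac` times the typical (median)
#' prominence of the candidate peaks on the trace.  Scaling the threshold
#' by the typical prominence rather than the trace range keeps genuinely
#' small oscillations in traces with high amplitude variability while still
#' rejecting shot-noise ripples; on a regular oscillation the two
#' conventions coincide.  Smoothing (moving average) is used for detection
#' only; reported peak heights are the raw values at the detected peak
#' times.
#'
#' @param time Numeric vector of frame times, min (uniform grid).
#' @param value Fluorescence values, same length.
#' @param min_prominence_frac Minimum prominence as a fraction of the
#'   median candidate-peak prominence, in `[0, 1]`.
#' @param smooth_window Moving-average window (frames) used for detection;
#'   1 disables smoothing.
#' @param min_separation Minimum time between reported peaks, min; of two
#'   candidates closer than this, the less prominent one is dropped.  The
#'   default (18 min) is under half the 41-min oscillation period.
#' @return A data frame with columns `time`, `height` (raw) and `index`;
#'   zero rows if the trace has fewer than 2 candidate peaks or is flat.
#' @export
find_peaks <- function(time, value, min_prominence_frac = 0.2,
                       smooth_window = 3, min_separation = 18) {
  n <- length(value)
  if (n != length(time)) stop("time and value lengths differ")
  if (n < 3 || diff(range(value)) <= 0)
    return(data.frame(time = numeric(0), height = numeric(0),
                      index = integer(0)))
  v <- if (smooth_window > 1) moving_average(value, smooth_window) else value
  cand <- local_maxima(v)
  if (!length(cand))
    return(data.frame(time = numeric(0), height = numeric(0),
                      index = integer(0)))
  prom <- vapply(cand, function(i) peak_prominence(v, i, cand), numeric(1))
  # drop shot-noise ripples before estimating the typical prominence
  scale <- stats::median(prom[prom > 0.02 * diff(range(v))])
  if (!is.finite(scale)) scale <- diff(range(v))
  keep <- prom >= min_prominence_frac * scale
  idx <- cand[keep]
  pr <- prom[keep]
  if (length(idx) > 1 && min_separation > 0) {
    # greedy by prominence: suppress neighbours closer than min_separation
    ord <- order(pr, decreasing = TRUE)
    sel <- logical(length(idx))
    for (j in ord) {
      if (!any(sel & abs(time[idx] - time[idx[j]]) < min_separation))
        sel[j] <- TRUE
    }
    idx <- sort(idx[sel])
  }
  # peak time from the smoothed series; height is the raw value there
  data.frame(time = time[idx], height = value[idx], index = idx)
}

moving_average <- function(x, w) {
  sm <- as.numeric(stats::filter(x, rep(1 / w, w), sides = 2))
  # keep edges unsmoothed instead of NA
  sm[is.na(sm)] <- x[is.na(sm)]
  sm
}

# topographic prominence: drop from the peak to the highest of the two
# key saddles separating it from higher ground (trace ends count as ground)
peak_prominence <- function(v, i, maxima) {
  left <- v[seq_len(i)]
  right <- v[i:length(v)]
  higher_l <- which(left > v[i])
  base_l <- if (length(higher_l)) min(left[max(higher_l):i]) else min(left)
  higher_r <- which(right > v[i])
  base_r <- if (length(higher_r)) min(right[1:min(higher_r)]) else min(right)
  v[i] - max(base_l, base_r)
}

#' Amplitude and period coefficients of variation of pooled peaks
#'
#' The coefficient of variation (sample SD with `n - 1` denominator divided
#' by the sample mean) of peak heights, and of complete peak-to-peak
#' intervals, pooled across all branches and lineages.
#'
#' @param peaks Data frame with columns `height` and `interval` as returned
#'   by [peak_statistics()]; `interval` rows may contain `NA` for the first
#'   peak of each branch.
#' @return Named list with `amplitude_cv`, `period_cv`, `mean_amplitude`,
#'   `mean_period`, `n_peaks`, `n_intervals`.
#' @export
amplitude_and_period_cv <- function(peaks) {
  amps <- peaks$height
  ints <- peaks$interval[!is.na(peaks$interval)]
  if (length(amps) < 2 || mean(amps) <= 0)
    stop("need at least 2 peaks with positive mean amplitude")
  list(
    amplitude_cv = stats::sd(amps) / mean(amps),
    period_cv = if (length(ints) >= 2) stats::sd(ints) / mean(ints)
                else NA_real_,
    mean_amplitude = mean(amps),
    mean_period = if (length(ints)) mean(ints) else NA_real_,
    n_peaks = length(amps),
    n_intervals = length(ints)
  )
}

#' Peaks and inter-peak intervals of a lineage tree
#'
#' Runs the shared peak detector along every root-to-leaf path of each
#' lineage (fluorescence is continuous across divisions, so oscillations
#' span cell boundaries), then de-duplicates peaks that lie on shared
#' ancestral segments so that every oscillation event is counted once per
#' branch point.  Intervals are time gaps between consecutive distinct
#' peaks along a path.
#'
#' @param tree A `lineage_tree` (see [lineage_tree()]).
#' @param transient Initial time span (min) per lineage excluded from
#'   statistics.
#' @param min_prominence_frac,smooth_window Passed to [find_peaks()].
#' @return Data frame with columns `lineage_id`, `cell_id`, `time`,
#'   `height`, `interval` (`NA` for the first peak of a path).
#' @export
peak_statistics <- function(tree, transient = 30, min_prominence_frac = 0.2,
                            smooth_window = 3) {
  stopifnot(inherits(tree, "lineage_tree"))
  res <- vector("list", 64)
  nres <- 0
  for (lid in unique(tree$cells$lineage_id)) {
    cells <- tree$cells[tree$cells$lineage_id == lid, ]
    frames <- tree$frames[tree$frames$lineage_id == lid, ]
    ord <- order(frames$cell_id, frames$time)
    cid <- as.character(frames$cell_id[ord])
    t_by_cell <- split(frames$time[ord], cid)
    v_by_cell <- split(frames$fluorescence[ord], cid)
    leaves <- cells$cell_id[!(cells$cell_id %in% cells$parent_id)]
    parent_of <- stats::setNames(cells$parent_id, as.character(cells$cell_id))
    seen <- character(0)     # "cellid@time" keys of peaks already counted
    for (leaf in leaves) {
      path <- character(0)
      cur <- leaf
      while (!is.na(cur)) {
        path <- c(as.character(cur), path)
        cur <- parent_of[[as.character(cur)]]
      }
      tt <- unlist(t_by_cell[path], use.names = FALSE)
      if (is.null(tt) || length(tt) < 3) next
      vv <- unlist(v_by_cell[path], use.names = FALSE)
      path_cells <- rep(path, lengths(t_by_cell[path]))
      keep <- tt >= transient
      if (sum(keep) < 3) next
      tt <- tt[keep]
      vv <- vv[keep]
      path_cells <- path_cells[keep]
      pk <- find_peaks(tt, vv, min_prominence_frac = min_prominence_frac,
                       smooth_window = smooth_window)
      if (!nrow(pk)) next
      pk$cell_id <- path_cells[pk$index]
      pk$interval <- c(NA_real_, diff(pk$time))
      key <- paste0(pk$cell_id, "@", pk$time)
      new <- !(key %in% seen)
      seen <- c(seen, key[new])
      pk <- pk[new, , drop = FALSE]
      if (!nrow(pk)) next
      pk$lineage_id <- lid
      nres <- nres + 1
      if (nres > length(res)) res <- c(res, vector("list", length(res)))
      res[[nres]] <- pk[c("lineage_id", "cell_id", "time", "height",
                          "interval")]
    }
  }
  if (!nres)
    return(data.frame(lineage_id = character(0), cell_id = character(0),
                      time = numeric(0), height = numeric(0),
                      interval = numeric(0)))
  do.call(rbind, res[seq_len(nres)])
}

#' Sister-cell correlation function
#'
#' For every division event, pairs the fluorescence of the two daughter
#' cells at the k-th frame after the division (nominal lag `3k` min on the
#' frame grid).  A pair contributes to a lag only while both sisters are
#' still tracked and neither has divided again, so correlations are not
#' mixed across generations.  The Pearson correlation is computed per
#' lineage at each lag and averaged across lineages (weighted equally);
#' with a single lineage the per-lineage value is returned.
#'
#' @param tree A `lineage_tree`.
#' @param max_lag Largest lag, min.
#' @param frame_dt Frame spacing, min.
#' @param transient Divisions before this time (min) are ignored.
#' @return Data frame of class `correlation_function` with columns `lag`,
#'   `rho` (`NA` where fewer than `min_pairs` pairs exist) and `n_pairs`
#'   (summed over lineages).
#' @param min_pairs Minimum complete pairs per lineage and lag.
#' @export
sister_correlation <- function(tree, max_lag = 30, frame_dt = 3,
                               transient = 0, min_pairs = 3) {
  stopifnot(inherits(tree, "lineage_tree"))
  lags <- seq(frame_dt, max_lag, by = frame_dt)
  nl <- length(lags)
  per_lineage <- list()
  for (lid in unique(tree$cells$lineage_id)) {
    cells <- tree$cells[tree$cells$lineage_id == lid, ]
    frames <- tree$frames[tree$frames$lineage_id == lid, ]
    fr_by_cell <- split(frames[c("time", "fluorescence")], frames$cell_id)
    x1 <- matrix(NA_real_, 0, nl)
    x2 <- matrix(NA_real_, 0, nl)
    for (pid in unique(cells$parent_id[!is.na(cells$parent_id)])) {
      sibs <- cells[which(!is.na(cells$parent_id) &
                            cells$parent_id == pid), ]
      if (nrow(sibs) != 2) next
      tdiv <- sibs$birth_time[1]
      if (tdiv < transient) next
      v <- lapply(seq_len(2), function(i) {
        f <- fr_by_cell[[as.character(sibs$cell_id[i])]]
        stop_t <- sibs$division_time[i]       # own next division (or end)
        out <- rep(NA_real_, nl)
        if (is.null(f)) return(out)
        f <- f[order(f$time), ]
        for (k in seq_len(nl)) {
          # k-th frame strictly after the division
          if (k <= nrow(f) && (is.na(stop_t) || f$time[k] <= stop_t + 1e-9))
            out[k] <- f$fluorescence[k]
        }
        out
      })
      x1 <- rbind(x1, v[[1]])
      x2 <- rbind(x2, v[[2]])
    }
    rho <- rep(NA_real_, nl)
    npair <- integer(nl)
    for (k in seq_len(nl)) {
      ok <- !is.na(x1[, k]) & !is.na(x2[, k])
      npair[k] <- sum(ok)
      if (npair[k] >= min_pairs &&
          stats::sd(x1[ok, k]) > 0 && stats::sd(x2[ok, k]) > 0)
        rho[k] <- stats::cor(x1[ok, k], x2[ok, k])
    }
    per_lineage[[as.character(lid)]] <- list(rho = rho, n = npair)
  }
  rho_mat <- do.call(rbind, lapply(per_lineage, `[[`, "rho"))
  n_mat <- do.call(rbind, lapply(per_lineage, `[[`, "n"))
  out <- data.frame(
    lag = lags,
    rho = apply(rho_mat, 2, function(z) {
      if (all(is.na(z))) NA_real_ else mean(z, na.rm = TRUE)
    }),
    n_pairs = colSums(n_mat)
  )
  class(out) <- c("correlation_function", "data.frame")
  out
}

#' Summary statistics of a lineage tree
#'
#' Convenience wrapper pooling [peak_statistics()],
#' [amplitude_and_period_cv()] and [sister_correlation()].
#'
#' @param tree A `lineage_tree`.
#' @param transient Initial transient excluded, min.
#' @param max_lag Largest sister-correlation lag, min.
#' @param ... Passed to [peak_statistics()].
#' @return List of class `summary_stats` with elements `amplitude_cv`,
#'   `period_cv`, `mean_amplitude`, `mean_period`, `corr` (correlation
#'   function), `amplitudes` (pooled peak heights), `n_peaks`.
#' @export
summary_stats <- function(tree, transient = 30, max_lag = 30, ...) {
  pk <- peak_statistics(tree, transient = transient, ...)
  if (nrow(pk) < 2) stop("too few peaks detected to compute statistics")
  cv <- amplitude_and_period_cv(pk)
  corr <- sister_correlation(tree, max_lag = max_lag, transient = transient)
  out <- c(cv, list(corr = corr, amplitudes = pk$height))
  class(out) <- "summary_stats"
  out
}

#' @export
print.summary_stats <- function(x, ...) {
  cat("Lineage summary statistics:\n")
  cat(sprintf("  amplitude CV : %.3f  (mean %.3g AU, %d peaks)\n",
              x$amplitude_cv, x$mean_amplitude, x$n_peaks))
  cat(sprintf("  period CV    : %.3f  (mean %.3g min, %d intervals)\n",
              x$period_cv, x$mean_period, x$n_intervals))
  rr <- x$corr$rho[!is.na(x$corr$rho)]
  if (length(rr))
    cat(sprintf("  sister corr  : rho(%g) = %.3f ... rho(%g) = %.3f\n",
                x$corr$lag[which(!is.na(x$corr$rho))[1]], rr[1],
                max(x$corr$lag[!is.na(x$corr$rho)]), rr[length(rr)]))
  invisible(x)
}

#' Distances between summary statistics
#'
#' `cv_distance()` is the absolute difference of two coefficients of
#' variation.  `corr_distance()` is the L2 norm of the pointwise difference
#' of two correlation functions over their shared lag grid (no averaging:
#' a constant offset of 0.1 over 10 lags gives `0.1 * sqrt(10)`).
#'
#' @param cv_sim,cv_exp Coefficients of variation.
#' @return Nonnegative distance.
#' @export
cv_distance <- function(cv_sim, cv_exp) abs(cv_sim - cv_exp)

#' @rdname cv_distance
#' @param c_sim,c_exp Correlation functions ([sister_correlation()] output).
#' @export
corr_distance <- function(c_sim, c_exp) {
  shared <- intersect(c_sim$lag[!is.na(c_sim$rho)],
                      c_exp$lag[!is.na(c_exp$rho)])
  if (!length(shared)) stop("correlation functions share no defined lags")
  d <- c_sim$rho[match(shared, c_sim$lag)] -
    c_exp$rho[match(shared, c_exp$lag)]
  sqrt(sum(d^2))
}

#' Kolmogorov-Smirnov comparison of amplitude distributions
#'
#' Two-sample KS test on mean-rescaled amplitude samples (each sample is
#' divided by its own mean, so only distribution shapes are compared).
#'
#' @param amps_a,amps_b Numeric amplitude samples (>= 10 values each).
#' @param conf Confidence level defining "pass".
#' @return List with `statistic`, `p_value`, `pass` (not rejected at
#'   `conf`).
#' @export
ks_compare <- function(amps_a, amps_b, conf = 0.95) {
  if (length(amps_a) < 10 || length(amps_b) < 10)
    stop("need at least 10 amplitudes per sample")
  kt <- suppressWarnings(stats::ks.test(amps_a / mean(amps_a),
                                        amps_b / mean(amps_b)))
  list(statistic = unname(kt$statistic), p_value = kt$p.value,
       pass = kt$p.value > 1 - conf)
}
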