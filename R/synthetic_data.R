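#' Specification for synthetic "experimental-style" lineage data
#'
#' Describes a synthetic dataset that emulates the structure of the
#' time-lapse microscopy output: 3-min frames, 3-6 h movies, branched
#' trajectories splitting at each division.  Three generators are
#' available: `"parametric_sine"` (branched sinusoids with tunable
#' amplitude/period variability and sister decorrelation; fast, with
#' exactly known targets, for testing the statistics pipeline),
#' `"toy_model"` (amplitude-phase oscillator lineages) and `"full_model"`
#' (delayed-SSA oscillator lineages).
#'
#' @param generator One of `"parametric_sine"`, `"toy_model"`,
#'   `"full_model"`.
#' @param n_lineages Number of progenitor cells.
#' @param duration Movie length, min (multiple of `frame_interval`; used to
#'   choose the number of generations).
#' @param frame_interval Frame spacing, min.
#' @param amplitude_cv,period,period_cv Targets for the parametric
#'   generator (peak-height CV, mean period in min, period CV).
#' @param frame_noise_cv Multiplicative white measurement noise per frame
#'   (parametric generator).
#' @param noise [noise_params()] for the model generators.
#' @param params [oscillator_params()] for the full model.
#' @param toy [toy_params()] for the toy model.
#' @param cc [cell_cycle_params()].
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(generator = c("parametric_sine", "toy_model",
                                         "full_model"),
                           n_lineages = 6, duration = 180,
                           frame_interval = 3, amplitude_cv = 0.47,
                           period = 41, period_cv = 0.11,
                           frame_noise_cv = 0.02,
                           noise = noise_params(),
                           params = oscillator_params(),
                           toy = toy_params(),
                           cc = cell_cycle_params()) {
  generator <- match.arg(generator)
  if (duration %% frame_interval != 0)
    stop("duration must be a multiple of frame_interval")
  if (amplitude_cv < 0 || period_cv < 0 || period <= 0)
    stop("infeasible parametric targets: CVs must be >= 0 and period > 0")
  structure(list(generator = generator, n_lineages = n_lineages,
                 duration = duration, frame_interval = frame_interval,
                 amplitude_cv = amplitude_cv, period = period,
                 period_cv = period_cv, frame_noise_cv = frame_noise_cv,
                 noise = noise, params = params, toy = toy, cc = cc),
            class = "synthetic_spec")
}

#' Generate a synthetic lineage dataset with known ground truth
#'
#' Runs the generator described by `spec` and, if `dir` is given, writes
#' the lineage table (shared CSV schema) plus a sidecar JSON with the
#' ground truth; the truth never enters the data table, so synthetic files
#' are interchangeable with experimental ones.
#'
#' @param spec A [synthetic_spec()].
#' @param dir Optional output directory.
#' @return List with `tree` (a [lineage_tree()]), `truth` (named list) and,
#'   if written, `csv` and `json` paths.
#' @export
generate_synthetic <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  gen_time <- log(2) / spec$cc$beta0
  n_gen <- max(1L, floor(spec$duration / gen_time))
  if (spec$generator == "parametric_sine") {
    trees <- lapply(seq_len(spec$n_lineages), function(i)
      sine_lineage(spec, lineage_id = i, n_generations = n_gen))
    tree <- rbind_trees_list(trees)
    truth <- list(generator = "parametric_sine",
                  amplitude_cv = spec$amplitude_cv, period = spec$period,
                  period_cv = spec$period_cv)
  } else if (spec$generator == "toy_model") {
    tp <- spec$toy
    trees <- lapply(seq_len(spec$n_lineages), function(i)
      toy_lineage(tp, n_generations = n_gen, lineage_id = i))
    tree <- rbind_trees_list(trees)
    truth <- list(generator = "toy_model", omega = tp$omega,
                  gamma_ext = tp$gamma_ext, q = tp$q)
  } else {
    tree <- simulate_lineages(spec$n_lineages, params = spec$params,
                              noise = spec$noise, cc = spec$cc,
                              n_generations = n_gen)
    truth <- list(generator = "full_model", omega = spec$noise$omega,
                  gamma_ext = spec$noise$gamma_ext, q = spec$noise$q)
  }
  out <- list(tree = tree, truth = truth)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    out$csv <- file.path(dir, "lineages.csv")
    out$json <- file.path(dir, "truth.json")
    write_lineage_csv(tree, out$csv)
    jsonlite::write_json(truth, out$json, auto_unbox = TRUE, digits = NA)
  }
  out
}

# branched sinusoid generator: peaks at times t_k with heights A_k; between
# consecutive peaks x(t) = A(t) 0.5 (1 + cos(2 pi (t - t_k) / P_k)) with the
# envelope interpolated linearly from A_k to A_{k+1}.  Period and next peak
# height are redrawn at every completed cycle, so sister branches (which
# copy the oscillator state at division) decorrelate on the cycle
# timescale; multiplicative white noise models measurement error.
sine_lineage <- function(spec, lineage_id, n_generations) {
  sdlog <- sqrt(log(1 + spec$amplitude_cv^2))
  draw_A <- function() stats::rlnorm(1, -sdlog^2 / 2, sdlog)
  draw_P <- function()
    max(spec$frame_interval * 2,
        stats::rnorm(1, spec$period, spec$period_cv * spec$period))
  Td <- log(2) / spec$cc$beta0
  frame_dt <- spec$frame_interval
  all_frames <- seq(frame_dt, by = frame_dt,
                    length.out = ceiling((n_generations + 1) * Td / frame_dt))
  state0 <- list(t_peak = 0, P = draw_P(), A = draw_A(), A_next = draw_A())
  stack <- list(list(st = state0, id = 1L, parent = NA_integer_,
                     birth = 0, gen = 0L))
  cells <- list()
  frames <- list()
  while (length(stack)) {
    item <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    st <- item$st
    t_div <- item$birth + Td
    fr <- all_frames[all_frames > item$birth + 1e-9 &
                       all_frames <= t_div + 1e-9]
    x <- numeric(length(fr))
    for (i in seq_along(fr)) {
      while (fr[i] >= st$t_peak + st$P) {
        st$t_peak <- st$t_peak + st$P
        st$A <- st$A_next
        st$A_next <- draw_A()
        st$P <- draw_P()
      }
      u <- (fr[i] - st$t_peak) / st$P
      env <- st$A + (st$A_next - st$A) * u
      x[i] <- env * 0.5 * (1 + cos(2 * pi * u)) *
        (1 + spec$frame_noise_cv * stats::rnorm(1))
    }
    k <- length(cells) + 1L
    cells[[k]] <- data.frame(lineage_id = lineage_id, cell_id = item$id,
                             parent_id = item$parent,
                             birth_time = item$birth,
                             division_time = t_div)
    if (length(fr))
      frames[[k]] <- data.frame(lineage_id = lineage_id,
                                cell_id = item$id, time = fr,
                                fluorescence = x)
    if (item$gen < n_generations) {
      for (j in 1:2)
        stack[[length(stack) + 1]] <-
          list(st = st, id = 2L * item$id + (j - 1L), parent = item$id,
               birth = t_div, gen = item$gen + 1L)
    }
  }
  lineage_tree(do.call(rbind, cells),
               do.call(rbind, frames[!vapply(frames, is.null, logical(1))]),
               frame_dt = frame_dt)
}

rbind_trees_list <- function(trees) {
  lineage_tree(do.call(rbind, lapply(trees, `[[`, "cells")),
               do.call(rbind, lapply(trees, `[[`, "frames")),
               frame_dt = trees[[1]]$frame_dt)
}

#' Write / read lineage trees in the shared CSV schema
#'
#' One row per frame with columns `lineage_id`, `cell_id`, `parent_id`
#' (empty for progenitors), `birth_time_min`, `division_time_min`,
#' `frame_time_min`, `fluorescence` -- the same schema for simulated and
#' experimental-style data, so the statistics pipeline cannot tell them
#' apart.
#'
#' @param tree A [lineage_tree()].
#' @param path CSV file path.
#' @return `write_lineage_csv()` returns `path` invisibly.
#' @export
write_lineage_csv <- function(tree, path) {
  stopifnot(inherits(tree, "lineage_tree"))
  m <- merge(tree$frames, tree$cells,
             by = c("lineage_id", "cell_id"), sort = FALSE)
  out <- data.frame(lineage_id = m$lineage_id, cell_id = m$cell_id,
                    parent_id = m$parent_id, birth_time_min = m$birth_time,
                    division_time_min = m$division_time,
                    frame_time_min = m$time, fluorescence = m$fluorescence)
  out <- out[order(out$lineage_id, out$cell_id, out$frame_time_min), ]
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_lineage_csv
#' @param dialect `"csv"` for the native schema, or `"table"` for an
#'   arbitrary delimited table (e.g. a spreadsheet export) with the column
#'   mapping given explicitly in `col_map`.
#' @param col_map Named character vector mapping the native column names
#'   (`lineage_id`, `cell_id`, `parent_id`, `birth_time_min`,
#'   `division_time_min`, `frame_time_min`, `fluorescence`) to the columns
#'   of the foreign table; required for `dialect = "table"`.
#' @param sep Field separator for `dialect = "table"`.
#' @return `read_lineage_table()` returns a validated [lineage_tree()];
#'   row order in the file is irrelevant.
#' @export
read_lineage_table <- function(path, dialect = c("csv", "table"),
                               col_map = NULL, sep = ",") {
  dialect <- match.arg(dialect)
  native <- c("lineage_id", "cell_id", "parent_id", "birth_time_min",
              "division_time_min", "frame_time_min", "fluorescence")
  if (dialect == "csv") {
    d <- utils::read.csv(path)
    missing_cols <- setdiff(native, names(d))
    if (length(missing_cols))
      stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  } else {
    if (is.null(col_map) || !all(native %in% names(col_map)))
      stop("dialect = \"table\" requires col_map naming all of: ",
           paste(native, collapse = ", "))
    raw <- utils::read.table(path, header = TRUE, sep = sep,
                             stringsAsFactors = FALSE)
    missing_cols <- setdiff(unname(col_map), names(raw))
    if (length(missing_cols))
      stop("column(s) not in file: ", paste(missing_cols, collapse = ", "))
    d <- stats::setNames(raw[unname(col_map)], names(col_map))
  }
  key <- paste(d$lineage_id, d$cell_id)
  first <- !duplicated(key)
  cells <- data.frame(lineage_id = d$lineage_id[first],
                      cell_id = d$cell_id[first],
                      parent_id = d$parent_id[first],
                      birth_time = d$birth_time_min[first],
                      division_time = d$division_time_min[first])
  cells$parent_id[cells$parent_id %in% c("", NA)] <- NA
  if (is.character(cells$cell_id) &&
        !anyNA(suppressWarnings(as.integer(cells$cell_id)))) {
    cells$cell_id <- as.integer(cells$cell_id)
    cells$parent_id <- as.integer(cells$parent_id)
  }
  cells <- cells[order(cells$lineage_id, cells$cell_id), ]
  frames <- data.frame(lineage_id = d$lineage_id, cell_id = d$cell_id,
                       time = d$frame_time_min,
                       fluorescence = d$fluorescence)
  if (is.character(frames$cell_id) && is.integer(cells$cell_id))
    frames$cell_id <- as.integer(frames$cell_id)
  frames <- frames[order(frames$lineage_id, frames$cell_id, frames$time), ]
  tm <- sort(unique(frames$time))
  frame_dt <- if (length(tm) > 1) min(diff(tm)) else 3
  lineage_tree(cells, frames, frame_dt = frame_dt)
}
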