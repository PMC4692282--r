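# hand-built two-generation lineage tree: progenitor (id 1) divides at
# t_div into sisters 2 and 3 whose fluorescence is supplied by f2/f3
toy_tree <- function(f2, f3, t_div = 30, t_end = 90, frame_dt = 3,
                     lineage_id = 1L, f1 = NULL) {
  fr1 <- seq(frame_dt, t_div, by = frame_dt)
  fr2 <- seq(t_div + frame_dt, t_end, by = frame_dt)
  if (is.null(f1)) f1 <- function(t) 1 + sin(2 * pi * t / 41)
  cells <- data.frame(
    lineage_id = lineage_id, cell_id = 1:3,
    parent_id = c(NA, 1L, 1L),
    birth_time = c(0, t_div, t_div),
    division_time = c(t_div, t_end, t_end)
  )
  frames <- rbind(
    data.frame(lineage_id = lineage_id, cell_id = 1L, time = fr1,
               fluorescence = f1(fr1)),
    data.frame(lineage_id = lineage_id, cell_id = 2L, time = fr2,
               fluorescence = f2(fr2)),
    data.frame(lineage_id = lineage_id, cell_id = 3L, time = fr2,
               fluorescence = f3(fr2))
  )
  lineage_tree(cells, frames, frame_dt = frame_dt)
}

# caterpillar lineage: at each of n_div divisions one daughter is a leaf
# and the other divides again, giving one sister pair per division; the
# pair's fluorescence over its window comes from make_pair(k) = list(f, g)
caterpillar_tree <- function(n_div, make_pair, window = 30, frame_dt = 3,
                             lineage_id = 1L) {
  cells <- data.frame(lineage_id = lineage_id, cell_id = 1L,
                      parent_id = NA_integer_, birth_time = 0,
                      division_time = window)
  frames <- data.frame(lineage_id = lineage_id, cell_id = 1L,
                       time = seq(frame_dt, window, frame_dt),
                       fluorescence = 1)
  spine <- 1L
  next_id <- 2L
  for (k in seq_len(n_div)) {
    t0 <- k * window
    t1 <- t0 + window
    tt <- seq(t0 + frame_dt, t1, frame_dt)
    pair <- make_pair(k)
    ids <- c(next_id, next_id + 1L)
    next_id <- next_id + 2L
    cells <- rbind(cells, data.frame(lineage_id = lineage_id,
                                     cell_id = ids, parent_id = spine,
                                     birth_time = t0,
                                     division_time = t1))
    frames <- rbind(frames,
                    data.frame(lineage_id = lineage_id, cell_id = ids[1],
                               time = tt, fluorescence = pair[[1]](tt)),
                    data.frame(lineage_id = lineage_id, cell_id = ids[2],
                               time = tt, fluorescence = pair[[2]](tt)))
    spine <- ids[2]
  }
  # the last spine cell must not look divided
  cells$division_time[cells$cell_id == spine] <- n_div * window + window
  lineage_tree(cells, frames, frame_dt = frame_dt)
}

# pool several single-lineage trees
pool_trees <- function(trees) {
  lineage_tree(do.call(rbind, lapply(trees, `[[`, "cells")),
               do.call(rbind, lapply(trees, `[[`, "frames")),
               frame_dt = trees[[1]]$frame_dt)
}

# plain (non-delayed) Gillespie SSA used as an independent oracle
standard_ssa <- function(rates, deltas, counts, t_end) {
  t <- 0
  repeat {
    a <- vapply(seq_along(rates), function(i) rates[[i]](counts),
                numeric(1))
    a0 <- sum(a)
    if (a0 <= 0) break
    t <- t + stats::rexp(1, a0)
    if (t >= t_end) break
    j <- sample.int(length(a), 1, prob = a)
    counts <- counts + deltas[[j]]
  }
  counts
}
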