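test_that("parametric lineages hit the requested targets", {
  set.seed(601)
  spec <- synthetic_spec("parametric_sine", n_lineages = 6,
                         duration = 180, amplitude_cv = 0.47,
                         period = 41, period_cv = 0.11)
  out <- generate_synthetic(spec)
  s <- summary_stats(out$tree)
  expect_equal(s$amplitude_cv, 0.47, tolerance = 0.075)
  expect_equal(s$mean_period, 41, tolerance = 0.05)
  expect_equal(s$period_cv, 0.11, tolerance = 0.35)
  # enough division rounds within a 3-h movie at a 23.5-min generation
  n_gen <- max(vapply(strtoi(out$tree$cells$cell_id), function(i)
    floor(log2(i)), numeric(1)))
  expect_gte(n_gen, 5)
  expect_equal(out$truth$amplitude_cv, 0.47)
})

test_that("infeasible parametric targets are rejected", {
  expect_error(synthetic_spec(amplitude_cv = -0.1), "infeasible")
  expect_error(synthetic_spec(duration = 100, frame_interval = 3),
               "multiple")
})

test_that("lineage tables survive a write/read round trip", {
  set.seed(602)
  spec <- synthetic_spec("parametric_sine", n_lineages = 2,
                         duration = 120)
  dir <- withr::local_tempdir()
  out <- generate_synthetic(spec, dir = dir)
  expect_true(file.exists(out$csv))
  expect_true(file.exists(out$json))
  back <- read_lineage_table(out$csv)
  expect_equal(back$cells[order(back$cells$lineage_id,
                                back$cells$cell_id), ],
               out$tree$cells[order(out$tree$cells$lineage_id,
                                    out$tree$cells$cell_id), ],
               ignore_attr = TRUE)
  o1 <- order(back$frames$lineage_id, back$frames$cell_id,
              back$frames$time)
  o2 <- order(out$tree$frames$lineage_id, out$tree$frames$cell_id,
              out$tree$frames$time)
  expect_equal(back$frames$fluorescence[o1],
               out$tree$frames$fluorescence[o2])
  # the ground truth lives in the sidecar, not the data table
  expect_false(any(grepl("amplitude_cv", readLines(out$csv))))
  truth <- jsonlite::read_json(out$json)
  expect_equal(truth$amplitude_cv, 0.47)
})

test_that("parsing is insensitive to row order and names offenders", {
  set.seed(603)
  spec <- synthetic_spec("parametric_sine", n_lineages = 2,
                         duration = 90)
  dir <- withr::local_tempdir()
  out <- generate_synthetic(spec, dir = dir)
  d <- utils::read.csv(out$csv)
  shuffled <- d[sample(nrow(d)), ]
  p2 <- file.path(dir, "shuffled.csv")
  utils::write.csv(shuffled, p2, row.names = FALSE, na = "")
  t1 <- read_lineage_table(out$csv)
  t2 <- read_lineage_table(p2)
  expect_equal(t2$cells, t1$cells, ignore_attr = TRUE)
  # orphan parent ids are reported by id
  bad <- d
  bad$parent_id[bad$cell_id == 2] <- 99
  p3 <- file.path(dir, "orphan.csv")
  utils::write.csv(bad, p3, row.names = FALSE, na = "")
  expect_error(read_lineage_table(p3), "orphan parent id\\(s\\) 99")
})

test_that("foreign delimited tables load through a column mapping", {
  set.seed(604)
  spec <- synthetic_spec("parametric_sine", n_lineages = 1,
                         duration = 90)
  dir <- withr::local_tempdir()
  out <- generate_synthetic(spec, dir = dir)
  d <- utils::read.csv(out$csv)
  foreign <- data.frame(run = d$lineage_id, cell = d$cell_id,
                        mother = d$parent_id, born = d$birth_time_min,
                        split = d$division_time_min,
                        t = d$frame_time_min, gfp = d$fluorescence)
  p <- file.path(dir, "foreign.tsv")
  utils::write.table(foreign, p, sep = "\t", row.names = FALSE)
  cm <- c(lineage_id = "run", cell_id = "cell", parent_id = "mother",
          birth_time_min = "born", division_time_min = "split",
          frame_time_min = "t", fluorescence = "gfp")
  tr <- read_lineage_table(p, dialect = "table", col_map = cm, sep = "\t")
  expect_equal(tr$cells, read_lineage_table(out$csv)$cells,
               ignore_attr = TRUE)
  expect_error(read_lineage_table(p, dialect = "table"), "col_map")
})

test_that("model generators record their noise levels as ground truth", {
  set.seed(605)
  spec <- synthetic_spec("toy_model", n_lineages = 2, duration = 120,
                         toy = toy_params(omega = 300, gamma_ext = 0.1))
  out <- generate_synthetic(spec)
  expect_equal(out$truth$omega, 300)
  expect_equal(out$truth$gamma_ext, 0.1)
  expect_s3_class(out$tree, "lineage_tree")
})
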