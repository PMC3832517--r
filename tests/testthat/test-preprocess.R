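test_that("read_trials parses well-formed files and both delimiters", {
  tr <- make_trials(c(500, 600, 700), stimulus_id = c("s1", "s2", "s3"))
  p_csv <- write_trials_csv(tr)
  got <- read_trials(p_csv)
  expect_equal(nrow(got), 3)
  expect_equal(got$latency_ms, c(500, 600, 700))
  expect_type(got$error, "logical")
  expect_equal(nrow(attr(got, "rejections")), 0)

  p_tsv <- write_trials_csv(tr, sep = "\t")
  expect_equal(read_trials(p_tsv)$latency_ms, c(500, 600, 700))
  expect_equal(read_trials(p_tsv, delim = "tab")$latency_ms,
               c(500, 600, 700))
})

test_that("read_trials rejects bad rows and reports missing columns", {
  tr <- make_trials(c(500, 600, 700), stimulus_id = c("s1", "s2", "s3"))
  tr$latency_ms <- as.character(tr$latency_ms)
  tr$latency_ms[2] <- "oops"
  p <- write_trials_csv(tr)
  expect_message(got <- read_trials(p), "rejected")
  expect_equal(nrow(got), 2)
  rej <- attr(got, "rejections")
  expect_equal(rej$row, 2)
  expect_match(rej$reason, "latency")

  tr2 <- make_trials(500)
  tr2$latency_ms <- NULL
  p2 <- write_trials_csv(tr2)
  expect_error(read_trials(p2), "latency_ms")

  # header only
  p3 <- tempfile(fileext = ".csv")
  writeLines(paste(names(make_trials(1)), collapse = ","), p3)
  expect_silent(empty <- read_trials(p3))
  expect_equal(nrow(empty), 0)
})

test_that("latency filter keeps the boundaries and is idempotent", {
  tr <- make_trials(c(250, 300, 5000, 10000, 10001),
                    stimulus_id = paste0("s", 1:5))
  kept <- filter_trials(tr)
  expect_equal(kept$latency_ms, c(300, 5000, 10000))
  expect_equal(sum(attr(kept, "n_removed")), 2)

  again <- filter_trials(kept)
  expect_equal(again, kept, ignore_attr = TRUE)

  ok <- make_trials(c(400, 900))
  expect_equal(filter_trials(ok)$latency_ms, c(400, 900))

  out <- make_trials(c(100, 20000))
  expect_warning(none <- filter_trials(out), "outside")
  expect_equal(nrow(none), 0)
})

test_that("respondent exclusions follow the configured criteria", {
  # 25 critical trials, 3 of them (12%) faster than 300 ms
  fast <- make_trials(c(rep(600, 22), 250, 260, 270), respondent_id = "Rfast",
                      stimulus_id = "s1")
  clean <- make_trials(rep(650, 25), respondent_id = "Rok",
                       stimulus_id = "s1")
  trials <- rbind(fast, clean)
  res <- apply_respondent_exclusions(trials)
  expect_equal(res$report$respondent_id, "Rfast")
  expect_equal(res$report$criterion, "fast_fraction")
  expect_equal(unique(res$trials$respondent_id), "Rok")

  # disabling all criteria returns the input unchanged
  off <- exclusion_criteria(require_all_critical_blocks = FALSE,
                            max_fast_fraction = NA, max_error_rate = NA)
  res2 <- apply_respondent_exclusions(trials, off)
  expect_equal(nrow(res2$report), 0)
  expect_equal(res2$trials$latency_ms, trials$latency_ms)

  # error-rate and missing-block criteria
  errs <- make_trials(rep(700, 10), respondent_id = "Rerr",
                      error = c(rep(TRUE, 4), rep(FALSE, 6)))
  miss <- make_trials(rep(700, 5), respondent_id = "Rmiss", block = 3L)
  both <- rbind(make_trials(rep(700, 5), respondent_id = "Rfull",
                            block = rep(c(3L, 4L), length.out = 5)),
                errs, miss)
  rep3 <- apply_respondent_exclusions(both)$report
  expect_true(all(c("Rerr", "Rmiss") %in% rep3$respondent_id))
  expect_false("Rfull" %in% rep3$respondent_id)
})

test_that("aggregation means latencies per cell and records missing cells", {
  tr <- rbind(
    make_trials(c(600, 800)),                                  # one cell, 2 trials
    make_trials(934, condition = "HOG_HEB"),                   # single trial
    make_trials(500, respondent_id = "R2", condition = "HEG_HOB"),
    make_trials(1000, stimulus_id = "tragic",
                stimulus_class = "attribute_negative"),
    make_trials(700, stimulus_id = "face1", stimulus_class = "target"),
    make_trials(700, block = 1L, block_role = "practice",
                condition = NA)
  )
  cells <- aggregate_cells(tr)
  # grid: 2 respondents x 2 conditions x 2 attribute stimuli
  expect_equal(nrow(cells), 8)
  one <- cells[cells$respondent_id == "R1" & cells$condition == "HEG_HOB" &
                 cells$stimulus_id == "pleasure", ]
  expect_equal(one$mean_latency_ms, 700)
  expect_equal(one$n_trials, 2L)
  single <- cells[cells$respondent_id == "R1" &
                    cells$condition == "HOG_HEB" &
                    cells$stimulus_id == "pleasure", ]
  expect_equal(single$mean_latency_ms, 934)
  holes <- cells[cells$n_trials == 0, ]
  expect_gt(nrow(holes), 0)
  expect_true(all(is.na(holes$mean_latency_ms)))
  # target and practice trials never form cells
  expect_false("face1" %in% cells$stimulus_id)
})

test_that("error trials can be excluded from cell means", {
  tr <- make_trials(c(600, 1200), error = c(FALSE, TRUE))
  with_err <- aggregate_cells(tr, include_error_trials = TRUE)
  no_err <- aggregate_cells(tr, include_error_trials = FALSE)
  expect_equal(with_err$mean_latency_ms[1], 900)
  expect_equal(no_err$mean_latency_ms[1], 600)
})

test_that("tertile cuts follow the linear-interpolation quantile", {
  cells <- data.frame(mean_latency_ms = seq(100, 900, by = 100))
  cuts <- compute_tertiles(cells)
  expect_equal(cuts$lower_cut_ms, 100 + 800 / 3, tolerance = 1e-12)
  expect_equal(cuts$upper_cut_ms, 100 + 1600 / 3, tolerance = 1e-12)

  same <- compute_tertiles(data.frame(mean_latency_ms = rep(700, 5)))
  expect_equal(same$lower_cut_ms, 700)
  expect_equal(same$upper_cut_ms, 700)

  tri <- compute_tertiles(data.frame(mean_latency_ms = c(1, 2, 3)))
  expect_lte(tri$lower_cut_ms, tri$upper_cut_ms)

  expect_error(compute_tertiles(data.frame(mean_latency_ms = c(1, 2))),
               "at least 3")
})

test_that("discretization maps latency to 3/2/1 with ties going fast", {
  cuts <- structure(list(lower_cut_ms = 300, upper_cut_ms = 600),
                    class = "tertile_cuts")
  cells <- data.frame(mean_latency_ms = c(250, 450, 800, 300, 600, NA))
  got <- discretize_cells(cells, cuts)$category
  expect_equal(got, c(3L, 2L, 1L, 3L, 2L, NA))

  all_slow <- data.frame(mean_latency_ms = c(700, 900, 1200))
  expect_equal(discretize_cells(all_slow, cuts)$category, rep(1L, 3))
})

test_that("tertile categories are balanced and antitone in latency", {
  set.seed(31)
  for (N in c(30, 91, 200)) {
    x <- data.frame(mean_latency_ms = stats::runif(N, 300, 2000))
    cells <- discretize_cells(x, compute_tertiles(x))
    counts <- table(cells$category)
    expect_true(all(counts >= floor(N / 3) & counts <= ceiling(N / 3)))
    ord <- order(cells$mean_latency_ms)
    expect_true(all(diff(cells$category[ord]) <= 0))
  }
})

test_that("the pipeline filters trials before aggregating", {
  # cell latencies 200 and 800: mean of raw trials would be 500 (category
  # differs); the fixed order filter -> aggregate must yield mean 800
  tr <- rbind(
    make_trials(c(200, 800)),
    make_trials(c(400, 500), condition = "HOG_HEB"),
    make_trials(c(600, 700), respondent_id = "R2"),
    make_trials(c(900, 1000), respondent_id = "R2", condition = "HOG_HEB")
  )
  prep <- preprocess_trials(tr, criteria = exclusion_criteria(
    require_all_critical_blocks = FALSE, max_fast_fraction = NA,
    max_error_rate = NA))
  cell <- prep$cells[prep$cells$respondent_id == "R1" &
                       prep$cells$condition == "HEG_HOB", ]
  expect_equal(cell$mean_latency_ms, 800)
  expect_equal(cell$n_trials, 1L)
})
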