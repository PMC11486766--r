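test_that("window length follows the reciprocal rule", {
  expect_identical(window_length_seconds(0.01), 100)
  expect_identical(window_length_seconds(1.0), 1)
  expect_identical(window_length_seconds(0.008), 125)
  expect_error(window_length_seconds(0), class = "fcp_domain_error")
  expect_error(window_length_seconds(-0.1), class = "fcp_domain_error")
})

test_that("window length in volumes floors the ratio and rejects tiny windows", {
  expect_identical(window_length_volumes(100, 2.0), 50L)
  expect_identical(window_length_volumes(100, 2.2), 45L)
  expect_identical(window_length_volumes(100, 3.0), 33L)
  expect_error(window_length_volumes(100, 100), class = "fcp_window_error")
})

test_that("sliding-window FC computes Pearson correlations per window", {
  spec <- sliding_window_spec(L = 4, step_volumes = 1)
  x <- rnorm(12)
  ts <- rbind(x, 2 * x + 1, -x)
  dfc <- sliding_window_fc(ts, spec, tr = 1)
  expect_identical(dim(dfc$windows)[3], 9L)
  for (w in 1:9) {
    expect_equal(dfc$windows[1, 2, w], 1)
    expect_equal(dfc$windows[1, 3, w], -1)
  }

  # hand-computed 3-volume toy: cor((1,2,3), (1,3,2)) = 0.5
  toy <- rbind(c(1, 2, 3), c(1, 3, 2))
  d <- sliding_window_fc(toy, sliding_window_spec(L = 3, step_volumes = 1),
                         tr = 1)
  expect_equal(d$windows[1, 2, 1], 0.5)
})

test_that("every FC matrix is symmetric with unit diagonal and bounded entries", {
  set.seed(31)
  ts <- matrix(rnorm(8 * 60), 8, 60)
  dfc <- sliding_window_fc(ts, sliding_window_spec(L = 20, step_volumes = 3),
                           tr = 1)
  for (w in seq_len(dim(dfc$windows)[3])) {
    m <- dfc$windows[, , w]
    expect_identical(max(abs(m - t(m))), 0)
    expect_equal(unname(diag(m)), rep(1, 8))
    expect_true(all(m >= -1 & m <= 1))
  }
})

test_that("Pearson windows are invariant to positive affine rescaling", {
  set.seed(12)
  ts <- matrix(rnorm(5 * 40), 5, 40)
  ts2 <- ts
  ts2[2, ] <- 3.7 * ts[2, ] + 11
  a <- sliding_window_fc(ts, sliding_window_spec(L = 10), tr = 1)
  b <- sliding_window_fc(ts2, sliding_window_spec(L = 10), tr = 1)
  expect_lt(max(abs(a$windows - b$windows)), 1e-12)
})

test_that("window counts match the enumeration oracle", {
  set.seed(99)
  for (i in 1:50) {
    n_i <- sample(2:30, 1)
    n_t <- n_i + sample(0:80, 1)
    step <- sample(1:7, 1)
    ts <- matrix(rnorm(3 * n_t), 3, n_t)
    dfc <- sliding_window_fc(ts, sliding_window_spec(L = n_i, step_volumes = step),
                             tr = 1)
    expect_identical(dim(dfc$windows)[3], count_windows(n_t, n_i, step))
  }
})

test_that("zero-variance segments raise a condition carrying ROI and window", {
  ts <- matrix(rnorm(4 * 30), 4, 30)
  ts[3, 11:20] <- 5  # constant only inside some windows
  err <- tryCatch(
    sliding_window_fc(ts, sliding_window_spec(L = 10), tr = 1, subject_id = "s1"),
    fcp_zero_variance_window = function(e) e)
  expect_s3_class(err, "fcp_zero_variance_window")
  expect_identical(err$roi, 3L)
  expect_identical(err$subject, "s1")
  expect_true(err$window >= 1)
})

test_that("the cohort screen excludes exactly the planted constant-ROI subjects", {
  gen <- make_study_cohort(planted = 2, seed = 6, n_subjects = 6, W = 30,
                           n_constant = 3)
  spec <- sliding_window_spec(W_target = 30)
  flagged <- gen$truth$qc_excluded_subjects
  kept_ids <- c()
  excl_ids <- c()
  for (set in gen$groups) {
    scr <- tryCatch(screen_subjects(set, spec),
                    fcp_empty_cohort_error = function(e) NULL)
    if (is.null(scr)) {
      excl_ids <- c(excl_ids, vapply(set$subjects, `[[`, "", "subject_id"))
    } else {
      kept_ids <- c(kept_ids, vapply(scr$kept, `[[`, "", "subject_id"))
      excl_ids <- c(excl_ids, scr$excluded$subject_id)
    }
  }
  expect_setequal(excl_ids, flagged)
  expect_length(intersect(kept_ids, flagged), 0)

  # no constant signals -> everyone kept
  gen2 <- make_study_cohort(planted = 2, seed = 6, n_subjects = 4, W = 30,
                            n_constant = 0)
  scr2 <- screen_subjects(gen2$groups$g, spec)
  expect_length(scr2$kept, 4)
  expect_identical(nrow(scr2$excluded), 0L)

  # all subjects constant -> empty-cohort error
  roi_ids <- letters[1:3]
  subs <- lapply(1:2, function(i) {
    list(subject_id = paste0("s", i), group = "g", tr = 1,
         signal = matrix(1, 3, 20))
  })
  allconst <- roi_timeseries_set(subs, roi_ids)
  expect_error(screen_subjects(allconst, sliding_window_spec(L = 5)),
               class = "fcp_empty_cohort_error")
})

test_that("truncation keeps the first windows and validates scan length", {
  # NYU-like geometry: 180 volumes, drop 4, 50-volume window, step 1
  ts <- matrix(rnorm(3 * 180), 3, 180)
  ts <- drop_initial_volumes(ts, 4)
  dfc <- sliding_window_fc(ts, sliding_window_spec(L = 100), tr = 2,
                           subject_id = "nyu")
  expect_identical(dim(dfc$windows)[3], 127L)
  tr120 <- truncate_windows(dfc, 120)
  expect_identical(dim(tr120$windows)[3], 120L)
  expect_identical(tr120$windows[, , 1:120], dfc$windows[, , 1:120])

  expect_identical(truncate_windows(tr120, 120), tr120)
  expect_error(truncate_windows(tr120, 121), class = "fcp_scan_length_error")
})
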