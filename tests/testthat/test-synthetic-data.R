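test_that("community memberships have the requested geometry", {
  # zero overlap forces disjoint sets
  sets <- generate_memberships(10, 2, 3, 0, seed = 1)
  expect_length(sets, 2)
  expect_length(intersect(sets[[1]], sets[[2]]), 0)
  expect_true(all(lengths(sets) == 3))

  # consecutive sets share exactly round(overlap * size) ROIs
  sets <- generate_memberships(6, 2, 3, 1 / 3, seed = 7)
  expect_length(intersect(sets[[1]], sets[[2]]), 1)

  for (ov in c(0, 0.2, 0.4)) {
    sets <- generate_memberships(60, 4, 10, ov, seed = 3)
    shared <- round(ov * 10)
    for (k in 2:4) {
      expect_length(intersect(sets[[k - 1]], sets[[k]]), shared)
    }
  }

  # infeasible geometry errors
  expect_error(generate_memberships(4, 3, 3, 0, seed = 0),
               class = "fcp_config_error")

  # determinism
  expect_identical(generate_memberships(50, 3, 8, 0.25, seed = 11),
                   generate_memberships(50, 3, 8, 0.25, seed = 11))
})

test_that("generated time series are deterministic and carry QC targets", {
  cfg <- synth_config(
    n_rois = 20,
    groups = list(synth_group("a", 4, 2, 2.0, 80),
                  synth_group("b", 3, 2, 2.0, 80)),
    community_size = 5, overlap_fraction = 0, snr = 3,
    n_constant_roi_subjects = 3, seed = 5)
  g1 <- generate_timeseries(cfg)
  g2 <- generate_timeseries(cfg)
  expect_identical(g1, g2)

  expect_length(g1$truth$qc_excluded_subjects, 3)
  n_const <- 0
  for (set in g1$groups) for (s in set$subjects) {
    if (any(apply(s$signal, 1, stats::sd) == 0)) {
      n_const <- n_const + 1
      expect_true(s$subject_id %in% g1$truth$qc_excluded_subjects)
    }
  }
  expect_identical(n_const, 3)
})

test_that("planted communities reproduce membership blocks in window correlations", {
  # near-noise-free cohort; check each community at the window where its
  # planted correlation course peaks
  gen <- make_study_cohort(planted = 3, seed = 2, n_subjects = 3, W = 60,
                           snr = 50)
  set <- gen$groups$g
  mem <- gen$truth$pattern_membership$g
  prof <- gen$truth$temporal_profiles$g
  s <- set$subjects[[1]]
  dfc <- sliding_window_fc(s$signal, sliding_window_spec(), s$tr)
  for (r in seq_along(mem)) {
    w <- which.max(prof[r, seq_len(dim(dfc$windows)[3])])
    block <- dfc$windows[mem[[r]], mem[[r]], w]
    expect_gt(mean(block[upper.tri(block)]), 0.95)
  }
})

test_that("planted temporal profiles are recovered by CP on the group tensor", {
  gen <- make_study_cohort(planted = 2, seed = 4, n_subjects = 12, W = 120)
  scr <- screen_subjects(gen$groups$g, sliding_window_spec(W_target = 120))
  dfc <- lapply(scr$kept, truncate_windows, W_target = 120)
  G <- build_group_tensor(dfc, W_target = 120)
  m <- nncp(G, 3, n_restarts = 2, max_iter = 200, tol = 1e-7, seed = 9)
  prof <- gen$truth$temporal_profiles$g[, 1:120]
  # each planted profile correlates strongly with its best temporal loading
  for (r in 1:2) {
    cors <- abs(cor(prof[r, ], m$temporal))
    expect_gt(max(cors), 0.9)
  }
})

test_that("feature tables plant standardized effects of the requested size", {
  eff <- data.frame(feature = c("ALFF", "GMV"), roi = c(5L, 9L), d = c(1, -0.8))
  cfg <- synth_config(
    n_rois = 12,
    groups = list(synth_group("a", 400, 2, 2, 80),
                  synth_group("b", 400, 2, 2, 80)),
    community_size = 4, overlap_fraction = 0, effect_rois = eff, seed = 21)
  tabs <- generate_feature_tables(cfg)
  expect_named(tabs, c("ALFF", "fALFF", "GMV"))
  expect_identical(tabs, generate_feature_tables(cfg))

  # empirical standardized mean difference within +/- 0.2 of d for n >= 50
  d_hat <- function(a, b) {
    (mean(b) - mean(a)) / sqrt((stats::var(a) + stats::var(b)) / 2)
  }
  expect_lt(abs(d_hat(tabs$ALFF$a[, 5], tabs$ALFF$b[, 5]) - 1), 0.2)
  expect_lt(abs(d_hat(tabs$GMV$a[, 9], tabs$GMV$b[, 9]) - (-0.8)), 0.2)
  # null ROIs differ only by sampling noise
  expect_lt(abs(d_hat(tabs$fALFF$a[, 3], tabs$fALFF$b[, 3])), 0.5)

  expect_error(
    synth_config(n_rois = 12,
                 groups = list(synth_group("a", 2, 1, 2, 80),
                               synth_group("b", 2, 1, 2, 80)),
                 effect_rois = data.frame(feature = "REHO", roi = 1, d = 1)),
    class = "fcp_config_error")
})

test_that("toy atlas assignment matches its stored truth on separated clusters", {
  atl <- generate_atlas(n_rois = 40, n_networks = 4, seed = 8)
  expect_identical(nrow(atl$centroids), 40L)
  nm <- assign_networks(atl$centroids, atl$reference)
  # reference clusters are tight (sd 3) around well-separated centers, so
  # nearest-reference and nearest-center agree
  expect_gt(mean(nm == atl$true_mapping), 0.97)

  one <- generate_atlas(10, 1, seed = 2)
  nm1 <- assign_networks(one$centroids, one$reference)
  expect_true(all(nm1 == nm1[1]))

  expect_error(generate_atlas(3, 5, seed = 1), class = "fcp_config_error")
})

test_that("cohorts round-trip through the on-disk TSV layout", {
  cfg <- synth_config(
    n_rois = 8,
    groups = list(synth_group("a", 2, 2, 2.0, 70),
                  synth_group("b", 2, 2, 2.0, 70)),
    community_size = 3, overlap_fraction = 0,
    n_constant_roi_subjects = 0, seed = 3)
  gen <- generate_timeseries(cfg)
  feats <- generate_feature_tables(cfg)
  atl <- generate_atlas(8, 2, seed = 3)
  dir <- withr::local_tempdir()
  mf <- write_cohort(gen, feats, atl, dir)
  expect_true(file.exists(file.path(dir, "manifest.tsv")))
  back <- read_cohort(dir)
  expect_named(back, c("a", "b"))
  orig <- gen$groups$a$subjects[[1]]$signal
  got <- back$a$subjects[[1]]$signal
  expect_equal(got, orig, tolerance = 1e-6)  # text round-trip precision
  expect_identical(back$a$subjects[[1]]$tr, 2.0)
})
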