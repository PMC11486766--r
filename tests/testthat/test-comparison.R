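test_that("network assignment takes the nearest reference with a stable tie rule", {
  cents <- data.frame(roi_id = c("r1", "r2"), x = c(0, 10), y = 0, z = 0)
  refs <- data.frame(x = c(0, 10), y = 0, z = 0, network = c("DMN", "VN"))
  nm <- assign_networks(cents, refs)
  expect_identical(unname(nm), c("DMN", "VN"))

  # exact tie -> lowest reference index
  tie <- data.frame(roi_id = "t", x = 5, y = 0, z = 0)
  expect_identical(unname(assign_networks(tie, refs)), "DMN")

  # brute-force oracle agreement on a random 2-cluster layout
  set.seed(6)
  cents2 <- data.frame(roi_id = sprintf("c%02d", 1:40),
                       x = rnorm(40, rep(c(-20, 20), each = 20), 3),
                       y = rnorm(40), z = rnorm(40))
  refs2 <- data.frame(x = c(-20, 20), y = 0, z = 0,
                      network = c("SCN", "FPN"))
  nm2 <- assign_networks(cents2, refs2)
  brute <- apply(as.matrix(cents2[, 2:4]), 1, function(p) {
    d <- sqrt(colSums((t(as.matrix(refs2[, 1:3])) - p)^2))
    refs2$network[which.min(d)]
  })
  expect_identical(unname(nm2), brute)
})

test_that("the vectorized Welch t matches stats::t.test", {
  set.seed(2)
  a <- matrix(rnorm(8 * 10), 8, 10)
  b <- matrix(rnorm(13 * 10, sd = 2), 13, 10)
  got <- roi_ttest(a, b)
  for (j in 1:10) {
    ref <- t.test(a[, j], b[, j])
    expect_equal(got$t[j], unname(ref$statistic), tolerance = 1e-9)
    expect_equal(got$p[j], ref$p.value, tolerance = 1e-9)
  }
  expect_identical(got$direction,
                   ifelse(colMeans(a) >= colMeans(b), "A>B", "A<B"))

  # textbook two-sample case, cross-checked against the Welch formula
  ref <- t.test(c(1, 2, 3, 4), c(3, 4, 5, 6))
  got2 <- roi_ttest(cbind(c(1, 2, 3, 4)), cbind(c(3, 4, 5, 6)))
  expect_equal(got2$t, unname(ref$statistic), tolerance = 1e-9)
  expect_equal(got2$p, ref$p.value, tolerance = 1e-9)

  # identical groups: t = 0, p = 1 everywhere
  same <- matrix(rnorm(20), 4, 5)
  got3 <- roi_ttest(same, same)
  expect_equal(got3$t, rep(0, 5))
  expect_equal(got3$p, rep(1, 5))

  # zero variance in both groups -> degenerate flag
  z <- roi_ttest(matrix(1, 3, 2), matrix(2, 3, 2))
  expect_true(all(z$degenerate))
  expect_equal(z$p, c(1, 1))
})

test_that("BH correction reproduces the hand example and the step-up oracle", {
  f <- fdr_correct(c(0.005, 0.02, 0.03, 0.04))
  expect_equal(f$q, c(0.02, 0.04, 0.04, 0.04))

  expect_equal(fdr_correct(1)$q, 1)
  expect_equal(fdr_correct(0.37)$q, 0.37)           # m = 1: q = p
  all1 <- fdr_correct(rep(1, 6))
  expect_equal(all1$q, rep(1, 6))
  expect_length(all1$significant, 0)

  set.seed(4)
  for (i in 1:100) {
    p <- runif(sample(1:50, 1))
    f <- fdr_correct(p)
    expect_lt(max(abs(f$q - bh_stepup(p))), 1e-12)
    expect_true(all(f$q >= p))                      # q >= p invariant
  }
  expect_error(fdr_correct(c(0.1, 1.2)), class = "fcp_domain_error")
})

test_that("feature comparisons report q-ordered top ROIs and significance", {
  set.seed(8)
  a <- matrix(rnorm(30 * 20), 30, 20)
  b <- matrix(rnorm(30 * 20), 30, 20)
  b[, 7] <- b[, 7] + 2
  colnames(a) <- colnames(b) <- sprintf("roi%02d", 1:20)
  fa <- feature_table(a, "ALFF", "g1")
  fb <- feature_table(b, "ALFF", "g2")
  cmp <- compare_features(fa, fb)
  expect_s3_class(cmp, "comparison_result")
  expect_identical(cmp$pair, c("g1", "g2"))
  expect_true(all(cmp$table$q >= cmp$table$p))
  expect_identical(cmp$table$significant, cmp$table$q < 0.05)
  expect_identical(nrow(cmp$top5), 5L)
  expect_true(all(diff(cmp$top5$q) >= 0))
  expect_identical(cmp$top5$roi[1], "roi07")
  expect_identical(cmp$table$direction[7], "A<B")
})

test_that("pattern-difference sets follow the symmetric-difference rule", {
  mk <- function(rank, roi_set, dom, group) {
    structure(list(rank = rank, lambda = 1, roi_set = roi_set,
                   dominant_networks = dom, group = group),
              class = "brain_pattern")
  }
  pats <- list(
    A = list(mk(1, c("1", "2", "3"), c(VN = 9L), "A"),
             mk(2, c("9"), c(DMN = 9L), "A")),
    B = list(mk(1, c("2", "3", "4"), c(VN = 9L), "B"),
             mk(2, c("8"), c(SCN = 9L, DMN = 6L), "B"))
  )
  groups <- match_patterns_across_groups(pats)
  pd <- pattern_difference_rois(groups, "A", "B")
  expect_setequal(pd$VN, c("1", "4"))
  # groups present in only one subtype contribute their full sets
  expect_setequal(pd$DMN, "9")
  expect_setequal(pd$`DMN+SCN`, "8")
  expect_setequal(attr(pd, "pooled"), c("1", "4", "9", "8"))

  # identical sets vanish
  pats2 <- list(A = list(mk(1, c("5", "6"), c(VN = 9L), "A")),
                B = list(mk(1, c("5", "6"), c(VN = 9L), "B")))
  pd2 <- pattern_difference_rois(match_patterns_across_groups(pats2), "A", "B")
  expect_length(pd2$VN, 0)
})

test_that("overlap reports count comparison membership per ROI", {
  sets <- list(pattern = c("A", "B"), ALFF = c("B", "C"), fALFF = c("C"),
               GMV = character(0))
  rep1 <- overlap_report(c("g1", "g2"), sets)
  expect_setequal(rep1$at_least_two, c("B", "C"))
  expect_length(rep1$more_than_two, 0)

  # permutation invariance in the order of the input sets
  rep2 <- overlap_report(c("g1", "g2"), rev(sets))
  expect_identical(rep1$at_least_two, rep2$at_least_two)

  all4 <- overlap_report(c("x", "y"),
                         list(pattern = "Z", ALFF = "Z", fALFF = "Z", GMV = "Z"))
  expect_identical(all4$more_than_two, "Z")

  empty <- overlap_report(c("x", "y"), list(pattern = character(0)))
  expect_length(empty$at_least_two, 0)

  expect_error(overlap_report(c("x", "y"), list(reho = "A")),
               class = "fcp_config_error")
})

test_that("network tallies count and sort mapped ROIs", {
  map <- setNames(c(rep("DMN", 3), "SCN"), c("a", "b", "c", "d"))
  expect_identical(network_tally(names(map), map), c(DMN = 3L, SCN = 1L))
  expect_length(network_tally(character(0), map), 0)
  expect_error(network_tally(c("a", "q"), map), class = "fcp_mapping_error")
  # loop oracle on random sets
  set.seed(3)
  big <- setNames(sample(network_labels(), 60, replace = TRUE),
                  sprintf("r%02d", 1:60))
  pick <- sample(names(big), 25)
  got <- network_tally(pick, big)
  for (nw in names(got)) {
    expect_identical(got[[nw]], sum(big[pick] == nw))
  }
})

test_that("BH-FDR controls family-wise false discoveries on null tables", {
  set.seed(77)
  n_rep <- 300
  any_fd <- logical(n_rep)
  for (i in 1:n_rep) {
    a <- matrix(rnorm(20 * 50), 20, 50)
    b <- matrix(rnorm(20 * 50), 20, 50)
    tt <- roi_ttest(a, b)
    any_fd[i] <- length(fdr_correct(tt$p)$significant) > 0
  }
  expect_lte(mean(any_fd), 0.09)  # ~alpha plus Monte-Carlo slack
})
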