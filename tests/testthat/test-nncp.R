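test_that("the block-principal-pivoting NNLS solver matches exhaustive search", {
  set.seed(17)
  for (i in 1:200) {
    r <- sample(2:4, 1)
    n <- r + sample(1:4, 1)
    A <- matrix(rnorm(n * r), n, r)
    B <- matrix(rnorm(n * 3), n, 3)
    X <- nnls_bpp(crossprod(A), crossprod(A, B))
    for (j in 1:3) {
      ref <- nnls_enumerate(A, B[, j])
      obj_got <- sum((A %*% X[, j] - B[, j])^2)
      obj_ref <- sum((A %*% ref - B[, j])^2)
      expect_lt(obj_got, obj_ref + 1e-8)
      expect_true(all(X[, j] >= 0))
    }
  }
})

test_that("an exact rank-one tensor is recovered to machine fit", {
  set.seed(1)
  u <- abs(rnorm(20)); u <- u / sqrt(sum(u^2))
  z <- abs(rnorm(15)); z <- z / sqrt(sum(z^2))
  G <- array(0, c(20, 20, 15))
  for (k in 1:15) G[, , k] <- 5 * z[k] * (u %*% t(u))
  m <- nncp(G, 1, n_restarts = 2, seed = 3)
  expect_gt(m$fit, 1 - 1e-6)
  expect_equal(m$lambdas, 5, tolerance = 1e-6)
  expect_gt(abs(sum(m$spatial[, 1] * u)), 0.9999)
  expect_gt(abs(sum(m$temporal[, 1] * z)), 0.9999)
})

test_that("planted components are recovered with high spatial congruence", {
  pt <- make_planted_tensor(3, n_rois = 40, W = 30, seed = 2)
  m <- nncp(pt$G, 3, n_restarts = 3, max_iter = 300, tol = 1e-9, seed = 5)
  expect_gt(m$fit, 1 - 1e-6)
  for (r in seq_along(pt$membership)) {
    u <- rep(0, 40); u[pt$membership[[r]]] <- 1 / sqrt(10)
    congr <- max(abs(crossprod(u, m$spatial)))
    expect_gt(congr, 0.99)
  }
})

test_that("degenerate inputs and invalid ranks are rejected", {
  expect_error(nncp(array(0, c(3, 3, 3)), 1),
               class = "fcp_degenerate_input_error")
  expect_error(nncp(array(runif(27), c(3, 3, 3)), 5),
               class = "fcp_config_error")
  expect_error(nncp(array(-runif(27), c(3, 3, 3)), 1),
               class = "fcp_value_error")
})

test_that("model structure honors its invariants", {
  G <- random_sym_tensor(8, 6, seed = 21)
  m <- nncp(G, 3, n_restarts = 2, max_iter = 150, seed = 7)
  expect_true(all(diff(m$lambdas) <= 1e-9))                # descending
  expect_true(all(m$spatial >= 0) && all(m$temporal >= 0))
  expect_equal(unname(colSums(m$spatial^2)), rep(1, 3), tolerance = 1e-9)
  expect_equal(unname(colSums(m$temporal^2)), rep(1, 3), tolerance = 1e-9)
  expect_identical(m$spatial, m$spatial_b)                 # symmetrized
  expect_true(m$fit >= 0 && m$fit <= 1)

  # fitted + residuals reconstruct the data
  expect_equal(fitted(m) + residuals(m), G, tolerance = 1e-9)

  # coef/summary/print methods behave
  cf <- coef(m)
  expect_named(cf, c("lambdas", "spatial", "temporal"))
  expect_output(print(m), "rank 3")
  expect_output(print(summary(m)), "pattern")
})

test_that("the best-restart fit is non-decreasing in rank", {
  G <- random_sym_tensor(10, 8, seed = 3)
  # the ALS objective itself (fit_raw); the symmetrized projection may
  # legitimately dip on random tensors whose factors are not symmetric
  fits <- vapply(1:4, function(r) {
    nncp(G, r, n_restarts = 3, max_iter = 400, tol = 1e-10, seed = 11)$fit_raw
  }, numeric(1))
  expect_true(all(diff(fits) > -1e-6))
})

test_that("symmetric-slice tensors yield symmetric factors on clean data", {
  pt <- make_planted_tensor(2, n_rois = 30, W = 20, seed = 6)
  m <- nncp(pt$G, 2, n_restarts = 2, max_iter = 300, tol = 1e-10, seed = 2)
  expect_lt(m$asymmetry, 1e-5)
})

test_that("core consistency is exact on CP-structured tensors and for R = 1", {
  pt <- make_planted_tensor(3, n_rois = 30, W = 20, seed = 4)
  m <- nncp(pt$G, 3, n_restarts = 2, max_iter = 400, tol = 1e-12, seed = 9)
  expect_equal(core_consistency(pt$G, m), 100, tolerance = 1e-6)

  G <- random_sym_tensor(6, 5, seed = 13)
  m1 <- nncp(G, 1, n_restarts = 1, max_iter = 200, seed = 4)
  expect_equal(core_consistency(G, m1), 100, tolerance = 1e-6)
})

test_that("core consistency matches the Kronecker least-squares oracle", {
  set.seed(23)
  for (i in 1:20) {
    dims <- sample(3:6, 3, replace = TRUE)
    R <- sample(1:3, 1)
    G <- array(runif(prod(dims)), dims)
    m <- nncp(G, R, n_restarts = 1, max_iter = 60, seed = i, symmetrize = FALSE)
    cc <- tryCatch(core_consistency(G, m),
                   fcp_ill_conditioned_error = function(e) NA_real_)
    if (!is.na(cc)) {
      expect_equal(cc, corcondia_kron(G, m), tolerance = 1e-8)
    }
  }
})

test_that("rank-deficient factors raise an ill-conditioned error", {
  G <- random_sym_tensor(6, 5, seed = 2)
  m <- nncp(G, 2, n_restarts = 1, max_iter = 50, seed = 1)
  m$spatial[, 2] <- m$spatial[, 1]   # force collinearity
  m$spatial_b <- m$spatial
  err <- tryCatch(core_consistency(G, m), error = function(e) e)
  expect_s3_class(err, "fcp_ill_conditioned_error")
  expect_true(is.numeric(err$condition_number))
})
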