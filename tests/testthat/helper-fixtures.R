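# Shared fixtures and independent oracles for the test suite. Everything is
# generated in code under fixed seeds; no data files.

# One-group study cohort at the validation-study scale: 100 ROIs, 20
# subjects, TR 2 s, scans long enough for 120 unit-step windows.
make_study_cohort <- function(planted, seed, n_subjects = 20L,
                              n_rois = 100L, W = 120L,
                              n_constant = 0L, snr = 3) {
  tr <- 2.0
  nv <- 50L + W - 1L
  cfg <- synth_config(
    n_rois = n_rois,
    groups = list(synth_group("g", n_subjects, planted, tr, nv),
                  synth_group("other", 2L, 1L, tr, nv)),
    community_size = 20L, overlap_fraction = 0.2, snr = snr,
    n_constant_roi_subjects = n_constant, seed = seed)
  generate_timeseries(cfg)
}

# Noise-free CP-structured tensor with r_true block communities and the
# generator's window-averaged correlation profiles as temporal loadings.
make_planted_tensor <- function(r_true, n_rois = 50L, W = 40L, seed = 1L,
                                community_size = 10L) {
  mem <- generate_memberships(n_rois, r_true, community_size, 0, seed)
  w_id <- seq_len(W)
  periods <- if (r_true <= 3) rep(30, r_true) else
    ifelse(seq_len(r_true) <= 3, 30, 46)
  phases <- if (r_true <= 3) (seq_len(r_true) - 1) * pi / r_true else
    ifelse(seq_len(r_true) <= 3, (seq_len(r_true) - 1) * pi / 3,
           pi / 6 + (seq_len(r_true) - 4) * pi / 3)
  G <- array(0, c(n_rois, n_rois, W))
  for (r in seq_len(r_true)) {
    u <- rep(0, n_rois)
    u[mem[[r]]] <- 1 / sqrt(community_size)
    prof <- 0.1 + cos(pi * w_id / periods[r] + phases[r])^2
    uu <- u %*% t(u)
    for (w in w_id) G[, , w] <- G[, , w] + 3 * prof[w] * uu
  }
  list(G = G, membership = mem)
}

# Small non-negative random tensor with symmetric slices.
random_sym_tensor <- function(n, W, seed) {
  set.seed(seed)
  G <- array(runif(n * n * W), c(n, n, W))
  for (w in seq_len(W)) {
    m <- G[, , w]
    G[, , w] <- (m + t(m)) / 2
  }
  G
}

# --- independent oracles ---------------------------------------------------

# NNLS by exhaustive active-set enumeration (reference for nnls_bpp).
nnls_enumerate <- function(A, b) {
  r <- ncol(A)
  best <- NULL
  for (mask in 0:(2^r - 1)) {
    passive <- as.logical(bitwAnd(mask, 2^(seq_len(r) - 1)))
    x <- rep(0, r)
    if (any(passive)) {
      sub <- A[, passive, drop = FALSE]
      xs <- tryCatch(qr.solve(sub, b), error = function(e) NULL)
      if (is.null(xs) || any(xs < -1e-10)) next
      x[passive] <- pmax(xs, 0)
    }
    obj <- sum((A %*% x - b)^2)
    if (is.null(best) || obj < best$obj - 1e-12) best <- list(x = x, obj = obj)
  }
  best$x
}

# Core consistency by explicit Kronecker least squares (reference).
corcondia_kron <- function(G, model) {
  A <- sweep(model$spatial, 2, model$lambdas, `*`)
  B <- model$spatial_b
  C <- model$temporal
  R <- model$rank
  K <- qr.solve(kronecker(C, kronecker(B, A)), as.vector(G))
  Tsup <- array(0, c(R, R, R))
  for (r in seq_len(R)) Tsup[r, r, r] <- 1
  100 * (1 - sum((K - as.vector(Tsup))^2) / R)
}

# Benjamini-Hochberg by the literal step-up definition (reference).
bh_stepup <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  prev <- 1
  for (i in m:1) {
    prev <- min(prev, p[o[i]] * m / i)
    q[o[i]] <- prev
  }
  pmin(q, 1)
}

# Mode-3 subject weights by dense eigendecomposition of U U' (reference).
weights_eigen <- function(stack) {
  d <- dim(stack)
  U <- matrix(aperm(stack, c(3, 1, 2)), nrow = d[3])
  ev <- eigen(U %*% t(U), symmetric = TRUE)$vectors[, 1]
  if (sum(ev) < 0) ev <- -ev
  ev
}

# Sliding-window count by explicit enumeration (reference).
count_windows <- function(n_t, n_i, step) {
  w <- 0L
  start <- 1L
  while (start + n_i - 1L <= n_t) {
    w <- w + 1L
    start <- start + step
  }
  w
}

expect_deep_equal <- function(a, b, tol = 0) {
  if (tol == 0) testthat::expect_identical(a, b) else
    testthat::expect_equal(a, b, tolerance = tol)
}
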