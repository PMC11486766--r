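# Group-level dynamic FC: per-window Tucker-derived subject weights and the
# non-negative group FC tensor consumed by the CP pattern extraction.

#' Subject weights for one window from the Tucker subject-mode factor
#'
#' Stacks the window-w FC matrices of all kept subjects into an N x N x S
#' tensor and takes the first column of the orthonormal subject-mode factor
#' of a full-dimension Tucker decomposition — equivalently the leading left
#' singular vector of the mode-3 unfolding (S x N^2). With full core
#' dimensions the Tucker factors are exactly the unfolding singular vectors,
#' so only one truncated SVD is needed; the full-reconstruction equivalence
#' is asserted in the test suite. The singular vector's sign is ambiguous;
#' it is flipped so the weights sum to a positive value.
#'
#' @param stack numeric N x N x S array (S >= 2 subjects).
#' @return list with `weights` (length-S unit vector) and `sv` (leading
#'   singular value).
#' @export
subject_weights <- function(stack) {
  d <- dim(stack)
  if (length(d) != 3L || d[3] < 2L) {
    fcp_stop("fcp_cohort_size_error", "need an N x N x S stack with S >= 2")
  }
  subject_weights_mat(unfold(stack, 3))      # S x N^2 unfolding
}

# Same computation on a precomputed S x N^2 mode-3 unfolding.
subject_weights_mat <- function(u) {
  if (any(rowSums(abs(u)) == 0)) {
    fcp_stop("fcp_degenerate_weights_error", "all-zero subject slice")
  }
  sv <- svd(u, nu = 1L, nv = 0L)
  z1 <- sv$u[, 1]
  s1 <- sum(z1)
  if (abs(s1) < 1e-12) {
    fcp_stop("fcp_degenerate_weights_error",
             "subject weights sum to zero within tolerance")
  }
  if (s1 < 0) z1 <- -z1
  list(weights = z1, sv = sv$d[1])
}

#' Weighted group-level FC for one window
#'
#' \eqn{\bar G = \sum_s Z_{1s} M_s / \sum_s Z_{1s}}: the subject FC matrices
#' averaged with the Tucker subject weights (weights normalized by their sum,
#' not constrained to be non-negative).
#'
#' @param fc_matrices list of S numeric N x N matrices.
#' @param weights length-S numeric vector (e.g. from [subject_weights()]).
#' @return numeric N x N matrix.
#' @export
group_fc_window <- function(fc_matrices, weights) {
  if (is.list(weights)) weights <- weights$weights
  if (length(fc_matrices) != length(weights)) {
    fcp_stop("fcp_shape_error", "one weight per subject matrix required")
  }
  sw <- sum(weights)
  if (abs(sw) < 1e-12) {
    fcp_stop("fcp_degenerate_weights_error", "weights sum to zero")
  }
  acc <- fc_matrices[[1]] * weights[1]
  for (s in seq_along(fc_matrices)[-1]) {
    acc <- acc + fc_matrices[[s]] * weights[s]
  }
  acc / sw
}

#' Build the non-negative group dynamic FC tensor for one subtype
#'
#' For each of the `W_target` windows: stack the kept subjects' FC matrices,
#' compute Tucker subject weights, average with them, take entrywise absolute
#' values (the CP stage is non-negative), and apply the diagonal policy. The
#' default zeroes each slice's diagonal: a constant unit diagonal carries no
#' connectivity information but dominates low-rank fits.
#'
#' @param dfc_list list of `dynamic_fc` objects, all truncated to
#'   `W_target` windows (see [truncate_windows()]).
#' @param W_target number of windows (default 120).
#' @param keep_unit_diagonal keep the literal unit diagonal instead of
#'   zeroing it (default `FALSE`).
#' @param weighting `"tucker"` (default) or `"mean"` (unweighted baseline
#'   for comparison runs).
#' @param group optional group label stored in the result.
#' @return an object of class `group_fc_tensor`: list with `group`, `G`
#'   (N x N x W array), `W`, `weights` (S x W matrix), `diagonal`.
#' @export
build_group_tensor <- function(dfc_list, W_target = 120L,
                               keep_unit_diagonal = FALSE,
                               weighting = c("tucker", "mean"),
                               group = NULL) {
  weighting <- match.arg(weighting)
  s_n <- length(dfc_list)
  if (s_n < 2L) {
    fcp_stop("fcp_cohort_size_error", "need at least 2 subjects per group")
  }
  for (dfc in dfc_list) {
    if (dim(dfc$windows)[3] != W_target) {
      fcp_stop("fcp_shape_error", sprintf(
        "subject %s has %d windows, expected %d (truncate first)",
        dfc$subject_id %||% "?", dim(dfc$windows)[3], W_target))
    }
  }
  n <- dim(dfc_list[[1]]$windows)[1]
  G <- array(NA_real_, c(n, n, W_target))
  wts <- matrix(NA_real_, s_n, W_target)
  for (w in seq_len(W_target)) {
    stack_mat <- vapply(dfc_list, function(d) as.vector(d$windows[, , w]),
                        numeric(n * n))               # N^2 x S
    z1 <- if (weighting == "tucker") subject_weights_mat(t(stack_mat))$weights
          else rep(1 / s_n, s_n)
    wts[, w] <- z1
    slice <- abs(matrix(stack_mat %*% z1, n, n) / sum(z1))
    if (!keep_unit_diagonal) diag(slice) <- 0
    G[, , w] <- (slice + t(slice)) / 2
  }
  structure(list(group = group, G = G, W = W_target,
                 weights = wts,
                 diagonal = if (keep_unit_diagonal) "unit" else "zero"),
            class = "group_fc_tensor")
}

#' @export
print.group_fc_tensor <- function(x, ...) {
  d <- dim(x$G)
  cat(sprintf(
    "Group FC tensor%s: %d x %d ROIs x %d windows (diagonal: %s)\n",
    if (is.null(x$group)) "" else paste0(" [", x$group, "]"),
    d[1], d[2], d[3], x$diagonal))
  invisible(x)
}
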