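# Core-consistency diagnostic (CORCONDIA) and rank selection by
# cross-validated sweep.

#' Core consistency of a CP model
#'
#' Given the fixed CP factor matrices (the weights absorbed into the first
#' ROI mode, following Bro & Kiers), computes the least-squares Tucker core
#' `K` of the data tensor via mode-wise pseudo-inverses and compares it with
#' the ideal superdiagonal tensor of ones `T`:
#' \deqn{cc = 100 (1 - \sum_{ijk} (k_{ijk} - t_{ijk})^2 / R).}
#' A model with perfect CP structure scores 100; overfactored models
#' collapse, usually far below 0.
#'
#' @param G a `group_fc_tensor` or numeric 3-way array.
#' @param model an `nncp` fit of `G`.
#' @param cond_limit factor condition number beyond which the core is
#'   considered unidentifiable (default 1e8).
#' @return the core-consistency value (<= 100).
#' @export
core_consistency <- function(G, model, cond_limit = 1e8) {
  Ga <- if (inherits(G, "group_fc_tensor")) G$G else G
  R <- model$rank
  A <- sweep(model$spatial, 2, model$lambdas, `*`)
  B <- model$spatial_b
  C <- model$temporal
  pa <- pinv_cond(A); pb <- pinv_cond(B); pc <- pinv_cond(C)
  cond <- max(pa$cond, pb$cond, pc$cond)
  if (!isTRUE(pa$full_rank) || !isTRUE(pb$full_rank) || !isTRUE(pc$full_rank) ||
      !is.finite(cond) || cond > cond_limit) {
    fcp_stop("fcp_ill_conditioned_error", sprintf(
      "factor matrices are rank deficient (condition number %.3g)", cond),
      condition_number = cond)
  }
  K <- ttm(ttm(ttm(Ga, pa$pinv, 1), pb$pinv, 2), pc$pinv, 3)
  Tsup <- array(0, c(R, R, R))
  for (r in seq_len(R)) Tsup[r, r, r] <- 1
  100 * (1 - sum((K - Tsup)^2) / R)
}

#' Core-consistency sweep over candidate ranks
#'
#' Fits [nncp()] and evaluates [core_consistency()] for each rank in
#' `R_range`. Ranks whose fit is degenerate (dead components making the
#' factors rank deficient) are recorded as `NA`: such a model cannot be
#' certified and counts as failing any threshold.
#'
#' @param G a `group_fc_tensor` or non-negative 3-way array.
#' @param R_range integer vector of candidate ranks (default 1:10).
#' @param seed integer seed.
#' @param n_restarts,max_iter,tol passed to [nncp()]; the sweep defaults are
#'   lighter than the final-fit defaults because only the diagnostic is
#'   needed here.
#' @return numeric vector of core-consistency values, named by rank.
#' @export
rank_sweep <- function(G, R_range = 1:10, seed = 1L, n_restarts = 2L,
                       max_iter = 100L, tol = 1e-6) {
  cc <- stats::setNames(rep(NA_real_, length(R_range)), R_range)
  for (i in seq_along(R_range)) {
    cc[i] <- cc_at_rank(G, R_range[i], seed = seed, n_restarts = n_restarts,
                        max_iter = max_iter, tol = tol)
  }
  cc
}

# fit one rank and return its core consistency (NA when uncertifiable)
cc_at_rank <- function(G, r, seed, n_restarts, max_iter, tol) {
  tryCatch({
    m <- nncp(G, rank = r, n_restarts = n_restarts, max_iter = max_iter,
              tol = tol, seed = derive_seed(seed, r))
    core_consistency(G, m)
  },
  fcp_ill_conditioned_error = function(e) NA_real_,
  fcp_config_error = function(e) NA_real_)
}

#' Select the number of brain patterns by cross-validated core consistency
#'
#' Splits the subjects of one group into `n_folds` seeded folds, builds a
#' group FC tensor from each fold's subjects alone, sweeps candidate ranks,
#' and selects the LARGEST rank whose fold-mean core consistency meets the
#' threshold — as many patterns as possible while the CP structure stays
#' trustworthy.
#'
#' @param dfc_list list of truncated `dynamic_fc` objects for one group.
#' @param R_range candidate ranks (default 1:10).
#' @param n_folds number of cross-validation folds (default 3).
#' @param threshold core-consistency acceptance threshold in percent
#'   (default 60).
#' @param seed integer seed controlling fold assignment and restarts.
#' @param W_target windows per subject (default taken from the data).
#' @param keep_unit_diagonal,weighting passed to [build_group_tensor()].
#' @param n_restarts,max_iter,tol passed to the per-rank [nncp()] fits.
#' @param early_stop abandon the sweep once the fold-mean core consistency
#'   has collapsed below 0 at two consecutive ranks (default `TRUE`); in
#'   practice the diagnostic never recovers after such a collapse, and the
#'   highest ranks are the costliest to fit. Ranks not visited are reported
#'   as `NA` and cannot be selected.
#' @return list with `selected` (the chosen rank), `fold_mean` (named
#'   vector), `profile` (data frame fold x rank x cc) and `threshold`.
#' @export
select_rank <- function(dfc_list, R_range = 1:10, n_folds = 3L,
                        threshold = 60, seed = 1L, W_target = NULL,
                        keep_unit_diagonal = FALSE,
                        weighting = "tucker",
                        n_restarts = 2L, max_iter = 100L, tol = 1e-6,
                        early_stop = TRUE) {
  s_n <- length(dfc_list)
  if (s_n < 2L * n_folds) {
    fcp_stop("fcp_cohort_size_error", sprintf(
      "need at least %d subjects (2 per fold) for %d folds",
      2L * n_folds, n_folds))
  }
  if (is.null(W_target)) W_target <- dim(dfc_list[[1]]$windows)[3]
  folds <- with_seed(derive_seed(seed, 17L), {
    sample(rep_len(seq_len(n_folds), s_n))
  })
  tensors <- lapply(seq_len(n_folds), function(f) {
    build_group_tensor(dfc_list[folds == f], W_target = W_target,
                       keep_unit_diagonal = keep_unit_diagonal,
                       weighting = weighting)
  })
  R_range <- sort(R_range)
  cc_mat <- matrix(NA_real_, n_folds, length(R_range))
  fold_mean <- stats::setNames(rep(NA_real_, length(R_range)), R_range)
  collapsed <- 0L
  for (i in seq_along(R_range)) {
    for (f in seq_len(n_folds)) {
      cc_mat[f, i] <- cc_at_rank(tensors[[f]], R_range[i],
                                 seed = derive_seed(seed, 100L + f),
                                 n_restarts = n_restarts,
                                 max_iter = max_iter, tol = tol)
    }
    vals <- cc_mat[, i]
    vals[is.na(vals)] <- -Inf   # uncertifiable fits fail the threshold
    fold_mean[i] <- mean(vals)
    collapsed <- if (fold_mean[i] < 0) collapsed + 1L else 0L
    if (early_stop && collapsed >= 2L && i < length(R_range)) break
  }
  prof <- data.frame(fold = rep(seq_len(n_folds), times = length(R_range)),
                     rank = rep(R_range, each = n_folds),
                     cc = as.vector(cc_mat))
  passing <- R_range[!is.na(fold_mean) & fold_mean >= threshold]
  if (length(passing) == 0L) {
    fcp_stop("fcp_selection_error", paste(
      "no rank reaches the core-consistency threshold;",
      "review the threshold or the data"))
  }
  list(selected = max(passing), fold_mean = fold_mean,
       profile = prof, threshold = threshold, folds = folds)
}
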