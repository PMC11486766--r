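# Sliding-window dynamic functional connectivity with zero-variance quality
# control and fixed-length truncation.

#' Sliding-window specification
#'
#' @param L window length in seconds. The default follows the reciprocal
#'   rule: the window must span one full period of the slowest retained
#'   frequency, so `L = 1 / f_low`.
#' @param step_volumes sliding step in volumes (default 1).
#' @param W_target number of windows retained per subject (default 120).
#' @return a `sliding_window_spec` list.
#' @export
sliding_window_spec <- function(L = 100, step_volumes = 1L, W_target = 120L) {
  if (!(L > 0) || !is_count(step_volumes) || !is_count(W_target)) {
    fcp_stop("fcp_config_error", "invalid sliding-window specification")
  }
  structure(list(L = L, step_volumes = as.integer(step_volumes),
                 W_target = as.integer(W_target)),
            class = "sliding_window_spec")
}

#' Window length in seconds from the band-pass low cutoff
#'
#' The sliding window must be long enough to contain one full cycle of the
#' lowest frequency kept by the band-pass filter, giving `L = 1 / f_low`.
#'
#' @param f_low low-end cutoff frequency in Hz (> 0).
#' @return window length in seconds.
#' @export
window_length_seconds <- function(f_low) {
  if (!(is.numeric(f_low) && length(f_low) == 1L && f_low > 0)) {
    fcp_stop("fcp_domain_error", "f_low must be a positive scalar")
  }
  1 / f_low
}

#' Window length in volumes for one site
#'
#' `floor(L / TR)`; fractional ratios (e.g. TR = 2.2 s) are floored so the
#' window never exceeds L seconds.
#'
#' @param L window length in seconds.
#' @param tr repetition time in seconds.
#' @return integer number of volumes (>= 2).
#' @export
window_length_volumes <- function(L, tr) {
  ni <- floor(L / tr)
  if (ni < 2) {
    fcp_stop("fcp_window_error", sprintf(
      "window of %g s holds only %d volume(s) at TR %g s", L, ni, tr))
  }
  as.integer(ni)
}

#' Sliding-window Pearson dynamic FC for one subject
#'
#' Window w (1-based) covers volumes `[(w-1)*step + 1, (w-1)*step + Ni]`;
#' each window yields the ROI-by-ROI Pearson correlation matrix of the
#' segments. Any ROI segment with zero standard deviation aborts with a
#' `fcp_zero_variance_window` condition carrying the ROI and window index —
#' the cohort-level screen turns that into a subject exclusion.
#'
#' @param ts numeric matrix, ROIs x volumes.
#' @param spec a [sliding_window_spec()].
#' @param tr repetition time in seconds.
#' @param subject_id optional identifier carried into results and errors.
#' @return an object of class `dynamic_fc`: list with `subject_id`,
#'   `windows` (N x N x W' array), `n_i`, `step`.
#' @export
sliding_window_fc <- function(ts, spec = sliding_window_spec(), tr,
                              subject_id = NULL) {
  n_i <- window_length_volumes(spec$L, tr)
  n_t <- ncol(ts)
  if (n_t < n_i) {
    fcp_stop("fcp_length_error", sprintf(
      "series of %d volumes is shorter than one %d-volume window", n_t, n_i))
  }
  step <- spec$step_volumes
  w_n <- (n_t - n_i) %/% step + 1L
  n <- nrow(ts)
  windows <- array(NA_real_, c(n, n, w_n))
  for (w in seq_len(w_n)) {
    idx <- ((w - 1L) * step + 1L):((w - 1L) * step + n_i)
    seg <- ts[, idx, drop = FALSE]
    cs <- seg - rowMeans(seg)
    ss <- sqrt(rowSums(cs * cs))
    if (any(ss == 0)) {
      roi <- which(ss == 0)[1]
      fcp_stop("fcp_zero_variance_window", sprintf(
        "zero-variance ROI segment (subject %s, ROI %d, window %d)",
        subject_id %||% "?", roi, w),
        subject = subject_id, roi = roi, window = w)
    }
    m <- tcrossprod(cs / ss)
    m <- (m + t(m)) / 2       # exact symmetry against fp round-off
    m[m > 1] <- 1; m[m < -1] <- -1
    diag(m) <- 1
    windows[, , w] <- m
  }
  structure(list(subject_id = subject_id, windows = windows, n_i = n_i,
                 step = step),
            class = "dynamic_fc")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.dynamic_fc <- function(x, ...) {
  d <- dim(x$windows)
  cat(sprintf("Dynamic FC (%s): %d x %d ROIs, %d windows of %d volumes, step %d\n",
              x$subject_id %||% "unnamed", d[1], d[2], d[3], x$n_i, x$step))
  invisible(x)
}

#' Compute dynamic FC for a cohort group and screen out bad subjects
#'
#' Runs [sliding_window_fc()] over every subject; any subject raising a
#' zero-variance window (a constant ROI signal somewhere in the scan) is
#' excluded and logged instead of propagating the error.
#'
#' @param ts_set a `roi_timeseries_set`.
#' @param spec a [sliding_window_spec()].
#' @return list with `kept` (list of `dynamic_fc`) and `excluded` (data
#'   frame subject_id, roi, window).
#' @export
screen_subjects <- function(ts_set, spec = sliding_window_spec()) {
  stopifnot(inherits(ts_set, "roi_timeseries_set"))
  kept <- list()
  excluded <- list()
  for (s in ts_set$subjects) {
    res <- tryCatch(
      sliding_window_fc(s$signal, spec, s$tr, subject_id = s$subject_id),
      fcp_zero_variance_window = function(e) e
    )
    if (inherits(res, "condition")) {
      excluded[[length(excluded) + 1L]] <- data.frame(
        subject_id = s$subject_id, roi = res$roi, window = res$window,
        stringsAsFactors = FALSE)
    } else {
      kept[[length(kept) + 1L]] <- res
    }
  }
  if (length(kept) == 0L) {
    fcp_stop("fcp_empty_cohort_error",
             "all subjects excluded by the zero-variance screen")
  }
  excluded <- if (length(excluded)) do.call(rbind, excluded) else
    data.frame(subject_id = character(0), roi = integer(0),
               window = integer(0), stringsAsFactors = FALSE)
  list(kept = kept, excluded = excluded)
}

#' Truncate a subject's dynamic FC to a fixed window count
#'
#' Sites differ in scan length, so window counts differ per subject; keeping
#' the first `W_target` windows puts every subject on a common grid.
#'
#' @param dfc a `dynamic_fc`.
#' @param W_target number of windows to keep (default 120).
#' @return the truncated `dynamic_fc`.
#' @export
truncate_windows <- function(dfc, W_target = 120L) {
  w_n <- dim(dfc$windows)[3]
  if (w_n < W_target) {
    fcp_stop("fcp_scan_length_error", sprintf(
      "subject %s has only %d windows (need %d)",
      dfc$subject_id %||% "?", w_n, W_target), subject = dfc$subject_id)
  }
  if (w_n > W_target) dfc$windows <- dfc$windows[, , seq_len(W_target), drop = FALSE]
  dfc
}
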