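# Spectral features (ALFF, fALFF), per-subject normalization, ROI
# aggregation and feature-table ingestion.

#' One-sided amplitude (or power) spectrum of a signal
#'
#' Periodogram on the DFT grid: with the `"amplitude"` estimator (the ALFF
#' convention) the value at each frequency is the square root of the
#' one-sided periodogram, i.e. proportional to the sinusoid amplitude at
#' that bin; `"power"` returns the periodogram itself.
#'
#' @param x numeric vector.
#' @param tr sampling interval in seconds.
#' @param estimator `"amplitude"` (default) or `"power"`.
#' @return list with `frequencies` (Hz, 0..Nyquist) and `amplitude`.
#' @export
amplitude_spectrum <- function(x, tr, estimator = c("amplitude", "power")) {
  estimator <- match.arg(estimator)
  n <- length(x)
  fs <- 1 / tr
  nf <- floor(n / 2) + 1L
  freq <- (seq_len(nf) - 1L) * fs / n
  mod2 <- Mod(stats::fft(x)[seq_len(nf)])^2
  # one-sided scaling: interior bins carry both halves of the spectrum
  scale <- rep(2, nf); scale[1] <- 1
  if (n %% 2 == 0) scale[nf] <- 1
  pgram <- scale * mod2 / n^2
  amp <- if (estimator == "amplitude") sqrt(pgram) else pgram
  list(frequencies = freq, amplitude = amp)
}

# trapezoid integral of spectrum over [lo, hi]
band_integral <- function(spec, lo, hi) {
  sel <- spec$frequencies >= lo & spec$frequencies <= hi
  if (sum(sel) < 2L) return(sum(spec$amplitude[sel]))
  pracma::trapz(spec$frequencies[sel], spec$amplitude[sel])
}

#' Amplitude of low-frequency fluctuation (ALFF)
#'
#' Averages the band-filtered signal's amplitude spectrum over the
#' low-frequency band: the trapezoid integral over `[f_low, f_high]`
#' divided by the band width. Filtering is applied in the spectral domain
#' (the signal's spectrum times the zero-phase filter's magnitude
#' response), which is exact and free of the time-domain edge transients
#' that would otherwise leak broadband energy into the band. A constant
#' signal returns 0.
#'
#' @param x numeric signal vector (length >= 32).
#' @param tr sampling interval in seconds.
#' @param band a [bandpass_spec()] (default 0.01-0.1 Hz).
#' @param estimator spectrum estimator, see [amplitude_spectrum()].
#' @return non-negative scalar.
#' @export
alff <- function(x, tr, band = bandpass_spec(), estimator = "amplitude") {
  if (length(x) < 32L) {
    fcp_stop("fcp_length_error", "need at least 32 samples for ALFF")
  }
  if (stats::sd(x) == 0) return(0)
  spec <- filtered_spectrum(x, tr, band, estimator)
  band_integral(spec, band$f_low, band$f_high) / (band$f_high - band$f_low)
}

# amplitude (or power) spectrum of the band-filtered signal, computed as
# the raw spectrum scaled by the filter's zero-phase magnitude response
filtered_spectrum <- function(x, tr, band, estimator) {
  spec <- amplitude_spectrum(x - mean(x), tr, estimator)
  gain <- bandpass_gain(spec$frequencies, tr, band)
  if (estimator == "power") gain <- gain^2
  spec$amplitude <- spec$amplitude * gain
  spec
}

#' Fractional ALFF (fALFF)
#'
#' Ratio of the band-limited amplitude of the filtered signal to the
#' full-band (0 to Nyquist) amplitude of the unfiltered signal. Values lie
#' in `[0, 1 + eps]` (eps from filter passband ripple).
#'
#' @inheritParams alff
#' @return scalar in approximately `[0, 1]`.
#' @export
falff <- function(x, tr, band = bandpass_spec(), estimator = "amplitude") {
  if (length(x) < 32L) {
    fcp_stop("fcp_length_error", "need at least 32 samples for fALFF")
  }
  if (stats::sd(x) == 0) {
    fcp_stop("fcp_undefined_feature_error",
             "fALFF is undefined for a constant signal")
  }
  x <- x - mean(x)
  spec_f <- filtered_spectrum(x, tr, band, estimator)
  spec_all <- amplitude_spectrum(x, tr, estimator)
  num <- band_integral(spec_f, band$f_low, band$f_high)
  den <- band_integral(spec_all, 0, 1 / (2 * tr))
  num / den
}

#' Z-score a vector (per-subject normalization)
#'
#' `(v - mean) / sd` with the sample standard deviation. A constant input
#' returns a zero vector with attribute `degenerate = TRUE`.
#'
#' @param values numeric vector (length >= 2).
#' @return normalized vector (attribute `degenerate` when sd was 0).
#' @export
zscore_subject <- function(values) {
  if (length(values) < 2L) {
    fcp_stop("fcp_length_error", "need at least 2 values to z-score")
  }
  s <- stats::sd(values)
  if (s == 0) {
    out <- rep(0, length(values))
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  (values - mean(values)) / s
}

#' Aggregate voxel values to ROI level
#'
#' Unweighted mean per ROI over the voxels carrying each label.
#'
#' @param voxel_values numeric vector over voxels.
#' @param atlas_labels integer vector (same length), label 0 = out of mask.
#' @param roi_labels labels that must be present (default: those found).
#' @return named numeric vector over ROIs (ascending label order).
#' @export
roi_aggregate <- function(voxel_values, atlas_labels, roi_labels = NULL) {
  stopifnot(length(voxel_values) == length(atlas_labels))
  lab <- as.integer(atlas_labels)
  present <- sort(unique(lab[lab > 0L]))
  if (is.null(roi_labels)) roi_labels <- present
  missing <- setdiff(as.integer(roi_labels), present)
  if (length(missing) > 0) {
    fcp_stop("fcp_missing_roi_error",
             sprintf("ROI label(s) with no voxels: %s",
                     paste(missing, collapse = ", ")), labels = missing)
  }
  keep <- lab %in% roi_labels
  out <- tapply(voxel_values[keep], lab[keep], mean)
  out <- out[as.character(sort(as.integer(roi_labels)))]
  stats::setNames(as.numeric(out), names(out))
}

#' Construct a feature table
#'
#' @param values numeric matrix, subjects x ROIs (dimnames recommended).
#' @param feature one of "ALFF", "fALFF", "GMV".
#' @param group group label.
#' @param normalize z-score each subject row across ROIs (default TRUE).
#' @return an object of class `feature_table`.
#' @export
feature_table <- function(values, feature = c("ALFF", "fALFF", "GMV"),
                          group = NULL, normalize = TRUE) {
  feature <- match.arg(feature)
  values <- as.matrix(values)
  if (!all(is.finite(values))) {
    fcp_stop("fcp_value_error", "feature table contains non-finite values")
  }
  degenerate <- logical(nrow(values))
  if (normalize) {
    for (i in seq_len(nrow(values))) {
      z <- zscore_subject(values[i, ])
      degenerate[i] <- isTRUE(attr(z, "degenerate"))
      values[i, ] <- z
    }
  }
  structure(list(values = values, feature = feature, group = group,
                 normalized = normalize, degenerate_rows = which(degenerate)),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("%s feature table%s: %d subjects x %d ROIs%s\n", x$feature,
              if (is.null(x$group)) "" else paste0(" [", x$group, "]"),
              nrow(x$values), ncol(x$values),
              if (x$normalized) " (z-scored per subject)" else ""))
  invisible(x)
}

#' Load an ROI-level feature table from TSV
#'
#' Expects subject rows (row names = subject ids) and N ROI columns; the
#' subjects are validated against a cohort manifest when given, and each
#' subject row is z-scored across ROIs.
#'
#' @param path TSV path.
#' @param feature "ALFF", "fALFF" or "GMV".
#' @param group group label; with a manifest, rows are checked against that
#'   group's subjects.
#' @param manifest optional manifest data frame (columns subject_id, group).
#' @return a [feature_table()].
#' @export
load_feature_table <- function(path, feature, group = NULL, manifest = NULL) {
  tab <- utils::read.delim(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(tab)
  if (!is.numeric(m)) {
    fcp_stop("fcp_parse_error", sprintf("non-numeric cells in %s", path))
  }
  if (!is.null(manifest)) {
    expected <- if (is.null(group)) manifest$subject_id
                else manifest$subject_id[manifest$group == group]
    missing <- setdiff(expected, rownames(m))
    if (length(missing) > 0) {
      fcp_stop("fcp_manifest_error", sprintf(
        "subject(s) missing from %s: %s", path,
        paste(utils::head(missing, 5), collapse = ", ")))
    }
    m <- m[expected, , drop = FALSE]
  }
  feature_table(m, feature = feature, group = group, normalize = TRUE)
}

#' @rdname load_feature_table
#' @export
load_gmv_table <- function(path, group = NULL, manifest = NULL) {
  load_feature_table(path, feature = "GMV", group = group, manifest = manifest)
}
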