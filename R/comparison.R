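# ROI-wise group comparison: network assignment, Welch t-tests,
# Benjamini-Hochberg FDR, pattern-difference sets, overlap reports and
# network tallies.

#' Assign ROIs to networks by nearest labelled reference point
#'
#' Each ROI centroid receives the network label of its Euclidean-nearest
#' reference point; exact ties go to the lowest reference index.
#'
#' @param centroids data frame with columns `roi_id`, `x`, `y`, `z`.
#' @param reference_points data frame with columns `x`, `y`, `z`, `network`.
#' @return named character vector, ROI id -> network label.
#' @export
assign_networks <- function(centroids, reference_points) {
  if (nrow(centroids) == 0L || nrow(reference_points) == 0L) {
    fcp_stop("fcp_config_error", "both coordinate tables must be non-empty")
  }
  cm <- as.matrix(centroids[, c("x", "y", "z")])
  rm_ <- as.matrix(reference_points[, c("x", "y", "z")])
  d2 <- outer(rowSums(cm^2), rowSums(rm_^2), `+`) - 2 * cm %*% t(rm_)
  nearest <- apply(d2, 1, which.min)   # which.min = lowest index on ties
  stats::setNames(as.character(reference_points$network[nearest]),
                  as.character(centroids$roi_id))
}

#' ROI-wise Welch two-sample t-tests
#'
#' Two-sided unequal-variance (Welch) t-test per ROI column; vectorized so
#' large null simulations stay cheap. Group sizes in this setting are very
#' unequal, which is why the Welch form is the default. ROIs with zero
#' variance in both groups get `t = 0, p = 1` and a degenerate flag.
#'
#' @param table_a,table_b numeric matrices (subjects x ROIs) or
#'   `feature_table`s with matching ROI columns.
#' @return data frame with columns `roi`, `t`, `p`, `direction`
#'   (`"A>B"`/`"A<B"`), `degenerate`.
#' @export
roi_ttest <- function(table_a, table_b) {
  a <- if (inherits(table_a, "feature_table")) table_a$values else as.matrix(table_a)
  b <- if (inherits(table_b, "feature_table")) table_b$values else as.matrix(table_b)
  if (ncol(a) != ncol(b)) {
    fcp_stop("fcp_shape_error", "feature tables differ in ROI count")
  }
  na <- nrow(a); nb <- nrow(b)
  if (na < 2L || nb < 2L) {
    fcp_stop("fcp_cohort_size_error", "need >= 2 subjects per group")
  }
  ma <- colMeans(a); mb <- colMeans(b)
  va <- colSums(sweep(a, 2, ma)^2) / (na - 1)
  vb <- colSums(sweep(b, 2, mb)^2) / (nb - 1)
  se2 <- va / na + vb / nb
  degenerate <- se2 == 0
  tstat <- ifelse(degenerate, 0, (ma - mb) / sqrt(ifelse(se2 == 0, 1, se2)))
  df <- ifelse(degenerate, na + nb - 2,
               se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1)))
  p <- ifelse(degenerate, 1, 2 * stats::pt(-abs(tstat), df))
  roi <- colnames(a) %||% as.character(seq_len(ncol(a)))
  data.frame(roi = roi, t = tstat, p = p,
             direction = ifelse(ma >= mb, "A>B", "A<B"),
             degenerate = degenerate, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up adjusted q-values (monotone, capped at 1) via
#' `stats::p.adjust(method = "BH")`; the significant set uses a strict
#' `q < alpha` rule.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @param alpha significance level (default 0.05).
#' @return list with `q` (adjusted values) and `significant` (indices).
#' @export
fdr_correct <- function(p, alpha = 0.05) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    fcp_stop("fcp_domain_error", "p-values must lie in [0, 1]")
  }
  q <- stats::p.adjust(p, method = "BH")
  list(q = q, significant = which(q < alpha))
}

#' Compare one feature between two groups, ROI by ROI
#'
#' Welch t-tests per ROI followed by BH-FDR within the comparison family
#' (all ROIs of this feature/pair), significance at `q < alpha`, and the
#' five ROIs with the smallest q-values.
#'
#' @param table_a,table_b `feature_table`s (same feature, two groups).
#' @param alpha significance level (default 0.05).
#' @param network_map optional named vector ROI -> network for annotation.
#' @return object of class `comparison_result`: `table` (data frame roi,
#'   network, t, p, q, direction, significant), `top5`, `feature`, `pair`,
#'   `alpha`.
#' @export
compare_features <- function(table_a, table_b, alpha = 0.05,
                             network_map = NULL) {
  feature <- if (inherits(table_a, "feature_table")) table_a$feature else NA
  pair <- c(if (inherits(table_a, "feature_table")) table_a$group else "A",
            if (inherits(table_b, "feature_table")) table_b$group else "B")
  tt <- roi_ttest(table_a, table_b)
  fdr <- fdr_correct(tt$p, alpha = alpha)
  tt$q <- fdr$q
  tt$significant <- tt$q < alpha
  tt$network <- if (!is.null(network_map)) unname(network_map[tt$roi]) else NA
  tt <- tt[, c("roi", "network", "t", "p", "q", "direction", "significant",
               "degenerate")]
  top5 <- tt[order(tt$q, tt$p), ][seq_len(min(5L, nrow(tt))), ]
  structure(list(table = tt, top5 = top5, feature = feature, pair = pair,
                 alpha = alpha),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s: %s vs %s — %d/%d ROIs significant at q < %g\n",
              x$feature, x$pair[1], x$pair[2], sum(x$table$significant),
              nrow(x$table), x$alpha))
  cat("Top ROIs by q-value:\n")
  print(x$top5[, c("roi", "network", "t", "q", "direction")],
        row.names = FALSE, digits = 4)
  invisible(x)
}

#' Pattern-difference ROI sets for a pair of subtypes
#'
#' For each matched pattern group: the symmetric difference of the two
#' subtypes' ROI sets (an ROI counts when it appears in one subtype's
#' pattern but not the other's); a pattern group present in only one of the
#' two subtypes contributes its full ROI set.
#'
#' @param pattern_groups result of [match_patterns_across_groups()].
#' @param subtype_a,subtype_b the two subtype labels to compare.
#' @return named list (pattern-group key -> character vector of ROI ids);
#'   attribute `pooled` holds the union.
#' @export
pattern_difference_rois <- function(pattern_groups, subtype_a, subtype_b) {
  out <- list()
  for (grp in pattern_groups) {
    in_a <- subtype_a %in% grp$members$subtype
    in_b <- subtype_b %in% grp$members$subtype
    if (!in_a && !in_b) next
    rois_of <- function(st) {
      sets <- lapply(grp$patterns[grp$members$subtype == st],
                     function(p) p$roi_set)
      unique(unlist(sets))
    }
    diff_set <- if (in_a && in_b) {
      a <- rois_of(subtype_a); b <- rois_of(subtype_b)
      union(setdiff(a, b), setdiff(b, a))
    } else if (in_a) rois_of(subtype_a) else rois_of(subtype_b)
    key <- if (nzchar(grp$key)) grp$key else "(no dominant network)"
    out[[key]] <- union(out[[key]], diff_set)
  }
  attr(out, "pooled") <- unique(unlist(out))
  out
}

#' Multi-comparison overlap report for one subtype pair
#'
#' Counts, per ROI, in how many of the four comparisons (brain pattern,
#' ALFF, fALFF, GMV) it appears, and reports the ROIs involved in at least
#' two and in more than two comparisons.
#'
#' @param pair character vector of the two subtype labels.
#' @param comparison_sets named list of ROI-id vectors with names among
#'   `pattern`, `ALFF`, `fALFF`, `GMV`.
#' @return object of class `overlap_report`: `membership` (named list ROI ->
#'   comparisons), `at_least_two`, `more_than_two`, `pair`.
#' @export
overlap_report <- function(pair, comparison_sets) {
  allowed <- c("pattern", "ALFF", "fALFF", "GMV")
  bad <- setdiff(names(comparison_sets), allowed)
  if (length(bad) > 0) {
    fcp_stop("fcp_config_error", sprintf(
      "unknown comparison name(s): %s", paste(bad, collapse = ", ")))
  }
  rois <- unique(unlist(comparison_sets))
  membership <- lapply(stats::setNames(rois, rois), function(r) {
    names(comparison_sets)[vapply(comparison_sets, function(s) r %in% s,
                                  logical(1))]
  })
  counts <- vapply(membership, length, integer(1))
  structure(list(pair = pair, membership = membership,
                 at_least_two = sort(names(counts)[counts >= 2]),
                 more_than_two = sort(names(counts)[counts > 2])),
            class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf("Overlap report %s vs %s:\n", x$pair[1], x$pair[2]))
  cat(sprintf("  ROIs in >= 2 comparisons: %d\n", length(x$at_least_two)))
  cat(sprintf("  ROIs in  > 2 comparisons: %d\n", length(x$more_than_two)))
  if (length(x$more_than_two) > 0) {
    cat("  ", paste(x$more_than_two, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Tally an ROI set by network
#'
#' @param roi_set character vector of ROI ids.
#' @param network_map named vector ROI id -> network label.
#' @return named integer vector (network -> count), descending.
#' @export
network_tally <- function(roi_set, network_map) {
  if (length(roi_set) == 0L) return(stats::setNames(integer(0), character(0)))
  unmapped <- setdiff(roi_set, names(network_map))
  if (length(unmapped) > 0) {
    fcp_stop("fcp_mapping_error", sprintf(
      "unmapped ROI(s): %s", paste(utils::head(unmapped, 5), collapse = ", ")))
  }
  counts <- sort(table(network_map[roi_set]), decreasing = TRUE)
  stats::setNames(as.integer(counts), names(counts))
}
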