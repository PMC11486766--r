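# From CP factors to brain patterns: loading thresholding, network
# annotation, dominant sub-networks, and cross-group pattern matching.

#' Threshold a spatial loading vector into an ROI community
#'
#' ROIs whose loading strictly exceeds the mean plus one sample standard
#' deviation belong to the pattern. A constant loading vector (sd 0) yields
#' an empty set.
#'
#' @param loadings non-negative numeric vector (length N >= 2).
#' @return integer vector of ROI indices.
#' @export
threshold_pattern <- function(loadings) {
  if (length(loadings) < 2L) {
    fcp_stop("fcp_config_error", "need at least 2 loadings")
  }
  which(loadings > mean(loadings) + stats::sd(loadings))
}

#' Build annotated brain patterns from a fitted CP model
#'
#' @param model an [nncp()] fit.
#' @param roi_ids character vector of ROI identifiers (defaults to indices).
#' @param network_map optional named character vector, ROI id -> network
#'   label; when given, dominant sub-networks are computed.
#' @param min_count dominance threshold on per-network ROI counts
#'   (default 5).
#' @return list of `brain_pattern` objects (rank-ordered by descending
#'   lambda), each with `rank`, `lambda`, `roi_set` (ids), `loadings`,
#'   `dominant_networks`.
#' @export
brain_patterns <- function(model, roi_ids = NULL, network_map = NULL,
                           min_count = 5L) {
  stopifnot(inherits(model, "nncp"))
  n <- nrow(model$spatial)
  if (is.null(roi_ids)) roi_ids <- as.character(seq_len(n))
  lapply(seq_len(model$rank), function(r) {
    idx <- threshold_pattern(model$spatial[, r])
    roi_set <- roi_ids[idx]
    dom <- if (!is.null(network_map)) {
      dominant_subnetworks(roi_set, network_map, min_count = min_count)
    } else NULL
    structure(list(rank = r, lambda = model$lambdas[r], roi_set = roi_set,
                   loadings = stats::setNames(model$spatial[, r], roi_ids),
                   dominant_networks = dom, group = model$group),
              class = "brain_pattern")
  })
}

#' @export
print.brain_pattern <- function(x, ...) {
  cat(sprintf("Brain pattern %d%s: lambda %.4g, %d ROIs",
              x$rank, if (is.null(x$group)) "" else paste0(" [", x$group, "]"),
              x$lambda, length(x$roi_set)))
  if (!is.null(x$dominant_networks) && length(x$dominant_networks) > 0) {
    cat(" | dominant: ", paste(sprintf("%s(%d)", names(x$dominant_networks),
                                       x$dominant_networks), collapse = ", "))
  }
  cat("\n")
  invisible(x)
}

#' Dominant sub-networks of an ROI set
#'
#' Counts ROIs per network and returns the networks whose count reaches
#' `min_count`, sorted by count descending.
#'
#' @param roi_set character vector of ROI ids (or a `brain_pattern`).
#' @param network_map named character vector, ROI id -> network label.
#' @param min_count dominance threshold (default 5).
#' @return named integer vector (network -> count), possibly empty.
#' @export
dominant_subnetworks <- function(roi_set, network_map, min_count = 5L) {
  if (inherits(roi_set, "brain_pattern")) roi_set <- roi_set$roi_set
  if (length(roi_set) == 0L) return(stats::setNames(integer(0), character(0)))
  unmapped <- setdiff(roi_set, names(network_map))
  if (length(unmapped) > 0L) {
    fcp_stop("fcp_mapping_error", sprintf(
      "ROI(s) without network label: %s",
      paste(utils::head(unmapped, 5), collapse = ", ")))
  }
  counts <- sort(table(network_map[roi_set]), decreasing = TRUE)
  counts <- counts[counts >= min_count]
  stats::setNames(as.integer(counts), names(counts))
}

#' Group brain patterns across subtypes by dominant sub-network sets
#'
#' Patterns from different subtypes whose dominant-network label SETS are
#' identical are grouped; everything else forms singleton groups. Patterns
#' with no dominant network never merge. Each member records its lambda rank
#' so order differences between subtypes stay visible.
#'
#' @param patterns_by_group named list (subtype -> list of `brain_pattern`
#'   with dominant networks computed).
#' @return list of pattern groups: each has `key` (sorted dominant labels),
#'   `members` (data frame subtype, rank, lambda), `patterns` (the member
#'   `brain_pattern`s), and `subtypes`.
#' @export
match_patterns_across_groups <- function(patterns_by_group) {
  entries <- list()
  for (g in names(patterns_by_group)) {
    for (p in patterns_by_group[[g]]) {
      if (is.null(p$dominant_networks)) {
        fcp_stop("fcp_value_error",
                 "dominant networks must be computed before matching")
      }
      key <- paste(sort(names(p$dominant_networks)), collapse = "+")
      entries[[length(entries) + 1L]] <- list(group = g, pattern = p,
                                              key = key)
    }
  }
  keys <- vapply(entries, `[[`, character(1), "key")
  groups <- list()
  used <- rep(FALSE, length(entries))
  for (i in seq_along(entries)) {
    if (used[i]) next
    same <- if (nzchar(keys[i])) which(keys == keys[i]) else i
    used[same] <- TRUE
    members <- do.call(rbind, lapply(entries[same], function(e) {
      data.frame(subtype = e$group, rank = e$pattern$rank,
                 lambda = e$pattern$lambda, stringsAsFactors = FALSE)
    }))
    groups[[length(groups) + 1L]] <- list(
      key = keys[i], members = members,
      patterns = lapply(entries[same], `[[`, "pattern"),
      subtypes = unique(members$subtype))
  }
  # larger groups first, then by best (max) lambda
  ord <- order(-vapply(groups, function(g) nrow(g$members), integer(1)),
               -vapply(groups, function(g) max(g$members$lambda), numeric(1)))
  groups[ord]
}
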