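# End-to-end orchestration: declarative run configuration, deterministic
# seeding, and the synthetic / file-based pipeline producing a results
# bundle.

#' Build a run configuration
#'
#' Aggregates every pipeline constant as a named default: band-pass
#' 0.01-0.1 Hz, 120 retained windows at step 1, rank sweep 1..10 with 3-fold
#' cross-validation and a 60% core-consistency threshold, significance level
#' 0.05, and network-dominance count 5. Overrides are recorded in the run
#' manifest of the results bundle.
#'
#' @param mode `"synthetic"` (generate a cohort) or `"files"` (read a cohort
#'   directory written by [write_cohort()]).
#' @param synth a [synth_config()] for synthetic mode.
#' @param input_dir cohort directory for files mode.
#' @param f_low,f_high band-pass edges in Hz.
#' @param W_target retained windows per subject.
#' @param step sliding step in volumes.
#' @param n_drop initial volumes to drop (files mode; synthetic series are
#'   generated post-discard).
#' @param assume_prefiltered skip band-pass filtering of the input series
#'   (synthetic series are generated already filtered).
#' @param R_range candidate ranks.
#' @param n_folds cross-validation folds for rank selection.
#' @param cc_threshold core-consistency threshold in percent.
#' @param alpha significance level for the feature comparisons.
#' @param min_count network-dominance ROI count.
#' @param keep_unit_diagonal diagonal policy for the group tensor.
#' @param n_restarts,max_iter,tol final-fit settings for [nncp()].
#' @param sweep_restarts,sweep_max_iter,sweep_tol settings for the rank
#'   sweep (lighter than the final fit).
#' @param seed root seed.
#' @param output_dir optional directory for TSV/JSON outputs.
#' @return a `run_config` list.
#' @export
run_config <- function(mode = c("synthetic", "files"),
                       synth = synth_config(),
                       input_dir = NULL,
                       f_low = 0.01, f_high = 0.1,
                       W_target = 120L, step = 1L, n_drop = 4L,
                       assume_prefiltered = (mode[1] == "synthetic"),
                       R_range = 1:10, n_folds = 3L, cc_threshold = 60,
                       alpha = 0.05, min_count = 5L,
                       keep_unit_diagonal = FALSE,
                       n_restarts = 10L, max_iter = 500L, tol = 1e-8,
                       sweep_restarts = 2L, sweep_max_iter = 100L,
                       sweep_tol = 1e-6,
                       seed = 1L, output_dir = NULL) {
  mode <- match.arg(mode)
  if (mode == "files" && is.null(input_dir)) {
    fcp_stop("fcp_config_error", "files mode requires input_dir")
  }
  structure(as.list(environment()), class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Top-level keys mirror the arguments of [run_config()]; a `synth` mapping
#' holds [synth_config()] fields, with `groups` a list of
#' label/n_subjects/pattern_count/tr/n_volumes mappings.
#'
#' @param path YAML file path.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$synth)) {
    if (!is.null(y$synth$groups)) {
      y$synth$groups <- lapply(y$synth$groups, function(g) do.call(synth_group, g))
    }
    y$synth <- do.call(synth_config, y$synth)
  }
  do.call(run_config, y)
}

#' Run the full analysis pipeline
#'
#' Executes: ROI signal ingestion (synthetic generation or cohort files) ->
#' sliding-window dynamic FC with zero-variance screening -> truncation ->
#' Tucker-weighted group FC tensors -> rank selection by cross-validated
#' core consistency -> non-negative CP brain patterns with network
#' annotation and cross-subtype grouping -> feature-table normalization ->
#' pairwise ROI comparisons with BH-FDR -> pattern-difference and
#' multi-comparison overlap reports.
#'
#' @param config a [run_config()].
#' @return an object of class `fcp_result` bundling per-group dynamic FC
#'   summaries, exclusion log, group tensors, rank profiles, fitted `nncp`
#'   models, annotated patterns, pattern groups, comparison results and
#'   overlap reports, plus a run manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  band <- bandpass_spec(config$f_low, config$f_high)
  wl <- window_length_seconds(band$f_low)
  swspec <- sliding_window_spec(L = wl, step_volumes = config$step,
                                W_target = config$W_target)

  stage <- function(what, expr) {
    tryCatch(expr, fcp_error = function(e) {
      e$message <- sprintf("[stage %s] %s", what, e$message)
      stop(e)
    })
  }

  # --- ingest -------------------------------------------------------------
  truth <- NULL
  atlas <- NULL
  if (config$mode == "synthetic") {
    gen <- stage("synthetic_data", generate_timeseries(config$synth))
    groups_ts <- gen$groups
    truth <- gen$truth
    feat_raw <- stage("synthetic_data",
                      generate_feature_tables(config$synth))
    atlas <- stage("synthetic_data",
                   generate_atlas(config$synth$n_rois, 12L,
                                  derive_seed(config$seed, 77L)))
  } else {
    groups_ts <- stage("roi_signals", read_cohort(config$input_dir))
    feat_raw <- NULL
    cdir <- config$input_dir
    if (file.exists(file.path(cdir, "atlas_centroids.tsv"))) {
      atlas <- list(
        centroids = utils::read.delim(file.path(cdir, "atlas_centroids.tsv")),
        reference = utils::read.delim(file.path(cdir, "atlas_reference.tsv")))
    }
  }
  roi_ids <- groups_ts[[1]]$roi_ids

  preprocess <- function(set) {
    if (config$mode == "files") {
      set$subjects <- lapply(set$subjects, function(s) {
        s$signal <- drop_initial_volumes(s$signal, config$n_drop)
        if (!config$assume_prefiltered) {
          s$signal <- bandpass_filter(s$signal, s$tr, band)
        }
        s
      })
    }
    set
  }

  # --- dynamic FC + QC + truncation --------------------------------------
  dfc <- list(); excluded <- list(); tensors <- list()
  selections <- list(); models <- list(); patterns <- list()
  network_map <- if (!is.null(atlas)) {
    stage("subtype_comparison", assign_networks(atlas$centroids, atlas$reference))
  } else NULL

  for (g in names(groups_ts)) {
    set <- preprocess(groups_ts[[g]])
    scr <- stage("dynamic_fc", screen_subjects(set, swspec))
    excluded[[g]] <- scr$excluded
    dfc[[g]] <- stage("dynamic_fc", lapply(scr$kept, truncate_windows,
                                           W_target = config$W_target))
    tensors[[g]] <- stage("group_tensor", build_group_tensor(
      dfc[[g]], W_target = config$W_target,
      keep_unit_diagonal = config$keep_unit_diagonal, group = g))
    selections[[g]] <- stage("cp_patterns", select_rank(
      dfc[[g]], R_range = config$R_range, n_folds = config$n_folds,
      threshold = config$cc_threshold, seed = derive_seed(config$seed, 300L),
      W_target = config$W_target,
      keep_unit_diagonal = config$keep_unit_diagonal,
      n_restarts = config$sweep_restarts,
      max_iter = config$sweep_max_iter, tol = config$sweep_tol))
    models[[g]] <- stage("cp_patterns", nncp(
      tensors[[g]], rank = selections[[g]]$selected,
      n_restarts = config$n_restarts, max_iter = config$max_iter,
      tol = config$tol, seed = derive_seed(config$seed, 400L)))
    patterns[[g]] <- stage("cp_patterns", brain_patterns(
      models[[g]], roi_ids = roi_ids, network_map = network_map,
      min_count = config$min_count))
  }

  pattern_groups <- stage("cp_patterns",
                          match_patterns_across_groups(patterns))

  # --- feature tables -----------------------------------------------------
  features <- list()
  if (!is.null(feat_raw)) {
    for (fname in names(feat_raw)) {
      features[[fname]] <- lapply(names(feat_raw[[fname]]), function(g) {
        feature_table(feat_raw[[fname]][[g]], feature = fname, group = g)
      })
      names(features[[fname]]) <- names(feat_raw[[fname]])
    }
  }

  # --- pairwise comparisons + overlaps ------------------------------------
  gnames <- names(groups_ts)
  pairs <- utils::combn(gnames, 2, simplify = FALSE)
  comparisons <- list(); overlaps <- list()
  for (pr in pairs) {
    key <- paste(pr, collapse = "_vs_")
    sets <- list()
    for (fname in names(features)) {
      cmp <- stage("subtype_comparison", compare_features(
        features[[fname]][[pr[1]]], features[[fname]][[pr[2]]],
        alpha = config$alpha, network_map = network_map))
      comparisons[[key]][[fname]] <- cmp
      sets[[fname]] <- cmp$table$roi[cmp$table$significant]
    }
    pd <- stage("subtype_comparison",
                pattern_difference_rois(pattern_groups, pr[1], pr[2]))
    sets$pattern <- attr(pd, "pooled") %||% character(0)
    overlaps[[key]] <- stage("subtype_comparison",
                             overlap_report(pr, sets))
    overlaps[[key]]$pattern_differences <- pd
  }

  manifest <- list(
    mode = config$mode, seed = config$seed,
    band = c(config$f_low, config$f_high),
    window = list(L_s = wl, step = config$step, W_target = config$W_target),
    sweep = list(R_range = range(config$R_range), n_folds = config$n_folds,
                 cc_threshold = config$cc_threshold),
    alpha = config$alpha, min_count = config$min_count,
    diagonal = if (config$keep_unit_diagonal) "unit" else "zero",
    n_excluded = sum(vapply(excluded, nrow, integer(1))),
    selected_ranks = vapply(selections, `[[`, numeric(1), "selected"),
    package_version = as.character(utils::packageVersion("fcpatterns")))

  res <- structure(
    list(config = config, manifest = manifest, truth = truth,
         exclusions = excluded, tensors = tensors, selections = selections,
         models = models, patterns = patterns,
         pattern_groups = pattern_groups, features = features,
         network_map = network_map, comparisons = comparisons,
         overlaps = overlaps, roi_ids = roi_ids),
    class = "fcp_result")
  if (!is.null(config$output_dir)) write_result(res, config$output_dir)
  res
}

#' @export
print.fcp_result <- function(x, ...) {
  cat("Dynamic-FC brain-pattern analysis\n")
  cat(sprintf("  groups: %s\n", paste(names(x$models), collapse = ", ")))
  cat(sprintf("  selected ranks: %s\n",
              paste(sprintf("%s=%d", names(x$manifest$selected_ranks),
                            x$manifest$selected_ranks), collapse = ", ")))
  cat(sprintf("  excluded subjects: %d\n", x$manifest$n_excluded))
  cat(sprintf("  pattern groups: %d\n", length(x$pattern_groups)))
  for (key in names(x$overlaps)) {
    o <- x$overlaps[[key]]
    cat(sprintf("  %s: %d ROIs in >= 2 comparisons\n", key,
                length(o$at_least_two)))
  }
  invisible(x)
}

#' Write a results bundle to TSV/JSON files
#'
#' @param res an `fcp_result`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_result <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(res$manifest, file.path(dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  excl <- do.call(rbind, res$exclusions)
  utils::write.table(excl, file.path(dir, "exclusions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (g in names(res$patterns)) {
    rows <- do.call(rbind, lapply(res$patterns[[g]], function(p) {
      if (length(p$roi_set) == 0) return(NULL)
      data.frame(pattern = p$rank, lambda = p$lambda, roi = p$roi_set,
                 loading = unname(p$loadings[p$roi_set]),
                 network = if (!is.null(res$network_map))
                   unname(res$network_map[p$roi_set]) else NA,
                 stringsAsFactors = FALSE)
    }))
    utils::write.table(rows, file.path(dir, sprintf("patterns_%s.tsv", g)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(res$selections[[g]]$profile,
                       file.path(dir, sprintf("cc_profile_%s.tsv", g)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  for (key in names(res$comparisons)) {
    for (fname in names(res$comparisons[[key]])) {
      utils::write.table(
        res$comparisons[[key]][[fname]]$table,
        file.path(dir, sprintf("compare_%s_%s.tsv", fname, key)),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
    o <- res$overlaps[[key]]
    jsonlite::write_json(
      list(pair = o$pair, at_least_two = o$at_least_two,
           more_than_two = o$more_than_two, membership = o$membership),
      file.path(dir, sprintf("overlap_%s.json", key)),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(dir)
}
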