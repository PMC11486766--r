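# Seeded synthetic cohort generator. Plants overlapping connectivity
# communities with smooth non-negative temporal envelopes into band-limited
# ROI time series, plants ROI-level effects into ALFF/fALFF/GMV feature
# tables, and builds a toy atlas, so that every downstream stage of the
# pipeline can be validated against known ground truth.

#' Configure a synthetic group
#'
#' One subtype group of a synthetic cohort: its label, size, number of planted
#' connectivity communities, repetition time and scan length.
#'
#' @param label group label (character scalar).
#' @param n_subjects number of subjects (>= 2).
#' @param pattern_count number of planted modulated connectivity
#'   communities. A noisy cohort's group tensor additionally carries one
#'   constant-course baseline pattern created by the pipeline's
#'   absolute-value step, so the group exhibits `pattern_count + 1`
#'   recoverable brain patterns.
#' @param tr repetition time in seconds.
#' @param n_volumes number of volumes per scan.
#' @return a `synth_group` list.
#' @export
synth_group <- function(label, n_subjects, pattern_count, tr, n_volumes) {
  if (!is_count(n_subjects, 2L)) {
    fcp_stop("fcp_config_error", "each group needs at least 2 subjects")
  }
  if (!is_count(pattern_count) || tr <= 0 || !is_count(n_volumes, 2L)) {
    fcp_stop("fcp_config_error", "invalid group definition")
  }
  structure(
    list(label = as.character(label), n_subjects = as.integer(n_subjects),
         pattern_count = as.integer(pattern_count), tr = as.numeric(tr),
         n_volumes = as.integer(n_volumes)),
    class = "synth_group"
  )
}

#' Configure a synthetic cohort
#'
#' Defaults emulate the multi-site autism-spectrum cohort geometry the
#' pipeline targets: three subtype groups of very unequal size (152/54/28),
#' site repetition times of 2.0/2.2/3.0 s, ~200 ROIs, two planted modulated
#' communities for the first ("autism-like") group and three for the other
#' two (the extra community standing for the subcortical/default-mode block
#' the others exhibit). On top of the planted communities, the pipeline's
#' absolute-value step always turns the averaged zero-mean background into
#' one additional constant-course baseline pattern, so these cohorts
#' exhibit 3 versus 4 recoverable brain patterns.
#'
#' @param n_rois number of ROIs.
#' @param groups list of [synth_group()] definitions. The first group is the
#'   reference ("autism-like") group; feature effects are planted into the
#'   second group.
#' @param community_size number of ROIs per planted community.
#' @param overlap_fraction fraction of ROIs shared between consecutive
#'   communities, in `[0, 1)`.
#' @param snr peak community-signal-to-noise ratio (> 0): at full envelope a
#'   member ROI's community signal has `snr` times the noise standard
#'   deviation, so its within-community correlation peaks at
#'   `snr^2 / (snr^2 + 1)`.
#' @param effect_rois data frame with columns `feature` (one of "ALFF",
#'   "fALFF", "GMV"), `roi` (1-based index) and `d` (Cohen's d shift applied
#'   to the second group), or `NULL`.
#' @param n_constant_roi_subjects number of subjects (across the cohort)
#'   given one constant ROI signal, as quality-control targets.
#' @param static_fc fraction (in `[0, 1)`) of each ROI's noise standard
#'   deviation carried by a group-shared static connectivity baseline —
#'   `n_static_factors` latent factors with fixed random loadings per group.
#'   Real resting-state noise is spatially correlated and group-stable
#'   (physiological noise, global-signal residue, the static connectome);
#'   without this term the off-community background of the group tensor
#'   would be unrealistically homogeneous.
#' @param n_static_factors number of static baseline factors (default 8).
#' @param seed integer root seed; all randomness derives from it.
#' @return a `synth_config` list.
#' @export
synth_config <- function(n_rois = 200L,
                         groups = list(
                           synth_group("autism", 152L, 2L, 2.0, 180L),
                           synth_group("asperger", 54L, 3L, 2.2, 170L),
                           synth_group("pddnos", 28L, 3L, 3.0, 160L)
                         ),
                         community_size = 20L,
                         overlap_fraction = 0.2,
                         snr = 3,
                         effect_rois = NULL,
                         n_constant_roi_subjects = 3L,
                         static_fc = 0.5,
                         n_static_factors = 10L,
                         seed = 1L) {
  if (!is_count(n_rois, 2L)) fcp_stop("fcp_config_error", "n_rois must be >= 2")
  if (!is_count(community_size, 2L)) {
    fcp_stop("fcp_config_error", "community_size must be >= 2")
  }
  stopifnot_scalar_prob(overlap_fraction, "overlap_fraction")
  if (!(is.numeric(snr) && length(snr) == 1L && snr > 0)) {
    fcp_stop("fcp_config_error", "snr must be a positive scalar")
  }
  if (!is.null(effect_rois)) {
    effect_rois <- as.data.frame(effect_rois)
    if (!all(c("feature", "roi", "d") %in% names(effect_rois))) {
      fcp_stop("fcp_config_error",
               "effect_rois needs columns feature, roi, d")
    }
    bad <- setdiff(unique(effect_rois$feature), c("ALFF", "fALFF", "GMV"))
    if (length(bad) > 0) {
      fcp_stop("fcp_config_error",
               sprintf("unknown feature name(s): %s", paste(bad, collapse = ", ")))
    }
    if (any(effect_rois$roi < 1 | effect_rois$roi > n_rois)) {
      fcp_stop("fcp_config_error", "effect_rois$roi out of range")
    }
  }
  if (!is_count(n_constant_roi_subjects, 0L)) {
    fcp_stop("fcp_config_error", "n_constant_roi_subjects must be >= 0")
  }
  stopifnot_scalar_prob(static_fc, "static_fc")
  if (!is_count(n_static_factors)) {
    fcp_stop("fcp_config_error", "n_static_factors must be a positive count")
  }
  groups <- lapply(groups, function(g) {
    if (!inherits(g, "synth_group")) do.call(synth_group, g) else g
  })
  structure(
    list(n_rois = as.integer(n_rois), groups = groups,
         community_size = as.integer(community_size),
         overlap_fraction = overlap_fraction, snr = snr,
         effect_rois = effect_rois,
         n_constant_roi_subjects = as.integer(n_constant_roi_subjects),
         static_fc = static_fc,
         n_static_factors = as.integer(n_static_factors),
         seed = as.integer(seed)),
    class = "synth_config"
  )
}

#' Generate overlapping community memberships
#'
#' Draws `r_true` ROI communities of `community_size` ROIs each such that
#' consecutive communities share exactly `round(overlap_fraction *
#' community_size)` ROIs; any remaining ROIs belong to no community.
#'
#' @param n_rois number of ROIs available.
#' @param r_true number of communities.
#' @param community_size ROIs per community.
#' @param overlap_fraction fraction shared between consecutive communities.
#' @param seed integer seed.
#' @return list of `r_true` integer vectors of ROI indices.
#' @export
generate_memberships <- function(n_rois, r_true, community_size,
                                 overlap_fraction, seed) {
  stopifnot_scalar_prob(overlap_fraction, "overlap_fraction")
  shared <- as.integer(round(overlap_fraction * community_size))
  fresh_per_set <- community_size - shared
  needed <- community_size + (r_true - 1L) * fresh_per_set
  if (needed > n_rois) {
    fcp_stop("fcp_config_error", sprintf(
      "infeasible community geometry: %d distinct ROIs needed, %d available",
      needed, n_rois))
  }
  with_seed(seed, {
    pool <- sample.int(n_rois)
    sets <- vector("list", r_true)
    sets[[1]] <- sort(pool[seq_len(community_size)])
    used <- community_size
    own <- pool[seq_len(community_size)]  # insertion order of previous set
    for (k in seq_len(r_true)[-1]) {
      carry <- if (shared > 0) own[seq(length(own) - shared + 1L, length(own))]
               else integer(0)
      fresh <- pool[used + seq_len(fresh_per_set)]
      used <- used + fresh_per_set
      sets[[k]] <- sort(c(carry, fresh))
      own <- c(carry, fresh)
    }
    sets
  })
}

# Planted within-community correlation course for community r: a squared
# raised cosine in CORRELATION space, peaking at rho_max = snr^2/(snr^2+1)
# (the correlation a unit-envelope community attains at the given
# signal-to-noise ratio). The amplitude envelope a_r(t) is obtained by
# inverting the correlation-compression rho = s a^2 / (s a^2 + 1): this
# plants the designed temporal curves into the quantity the decomposition
# actually sees (window correlations), rather than into the amplitude
# domain where the compression would distort and entangle them.
rho_course <- function(t_s, period_s, phase, snr) {
  s2 <- snr^2
  (s2 / (s2 + 1)) * cos(pi * t_s / period_s + phase)^2
}

envelope_from_rho <- function(rho, snr) {
  sqrt(rho / (snr^2 * (1 - rho)))
}

#' Generate synthetic ROI time series for a cohort
#'
#' Each member ROI of community r carries the product of a band-limited
#' (0.01-0.1 Hz) latent Gaussian signal and a smooth non-negative envelope,
#' plus independent band-limited noise scaled by `1/snr`. Envelopes are
#' derived from squared-raised-cosine target curves specified in correlation
#' space (distinct period and phase per community), so the planted
#' within-community window correlations follow the designed curves directly.
#' Designated quality-control subjects get one ROI replaced by a constant,
#' so the zero-variance screen can find them.
#'
#' @param config a [synth_config()].
#' @return list with `groups` (named list of `roi_timeseries_set`) and
#'   `truth` (a `synthetic_truth` list with `pattern_membership`,
#'   `temporal_profiles`, `planted_effects`, `qc_excluded_subjects`).
#' @export
generate_timeseries <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  n <- config$n_rois
  band <- bandpass_spec(0.01, 0.1)
  roi_ids <- sprintf("roi%03d", seq_len(n))

  all_ids <- unlist(lapply(config$groups, function(g) {
    paste0(g$label, "_", sprintf("s%03d", seq_len(g$n_subjects)))
  }))
  qc_ids <- with_seed(derive_seed(config$seed, 999L), {
    if (config$n_constant_roi_subjects > 0) {
      sort(sample(all_ids, min(config$n_constant_roi_subjects, length(all_ids))))
    } else character(0)
  })

  groups <- list()
  membership <- list()
  profiles <- list()
  subj_counter <- 0L
  for (gi in seq_along(config$groups)) {
    g <- config$groups[[gi]]
    r_true <- g$pattern_count
    mem <- generate_memberships(n, r_true, config$community_size,
                                config$overlap_fraction,
                                derive_seed(config$seed, gi))
    # Envelope periods (seconds) and phases: periods must exceed twice the
    # 100 s analysis window (or window averaging flattens them) yet fit
    # within a typical scan; phases are staggered so the window-averaged
    # profiles stay well conditioned (condition number <= 9 for up to 4
    # communities on all site geometries; usable to 5). For <= 3 communities
    # a single period with phases at pi/r spacing makes the correlation
    # curves sum to a constant, so no further constant-course component can
    # masquerade as an extra certifiable pattern beyond the baseline.
    rr <- seq_len(r_true)
    if (r_true <= 3L) {
      periods <- rep(220, r_true)
      phases <- (rr - 1L) * pi / r_true
    } else {
      periods <- ifelse(rr <= 3L, 220, 340)
      phases <- ifelse(rr <= 3L, (rr - 1L) * pi / 3, pi / 6 + (rr - 4L) * pi / 3)
    }
    t_s <- (seq_len(g$n_volumes) - 1L) * g$tr
    rho_mat <- vapply(seq_len(r_true),
                      function(r) rho_course(t_s, periods[r], phases[r],
                                             config$snr),
                      numeric(g$n_volumes))                  # T x r
    env_mat <- envelope_from_rho(rho_mat, config$snr)
    # group-shared static baseline loadings (unit-norm rows)
    q_s <- config$n_static_factors
    beta <- config$static_fc
    g_stat <- with_seed(derive_seed(config$seed, 2000L + gi), {
      m <- matrix(rnorm(n * q_s), n, q_s)
      m / sqrt(rowSums(m^2))
    })

    subjects <- vector("list", g$n_subjects)
    for (si in seq_len(g$n_subjects)) {
      subj_counter <- subj_counter + 1L
      sid <- paste0(g$label, "_", sprintf("s%03d", si))
      sig <- with_seed(derive_seed(config$seed, 10000L + subj_counter), {
        # band-limited unit-sd latents, one per community
        lat <- matrix(rnorm(g$n_volumes * r_true), g$n_volumes, r_true)
        lat <- t(bandpass_filter(t(lat), g$tr, band))
        lat <- sweep(lat, 2, apply(lat, 2, stats::sd), `/`)
        comp <- lat * env_mat                      # T x r modulated latents
        s <- matrix(0, n, g$n_volumes)
        for (r in seq_len(r_true)) {
          s[mem[[r]], ] <- s[mem[[r]], ] +
            matrix(comp[, r], nrow = length(mem[[r]]), ncol = g$n_volumes,
                   byrow = TRUE)
        }
        # band-limited unit-sd noise scaled by 1/snr, so a unit-envelope
        # community attains correlation snr^2/(snr^2+1) exactly; a fraction
        # beta of the noise sd is the group-shared static baseline; the sum
        # of band-limited terms needs no further filtering
        eps <- matrix(rnorm(n * g$n_volumes), n, g$n_volumes)
        eps <- bandpass_filter(eps, g$tr, band)
        eps <- eps / apply(eps, 1, stats::sd)
        if (beta > 0) {
          v <- matrix(rnorm(g$n_volumes * q_s), g$n_volumes, q_s)
          v <- t(bandpass_filter(t(v), g$tr, band))
          v <- sweep(v, 2, apply(v, 2, stats::sd), `/`)
          eps <- sqrt(1 - beta^2) * eps + beta * (g_stat %*% t(v))
        }
        s + eps / config$snr
      })
      if (sid %in% qc_ids) {
        roi_const <- 1L + (subj_counter %% n)
        sig[roi_const, ] <- 100
      }
      subjects[[si]] <- list(subject_id = sid, group = g$label, tr = g$tr,
                             signal = sig)
    }
    groups[[g$label]] <- roi_timeseries_set(subjects, roi_ids)
    membership[[g$label]] <- mem
    # Temporal profile of community r: the planted correlation course
    # averaged over each 100 s window at unit step (the default
    # sliding-window grid) — the curve the temporal CP loadings recover.
    ni <- window_length_volumes(window_length_seconds(band$f_low), g$tr)
    wn <- g$n_volumes - ni + 1L
    prof <- matrix(0, r_true, wn)
    for (r in seq_len(r_true)) {
      cs <- c(0, cumsum(rho_mat[, r]))
      prof[r, ] <- (cs[(ni + 1):(wn + ni)] - cs[1:wn]) / ni
    }
    profiles[[g$label]] <- prof
  }

  truth <- structure(
    list(pattern_membership = membership, temporal_profiles = profiles,
         planted_effects = config$effect_rois, qc_excluded_subjects = qc_ids),
    class = "synthetic_truth"
  )
  list(groups = groups, truth = truth)
}

#' Generate ROI-level feature tables with planted effects
#'
#' Baseline values are i.i.d. standard normal; each planted effect shifts the
#' mean of the second group at one ROI by Cohen's d.
#'
#' @param config a [synth_config()].
#' @param seed integer seed (defaults to the config seed).
#' @return named list (`ALFF`, `fALFF`, `GMV`) of named lists of
#'   subjects-by-ROI matrices, one per group.
#' @export
generate_feature_tables <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "synth_config"))
  n <- config$n_rois
  feats <- c("ALFF", "fALFF", "GMV")
  out <- stats::setNames(vector("list", length(feats)), feats)
  for (fi in seq_along(feats)) {
    fname <- feats[fi]
    tabs <- list()
    for (gi in seq_along(config$groups)) {
      g <- config$groups[[gi]]
      m <- with_seed(derive_seed(seed, 500L + 10L * fi + gi), {
        matrix(rnorm(g$n_subjects * n), g$n_subjects, n)
      })
      rownames(m) <- paste0(g$label, "_", sprintf("s%03d", seq_len(g$n_subjects)))
      colnames(m) <- sprintf("roi%03d", seq_len(n))
      if (gi == 2L && !is.null(config$effect_rois)) {
        eff <- config$effect_rois[config$effect_rois$feature == fname, ,
                                  drop = FALSE]
        for (k in seq_len(nrow(eff))) {
          m[, eff$roi[k]] <- m[, eff$roi[k]] + eff$d[k]
        }
      }
      tabs[[g$label]] <- m
    }
    out[[fname]] <- tabs
  }
  out
}

#' Generate a toy atlas with labelled reference points
#'
#' ROI centroids are uniform in an MNI-like box; reference points are drawn
#' near `n_networks` well-separated cluster centers carrying network labels
#' from the canonical 12-network vocabulary.
#'
#' @param n_rois number of ROI centroids.
#' @param n_networks number of labelled networks (<= 12 and <= n_rois).
#' @param seed integer seed.
#' @return list with `centroids` (data frame roi_id, x, y, z), `reference`
#'   (data frame x, y, z, network) and `true_mapping` (character vector, the
#'   nearest-cluster-center label per ROI).
#' @export
generate_atlas <- function(n_rois, n_networks, seed) {
  if (n_networks > n_rois) {
    fcp_stop("fcp_config_error", "n_networks must be <= n_rois")
  }
  labels <- network_labels()[seq_len(min(n_networks, 12L))]
  with_seed(seed, {
    # well-separated cluster centers on a coarse lattice, with jitter
    lat <- as.matrix(expand.grid(x = c(-60, 0, 60), y = c(-60, 0, 60),
                                 z = c(-40, 40)))
    centers <- lat[seq_len(length(labels)), , drop = FALSE] +
      matrix(stats::runif(length(labels) * 3, -5, 5), ncol = 3)
    centroids <- matrix(stats::runif(n_rois * 3, -90, 90), ncol = 3)
    refs <- do.call(rbind, lapply(seq_along(labels), function(k) {
      p <- centers[rep(k, 3L), , drop = FALSE] +
        matrix(stats::rnorm(9, sd = 3), ncol = 3)
      data.frame(x = p[, 1], y = p[, 2], z = p[, 3], network = labels[k],
                 stringsAsFactors = FALSE)
    }))
    d2 <- outer(rowSums(centroids^2), rowSums(centers^2), `+`) -
      2 * centroids %*% t(centers)
    true_map <- labels[apply(d2, 1, which.min)]
    list(
      centroids = data.frame(roi_id = sprintf("roi%03d", seq_len(n_rois)),
                             x = centroids[, 1], y = centroids[, 2],
                             z = centroids[, 3], stringsAsFactors = FALSE),
      reference = refs,
      true_mapping = stats::setNames(true_map, sprintf("roi%03d", seq_len(n_rois)))
    )
  })
}

#' The canonical 12 resting-state network labels
#' @return character vector of length 12.
#' @export
network_labels <- function() {
  c("SMH", "SMM", "CON", "AN", "DMN", "CPN", "VN", "FPN", "SAN", "SCN",
    "VAN", "DAN")
}

#' Write a synthetic cohort to disk as plain-text tables
#'
#' One TSV per subject (rows = volumes, columns = ROIs), a cohort manifest
#' TSV, per-feature tables, atlas tables and the ground truth as JSON.
#'
#' @param cohort result of [generate_timeseries()].
#' @param features result of [generate_feature_tables()] or `NULL`.
#' @param atlas result of [generate_atlas()] or `NULL`.
#' @param dir output directory (created if missing).
#' @return the manifest data frame, invisibly.
#' @export
write_cohort <- function(cohort, features = NULL, atlas = NULL, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "timeseries"), showWarnings = FALSE)
  manifest <- list()
  for (gname in names(cohort$groups)) {
    set <- cohort$groups[[gname]]
    for (s in set$subjects) {
      path <- file.path("timeseries", paste0(s$subject_id, ".tsv"))
      m <- t(s$signal)
      colnames(m) <- set$roi_ids
      utils::write.table(m, file.path(dir, path), sep = "\t", quote = FALSE,
                         row.names = FALSE)
      manifest[[length(manifest) + 1L]] <- data.frame(
        subject_id = s$subject_id, group = s$group, TR_s = s$tr,
        n_volumes = ncol(s$signal), path = path, stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, manifest)
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(features)) {
    for (fname in names(features)) {
      for (gname in names(features[[fname]])) {
        utils::write.table(
          features[[fname]][[gname]],
          file.path(dir, sprintf("%s_%s.tsv", fname, gname)),
          sep = "\t", quote = FALSE, row.names = TRUE, col.names = NA)
      }
    }
  }
  if (!is.null(atlas)) {
    utils::write.table(atlas$centroids, file.path(dir, "atlas_centroids.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(atlas$reference, file.path(dir, "atlas_reference.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(
    list(qc_excluded_subjects = cohort$truth$qc_excluded_subjects,
         pattern_membership = cohort$truth$pattern_membership),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
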