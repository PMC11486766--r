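# fcpatterns

Brain-pattern extraction and subgroup comparison for resting-state fMRI
cohorts, built around non-negative tensor decomposition of dynamic
functional connectivity (FC).

## Who this is for

Neuroimaging researchers comparing diagnostic subgroups (the motivating
case: autism-spectrum subtypes in a multi-site cohort) who want, from
ROI-level resting-state data:

* **overlapping brain patterns** — ROI communities extracted per subgroup
  from group-level dynamic FC, with their temporal activity profiles;
* a principled, cross-validated choice of **how many** patterns each
  subgroup exhibits;
* ROI-wise subgroup comparisons of **ALFF, fALFF and gray-matter volume**
  with FDR control, and a report of ROIs recurring across comparisons.

## The model

Per subject, sliding-window Pearson correlation gives a sequence of
N x N FC matrices: the window spans `L = 1/f_low` seconds (100 s for a
0.01–0.1 Hz band-pass), i.e. `floor(L/TR)` volumes, sliding by one
volume; the first 120 windows are retained. Per subgroup and window `w`,
subjects are averaged with weights from the subject-mode factor of a
Tucker decomposition of the ROI x ROI x subject stack (the first column
of the orthonormal subject factor — equivalently the leading left
singular vector of the mode-3 unfolding):

    Ḡ_w = Σ_s Z1_s M_s,w / Σ_s Z1_s

The absolute values of the Ḡ_w form a non-negative tensor
G ∈ R^(N x N x W), decomposed by non-negative CANDECOMP/PARAFAC:

    G ≈ Σ_{r=1..R} λ_r · x_r ∘ x_r ∘ z_r,   x_r, z_r ≥ 0, ‖x_r‖ = ‖z_r‖ = 1

Each rank-one term is a *brain pattern*: `x_r` scores every ROI's
participation (ROIs above mean + 1 SD form the pattern's community),
`z_r` is its temporal profile, `λ_r` its energy. `R` is chosen by the
core-consistency diagnostic (CORCONDIA) — the largest `R` whose fold-mean
core consistency under 3-fold subject cross-validation stays ≥ 60%.
Feature tables are compared per ROI with Welch t-tests and
Benjamini–Hochberg FDR (`q < 0.05`).

The alternating non-negative least squares uses an exact block principal
pivoting solver per subproblem, a deterministic SVD-based initialization
plus random restarts, and post-hoc symmetrization of the two ROI modes.
See the methods vignette (`vignettes/brain-pattern-extraction.Rmd`) for
every numerical choice and the validation design.

## Worked example

A seeded synthetic cohort (the package ships a generator with planted
connectivity communities and known ground truth) with three subgroups:
the first planted with 1 modulated community, the other two with 2 —
plus the constant baseline pattern that the absolute-value step always
contributes, these subgroups exhibit 2 vs 3 vs 3 patterns:

```r
library(fcpatterns)
cfg <- run_config(
  mode = "synthetic",
  synth = synth_config(
    n_rois = 40,
    groups = list(synth_group("autism",   7, 1, 2.0, 169),
                  synth_group("asperger", 7, 2, 2.0, 169),
                  synth_group("pddnos",   7, 2, 2.0, 169)),
    community_size = 8, overlap_fraction = 0.2, snr = 3,
    effect_rois = data.frame(feature = "ALFF", roi = 5L, d = 2),
    n_constant_roi_subjects = 1, seed = 7),
  W_target = 120L, R_range = 1:5,
  sweep_restarts = 1L, sweep_max_iter = 120L,
  seed = 7)
res <- run_pipeline(cfg)
print(res)
#> Dynamic-FC brain-pattern analysis
#>   groups: autism, asperger, pddnos
#>   selected ranks: autism=2, asperger=3, pddnos=3
#>   excluded subjects: 1
#>   pattern groups: 8
#>   autism_vs_asperger: 0 ROIs in >= 2 comparisons
#>   autism_vs_pddnos: 0 ROIs in >= 2 comparisons
#>   asperger_vs_pddnos: 1 ROIs in >= 2 comparisons
summary(res$models$asperger)
#> Non-negative CP model: rank 3, fit 0.5542, asymmetry 1.86e-05
#>  pattern lambda rois_above_threshold
#>        1  40.26                    8
#>        2  39.20                    8
#>        3  32.16                    7
```

Reading the output: rank selection recovered the planted pattern counts
(1+baseline vs 2+baseline); the one subject given a constant ROI signal
was caught by the zero-variance screen; each of the asperger-like
subgroup's three patterns concentrates on ~8 of 40 ROIs (the planted
community size), with `lambda` ordering the patterns by energy and `fit`
the tensor variance explained at rank 3. The comparison lines count ROIs
involved in at least two of the four subgroup comparisons (pattern
differences, ALFF, fALFF, GMV).

Larger, full-scale cohorts (200 ROIs, 152/54/28 subjects, mixed TRs)
are the `synth_config()` defaults; `run_config(mode = "files",
input_dir = ...)` ingests a cohort directory written by `write_cohort()`
(per-subject TSV time series plus a manifest).

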