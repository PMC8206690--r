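# End-to-end pipeline plumbing: wires simulate -> features -> screen ->
# evaluate -> controls, writes every artefact as delimited text or JSON
# next to a run manifest, and is byte-reproducible given the manifest.

#' Run the screening pipeline
#'
#' Executes the requested stages in order and writes their outputs under
#' `out_dir`, together with `manifest.json` recording the full
#' configuration, seeds and package version. Identical manifests yield
#' byte-identical outputs. Stages:
#' \describe{
#'   \item{simulate}{generate a synthetic cohort (`cohort.csv`); skipped
#'     when `input` is given.}
#'   \item{features}{night feature matrix (`features.csv`).}
#'   \item{screen}{two-layer screening; `screen_subjects.csv`,
#'     `screen_nights.csv`, `metrics.json`.}
#'   \item{evaluate}{per-feature statistics (`feature_stats.csv`),
#'     threshold sweep (`threshold_sweep.csv`), subject-level ROC points
#'     (`roc.csv`).}
#'   \item{randomize}{random-label control (`randomization.csv`).}
#'   \item{ablate}{night-count ablation (`ablation.csv`).}
#' }
#'
#' @param out_dir Output directory (created if missing).
#' @param stages Character vector of stages, in the order above.
#' @param input Optional path to an existing cohort file
#'   ([read_cohort()] format); replaces the simulate stage.
#' @param classifier `"rf"` or `"svm"`.
#' @param sim Arguments for [sim_config()] as a named list.
#' @param levels,sampen_m,sampen_r_fraction,swr_orientation Feature
#'   settings.
#' @param n_perm Permutations for the randomize stage.
#' @param k_range Night counts for the ablate stage.
#' @param seed Master seed; each stage derives its own seed from it.
#' @return Invisibly, a named list of the written file paths plus the
#'   fitted `ci_screen` object (`$fit`) when the screen stage ran.
#' @export
run_pipeline <- function(out_dir,
                         stages = c("simulate", "features", "screen",
                                    "evaluate"),
                         input = NULL, classifier = "rf", sim = list(),
                         levels = c(0, 20, 40, 80), sampen_m = 2L,
                         sampen_r_fraction = 0.2,
                         swr_orientation = "tst_over_waso",
                         n_perm = 20L, k_range = 3:7, seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    package = "actiscreen",
    version = as.character(utils::packageVersion("actiscreen")),
    stages = stages, input = input, classifier = classifier, sim = sim,
    levels = levels, sampen_m = sampen_m,
    sampen_r_fraction = sampen_r_fraction,
    swr_orientation = swr_orientation, n_perm = n_perm,
    k_range = k_range, seed = seed,
    stage_seeds = list(simulate = derive_seed(seed, 1L),
                       screen = derive_seed(seed, 2L),
                       randomize = derive_seed(seed, 3L),
                       ablate = derive_seed(seed, 4L)))
  paths <- list(manifest = file.path(out_dir, "manifest.json"))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")

  cohort <- NULL
  if (!is.null(input)) {
    if (!file.exists(input)) stop("stage input: file not found: ", input)
    cohort <- read_cohort(input)
  } else if ("simulate" %in% stages) {
    cohort <- do.call(simulate_cohort,
                      c(sim, list(seed = manifest$stage_seeds$simulate)))
    paths$cohort <- file.path(out_dir, "cohort.csv")
    write_cohort(cohort, paths$cohort)
  }
  if (is.null(cohort))
    stop("no cohort: provide 'input' or include the simulate stage")

  features <- night_feature_matrix(
    cohort, levels = levels, sampen_m = sampen_m,
    sampen_r_fraction = sampen_r_fraction,
    swr_orientation = swr_orientation)
  if ("features" %in% stages) {
    paths$features <- file.path(out_dir, "features.csv")
    write_feature_matrix(features, paths$features)
  }

  fit <- NULL
  if ("screen" %in% stages) {
    fit <- ci_screen(cohort, classifier = classifier,
                     features = features, levels = levels,
                     seed = manifest$stage_seeds$screen)
    paths$screen_subjects <- file.path(out_dir, "screen_subjects.csv")
    data.table::fwrite(fit$subject_table, paths$screen_subjects)
    paths$screen_nights <- file.path(out_dir, "screen_nights.csv")
    data.table::fwrite(fit$night_predictions, paths$screen_nights)
    paths$metrics <- file.path(out_dir, "metrics.json")
    jsonlite::write_json(
      list(subject = as.list(fit$metrics),
           night = as.list(fit$night_metrics),
           confusion = as.list(fit$confusion),
           threshold_modal = fit$threshold_modal),
      paths$metrics, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  if ("evaluate" %in% stages) {
    paths$feature_stats <- file.path(out_dir, "feature_stats.csv")
    data.table::fwrite(feature_stats(features), paths$feature_stats)
    if (!is.null(fit)) {
      paths$threshold_sweep <- file.path(out_dir, "threshold_sweep.csv")
      data.table::fwrite(threshold_sweep(fit), paths$threshold_sweep)
      st <- fit$subject_table
      roc <- roc_curve(st$bad_fraction, as.integer(st$group == "CI"))
      paths$roc <- file.path(out_dir, "roc.csv")
      data.table::fwrite(roc$points, paths$roc)
    }
  }

  if ("randomize" %in% stages) {
    paths$randomization <- file.path(out_dir, "randomization.csv")
    data.table::fwrite(
      randomization_control(cohort, n_perm = n_perm,
                            classifier = classifier,
                            features = features,
                            seed = manifest$stage_seeds$randomize),
      paths$randomization)
  }

  if ("ablate" %in% stages) {
    paths$ablation <- file.path(out_dir, "ablation.csv")
    data.table::fwrite(
      night_ablation(cohort, k_range = k_range,
                     classifier = classifier, features = features,
                     seed = manifest$stage_seeds$ablate),
      paths$ablation)
  }

  out <- paths
  out$fit <- fit
  invisible(out)
}
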