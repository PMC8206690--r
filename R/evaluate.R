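# Evaluation machinery: confusion metrics, per-feature group statistics,
# ROC/AUC, threshold sweep, night-count ablation, random-label control.

#' Sensitivity, specificity and accuracy from confusion counts
#'
#' All three on the percent scale: sensitivity = 100 TP/(TP+FN) (CI
#' subjects correctly screened), specificity = 100 TN/(TN+FP), accuracy =
#' 100 (TP+TN)/total. An empty class makes the corresponding rate
#' undefined: it is returned as `NA` with a warning rather than silently
#' zero.
#'
#' @param confusion Named vector or separate counts with elements
#'   `TP`, `FP`, `TN`, `FN`.
#' @return Named numeric vector `sensitivity`, `specificity`, `accuracy`.
#' @examples
#' screen_metrics(c(TP = 8, FP = 1, TN = 9, FN = 2))
#' @export
screen_metrics <- function(confusion) {
  stopifnot(all(c("TP", "FP", "TN", "FN") %in% names(confusion)),
            all(confusion >= 0))
  tp <- confusion[["TP"]]; fp <- confusion[["FP"]]
  tn <- confusion[["TN"]]; fn <- confusion[["FN"]]
  if (tp + fp + tn + fn == 0) stop("no observations")
  sens <- if (tp + fn == 0) {
    warning("no positives: sensitivity undefined"); NA_real_
  } else 100 * tp / (tp + fn)
  spec <- if (tn + fp == 0) {
    warning("no negatives: specificity undefined"); NA_real_
  } else 100 * tn / (tn + fp)
  c(sensitivity = sens, specificity = spec,
    accuracy = 100 * (tp + tn) / (tp + fp + tn + fn))
}

# midrank (Mann-Whitney) AUC of a score for class 1
midrank_auc <- function(score, label) {
  n1 <- sum(label == 1L); n0 <- sum(label == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(score)                        # midranks under ties
  (sum(r[label == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Per-feature group statistics
#'
#' For every feature column: group mean and standard deviation, a
#' two-sided Mann-Whitney U p-value, and the AUC of the feature used as a
#' score for CI nights (midrank formula, so `auc = U/(n1 n2)` holds
#' exactly under ties). The p-value uses the normal approximation with
#' tie correction, the appropriate choice for tie-heavy count-derived
#' features; no multiple-testing correction is applied across rows.
#'
#' @param features Night feature matrix with a `group` column.
#' @param labels Optional 0/1 night labels; defaults to group membership.
#' @return Data frame: `feature`, `mean_healthy`, `sd_healthy`,
#'   `mean_ci`, `sd_ci`, `p_value`, `auc`.
#' @export
feature_stats <- function(features, labels = NULL) {
  labels <- labels %||% night_labels(features)
  if (length(unique(labels)) < 2L) stop("both classes must be present")
  if (min(table(labels)) < 2L) stop("need >= 2 nights per group")
  cols <- feature_columns(features)
  rows <- lapply(cols, function(cn) {
    x <- features[[cn]]
    # a feature constant across all nights carries no discrimination:
    # the normal approximation degenerates, so score it p = 1 directly
    p <- if (length(unique(x)) == 1L) 1 else suppressWarnings(
      wilcox.test(x[labels == 1L], x[labels == 0L], exact = FALSE,
                  correct = FALSE)$p.value)
    data.frame(feature = cn,
               mean_healthy = mean(x[labels == 0L]),
               sd_healthy = sd(x[labels == 0L]),
               mean_ci = mean(x[labels == 1L]),
               sd_ci = sd(x[labels == 1L]),
               p_value = p,
               auc = midrank_auc(x, labels),
               row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Subject-level metrics across all bad-night thresholds
#'
#' Applies the count >= Th screening rule for every Th from 1 to the
#' largest night count and reports the resulting confusion metrics. By
#' construction, sensitivity is nonincreasing and specificity
#' nondecreasing in Th.
#'
#' @param predictions A `ci_screen` fit, or a night-prediction data frame
#'   from [loso_night_predictions()] (then `groups` is required).
#' @param groups Named group vector (`"CI"`/`"healthy"`) per subject.
#' @return Data frame: `th`, `TP`, `FP`, `TN`, `FN`, `sensitivity`,
#'   `specificity`, `accuracy`.
#' @export
threshold_sweep <- function(predictions, groups = NULL) {
  if (inherits(predictions, "ci_screen")) {
    st <- predictions$subject_table
    groups <- stats::setNames(st$group, st$subject_id)
    predictions <- predictions$night_predictions
  }
  stopifnot(!is.null(groups))
  ids <- names(groups)
  bad <- vapply(ids, function(s)
    sum(predictions$pred[predictions$subject_id == s]), integer(1))
  nn <- vapply(ids, function(s)
    sum(predictions$subject_id == s), integer(1))
  is_ci <- groups == "CI"
  rows <- lapply(seq_len(max(nn)), function(th) {
    p <- bad >= th
    conf <- c(TP = sum(is_ci & p), FP = sum(!is_ci & p),
              TN = sum(!is_ci & !p), FN = sum(is_ci & !p))
    cbind(data.frame(th = th), as.data.frame(t(conf)),
          as.data.frame(t(suppressWarnings(screen_metrics(conf)))))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Night-count ablation
#'
#' Reruns the full two-layer pipeline using only each subject's first `k`
#' nights, for each `k` in `k_range`, mirroring the question of how many
#' monitoring nights a deployment needs. A precomputed feature matrix for
#' the full cohort is subset rather than recomputed.
#'
#' @param cohort An `actigraphy_cohort`.
#' @param k_range Night counts to evaluate (default `3:7`).
#' @param classifier,seed,features,... Passed to [ci_screen()].
#' @return Data frame: `k`, subject-level `sensitivity`, `specificity`,
#'   `accuracy`, `threshold_modal`.
#' @export
night_ablation <- function(cohort, k_range = 3:7, classifier = "rf",
                           seed = 1L, features = NULL, ...) {
  features <- features %||% night_feature_matrix(cohort)
  rows <- lapply(k_range, function(k) {
    coh_k <- truncate_nights(cohort, k)
    nt_k <- night_table(coh_k)
    keep <- paste(features$subject_id, features$night_index) %in%
      paste(nt_k$subject_id, nt_k$night_index)
    fit <- ci_screen(coh_k, classifier = classifier,
                     features = features[keep, , drop = FALSE],
                     seed = seed, ...)
    data.frame(k = k, t(fit$metrics),
               threshold_modal = fit$threshold_modal)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Random-label control
#'
#' Permutes the good/bad night labels uniformly at random across all
#' nights (preserving the overall label balance), retrains both layers on
#' the permuted labels, and reports subject-level metrics against the
#' true groups. If the screening signal is real, permuted labels should
#' drive accuracy to chance. `scheme = "iid"` draws fresh Bernoulli
#' labels instead of permuting, for the variant that does not preserve
#' balance. With `n_perm > 1` each permutation is reported as one row.
#'
#' @param cohort An `actigraphy_cohort`.
#' @param n_perm Number of permutations (default 1).
#' @param classifier,seed,features,... Passed to [ci_screen()].
#' @param scheme `"permute"` (default) or `"iid"`.
#' @return Data frame: `perm`, `sensitivity`, `specificity`, `accuracy`.
#' @export
randomization_control <- function(cohort, n_perm = 1L, classifier = "rf",
                                  seed = 1L, features = NULL,
                                  scheme = c("permute", "iid"), ...) {
  scheme <- match.arg(scheme)
  features <- features %||% night_feature_matrix(cohort)
  base_labels <- night_labels(features)
  rows <- lapply(seq_len(n_perm), function(p) {
    set.seed(derive_seed(seed, 7000L + p))
    lab <- if (scheme == "permute") sample(base_labels)
    else rbinom(length(base_labels), 1L, mean(base_labels))
    if (length(unique(lab)) < 2L) lab <- sample(base_labels)
    fit <- ci_screen(cohort, classifier = classifier,
                     features = features, labels = lab,
                     seed = derive_seed(seed, 9000L + p), ...)
    data.frame(perm = p, t(fit$metrics))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Receiver operating characteristic curve
#'
#' Standard ROC by sweeping a decision threshold over the observed
#' scores (classifying score >= t as positive), with trapezoidal AUC.
#' The trapezoidal AUC over the observed scores equals the midrank
#' Mann-Whitney statistic.
#'
#' @param scores Numeric scores, larger meaning more positive.
#' @param labels 0/1 labels, both classes present.
#' @return List with `points` (data frame `threshold`, `fpr`, `tpr`) and
#'   `auc`.
#' @export
roc_curve <- function(scores, labels) {
  stopifnot(length(scores) == length(labels),
            all(labels %in% c(0, 1)))
  if (length(unique(labels)) < 2L) stop("both classes must be present")
  np <- sum(labels == 1); nn <- sum(labels == 0)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  pts <- t(vapply(thr, function(t) {
    p <- scores >= t
    c(fpr = sum(p & labels == 0) / nn, tpr = sum(p & labels == 1) / np)
  }, numeric(2)))
  pts <- data.frame(threshold = thr, fpr = pts[, "fpr"],
                    tpr = pts[, "tpr"])
  auc <- sum(diff(pts$fpr) * (head(pts$tpr, -1) + tail(pts$tpr, -1)) / 2)
  list(points = pts, auc = auc)
}
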