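# Two-layer screening model.
# Layer 1: night-level good(0)/bad(1) classification under
# leave-one-subject-out (LOSO) cross-validation; every night of a healthy
# sleeper is labelled good, every night of a CI subject bad.
# Layer 2: per left-out subject, a bad-night-count threshold Th learned
# from the out-of-fold predictions of the remaining subjects; a subject
# with >= Th predicted bad nights is screened as CI.

#' Classifier configuration for the night-level layer
#'
#' Random forest: 100 trees, square root of the feature count tried at
#' each split, unrestricted tree depth (growth bounded only by the
#' training-set size). Linear support vector machine: box constraint 1,
#' features standardised with training-fold statistics. An optional inner
#' stratified 10-fold cross-validation over a small user-supplied grid
#' (`mtry` for the forest, `cost` for the SVM) can replace the fixed
#' hyperparameters; the default grid is empty.
#'
#' @param kind `"rf"` or `"svm"`.
#' @param rf_n_trees Trees in the forest (default 100).
#' @param svm_cost SVM box constraint (default 1).
#' @param standardize Standardise features with training-fold statistics.
#'   Default: `TRUE` for the SVM, `FALSE` for the scale-invariant forest.
#' @param inner_cv_folds Folds of the inner model-selection CV (default
#'   10).
#' @param grid Named list of hyperparameter candidates (`mtry` or `cost`),
#'   or `NULL` for the fixed configuration.
#' @return A `classifier_spec` list.
#' @export
classifier_spec <- function(kind = c("rf", "svm"), rf_n_trees = 100L,
                            svm_cost = 1, standardize = NULL,
                            inner_cv_folds = 10L, grid = NULL) {
  kind <- match.arg(kind)
  stopifnot(rf_n_trees >= 1L, svm_cost > 0, inner_cv_folds >= 2L)
  structure(list(kind = kind, rf_n_trees = as.integer(rf_n_trees),
                 svm_cost = svm_cost,
                 standardize = standardize %||% (kind == "svm"),
                 inner_cv_folds = as.integer(inner_cv_folds),
                 grid = grid),
            class = "classifier_spec")
}

#' Night labels implied by group membership
#'
#' @param features A night feature matrix (or any data frame with a
#'   `group` column).
#' @return Integer vector: 1 ("bad night") for CI subjects' nights, 0
#'   ("good night") for healthy sleepers' nights.
#' @export
night_labels <- function(features) {
  stopifnot("group" %in% names(features))
  as.integer(features$group == "CI")
}

standardize_fit <- function(x) {
  ctr <- colMeans(x)
  scl <- apply(x, 2L, sd)
  scl[scl == 0] <- 1
  list(center = ctr, scale = scl)
}

standardize_apply <- function(x, fit) {
  scale(x, center = fit$center, scale = fit$scale)
}

# fit one night-level classifier and score new nights; returns
# list(pred = 0/1 integer, score = bad-class score in (0,1))
fit_and_score <- function(train_x, train_y, test_x, spec, seed,
                          hyper = list()) {
  if (spec$standardize) {
    sf <- standardize_fit(train_x)
    train_x <- standardize_apply(train_x, sf)
    test_x <- standardize_apply(test_x, sf)
  }
  yf <- factor(train_y, levels = c(0L, 1L))
  if (spec$kind == "rf") {
    mtry <- hyper$mtry %||% max(1L, floor(sqrt(ncol(train_x))))
    fit <- ranger::ranger(
      x = as.data.frame(train_x), y = yf,
      num.trees = spec$rf_n_trees, mtry = mtry,
      probability = TRUE, num.threads = 1L, seed = seed,
      max.depth = 0L)
    score <- predict(fit, as.data.frame(test_x),
                     num.threads = 1L)$predictions[, "1"]
    pred <- as.integer(score >= 0.5)
  } else {
    cost <- hyper$cost %||% spec$svm_cost
    set.seed(seed)
    fit <- e1071::svm(x = train_x, y = yf, kernel = "linear",
                      cost = cost, scale = FALSE)
    pr <- predict(fit, test_x, decision.values = TRUE)
    dv <- drop(attr(pr, "decision.values"))
    pos <- strsplit(colnames(attr(pr, "decision.values")), "/")[[1L]][1L]
    # decision values are signed toward the first-named class
    score <- if (pos == "1") plogis(dv) else plogis(-dv)
    pred <- as.integer(as.character(pr))
  }
  list(pred = pred, score = as.numeric(score))
}

# inner stratified k-fold CV over a small grid; returns the chosen
# hyperparameter list (empty when no grid is supplied)
select_hyperparams <- function(train_x, train_y, spec, seed) {
  grid <- spec$grid
  if (is.null(grid) || length(grid) == 0L) return(list())
  par <- names(grid)[1L]
  cands <- grid[[1L]]
  if (length(cands) == 1L) return(stats::setNames(list(cands), par))
  k <- min(spec$inner_cv_folds, min(table(train_y)))
  set.seed(seed)
  fold_of <- integer(length(train_y))
  for (cl in unique(train_y)) {
    idx <- which(train_y == cl)
    fold_of[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  acc <- vapply(cands, function(v) {
    hits <- 0L
    for (f in seq_len(k)) {
      tr <- fold_of != f
      res <- fit_and_score(train_x[tr, , drop = FALSE], train_y[tr],
                           train_x[!tr, , drop = FALSE], spec, seed,
                           hyper = stats::setNames(list(v), par))
      hits <- hits + sum(res$pred == train_y[!tr])
    }
    hits / length(train_y)
  }, numeric(1))
  stats::setNames(list(cands[which.max(acc)]), par)
}

#' Leave-one-subject-out night-label predictions (layer 1)
#'
#' For each subject in turn, fits the night-level classifier on all
#' nights of the remaining subjects and predicts the held-out subject's
#' nights, so that every night receives exactly one out-of-fold
#' prediction and no subject's model ever saw that subject's data.
#'
#' @param features Night feature matrix ([night_feature_matrix()]).
#' @param labels Night labels (0 good / 1 bad); derived from `group` via
#'   [night_labels()] when `NULL`. Supplying permuted labels gives the
#'   random-label control.
#' @param spec A [classifier_spec()].
#' @param seed Integer seed; the run is deterministic given it.
#' @return Data frame with one row per night: `subject_id`,
#'   `night_index`, `truth`, `pred`, `score` (bad-class score in
#'   \[0, 1\]), `fold` (the left-out subject). The training-fold
#'   composition is attached as attribute `"fold_members"` for leakage
#'   audits.
#' @export
loso_night_predictions <- function(features, labels = NULL,
                                   spec = classifier_spec("rf"),
                                   seed = 1L) {
  stopifnot(inherits(spec, "classifier_spec"))
  labels <- labels %||% night_labels(features)
  stopifnot(length(labels) == nrow(features),
            all(labels %in% c(0L, 1L)))
  subjects <- unique(features$subject_id)
  if (length(subjects) < 2L)
    stop("leave-one-subject-out needs at least 2 subjects")
  xmat <- as.matrix(features[, feature_columns(features), drop = FALSE])
  out <- vector("list", length(subjects))
  fold_members <- vector("list", length(subjects))
  names(fold_members) <- subjects
  for (si in seq_along(subjects)) {
    s <- subjects[si]
    te <- features$subject_id == s
    train_y <- labels[!te]
    if (length(unique(train_y)) < 2L)
      stop("training fold for subject ", s, " contains a single class")
    fold_seed <- derive_seed(seed, si)
    hyper <- select_hyperparams(xmat[!te, , drop = FALSE], train_y,
                                spec, fold_seed)
    res <- fit_and_score(xmat[!te, , drop = FALSE], train_y,
                         xmat[te, , drop = FALSE], spec, fold_seed,
                         hyper = hyper)
    out[[si]] <- data.frame(subject_id = features$subject_id[te],
                            night_index = features$night_index[te],
                            truth = labels[te], pred = res$pred,
                            score = res$score, fold = s,
                            row.names = NULL)
    fold_members[[si]] <- setdiff(subjects, s)
  }
  preds <- do.call(rbind, out)
  attr(preds, "fold_members") <- fold_members
  preds
}

#' Learn the bad-night-count threshold (layer 2)
#'
#' Sweeps candidate thresholds Th = 1..max nights: a subject with at
#' least Th predicted bad nights is classified CI. Returns the Th that
#' maximises subject-level accuracy over the supplied training subjects;
#' ties break toward the smallest Th, which favours sensitivity — the
#' preferred error direction for a pre-screening tool.
#'
#' @param bad_counts Integer vector: predicted bad nights per training
#'   subject.
#' @param groups True groups (`"CI"`/`"healthy"`) of those subjects.
#' @param n_nights Nights analysed per subject (defines the candidate
#'   range); defaults to `max(bad_counts, 1)`.
#' @return List with `th` (chosen threshold) and `accuracy` (training
#'   accuracy per candidate).
#' @export
optimize_threshold <- function(bad_counts, groups, n_nights = NULL) {
  if (length(bad_counts) == 0L) stop("empty training set")
  stopifnot(length(bad_counts) == length(groups),
            all(groups %in% .group_levels))
  max_th <- max(if (is.null(n_nights)) max(bad_counts, 1L)
                else max(n_nights), 1L)
  cands <- seq_len(max_th)
  is_ci <- groups == "CI"
  acc <- vapply(cands, function(th)
    mean((bad_counts >= th) == is_ci), numeric(1))
  list(th = cands[which.max(acc)], accuracy = stats::setNames(acc, cands))
}

#' Classify one subject from a bad-night count
#'
#' @param bad_count Predicted bad nights (>= 0).
#' @param th Threshold learned by [optimize_threshold()] (list or
#'   integer).
#' @return `"CI"` if `bad_count >= th` (boundary inclusive), else
#'   `"healthy"`.
#' @export
classify_subject <- function(bad_count, th) {
  if (is.list(th)) th <- th$th
  stopifnot(bad_count >= 0, th >= 1)
  if (bad_count >= th) "CI" else "healthy"
}

#' Two-layer chronic-insomnia screening
#'
#' Runs the complete screening pipeline on a cohort: extracts the
#' 48-feature night matrix (unless one is supplied), labels every CI
#' night bad and every healthy night good, obtains out-of-fold night
#' predictions under leave-one-subject-out cross-validation, and then,
#' for each subject, learns the bad-night-count threshold from the
#' out-of-fold predictions of the other subjects only and classifies the
#' held-out subject. Neither layer ever sees the subject being
#' classified.
#'
#' @param cohort An `actigraphy_cohort` with both groups present.
#' @param classifier `"rf"` (random forest) or `"svm"` (linear SVM); the
#'   night-level learner.
#' @param spec A [classifier_spec()]; overrides `classifier` when given.
#' @param levels Intensity-filter levels.
#' @param sampen_m,sampen_r_fraction,swr_orientation Feature-extraction
#'   settings, see [night_feature_vector()].
#' @param features Optional precomputed night feature matrix for this
#'   cohort (saves recomputation in sweeps and controls).
#' @param labels Optional night-label override (0/1 per feature row); by
#'   default labels derive from group membership. Used by the
#'   random-label control.
#' @param threshold_rule `"count"` (absolute bad-night count, the
#'   canonical rule — subjects monitored for fewer nights than Th can
#'   then only be screened healthy) or `"proportion"` (bad-night
#'   fraction, a sensitivity-analysis variant for unequal night counts).
#' @param seed Integer seed; the whole run is deterministic given it.
#' @return An object of class `ci_screen` with components
#'   `night_predictions`, `subject_table`, `confusion` (TP/FP/TN/FN),
#'   `metrics` (subject-level sensitivity/specificity/accuracy, percent),
#'   `night_metrics`, `thresholds` (per fold), `threshold_modal`, and the
#'   configuration used.
#' @examples
#' \donttest{
#' coh <- simulate_cohort(n_pairs = 6, nights = 5, effect_size = 3,
#'                        seed = 7)
#' fit <- ci_screen(coh, classifier = "rf", seed = 7)
#' print(fit)
#' }
#' @export
ci_screen <- function(cohort, classifier = c("rf", "svm"), spec = NULL,
                      levels = c(0, 20, 40, 80), sampen_m = 2L,
                      sampen_r_fraction = 0.2,
                      swr_orientation = "tst_over_waso",
                      features = NULL, labels = NULL,
                      threshold_rule = c("count", "proportion"),
                      seed = 1L) {
  classifier <- match.arg(classifier)
  threshold_rule <- match.arg(threshold_rule)
  spec <- spec %||% classifier_spec(classifier)
  validate_cohort(cohort, require_both_groups = TRUE)
  if (is.null(features))
    features <- night_feature_matrix(cohort, levels = levels,
                                     sampen_m = sampen_m,
                                     sampen_r_fraction = sampen_r_fraction,
                                     swr_orientation = swr_orientation)
  preds <- loso_night_predictions(features, labels = labels, spec = spec,
                                  seed = seed)
  groups <- cohort_groups(cohort)
  subjects <- names(groups)
  bad <- vapply(subjects, function(s)
    sum(preds$pred[preds$subject_id == s]), integer(1))
  nn <- vapply(subjects, function(s)
    sum(preds$subject_id == s), integer(1))
  # layer 2, leave-one-out: threshold for s learned from the others
  th_of <- numeric(length(subjects))
  pred_grp <- character(length(subjects))
  for (si in seq_along(subjects)) {
    oth <- setdiff(seq_along(subjects), si)
    if (threshold_rule == "count") {
      opt <- optimize_threshold(bad[oth], groups[oth], n_nights = nn[oth])
      th_of[si] <- opt$th
      pred_grp[si] <- classify_subject(bad[si], opt$th)
    } else {
      frac <- bad / nn
      cands <- sort(unique(frac[oth]))
      acc <- vapply(cands, function(th)
        mean((frac[oth] >= th) == (groups[oth] == "CI")), numeric(1))
      th_of[si] <- cands[which.max(acc)]
      pred_grp[si] <- if (frac[si] >= th_of[si]) "CI" else "healthy"
    }
  }
  subject_table <- data.frame(
    subject_id = subjects, group = unname(groups),
    n_nights = unname(nn), bad_nights = unname(bad),
    bad_fraction = unname(bad / nn), threshold = th_of,
    predicted = pred_grp, row.names = NULL)
  confusion <- c(
    TP = sum(groups == "CI" & pred_grp == "CI"),
    FP = sum(groups == "healthy" & pred_grp == "CI"),
    TN = sum(groups == "healthy" & pred_grp == "healthy"),
    FN = sum(groups == "CI" & pred_grp == "healthy"))
  night_conf <- c(TP = sum(preds$truth == 1L & preds$pred == 1L),
                  FP = sum(preds$truth == 0L & preds$pred == 1L),
                  TN = sum(preds$truth == 0L & preds$pred == 0L),
                  FN = sum(preds$truth == 1L & preds$pred == 0L))
  ths <- as.numeric(th_of)
  structure(list(
    call = match.call(), classifier = spec$kind, spec = spec,
    levels = levels,
    feature_args = list(levels = levels, sampen_m = sampen_m,
                        sampen_r_fraction = sampen_r_fraction,
                        swr_orientation = swr_orientation),
    threshold_rule = threshold_rule, seed = seed,
    features = features, night_predictions = preds,
    subject_table = subject_table, confusion = confusion,
    metrics = screen_metrics(confusion),
    night_metrics = screen_metrics(night_conf),
    thresholds = ths,
    threshold_modal = as.numeric(names(sort(-table(ths)))[1L])),
    class = "ci_screen")
}

#' @export
print.ci_screen <- function(x, ...) {
  cat("Two-layer actigraphy screening (", x$classifier,
      ", leave-one-subject-out)\n", sep = "")
  st <- x$subject_table
  cat("subjects: ", nrow(st), " (", sum(st$group == "CI"), " CI / ",
      sum(st$group == "healthy"), " healthy), nights: ",
      nrow(x$night_predictions), "\n", sep = "")
  cat("learned bad-night threshold (modal): ", x$threshold_modal,
      "\n", sep = "")
  m <- x$metrics
  cat(sprintf("subject level: accuracy %.1f%%, sensitivity %.1f%%, specificity %.1f%%\n",
              m["accuracy"], m["sensitivity"], m["specificity"]))
  m <- x$night_metrics
  cat(sprintf("night level:   accuracy %.1f%%, sensitivity %.1f%%, specificity %.1f%%\n",
              m["accuracy"], m["sensitivity"], m["specificity"]))
  invisible(x)
}

#' @export
summary.ci_screen <- function(object, ...) {
  structure(list(fit = object,
                 sweep = threshold_sweep(object),
                 confusion = object$confusion),
            class = "summary.ci_screen")
}

#' @export
print.summary.ci_screen <- function(x, ...) {
  print(x$fit)
  cat("\nconfusion (subject level): TP=", x$confusion["TP"],
      " FP=", x$confusion["FP"], " TN=", x$confusion["TN"],
      " FN=", x$confusion["FN"], "\n", sep = "")
  cat("\nthreshold sweep:\n")
  print(x$sweep, digits = 3)
  invisible(x)
}

#' Plot a screening fit
#'
#' `type = "sweep"` draws subject-level accuracy, sensitivity and
#' specificity against the bad-night threshold Th; `type = "roc"` draws
#' the subject-level ROC built from the bad-night fraction.
#'
#' @param x A `ci_screen` fit.
#' @param type `"sweep"` or `"roc"`.
#' @param ... Passed to the base plotting calls.
#' @return Invisibly, the plotted table (sweep) or ROC list.
#' @export
plot.ci_screen <- function(x, type = c("sweep", "roc"), ...) {
  type <- match.arg(type)
  if (type == "sweep") {
    sw <- threshold_sweep(x)
    graphics::plot(sw$th, sw$accuracy, type = "b", pch = 19,
                   ylim = c(0, 100), xlab = "bad-night threshold Th",
                   ylab = "percent", ...)
    graphics::lines(sw$th, sw$sensitivity, type = "b", pch = 1, lty = 2)
    graphics::lines(sw$th, sw$specificity, type = "b", pch = 2, lty = 3)
    graphics::abline(v = x$threshold_modal, col = "grey60", lty = 3)
    graphics::legend("bottomleft",
                     c("accuracy", "sensitivity", "specificity"),
                     pch = c(19, 1, 2), lty = 1:3, bty = "n")
    return(invisible(sw))
  }
  st <- x$subject_table
  roc <- roc_curve(st$bad_fraction, as.integer(st$group == "CI"))
  graphics::plot(roc$points$fpr, roc$points$tpr, type = "l",
                 xlab = "false positive rate",
                 ylab = "true positive rate", ...)
  graphics::abline(0, 1, lty = 3, col = "grey60")
  graphics::legend("bottomright",
                   sprintf("AUC = %.3f", roc$auc), bty = "n")
  invisible(roc)
}

#' Screen a new cohort with a fitted model
#'
#' Refits the night-level classifier on every night of the training
#' cohort and applies it, together with the modal learned threshold, to
#' the nights of `newdata`.
#'
#' @param object A `ci_screen` fit.
#' @param newdata An `actigraphy_cohort` of subjects to screen.
#' @param ... Unused.
#' @return Data frame with `subject_id`, `n_nights`, `bad_nights` and
#'   `predicted` group per new subject.
#' @export
predict.ci_screen <- function(object, newdata, ...) {
  stopifnot(inherits(newdata, "actigraphy_cohort"))
  validate_cohort(newdata)
  feats_new <- do.call(night_feature_matrix,
                       c(list(newdata), object$feature_args))
  tr <- object$features
  res <- fit_and_score(
    as.matrix(tr[, feature_columns(tr), drop = FALSE]),
    night_labels(tr),
    as.matrix(feats_new[, feature_columns(feats_new), drop = FALSE]),
    object$spec, derive_seed(object$seed, 0L))
  ids <- unique(feats_new$subject_id)
  bad <- vapply(ids, function(s)
    sum(res$pred[feats_new$subject_id == s]), integer(1))
  nn <- vapply(ids, function(s)
    sum(feats_new$subject_id == s), integer(1))
  data.frame(subject_id = ids, n_nights = unname(nn),
             bad_nights = unname(bad),
             predicted = ifelse(bad >= object$threshold_modal, "CI",
                                "healthy"),
             row.names = NULL)
}
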