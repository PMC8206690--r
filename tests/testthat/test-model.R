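# Two-layer screening model: night labelling, LOSO predictions,
# threshold learning, subject classification.

test_that("night labels follow group membership and tally per group", {
  coh <- random_cohort(n_per_group = 2L, nights = 3L)
  fm <- night_feature_matrix(coh)
  lab <- night_labels(fm)
  expect_identical(lab, as.integer(fm$group == "CI"))
  expect_equal(sum(lab == 1L), sum(fm$group == "CI"))
  expect_equal(sum(lab == 0L), sum(fm$group == "healthy"))
})

test_that("LOSO bookkeeping: one fold per subject, own nights excluded", {
  set.seed(10)
  coh <- random_cohort(n_per_group = 2L, nights = 2L, n_epochs = 30L)
  # drop one subject to get N = 3
  coh$subjects$hc02 <- NULL
  fm <- night_feature_matrix(coh)
  # explicit mixed labels keep every 2-subject training fold two-class
  lab <- rep_len(c(0L, 1L), nrow(fm))
  preds <- loso_night_predictions(fm, labels = lab,
                                  spec = classifier_spec("rf"),
                                  seed = 1)
  expect_equal(sort(unique(preds$fold)), sort(unique(fm$subject_id)))
  expect_equal(nrow(preds), nrow(fm))
  expect_equal(anyDuplicated(preds[c("subject_id", "night_index")]), 0L)
  # every prediction comes from the fold that left that subject out
  expect_true(all(preds$fold == preds$subject_id))
  fold_members <- attr(preds, "fold_members")
  for (s in names(fold_members))
    expect_false(s %in% fold_members[[s]])
})

test_that("a training fold with a single class is refused by name", {
  coh <- make_cohort(
    a = list(group = "CI", nights = list(`1` = random_night(30))),
    b = list(group = "healthy", nights = list(`1` = random_night(30))))
  fm <- night_feature_matrix(coh)
  expect_error(loso_night_predictions(fm, seed = 1),
               "single class")
})

test_that("threshold learning sweeps candidates and breaks ties downward", {
  opt <- optimize_threshold(c(6L, 5L, 7L, 1L, 0L, 2L),
                            c("CI", "CI", "CI",
                              "healthy", "healthy", "healthy"),
                            n_nights = rep(7L, 6))
  expect_equal(opt$th, 3L)                       # 3..5 all perfect
  expect_equal(unname(opt$accuracy[3:5]), rep(1, 3))
  same <- optimize_threshold(rep(4L, 4),
                             c("CI", "CI", "healthy", "healthy"),
                             n_nights = rep(7L, 4))
  expect_equal(same$th, 1L)                      # all ties -> smallest
  expect_error(optimize_threshold(integer(0), character(0)), "empty")
})

test_that("subject classification is boundary-inclusive", {
  expect_equal(classify_subject(5, 4), "CI")
  expect_equal(classify_subject(4, 4), "CI")
  expect_equal(classify_subject(3, 4), "healthy")
})

test_that("widely separated groups are recovered almost perfectly", {
  coh <- simulate_cohort(n_pairs = 8, nights = 5, effect_size = 3,
                         p_flip = 0, seed = 21)
  fit <- ci_screen(coh, classifier = "rf", seed = 21)
  expect_gte(fit$night_metrics[["accuracy"]], 85)
  expect_gte(fit$metrics[["accuracy"]], 90)
  st <- fit$subject_table
  expect_equal(sum(st$group == "CI"),
               fit$confusion[["TP"]] + fit$confusion[["FN"]])
  expect_equal(sum(st$group == "healthy"),
               fit$confusion[["TN"]] + fit$confusion[["FP"]])
})

test_that("identical runs are deterministic; both classifiers run", {
  coh <- simulate_cohort(n_pairs = 4, nights = 3, seed = 5)
  fm <- night_feature_matrix(coh)
  for (cls in c("rf", "svm")) {
    f1 <- ci_screen(coh, classifier = cls, features = fm, seed = 9)
    f2 <- ci_screen(coh, classifier = cls, features = fm, seed = 9)
    expect_identical(f1$night_predictions, f2$night_predictions)
    expect_identical(f1$subject_table, f2$subject_table)
    expect_identical(f1$metrics, f2$metrics)
  }
})

test_that("single-night cohorts run with the threshold forced to 1", {
  coh <- simulate_cohort(n_pairs = 4, nights = 1, seed = 6)
  fit <- ci_screen(coh, classifier = "rf", seed = 6)
  expect_true(all(fit$thresholds == 1))
  expect_equal(nrow(fit$night_predictions), 8L)
})

test_that("the proportional threshold variant runs and is sane", {
  coh <- simulate_cohort(n_pairs = 5, nights = 4, effect_size = 3,
                         p_flip = 0, seed = 13)
  fit <- ci_screen(coh, classifier = "rf",
                   threshold_rule = "proportion", seed = 13)
  expect_true(all(fit$subject_table$predicted %in% c("CI", "healthy")))
  expect_gte(fit$metrics[["accuracy"]], 80)
})

test_that("prediction on a new cohort uses the learned model and threshold", {
  coh <- simulate_cohort(n_pairs = 6, nights = 4, effect_size = 3,
                         p_flip = 0, seed = 31)
  fit <- ci_screen(coh, classifier = "rf", seed = 31)
  new_coh <- simulate_cohort(n_pairs = 4, nights = 4, effect_size = 3,
                             p_flip = 0, seed = 32)
  out <- predict(fit, new_coh)
  expect_setequal(out$subject_id, names(new_coh$subjects))
  expect_true(all(out$bad_nights <= out$n_nights))
  truth <- cohort_groups(new_coh)[out$subject_id]
  expect_gte(mean(out$predicted == truth), 0.75)
})

test_that("an inner CV grid selects a hyperparameter and stays deterministic", {
  coh <- simulate_cohort(n_pairs = 4, nights = 3, effect_size = 2,
                         seed = 17)
  fm <- night_feature_matrix(coh)
  spec <- classifier_spec("rf", grid = list(mtry = c(2L, 6L)),
                          inner_cv_folds = 3L)
  p1 <- loso_night_predictions(fm, spec = spec, seed = 3)
  p2 <- loso_night_predictions(fm, spec = spec, seed = 3)
  expect_identical(p1, p2)
  spec_svm <- classifier_spec("svm", grid = list(cost = c(0.1, 1)),
                              inner_cv_folds = 3L)
  expect_s3_class(loso_night_predictions(fm, spec = spec_svm, seed = 3),
                  "data.frame")
})
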