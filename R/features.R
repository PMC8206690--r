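# Night-level feature extraction: 12 features per filtered signal
# (Table-order: mean, sd, SD1, SD2, ratio, CCM, SampEn, TST, SL, WASO,
# SWR, SE), repeated over the filter bank.

.feature_base_names <- c("mean", "sd", "SD1", "SD2", "ratio", "CCM",
                         "SampEn", "TST", "SL", "WASO", "SWR", "SE")

#' Names of the night features for a filter bank
#'
#' @param levels Intensity-filter levels.
#' @return Character vector, 12 names per level, levels ascending, e.g.
#'   `"mean@InF0"`, ..., `"SE@InF80"`.
#' @export
feature_names <- function(levels = c(0, 20, 40, 80)) {
  as.vector(vapply(levels, function(L)
    paste0(.feature_base_names, "@InF", L),
    character(length(.feature_base_names))))
}

#' Mean and standard deviation of a night signal
#'
#' @param counts Numeric vector (length >= 2).
#' @return List with `mean` (arithmetic) and `sd` (sample, denominator
#'   N-1).
#' @export
stat_features <- function(counts) {
  if (length(counts) < 2L) stop("need at least 2 epochs")
  list(mean = mean(counts), sd = sd(counts))
}

# population standard deviation
pop_sd <- function(v) sqrt(mean((v - mean(v))^2))

#' Poincare plot descriptors of a night signal
#'
#' Builds the lag-1 Poincare plot (points \eqn{P_i = (x_i, x_{i+1})}) and
#' returns its standard descriptors: `sd1`, the dispersion perpendicular
#' to the identity line (short-term variability, the population s.d. of
#' \eqn{(x_{i+1}-x_i)/\sqrt 2}); `sd2`, the dispersion along it
#' (long-term variability); their `ratio` sd1/sd2; and `ccm`, the complex
#' correlation measure: the mean absolute area of the triangles spanned by
#' consecutive point triplets, normalised by \eqn{C_n = \pi \cdot
#' SD1 \cdot SD2}. CCM captures temporal ordering that SD1/SD2, which are
#' permutation-blind within the point cloud, cannot see.
#'
#' Degenerate policies: `ratio = 0` when `sd2 = 0`; `ccm = 0` when
#' \eqn{C_n = 0} (constant or perfectly collinear signals).
#'
#' @param counts Numeric vector, length >= 4.
#' @return List with `sd1`, `sd2`, `ratio`, `ccm`.
#' @export
poincare_descriptors <- function(counts) {
  n <- length(counts)
  if (n < 4L) stop("Poincare descriptors need at least 4 epochs")
  x1 <- counts[-n]
  x2 <- counts[-1]
  sd1 <- pop_sd((x2 - x1) / sqrt(2))
  sd2 <- pop_sd((x2 + x1) / sqrt(2))
  ratio <- if (sd2 == 0) 0 else sd1 / sd2
  # triangle areas over consecutive Poincare points P_i, P_{i+1}, P_{i+2}
  m <- n - 1L                       # number of points
  ax <- x1[1:(m - 2L)]; ay <- x2[1:(m - 2L)]
  bx <- x1[2:(m - 1L)]; by <- x2[2:(m - 1L)]
  cx <- x1[3:m];        cy <- x2[3:m]
  area <- 0.5 * abs((bx - ax) * (cy - ay) - (cx - ax) * (by - ay))
  cn <- pi * sd1 * sd2
  ccm <- if (cn == 0) 0 else sum(area) / (cn * (n - 3L))
  list(sd1 = sd1, sd2 = sd2, ratio = ratio, ccm = ccm)
}

#' Sample entropy of a night signal
#'
#' SampEn(m, r): the negative log of the conditional probability that two
#' templates matching within tolerance `r` (Chebyshev distance) at length
#' `m` still match at length `m + 1`, self-matches excluded. Matches are
#' counted over ordered pairs i != j with i, j <= N - m for length-m
#' templates and i, j <= N - m - 1 for length m + 1. The tolerance is
#' `r_fraction` times the sample standard deviation of the (filtered)
#' signal, recomputed per filtered series.
#'
#' Degenerate policies, chosen so the feature is always finite: a constant
#' signal (sd = 0, every template matches) gives 0; if no template pair
#' matches at either length the value is capped at
#' \eqn{\log((N-m-1)(N-m))}, the negative log of the smallest nonzero
#' conditional probability, and the result carries attribute
#' `capped = TRUE`.
#'
#' @param counts Numeric vector, length >= m + 2.
#' @param m Template length in epochs (default 2).
#' @param r_fraction Tolerance as a fraction of the signal s.d. (default
#'   0.2).
#' @return SampEn value (nonnegative scalar).
#' @export
sample_entropy <- function(counts, m = 2L, r_fraction = 0.2) {
  n <- length(counts)
  m <- as.integer(m)
  if (m < 1L) stop("m must be >= 1")
  if (r_fraction <= 0) stop("r_fraction must be positive")
  if (n < m + 2L) stop("need at least m + 2 epochs")
  s <- sd(counts)
  if (s == 0) return(0)
  r <- r_fraction * s
  cnt <- sampen_counts(as.numeric(counts), m, r)
  b <- cnt[1L]; a <- cnt[2L]
  if (a == 0 || b == 0) {
    out <- log((n - m - 1) * (n - m))
    attr(out, "capped") <- TRUE
    return(out)
  }
  -log(a / b)
}

#' Sleep onset of a night
#'
#' Sleep onset (SO) is the start of the first run of 10 consecutive
#' zero-count epochs (10 minutes of continuous inactivity).
#'
#' @param counts Numeric vector, length >= 10.
#' @return 1-based epoch index of SO, or `NA_integer_` if no such run
#'   exists.
#' @export
sleep_onset <- function(counts) {
  n <- length(counts)
  if (n < 10L) stop("need at least 10 epochs")
  z <- as.integer(counts == 0)
  cs <- c(0L, cumsum(z))
  # run of 10 zeros starting at i  <=>  cs[i+10] - cs[i] == 10
  ok <- which(cs[11:(n + 1L)] - cs[1:(n - 9L)] == 10L)
  if (length(ok) == 0L) return(NA_integer_)
  ok[1L]
}

#' Rule-based sleep parameters of a night
#'
#' From the (filtered) night signal and the sleep-onset rule, computes:
#' `sl` sleep latency, minutes from the start of the recording to SO;
#' `tst` total sleep time, the number of zero-count epochs from SO onward
#' (the SO epoch included); `waso` wake after sleep onset, the number of
#' nonzero epochs after SO; `swr` the sleep-wake ratio; and `se` sleep
#' efficiency, TST as a percentage of TIB. When SO exists,
#' `sl + tst + waso` equals TIB. When no 10-minute inactivity run exists
#' the night is scored as unslept: `tst = waso = 0`, `sl = tib`,
#' `swr = se = 0`.
#'
#' The printed definition of SWR is TST/WASO, the default here (with the
#' denominator floored at 1 minute to keep perfect nights finite);
#' `swr_orientation = "waso_over_tst"` selects the reciprocal convention,
#' whose scale matches published group tables for this method.
#'
#' @param counts Numeric vector of per-epoch counts.
#' @param swr_orientation `"tst_over_waso"` (default) or
#'   `"waso_over_tst"`.
#' @return List with `so_index` (1-based, or `NA`), `tst`, `sl`, `waso`,
#'   `swr`, `se` (minutes / percent).
#' @export
sleep_parameters <- function(counts,
                             swr_orientation = c("tst_over_waso",
                                                 "waso_over_tst")) {
  swr_orientation <- match.arg(swr_orientation)
  tib <- length(counts)
  so <- sleep_onset(counts)
  if (is.na(so)) {
    return(list(so_index = NA_integer_, tst = 0, sl = tib, waso = 0,
                swr = 0, se = 0))
  }
  post <- counts[so:tib]
  tst <- sum(post == 0)
  waso <- sum(post != 0)
  sl <- so - 1L
  swr <- if (swr_orientation == "tst_over_waso")
    tst / max(waso, 1) else waso / max(tst, 1)
  se <- 100 * tst / tib
  list(so_index = so, tst = tst, sl = sl, waso = waso, swr = swr, se = se)
}

#' Extract the full night feature vector
#'
#' Applies the intensity-filter bank and computes the 12 features on each
#' filtered signal, yielding `12 * length(levels)` values (48 under the
#' default bank) in a frozen order: table order within level, levels
#' ascending. All statistical, Poincare and entropy features are computed
#' over the full TIB signal, not restricted to post-onset epochs.
#'
#' @param counts Nonnegative integer vector, one activity count per
#'   60-second epoch, length >= 20.
#' @param levels Intensity-filter levels (strictly increasing).
#' @param sampen_m,sampen_r_fraction Sample-entropy parameters, see
#'   [sample_entropy()].
#' @param swr_orientation See [sleep_parameters()].
#' @return Named numeric vector of finite feature values.
#' @export
night_feature_vector <- function(counts, levels = c(0, 20, 40, 80),
                                 sampen_m = 2L, sampen_r_fraction = 0.2,
                                 swr_orientation = "tst_over_waso") {
  check_counts(counts, "night")
  vals <- lapply(levels, function(L) {
    f <- apply_intensity_filter(counts, L)
    st <- stat_features(f)
    pc <- poincare_descriptors(f)
    en <- sample_entropy(f, m = sampen_m, r_fraction = sampen_r_fraction)
    sp <- sleep_parameters(f, swr_orientation = swr_orientation)
    c(st$mean, st$sd, pc$sd1, pc$sd2, pc$ratio, pc$ccm, as.numeric(en),
      sp$tst, sp$sl, sp$waso, sp$swr, sp$se)
  })
  out <- unlist(vals, use.names = FALSE)
  names(out) <- feature_names(levels)
  if (any(!is.finite(out)))
    stop("non-finite feature value: ",
         paste(names(out)[!is.finite(out)], collapse = ", "))
  out
}

#' Night feature matrix of a cohort
#'
#' @param cohort An `actigraphy_cohort`.
#' @inheritParams night_feature_vector
#' @return Data frame, one row per night: `subject_id`, `night_index`,
#'   `group`, then the named feature columns.
#' @export
night_feature_matrix <- function(cohort, levels = c(0, 20, 40, 80),
                                 sampen_m = 2L, sampen_r_fraction = 0.2,
                                 swr_orientation = "tst_over_waso") {
  validate_cohort(cohort)
  nt <- night_table(cohort)
  feats <- t(vapply(seq_len(nrow(nt)), function(i) {
    cnt <- cohort$subjects[[nt$subject_id[i]]]$nights[[
      as.character(nt$night_index[i])]]
    night_feature_vector(cnt, levels = levels, sampen_m = sampen_m,
                         sampen_r_fraction = sampen_r_fraction,
                         swr_orientation = swr_orientation)
  }, numeric(12L * length(levels))))
  out <- data.frame(subject_id = nt$subject_id,
                    night_index = nt$night_index,
                    group = nt$group, check.names = FALSE)
  out <- cbind(out, as.data.frame(feats, check.names = FALSE))
  rownames(out) <- NULL
  out
}

# columns of a feature matrix that hold features (not keys)
feature_columns <- function(features) {
  setdiff(names(features), c("subject_id", "night_index", "group"))
}
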