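# Night features: moments, Poincare descriptors, sample entropy, sleep
# parameters, and the assembled 48-entry vector.

test_that("mean and sample s.d. match hand values and a textbook oracle", {
  expect_equal(stat_features(c(2, 2, 2, 2)), list(mean = 2, sd = 0))
  expect_equal(stat_features(c(0, 10)), list(mean = 5, sd = sqrt(50)))
  set.seed(3)
  x <- random_night(80)
  st <- stat_features(x)
  # one-pass textbook formulas
  expect_equal(st$mean, sum(x) / length(x))
  expect_equal(st$sd,
               sqrt((sum(x^2) - length(x) * st$mean^2) / (length(x) - 1)))
  expect_error(stat_features(5), "at least 2")
})

test_that("Poincare descriptors honour the degenerate policies", {
  cst <- poincare_descriptors(rep(7, 10))
  expect_equal(cst, list(sd1 = 0, sd2 = 0, ratio = 0, ccm = 0))
  ramp <- poincare_descriptors(1:6)
  expect_equal(ramp$sd1, 0)        # successive differences all equal
  expect_equal(ramp$ccm, 0)        # collinear points, Cn = 0
  expect_gt(ramp$sd2, 0)
  expect_error(poincare_descriptors(1:3), "at least 4")
})

test_that("SD1^2 + SD2^2 equals the two-sided variance sum and CCM matches its oracle", {
  set.seed(4)
  for (i in 1:20) {
    x <- random_night(50)
    pc <- poincare_descriptors(x)
    n <- length(x)
    pv <- function(v) mean((v - mean(v))^2)
    expect_equal(pc$sd1^2 + pc$sd2^2, pv(x[-1]) + pv(x[-n]),
                 tolerance = 1e-9)
    expect_equal(pc$ccm, oracle_ccm(x), tolerance = 1e-12)
  }
})

test_that("sample entropy agrees exactly with the template-counting oracle", {
  expect_equal(sample_entropy(rep(5, 30)), 0)
  per <- rep(c(1, 2, 3), 4)
  expect_equal(sample_entropy(per, m = 2), oracle_sampen(per, m = 2))
  set.seed(5)
  x <- sample(0:100, 200, replace = TRUE)
  expect_equal(sample_entropy(x), oracle_sampen(x))
  expect_equal(sample_entropy(x, m = 3), oracle_sampen(x, m = 3))
  expect_error(sample_entropy(1:3, m = 2), "at least m \\+ 2")
})

test_that("a zero match count at length m + 1 triggers the finite cap", {
  # (0,0) recurs, but its successor always differs by far more than r
  x <- c(0, 0, 10, 0, 0, 20, 0, 0, 30)
  v <- sample_entropy(x, m = 2)
  n <- length(x)
  expect_equal(as.numeric(v), log((n - 2 - 1) * (n - 2)))
  expect_true(isTRUE(attr(v, "capped")))
  expect_equal(as.numeric(v), oracle_sampen(x, m = 2))
})

test_that("sleep onset is the first 10-minute run of zeros", {
  expect_equal(sleep_onset(c(5, rep(0, 10), 3, 2)), 2L)
  expect_true(is.na(sleep_onset(rep(c(0, 1), 20))))
  x <- c(20, rep(0, 9), 100, rep(0, 10))
  expect_equal(sleep_onset(x), 12L)                       # SL 11 min
  expect_equal(sleep_onset(apply_intensity_filter(x, 20)), 1L)
  expect_error(sleep_onset(1:5), "at least 10")
})

test_that("sleep parameters match the hand-traced examples", {
  perfect <- sleep_parameters(rep(0, 480))
  expect_equal(perfect[c("sl", "tst", "waso", "swr", "se")],
               list(sl = 0L, tst = 480L, waso = 0L, swr = 480,
                    se = 100))
  one_wake <- sleep_parameters(c(rep(0, 10), 50, rep(0, 469)))
  expect_equal(one_wake$tst, 479L)
  expect_equal(one_wake$waso, 1L)
  expect_equal(one_wake$sl, 0L)
  expect_equal(one_wake$swr, 479)
  expect_equal(one_wake$se, 100 * 479 / 480)
  # no 10-minute inactivity anywhere: scored as unslept
  none <- sleep_parameters(rep(c(0, 1), 15))
  expect_equal(none[c("tst", "waso", "sl", "swr", "se")],
               list(tst = 0, waso = 0, sl = 30L, swr = 0, se = 0))
  # reciprocal SWR convention
  rev <- sleep_parameters(c(rep(0, 10), 50, rep(0, 469)),
                          swr_orientation = "waso_over_tst")
  expect_equal(rev$swr, 1 / 479)
})

test_that("SL + TST + WASO = TIB whenever onset exists", {
  set.seed(6)
  for (i in 1:50) {
    x <- random_night()
    sp <- sleep_parameters(x)
    if (!is.na(sp$so_index))
      expect_equal(sp$sl + sp$tst + sp$waso, length(x))
  }
})

test_that("the WASO non-monotonicity counterexample behaves as documented", {
  x <- c(20, rep(0, 9), 100, rep(0, 10))
  sp0 <- sleep_parameters(apply_intensity_filter(x, 0))
  sp20 <- sleep_parameters(apply_intensity_filter(x, 20))
  expect_equal(sp0$waso, 0L)     # onset after the isolated spike
  expect_equal(sp20$waso, 1L)    # earlier onset exposes the spike
  expect_lt(sp20$sl, sp0$sl)
  expect_gte(sp20$tst, sp0$tst)
})

test_that("the night vector has 12 features per level in frozen order", {
  x <- random_night(60)
  v <- night_feature_vector(x)
  expect_length(v, 48L)
  expect_true(all(is.finite(v)))
  expect_identical(names(v), feature_names())
  expect_identical(names(v)[1:12],
                   paste0(c("mean", "sd", "SD1", "SD2", "ratio", "CCM",
                            "SampEn", "TST", "SL", "WASO", "SWR", "SE"),
                          "@InF0"))
  expect_length(night_feature_vector(x, levels = 0), 12L)
  # all-zero night: a perfect sleep at every level
  z <- night_feature_vector(rep(0L, 40))
  for (L in c(0, 20, 40, 80)) {
    expect_equal(unname(z[paste0(c("mean", "sd", "SD1", "SD2", "SampEn",
                                   "WASO", "SL"), "@InF", L)]),
                 rep(0, 7))
    expect_equal(unname(z[paste0("SE@InF", L)]), 100)
  }
})

test_that("TST and SE never decrease, and SL never increases, with the level", {
  set.seed(8)
  for (i in 1:60) {
    v <- night_feature_vector(random_night())
    tst <- v[paste0("TST@InF", c(0, 20, 40, 80))]
    se <- v[paste0("SE@InF", c(0, 20, 40, 80))]
    sl <- v[paste0("SL@InF", c(0, 20, 40, 80))]
    expect_true(all(diff(tst) >= 0))
    expect_true(all(diff(se) >= 0))
    expect_true(all(diff(sl) <= 0))
  }
})
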