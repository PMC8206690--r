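# Independent brute-force oracles and small fixture builders.
# The oracles deliberately use different constructions (embed(), explicit
# pair loops) from the package internals they check.

# random night of zero-inflated counts (always valid: nonnegative ints,
# length >= 20, zeros frequent enough for the sleep rules to engage)
random_night <- function(n = sample(30:120, 1), p_zero = 0.6,
                         max_count = 150L) {
  ifelse(runif(n) < p_zero, 0L, sample.int(max_count + 1L, n,
                                           replace = TRUE) - 1L)
}

# sample entropy by explicit template matrices (embed() reverses columns,
# which leaves Chebyshev distances unchanged)
oracle_sampen <- function(x, m = 2L, r_fraction = 0.2) {
  n <- length(x)
  s <- stats::sd(x)
  if (s == 0) return(0)
  r <- r_fraction * s
  count_pairs <- function(len, ntmpl) {
    tm <- stats::embed(x, len)[seq_len(ntmpl), , drop = FALSE]
    tot <- 0L
    for (i in seq_len(ntmpl)) {
      d <- apply(abs(sweep(tm, 2L, tm[i, ])), 1L, max)
      tot <- tot + sum(d <= r) - 1L   # drop the self-match
    }
    tot
  }
  b <- count_pairs(m, n - m)
  a <- count_pairs(m + 1L, n - m - 1L)
  if (a == 0L || b == 0L) return(log((n - m - 1) * (n - m)))
  -log(a / b)
}

# CCM by an explicit loop over consecutive Poincare triplets
oracle_ccm <- function(x) {
  n <- length(x)
  pts <- cbind(x[-n], x[-1])
  sd1 <- sqrt(mean((((pts[, 2] - pts[, 1]) / sqrt(2)) -
                      mean((pts[, 2] - pts[, 1]) / sqrt(2)))^2))
  sd2 <- sqrt(mean((((pts[, 2] + pts[, 1]) / sqrt(2)) -
                      mean((pts[, 2] + pts[, 1]) / sqrt(2)))^2))
  cn <- pi * sd1 * sd2
  if (cn == 0) return(0)
  tot <- 0
  for (i in seq_len(nrow(pts) - 2L)) {
    a <- pts[i, ]; b <- pts[i + 1L, ]; c <- pts[i + 2L, ]
    tot <- tot + 0.5 * abs((b[1] - a[1]) * (c[2] - a[2]) -
                             (c[1] - a[1]) * (b[2] - a[2]))
  }
  tot / (cn * (n - 3L))
}

# AUC by pair counting: wins plus half-ties over all (pos, neg) pairs
oracle_auc <- function(score, label) {
  pos <- score[label == 1]
  neg <- score[label == 0]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# cohort built from explicit per-subject night lists
make_cohort <- function(...) {
  cohort_dataset(list(...))
}

# quick two-group cohort of random nights (no group difference)
random_cohort <- function(n_per_group = 2L, nights = 2L, n_epochs = 40L) {
  subs <- list()
  for (i in seq_len(n_per_group)) {
    for (g in c("CI", "healthy")) {
      nn <- lapply(seq_len(nights), function(k) random_night(n_epochs))
      names(nn) <- as.character(seq_len(nights))
      subs[[sprintf("%s%02d", if (g == "CI") "ci" else "hc", i)]] <-
        list(group = g, nights = nn)
    }
  }
  cohort_dataset(subs)
}
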