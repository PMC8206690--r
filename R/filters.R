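#' Apply a wake-sensitivity intensity filter
#'
#' Sets every activity count less than or equal to `level` to zero and
#' leaves the rest untouched. The filter acts as a low-pass on subtle
#' motor activity: at level 0 only zero counts are affected (identity on
#' count data), while higher levels suppress progressively larger
#' movements. The operation is idempotent at a fixed level, and the set of
#' zeroed epochs grows monotonically with the level.
#'
#' @param counts Nonnegative numeric vector of per-epoch activity counts.
#' @param level Nonnegative integer threshold.
#' @return Filtered vector, same length as `counts`.
#' @examples
#' apply_intensity_filter(c(0, 15, 20, 21, 80, 81), 20)
#' @export
apply_intensity_filter <- function(counts, level) {
  if (length(level) != 1L || !is.finite(level) || level < 0)
    stop("filter level must be a single nonnegative number")
  out <- counts
  out[out <= level] <- 0L    # integer zero keeps integer inputs integer
  out
}

#' Apply a bank of intensity filters
#'
#' Produces one filtered copy of the night per configured level, in
#' configuration order. The default bank uses the four device
#' wake-sensitivity limits: 0 (none), 20 (high sensitivity), 40 (medium)
#' and 80 (low).
#'
#' @param counts Nonnegative numeric vector of per-epoch activity counts.
#' @param levels Strictly increasing nonnegative integer thresholds.
#' @return Named list of filtered vectors (`"InF0"`, `"InF20"`, ...).
#' @export
filter_bank <- function(counts, levels = c(0, 20, 40, 80)) {
  if (length(levels) < 1L || any(levels < 0) ||
      any(diff(levels) <= 0))
    stop("filter levels must be strictly increasing and nonnegative")
  out <- lapply(levels, function(L) apply_intensity_filter(counts, L))
  names(out) <- paste0("InF", levels)
  out
}
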