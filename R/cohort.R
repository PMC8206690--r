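#' Construct an actigraphy cohort
#'
#' An `actigraphy_cohort` holds one or more subjects, each with a group
#' label (`"CI"` or `"healthy"`) and an ordered set of nights. A night is a
#' vector of nonnegative integer activity counts, one per 60-second epoch,
#' spanning the time-in-bed (TIB) interval; TIB in minutes equals the
#' number of epochs. Nights shorter than 20 epochs are rejected: the
#' 10-minute sleep-onset rule and the lag-based features are not well
#' defined on shorter records.
#'
#' @param subjects A named list, one element per subject. Each element is a
#'   list with components `group` (`"CI"` or `"healthy"`) and `nights`, a
#'   list of integer count vectors named by night index (`"1"`, `"2"`, ...).
#' @return An object of class `actigraphy_cohort`.
#' @examples
#' coh <- cohort_dataset(list(
#'   A = list(group = "CI",      nights = list(`1` = rep(0L, 30))),
#'   B = list(group = "healthy", nights = list(`1` = rep(0L, 30)))
#' ))
#' print(coh)
#' @export
cohort_dataset <- function(subjects) {
  x <- structure(list(subjects = subjects), class = "actigraphy_cohort")
  validate_cohort(x)
  x
}

#' Validate an actigraphy cohort
#'
#' Checks the data-model invariants: unique subject ids, valid group
#' labels, at least one night per subject, unique night indices, and
#' per-night count vectors that are nonnegative, integral and at least 20
#' epochs long. With `require_both_groups = TRUE` it additionally checks
#' that the cohort contains at least two subjects and at least one subject
#' per group, the minimum for leave-one-subject-out cross-validation.
#'
#' @param cohort An `actigraphy_cohort`.
#' @param require_both_groups Also enforce the cross-validation
#'   prerequisite (default `FALSE`).
#' @return The cohort, invisibly; errors describe the offending record.
#' @export
validate_cohort <- function(cohort, require_both_groups = FALSE) {
  stopifnot(inherits(cohort, "actigraphy_cohort"))
  subs <- cohort$subjects
  if (length(subs) < 1L) stop("cohort contains no subjects")
  ids <- names(subs)
  if (is.null(ids) || anyNA(ids) || any(ids == ""))
    stop("every subject needs a non-empty id (list names)")
  if (anyDuplicated(ids))
    stop("duplicate subject_id: ", ids[duplicated(ids)][1L])
  for (id in ids) {
    s <- subs[[id]]
    if (!is.list(s) || is.null(s$group) || is.null(s$nights))
      stop("subject ", id, ": needs 'group' and 'nights'")
    if (!s$group %in% .group_levels)
      stop("subject ", id, ": group must be 'CI' or 'healthy', got '",
           s$group, "'")
    if (length(s$nights) < 1L)
      stop("subject ", id, ": at least one night is required")
    ni <- suppressWarnings(as.integer(names(s$nights)))
    if (anyNA(ni) || any(ni < 1L))
      stop("subject ", id, ": night indices must be integers >= 1")
    if (anyDuplicated(ni))
      stop("subject ", id, ": duplicate night_index ",
           ni[duplicated(ni)][1L])
    for (k in seq_along(s$nights)) {
      cnt <- s$nights[[k]]
      check_counts(cnt, sprintf("subject %s night %s", id,
                                names(s$nights)[k]))
    }
  }
  if (require_both_groups) {
    g <- cohort_groups(cohort)
    if (length(g) < 2L || length(unique(g)) < 2L)
      stop("cross-validation needs >= 2 subjects with both groups present")
  }
  invisible(cohort)
}

# boundary validation for one night of counts
check_counts <- function(counts, what) {
  if (!is.numeric(counts) || length(counts) == 0L)
    stop(what, ": counts must be a numeric vector")
  if (anyNA(counts) || any(!is.finite(counts)))
    stop(what, ": counts contain missing or non-finite values")
  if (any(counts < 0))
    stop(what, ": negative count at epoch ",
         which(counts < 0)[1L] - 1L)
  if (any(counts != floor(counts)))
    stop(what, ": non-integer count at epoch ",
         which(counts != floor(counts))[1L] - 1L)
  if (length(counts) < MIN_TIB)
    stop(what, ": night has ", length(counts),
         " epochs; minimum is ", MIN_TIB)
  invisible(counts)
}

#' @export
print.actigraphy_cohort <- function(x, ...) {
  g <- cohort_groups(x)
  nt <- night_table(x)
  cat("actigraphy cohort: ", length(g), " subjects (",
      sum(g == "CI"), " CI / ", sum(g == "healthy"), " healthy), ",
      nrow(nt), " nights\n", sep = "")
  cat("nights per subject: ", paste(range(table(nt$subject_id)),
                                    collapse = "-"),
      "; TIB range ", paste(range(nt$tib_minutes), collapse = "-"),
      " min\n", sep = "")
  invisible(x)
}

#' Group label of each subject
#'
#' @param cohort An `actigraphy_cohort`.
#' @return Named character vector (`"CI"`/`"healthy"`), one per subject.
#' @export
cohort_groups <- function(cohort) {
  vapply(cohort$subjects, function(s) s$group, character(1))
}

#' Tabulate the nights of a cohort
#'
#' @param cohort An `actigraphy_cohort`.
#' @return A data.frame with one row per night: `subject_id`, `group`,
#'   `night_index`, `tib_minutes`.
#' @export
night_table <- function(cohort) {
  rows <- lapply(names(cohort$subjects), function(id) {
    s <- cohort$subjects[[id]]
    data.frame(subject_id = id, group = s$group,
               night_index = as.integer(names(s$nights)),
               tib_minutes = vapply(s$nights, length, integer(1)),
               row.names = NULL)
  })
  out <- do.call(rbind, rows)
  out[order(out$subject_id, out$night_index), , drop = FALSE]
}

#' Keep only each subject's first k nights
#'
#' Used by the night-count ablation: nights are ranked by night index and
#' the earliest `k` retained (subjects with fewer keep what they have).
#'
#' @param cohort An `actigraphy_cohort`.
#' @param k Number of nights to keep per subject.
#' @return A truncated `actigraphy_cohort`.
#' @export
truncate_nights <- function(cohort, k) {
  stopifnot(k >= 1)
  subs <- lapply(cohort$subjects, function(s) {
    ord <- order(as.integer(names(s$nights)))
    keep <- ord[seq_len(min(k, length(ord)))]
    list(group = s$group, nights = s$nights[keep])
  })
  structure(list(subjects = subs), class = "actigraphy_cohort")
}

#' Read a cohort from a long epoch table
#'
#' The canonical on-disk format is a delimited UTF-8 text file with a
#' header and one row per epoch: columns `subject_id`, `group`,
#' `night_index`, `epoch_index`, `count`. `epoch_index` must run
#' contiguously from 0 within each (subject, night). Raw device exports
#' are deliberately not parsed; segmentation into TIB intervals is assumed
#' done upstream (device rest intervals are taken as TIB).
#'
#' @param path File path. Comma- or tab-delimited (autodetected).
#' @return A validated `actigraphy_cohort`.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, colClasses = list(character = "subject_id"))
  need <- c("subject_id", "group", "night_index", "epoch_index", "count")
  miss <- setdiff(need, names(dt))
  if (length(miss))
    stop("format error: missing column(s) ", paste(miss, collapse = ", "))
  df <- as.data.frame(dt)
  ids <- unique(df$subject_id)          # keep file appearance order
  df <- df[order(match(df$subject_id, ids), df$night_index,
                 df$epoch_index), ]
  subs <- list()
  for (id in ids) {
    di <- df[df$subject_id == id, ]
    grp <- unique(di$group)
    if (length(grp) != 1L)
      stop("subject ", id, ": inconsistent group labels")
    nights <- list()
    for (nidx in unique(di$night_index)) {
      dn <- di[di$night_index == nidx, ]
      ei <- dn$epoch_index
      if (!identical(as.integer(ei), seq_len(nrow(dn)) - 1L))
        stop("subject ", id, " night ", nidx,
             ": epoch_index not contiguous from 0")
      cnt <- dn$count
      check_counts(cnt, sprintf("subject %s night %s", id, nidx))
      nights[[as.character(nidx)]] <- as.integer(cnt)
    }
    subs[[as.character(id)]] <- list(group = grp, nights = nights)
  }
  cohort_dataset(subs)
}

#' Write a cohort as a long epoch table
#'
#' Inverse of [read_cohort()]: `read_cohort(write_cohort(x, p))` restores
#' the cohort exactly (counts, labels, ordering).
#'
#' @param cohort An `actigraphy_cohort`.
#' @param path Output file path.
#' @param sep Field delimiter, `","` (default) or `"\t"`.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, sep = ",") {
  validate_cohort(cohort)
  rows <- list()
  i <- 1L
  for (id in names(cohort$subjects)) {
    s <- cohort$subjects[[id]]
    for (nm in names(s$nights)[order(as.integer(names(s$nights)))]) {
      cnt <- s$nights[[nm]]
      rows[[i]] <- data.table::data.table(
        subject_id = id, group = s$group,
        night_index = as.integer(nm),
        epoch_index = seq_along(cnt) - 1L,
        count = as.integer(cnt))
      i <- i + 1L
    }
  }
  dt <- data.table::rbindlist(rows)
  data.table::fwrite(dt, path, sep = sep)
  invisible(path)
}

#' Write a night feature matrix
#'
#' One row per night: `subject_id`, `night_index`, `group`, then the named
#' feature columns (`<feature>@InF<level>`), in the frozen order produced
#' by [night_feature_matrix()].
#'
#' @param features Data frame as returned by [night_feature_matrix()].
#' @param path Output file path.
#' @param sep Field delimiter.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(features, path, sep = ",") {
  need <- c("subject_id", "night_index", "group")
  if (!all(need %in% names(features)))
    stop("feature matrix must carry columns ",
         paste(need, collapse = ", "))
  data.table::fwrite(data.table::as.data.table(features), path, sep = sep)
  invisible(path)
}

#' Read a night feature matrix written by [write_feature_matrix()]
#'
#' @param path File path.
#' @return Data frame with key columns and named feature columns.
#' @export
read_feature_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, colClasses = list(character = "subject_id"))
  as.data.frame(dt, check.names = FALSE)
}
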