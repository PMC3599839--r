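#' Construct a validated longitudinal count dataset
#'
#' Builds the long-format container used throughout the package: one row per
#' subject-by-wave observation of a non-negative integer count outcome, with
#' an ordered set of measurement waves and any number of subject covariates.
#' Validation enforces the structural invariants the likelihood code relies
#' on: integer outcomes \eqn{y \ge 0}, unique (subject, wave) pairs, and every
#' wave drawn from the declared wave set. Subjects may be observed at any
#' subset of the waves (available-case analysis under dropout); no imputation
#' is performed.
#'
#' @param data A data.frame holding at least the subject, wave and outcome
#'   columns.
#' @param subject,wave,outcome Names of the subject-identifier, wave-label and
#'   count-outcome columns in `data`.
#' @param covariates Character vector of covariate column names to carry along
#'   (e.g. an education indicator). Factor columns keep their level order;
#'   the first level is the reference when dummies are built.
#' @param wave_levels Ordered character vector declaring the wave set. Defaults
#'   to the sorted unique wave labels.
#' @param time_values Numeric time value per wave (e.g. months), named or in
#'   wave order. Defaults to the 0-based wave index.
#' @return An object of class `"longdata"`: a data.frame with columns
#'   `subject`, `wave` (factor over `wave_levels`), the covariates, and `y`,
#'   plus attributes `covariates` and `time_values`.
#' @examples
#' d <- data.frame(id = rep(1:2, each = 3), t = rep(c("T0", "T1", "T2"), 2),
#'                 y = c(0, 1, 4, 0, 0, 2))
#' ld <- longitudinal_data(d, subject = "id", wave = "t", outcome = "y")
#' nlevels(ld$wave)
#' @export
longitudinal_data <- function(data, subject = "subject", wave = "wave",
                              outcome = "y", covariates = character(),
                              wave_levels = NULL, time_values = NULL) {
  data <- as.data.frame(data)
  needed <- c(subject, wave, outcome, covariates)
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols))
    stop("column(s) not found in data: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)

  y <- data[[outcome]]
  if (is.character(y)) y <- suppressWarnings(as.numeric(y))
  bad <- which(!is.na(y) & (y < 0 | y != round(y) | !is.finite(y)))
  if (length(bad))
    stop("outcome must be a non-negative integer; offending row(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  if (anyNA(y))
    stop("outcome contains missing values; drop or handle them before ",
         "constructing the dataset (see read_long_table)", call. = FALSE)

  wv <- as.character(data[[wave]])
  if (is.null(wave_levels)) wave_levels <- sort(unique(wv))
  unknown <- setdiff(unique(wv), wave_levels)
  if (length(unknown))
    stop("wave label(s) not in the declared wave set: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  if (length(wave_levels) < 1L) stop("empty wave set", call. = FALSE)

  sid <- as.character(data[[subject]])
  key <- paste(sid, wv, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (subject, wave) pair(s), e.g. subject ",
         sid[which(duplicated(key))[1L]], " at wave ",
         wv[which(duplicated(key))[1L]], call. = FALSE)

  if (is.null(time_values)) {
    time_values <- seq_along(wave_levels) - 1
    names(time_values) <- wave_levels
  } else {
    if (is.null(names(time_values))) names(time_values) <- wave_levels
    if (!all(wave_levels %in% names(time_values)))
      stop("time_values must cover every declared wave", call. = FALSE)
    time_values <- time_values[wave_levels]
  }

  out <- data.frame(subject = sid,
                    wave = factor(wv, levels = wave_levels),
                    stringsAsFactors = FALSE)
  for (cv in covariates) out[[cv]] <- data[[cv]]
  out$y <- as.integer(round(y))
  out <- out[order(out$subject, as.integer(out$wave)), , drop = FALSE]
  rownames(out) <- NULL
  structure(out,
            covariates = covariates,
            time_values = time_values,
            class = c("longdata", "data.frame"))
}

#' Read a long-format longitudinal table from a delimited file
#'
#' Reads a CSV/TSV file with one row per subject-by-wave record and returns a
#' validated [longitudinal_data()] object. Rows whose outcome cell is missing
#' or blank are dropped (available-case analysis) and the number of drops is
#' reported in a message.
#'
#' @inheritParams longitudinal_data
#' @param path Path to a delimited text file with a header row.
#' @param sep Field separator; guessed from the file extension when `NULL`
#'   (`.tsv`/`.txt` gives tab, anything else comma).
#' @param covariate_levels Optional named list giving the level order for
#'   factor covariates, e.g. `list(education = c("low", "high"))`; the first
#'   level becomes the dummy-coding reference.
#' @return A `"longdata"` object.
#' @seealso [write_long_table()], [summarize_events()]
#' @export
read_long_table <- function(path, subject = "subject", wave = "wave",
                            outcome = "y", covariates = character(),
                            wave_levels = NULL, time_values = NULL,
                            covariate_levels = NULL, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep))
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE,
                           na.strings = c("NA", ""), check.names = FALSE)
  missing_cols <- setdiff(c(subject, wave, outcome, covariates), names(raw))
  if (length(missing_cols))
    stop("column(s) not found in ", path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)

  n_na <- sum(is.na(raw[[outcome]]))
  if (n_na > 0L) {
    message("dropped ", n_na, " row(s) with missing outcome (available-case)")
    raw <- raw[!is.na(raw[[outcome]]), , drop = FALSE]
  }
  for (cv in names(covariate_levels %||% list())) {
    if (cv %in% names(raw))
      raw[[cv]] <- factor(raw[[cv]], levels = covariate_levels[[cv]])
  }
  longitudinal_data(raw, subject = subject, wave = wave, outcome = outcome,
                    covariates = covariates, wave_levels = wave_levels,
                    time_values = time_values)
}

#' Write a longitudinal dataset back to a delimited file
#'
#' Inverse of [read_long_table()]: the written file round-trips through the
#' reader to an identical dataset.
#'
#' @param data A `"longdata"` object.
#' @param path Output file path; extension picks the separator as in
#'   [read_long_table()].
#' @return `path`, invisibly.
#' @export
write_long_table <- function(data, path) {
  stopifnot(inherits(data, "longdata"))
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(as.data.frame(data), path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-wave event summary (proportion and median of subjects with >= 1 event)
#'
#' For each wave (optionally split by a covariate) reports the number and
#' percentage of subjects with at least one event, the complementary
#' percentage with zero events, and the median count among subjects with at
#' least one event — the descriptive layout commonly used for zero-heavy
#' count outcomes in cohort studies.
#'
#' Percentages are computed at full precision and rounded to one decimal for
#' reporting; `pct_zero` is the exact complement `100 - pct_ge1` before
#' rounding. The median is taken over the \eqn{y \ge 1} subset only and is
#' `NA` when a cell has no events.
#'
#' @param data A `"longdata"` object.
#' @param group_by Optional covariate name to stratify by; a `"total"` stratum
#'   over all subjects is always included.
#' @return A data.frame of class `"event_summary"` with columns `wave`,
#'   `group`, `n_total`, `n_ge1`, `pct_ge1`, `pct_zero`, `median_ge1`.
#' @examples
#' d <- data.frame(id = 1:5, t = "T0", y = c(0, 0, 4, 2, 0))
#' ld <- longitudinal_data(d, "id", "t", "y", wave_levels = "T0")
#' summarize_events(ld)
#' @export
summarize_events <- function(data, group_by = NULL) {
  stopifnot(inherits(data, "longdata"))
  if (nrow(data) == 0L) stop("empty dataset", call. = FALSE)
  waves <- levels(data$wave)
  n_by_wave <- table(data$wave)
  empty <- waves[n_by_wave == 0L]
  if (length(empty))
    stop("no observed subjects at wave(s): ", paste(empty, collapse = ", "),
         call. = FALSE)

  groups <- list(total = rep(TRUE, nrow(data)))
  if (!is.null(group_by)) {
    if (!group_by %in% attr(data, "covariates"))
      stop("unknown covariate: ", group_by, call. = FALSE)
    g <- data[[group_by]]
    lv <- if (is.factor(g)) levels(g) else sort(unique(as.character(g)))
    for (l in lv) groups[[as.character(l)]] <- (as.character(g) == l)
  }

  rows <- list()
  for (gname in names(groups)) {
    sel <- groups[[gname]]
    for (w in waves) {
      idx <- sel & (data$wave == w)
      n_total <- sum(idx)
      if (n_total == 0L) next
      yv <- data$y[idx]
      n_ge1 <- sum(yv >= 1L)
      pct_ge1 <- 100 * n_ge1 / n_total
      rows[[length(rows) + 1L]] <- data.frame(
        wave = w, group = gname, n_total = n_total, n_ge1 = n_ge1,
        pct_ge1 = round(pct_ge1, 1), pct_zero = round(100 - pct_ge1, 1),
        median_ge1 = if (n_ge1 > 0L) stats::median(yv[yv >= 1L]) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("event_summary", "data.frame")
  out
}

#' @export
print.event_summary <- function(x, ...) {
  cat("Subjects with >= 1 event, by wave\n")
  df <- as.data.frame(x)
  df$pct_ge1 <- sprintf("%.1f%%", df$pct_ge1)
  df$pct_zero <- sprintf("%.1f%%", df$pct_zero)
  print(df, row.names = FALSE)
  invisible(x)
}
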