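#' Build fixed- and random-effects design matrices
#'
#' Constructs the design used by every model family, with a canonical column
#' order so coefficient vectors are comparable across families: an intercept
#' column first, then one dummy per non-reference covariate level (reference =
#' first factor level), then one dummy per non-baseline wave (baseline = first
#' declared wave). The random-effects matrix `Z` has an intercept column and,
#' for `random = "intercept_slope"`, a linear time score equal to the 0-based
#' wave index.
#'
#' @param data A `"longdata"` object.
#' @param covariates Covariate names to enter the fixed part; default none.
#' @param waves Logical; include wave dummies in the fixed part (default
#'   `TRUE`).
#' @param random `"intercept"` or `"intercept_slope"`.
#' @return A list with elements `X` (n x p fixed matrix), `Z` (n x d random
#'   matrix, d = 1 or 2), `subject_index` (integer row-to-subject map),
#'   `subjects` (unique ids in index order), `y`, and `n_subjects`.
#' @examples
#' d <- data.frame(id = rep(1:2, each = 3), t = rep(c("T0","T1","T2"), 2),
#'                 edu = "low", y = 0)
#' ld <- longitudinal_data(d, "id", "t", "y", covariates = "edu")
#' colnames(build_design(ld, covariates = "edu")$X)
#' @export
build_design <- function(data, covariates = character(), waves = TRUE,
                         random = c("intercept", "intercept_slope")) {
  stopifnot(inherits(data, "longdata"))
  random <- match.arg(random)
  n <- nrow(data)
  wave_levels <- levels(data$wave)

  cols <- list("(Intercept)" = rep(1, n))
  for (cv in covariates) {
    if (!cv %in% attr(data, "covariates"))
      stop("unknown covariate: ", cv, call. = FALSE)
    v <- data[[cv]]
    if (is.numeric(v)) {
      cols[[cv]] <- as.numeric(v)
    } else {
      lv <- if (is.factor(v)) levels(v) else sort(unique(as.character(v)))
      obs <- unique(as.character(v))
      if (is.factor(v) && any(is.na(v)))
        stop("covariate ", cv, " has values outside its declared levels; ",
             "observed levels: ", paste(obs, collapse = ", "), call. = FALSE)
      for (l in lv[-1L])
        cols[[paste(cv, l, sep = "_")]] <- as.numeric(as.character(v) == l)
    }
  }
  if (waves && length(wave_levels) >= 2L) {
    for (w in wave_levels[-1L])
      cols[[paste0("wave", w)]] <- as.numeric(data$wave == w)
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)

  time_score <- as.integer(data$wave) - 1L
  Z <- if (random == "intercept") matrix(1, n, 1L,
                                         dimnames = list(NULL, "(Intercept)"))
       else cbind("(Intercept)" = rep(1, n), time = as.numeric(time_score))

  subjects <- unique(data$subject)
  list(X = X, Z = Z,
       subject_index = match(data$subject, subjects),
       subjects = subjects, y = data$y, n_subjects = length(subjects))
}
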