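#' Multi-rater complication grades
#'
#' Container for the grading workflow in which two (or more) raters
#' independently assign an Accordion grade to every complication and an
#' optional adjudicator settles disagreements.
#'
#' @param items character vector of complication labels.
#' @param grades integer matrix, one row per item and one column per rater,
#'   all entries in 1..6, no missing cells.  At least 2 items and 2 raters.
#' @param adjudicator optional integer vector of adjudicator grades (may be
#'   `NA` for items where the raters agree).
#' @return an object of class `"rater_grades"`.
#' @export
rater_grades <- function(items, grades, adjudicator = NULL) {
  grades <- as.matrix(grades)
  if (nrow(grades) < 2L || ncol(grades) < 2L) {
    stop("need at least 2 items and 2 raters", call. = FALSE)
  }
  if (length(items) != nrow(grades)) {
    stop("'items' must label every row of 'grades'", call. = FALSE)
  }
  if (anyNA(grades) || any(grades != as.integer(grades)) ||
      any(grades < 1) || any(grades > 6)) {
    stop("all grades must be integers in 1..6 with no missing cells", call. = FALSE)
  }
  if (!is.null(adjudicator)) {
    if (length(adjudicator) != nrow(grades)) {
      stop("'adjudicator' must have one entry per item", call. = FALSE)
    }
    ok <- is.na(adjudicator) | (adjudicator >= 1 & adjudicator <= 6 &
                                  adjudicator == as.integer(adjudicator))
    if (!all(ok)) stop("adjudicator grades must be integers in 1..6 or NA", call. = FALSE)
  }
  structure(list(items = as.character(items), grades = grades,
                 adjudicator = adjudicator),
            class = "rater_grades")
}

#' Intraclass correlation coefficient for complication grading
#'
#' Inter-rater reliability of the grade assignments, by default the two-way
#' random-effects, absolute-agreement, single-rater form ICC(2,1): items and
#' raters are both treated as random samples and systematic rater offsets
#' count against agreement.  Computed from the two-way ANOVA mean squares
#' (`MSR` rows/items, `MSC` columns/raters, `MSE` residual) as
#' \deqn{ICC(2,1) = \frac{MSR - MSE}{MSR + (k-1) MSE + \frac{k}{n}(MSC - MSE)}}
#' with `n` items and `k` raters.  The consistency forms (raters fixed) and
#' the average-rater forms are available through `form`.
#'
#' The band label follows the conventional cutpoints: below 0.50 poor,
#' 0.50--0.75 moderate, above 0.75 up to 0.90 good, above 0.90 excellent.
#'
#' @param grades a [rater_grades()] object (the adjudicator column, if any,
#'   is not used) or a bare items-by-raters matrix.
#' @param form ICC variant: `"2,1"` (default), `"2,k"`, `"3,1"` or `"3,k"`.
#' @return object of class `"icc"`: `value`, `band`, `form`, `n_items`,
#'   `n_raters` and the mean squares.  If the grades carry no variance at
#'   all the coefficient is undefined; `NA` is returned with a warning.
#' @export
icc <- function(grades, form = c("2,1", "2,k", "3,1", "3,k")) {
  form <- match.arg(form)
  x <- if (inherits(grades, "rater_grades")) grades$grades else as.matrix(grades)
  if (nrow(x) < 2L || ncol(x) < 2L) {
    stop("need at least 2 items and 2 raters", call. = FALSE)
  }
  if (anyNA(x)) stop("grades must have no missing cells", call. = FALSE)
  n <- nrow(x); k <- ncol(x)

  grand <- mean(x)
  row_m <- rowMeans(x)
  col_m <- colMeans(x)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sst <- sum((x - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))

  if (sst < .Machine$double.eps) {
    warning("grades are constant: between-item variance is zero, ICC undefined")
    value <- NA_real_
  } else {
    value <- switch(form,
      "2,1" = (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse)),
      "2,k" = (msr - mse) / (msr + (msc - mse) / n),
      "3,1" = (msr - mse) / (msr + (k - 1) * mse),
      "3,k" = (msr - mse) / msr)
  }
  structure(list(value = value, band = icc_band(value), form = form,
                 n_items = n, n_raters = k,
                 ms = c(MSR = msr, MSC = msc, MSE = mse)),
            class = "icc")
}

#' @rdname icc
#' @param value an ICC value (or `NA`).
#' @export
icc_band <- function(value) {
  if (is.na(value)) return(NA_character_)
  if (value < 0.50) "poor"
  else if (value <= 0.75) "moderate"
  else if (value <= 0.90) "good"
  else "excellent"
}

#' @export
print.icc <- function(x, digits = 3, ...) {
  cat(sprintf("ICC(%s) = %s over %d items x %d raters",
              x$form, format(round(x$value, digits)), x$n_items, x$n_raters))
  if (!is.na(x$band)) cat(sprintf("  [%s reliability]", x$band))
  cat("\n")
  invisible(x)
}

#' Resolve two-rater disagreements with an adjudicator
#'
#' When the two raters agree the common grade stands; when they disagree the
#' adjudicator's grade is final.  An item with disagreement but no
#' adjudicator grade is an error, named in the message.
#'
#' @param grades a [rater_grades()] object with exactly 2 rater columns.
#' @return integer vector of final grades, named by item.
#' @export
adjudicate <- function(grades) {
  if (!inherits(grades, "rater_grades")) {
    stop("'grades' must be a rater_grades object", call. = FALSE)
  }
  x <- grades$grades
  if (ncol(x) != 2L) stop("adjudication expects exactly 2 raters", call. = FALSE)
  disagree <- x[, 1L] != x[, 2L]
  adj <- grades$adjudicator
  if (is.null(adj)) adj <- rep(NA_integer_, nrow(x))
  missing_adj <- disagree & is.na(adj)
  if (any(missing_adj)) {
    stop("raters disagree on item(s) without an adjudicator grade: ",
         paste(grades$items[missing_adj], collapse = ", "), call. = FALSE)
  }
  final <- x[, 1L]
  final[disagree] <- adj[disagree]
  stats::setNames(as.integer(final), grades$items)
}
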