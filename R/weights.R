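#' Accordion severity weight table
#'
#' The Accordion Severity Grading System scores postoperative complications on
#' a six-point ordinal scale (1 = minor bedside intervention, 2 =
#' pharmacological treatment, 3 = invasive procedure without general
#' anaesthesia, 4 = operation under general anaesthesia, 5 = organ-system
#' failure, 6 = postoperative death).  The postoperative morbidity index (PMI)
#' multiplies each complication's frequency by a published per-grade severity
#' weight; the default vector is the ACS-NSQIP Accordion weight set with
#' death anchoring the top of the scale at 1.
#'
#' @param weights numeric vector of length 6 giving the severity weight of
#'   grades 1 through 6.  Must be strictly increasing, lie in `[0, 1]`, and
#'   end at exactly 1 (a PMI of 1 means every treated patient died).
#'
#' @return a named numeric vector of class `"accordion_weights"`.
#' @examples
#' w <- accordion_weights()
#' accordion_weight(4, w)   # operation under general anaesthesia -> 0.600
#' @seealso [accordion_weight()], [read_weight_table()]
#' @export
accordion_weights <- function(weights = c(0.110, 0.260, 0.370, 0.600, 0.790, 1.000)) {
  weights <- as.numeric(weights)
  if (length(weights) != 6L || anyNA(weights)) {
    stop("'weights' must be 6 non-missing values, one per Accordion grade", call. = FALSE)
  }
  if (any(weights < 0) || any(weights > 1)) {
    stop("severity weights must lie in [0, 1]", call. = FALSE)
  }
  if (any(diff(weights) <= 0)) {
    stop("severity weights must be strictly increasing in grade", call. = FALSE)
  }
  if (weights[6L] != 1) {
    stop("weight of grade 6 (postoperative death) must equal 1", call. = FALSE)
  }
  names(weights) <- paste0("grade", 1:6)
  structure(weights, class = "accordion_weights")
}

#' Look up the severity weight of an Accordion grade
#'
#' @param grade integer vector of Accordion grades (1--6).
#' @param table weight table from [accordion_weights()].
#' @return numeric vector of severity weights.
#' @export
accordion_weight <- function(grade, table = accordion_weights()) {
  table <- as_accordion_weights(table)
  if (length(grade) == 0L) return(numeric(0))
  g <- suppressWarnings(as.integer(grade))
  if (anyNA(g) || any(g != grade) || any(g < 1L) || any(g > 6L)) {
    stop("Accordion grades must be integers in 1..6", call. = FALSE)
  }
  unname(unclass(table)[g])
}

as_accordion_weights <- function(x) {
  if (inherits(x, "accordion_weights")) return(x)
  accordion_weights(x)
}

#' Read a grade-to-weight table from a CSV config
#'
#' Expects columns `grade` (1--6, each exactly once) and `weight`.
#'
#' @param file path to a CSV file.
#' @return an [accordion_weights()] table.
#' @export
read_weight_table <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("grade", "weight")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("weight table is missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  if (!setequal(df$grade, 1:6) || nrow(df) != 6L) {
    stop("weight table must contain each grade 1..6 exactly once", call. = FALSE)
  }
  accordion_weights(df$weight[order(df$grade)])
}

#' @export
print.accordion_weights <- function(x, ...) {
  cat("Accordion severity weights (grade 1..6):\n")
  print(format(unclass(x), nsmall = 3), quote = FALSE)
  invisible(x)
}
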