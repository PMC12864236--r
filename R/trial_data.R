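#' @importFrom stats quantile rbinom rnorm runif setNames aggregate median coef simulate
#' @importFrom utils read.csv write.csv
NULL

HORIZONS <- c("short", "long")

round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Construct a trial arm from complication records
#'
#' A trial arm bundles the arm label, the number of treated patients, and one
#' record per complication: the event rate (as a proportion and as the printed
#' one-decimal percent), the recovered integer event count, the observation
#' horizon (`"short"` = through 3 months, `"long"` = through 5 years), and the
#' typical/minimum/maximum plausible Accordion grade.
#'
#' @param name arm label.
#' @param n_patients number of treated patients (positive integer).
#' @param records data frame with columns `name`, `horizon`, `grade_typical`,
#'   optionally `grade_min`, `grade_max` (default the typical grade), and at
#'   least one of `rate_percent` (one-decimal percent) or `count` (integer
#'   events).  Zero-row inputs are allowed.
#' @return an object of class `"trial_arm"`.
#' @export
trial_arm <- function(name, n_patients, records) {
  if (!is.character(name) || length(name) != 1L || is.na(name) || !nzchar(name)) {
    stop("arm 'name' must be a non-empty string", call. = FALSE)
  }
  n <- suppressWarnings(as.integer(n_patients))
  if (length(n) != 1L || is.na(n) || n <= 0L) {
    stop("'n_patients' must be a positive integer", call. = FALSE)
  }
  records <- normalize_records(as.data.frame(records), n, arm = name)
  structure(list(name = name, n_patients = n, records = records),
            class = "trial_arm")
}

# Validates and completes a record data frame for one arm:
# grades in 1..6 with min <= typical <= max, known horizon tokens, rate and
# count made mutually consistent (count recovered from the printed percent
# when absent; rate from count/n when the percent is absent).
normalize_records <- function(df, n, arm) {
  required <- c("name", "horizon", "grade_typical")
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop("complication table is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (!("rate_percent" %in% names(df)) && !("count" %in% names(df))) {
    stop("complication table is missing required column(s): rate_percent or count",
         call. = FALSE)
  }
  if (nrow(df) == 0L) {
    return(data.frame(name = character(0), horizon = character(0),
                      rate = numeric(0), rate_percent = numeric(0),
                      count = integer(0), grade_typical = integer(0),
                      grade_min = integer(0), grade_max = integer(0),
                      stringsAsFactors = FALSE))
  }
  if (!all(df$horizon %in% HORIZONS)) {
    bad <- which(!(df$horizon %in% HORIZONS))[1L]
    stop(sprintf("unknown horizon token '%s' in row %d (expected 'short' or 'long')",
                 df$horizon[bad], bad), call. = FALSE)
  }
  if (!("grade_min" %in% names(df))) df$grade_min <- df$grade_typical
  if (!("grade_max" %in% names(df))) df$grade_max <- df$grade_typical
  df$grade_min[is.na(df$grade_min)] <- df$grade_typical[is.na(df$grade_min)]
  df$grade_max[is.na(df$grade_max)] <- df$grade_typical[is.na(df$grade_max)]
  for (col in c("grade_typical", "grade_min", "grade_max")) {
    g <- df[[col]]
    bad <- which(is.na(g) | g != as.integer(g) | g < 1 | g > 6)
    if (length(bad)) {
      stop(sprintf("%s outside 1..6 in row %d", col, bad[1L]), call. = FALSE)
    }
    df[[col]] <- as.integer(g)
  }
  bad <- which(df$grade_min > df$grade_typical | df$grade_typical > df$grade_max)
  if (length(bad)) {
    stop(sprintf("grade ordering violated (need min <= typical <= max) in row %d",
                 bad[1L]), call. = FALSE)
  }

  if (!("rate_percent" %in% names(df))) df$rate_percent <- NA_real_
  if (!("count" %in% names(df))) df$count <- NA_integer_
  df$rate_percent <- as.numeric(df$rate_percent)
  df$count <- suppressWarnings(as.integer(df$count))

  need_one <- is.na(df$rate_percent) & is.na(df$count)
  if (any(need_one)) {
    stop(sprintf("row %d has neither rate_percent nor count", which(need_one)[1L]),
         call. = FALSE)
  }
  bad <- which(!is.na(df$rate_percent) & (df$rate_percent < 0 | df$rate_percent > 100))
  if (length(bad)) stop(sprintf("rate_percent outside [0, 100] in row %d", bad[1L]),
                        call. = FALSE)
  bad <- which(!is.na(df$count) & df$count < 0)
  if (length(bad)) stop(sprintf("negative count in row %d", bad[1L]), call. = FALSE)

  # complete the missing member of (percent, count); check both when given.
  # The exact proportion follows the field that was actually supplied:
  # printed percent / 100 when the percent came from a published table,
  # count / n when the row was specified by count.
  from_pct <- !is.na(df$rate_percent)
  fill <- is.na(df$count)
  if (any(fill)) {
    df$count[fill] <- vapply(df$rate_percent[fill], function(p)
      suppressWarnings(rate_to_count(p, n)), integer(1))
  }
  fill <- is.na(df$rate_percent)
  df$rate_percent[fill] <- round_half_up(100 * df$count[fill] / n, 1)
  mismatch <- which(from_pct & abs(df$count / n - df$rate_percent / 100) >= 0.0005)
  if (length(mismatch)) {
    stop(sprintf(
      "row %d: count %d/%d does not round-trip to the printed %.1f%% (off by >0.05 points)",
      mismatch[1L], df$count[mismatch[1L]], n, df$rate_percent[mismatch[1L]]),
      call. = FALSE)
  }
  df$rate <- ifelse(from_pct, df$rate_percent / 100, df$count / n)

  df$name <- as.character(df$name)
  df$horizon <- as.character(df$horizon)
  rownames(df) <- NULL
  df[, c("name", "horizon", "rate", "rate_percent", "count",
         "grade_typical", "grade_min", "grade_max")]
}

#' @export
print.trial_arm <- function(x, ...) {
  cat(sprintf("Trial arm '%s': n = %d patients, %d complication record(s)\n",
              x$name, x$n_patients, nrow(x$records)))
  if (nrow(x$records)) print(x$records)
  invisible(x)
}

#' Read a complication table into trial arms
#'
#' Reads the canonical aggregate complication table: a UTF-8 CSV with a header
#' and columns `name`, `arm`, `horizon` (`"short"` or `"long"`), one or both
#' of `rate_percent` (printed one-decimal percent) and `count` (integer
#' events), `grade_typical`, and optional `grade_min` / `grade_max`.  Arm
#' sizes come from a sidecar: either a named vector or a JSON file mapping
#' arm label to number of treated patients.
#'
#' @param file path to the CSV table (or a connection).
#' @param arm_sizes named integer vector (`c(Rezum = 136, ...)`) or path to a
#'   JSON object with the same content.
#' @return a list of [trial_arm()] objects of class `"trial_arms"`, one per
#'   arm named in the table (empty list for a header-only table).
#' @examples
#' tab <- system.file("extdata", "longterm_results.csv", package = "pmindex")
#' sizes <- system.file("extdata", "arm_sizes.json", package = "pmindex")
#' arms <- read_complication_table(tab, sizes)
#' @export
read_complication_table <- function(file, arm_sizes) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (is.character(arm_sizes) && length(arm_sizes) == 1L && file.exists(arm_sizes)) {
    arm_sizes <- unlist(jsonlite::read_json(arm_sizes))
  }
  if (is.null(names(arm_sizes)) || any(!nzchar(names(arm_sizes)))) {
    stop("'arm_sizes' must be a named vector or JSON object of arm sizes", call. = FALSE)
  }
  required <- c("name", "arm", "horizon", "grade_typical")
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop("complication table is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (!("rate_percent" %in% names(df)) && !("count" %in% names(df))) {
    stop("complication table is missing required column(s): rate_percent or count",
         call. = FALSE)
  }
  arms <- unique(df$arm)
  if (nrow(df) == 0L) {
    return(structure(list(), class = "trial_arms"))
  }
  unknown <- setdiff(arms, names(arm_sizes))
  if (length(unknown)) {
    stop("no arm size given for arm(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  out <- lapply(arms, function(a) {
    trial_arm(a, arm_sizes[[a]], df[df$arm == a, setdiff(names(df), "arm")])
  })
  names(out) <- arms
  structure(out, class = "trial_arms")
}

#' Write trial arms back to the canonical CSV dialect
#'
#' Inverse of [read_complication_table()]; a write/read round trip reproduces
#' the record set field for field at stored precision.
#'
#' @param arms a `trial_arms` list or single [trial_arm()].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_complication_table <- function(arms, file) {
  if (inherits(arms, "trial_arm")) arms <- structure(list(arms), class = "trial_arms")
  rows <- lapply(arms, function(a) {
    if (nrow(a$records) == 0L) return(NULL)
    cbind(a$records[, "name", drop = FALSE], arm = a$name,
          a$records[, setdiff(names(a$records), "name")])
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) {
    df <- data.frame(name = character(0), arm = character(0), horizon = character(0),
                     rate = numeric(0), rate_percent = numeric(0), count = integer(0),
                     grade_typical = integer(0), grade_min = integer(0),
                     grade_max = integer(0))
  }
  utils::write.csv(df, file, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(file)
}

#' Recover an integer event count from a printed one-decimal percent
#'
#' Published tables print rates as one-decimal percentages; binomial sampling
#' needs the underlying integer count.  The count is the nearest integer to
#' `rate_percent/100 * n` (ties round half away from zero).  If the recovered
#' count does not re-round to the printed percent, a warning of class
#' `"pmindex_roundtrip_warning"` is signalled — the printed value then cannot
#' have arisen from an integer count at this `n`.
#'
#' @param rate_percent percentage in `[0, 100]`.
#' @param n number of patients at risk (positive integer).
#' @return integer event count.
#' @examples
#' rate_to_count(11.0, 136)  # 15 events; 15/136 re-prints as 11.0%
#' @export
rate_to_count <- function(rate_percent, n) {
  if (length(rate_percent) != 1L || is.na(rate_percent) ||
      rate_percent < 0 || rate_percent > 100) {
    stop("'rate_percent' must be a single value in [0, 100]", call. = FALSE)
  }
  if (length(n) != 1L || is.na(n) || n <= 0 || n != as.integer(n)) {
    stop("'n' must be a positive integer", call. = FALSE)
  }
  count <- as.integer(round_half_up(rate_percent / 100 * n))
  back <- round_half_up(100 * count / n, 1)
  if (abs(back - round_half_up(rate_percent, 1)) > 1e-9) {
    warning(warningCondition(
      sprintf("count %d/%d re-rounds to %.1f%%, not the printed %.1f%%",
              count, n, back, rate_percent),
      class = "pmindex_roundtrip_warning"))
  }
  count
}

#' Diagnostic report for a set of trial arms
#'
#' Pure summary pass over validated arms: per-arm record counts and horizon
#' coverage, plus warnings for percent/count round-trip mismatches beyond
#' 0.05 percentage points and for duplicated (name, arm, horizon) rows.
#'
#' @param arms a `trial_arms` list (or a single [trial_arm()]).
#' @return a list of class `"arm_diagnostics"` with elements `summary`
#'   (data frame) and `warnings` (character vector, empty when clean).
#' @export
validate_arms <- function(arms) {
  if (inherits(arms, "trial_arm")) arms <- structure(list(arms), class = "trial_arms")
  summ <- do.call(rbind, lapply(arms, function(a) {
    data.frame(arm = a$name, n_patients = a$n_patients,
               n_records = nrow(a$records),
               horizons = paste(sort(unique(a$records$horizon)), collapse = ","),
               stringsAsFactors = FALSE)
  }))
  if (is.null(summ)) {
    summ <- data.frame(arm = character(0), n_patients = integer(0),
                       n_records = integer(0), horizons = character(0))
  }
  rownames(summ) <- NULL
  warnings <- character(0)
  for (a in arms) {
    r <- a$records
    if (nrow(r) == 0L) next
    off <- abs(r$count / a$n_patients - r$rate_percent / 100) * 100
    for (i in which(off > 0.05)) {
      warnings <- c(warnings, sprintf(
        "%s/%s: count %d/%d differs from printed %.1f%% by %.2f points",
        a$name, r$name[i], r$count[i], a$n_patients, r$rate_percent[i], off[i]))
    }
    key <- paste(r$name, r$horizon, sep = "\r")
    for (d in unique(key[duplicated(key)])) {
      warnings <- c(warnings, sprintf("%s: duplicate record '%s' (%s)",
                                      a$name, sub("\r.*", "", d), sub(".*\r", "", d)))
    }
  }
  structure(list(summary = summ, warnings = warnings), class = "arm_diagnostics")
}

#' @export
print.arm_diagnostics <- function(x, ...) {
  cat("Complication table diagnostics\n")
  print(x$summary)
  if (length(x$warnings)) {
    cat("Warnings:\n")
    cat(paste0("  - ", x$warnings, collapse = "\n"), "\n")
  } else {
    cat("No warnings.\n")
  }
  invisible(x)
}

# records of one arm restricted to a horizon, erroring on mixed use
arm_records <- function(arm, horizon = NULL) {
  r <- arm$records
  if (!is.null(horizon)) {
    horizon <- match.arg(horizon, HORIZONS)
    r <- r[r$horizon == horizon, , drop = FALSE]
  } else if (length(unique(r$horizon)) > 1L) {
    stop("arm mixes short- and long-horizon records; pass 'horizon' explicitly",
         call. = FALSE)
  }
  r
}
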