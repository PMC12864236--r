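#' Postoperative morbidity index for a trial arm
#'
#' The postoperative morbidity index (PMI) summarises complication burden per
#' treated patient: the sum, over treated patients, of severity weights of
#' the complications they experienced, divided by the number of treated
#' patients.  It ranges from 0 (no complications) to 1 (every patient died
#' postoperatively).
#'
#' Two aggregation modes are supported.  `"sum_all"` works directly from
#' aggregate per-complication rates,
#' \deqn{PMI = \sum_i r_i \, w(g_i),}
#' where \eqn{r_i} is the event rate of complication \eqn{i} and
#' \eqn{w(g_i)} the severity weight of its typical grade.  This reproduces
#' the usual published arithmetic; because one patient can carry several
#' complications it is not intrinsically bounded by 1, and values above 1
#' trigger a warning rather than being capped.  `"max_per_patient"` is the
#' bounded per-patient variant — each patient contributes the weight of
#' their most severe complication — and requires patient-level data (see
#' [generate_trial()]).
#'
#' @param arm a [trial_arm()] (mode `"sum_all"`), or for
#'   `"max_per_patient"` the arm label to select from `patients`.
#' @param weights an [accordion_weights()] table.
#' @param horizon `"short"` (3 months) or `"long"` (5 years); required when
#'   the arm carries records on both horizons.
#' @param mode aggregation mode, see Details.
#' @param patients patient-level data frame as produced by
#'   [generate_trial()]; used only in `"max_per_patient"` mode.
#' @return an object of class `"pmi"` with components `value`,
#'   `contributions` (per-complication `rate * weight` terms in
#'   `"sum_all"` mode), `mode`, `horizon`, `arm`, `weights`, and
#'   `n_patients`.  Supports `print()`, `summary()`, `coef()`, `plot()` and
#'   [simulate()][simulate.pmi].
#' @examples
#' rez <- trial_arm("Rezum", 136, data.frame(
#'   name = c("medical retreatment", "surgical retreatment"),
#'   horizon = "long", rate_percent = c(11.0, 4.4), grade_typical = c(2L, 4L)))
#' pmi(rez)   # 0.055
#' @export
pmi <- function(arm, weights = accordion_weights(), horizon = NULL,
                mode = c("sum_all", "max_per_patient"), patients = NULL) {
  mode <- match.arg(mode)
  weights <- as_accordion_weights(weights)

  if (mode == "max_per_patient") {
    if (is.null(patients)) {
      stop("'max_per_patient' mode needs patient-level data in 'patients'",
           call. = FALSE)
    }
    label <- if (inherits(arm, "trial_arm")) arm$name else as.character(arm)
    p <- patients[patients$arm == label, , drop = FALSE]
    if (nrow(p) == 0L) stop("no patients found for arm '", label, "'", call. = FALSE)
    ids <- unique(p$patient)
    ev <- p[p$event, , drop = FALSE]
    per_patient <- rep(0, length(ids))
    names(per_patient) <- ids
    if (nrow(ev)) {
      mx <- tapply(accordion_weight(ev$grade, weights), ev$patient, max)
      per_patient[names(mx)] <- mx
    }
    value <- mean(per_patient)
    out <- list(value = value, contributions = NULL, mode = mode,
                horizon = horizon, arm = label, weights = weights,
                n_patients = length(ids), per_patient = unname(per_patient))
    return(structure(out, class = "pmi"))
  }

  if (!inherits(arm, "trial_arm")) {
    stop("'arm' must be a trial_arm object in 'sum_all' mode", call. = FALSE)
  }
  r <- arm_records(arm, horizon)
  w <- accordion_weight(r$grade_typical, weights)
  contributions <- data.frame(name = r$name, rate = r$rate,
                              grade_typical = r$grade_typical, weight = w,
                              contribution = r$rate * w,
                              stringsAsFactors = FALSE)
  value <- sum(contributions$contribution)
  if (value > 1) {
    warning("sum_all PMI exceeds 1 (patients carry multiple complications); not capped")
  }
  structure(list(value = value, contributions = contributions, mode = mode,
                 horizon = if (is.null(horizon)) unique(r$horizon) else horizon,
                 arm = arm, weights = weights, n_patients = arm$n_patients,
                 records = r),
            class = "pmi")
}

#' @export
print.pmi <- function(x, digits = 3, ...) {
  label <- if (inherits(x$arm, "trial_arm")) x$arm$name else x$arm
  cat(sprintf("Postoperative morbidity index (%s mode)\n", x$mode))
  cat(sprintf("Arm: %s (n = %d)%s\n", label, x$n_patients,
              if (length(x$horizon)) paste0(", horizon: ", x$horizon) else ""))
  cat(sprintf("PMI = %.*f\n", digits, x$value))
  invisible(x)
}

#' @export
summary.pmi <- function(object, ...) {
  print(object)
  if (!is.null(object$contributions) && nrow(object$contributions)) {
    cat("\nPer-complication contributions (rate x weight):\n")
    print(object$contributions, row.names = FALSE)
  }
  invisible(object)
}

#' @export
coef.pmi <- function(object, ...) {
  if (is.null(object$contributions)) {
    return(stats::setNames(object$value, "pmi"))
  }
  stats::setNames(object$contributions$contribution, object$contributions$name)
}

#' @export
plot.pmi <- function(x, ...) {
  if (is.null(x$contributions) || !nrow(x$contributions)) {
    stop("nothing to plot: no per-complication contributions", call. = FALSE)
  }
  graphics::barplot(x$contributions$contribution,
                    names.arg = x$contributions$name, las = 2,
                    ylab = "PMI contribution (rate x weight)",
                    main = sprintf("PMI = %.3f", x$value), ...)
  invisible(x)
}

#' Cumulative incidence of complications in an arm
#'
#' Sum of per-complication event rates over the requested horizon, under the
#' assumption that the records count distinct patients (the convention for
#' published 5-year retreatment/removal rates).  Sums above 1 are capped at 1
#' with a warning, since a proportion of patients cannot exceed 1.
#'
#' @inheritParams pmi
#' @return a proportion in `[0, 1]`.
#' @export
cumulative_incidence <- function(arm, horizon = NULL) {
  r <- arm_records(arm, horizon)
  total <- sum(r$rate)
  if (total > 1) {
    warning("summed rates exceed 1; capping cumulative incidence at 1 ",
            "(distinct-patient assumption violated?)")
    total <- 1
  }
  total
}

#' Inclusion-exclusion bounds on the probability of at least one complication
#'
#' When only marginal complication rates are published, the proportion of
#' patients with at least one complication is not identified: it depends on
#' how events overlap across patients.  The extremes are total overlap
#' (`lower = max(rates)`) and disjoint events (`upper = min(1, sum(rates))`).
#'
#' @param rates vector of per-complication proportions in `[0, 1]`.
#' @return named numeric `c(lower=, upper=)`; `c(0, 0)` for empty input.
#' @seealso [union_independent()] for the independence point value.
#' @export
union_bounds <- function(rates) {
  check_rates(rates)
  if (length(rates) == 0L) return(c(lower = 0, upper = 0))
  c(lower = max(rates), upper = min(1, sum(rates)))
}

#' Probability of at least one complication under independence
#'
#' `1 - prod(1 - rates)`: the union probability when events are independent
#' across complications.  Always lies inside [union_bounds()]; used as the
#' mode of the triangular distribution over the union rate in the
#' short-horizon simulation model.
#'
#' @inheritParams union_bounds
#' @return a proportion.
#' @export
union_independent <- function(rates) {
  check_rates(rates)
  1 - prod(1 - rates)
}

check_rates <- function(rates) {
  if (length(rates) && (anyNA(rates) || any(rates < 0) || any(rates > 1))) {
    stop("rates must lie in [0, 1]", call. = FALSE)
  }
  invisible(rates)
}
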