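#' Configuration for a synthetic two-arm complication trial
#'
#' Describes a patient-level trial with the statistical structure the
#' aggregate analysis assumes: per-complication Bernoulli events with
#' configurable rates, ordinal grade assignment around a typical grade, an
#' optional shared-frailty overlap model (some patients are complication
#' prone, so events co-occur within patients), and rater noise for
#' exercising the reliability workflow.
#'
#' @param arms list of arms; each a list with `name`, `n_patients`, and
#'   `complications` — a data frame with columns `name`, `rate`, and
#'   `grade_typical` (optional `grade_min` / `grade_max`, defaulting to the
#'   typical grade).
#' @param typical_mass probability mass placed on the typical grade when an
#'   event's grade is drawn; the remainder is split evenly between the
#'   minimum and maximum plausible grades.  Default 0.8.
#' @param overlap `"independent"` (events independent across complications)
#'   or `"shared_frailty"` (a log-normal per-patient multiplier on the odds
#'   of every complication).
#' @param frailty_sd standard deviation of the per-patient log-odds
#'   frailty; 0 reduces `"shared_frailty"` to the independent model.
#' @param rater_noise probability that a rater mis-grades an event to an
#'   adjacent grade; used by [simulate_raters()].
#' @param horizon horizon label stamped on aggregated records
#'   (default `"short"`).
#' @return validated config of class `"synthetic_trial_config"`.
#' @export
synthetic_trial_config <- function(arms, typical_mass = 0.8,
                                   overlap = c("independent", "shared_frailty"),
                                   frailty_sd = 0, rater_noise = 0,
                                   horizon = c("short", "long")) {
  overlap <- match.arg(overlap)
  horizon <- match.arg(horizon)
  if (typical_mass < 0 || typical_mass > 1) {
    stop("'typical_mass' must lie in [0, 1]", call. = FALSE)
  }
  if (frailty_sd < 0) stop("'frailty_sd' must be nonnegative", call. = FALSE)
  if (rater_noise < 0 || rater_noise > 1) {
    stop("'rater_noise' must lie in [0, 1]", call. = FALSE)
  }
  if (!length(arms)) stop("at least one arm is required", call. = FALSE)
  arms <- lapply(arms, function(a) {
    if (is.null(a$name) || is.null(a$n_patients) || is.null(a$complications)) {
      stop("each arm needs 'name', 'n_patients' and 'complications'", call. = FALSE)
    }
    if (a$n_patients < 1) stop("'n_patients' must be positive", call. = FALSE)
    comp <- as.data.frame(a$complications)
    need <- c("name", "rate", "grade_typical")
    miss <- setdiff(need, names(comp))
    if (length(miss)) {
      stop("complication spec missing column(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    if (any(comp$rate < 0 | comp$rate > 1)) {
      stop("complication rates must lie in [0, 1]", call. = FALSE)
    }
    if (!("grade_min" %in% names(comp))) comp$grade_min <- comp$grade_typical
    if (!("grade_max" %in% names(comp))) comp$grade_max <- comp$grade_typical
    for (col in c("grade_min", "grade_typical", "grade_max")) {
      g <- comp[[col]]
      if (any(is.na(g) | g != as.integer(g) | g < 1 | g > 6)) {
        stop("'", col, "' must contain integers in 1..6", call. = FALSE)
      }
    }
    if (any(comp$grade_min > comp$grade_typical | comp$grade_typical > comp$grade_max)) {
      stop("need grade_min <= grade_typical <= grade_max", call. = FALSE)
    }
    a$complications <- comp
    a
  })
  structure(list(arms = arms, typical_mass = typical_mass, overlap = overlap,
                 frailty_sd = frailty_sd, rater_noise = rater_noise,
                 horizon = horizon),
            class = "synthetic_trial_config")
}

#' Generate a patient-level synthetic trial
#'
#' Draws, for every patient and complication, a Bernoulli event indicator
#' and (for events) an Accordion grade.  Under the `"independent"` overlap
#' model the indicator is `Bernoulli(rate)`; under `"shared_frailty"` each
#' patient carries a latent log-odds shift `N(0, frailty_sd)` applied to
#' every complication, so events cluster within patients while marginal
#' rates stay near the configured values.  Grades put `typical_mass` on the
#' typical grade and split the remainder evenly between the minimum and
#' maximum plausible grades.
#'
#' @param config a [synthetic_trial_config()].
#' @inheritParams rtri
#' @return long-format data frame, one row per (patient, complication):
#'   columns `patient`, `arm`, `complication`, `event` (logical),
#'   `grade_typical`/`grade_min`/`grade_max` (the truth used for grading)
#'   and `grade` (`NA` unless `event`).
#' @export
generate_trial <- function(config, seed = NULL) {
  stopifnot(inherits(config, "synthetic_trial_config"))
  with_seed(seed, {
    out <- lapply(config$arms, function(a) {
      n <- a$n_patients
      comp <- a$complications
      frail <- if (config$overlap == "shared_frailty" && config$frailty_sd > 0) {
        stats::rnorm(n, 0, config$frailty_sd)
      } else {
        rep(0, n)
      }
      blocks <- lapply(seq_len(nrow(comp)), function(i) {
        p <- comp$rate[i]
        pj <- if (p <= 0 || p >= 1) rep(p, n) else stats::plogis(stats::qlogis(p) + frail)
        event <- stats::runif(n) < pj
        grade <- rep(NA_integer_, n)
        if (any(event)) {
          grade[event] <- draw_grades(sum(event), comp$grade_min[i],
                                      comp$grade_typical[i], comp$grade_max[i],
                                      config$typical_mass)
        }
        data.frame(patient = sprintf("%s_%04d", a$name, seq_len(n)),
                   arm = a$name, complication = comp$name[i], event = event,
                   grade_min = comp$grade_min[i],
                   grade_typical = comp$grade_typical[i],
                   grade_max = comp$grade_max[i], grade = grade,
                   stringsAsFactors = FALSE)
      })
      do.call(rbind, blocks)
    })
    df <- do.call(rbind, out)
    rownames(df) <- NULL
    df
  })
}

# Grade sampler: typical grade with probability `mass`, the rest split
# evenly between min and max (which may coincide with the typical grade).
draw_grades <- function(k, gmin, gtyp, gmax, mass) {
  choices <- c(gtyp, gmin, gmax)
  probs <- c(mass, (1 - mass) / 2, (1 - mass) / 2)
  choices[sample.int(3L, k, replace = TRUE, prob = probs)]
}

#' Expected severity weight of a synthetic complication's grade draw
#'
#' Helper for parameter-recovery checks: the mean weight implied by the
#' typical-mass grade model.
#'
#' @param gmin,gtyp,gmax plausible grade range.
#' @param mass typical-grade probability mass.
#' @param table an [accordion_weights()] table.
#' @return expected severity weight.
#' @export
expected_grade_weight <- function(gmin, gtyp, gmax, mass = 0.8,
                                  table = accordion_weights()) {
  w <- accordion_weight(c(gtyp, gmin, gmax), table)
  sum(w * c(mass, (1 - mass) / 2, (1 - mass) / 2))
}

#' Aggregate patient-level records into trial arms
#'
#' Bridges the patient level back to the aggregate table shape: for each
#' arm and complication the observed rate is `events / n`, the typical
#' grade is the modal assigned grade (smallest on ties), and the plausible
#' range is the observed minimum and maximum.  Complications with no
#' events are dropped, matching published tables that list only observed
#' complications.
#'
#' @param records data frame from [generate_trial()].
#' @param horizon horizon stamped on the aggregate records.
#' @return a `trial_arms` list (see [read_complication_table()]).
#' @export
aggregate_patients <- function(records, horizon = "short") {
  if (is.null(records) || nrow(records) == 0L) {
    stop("'records' must be a nonempty patient-level data frame", call. = FALSE)
  }
  horizon <- match.arg(horizon, HORIZONS)
  arms <- unique(records$arm)
  out <- lapply(arms, function(a) {
    sub <- records[records$arm == a, , drop = FALSE]
    n <- length(unique(sub$patient))
    rows <- lapply(unique(sub$complication), function(cc) {
      ev <- sub[sub$complication == cc & sub$event, , drop = FALSE]
      if (nrow(ev) == 0L) return(NULL)
      tab <- table(ev$grade)
      modal <- as.integer(names(tab)[which.max(tab)])
      data.frame(name = cc, horizon = horizon, count = nrow(ev),
                 grade_typical = modal,
                 grade_min = min(min(ev$grade), modal),
                 grade_max = max(max(ev$grade), modal),
                 stringsAsFactors = FALSE)
    })
    rows <- do.call(rbind, rows)
    if (is.null(rows)) {
      rows <- data.frame(name = character(0), horizon = character(0),
                         count = integer(0), grade_typical = integer(0),
                         grade_min = integer(0), grade_max = integer(0))
    }
    trial_arm(a, n, rows)
  })
  names(out) <- arms
  structure(out, class = "trial_arms")
}

#' Simulate noisy raters over synthetic events
#'
#' Each observed event becomes an item graded by two raters who report the
#' true grade with probability `1 - noise` and otherwise an adjacent grade
#' (one step up or down, equally likely, clamped to 1..6 — so an intended
#' step off the end of the scale returns the true grade).  The adjudicator
#' always reports the truth.
#'
#' @param records data frame from [generate_trial()].
#' @param noise per-rater mis-grading probability in `[0, 1]`.
#' @inheritParams rtri
#' @return a [rater_grades()] object with the adjudicator column set.
#' @export
simulate_raters <- function(records, noise, seed = NULL) {
  if (noise < 0 || noise > 1) stop("'noise' must lie in [0, 1]", call. = FALSE)
  ev <- records[records$event, , drop = FALSE]
  if (nrow(ev) < 2L) {
    stop("need at least 2 observed events to build a rater matrix", call. = FALSE)
  }
  truth <- ev$grade
  with_seed(seed, {
    report <- function() {
      err <- stats::runif(length(truth)) < noise
      step <- sample(c(-1L, 1L), length(truth), replace = TRUE)
      g <- truth
      g[err] <- pmin(6L, pmax(1L, truth[err] + step[err]))
      g
    }
    rater_grades(items = paste(ev$patient, ev$complication, sep = ":"),
                 grades = cbind(rater1 = report(), rater2 = report()),
                 adjudicator = truth)
  })
}
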