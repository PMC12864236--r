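# Runs `code` under a temporary RNG state seeded with `seed` (NULL = use the
# current stream), restoring the caller's state afterwards.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) stats::runif(1)
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    set.seed(seed)
  }
  force(code)
}

#' Triangular distribution
#'
#' Density-free inverse-CDF sampler and distribution functions for the
#' triangular distribution on `[a, b]` with mode `m`.  Used to model
#' uncertainty in complication rates (bounded by the inclusion-exclusion
#' extremes) and in grade weights (bounded by the minimum and maximum
#' plausible grades).  `a = m = b` is allowed and degenerates to a point
#' mass.
#'
#' @param n number of draws.
#' @param a,b lower and upper limits, `a <= b`.
#' @param m mode, in `[a, b]`.
#' @param q,p quantile / probability arguments.
#' @param seed optional integer; when given, draws are taken from a
#'   temporary RNG stream seeded with it and the caller's RNG state is left
#'   untouched.
#' @return `rtri()` a vector of `n` draws; `ptri()` CDF values; `qtri()`
#'   quantiles.
#' @examples
#' rtri(5, 0, 0.2, 1, seed = 1)
#' @export
rtri <- function(n, a, m, b, seed = NULL) {
  check_tri(a, m, b)
  with_seed(seed, qtri(stats::runif(n), a, m, b))
}

#' @rdname rtri
#' @export
qtri <- function(p, a, m, b) {
  check_tri(a, m, b)
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("'p' must lie in [0, 1]", call. = FALSE)
  if (a == b) return(rep(a, length(p)))
  pm <- (m - a) / (b - a)
  lower <- !is.na(p) & p < pm
  out <- numeric(length(p))
  out[lower] <- a + sqrt(p[lower] * (b - a) * (m - a))
  out[!lower] <- b - sqrt((1 - p[!lower]) * (b - a) * (b - m))
  out[is.na(p)] <- NA_real_
  out
}

#' @rdname rtri
#' @export
ptri <- function(q, a, m, b) {
  check_tri(a, m, b)
  if (a == b) return(as.numeric(q >= a))
  out <- numeric(length(q))
  out[q >= b] <- 1
  rising <- q > a & q < m          # empty when m == a
  out[rising] <- (q[rising] - a)^2 / ((b - a) * (m - a))
  falling <- q >= m & q < b        # empty when m == b
  out[falling] <- 1 - (b - q[falling])^2 / ((b - a) * (b - m))
  out
}

check_tri <- function(a, m, b) {
  if (anyNA(c(a, m, b))) stop("triangular parameters must be non-missing", call. = FALSE)
  if (a > b) stop("triangular: need a <= b", call. = FALSE)
  if (m < a || m > b) stop("triangular: mode must lie in [a, b]", call. = FALSE)
  # degenerate edges (a == m or m == b) are fine with the inverse CDF
  invisible(TRUE)
}

#' Sample complication event counts from a binomial model
#'
#' Thin validated wrapper around [stats::rbinom()]: event counts among `n`
#' patients when each experiences the complication with probability `p`.
#'
#' @param n patients at risk (positive integer).
#' @param p event probability.
#' @param draws number of Monte Carlo draws.
#' @inheritParams rtri
#' @return integer vector of `draws` counts.
#' @export
sample_count_binomial <- function(n, p, draws, seed = NULL) {
  if (length(n) != 1L || is.na(n) || n < 1 || n != as.integer(n)) {
    stop("'n' must be a positive integer", call. = FALSE)
  }
  if (length(p) != 1L || is.na(p) || p < 0 || p > 1) {
    stop("'p' must lie in [0, 1]", call. = FALSE)
  }
  with_seed(seed, stats::rbinom(draws, n, p))
}

#' Sample severity weights for one complication's grade uncertainty
#'
#' Grade uncertainty is propagated in weight space: draws come from a
#' triangular distribution whose vertices are the severity weights of the
#' minimum, typical, and maximum plausible grades.  When all three grades
#' coincide the draws are constant.
#'
#' @param record a single complication record: anything with fields
#'   `grade_min`, `grade_typical`, `grade_max` (e.g. one row of
#'   `trial_arm$records`).
#' @param table an [accordion_weights()] table.
#' @inheritParams sample_count_binomial
#' @return numeric vector of `draws` severity weights, each inside
#'   `[weight(grade_min), weight(grade_max)]`.
#' @export
sample_grade_weight <- function(record, table = accordion_weights(), draws, seed = NULL) {
  w <- accordion_weight(c(record$grade_min, record$grade_typical, record$grade_max),
                        table)
  rtri(draws, w[1L], w[2L], w[3L], seed = seed)
}

#' Monte Carlo PMI distribution for a fitted arm
#'
#' Propagates uncertainty in both complication frequencies and severity
#' grades through the PMI.  For the long (5-year) horizon, each
#' complication's event count is drawn from `Binomial(n, count/n)` (the
#' integer count recovered from the printed rate) and its severity weight
#' from the grade triangular model; the PMI draw is
#' `sum(count_i * weight_i) / n`.  For the short horizon the same
#' per-complication binomial model is the default; alternatively
#' (`rate_model = "triangular_union"`) the overall complication frequency is
#' drawn from a triangular distribution bounded by the inclusion-exclusion
#' extremes with mode at the independence value, and multiplied by the
#' rate-weighted mean severity weight.
#'
#' @param object a `"pmi"` fit in `"sum_all"` mode.
#' @param nsim number of Monte Carlo iterations (default 1000).
#' @param seed optional integer seed; identical seeds give bit-identical
#'   draw vectors and the caller's RNG state is preserved.
#' @param rate_model frequency model for short-horizon records, see Details.
#' @param grade_model `"triangular_weight"` (default; triangular over the
#'   min/typical/max grade weights) or `"fixed_typical"` (typical grade's
#'   weight, no grade uncertainty).
#' @param ... unused.
#' @return numeric vector of `nsim` PMI draws with attributes recording the
#'   arm, models, and seed.
#' @examples
#' rez <- trial_arm("Rezum", 136, data.frame(
#'   name = c("medical", "surgical"), horizon = "long",
#'   rate_percent = c(11.0, 4.4), grade_typical = c(2L, 4L)))
#' draws <- simulate(pmi(rez), nsim = 500, seed = 42)
#' credible_interval(draws)
#' @export
simulate.pmi <- function(object, nsim = 1000, seed = NULL,
                         rate_model = c("per_complication_binomial", "triangular_union"),
                         grade_model = c("triangular_weight", "fixed_typical"), ...) {
  rate_model <- match.arg(rate_model)
  grade_model <- match.arg(grade_model)
  if (object$mode != "sum_all") {
    stop("simulate() needs a 'sum_all' fit carrying aggregate records", call. = FALSE)
  }
  if (nsim < 1) stop("'nsim' must be at least 1", call. = FALSE)
  r <- object$records
  n <- object$n_patients
  horizon <- object$horizon
  if (rate_model == "triangular_union" && !identical(horizon, "short")) {
    stop("the triangular union-rate model applies to the short horizon only",
         call. = FALSE)
  }

  draws <- with_seed(seed, {
    if (nrow(r) == 0L) {
      warning("no complication records; returning all-zero PMI draws")
      rep(0, nsim)
    } else {
      k <- nrow(r)
      W <- matrix(0, nsim, k)
      for (i in seq_len(k)) {
        W[, i] <- if (grade_model == "fixed_typical") {
          rep(accordion_weight(r$grade_typical[i], object$weights), nsim)
        } else {
          sample_grade_weight(r[i, ], object$weights, nsim)
        }
      }
      if (rate_model == "per_complication_binomial") {
        counts <- matrix(0L, nsim, k)
        for (i in seq_len(k)) {
          counts[, i] <- stats::rbinom(nsim, n, r$count[i] / n)
        }
        rowSums(counts * W) / n
      } else {
        bounds <- union_bounds(r$rate)
        mode_rate <- union_independent(r$rate)
        u <- qtri(stats::runif(nsim), bounds[["lower"]], mode_rate, bounds[["upper"]])
        wbar <- as.vector(W %*% r$rate) / sum(r$rate)
        u * wbar
      }
    }
  })
  structure(draws,
            arm = if (inherits(object$arm, "trial_arm")) object$arm$name else object$arm,
            horizon = horizon, nsim = nsim, seed = seed,
            rate_model = rate_model, grade_model = grade_model)
}

#' Equal-tailed credible interval of a draw vector
#'
#' Percentile interval at probabilities `(1-level)/2` and `1-(1-level)/2`
#' (R's default type-7 quantile rule).
#'
#' @param draws nonempty numeric vector of Monte Carlo draws.
#' @param level credible level strictly between 0 and 1 (default 0.95).
#' @return named numeric `c(lower=, upper=)`.
#' @export
credible_interval <- function(draws, level = 0.95) {
  if (length(draws) == 0L || anyNA(draws)) {
    stop("'draws' must be a nonempty vector without missing values", call. = FALSE)
  }
  if (length(level) != 1L || is.na(level) || level <= 0 || level >= 1) {
    stop("'level' must lie strictly between 0 and 1", call. = FALSE)
  }
  alpha <- (1 - level) / 2
  q <- stats::quantile(draws, c(alpha, 1 - alpha), names = FALSE, type = 7)
  c(lower = q[1L], upper = q[2L])
}

#' Summarise a Monte Carlo draw vector
#'
#' @inheritParams credible_interval
#' @return data frame with `mean`, `median`, `ci_lower`, `ci_upper`.
#' @export
mc_summary <- function(draws, level = 0.95) {
  ci <- credible_interval(draws, level)
  data.frame(mean = mean(draws), median = stats::median(draws),
             ci_lower = ci[["lower"]], ci_upper = ci[["upper"]],
             level = level)
}

#' Compare two paired Monte Carlo draw vectors
#'
#' Summarises the iteration-wise difference `draws_a - draws_b` and reports
#' the fraction of iterations favouring the first arm (lower PMI), counting
#' exact ties as half an iteration so identical arms score exactly 0.5.
#'
#' @param draws_a,draws_b equal-length draw vectors, paired by iteration
#'   index.
#' @inheritParams credible_interval
#' @return object of class `"pmi_comparison"`: mean/median difference, its
#'   credible interval, `fraction_favoring_first`, `n_favoring_first`
#'   (ties counted as half), and the difference draws.
#' @export
compare_arms <- function(draws_a, draws_b, level = 0.95) {
  if (length(draws_a) != length(draws_b)) {
    stop("draw vectors must have equal length (paired iterations)", call. = FALSE)
  }
  d <- as.numeric(draws_a) - as.numeric(draws_b)
  ci <- credible_interval(d, level)
  n_fav <- sum(draws_a < draws_b) + 0.5 * sum(draws_a == draws_b)
  structure(list(
    arms = c(attr(draws_a, "arm") %||% "A", attr(draws_b, "arm") %||% "B"),
    mean = mean(d), median = stats::median(d),
    ci_lower = ci[["lower"]], ci_upper = ci[["upper"]], level = level,
    fraction_favoring_first = n_fav / length(d),
    n_favoring_first = n_fav, n_iterations = length(d), differences = d),
    class = "pmi_comparison")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate and compare the PMI of two arms
#'
#' Runs [simulate.pmi()] for each fit on its own RNG stream (`seed` for the
#' first arm, `seed + 1` for the second), pairs the draws by iteration
#' index, and summarises the difference with [compare_arms()].
#'
#' @param fit_a,fit_b `"pmi"` fits (first minus second).
#' @inheritParams simulate.pmi
#' @inheritParams credible_interval
#' @param ... passed on to [simulate.pmi()] (`rate_model`, `grade_model`).
#' @return a `"pmi_comparison"` with per-arm draw summaries attached in
#'   `$arm_summaries` and the raw draws in `$draws`.
#' @export
compare_pmi <- function(fit_a, fit_b, nsim = 1000, seed = NULL, level = 0.95, ...) {
  draws_a <- simulate(fit_a, nsim = nsim, seed = seed, ...)
  draws_b <- simulate(fit_b, nsim = nsim,
                      seed = if (is.null(seed)) NULL else seed + 1L, ...)
  out <- compare_arms(draws_a, draws_b, level)
  out$arm_summaries <- rbind(
    cbind(arm = attr(draws_a, "arm"), mc_summary(draws_a, level)),
    cbind(arm = attr(draws_b, "arm"), mc_summary(draws_b, level)))
  out$draws <- list(draws_a, draws_b)
  out
}

#' @export
print.pmi_comparison <- function(x, digits = 4, ...) {
  cat(sprintf("PMI difference, %s - %s (%d paired iterations)\n",
              x$arms[1L], x$arms[2L], x$n_iterations))
  cat(sprintf("  mean %.*f, median %.*f, %d%% CrI [%.*f, %.*f]\n",
              digits, x$mean, digits, x$median, round(100 * x$level),
              digits, x$ci_lower, digits, x$ci_upper))
  cat(sprintf("  %.1f%% of iterations favour %s (ties as half)\n",
              100 * x$fraction_favoring_first, x$arms[1L]))
  if (!is.null(x$arm_summaries)) {
    cat("Per-arm PMI draw summaries:\n")
    print(x$arm_summaries, row.names = FALSE)
  }
  invisible(x)
}

#' @export
plot.pmi_comparison <- function(x, breaks = 30, ...) {
  graphics::hist(x$differences, breaks = breaks,
                 main = sprintf("PMI difference: %s - %s", x$arms[1L], x$arms[2L]),
                 xlab = "difference in PMI", ...)
  graphics::abline(v = 0, lty = 2)
  graphics::abline(v = c(x$ci_lower, x$ci_upper), col = "grey40")
  invisible(x)
}
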