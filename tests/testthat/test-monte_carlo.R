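test_that("triangular sampler matches its analytic distribution", {
  # degenerate point mass
  expect_equal(rtri(50, 0.3, 0.3, 0.3, seed = 1), rep(0.3, 50))
  expect_error(rtri(10, 1, 0.5, 0), "a <= b")
  expect_error(rtri(10, 0, 2, 1), "mode")

  x <- rtri(10000, 0.1, 0.4, 0.9, seed = 2)
  expect_true(all(x >= 0.1 & x <= 0.9))
  # closed-form mean (a + m + b) / 3 within 3 standard errors
  m_an <- (0.1 + 0.4 + 0.9) / 3
  v_an <- (0.1^2 + 0.4^2 + 0.9^2 - 0.1 * 0.4 - 0.1 * 0.9 - 0.4 * 0.9) / 18
  expect_lt(abs(mean(x) - m_an), 3 * sqrt(v_an / 10000))

  # sup-distance between the empirical CDF and the analytic CDF, the latter
  # written out independently here
  tri_cdf <- function(q, a, m, b) {
    ifelse(q <= a, 0,
    ifelse(q >= b, 1,
    ifelse(q < m, (q - a)^2 / ((b - a) * (m - a)),
                  1 - (b - q)^2 / ((b - a) * (b - m)))))
  }
  grid <- seq(0.1, 0.9, length.out = 400)
  emp <- ecdf(x)
  expect_lt(max(abs(emp(grid) - tri_cdf(grid, 0.1, 0.4, 0.9))), 0.02)
  # edge-mode cases stay inside the support
  expect_true(all(rtri(2000, 0, 0, 1, seed = 3) <= 1))
  expect_true(all(rtri(2000, 0, 1, 1, seed = 3) >= 0))
})

test_that("binomial count sampler hits its closed-form mean and edge cases", {
  expect_equal(sample_count_binomial(50, 0, 100, seed = 1), rep(0L, 100))
  expect_equal(sample_count_binomial(1, 1, 100, seed = 1), rep(1L, 100))
  x <- sample_count_binomial(136, 15 / 136, 10000, seed = 4)
  se <- sqrt(15 * (1 - 15 / 136) / 10000)
  expect_lt(abs(mean(x) - 15), 3 * se)
  expect_error(sample_count_binomial(136, 1.4, 10), "\\[0, 1\\]")
})

test_that("grade-weight draws respect the plausible grade range", {
  rec <- function(gmin, gtyp, gmax) list(grade_min = gmin, grade_typical = gtyp,
                                         grade_max = gmax)
  expect_equal(sample_grade_weight(rec(2, 2, 2), draws = 20, seed = 1),
               rep(0.260, 20))
  x <- sample_grade_weight(rec(3, 4, 4), draws = 5000, seed = 2)
  expect_true(all(x >= 0.370 & x <= 0.600))
  y <- sample_grade_weight(rec(1, 2, 3), draws = 10000, seed = 3)
  m_an <- (0.110 + 0.260 + 0.370) / 3
  expect_lt(abs(mean(y) - m_an), 3 * sd(y) / sqrt(10000))
})

test_that("simulated PMI draws are reproducible and preserve the point PMI", {
  fit <- pmi(rezum_long())
  a <- simulate(fit, nsim = 500, seed = 9)
  b <- simulate(fit, nsim = 500, seed = 9)
  expect_identical(as.numeric(a), as.numeric(b))
  expect_false(identical(as.numeric(a),
                         as.numeric(simulate(fit, nsim = 500, seed = 10))))
  # the caller's RNG stream is untouched
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(simulate(fit, nsim = 10, seed = 1)); after <- runif(1)
  expect_identical(before, after)

  # law of large numbers: draw mean converges to the point PMI
  x <- simulate(fit, nsim = 10000, seed = 11, grade_model = "fixed_typical")
  expect_lt(abs(mean(x) - fit$value), 3 * sd(x) / sqrt(10000))

  # no randomness left: p = 1 events at a fixed grade reproduce pmi() exactly
  sure <- trial_arm("sure", 50, data.frame(
    name = "always", horizon = "long", rate_percent = 100, grade_typical = 3L))
  fit_sure <- pmi(sure)
  expect_equal(as.numeric(simulate(fit_sure, nsim = 50, seed = 1,
                                   grade_model = "fixed_typical")),
               rep(fit_sure$value, 50))

  # all-zero rates give all-zero draws
  zero <- trial_arm("zero", 50, data.frame(
    name = "never", horizon = "long", count = 0L, grade_typical = 2L))
  expect_equal(as.numeric(simulate(pmi(zero), nsim = 20, seed = 1)), rep(0, 20))

  # empty record set warns and returns zero draws
  empty <- trial_arm("none", 10, data.frame(name = character(0),
                                            horizon = character(0),
                                            count = integer(0),
                                            grade_typical = integer(0)))
  expect_warning(z <- simulate(pmi(empty), nsim = 20, seed = 1), "all-zero")
  expect_equal(as.numeric(z), rep(0, 20))
})

test_that("short-horizon union-triangular model stays within the union bounds", {
  arms <- short_arms_synthetic()
  fit <- pmi(arms$Rezum, horizon = "short")
  x <- simulate(fit, nsim = 2000, seed = 5, rate_model = "triangular_union")
  b <- union_bounds(fit$records$rate)
  wmax <- max(accordion_weight(fit$records$grade_max))
  expect_true(all(x >= 0))
  expect_true(all(x <= b[["upper"]] * wmax + 1e-12))
  # the union model is rejected for the long horizon
  expect_error(simulate(pmi(rezum_long()), nsim = 10,
                        rate_model = "triangular_union"), "short horizon")
})

test_that("credible intervals follow the stated percentile rule", {
  expect_equal(credible_interval(rep(2.5, 40)), c(lower = 2.5, upper = 2.5))
  # order-statistic oracle for the default interpolation rule: with sorted x
  # and probability p, h = (n-1)p + 1 and q = x[floor(h)] + (h - floor(h)) *
  # (x[floor(h)+1] - x[floor(h)])
  x <- sample(1:100)
  oracle <- function(x, p) {
    s <- sort(x); h <- (length(s) - 1) * p + 1
    s[floor(h)] + (h - floor(h)) * (s[floor(h) + 1] - s[floor(h)])
  }
  ci <- credible_interval(x, 0.95)
  expect_equal(ci[["lower"]], oracle(x, 0.025))
  expect_equal(ci[["upper"]], oracle(x, 0.975))
  expect_equal(unname(ci), c(3.475, 97.525))
  expect_error(credible_interval(numeric(0)), "nonempty")
  expect_error(credible_interval(1:10, 0), "strictly between")
  expect_error(credible_interval(1:10, 1), "strictly between")
})

test_that("paired arm comparison handles ties, dominance, and mismatches", {
  x <- rtri(500, 0, 0.3, 1, seed = 6)
  same <- compare_arms(x, x)
  expect_equal(same$mean, 0)
  expect_equal(same$fraction_favoring_first, 0.5)   # ties count as half
  dom <- compare_arms(x - 0.11, x)
  expect_equal(dom$fraction_favoring_first, 1.0)
  expect_equal(dom$mean, -0.11, tolerance = 1e-12)
  expect_error(compare_arms(x, x[-1]), "equal length")
})
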