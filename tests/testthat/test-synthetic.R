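two_comp_config <- function(n = 1000, rates = c(0.11, 0.044),
                            grades = c(2L, 4L), ...) {
  synthetic_trial_config(list(list(
    name = "A", n_patients = n,
    complications = data.frame(name = paste0("c", seq_along(rates)),
                               rate = rates, grade_typical = grades))), ...)
}

test_that("event generation respects degenerate and configured rates", {
  none <- generate_trial(two_comp_config(rates = c(0, 0)), seed = 1)
  expect_false(any(none$event))
  expect_true(all(is.na(none$grade)))

  all_ev <- generate_trial(two_comp_config(rates = c(1, 1)), seed = 1)
  expect_true(all(all_ev$event))
  expect_false(anyNA(all_ev$grade))

  big <- generate_trial(two_comp_config(n = 10000, rates = 0.11, grades = 2L),
                        seed = 2)
  obs <- mean(big$event)
  expect_lt(abs(obs - 0.11), 3 * sqrt(0.11 * 0.89 / 10000))
  expect_error(two_comp_config(rates = 1.2), "\\[0, 1\\]")
})

test_that("generation is reproducible and frailty strength 0 matches independence", {
  cfg_ind <- two_comp_config(overlap = "independent")
  cfg_fr0 <- two_comp_config(overlap = "shared_frailty", frailty_sd = 0)
  expect_identical(generate_trial(cfg_ind, seed = 7), generate_trial(cfg_ind, seed = 7))
  expect_identical(generate_trial(cfg_ind, seed = 7), generate_trial(cfg_fr0, seed = 7))
})

test_that("aggregation recovers rates and grade ranges from patient data", {
  one <- data.frame(patient = "A_0001", arm = "A", complication = "uti",
                    event = TRUE, grade_min = 3L, grade_typical = 3L,
                    grade_max = 3L, grade = 3L)
  agg <- aggregate_patients(one)
  expect_equal(agg$A$records$rate, 1.0)
  expect_equal(unlist(agg$A$records[, c("grade_min", "grade_typical", "grade_max")],
                      use.names = FALSE), c(3L, 3L, 3L))

  # hand-enumerated 20-patient fixture
  pts <- sprintf("A_%04d", 1:20)
  fix <- rbind(
    data.frame(patient = pts, arm = "A", complication = "uti",
               event = pts %in% pts[1:5], grade_min = 2L, grade_typical = 2L,
               grade_max = 4L,
               grade = ifelse(pts %in% pts[1:5], c(2L, 2L, 3L, 2L, 4L)[match(pts, pts[1:5])], NA)),
    data.frame(patient = pts, arm = "A", complication = "bleed",
               event = pts %in% pts[c(3, 10)], grade_min = 1L, grade_typical = 1L,
               grade_max = 1L,
               grade = ifelse(pts %in% pts[c(3, 10)], 1L, NA)))
  agg <- aggregate_patients(fix)
  r <- agg$A$records
  expect_equal(agg$A$n_patients, 20L)
  expect_equal(r$count[r$name == "uti"], 5L)
  expect_equal(r$rate[r$name == "uti"], 0.25)
  expect_equal(r$grade_typical[r$name == "uti"], 2L)   # modal grade
  expect_equal(r$grade_min[r$name == "uti"], 2L)
  expect_equal(r$grade_max[r$name == "uti"], 4L)
  expect_equal(r$rate[r$name == "bleed"], 0.10)

  # no events -> no aggregate records for the arm
  quiet <- generate_trial(two_comp_config(n = 5, rates = c(0, 0)), seed = 1)
  expect_equal(nrow(aggregate_patients(quiet)$A$records), 0L)
})

test_that("observed union rate lies within the bounds of observed marginals", {
  cfg <- synthetic_trial_config(list(list(
    name = "A", n_patients = 300,
    complications = data.frame(name = c("c1", "c2", "c3"),
                               rate = c(0.25, 0.15, 0.10),
                               grade_typical = c(1L, 2L, 3L)))),
    overlap = "shared_frailty", frailty_sd = 1.5)
  for (s in 1:8) {
    rec <- generate_trial(cfg, seed = 300 + s)
    marg <- tapply(rec$event, rec$complication, mean)
    has_any <- tapply(rec$event, rec$patient, any)
    b <- union_bounds(as.numeric(marg))
    expect_gte(mean(has_any), b[["lower"]] - 1e-12)
    expect_lte(mean(has_any), b[["upper"]] + 1e-12)
  }
})

test_that("the pipeline recovers the configured expected PMI end to end", {
  # degenerate grade ranges: aggregate -> pmi() must recover sum(rate * weight)
  cfg <- two_comp_config(n = 10000)
  rec <- generate_trial(cfg, seed = 42)
  fit <- pmi(aggregate_patients(rec, horizon = "long")$A, horizon = "long")
  expected <- sum(c(0.11, 0.044) * accordion_weight(c(2, 4)))
  se <- sqrt(sum(accordion_weight(c(2, 4))^2 *
                   c(0.11, 0.044) * (1 - c(0.11, 0.044))) / 10000)
  expect_lt(abs(fit$value - expected), 3 * se)

  # spread grades: patient-level mean burden matches sum(rate * E[weight])
  cfg2 <- synthetic_trial_config(list(list(
    name = "A", n_patients = 10000,
    complications = data.frame(name = "c1", rate = 0.2, grade_min = 1L,
                               grade_typical = 2L, grade_max = 3L))),
    typical_mass = 0.8)
  rec2 <- generate_trial(cfg2, seed = 43)
  burden <- sum(accordion_weight(rec2$grade[rec2$event])) / 10000
  ew <- expected_grade_weight(1, 2, 3, 0.8)
  expect_equal(ew, 0.8 * 0.26 + 0.1 * 0.11 + 0.1 * 0.37)
  se2 <- sqrt(0.2 * ew^2 / 10000)   # conservative scale for the burden mean
  expect_lt(abs(burden - 0.2 * ew), 3 * se2)
})

test_that("simulated raters reproduce the configured disagreement structure", {
  cfg <- synthetic_trial_config(list(list(
    name = "A", n_patients = 500,
    complications = data.frame(name = "c1", rate = 1, grade_min = 2L,
                               grade_typical = 3L, grade_max = 4L))))
  rec <- generate_trial(cfg, seed = 50)

  clean <- simulate_raters(rec, noise = 0, seed = 51)
  expect_equal(clean$grades[, 1], clean$grades[, 2], ignore_attr = TRUE)
  expect_equal(icc(clean)$value, 1)
  expect_equal(unname(adjudicate(clean)), rec$grade[rec$event])

  # interior truth grades: at noise 1 every report is exactly one grade off
  noisy <- simulate_raters(rec, noise = 1, seed = 52)
  truth <- rec$grade[rec$event]
  expect_true(all(abs(noisy$grades[, 1] - truth) == 1))
  expect_true(all(abs(noisy$grades[, 2] - truth) == 1))

  # disagreement probability: one rater errs (2 p (1-p)) or both err and land
  # on opposite neighbours (p^2 / 2), enumerated for interior grades
  p <- 0.2
  p_dis <- 2 * p * (1 - p) + p^2 * 0.5
  some <- simulate_raters(rec, noise = p, seed = 53)
  obs <- mean(some$grades[, 1] != some$grades[, 2])
  expect_lt(abs(obs - p_dis), 3 * sqrt(p_dis * (1 - p_dis) / 500))
})

test_that("ICC degrades monotonically in expectation as rater noise grows", {
  cfg <- synthetic_trial_config(list(list(
    name = "A", n_patients = 200,
    complications = data.frame(name = "c1", rate = 1, grade_min = 1L,
                               grade_typical = 3L, grade_max = 6L))),
    typical_mass = 0.5)
  rec <- generate_trial(cfg, seed = 60)
  mean_icc <- function(noise) {
    mean(vapply(1:6, function(s)
      icc(simulate_raters(rec, noise, seed = 60 + s))$value, numeric(1)))
  }
  vals <- vapply(c(0.05, 0.3, 0.6), mean_icc, numeric(1))
  expect_true(all(diff(vals) < 0))
})
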