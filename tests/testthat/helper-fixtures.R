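# Fixture arms built in code: the published 5-year complication tables of the
# two pivotal minimally invasive BPH trials (rates as printed, one decimal).

rezum_long <- function() {
  trial_arm("Rezum", 136, data.frame(
    name = c("medical retreatment", "surgical retreatment"),
    horizon = "long",
    rate_percent = c(11.0, 4.4),
    grade_typical = c(2L, 4L)))
}

urolift_long <- function() {
  trial_arm("Urolift", 140, data.frame(
    name = c("medical retreatment", "surgical retreatment", "surgical implant removal"),
    horizon = "long",
    rate_percent = c(10.7, 13.6, 9.3),
    grade_typical = c(2L, 4L, 4L)))
}

# Synthetic partial short-term tables: only the four complications whose rates
# are printed in the main text, with clinically assigned grades.
short_arms_synthetic <- function() {
  read_complication_table(
    system.file("extdata", "shortterm_synthetic.csv", package = "pmindex"),
    system.file("extdata", "arm_sizes.json", package = "pmindex"))
}

# Exhaustive minimum/maximum of |A_1 u ... u A_k| over all ways of placing
# counts c into n patients; independent oracle for union_bounds().
union_extremes_bruteforce <- function(n, counts) {
  subsets <- lapply(counts, function(c) utils::combn(n, c, simplify = FALSE))
  grid <- expand.grid(lapply(subsets, seq_along))
  sizes <- apply(grid, 1, function(idx) {
    length(unique(unlist(mapply(function(s, i) s[[i]], subsets, idx,
                                SIMPLIFY = FALSE))))
  })
  c(min = min(sizes), max = max(sizes))
}

# ICC(2,1) via R's ANOVA machinery: independent route through aov() mean
# squares rather than the package's closed-form sums.
icc21_aov <- function(mat) {
  df <- data.frame(y = as.vector(mat),
                   item = factor(rep(seq_len(nrow(mat)), ncol(mat))),
                   rater = factor(rep(seq_len(ncol(mat)), each = nrow(mat))))
  ms <- summary(stats::aov(y ~ item + rater, data = df))[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  n <- nrow(mat); k <- ncol(mat)
  (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
}
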