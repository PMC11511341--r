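test_that("Bland-Altman: identical methods, hand case, translation", {
  x <- c(1, 2, 3, 4)
  ba0 <- bland_altman(x, x)
  expect_equal(ba0$bias, 0)
  expect_equal(ba0$loa_lower, 0)
  expect_equal(ba0$loa_upper, 0)
  expect_equal(ba0$rmse, 0)

  # d = {-1, 0, 1}: bias 0, sd 1, LoA -/+ 1.96, t(0.975, 2) CIs
  ba <- bland_altman(c(1, 2, 3), c(0, 2, 4))
  expect_equal(ba$bias, 0)
  expect_equal(ba$sd_diff, 1)
  expect_equal(ba$loa_lower, -1.96)
  expect_equal(ba$loa_upper, 1.96)
  tq <- qt(0.975, 2)
  expect_equal(ba$bias_ci, c(-1, 1) * tq / sqrt(3), tolerance = 1e-12)
  expect_equal(ba$loa_upper_ci, 1.96 + c(-1, 1) * tq * sqrt(3 / 3),
               tolerance = 1e-12)

  set.seed(8)
  y <- x + rnorm(4)
  ba1 <- bland_altman(x, y)
  ba2 <- bland_altman(x, y + 0.25)
  expect_equal(ba2$bias, ba1$bias + 0.25)
  expect_equal(ba2$loa_lower, ba1$loa_lower + 0.25)
  expect_equal(ba2$loa_upper, ba1$loa_upper + 0.25)
  expect_error(bland_altman(1:2, 1:2), "n >= 3")
})

test_that("RMSE: hand case and the bias/sd decomposition identity", {
  expect_equal(rmse(c(0, 0), c(3, 4)), sqrt(25 / 2), tolerance = 1e-12)
  expect_equal(rmse(1:5, 1:5), 0)
  set.seed(9)
  x <- rnorm(12); y <- rnorm(12)
  d <- y - x
  n <- length(d)
  expect_equal(rmse(x, y)^2, mean(d)^2 + (n - 1) / n * sd(d)^2,
               tolerance = 1e-12)
})

test_that("agreement statistics are invariant under trial reordering", {
  set.seed(10)
  x <- rnorm(15); y <- x + rnorm(15, 0.1, 0.2)
  p <- sample(15)
  expect_equal(bland_altman(x, y)$bias, bland_altman(x[p], y[p])$bias)
  expect_equal(rmse(x, y), rmse(x[p], y[p]))
  expect_equal(pearson_r(x, y)$r, pearson_r(x[p], y[p])$r)
})

test_that("Pearson r: perfect fits, oracle formula, Fisher CI", {
  x <- 1:10
  expect_equal(pearson_r(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_r(x, -x)$r, -1)
  set.seed(12)
  y <- x + rnorm(10)
  pr <- pearson_r(x, y)
  # direct product-moment evaluation as the oracle
  r_direct <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pr$r, r_direct, tolerance = 1e-12)
  # CI matches cor.test (which also uses Fisher z with 1/sqrt(n-3))
  ct <- cor.test(x, y)
  expect_equal(pr$ci, as.numeric(ct$conf.int), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_error(pearson_r(rep(1, 5), 1:5), "zero variance")
  expect_equal(pearson_r(x, y)$label, r_magnitude_label(pr$r))
  expect_equal(r_magnitude_label(0.2), "negligible")
  expect_equal(r_magnitude_label(0.95), "very high")
})

test_that("ICC(3,1): perfect agreement, offset insensitivity, ANOVA oracle", {
  r1 <- c(9, 7, 5, 8, 6, 7.5)
  expect_equal(icc_3_1(cbind(r1, r1))$icc, 1)
  expect_equal(icc_3_1(cbind(r1, r1 + 2))$icc, 1, tolerance = 1e-12)
  # consistency form is insensitive to additive offsets only: a genuine
  # rescaling (b != 1) creates rater-target interaction and lowers the ICC
  expect_lt(icc_3_1(cbind(r1, 0.3 + 1.7 * r1))$icc, 1)

  # fixed 6 x 2 table against lm() mean squares as the oracle
  r2 <- c(9.1, 6.5, 5.4, 8.3, 5.9, 7.9)
  m <- cbind(r1, r2)
  long <- data.frame(y = as.vector(m),
                     target = factor(rep(1:6, 2)),
                     rater = factor(rep(1:2, each = 6)))
  an <- anova(lm(y ~ target + rater, data = long))
  bms <- an["target", "Mean Sq"]
  ems <- an["Residuals", "Mean Sq"]
  icc_oracle <- (bms - ems) / (bms + ems)
  got <- icc_3_1(m)
  expect_equal(got$icc, icc_oracle, tolerance = 1e-10)
  expect_equal(got$bms, bms, tolerance = 1e-10)
  expect_equal(got$ems, ems, tolerance = 1e-10)
  # Shrout-Fleiss style F-based CI brackets the estimate
  expect_lt(got$ci[1], got$icc)
  expect_gt(got$ci[2], got$icc)
  expect_error(icc_3_1(cbind(r1, c(NA, r2[-1]))), "incomplete")
})

make_ww_data <- function(n = 8, method_effect = 0, side_effect = 0,
                         inter = 0, seed = 20) {
  set.seed(seed)
  base <- rnorm(n, 10, 2)
  g <- expand.grid(case = paste0("t", seq_len(n)),
                   method = c("m1", "m2"), side = c("L", "R"),
                   stringsAsFactors = FALSE)
  g$value <- base[match(g$case, paste0("t", seq_len(n)))] +
    ifelse(g$method == "m2", method_effect, 0) +
    ifelse(g$side == "R", side_effect, 0) +
    ifelse(g$method == "m2" & g$side == "R", inter, 0) +
    rnorm(nrow(g), 0, 0.3)
  g
}

test_that("within-within ANOVA matches aov() with Error strata", {
  d <- make_ww_data(method_effect = 0.8)
  got <- rm_anova_2way(d)
  oracle <- summary(aov(value ~ method * side + Error(case / (method * side)),
                        data = transform(d, case = factor(case),
                                         method = factor(method),
                                         side = factor(side))))
  f_m <- oracle[["Error: case:method"]][[1]]["method", "F value"]
  f_s <- oracle[["Error: case:side"]][[1]]["side", "F value"]
  f_i <- oracle[["Error: case:method:side"]][[1]]["method:side", "F value"]
  expect_equal(got$table$F[1], f_m, tolerance = 1e-9)
  expect_equal(got$table$F[2], f_s, tolerance = 1e-9)
  expect_equal(got$table$F[3], f_i, tolerance = 1e-9)
  expect_equal(got$table$df, c(1, 1, 1))
  expect_equal(got$table$error_df, rep(nrow(d) / 4 - 1, 3))
  # a clear method effect, negligible side effect
  expect_gt(got$table$F[1], 10)
  expect_lt(got$table$F[2], 5)
})

test_that("ANOVA: null effects, SS conservation, case-label exchangeability", {
  # identical values in all four cells per case -> all F = 0
  g <- expand.grid(case = paste0("t", 1:6), method = c("m1", "m2"),
                   side = c("L", "R"), stringsAsFactors = FALSE)
  g$value <- as.numeric(factor(g$case))
  got0 <- rm_anova_2way(g)
  expect_equal(got0$table$F, c(0, 0, 0), tolerance = 1e-12)

  d <- make_ww_data(method_effect = 0.5, side_effect = 0.2, inter = 0.1)
  got <- rm_anova_2way(d)
  parts <- sum(got$table$ss) + sum(got$table$error_ss) + got$ss_case
  expect_equal(parts, got$ss_total, tolerance = 1e-9)

  # permuting case labels leaves all F unchanged
  perm <- setNames(sample(unique(d$case)), unique(d$case))
  d2 <- d; d2$case <- unname(perm[d$case])
  expect_equal(rm_anova_2way(d2)$table$F, got$table$F, tolerance = 1e-9)

  expect_error(rm_anova_2way(d[-1, ]), "unbalanced")
})

test_that("harmonic-SD Cohen's d: hand case, reductions, sign flip", {
  set.seed(30)
  g1 <- rnorm(20); g2 <- g1
  d0 <- cohens_d_harmonic(g1, g2)
  expect_equal(d0$d, 0)
  expect_equal(d0$magnitude, "trivial")

  # printed-summary case: means 0.243 vs 0.210, SDs 0.038 / 0.036
  cd <- cohens_d_from_summary(0.243, 0.038, 60, 0.210, 0.036, 60)
  expect_equal(cd$hsd, 2 * 0.038 * 0.036 / (0.038 + 0.036), tolerance = 1e-12)
  expect_equal(round(cd$hsd, 6), 0.036973)
  expect_equal(cd$d, (0.210 - 0.243) / cd$hsd, tolerance = 1e-12)
  expect_equal(round(cd$d, 4), -0.8925)
  expect_equal(cd$magnitude, "large")

  # equal SDs: harmonic mean reduces to the common SD
  cd2 <- cohens_d_from_summary(1, 0.5, 10, 1.4, 0.5, 10)
  expect_equal(cd2$d, 0.4 / 0.5, tolerance = 1e-12)

  # sign flips exactly under group exchange
  g2 <- rnorm(20, 0.6)
  a <- cohens_d_harmonic(g1, g2)
  b <- cohens_d_harmonic(g2, g1)
  expect_equal(a$d, -b$d, tolerance = 1e-12)
  expect_error(cohens_d_harmonic(rep(1, 5), g2), "positive")
})

test_that("clearness rule: unclear iff the CI spans -0.2 and +0.2", {
  # tiny effect, tiny n -> wide CI spanning both substantial signs
  small_n <- cohens_d_from_summary(0, 1, 4, 0.01, 1, 4)
  expect_equal(small_n$clearness, "unclear")
  # strong effect, large n -> clear
  big <- cohens_d_from_summary(0, 1, 200, 1, 1, 200)
  expect_equal(big$clearness, "clear")
  expect_equal(d_magnitude_label(1.5), "very large")
  expect_equal(d_magnitude_label(0.3), "small")
})

test_that("time normalisation: constants, ramps, grid coincidence", {
  expect_equal(time_normalize(rep(2, 7), 101), rep(2, 101))
  ramp <- seq(0, 1, length.out = 50)
  tn <- time_normalize(ramp, 101)
  expect_equal(tn, seq(0, 1, length.out = 101), tolerance = 1e-12)
  x <- rnorm(101)
  expect_equal(time_normalize(x, 101), x)  # identity on a matching grid
  expect_error(time_normalize(1, 101), "length >= 2")
})

test_that("curve-level agreement: identity, constant offset, CI bands", {
  set.seed(40)
  curves <- t(replicate(12, sin(seq(0, pi, length.out = 101)) +
                          rnorm(101, 0, 0.01)))
  ag0 <- trajectory_agreement(curves, curves)
  expect_equal(ag0$pooled$bias, 0)
  expect_equal(ag0$pooled$loa_lower, 0)
  expect_equal(ag0$r$r, 1)

  ag <- trajectory_agreement(curves, curves + 0.02)
  expect_equal(ag$pooled$bias, 0.02, tolerance = 1e-12)
  # bands: mean curve inside its own CI band
  st <- ag$stations
  expect_true(all(st$lo_x <= st$mean_x & st$mean_x <= st$hi_x))
  expect_error(trajectory_agreement(curves, curves[, 1:50]), "station")
})
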