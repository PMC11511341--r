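#' Bland--Altman agreement between two methods
#'
#' For paired measurements `x` (reference method) and `y` (comparison
#' method), differences `d = y - x` are summarised by their mean (bias) and
#' `bias +/- 1.96 sd(d)` (limits of agreement, LoA; sample SD on `n - 1`
#' df). Confidence intervals: bias CI uses `t(0.975, n-1) * sd / sqrt(n)`;
#' each LoA CI uses the approximation `SE = sd * sqrt(3 / n)` with the same
#' t quantile.
#'
#' @param x,y Equal-length numeric vectors (n >= 3), no missing values.
#' @param conf Confidence level (default 0.95).
#' @return An object of class `bland_altman`: `bias`, `bias_ci`,
#'   `loa_lower`, `loa_lower_ci`, `loa_upper`, `loa_upper_ci`, `sd_diff`,
#'   `rmse`, `n`.
#' @export
#' @examples
#' bland_altman(c(1, 2, 3), c(0, 2, 4))  # d = {-1, 0, 1}
bland_altman <- function(x, y, conf = 0.95) {
  stopifnot(length(x) == length(y))
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed", call. = FALSE)
  n <- length(x)
  if (n < 3) stop("need n >= 3 pairs", call. = FALSE)
  d <- y - x
  bias <- mean(d)
  s <- stats::sd(d)
  tq <- stats::qt(1 - (1 - conf) / 2, df = n - 1)
  se_bias <- s / sqrt(n)
  se_loa <- s * sqrt(3 / n)
  z <- 1.96
  structure(list(
    bias = bias,
    bias_ci = bias + c(-1, 1) * tq * se_bias,
    loa_lower = bias - z * s,
    loa_lower_ci = bias - z * s + c(-1, 1) * tq * se_loa,
    loa_upper = bias + z * s,
    loa_upper_ci = bias + z * s + c(-1, 1) * tq * se_loa,
    sd_diff = s,
    rmse = rmse(x, y),
    n = n
  ), class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  ci <- function(v) sprintf("(%.4f to %.4f)", v[1], v[2])
  cat(sprintf("Bland-Altman (n = %d)\n", x$n))
  cat(sprintf("  bias      %8.4f %s\n", x$bias, ci(x$bias_ci)))
  cat(sprintf("  LoA lower %8.4f %s\n", x$loa_lower, ci(x$loa_lower_ci)))
  cat(sprintf("  LoA upper %8.4f %s\n", x$loa_upper, ci(x$loa_upper_ci)))
  cat(sprintf("  RMSE      %8.4f\n", x$rmse))
  invisible(x)
}

#' Root mean square error between paired measurements
#'
#' @param x,y Equal-length numeric vectors.
#' @return `sqrt(mean((y - x)^2))`.
#' @export
rmse <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (!length(x)) stop("empty input", call. = FALSE)
  sqrt(mean((y - x)^2))
}

#' Pearson correlation with Fisher-z confidence interval
#'
#' Sample product-moment correlation, a 95% CI via the Fisher z transform
#' with `SE = 1 / sqrt(n - 3)`, and the conventional magnitude label
#' (negligible < 0.3, low 0.3--0.5, moderate 0.5--0.7, high 0.7--0.9, very
#' high 0.9--1.0 on `|r|`).
#'
#' @param x,y Equal-length numeric vectors, n >= 4, non-degenerate.
#' @param conf Confidence level (default 0.95).
#' @return An object of class `pearson_r`: `r`, `ci`, `label`, `n`.
#' @export
pearson_r <- function(x, y, conf = 0.95) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 4) stop("need n >= 4 pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: zero variance", call. = FALSE)
  r <- stats::cor(x, y)
  zq <- stats::qnorm(1 - (1 - conf) / 2)
  zr <- atanh(min(1 - 1e-15, max(-1 + 1e-15, r)))
  ci <- tanh(zr + c(-1, 1) * zq / sqrt(n - 3))
  structure(list(r = r, ci = ci, label = r_magnitude_label(r), n = n),
            class = "pearson_r")
}

#' Correlation magnitude label
#'
#' @param r Correlation coefficient.
#' @return One of `"negligible"`, `"low"`, `"moderate"`, `"high"`,
#'   `"very high"`.
#' @export
r_magnitude_label <- function(r) {
  a <- abs(r)
  if (a < 0.3) "negligible"
  else if (a < 0.5) "low"
  else if (a < 0.7) "moderate"
  else if (a < 0.9) "high"
  else "very high"
}

#' @export
print.pearson_r <- function(x, ...) {
  cat(sprintf("r = %.4f (%.4f to %.4f), %s (n = %d)\n",
              x$r, x$ci[1], x$ci[2], x$label, x$n))
  invisible(x)
}

#' ICC(3,1): two-way mixed, consistency, single measures
#'
#' From the two-way (targets x raters) ANOVA mean squares,
#' `ICC = (BMS - EMS) / (BMS + (k - 1) EMS)` with BMS the between-targets
#' and EMS the residual mean square. The confidence interval follows the
#' F-distribution bounds on `BMS / EMS`. Insensitive to fixed offsets
#' between raters (consistency definition).
#'
#' @param ratings Numeric matrix or data frame, `n` targets x `k` raters
#'   (complete; n >= 3).
#' @param conf Confidence level (default 0.95).
#' @return An object of class `icc`: `icc`, `ci`, `df1`, `df2`, and the
#'   mean squares `bms`, `ems`, `jms`.
#' @export
icc_3_1 <- function(ratings, conf = 0.95) {
  m <- as.matrix(ratings)
  if (anyNA(m)) stop("incomplete ratings table", call. = FALSE)
  n <- nrow(m); k <- ncol(m)
  if (n < 3 || k < 2) stop("need >= 3 targets and >= 2 raters", call. = FALSE)
  grand <- mean(m)
  row_m <- rowMeans(m)
  col_m <- colMeans(m)
  bms <- k * sum((row_m - grand)^2) / (n - 1)
  jms <- n * sum((col_m - grand)^2) / (k - 1)
  resid <- m - outer(row_m, rep(1, k)) - outer(rep(1, n), col_m) + grand
  ems <- sum(resid^2) / ((n - 1) * (k - 1))
  icc <- (bms - ems) / (bms + (k - 1) * ems)
  df1 <- n - 1; df2 <- (n - 1) * (k - 1)
  alpha <- 1 - conf
  if (ems > 0) {
    fobs <- bms / ems
    fl <- fobs / stats::qf(1 - alpha / 2, df1, df2)
    fu <- fobs * stats::qf(1 - alpha / 2, df2, df1)
    ci <- c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
  } else ci <- c(1, 1)
  structure(list(icc = icc, ci = ci, df1 = df1, df2 = df2,
                 bms = bms, jms = jms, ems = ems),
            class = "icc")
}

#' @export
print.icc <- function(x, ...) {
  cat(sprintf("ICC(3,1) = %.4f (%.4f to %.4f), df = (%d, %d)\n",
              x$icc, x$ci[1], x$ci[2], x$df1, x$df2))
  invisible(x)
}

#' Two-way repeated-measures (within-within) ANOVA
#'
#' Fully-within two-factor design with one observation per cell: every case
#' (blocking unit, e.g. a trial) is observed in all four `method x side`
#' cells. Each within factor and the interaction is tested against its own
#' case-by-factor interaction error term.
#'
#' @param data Data frame with columns `value`, `case`, and the two factor
#'   columns named by `factors`.
#' @param factors Character vector of the two within-factor column names
#'   (default `c("method", "side")`).
#' @return An object of class `rm_anova_2way`: a data frame `table` with
#'   rows for the two factors and their interaction (`ss`, `df`, `ms`,
#'   `error_ss`, `error_df`, `error_ms`, `F`, `p`) plus `ss_total` and
#'   `ss_case`.
#' @export
rm_anova_2way <- function(data, factors = c("method", "side")) {
  stopifnot(is.data.frame(data), all(c("value", "case", factors) %in%
                                       names(data)))
  fA <- factor(data[[factors[1]]])
  fB <- factor(data[[factors[2]]])
  case <- factor(data$case)
  y <- data$value
  if (anyNA(y)) stop("missing values not allowed", call. = FALSE)
  a <- nlevels(fA); b <- nlevels(fB); n <- nlevels(case)
  tab <- table(case, fA, fB)
  if (any(tab != 1))
    stop("unbalanced design: every case must be observed exactly once in ",
         "each cell", call. = FALSE)
  grand <- mean(y)
  cm <- function(f) tapply(y, f, mean)
  ss <- function(means, mult) mult * sum((means - grand)^2)

  ss_A <- ss(cm(fA), b * n)
  ss_B <- ss(cm(fB), a * n)
  ss_case <- ss(cm(case), a * b)
  inter_resid <- function(mrow, rowm, colm) {
    sweep(sweep(mrow, 1, rowm), 2, colm) + grand
  }
  m_AB <- tapply(y, list(fA, fB), mean)
  ss_AB <- n * sum(inter_resid(m_AB, cm(fA), cm(fB))^2)
  m_Ac <- tapply(y, list(fA, case), mean)
  ss_Ac <- b * sum(inter_resid(m_Ac, cm(fA), cm(case))^2)
  m_Bc <- tapply(y, list(fB, case), mean)
  ss_Bc <- a * sum(inter_resid(m_Bc, cm(fB), cm(case))^2)
  ss_tot <- sum((y - grand)^2)
  ss_ABc <- ss_tot - ss_A - ss_B - ss_case - ss_AB - ss_Ac - ss_Bc

  dfs <- c(A = (a - 1), B = (b - 1), AB = (a - 1) * (b - 1))
  err_ss <- c(A = ss_Ac, B = ss_Bc, AB = ss_ABc)
  err_df <- c(A = (a - 1) * (n - 1), B = (b - 1) * (n - 1),
              AB = (a - 1) * (b - 1) * (n - 1))
  eff_ss <- c(A = ss_A, B = ss_B, AB = ss_AB)
  ms <- eff_ss / dfs
  err_ms <- err_ss / err_df
  Fv <- ifelse(ms == 0, 0, ms / err_ms)  # no effect variance -> F = 0
  p <- stats::pf(Fv, dfs, err_df, lower.tail = FALSE)
  rn <- c(factors, paste(factors, collapse = ":"))
  structure(list(
    table = data.frame(effect = rn, ss = eff_ss, df = dfs, ms = ms,
                       error_ss = err_ss, error_df = err_df,
                       error_ms = err_ms, F = Fv, p = p,
                       row.names = NULL),
    ss_total = ss_tot, ss_case = ss_case, n_cases = n
  ), class = "rm_anova_2way")
}

#' @export
print.rm_anova_2way <- function(x, ...) {
  cat(sprintf("Two-way within-within ANOVA (%d cases)\n", x$n_cases))
  tb <- x$table
  for (r in seq_len(nrow(tb)))
    cat(sprintf("  %-14s F(%d, %d) = %9.3f, p = %.4g\n",
                tb$effect[r], tb$df[r], tb$error_df[r], tb$F[r], tb$p[r]))
  invisible(x)
}

#' Cohen's d standardised by the harmonic mean of the SDs
#'
#' `d = (mean(g2) - mean(g1)) / hsd` with
#' `hsd = 2 s1 s2 / (s1 + s2)`. The 95% CI uses the normal approximation
#' `SE = sqrt((n1 + n2) / (n1 n2) + d^2 / (2 (n1 + n2)))`. Magnitude labels:
#' trivial < 0.2, small 0.2--0.5, moderate 0.5--0.8, large 0.8--1.3, very
#' large > 1.3 (on `|d|`). The effect is `"unclear"` when the CI spans both
#' substantial positive and negative values (+0.20 and -0.20), `"clear"`
#' otherwise.
#'
#' @param g1,g2 Numeric vectors (each n >= 2, positive SD).
#' @return An object of class `cohens_d`: `d`, `ci`, `magnitude`,
#'   `clearness`, `hsd`, `n1`, `n2`.
#' @export
cohens_d_harmonic <- function(g1, g2) {
  n1 <- length(g1); n2 <- length(g2)
  if (n1 < 2 || n2 < 2) stop("each group needs n >= 2", call. = FALSE)
  cohens_d_from_summary(mean(g1), stats::sd(g1), n1,
                        mean(g2), stats::sd(g2), n2)
}

#' Cohen's d (harmonic-SD form) from summary statistics
#'
#' Same statistic as [cohens_d_harmonic()], computed from printed group
#' means, SDs and sizes, so effect sizes can be recomputed from published
#' summary tables.
#'
#' @param m1,s1,n1 Mean, SD, and size of group 1 (reference).
#' @param m2,s2,n2 Mean, SD, and size of group 2 (comparison).
#' @param threshold Substantial-effect threshold for the clearness rule
#'   (default 0.20).
#' @return An object of class `cohens_d`; see [cohens_d_harmonic()].
#' @export
#' @examples
#' # propulsive-phase example: marker 0.243 (0.038) vs markerless 0.210 (0.036)
#' cohens_d_from_summary(0.243, 0.038, 60, 0.210, 0.036, 60)
cohens_d_from_summary <- function(m1, s1, n1, m2, s2, n2, threshold = 0.20) {
  if (s1 <= 0 || s2 <= 0) stop("group SDs must be positive", call. = FALSE)
  hsd <- 2 * s1 * s2 / (s1 + s2)
  d <- (m2 - m1) / hsd
  se <- sqrt((n1 + n2) / (n1 * n2) + d^2 / (2 * (n1 + n2)))
  ci <- d + c(-1, 1) * 1.96 * se
  structure(list(
    d = d, ci = ci,
    magnitude = d_magnitude_label(d),
    clearness = if (ci[1] < -threshold && ci[2] > threshold) "unclear"
                else "clear",
    hsd = hsd, n1 = n1, n2 = n2
  ), class = "cohens_d")
}

#' Effect-size magnitude label
#'
#' @param d Cohen's d.
#' @return One of `"trivial"`, `"small"`, `"moderate"`, `"large"`,
#'   `"very large"`.
#' @export
d_magnitude_label <- function(d) {
  a <- abs(d)
  if (a < 0.2) "trivial"
  else if (a < 0.5) "small"
  else if (a < 0.8) "moderate"
  else if (a < 1.3) "large"
  else "very large"
}

#' @export
print.cohens_d <- function(x, ...) {
  cat(sprintf("d = %.4f (%.4f to %.4f), %s, %s\n",
              x$d, x$ci[1], x$ci[2], x$magnitude, x$clearness))
  invisible(x)
}

#' Time-normalise a series to a fixed station grid
#'
#' Linear interpolation onto `n_points` equally spaced stations across 0%
#' to 100% of the series duration.
#'
#' @param series Numeric vector, length >= 2.
#' @param n_points Number of stations (default 101).
#' @return Numeric vector of length `n_points`.
#' @export
time_normalize <- function(series, n_points = 101) {
  x <- as.numeric(series)
  n <- length(x)
  if (n < 2 || n_points < 2)
    stop("need input length >= 2 and n_points >= 2", call. = FALSE)
  stats::approx(seq(0, 1, length.out = n), x,
                xout = seq(0, 1, length.out = n_points))$y
}

#' Station-wise and pooled agreement between two sets of curves
#'
#' Inputs are matrices of time-normalised curves (one row per trial, one
#' column per station; both methods on the same station grid). Returns the
#' per-station across-trial mean and 95% CI band for each method, plus
#' pooled Bland--Altman/RMSE/r statistics over all stations of all trials
#' concatenated.
#'
#' @param curves_x,curves_y Trial-by-station matrices for methods 1 and 2.
#' @param conf Confidence level for the station bands (default 0.95).
#' @return An object of class `trajectory_agreement`: `stations` data frame
#'   (`station_pct`, `mean_x`, `lo_x`, `hi_x`, `mean_y`, `lo_y`, `hi_y`),
#'   `pooled` ([bland_altman()]), `r` ([pearson_r()]).
#' @export
trajectory_agreement <- function(curves_x, curves_y, conf = 0.95) {
  X <- as.matrix(curves_x); Y <- as.matrix(curves_y)
  if (ncol(X) != ncol(Y))
    stop("mismatched station counts", call. = FALSE)
  band <- function(M) {
    n <- nrow(M)
    mu <- colMeans(M)
    se <- apply(M, 2, stats::sd) / sqrt(n)
    tq <- if (n > 1) stats::qt(1 - (1 - conf) / 2, n - 1) else 0
    list(mean = mu, lo = mu - tq * se, hi = mu + tq * se)
  }
  bx <- band(X); by <- band(Y)
  st <- data.frame(station_pct = seq(0, 100, length.out = ncol(X)),
                   mean_x = bx$mean, lo_x = bx$lo, hi_x = bx$hi,
                   mean_y = by$mean, lo_y = by$lo, hi_y = by$hi)
  structure(list(stations = st,
                 pooled = bland_altman(as.vector(X), as.vector(Y)),
                 r = pearson_r(as.vector(X), as.vector(Y))),
            class = "trajectory_agreement")
}

#' @export
print.trajectory_agreement <- function(x, ...) {
  cat(sprintf("<trajectory_agreement> %d stations\n", nrow(x$stations)))
  cat("pooled: "); print(x$pooled)
  print(x$r)
  invisible(x)
}
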