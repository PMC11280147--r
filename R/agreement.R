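paired_vectors <- function(data, x, y, min_n = 2L) {
  x <- rlang::eval_tidy(rlang::enquo(x), data)
  y <- rlang::eval_tidy(rlang::enquo(y), data)
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("paired samples must have no missing values",
                                 call. = FALSE)
  if (length(x) < min_n) {
    stop("need at least ", min_n, " pairs", call. = FALSE)
  }
  list(x = as.numeric(x), y = as.numeric(y))
}

#' Normality-gated paired comparison
#'
#' Tests whether two paired measurement sets differ: Shapiro-Wilk is run on
#' the paired differences; if its p-value exceeds `alpha` the differences are
#' treated as Gaussian and a two-tailed paired t-test is used, otherwise a
#' Wilcoxon signed-rank test. The test that fired is reported alongside its
#' p-value.
#'
#' @param data A data frame.
#' @param x,y Columns (unquoted) holding the paired measurements.
#' @param alpha Normality-gate threshold on the Shapiro-Wilk p-value.
#'   Default 0.05.
#' @return A one-row tibble: `test_used`, `p_value`, `shapiro_p`, `n`.
#' @export
#' @examples
#' paired_compare(load_patient_table("bundled"), q_svc, qp_cath)
paired_compare <- function(data, x, y, alpha = 0.05) {
  v <- paired_vectors(data, {{ x }}, {{ y }}, min_n = 3L)
  d <- v$x - v$y
  if (stats::sd(d) == 0) {
    stop("degenerate paired sample: all differences identical", call. = FALSE)
  }
  sw <- stats::shapiro.test(d)
  if (sw$p.value > alpha) {
    tt <- stats::t.test(v$x, v$y, paired = TRUE)
    test_used <- "paired t-test"
    p <- tt$p.value
  } else {
    wt <- stats::wilcox.test(v$x, v$y, paired = TRUE, exact = FALSE)
    test_used <- "wilcoxon signed-rank"
    p <- wt$p.value
  }
  tibble::tibble(test_used = test_used, p_value = p,
                 shapiro_p = sw$p.value, n = length(d))
}

#' Intraclass correlation coefficient, ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-measure ICC between two
#' paired measurement sets, with the F-distribution-based 95% confidence
#' interval of Shrout & Fleiss. Measurements are rows of a subjects-by-raters
#' mean-squares decomposition (MSR between subjects, MSC between raters, MSE
#' residual):
#' \deqn{ICC = \frac{MSR - MSE}{MSR + (k-1)MSE + \frac{k}{n}(MSC - MSE)}}
#'
#' @inheritParams paired_compare
#' @param conf_level Confidence level for the interval. Default 0.95.
#' @return A one-row tibble: `icc`, `ci_low`, `ci_high`, `n`.
#' @export
#' @examples
#' icc_agreement(load_patient_table("bundled"), q_svc, qp_cath)
icc_agreement <- function(data, x, y, conf_level = 0.95) {
  v <- paired_vectors(data, {{ x }}, {{ y }}, min_n = 3L)
  m <- cbind(v$x, v$y)
  n <- nrow(m)
  k <- 2L
  gm <- mean(m)
  rowm <- rowMeans(m)
  colm <- colMeans(m)
  ssr <- k * sum((rowm - gm)^2)
  ssc <- n * sum((colm - gm)^2)
  sse <- sum((m - gm)^2) - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  if (ssr == 0) {
    stop("undefined ICC: no between-subject variance", call. = FALSE)
  }
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)

  alpha <- 1 - conf_level
  if (mse == 0 && msc == 0) {
    ci <- c(1, 1) # perfect agreement, interval degenerates
  } else {
    a <- k * icc / (n * (1 - icc))
    b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
    v_df <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    f_l <- stats::qf(1 - alpha / 2, n - 1, v_df)
    f_u <- stats::qf(1 - alpha / 2, v_df, n - 1)
    lo <- n * (msr - f_l * mse) /
      (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
    hi <- n * (f_u * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * f_u * msr)
    ci <- c(lo, hi)
  }
  tibble::tibble(icc = icc, ci_low = ci[1], ci_high = ci[2], n = n)
}

#' Bland-Altman agreement analysis
#'
#' Bias (mean of the pairwise differences `x - y`) and 95% limits of
#' agreement `bias +/- 1.96 * SD(differences)` with the sample (n - 1) SD.
#'
#' @inheritParams paired_compare
#' @return A one-row tibble: `bias`, `sd_diff`, `loa_low`, `loa_high`, `n`.
#' @export
bland_altman <- function(data, x, y) {
  v <- paired_vectors(data, {{ x }}, {{ y }}, min_n = 2L)
  d <- v$x - v$y
  bias <- mean(d)
  s <- stats::sd(d)
  tibble::tibble(bias = bias, sd_diff = s,
                 loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
                 n = length(d))
}

#' Percent difference between paired measurements
#'
#' Per pair, `100 * (ref - other) / ref`; the mean and sample SD across pairs
#' are reported. The reference must be nonzero for every pair.
#'
#' @param data A data frame.
#' @param ref,other Columns (unquoted): the reference measurement and the one
#'   compared against it.
#' @return A one-row tibble: `mean_pct`, `sd_pct`, `n`.
#' @export
percent_difference <- function(data, ref, other) {
  v <- paired_vectors(data, {{ ref }}, {{ other }}, min_n = 2L)
  zero <- which(v$x == 0)
  if (length(zero)) {
    stop("zero reference value in pair ", zero[1L],
         ": percent difference undefined", call. = FALSE)
  }
  pct <- 100 * (v$x - v$y) / v$x
  tibble::tibble(mean_pct = mean(pct), sd_pct = stats::sd(pct), n = length(pct))
}

#' Full method-agreement report for two paired measurement sets
#'
#' One comparison-table row: group means with SD, mean and percent
#' differences, ICC(2,1) with 95% CI, Bland-Altman bias and limits of
#' agreement, and the normality-gated paired-test p-value.
#'
#' @inheritParams paired_compare
#' @param label Name for the comparison row.
#' @return A one-row tibble.
#' @export
#' @examples
#' agreement_report(load_patient_table("bundled"), q_svc, qp_cath,
#'                  label = "CMR vs CATH Qp")
agreement_report <- function(data, x, y, label = "x vs y") {
  v <- paired_vectors(data, {{ x }}, {{ y }}, min_n = 3L)
  d <- tibble::tibble(x = v$x, y = v$y)
  cmp <- paired_compare(d, x, y)
  ic <- icc_agreement(d, x, y)
  ba <- bland_altman(d, x, y)
  pct <- percent_difference(d, x, y)
  tibble::tibble(
    comparison = label, n = nrow(d),
    mean_x = mean(d$x), sd_x = stats::sd(d$x),
    mean_y = mean(d$y), sd_y = stats::sd(d$y),
    diff_mean = ba$bias, diff_sd = ba$sd_diff,
    pct_diff_mean = pct$mean_pct, pct_diff_sd = pct$sd_pct,
    icc = ic$icc, icc_ci_low = ic$ci_low, icc_ci_high = ic$ci_high,
    loa_low = ba$loa_low, loa_high = ba$loa_high,
    test_used = cmp$test_used, p_value = cmp$p_value
  )
}

#' Bland-Altman plot
#'
#' @inheritParams paired_compare
#' @return A ggplot.
#' @export
plot_bland_altman <- function(data, x, y) {
  v <- paired_vectors(data, {{ x }}, {{ y }}, min_n = 2L)
  ba <- bland_altman(tibble::tibble(x = v$x, y = v$y), x, y)
  d <- tibble::tibble(avg = (v$x + v$y) / 2, diff = v$x - v$y)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$avg, y = .data$diff)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = ba$bias, linetype = "solid") +
    ggplot2::geom_hline(yintercept = c(ba$loa_low, ba$loa_high),
                        linetype = "dashed") +
    ggplot2::labs(x = "pair mean", y = "pair difference")
}
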