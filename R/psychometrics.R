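#' @title Validation statistics
#' @description Pearson construct validity, Cronbach's alpha internal
#'   consistency, test-retest reliability (Pearson and an absolute-agreement
#'   single-measures intraclass coefficient), and independent-samples t-tests.
#' @name psychometrics
NULL

check_paired <- function(x, y, min_n = 3L) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y))
    stop("series must be paired (equal length)")
  keep <- !(is.na(x) | is.na(y))
  x <- x[keep]; y <- y[keep]
  if (length(x) < min_n)
    stop("need at least ", min_n, " complete pairs, have ", length(x))
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant series: correlation is undefined")
  list(x = x, y = y, n = length(x))
}

#' Pearson product-moment correlation with two-sided p-value
#'
#' The p-value comes from the t transform with n - 2 degrees of freedom.
#' Pairs with a missing value in either series are dropped (pairwise
#' deletion).
#'
#' @param x,y Paired numeric vectors.
#' @return List with `r`, `p_value`, `n`.
#' @export
pearson <- function(x, y) {
  p <- check_paired(x, y)
  ct <- stats::cor.test(p$x, p$y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = p$n)
}

#' Construct-validity flag for a correlation
#'
#' Good construct validity is indicated by correlations above 0.4 but below
#' 0.9 against criteria expected to relate to the construct.
#'
#' @param r Correlation in \[-1, 1\].
#' @return `"good"`, `"too_low"` or `"too_high"`.
#' @export
construct_validity_flag <- function(r) {
  if (is.na(r) || r < -1 || r > 1) stop("r must lie in [-1, 1]")
  if (r <= 0.4) "too_low" else if (r >= 0.9) "too_high" else "good"
}

#' Cronbach's alpha
#'
#' `alpha = k/(k-1) * (1 - sum(item variances) / variance(total score))`
#' with n-1 sample variances throughout.
#'
#' @param m Respondents x items numeric matrix (or data.frame), k >= 2 items.
#' @return Alpha coefficient (<= 1; can be negative).
#' @export
cronbach_alpha <- function(m) {
  m <- as.matrix(m)
  if (anyNA(m)) stop("item score matrix has missing cells")
  k <- ncol(m)
  if (k < 2L) stop("need at least 2 items")
  if (nrow(m) < 2L) stop("need at least 2 respondents")
  total_var <- stats::var(rowSums(m))
  if (total_var == 0) stop("total score variance is zero: alpha is undefined")
  k / (k - 1) * (1 - sum(apply(m, 2L, stats::var)) / total_var)
}

#' Intraclass correlation, two-way random effects, absolute agreement,
#' single measures
#'
#' ICC(A,1): `(MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))` from the
#' two-way ANOVA mean squares of an n-subjects x k-measurements layout.
#' Absolute agreement penalizes systematic shifts between measurements, so a
#' constant offset between test and retest lowers the ICC but not the
#' Pearson correlation.
#'
#' @param m Subjects x measurements numeric matrix (k >= 2 columns).
#' @return ICC coefficient.
#' @export
icc_agreement <- function(m) {
  m <- as.matrix(m)
  if (anyNA(m)) stop("ICC input has missing cells")
  n <- nrow(m); k <- ncol(m)
  if (n < 3L) stop("need at least 3 subjects")
  if (k < 2L) stop("need at least 2 measurements per subject")
  grand <- mean(m)
  row_means <- rowMeans(m)
  col_means <- colMeans(m)
  ssr <- k * sum((row_means - grand)^2)
  ssc <- n * sum((col_means - grand)^2)
  sst <- sum((m - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + (k / n) * (msc - mse)
  if (denom == 0) stop("degenerate ICC: zero denominator")
  (msr - mse) / denom
}

#' Test-retest reliability
#'
#' Reports the Pearson coefficient (the headline statistic) and the
#' absolute-agreement single-measures intraclass coefficient side by side;
#' the reliability flag compares the chosen coefficient with the 0.7 cut-off.
#'
#' @param scores_t1,scores_t2 Paired score vectors (one value per respondent,
#'   same order).
#' @param cutoff Reliability cut-off, default 0.7.
#' @return List with `pearson_r`, `p_value`, `icc`, `n`, `reliable`
#'   (Pearson vs cut-off) and `reliable_icc`.
#' @export
test_retest <- function(scores_t1, scores_t2, cutoff = 0.7) {
  p <- check_paired(scores_t1, scores_t2)
  pe <- pearson(p$x, p$y)
  icc <- icc_agreement(cbind(p$x, p$y))
  list(pearson_r = pe$r, p_value = pe$p_value, icc = icc, n = p$n,
       cutoff = cutoff,
       reliable = pe$r >= cutoff,
       reliable_icc = icc >= cutoff)
}

#' Independent-samples t-test
#'
#' Two-sided pooled-variance test by default (matching the classical SPSS
#' default); Welch's unequal-variance correction available via `welch`.
#'
#' @param a,b Numeric vectors, each of size >= 2.
#' @param welch Use the Welch correction (default `FALSE`).
#' @param alpha Significance level for the flag, default 0.05.
#' @return List with `t`, `df`, `p_value`, `means`, `significant`.
#' @export
independent_t_test <- function(a, b, welch = FALSE, alpha = 0.05) {
  a <- as.numeric(a)[!is.na(a)]
  b <- as.numeric(b)[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 observations")
  tt <- stats::t.test(a, b, var.equal = !welch, alternative = "two.sided")
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value,
       means = c(mean(a), mean(b)),
       significant = tt$p.value < alpha)
}
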