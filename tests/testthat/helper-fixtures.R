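# shared fixtures and independent oracles

bundled <- bundled_iflt()

# uniform random response table over all options of every item
random_responses <- function(inst, n, seed) {
  set.seed(seed)
  out <- data.frame(respondent_id = sprintf("s%05d", seq_len(n)),
                    stringsAsFactors = FALSE)
  for (it in inst$items)
    out[[it$item_id]] <- sample(iflt:::option_labels(it), n, replace = TRUE)
  out
}

response_from_table <- function(responses, row) {
  ans <- as.list(responses[row, setdiff(names(responses), "respondent_id")])
  response(ans, respondent_id = responses$respondent_id[row])
}

# --- independent direct-formula oracles --------------------------------------

oracle_pearson <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  r <- (n * sum(x * y) - sx * sy) /
    sqrt((n * sum(x^2) - sx^2) * (n * sum(y^2) - sy^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p_value = 2 * stats::pt(-abs(t), n - 2))
}

oracle_alpha <- function(m) {
  # covariance-matrix route: total variance = sum of the covariance matrix
  S <- stats::cov(m)
  k <- ncol(m)
  k / (k - 1) * (1 - sum(diag(S)) / sum(S))
}

oracle_icc_a1 <- function(m) {
  # two-way ANOVA mean squares via stats::aov, then the ICC(A,1) formula
  n <- nrow(m); k <- ncol(m)
  d <- data.frame(y = as.vector(m),
                  subj = factor(rep(seq_len(n), times = k)),
                  meas = factor(rep(seq_len(k), each = n)))
  av <- summary(stats::aov(y ~ subj + meas, data = d))[[1]]
  msr <- av["subj", "Mean Sq"]
  msc <- av["meas", "Mean Sq"]
  mse <- av["Residuals", "Mean Sq"]
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

oracle_pooled_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = t, df = na + nb - 2,
       p_value = 2 * stats::pt(-abs(t), na + nb - 2))
}
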