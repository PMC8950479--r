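# Independent brute-force oracles used to cross-check the in-package
# implementations. These deliberately avoid the code paths they verify.

# closed-form simple linear regression via the textbook normal equations
ols_oracle <- function(x, y) {
  sx <- sum(x); sy <- sum(y); n <- length(x)
  slope <- (n * sum(x * y) - sx * sy) / (n * sum(x^2) - sx^2)
  intercept <- (sy - slope * sx) / n
  list(slope = slope, intercept = intercept)
}

# LDA discriminant scores by explicit Mahalanobis arithmetic, loops only
lda_oracle_scores <- function(x, means, sigma, priors) {
  si <- solve(sigma)
  t(apply(x, 1, function(row) {
    vapply(seq_len(nrow(means)), function(k) {
      mu <- means[k, ]
      sum(row * (si %*% mu)) - 0.5 * sum(mu * (si %*% mu)) + log(priors[k])
    }, numeric(1))
  }))
}

# factorial coefficients as classical contrast averages over the corners
contrast_oracle <- function(x1, x2, y) {
  corner <- x1 != 0 & x2 != 0
  c(b0 = mean(y),
    b1 = sum(y[corner] * x1[corner]) / 4,
    b2 = sum(y[corner] * x2[corner]) / 4,
    b12 = sum(y[corner] * x1[corner] * x2[corner]) / 4)
}

# sample skewness (moment estimator)
skewness_oracle <- function(x) {
  m <- mean(x)
  mean((x - m)^3) / mean((x - m)^2)^1.5
}

# small censored table built by hand for reader/summary tests
toy_panel <- function() {
  element_panel(element = c("Mn", "Hg", "Cd"),
                isotope = c(55L, 202L, 111L),
                mode = c("KED", "standard", "KED"),
                lod = c(8, 6, 0.3), loq = c(27, 20, 1.0),
                cal_low = c(0.1, 0.1, 0.01), cal_high = c(500, 50, 50))
}
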