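# shared fixtures and independent oracles for the test suite

# Table-2-style planted coefficient vectors used as ground truth in
# identification tests (frequency and compound-emotion outcomes)
PLANTED_B_FREQ <- c(4.948, -0.028, 0.741, 0.032, 4.884, -0.132, 1.512, 0.114)
PLANTED_B_EMO  <- c(0.231, -0.002, 0.015, 0.002, 0.034, -0.001, 0.011, 0.000)

# deterministic two-group series from a coefficient vector (zero noise
# unless sd > 0)
make_group_series <- function(b, W = 52, t0 = 11, sd = 0,
                              groups = c("NMH", "MH")) {
  wk <- seq_len(W)
  d <- data.table::data.table(group = rep(groups, each = W),
                              week = rep(wk, 2L))
  g <- as.numeric(d$group == groups[2])
  D <- as.numeric(d$week >= t0)
  P <- (d$week - t0) * D
  X <- cbind(1, d$week, D, P, g, g * d$week, g * D, g * P)
  d$value <- drop(X %*% b) + if (sd > 0) rnorm(nrow(d), sd = sd) else 0
  d
}

# brute-force OLS via the normal equations (independent of fit_ols's QR
# path)
ols_normal_equations <- function(X, y) {
  drop(solve(crossprod(X), crossprod(X, y)))
}

# White (heteroskedasticity-robust, HC1) covariance by the direct
# formula, as the L = 0 oracle for newey_west_cov
white_cov_direct <- function(X, e) {
  n <- nrow(X); k <- ncol(X)
  bread <- solve(crossprod(X))
  meat <- t(X) %*% diag(e^2) %*% X
  n / (n - k) * bread %*% meat %*% bread
}

# group-heteroskedastic OLS sandwich standard errors: per-group residual
# variance, correctly calibrated when the two cohorts' weekly noise
# scales differ (the pooled classical estimator is not)
groupwise_ols_se <- function(X, residuals, group, k_per_group = 4L) {
  XtXi <- solve(crossprod(X))
  meat <- matrix(0, ncol(X), ncol(X))
  for (gl in unique(group)) {
    i <- group == gl
    s2 <- sum(residuals[i]^2) / (sum(i) - k_per_group)
    meat <- meat + s2 * crossprod(X[i, , drop = FALSE])
  }
  sqrt(diag(XtXi %*% meat %*% XtXi))
}

# effective planted coefficients of a corpus: the closed-form expected
# frequency path regressed on the segmented design
planted_freq_coefficients <- function(corpus, t0 = 11) {
  des <- build_design(planted_frequency_path(corpus), t0)
  fit_ols(des$X, des$y)$beta
}

# small handmade record table spanning all four communities
tiny_records <- function() {
  wb <- week_bounds(2020)
  ts <- function(w, off = 3600) wb$start[w] + off
  data.table::data.table(
    id = sprintf("t_%02d", 1:8),
    author = c("ann", "ann", "bob", "bob", "cat", "cat", "dan", "eve"),
    community = c("teen", "teen", "teen", "anxiety", "teen", "teen",
                  "depression", "teen"),
    created_utc = c(ts(1), ts(1, 7200), ts(1, 9000), ts(2), ts(1), ts(2),
                    ts(1), ts(2)),
    title = "", body = c("scared afraid", "happy school", "sad lonely",
                         "anxious", "school book", "angry mad",
                         "depressed", "fun game"),
    kind = c("post", "comment", "post", "comment", "comment", "post",
             "post", "comment"))
}
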