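#' Build the two-group segmented-regression design
#'
#' Stacks both groups' weekly series into one response vector and the
#' eight-column design `[1, t, D, P, g, g*t, g*D, g*P]`, where
#' `D = 1{t >= t0}` is the post-interruption indicator,
#' `P = (t - t0) * D` the post-interruption time (so `P = 0` at the
#' interruption week itself), and `g` the group flag (0 = reference,
#' e.g. NMH; 1 = comparison, e.g. MH). Coefficients map to
#' `b0..b7`: pre-period level and slope of the reference group (b0,
#' b1), its level and slope change at the interruption (b2, b3), and
#' the group differences in those four quantities (b4..b7).
#'
#' @param series_by_group data.frame with columns `group` (two levels;
#'   0/1, or labels ordered so the reference sorts first — `"NMH"` is
#'   always taken as reference when present), `week` and `value`. Both
#'   groups must cover the same weeks.
#' @param t0 Interruption week (first post-period week).
#' @return List of class `itsa_design`: `X` (n x 8 matrix), `y`,
#'   `group` (0/1 per row), `week`, `t0`, `group_levels`.
#' @export
build_design <- function(series_by_group, t0) {
  d <- data.table::as.data.table(series_by_group)
  stopifnot(all(c("group", "week", "value") %in% names(d)))
  lev <- unique(as.character(d$group))
  if (length(lev) != 2L) stop("exactly two groups are required")
  if ("NMH" %in% lev) lev <- c("NMH", setdiff(lev, "NMH"))
  else lev <- sort(lev)
  w0 <- sort(unique(d[group == lev[1], week]))
  w1 <- sort(unique(d[group == lev[2], week]))
  if (!identical(w0, w1))
    stop("groups must cover identical week ranges")
  if (anyNA(d$value))
    stop("missing weekly values are not imputed; supply complete series")
  if (t0 < min(w0) || t0 > max(w0))
    stop("interruption week t0 must lie inside the observed week range")
  d[, g := as.numeric(as.character(group) == lev[2])]
  data.table::setorder(d, g, week)
  t <- d$week
  D <- as.numeric(t >= t0)
  P <- (t - t0) * D
  g <- d$g
  X <- cbind(`(Intercept)` = 1, t = t, D = D, P = P,
             g = g, g_t = g * t, g_D = g * D, g_P = g * P)
  structure(list(X = X, y = d$value, group = g, week = t, t0 = t0,
                 group_levels = lev),
            class = "itsa_design")
}

#' Ordinary least squares with explicit rank checking
#'
#' @param X Full-column-rank design matrix with more rows than
#'   columns.
#' @param y Response vector.
#' @return List: `beta`, `fitted`, `residuals`, `r_square`
#'   (`1 - SSR/SST` with SST centred on the grand mean; defined as 0
#'   when SST is 0), `n`, `k`.
#' @export
fit_ols <- function(X, y) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y), nrow(X) > ncol(X))
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    dropped <- colnames(X)[qrx$pivot[(qrx$rank + 1L):ncol(X)]]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(dropped, collapse = ", "))
  }
  beta <- qr.coef(qrx, y)
  fitted <- drop(X %*% beta)
  res <- y - fitted
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - sum(res^2) / sst else 0
  list(beta = beta, fitted = fitted, residuals = res, r_square = r2,
       n = nrow(X), k = ncol(X))
}

#' Newey-West (HAC) covariance for stacked group time series
#'
#' Sandwich covariance `(X'X)^-1 M (X'X)^-1` whose meat accumulates
#' squared-residual outer products plus Bartlett-weighted
#' (`w_l = 1 - l/(L+1)`) lag-l residual cross products up to lag `L`.
#' Lagged products are taken only within each group's own time-ordered
#' series, never across the group boundary. The small-sample factor
#' `n/(n - k)` is applied (toggleable).
#'
#' @param X Design matrix (rows time-ordered within each group).
#' @param residuals OLS residuals aligned with the rows of `X`.
#' @param L Maximum lag (>= 0); must be smaller than every group's
#'   series length.
#' @param group Group id per row (single series when omitted).
#' @param small_sample Apply the `n/(n - k)` correction.
#' @return `k x k` covariance matrix (symmetric, positive
#'   semidefinite).
#' @export
newey_west_cov <- function(X, residuals, L, group = NULL,
                           small_sample = TRUE) {
  X <- as.matrix(X)
  n <- nrow(X)
  k <- ncol(X)
  stopifnot(length(residuals) == n, L >= 0, L == as.integer(L))
  if (is.null(group)) group <- rep(1L, n)
  stopifnot(length(group) == n)
  for (gl in unique(group)) {
    if (L >= sum(group == gl))
      stop("lag L must be smaller than each group's series length")
  }
  M <- crossprod(X * residuals)           # lag-0 term
  if (L > 0) {
    for (gl in unique(group)) {
      idx <- which(group == gl)
      Xg <- X[idx, , drop = FALSE]
      eg <- residuals[idx]
      ng <- length(idx)
      for (l in seq_len(L)) {
        w <- 1 - l / (L + 1)
        i2 <- (l + 1L):ng
        A <- crossprod(Xg[i2, , drop = FALSE] * (eg[i2] * eg[i2 - l]),
                       Xg[i2 - l, , drop = FALSE])
        M <- M + w * (A + t(A))
      }
    }
  }
  bread <- solve(crossprod(X))
  V <- bread %*% M %*% bread
  if (small_sample) V <- V * n / (n - k)
  V <- (V + t(V)) / 2
  dimnames(V) <- list(colnames(X), colnames(X))
  V
}

#' Residual-autocorrelation lag diagnostic
#'
#' Computes per-group residual autocorrelations with the usual
#' large-sample significance bounds `+/- z_(1-alpha/2) / sqrt(n)` and
#' suggests the largest lag (up to `max_lag`) at which any group's
#' autocorrelation is significant, or 0 when none is. This transparent
#' ACF rule is a diagnostic aid; the HAC lag stays a user-settable
#' modelling choice.
#'
#' @param residuals Residual vector.
#' @param max_lag Largest lag examined (positive, below the shortest
#'   group's series length).
#' @param alpha Significance level of the bounds.
#' @param group Optional group id per residual.
#' @return List of class `lag_diagnostic`: `lag` (suggested L) and
#'   `table` (group, lag, acf, bound, significant).
#' @export
select_lag <- function(residuals, max_lag, alpha = 0.05, group = NULL) {
  if (max_lag <= 0) stop("max_lag must be positive")
  if (is.null(group)) group <- rep(1L, length(residuals))
  z <- qnorm(1 - alpha / 2)
  tabs <- list()
  for (gl in unique(group)) {
    e <- residuals[group == gl]
    if (max_lag >= length(e))
      stop("max_lag must be below the series length")
    if (sd(e) == 0) {
      warning("constant residuals: autocorrelation undefined, using L = 0")
      r <- rep(NA_real_, max_lag)
    } else {
      r <- drop(acf(e, lag.max = max_lag, plot = FALSE,
                    demean = TRUE)$acf)[-1L]
    }
    tabs[[length(tabs) + 1L]] <- data.table::data.table(
      group = gl, lag = seq_len(max_lag), acf = r,
      bound = z / sqrt(length(e)),
      significant = !is.na(r) & abs(r) > z / sqrt(length(e)))
  }
  tab <- data.table::rbindlist(tabs)
  sug <- if (any(tab$significant)) max(tab$lag[tab$significant]) else 0L
  structure(list(lag = as.integer(sug), table = tab[]),
            class = "lag_diagnostic")
}

#' @export
print.lag_diagnostic <- function(x, ...) {
  cat("suggested HAC lag:", x$lag, "\n")
  print(x$table)
  invisible(x)
}

#' Fit the two-group interrupted time series model
#'
#' Composes [build_design()], [fit_ols()] and [newey_west_cov()]:
#' segmented OLS over both groups' weekly series with Newey-West
#' standard errors, t statistics `b / se`, and two-sided p-values from
#' a Student-t distribution with `n - 8` degrees of freedom.
#'
#' @inheritParams build_design
#' @param L HAC lag (the analysis default for a 52-week series with
#'   strong autocorrelation is 12; see [select_lag()]).
#' @param small_sample Passed to [newey_west_cov()].
#' @return Object of class `itsa_fit`: `coefficients` (data.table with
#'   parameter, estimate, hac_se, t_value, p_value), `beta`, `vcov`,
#'   `r_square`, `residuals`, `n`, `L`, `t0`, `group_levels`,
#'   `lag_diagnostic`.
#' @export
fit_itsa <- function(series_by_group, t0, L = 12L, small_sample = TRUE) {
  des <- build_design(series_by_group, t0)
  fit <- fit_ols(des$X, des$y)
  V <- newey_west_cov(des$X, fit$residuals, L, group = des$group,
                      small_sample = small_sample)
  se <- sqrt(diag(V))
  tval <- fit$beta / se
  dof <- fit$n - fit$k
  pval <- 2 * pt(-abs(tval), df = dof)
  max_diag_lag <- min(tabulate(factor(des$group))) - 1L
  diag_lag <- tryCatch(
    select_lag(fit$residuals, max_lag = min(max_diag_lag, 20L),
               group = des$group),
    warning = function(w) NULL, error = function(e) NULL)
  coefs <- data.table::data.table(
    parameter = paste0("b", 0:7),
    term = colnames(des$X),
    estimate = unname(fit$beta),
    hac_se = unname(se),
    t_value = unname(tval),
    p_value = unname(pval))
  structure(list(coefficients = coefs, beta = fit$beta, vcov = V,
                 r_square = fit$r_square, residuals = fit$residuals,
                 fitted = fit$fitted, n = fit$n, k = fit$k, dof = dof,
                 L = as.integer(L), t0 = t0,
                 group_levels = des$group_levels,
                 lag_diagnostic = diag_lag),
            class = "itsa_fit")
}

#' @export
coef.itsa_fit <- function(object, ...) object$beta

#' @export
vcov.itsa_fit <- function(object, ...) object$vcov

#' @export
print.itsa_fit <- function(x, digits = 3, ...) {
  cat("Two-group interrupted time series fit\n")
  cat("  groups:", paste(x$group_levels, collapse = " vs "),
      " (reference:", x$group_levels[1], ")\n")
  cat("  n =", x$n, " interruption week =", x$t0,
      " Newey-West lag =", x$L, "\n\n")
  tab <- data.frame(
    Parameter = x$coefficients$parameter,
    b = round(x$coefficients$estimate, digits),
    `Approx. SE` = round(x$coefficients$hac_se, digits),
    `t Value` = round(x$coefficients$t_value, 2),
    `Pr > |t|` = format.pval(x$coefficients$p_value, digits = 3,
                             eps = 1e-4),
    check.names = FALSE)
  print(tab, row.names = FALSE)
  cat("\nR-square =", round(x$r_square, 3), "\n")
  invisible(x)
}

#' Confidence intervals for ITSA coefficients
#'
#' Student-t intervals on the HAC standard errors with `n - 8` degrees
#' of freedom.
#'
#' @param object An `itsa_fit`.
#' @param parm Coefficient indices or `b*` names.
#' @param level Confidence level.
#' @param ... Unused.
#' @return Matrix with `lower`/`upper` columns.
#' @export
confint.itsa_fit <- function(object, parm = 1:8, level = 0.95, ...) {
  if (is.character(parm))
    parm <- match(parm, object$coefficients$parameter)
  q <- qt(1 - (1 - level) / 2, df = object$dof)
  est <- object$coefficients$estimate[parm]
  se <- object$coefficients$hac_se[parm]
  out <- cbind(lower = est - q * se, upper = est + q * se)
  rownames(out) <- object$coefficients$parameter[parm]
  out
}
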