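#' Fixed-effects least-squares fit
#'
#' Ordinary least squares with categorical terms dummy-coded against the
#' alphabetically first level (R's default treatment contrasts). The
#' Gaussian log-likelihood uses the maximum-likelihood variance RSS/n, as
#' required for information criteria.
#'
#' @param formula Model formula.
#' @param data Data frame; character columns are treated as factors.
#' @return An object of class `lin_fit`: the underlying `lm` plus `n`,
#'   `k` (estimated coefficients incl. intercept), `rss`, `r_squared` and
#'   `log_lik`.
#' @export
#' @examples
#' d <- data.frame(x = 1:10, y = 2 * (1:10) + 1)
#' fit_linear(y ~ x, d)$r_squared
fit_linear <- function(formula, data) {
  fit <- stats::lm(formula, data = data)
  cf <- coef(fit)
  if (anyNA(cf)) {
    stop("Design is rank deficient; aliased terms: ",
         paste(names(cf)[is.na(cf)], collapse = ", "), call. = FALSE)
  }
  n <- length(stats::residuals(fit))
  rss <- sum(stats::residuals(fit)^2)
  y <- stats::model.response(stats::model.frame(fit))
  tss <- if (attr(terms(fit), "intercept") == 1) {
    sum((y - mean(y))^2)
  } else {
    sum(y^2)
  }
  structure(list(
    formula = formula,
    lm = fit,
    response = all.vars(formula)[1],
    n = n,
    k = length(cf),
    rss = rss,
    r_squared = if (tss > 0) 1 - rss / tss else NA_real_,
    log_lik = -n / 2 * (log(2 * pi) + log(rss / n) + 1)
  ), class = "lin_fit")
}

#' @export
print.lin_fit <- function(x, ...) {
  cat("<lin_fit> ", deparse(x$formula), "\n", sep = "")
  cat(sprintf("  n = %d, k = %d, RSS = %.4g, R^2 = %.3f, logLik = %.3f\n",
              x$n, x$k, x$rss, x$r_squared, x$log_lik))
  invisible(x)
}

#' Corrected Akaike information criterion
#'
#' `AICc = -2 logLik + 2p + 2p(p+1)/(n - p - 1)` with `p = k + 1` parameters
#' (the estimated coefficients plus the residual variance, the convention
#' under which a year+site model over four years and four sites has 8 df).
#'
#' @param fit A [fit_linear()] object.
#' @return The AICc value.
#' @export
aicc <- function(fit) {
  stopifnot(inherits(fit, "lin_fit"))
  p <- fit$k + 1
  if (fit$n - p - 1 <= 0) {
    stop("AICc undefined: need n > k + 2 (here n = ", fit$n,
         ", parameters incl. variance = ", p, ").", call. = FALSE)
  }
  -2 * fit$log_lik + 2 * p + 2 * p * (p + 1) / (fit$n - p - 1)
}

#' F test of nested fixed-effects models
#'
#' Tests the terms the full model adds over the null:
#' `F = ((RSS0 - RSS1)/dk) / (RSS1/(n - k1))`, with the p-value from the
#' F(dk, n - k1) distribution.
#'
#' @param null_fit,full_fit [fit_linear()] objects on the same data, the
#'   null model's terms a strict subset of the full model's.
#' @return A list: `F`, `df1`, `df2`, `p`.
#' @export
compare_nested <- function(null_fit, full_fit) {
  stopifnot(inherits(null_fit, "lin_fit"), inherits(full_fit, "lin_fit"))
  if (null_fit$n != full_fit$n) {
    stop("Models were fitted to different numbers of observations.",
         call. = FALSE)
  }
  t0 <- attr(terms(null_fit$lm), "term.labels")
  t1 <- attr(terms(full_fit$lm), "term.labels")
  if (!all(t0 %in% t1)) {
    stop("Models are not nested: null terms ",
         paste(setdiff(t0, t1), collapse = ", "),
         " are absent from the full model.", call. = FALSE)
  }
  dk <- full_fit$k - null_fit$k
  if (dk <= 0) {
    stop("Full model adds no parameters over the null (delta k = ", dk,
         ").", call. = FALSE)
  }
  df2 <- full_fit$n - full_fit$k
  Fval <- ((null_fit$rss - full_fit$rss) / dk) / (full_fit$rss / df2)
  list(F = Fval, df1 = dk, df2 = df2,
       p = pf(Fval, dk, df2, lower.tail = FALSE))
}

#' Marginal R-squared of a focal fixed term
#'
#' The share of response variance attributable to one model term: the
#' variance of that term's contribution to the fitted values divided by the
#' variance of the response (the all-fixed-effects analogue of a marginal
#' R-squared). For a single-predictor model this equals the ordinary
#' R-squared.
#'
#' @param fit A [fit_linear()] object.
#' @param term Name of a term in the model (as in the formula).
#' @return The focal term's variance share.
#' @export
marginal_r2 <- function(fit, term) {
  stopifnot(inherits(fit, "lin_fit"))
  labels <- attr(terms(fit$lm), "term.labels")
  if (!term %in% labels) {
    stop("Term '", term, "' is not in the model (terms: ",
         paste(labels, collapse = ", "), ").", call. = FALSE)
  }
  X <- model.matrix(fit$lm)
  asg <- attr(X, "assign")
  cols <- which(asg == match(term, labels))
  contrib <- X[, cols, drop = FALSE] %*% coef(fit$lm)[cols]
  y <- fit$lm$model[[1]]
  as.numeric(var(contrib) / var(y))
}

#' Exact two-sided binomial test
#'
#' The two-sided exact binomial p-value: the total probability of all
#' outcomes whose point probability does not exceed that of the observed
#' `k`, under success probability `p0`.
#'
#' @param k Observed successes.
#' @param n Trials.
#' @param p0 Null success probability.
#' @return The p-value.
#' @export
#' @examples
#' exact_binomial(17, 18)  # ~1.45e-4
exact_binomial <- function(k, n, p0 = 0.5) {
  if (length(k) != 1L || length(n) != 1L || is.na(k) || is.na(n) ||
      k != round(k) || n != round(n) || n < 1 || k < 0 || k > n) {
    stop("Need integers 0 <= k <= n with n >= 1.", call. = FALSE)
  }
  if (p0 <= 0 || p0 >= 1) {
    stop("`p0` must lie in (0, 1).", call. = FALSE)
  }
  binom.test(k, n, p = p0)$p.value
}
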