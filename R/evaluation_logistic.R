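#' Logistic regression of the within-window label on intensity ratios
#'
#' Maximum-likelihood fit (iteratively reweighted least squares via
#' [stats::glm()]) of `logit P(within window) = alpha + sum(beta_j * x_j)`.
#' Reports per-coefficient standard errors, t statistics (beta / SE) and
#' p values, the model chi-square against the intercept-only null
#' (`2 (lnL_model - lnL_null)` on `#predictors` degrees of freedom) and the
#' small-sample-corrected Akaike criterion
#' `AICc = -2 lnL + 2k + 2k(k+1)/(n-k-1)` with `k` parameters including the
#' intercept. Perfect separation is detected (fitted probabilities collapse
#' onto the labels) and raised as a typed non-convergence error because the
#' coefficients diverge.
#'
#' @param table a data.frame (e.g. a `cohort_table`) with the response and
#'   predictor columns; rows with missing predictor values are an error.
#' @param predictors character vector of predictor column names (may be
#'   empty for the intercept-only model).
#' @param response response column name (0/1), default `"label"`.
#' @return object of class `stroke_logit`: `fit` (the glm), `coefficients`
#'   data.frame (term, beta, se, t, p), `chisq`, `df`, `p_model`, `aicc`,
#'   `fitted`, `n`.
#' @export
fit_logistic <- function(table, predictors, response = "label") {
  missing_cols <- setdiff(c(response, predictors), names(table))
  if (length(missing_cols))
    stop_strokeclock("bad_input", "missing columns: %s", paste(missing_cols, collapse = ", "))
  df <- table[, c(response, predictors), drop = FALSE]
  if (anyNA(df))
    stop_strokeclock("bad_input", "missing predictor or response values")
  n <- nrow(df)
  if (n <= length(predictors) + 1L)
    stop_strokeclock("bad_input", "need n > #predictors + 1 observations")
  f <- stats::reformulate(if (length(predictors)) predictors else "1", response)
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    stats::glm(f, data = df, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep_warn <<- TRUE
      invokeRestart("muffleWarning")
    }
  )
  y <- df[[response]]
  separated <- sep_warn && mean(abs(stats::fitted(fit) - y)) < 1e-6
  if (!fit$converged || separated)
    stop_strokeclock("separation",
                     "logistic fit did not converge (perfect separation: coefficients diverge)")
  sm <- summary(fit)$coefficients
  k <- length(stats::coef(fit))
  aicc <- stats::AIC(fit) + 2 * k * (k + 1) / (n - k - 1)
  chisq <- fit$null.deviance - fit$deviance
  dfree <- length(predictors)
  structure(
    list(
      fit = fit,
      coefficients = data.frame(
        term = rownames(sm), beta = sm[, 1], se = sm[, 2],
        t = sm[, 3], p = sm[, 4], row.names = NULL, stringsAsFactors = FALSE
      ),
      chisq = chisq, df = dfree,
      p_model = if (dfree > 0) stats::pchisq(chisq, dfree, lower.tail = FALSE) else NA_real_,
      aicc = aicc, fitted = as.numeric(stats::fitted(fit)), n = n
    ),
    class = "stroke_logit"
  )
}

#' Probability of being within the treatment window
#'
#' Inverse-logit of the linear predictor: `P = exp(Y) / (1 + exp(Y))` with
#' `Y = alpha + sum(beta_j * x_j)`. Accepts either a fitted [fit_logistic()]
#' model with a data.frame of new ratios, or a plain list with `intercept`
#' and named `coefficients` applied to a named vector / data.frame.
#'
#' @param model a `stroke_logit`, or `list(intercept =, coefficients = c(...))`.
#' @param newdata data.frame of predictor values (or named numeric vector for
#'   the list form).
#' @return numeric probabilities in (0, 1).
#' @export
predict_probability <- function(model, newdata) {
  if (inherits(model, "stroke_logit")) {
    if (!is.data.frame(newdata)) newdata <- as.data.frame(as.list(newdata))
    eta <- stats::predict(model$fit, newdata = newdata, type = "link")
  } else if (is.list(model) && !is.null(model$intercept)) {
    cf <- model$coefficients %||% numeric(0)
    if (is.data.frame(newdata)) newdata <- as.matrix(newdata[, names(cf), drop = FALSE])
    if (is.matrix(newdata)) {
      eta <- model$intercept + as.numeric(newdata %*% cf[colnames(newdata)])
    } else {
      if (length(cf) == 1L && is.null(names(newdata)))
        eta <- model$intercept + cf * newdata  # single-predictor vector of ratios
      else eta <- model$intercept + sum(cf * newdata[names(cf)])
    }
  } else {
    stop_strokeclock("bad_input", "model must be a stroke_logit or an intercept/coefficients list")
  }
  as.numeric(stats::plogis(eta))
}
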