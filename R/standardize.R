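#' Fit the prediction model used for covariate standardization
#'
#' Weighted generalized-linear fit of the health variable on wealth terms
#' plus control covariates. The fitted object records which design-matrix
#' columns belong to the wealth terms and the weighted means of the control
#' columns, which is what the standardization step needs.
#'
#' @param h outcome vector.
#' @param data data frame holding the model variables.
#' @param wealth one-sided formula for the wealth terms, e.g.
#'   `~ wealth_quintile` or `~ wealth_score`.
#' @param controls one-sided formula for the control covariates, e.g.
#'   `~ education + residence`; `~ 1` (or `NULL`) for no controls.
#' @param weights positive sampling weights (default equal).
#' @param link `"identity"` (linear model, the default: the convenient
#'   regression framework is linear), `"log"` (Poisson-family) or
#'   `"logit"` (binomial-family).
#' @return object of class `prediction_model` wrapping the fit.
#' @export
fit_prediction_model <- function(h, data, wealth, controls = NULL,
                                 weights = NULL, link = "identity") {
  stopifnot(is.data.frame(data))
  n <- length(h)
  if (n != nrow(data)) stop("`h` must match `data` rows", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, n)
  if (any(weights <= 0)) stop("`weights` must be positive", call. = FALSE)
  link <- match.arg(link, c("identity", "log", "logit"))
  if (is.null(controls)) controls <- ~ 1

  Xw <- stats::model.matrix(wealth, data)
  Xc <- stats::model.matrix(controls, data)
  # drop the duplicate intercept from the control block
  Xc <- Xc[, colnames(Xc) != "(Intercept)", drop = FALSE]
  X <- cbind(Xw, Xc)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  dat <- data.frame(.h = h, X[, -1L, drop = FALSE], check.names = FALSE)
  form <- stats::as.formula(paste(
    ".h ~", paste(sprintf("`%s`", colnames(X)[-1L]), collapse = " + ")))
  fam <- switch(link,
                identity = stats::gaussian(),
                log = stats::poisson(link = "log"),
                logit = stats::binomial(link = "logit"))
  fit <- suppressWarnings(
    stats::glm(form, data = dat, weights = weights, family = fam)
  )
  wn <- weights / sum(weights)
  structure(
    list(fit = fit,
         link = link,
         wealth_formula = wealth,
         controls_formula = controls,
         wealth_cols = colnames(Xw),
         control_cols = colnames(Xc),
         control_means = colSums(wn * Xc),
         X = X,
         weights = weights),
    class = "prediction_model"
  )
}

#' @export
print.prediction_model <- function(x, ...) {
  cat(sprintf("Standardization model (%s link): %d wealth term(s), %d control(s)\n",
              x$link, length(x$wealth_cols) - 1L, length(x$control_cols)))
  print(stats::coef(x$fit))
  invisible(x)
}

#' @export
coef.prediction_model <- function(object, ...) stats::coef(object$fit)

#' Predict the outcome with controls frozen at their weighted means
#'
#' Per-record predictions use each record's own wealth terms while every
#' control column of the design matrix is replaced by its weighted mean, so
#' the remaining variation in the predictions is the wealth gradient net of
#' the controls. Identity-link predictions can in principle be negative;
#' they are returned as-is.
#'
#' @param model a [fit_prediction_model()] object.
#' @param newdata optional data frame; default is the training data's
#'   design.
#' @return numeric vector of adjusted outcome values (response scale).
#' @export
predict_at_means <- function(model, newdata = NULL) {
  stopifnot(inherits(model, "prediction_model"))
  X <- if (is.null(newdata)) {
    model$X
  } else {
    Xw <- stats::model.matrix(model$wealth_formula, newdata)
    Xc <- stats::model.matrix(model$controls_formula, newdata)
    Xc <- Xc[, colnames(Xc) != "(Intercept)", drop = FALSE]
    cbind(Xw, Xc)
  }
  X[, model$control_cols] <- rep(model$control_means,
                                 each = nrow(X))
  beta <- stats::coef(model$fit)
  names(beta) <- gsub("^`|`$", "", names(beta))  # glm backticks odd names
  eta <- unname(drop(X[, names(beta), drop = FALSE] %*% beta))
  switch(model$link,
         identity = eta,
         log = exp(eta),
         logit = stats::plogis(eta))
}

#' Covariate-standardized concentration index
#'
#' Computes the concentration index of the outcome values predicted with all
#' control covariates held at their weighted means (`mode = "direct"`, the
#' partial standardization of the wealth-outcome relation), or of the
#' indirectly standardized values `h - h_hat + mean(h)` (`mode =
#' "indirect"`, the classical alternative in which the prediction model's
#' wealth terms are dropped and only need-like controls predict).
#'
#' The point estimate is the covariance-formula index of the standardized
#' values. Its standard error comes from a weighted regression of the
#' untransformed standardized outcome on the transformed rank regressor
#' `RW_i = mu * r_i / (2 * var_w(r))`, whose slope reproduces the index
#' exactly (the rank variance depends only on the weights, so it is treated
#' as a constant) and whose conventional slope standard error is reported.
#'
#' @param h outcome vector.
#' @param data data frame with wealth terms and controls.
#' @param wealth,controls one-sided formulas as in
#'   [fit_prediction_model()].
#' @param ranking numeric vector used to compute fractional ranks (the
#'   continuous wealth score); defaults to the single variable named in
#'   `wealth` if that is numeric.
#' @param weights positive sampling weights.
#' @param link link function for the prediction model.
#' @param mode `"direct"` (controls frozen at means) or `"indirect"`.
#' @param robust heteroskedasticity-robust standard error flag.
#' @return a `conc_estimate` with `adjusted = TRUE`, carrying the
#'   standardized values in `$standardized` and the prediction model in
#'   `$model`.
#' @export
ci_adjusted <- function(h, data, wealth, controls, ranking = NULL,
                        weights = NULL, link = "identity",
                        mode = c("direct", "indirect"), robust = FALSE) {
  mode <- match.arg(mode)
  n <- length(h)
  if (is.null(weights)) weights <- rep(1, n)
  if (is.null(ranking)) {
    v <- all.vars(wealth)
    if (length(v) == 1L && is.numeric(data[[v]])) {
      ranking <- data[[v]]
    } else {
      stop("supply `ranking` (a continuous wealth score) when the wealth terms are categorical",
           call. = FALSE)
    }
  }
  no_controls <- is.null(controls) ||
    (inherits(controls, "formula") && length(all.vars(controls)) == 0L)
  if (no_controls) {
    # nothing to standardize for: the adjusted index reduces to the
    # unadjusted index of the raw outcome, whatever the wealth terms
    model <- fit_prediction_model(h, data, wealth, NULL, weights, link)
    h_std <- h
  } else {
    model <- fit_prediction_model(h, data, wealth, controls, weights, link)
    if (mode == "direct") {
      h_std <- predict_at_means(model)
    } else {
      h_hat <- stats::fitted(model$fit)
      h_std <- h - h_hat + wmean(h, weights)
    }
  }
  ro <- ranked_outcome(h_std, wealth = ranking, weights = weights)
  if (ro$mu <= 0)
    stop("standardized outcome has non-positive weighted mean; identity-link predictions are pathological here",
         call. = FALSE)
  est <- ci_covariance(ro)$estimate
  # transformed-regressor route for the standard error
  v <- wvar(ro$r, ro$w)
  rw <- ro$mu * ro$r / (2 * v)
  dat <- data.frame(y = h_std, rw = rw, w = ro$w)
  fit <- stats::lm(y ~ rw, data = dat, weights = w)
  slope <- unname(stats::coef(fit)[["rw"]])
  se <- slope_se(fit, robust)
  out <- new_conc_estimate(slope, se, "regression", TRUE, n,
                           extra = list(standardized = h_std, model = model,
                                        fit = fit, mode = mode,
                                        covariance_estimate = est))
  out
}
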