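#' Fit a concentration index to survey data
#'
#' The central fitting function of the package: measures wealth-related
#' inequality in a health variable as the concentration index — twice the
#' weighted covariance between the variable and the fractional wealth rank,
#' divided by the variable's mean; equivalently twice the area between the
#' concentration curve and the line of equality. Positive values mean the
#' variable is concentrated among the rich.
#'
#' The right-hand side of `formula` names the living-standards variable used
#' for ranking. Without `adjust`, the index is estimated unadjusted by the
#' requested route; the `"regression"` route (the convenient regression of
#' the transformed outcome on the rank) also yields a standard error. With
#' `adjust`, the index is standardized for the control covariates via
#' [ci_adjusted()]: the outcome is predicted with controls frozen at their
#' weighted means and the index of those predictions is reported, with a
#' standard error from the transformed-rank-regressor regression.
#'
#' @param formula `health_variable ~ wealth_score`. The wealth side must be
#'   a single numeric living-standards variable (it is only used through its
#'   ranks).
#' @param data data frame containing the variables.
#' @param weights sampling weights: a column name (unquoted or character) or
#'   a numeric vector. Default equal weights.
#' @param method estimation route: `"regression"` (convenient regression,
#'   default — has a standard error), `"covariance"` (plug-in identity) or
#'   `"area"` (twice the area between curve and diagonal).
#' @param grouping curve construction for `method = "area"` and for
#'   [plot.concindex()]: `"individual"` or `"quintile"`.
#' @param adjust optional one-sided formula of control covariates for
#'   standardization, e.g. `~ education + residence`.
#' @param wealth_terms how wealth enters the standardization prediction
#'   model: `"quintile"` (indicators, default), `"score"` (the continuous
#'   variable) or `"rank"` (the fractional rank).
#' @param link link for the standardization prediction model.
#' @param mode standardization mode, `"direct"` or `"indirect"` (see
#'   [ci_adjusted()]).
#' @param robust heteroskedasticity-robust standard errors.
#' @return object of class `concindex` with components `estimate`, `se`,
#'   `method`, `adjusted`, `n`, `ranked` (the [ranked_outcome()]), `curve`
#'   (the [concentration_curve()]), and for adjusted fits the standardized
#'   values and prediction model. Methods: `print`, `summary`, `coef`,
#'   `confint`, `plot`, `residuals`.
#' @examples
#' d <- data.frame(visits = c(1, 2, 3, 4, 5), wealth = 1:5)
#' fit <- concindex(visits ~ wealth, d)
#' coef(fit)        # 0.2667: visits concentrated among the rich
#' confint(fit)
#' @export
concindex <- function(formula, data, weights = NULL,
                      method = c("regression", "covariance", "area"),
                      grouping = c("individual", "quintile"),
                      adjust = NULL,
                      wealth_terms = c("quintile", "score", "rank"),
                      link = "identity",
                      mode = c("direct", "indirect"),
                      robust = FALSE) {
  stopifnot(inherits(formula, "formula"), length(formula) == 3L,
            is.data.frame(data))
  method <- match.arg(method)
  grouping <- match.arg(grouping)
  wealth_terms <- match.arg(wealth_terms)
  mode <- match.arg(mode)

  h <- eval(formula[[2L]], data, environment(formula))
  wealth_var <- all.vars(formula[[3L]])
  if (length(wealth_var) != 1L)
    stop("the right-hand side must name a single wealth variable",
         call. = FALSE)
  wealth <- data[[wealth_var]]
  if (is.null(wealth))
    stop(sprintf("wealth variable `%s` not found in `data`", wealth_var),
         call. = FALSE)

  w <- substitute(weights)
  w <- if (is.null(w)) NULL else tryCatch(eval(w, data, parent.frame()),
                                          error = function(e) weights)
  if (is.character(w) && length(w) == 1L) w <- data[[w]]
  if (is.null(w)) w <- rep(1, length(h))

  ranked <- ranked_outcome(h, wealth = wealth, weights = w)
  curve <- concentration_curve(ranked, grouping = grouping)

  if (is.null(adjust)) {
    est <- switch(method,
                  regression = ci_regression(ranked, robust = robust),
                  covariance = ci_covariance(ranked),
                  area = ci_area(curve))
  } else {
    stopifnot(inherits(adjust, "formula"))
    wform <- switch(wealth_terms,
                    quintile = {
                      data$.wq <- assign_quintiles(wealth, w)
                      ~.wq
                    },
                    score = stats::as.formula(paste("~", wealth_var)),
                    rank = {
                      data$.wr <- ranked$r
                      ~.wr
                    })
    est <- ci_adjusted(h, data, wform, adjust, ranking = wealth,
                       weights = w, link = link, mode = mode,
                       robust = robust)
    # curve of the standardized values
    curve <- concentration_curve(
      ranked_outcome(est$standardized, wealth = wealth, weights = w),
      grouping = grouping)
  }

  structure(
    list(estimate = est$estimate, se = est$se, method = est$method,
         adjusted = est$adjusted, n = ranked$n, ranked = ranked,
         curve = curve, conc = est,
         call = match.call(), outcome = deparse(formula[[2L]]),
         wealth_var = wealth_var,
         controls = if (is.null(adjust)) NULL else all.vars(adjust)),
    class = "concindex"
  )
}

#' @export
print.concindex <- function(x, digits = 6, ...) {
  cat("Concentration index fit\n")
  cat("  outcome:", x$outcome, " ranked by:", x$wealth_var, "\n")
  if (x$adjusted)
    cat("  standardized for:", paste(x$controls, collapse = ", "), "\n")
  cat(sprintf("  CI = %s (%s method%s), n = %d\n",
              format(x$estimate, digits = digits), x$method,
              if (is.na(x$se)) "" else
                paste0(", SE = ", format(x$se, digits = digits)),
              x$n))
  invisible(x)
}

#' @export
coef.concindex <- function(object, ...) {
  stats::setNames(object$estimate, "concentration_index")
}

#' @export
confint.concindex <- function(object, parm, level = 0.95, ...) {
  if (is.na(object$se))
    stop("no standard error available from the area/covariance route; refit with method = \"regression\"",
         call. = FALSE)
  z <- stats::qnorm(1 - (1 - level) / 2)
  ci <- object$estimate + c(-1, 1) * z * object$se
  m <- matrix(ci, nrow = 1,
              dimnames = list("concentration_index",
                              sprintf("%.1f %%", 100 * c((1 - level) / 2,
                                                         1 - (1 - level) / 2))))
  m
}

#' @export
summary.concindex <- function(object, level = 0.95, ...) {
  z <- if (is.na(object$se)) NA_real_ else object$estimate / object$se
  p <- if (is.na(z)) NA_real_ else 2 * stats::pnorm(-abs(z))
  structure(
    list(fit = object, z = z, p = p, level = level,
         bounds = if (is.na(object$se)) c(NA_real_, NA_real_) else
           object$estimate + c(-1, 1) * stats::qnorm(1 - (1 - level) / 2) *
           object$se),
    class = "summary.concindex"
  )
}

#' @export
print.summary.concindex <- function(x, digits = 6, ...) {
  print(x$fit, digits = digits)
  if (!is.na(x$z)) {
    cat(sprintf("  %.0f%% CI: [%s, %s]   z = %s, p = %s\n",
                100 * x$level, format(x$bounds[1], digits = digits),
                format(x$bounds[2], digits = digits),
                format(x$z, digits = 4), format.pval(x$p, digits = 4)))
  }
  cat(sprintf("  interpretation: %s\n",
              if (abs(x$fit$estimate) < 1e-12) "equally distributed" else
                if (x$fit$estimate > 0) "concentrated among the rich (pro-rich)"
              else "concentrated among the poor (pro-poor)"))
  invisible(x)
}

#' @export
plot.concindex <- function(x, ...) {
  plot(x$curve, ...)
  graphics::legend("topleft", bty = "n",
                   legend = sprintf("CI = %.4f%s", x$estimate,
                                    if (x$adjusted) " (adjusted)" else ""))
  invisible(x)
}

#' @export
residuals.concindex <- function(object, ...) {
  if (is.null(object$conc$fit))
    stop("residuals are defined for the regression route only", call. = FALSE)
  stats::residuals(object$conc$fit)
}
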