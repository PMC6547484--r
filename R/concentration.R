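#' Concentration curve of an outcome over the wealth distribution
#'
#' Orders individuals from poorest to richest and accumulates population
#' share against outcome share. With `grouping = "quintile"` the curve is the
#' five-point construction used for survey tabulations (cumulative outcome
#' share at the weighted quintile boundaries); with `grouping = "individual"`
#' every record contributes a vertex.
#'
#' @param ranked a [ranked_outcome()].
#' @param grouping `"individual"` or `"quintile"`.
#' @return object of class `concentration_curve`: a data frame with columns
#'   `p` (cumulative population share) and `L` (cumulative outcome share),
#'   starting at (0, 0) and ending at (1, 1), with the grouping stored as an
#'   attribute.
#' @examples
#' ro <- ranked_outcome(1:5, wealth = 1:5)
#' concentration_curve(ro)
#' @export
concentration_curve <- function(ranked,
                                grouping = c("individual", "quintile")) {
  stopifnot(inherits(ranked, "ranked_outcome"))
  grouping <- match.arg(grouping)
  if (ranked$mu <= 0)
    stop("concentration curve undefined: weighted mean of outcome is not positive",
         call. = FALSE)
  ord <- order(ranked$r)
  w <- ranked$w[ord]
  hw <- (ranked$w * ranked$h)[ord]
  p <- cumsum(w)
  L <- cumsum(hw) / sum(hw)
  if (grouping == "quintile") {
    # each record sits in the fifth containing its rank midpoint; curve
    # vertices are the cumulative shares of the five groups
    r <- ranked$r[ord]
    q <- findInterval(r, c(0.2, 0.4, 0.6, 0.8)) + 1L
    p <- cumsum(tapply(w, factor(q, levels = 1:5), sum, default = 0))
    L <- cumsum(tapply(hw, factor(q, levels = 1:5), sum, default = 0)) /
      sum(hw)
    p <- unname(p); L <- unname(L)
  }
  p[length(p)] <- 1
  L[length(L)] <- 1
  out <- data.frame(p = c(0, p), L = c(0, L))
  structure(out, class = c("concentration_curve", "data.frame"),
            grouping = grouping)
}

new_conc_estimate <- function(estimate, se, method, adjusted, n,
                              extra = list()) {
  structure(
    c(list(estimate = estimate, se = se, method = method,
           adjusted = adjusted, n = n), extra),
    class = "conc_estimate"
  )
}

#' @export
print.conc_estimate <- function(x, digits = 6, ...) {
  cat(sprintf("Concentration index (%s%s): %s",
              x$method, if (x$adjusted) ", adjusted" else "",
              format(x$estimate, digits = digits)))
  if (!is.null(x$se) && !is.na(x$se))
    cat("  SE:", format(x$se, digits = digits))
  cat("  n:", x$n, "\n")
  invisible(x)
}

#' Concentration index as twice the area between curve and line of equality
#'
#' Integrates the concentration curve by the trapezoid rule and returns
#' `1 - 2 * area`, positive when the curve lies below the diagonal (outcome
#' concentrated among the rich). No standard error is available from this
#' route.
#'
#' @param curve a [concentration_curve()].
#' @return a `conc_estimate` with `method = "area"` and `se = NA`.
#' @export
ci_area <- function(curve) {
  stopifnot(inherits(curve, "concentration_curve"))
  p <- curve$p; L <- curve$L
  if (any(diff(p) < -1e-12) || any(diff(L) < -1e-12))
    stop("curve coordinates must be non-decreasing", call. = FALSE)
  area <- sum(diff(p) * (L[-1] + L[-length(L)]) / 2)
  new_conc_estimate(1 - 2 * area, NA_real_, "area", FALSE,
                    n = length(p) - 1L)
}

#' Concentration index by the weighted covariance formula
#'
#' The plug-in identity `CI = 2 * cov_w(h, r) / mu`, with `r` the fractional
#' wealth rank. This is the reference route against which the regression and
#' curve-area estimators are checked; it carries no standard error.
#'
#' @param ranked a [ranked_outcome()].
#' @return a `conc_estimate` with `method = "covariance"`.
#' @export
ci_covariance <- function(ranked) {
  stopifnot(inherits(ranked, "ranked_outcome"))
  if (ranked$mu <= 0)
    stop("concentration index undefined: weighted mean of outcome is not positive",
         call. = FALSE)
  est <- 2 * wcov(ranked$h, ranked$r, ranked$w) / ranked$mu
  new_conc_estimate(est, NA_real_, "covariance", FALSE, ranked$n)
}

#' Concentration index by the convenient regression
#'
#' Weighted least squares of the transformed outcome
#' \eqn{2\sigma_r^2\, h_i/\mu} on the fractional rank \eqn{r_i}, with the
#' sampling weights as WLS weights; the slope equals the concentration index
#' and its conventional slope standard error is returned as a by-product.
#' \eqn{\sigma_r^2} is the weighted variance of the ranks.
#'
#' @param ranked a [ranked_outcome()].
#' @param robust logical; heteroskedasticity-robust (HC1 sandwich) slope
#'   standard error instead of the conventional one. Requires the
#'   \pkg{sandwich} package.
#' @return a `conc_estimate` with `method = "regression"`, a standard error,
#'   and the underlying `lm` fit in `$fit`.
#' @export
ci_regression <- function(ranked, robust = FALSE) {
  stopifnot(inherits(ranked, "ranked_outcome"))
  if (ranked$mu <= 0)
    stop("concentration index undefined: weighted mean of outcome is not positive",
         call. = FALSE)
  v <- wvar(ranked$r, ranked$w)
  if (v <= 0)
    stop("degenerate rank variance: all wealth scores tied", call. = FALSE)
  y <- 2 * v * ranked$h / ranked$mu
  dat <- data.frame(y = y, r = ranked$r, w = ranked$w)
  fit <- stats::lm(y ~ r, data = dat, weights = w)
  est <- unname(stats::coef(fit)[["r"]])
  se <- slope_se(fit, robust)
  new_conc_estimate(est, se, "regression", FALSE, ranked$n,
                    extra = list(fit = fit))
}

slope_se <- function(fit, robust = FALSE, term = 2L) {
  if (robust) {
    if (!requireNamespace("sandwich", quietly = TRUE))
      stop("robust standard errors require the `sandwich` package",
           call. = FALSE)
    sqrt(diag(sandwich::vcovHC(fit, type = "HC1")))[term]
  } else {
    sqrt(diag(stats::vcov(fit)))[term]
  }
}

#' Dominance classification of two concentration curves
#'
#' Linearly interpolates both curves onto the union of their abscissae and
#' compares ordinates. Curve A dominates (is closer to, or above, the line
#' of equality from below) when its ordinates are at least B's everywhere
#' and strictly larger somewhere; crossing curves demonstrate non-dominance.
#'
#' @param curve_a,curve_b [concentration_curve()] objects.
#' @param tol differences in ordinate below `tol` are treated as coincident.
#' @return one of `"a_dominates"`, `"b_dominates"`, `"cross"`, `"coincide"`.
#' @export
dominance <- function(curve_a, curve_b, tol = 1e-9) {
  stopifnot(inherits(curve_a, "concentration_curve"),
            inherits(curve_b, "concentration_curve"))
  grid <- sort(unique(c(curve_a$p, curve_b$p)))
  La <- stats::approx(curve_a$p, curve_a$L, xout = grid, ties = "ordered")$y
  Lb <- stats::approx(curve_b$p, curve_b$L, xout = grid, ties = "ordered")$y
  d <- La - Lb
  above <- any(d > tol)
  below <- any(d < -tol)
  if (above && below) return("cross")
  if (above) return("a_dominates")
  if (below) return("b_dominates")
  "coincide"
}

#' @export
plot.concentration_curve <- function(x, ..., add = FALSE,
                                     col = "steelblue", lwd = 2) {
  if (!add) {
    graphics::plot(NA, xlim = c(0, 1), ylim = c(0, 1),
                   xlab = "Cumulative population share (poorest to richest)",
                   ylab = "Cumulative outcome share", ...)
    graphics::abline(0, 1, lty = 2, col = "grey40")
  }
  graphics::lines(x$p, x$L, col = col, lwd = lwd)
  invisible(x)
}
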