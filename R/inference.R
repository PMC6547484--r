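as_est_pair <- function(x, label) {
  if (inherits(x, c("conc_estimate", "concindex")))
    x <- list(estimate = x$estimate, se = x$se)
  if (!is.list(x) || is.null(x$estimate) || is.null(x$se) || is.na(x$se))
    stop(sprintf("`%s` must carry an estimate and a standard error", label),
         call. = FALSE)
  list(estimate = as.numeric(x$estimate), se = as.numeric(x$se))
}

#' Test the difference between two concentration indices
#'
#' Two-sample z test for the change in a concentration index between
#' surveys: `z = |est_a - est_b| / sqrt(se_a^2 + se_b^2)`, referred to the
#' standard normal. Two-sided by default.
#'
#' @param est_a,est_b `conc_estimate`/`concindex` objects, or lists with
#'   `estimate` and `se`.
#' @param sided `"two"` (default) or `"one"` (upper tail).
#' @return an object of class `htest`.
#' @examples
#' ci_difference_test(list(estimate = 0.009612, se = 0.000584),
#'                    list(estimate = 0.002264, se = 0.000351))
#' @export
ci_difference_test <- function(est_a, est_b, sided = c("two", "one")) {
  sided <- match.arg(sided)
  a <- as_est_pair(est_a, "est_a")
  b <- as_est_pair(est_b, "est_b")
  se <- sqrt(a$se^2 + b$se^2)
  if (se == 0) stop("both standard errors are zero", call. = FALSE)
  z <- abs(a$estimate - b$estimate) / se
  p <- if (sided == "two") 2 * stats::pnorm(-z) else stats::pnorm(-z)
  structure(
    list(statistic = c(z = z), p.value = p,
         estimate = c(estimate_a = a$estimate, estimate_b = b$estimate),
         method = sprintf("%s-sided z test for equality of concentration indices",
                          sided),
         alternative = if (sided == "two") "two.sided" else "greater",
         data.name = "two concentration-index estimates"),
    class = "htest"
  )
}

#' Test equality of two odds ratios
#'
#' z test on the odds-ratio scale: `z = |or_a - or_b| / sqrt(se_a^2 +
#' se_b^2)` with the standard errors given on the OR scale; one-sided
#' (upper-tail) by default. A log-scale variant compares `log(or)` using
#' delta-method standard errors `se/or` — the two disagree in general, and
#' the OR-scale version is the survey-tabulation convention this package
#' follows by default.
#'
#' @param or_a,or_b positive odds ratios.
#' @param se_a,se_b their standard errors on the OR scale.
#' @param sided `"one"` (default) or `"two"`.
#' @param scale `"or"` or `"log"`.
#' @return an object of class `htest`.
#' @examples
#' or_equality_test(3.24, 0.340, 2.55, 0.177)  # z = 1.80, p = 0.0359
#' @export
or_equality_test <- function(or_a, se_a, or_b, se_b,
                             sided = c("one", "two"), scale = c("or", "log")) {
  sided <- match.arg(sided)
  scale <- match.arg(scale)
  if (or_a <= 0 || or_b <= 0) stop("odds ratios must be positive", call. = FALSE)
  if (se_a < 0 || se_b < 0) stop("standard errors must be non-negative", call. = FALSE)
  if (se_a == 0 && se_b == 0) stop("both standard errors are zero", call. = FALSE)
  if (scale == "log") {
    d <- abs(log(or_a) - log(or_b))
    se <- sqrt((se_a / or_a)^2 + (se_b / or_b)^2)
  } else {
    d <- abs(or_a - or_b)
    se <- sqrt(se_a^2 + se_b^2)
  }
  z <- d / se
  p <- if (sided == "two") 2 * stats::pnorm(-z) else stats::pnorm(-z)
  structure(
    list(statistic = c(z = z), p.value = p,
         estimate = c(or_a = or_a, or_b = or_b),
         method = sprintf("%s-sided z test for equality of odds ratios (%s scale)",
                          sided, scale),
         alternative = if (sided == "two") "two.sided" else "greater",
         data.name = "two odds-ratio estimates"),
    class = "htest"
  )
}

#' Survey-weighted logistic regression for institutional delivery
#'
#' Fits binary logistic models for facility delivery and reports per-level
#' odds ratios with normal-approximation 95% confidence intervals and Wald
#' p-values. `adjusted = TRUE` fits all covariates jointly; `adjusted =
#' FALSE` fits one single-covariate model per covariate. Sampling weights
#' are applied as frequency-style weights normalized to sum to the number of
#' records; `robust = TRUE` switches to heteroskedasticity-robust (sandwich)
#' variance.
#'
#' Reference levels follow the tabulation convention: poorest wealth
#' quintile, no education, no occupation, urban residence, first ethnicity
#' group, Christianity, youngest age band.
#'
#' @param data data frame containing `delivered_in_facility`, a wealth
#'   variable and the sociodemographic covariates.
#' @param weights sampling weights (vector or column name; default the
#'   `sampling_weight` column, else equal).
#' @param adjusted jointly adjusted model (default) or per-covariate
#'   unadjusted models.
#' @param covariates character vector of covariate column names; defaults to
#'   the generator's sociodemographic set present in `data`.
#' @param wealth_as `"quintile"` (indicators from `wealth_score`, default),
#'   `"rank"` (fractional rank) or `"none"`.
#' @param outcome outcome column name.
#' @param robust sandwich variance flag.
#' @param level confidence level.
#' @return object of class `delivery_fit`: a data frame of results
#'   (`covariate`, `level`, `or`, `lo`, `hi`, `p`, `adjusted`) with the
#'   underlying `glm` fit(s) attached.
#' @export
fit_delivery_model <- function(data, weights = NULL, adjusted = TRUE,
                               covariates = NULL,
                               wealth_as = c("quintile", "rank", "none"),
                               outcome = "delivered_in_facility",
                               robust = FALSE, level = 0.95) {
  stopifnot(is.data.frame(data), outcome %in% names(data))
  wealth_as <- match.arg(wealth_as)
  y <- data[[outcome]]
  if (!all(y %in% c(0, 1)))
    stop("outcome must be binary (0/1)", call. = FALSE)
  if (length(unique(y)) < 2L)
    stop("outcome is constant: the model is degenerate (complete separation)",
         call. = FALSE)
  if (is.null(weights)) {
    weights <- if ("sampling_weight" %in% names(data))
      data$sampling_weight else rep(1, nrow(data))
  }
  if (is.character(weights) && length(weights) == 1L)
    weights <- data[[weights]]
  wn <- weights / sum(weights) * nrow(data)

  d <- data
  if (wealth_as == "quintile" && "wealth_score" %in% names(d)) {
    d$wealth_quintile <- assign_quintiles(d$wealth_score, weights)
  } else if (wealth_as == "rank" && "wealth_score" %in% names(d)) {
    d$wealth_rank <- fractional_rank(d$wealth_score, weights)
  }
  if (is.null(covariates)) {
    candidates <- c(
      switch(wealth_as, quintile = "wealth_quintile",
             rank = "wealth_rank", none = NULL),
      "education", "occupation", "residence", "ethnicity", "religion",
      "age_band", "n_children")
    covariates <- intersect(candidates, names(d))
  }
  if (length(covariates) == 0L)
    stop("no covariates to fit", call. = FALSE)
  d$.y <- y
  d$.w <- wn

  fit_one <- function(covs) {
    form <- stats::as.formula(paste(".y ~", paste(covs, collapse = " + ")))
    fit <- suppressWarnings(
      stats::glm(form, data = d, weights = .w, family = stats::binomial())
    )
    if (!fit$converged || any(abs(stats::coef(fit)) > 30, na.rm = TRUE) ||
        anyNA(stats::coef(fit))) {
      big <- names(which(abs(stats::coef(fit)) > 30))
      stop("separation or non-convergence in logistic fit",
           if (length(big)) paste0("; offending level(s): ",
                                   paste(big, collapse = ", ")) else "",
           call. = FALSE)
    }
    fit
  }

  or_rows <- function(fit, covs) {
    beta <- stats::coef(fit)
    V <- if (robust) {
      if (!requireNamespace("sandwich", quietly = TRUE))
        stop("robust variance requires the `sandwich` package", call. = FALSE)
      sandwich::vcovHC(fit, type = "HC0")
    } else {
      stats::vcov(fit)
    }
    se <- sqrt(diag(V))
    z <- stats::qnorm(1 - (1 - level) / 2)
    rows <- list()
    for (cv in covs) {
      x <- d[[cv]]
      if (is.factor(x)) {
        levs <- levels(x)
        for (li in seq_along(levs)) {
          nm <- paste0(cv, levs[li])
          if (li == 1L) {
            rows[[length(rows) + 1L]] <- data.frame(
              covariate = cv, level = levs[li], or = 1, lo = NA_real_,
              hi = NA_real_, se = NA_real_, p = NA_real_)
          } else if (nm %in% names(beta)) {
            b <- beta[[nm]]; s <- se[[nm]]
            rows[[length(rows) + 1L]] <- data.frame(
              covariate = cv, level = levs[li], or = exp(b),
              lo = exp(b - z * s), hi = exp(b + z * s),
              se = exp(b) * s,  # delta-method SE on the OR scale
              p = 2 * stats::pnorm(-abs(b / s)))
          }
        }
      } else if (cv %in% names(beta)) {
        b <- beta[[cv]]; s <- se[[cv]]
        rows[[length(rows) + 1L]] <- data.frame(
          covariate = cv, level = "", or = exp(b),
          lo = exp(b - z * s), hi = exp(b + z * s), se = exp(b) * s,
          p = 2 * stats::pnorm(-abs(b / s)))
      }
    }
    do.call(rbind, rows)
  }

  if (adjusted) {
    fit <- fit_one(covariates)
    tab <- or_rows(fit, covariates)
    fits <- list(joint = fit)
  } else {
    fits <- lapply(covariates, function(cv) fit_one(cv))
    names(fits) <- covariates
    tab <- do.call(rbind, Map(or_rows, fits, covariates))
  }
  tab$adjusted <- adjusted
  rownames(tab) <- NULL
  structure(list(table = tab, fits = fits, adjusted = adjusted,
                 level = level, n = nrow(d)),
            class = "delivery_fit")
}

#' @export
print.delivery_fit <- function(x, digits = 3, ...) {
  cat(sprintf("%s logistic regression for institutional delivery (n = %d)\n",
              if (x$adjusted) "Adjusted" else "Unadjusted", x$n))
  tab <- x$table
  tab$or <- round(tab$or, digits)
  tab$lo <- round(tab$lo, digits)
  tab$hi <- round(tab$hi, digits)
  tab$p <- signif(tab$p, digits)
  print(tab[, c("covariate", "level", "or", "lo", "hi", "p")],
        row.names = FALSE)
  invisible(x)
}

#' @export
coef.delivery_fit <- function(object, ...) {
  if (object$adjusted) stats::coef(object$fits$joint)
  else lapply(object$fits, stats::coef)
}
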