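test_that("index difference test reproduces tabulated survey comparisons", {
  # ANC unadjusted, 2008 vs 2013
  t1 <- ci_difference_test(list(estimate = 0.009612, se = 0.000584),
                           list(estimate = 0.002264, se = 0.000351))
  expect_equal(round(unname(t1$statistic), 2), 10.78)
  expect_lt(t1$p.value, 0.001)
  # PNC unadjusted
  t2 <- ci_difference_test(list(estimate = -0.000386, se = 0.000133),
                           list(estimate = -0.001769, se = 0.000158))
  expect_equal(round(unname(t2$statistic), 2), 6.70)
  # identical estimates
  t3 <- ci_difference_test(list(estimate = 0.01, se = 0.002),
                           list(estimate = 0.01, se = 0.002))
  expect_equal(unname(t3$statistic), 0)
  expect_equal(t3$p.value, 1)
})

test_that("index difference test is symmetric and validates inputs", {
  a <- list(estimate = 0.02, se = 0.004)
  b <- list(estimate = -0.01, se = 0.003)
  expect_equal(ci_difference_test(a, b)$statistic,
               ci_difference_test(b, a)$statistic)
  expect_error(ci_difference_test(list(estimate = 1, se = NA), b), "standard error")
  # accepts fitted concindex objects directly
  set.seed(2)
  d <- data.frame(h = rpois(200, 3), wealth = rnorm(200))
  f <- concindex(h ~ wealth, d)
  expect_s3_class(ci_difference_test(f, b), "htest")
})

test_that("odds-ratio equality test matches the OR-scale convention", {
  t1 <- or_equality_test(3.24, 0.340, 2.55, 0.177)
  expect_equal(round(unname(t1$statistic), 2), 1.80)
  expect_equal(round(t1$p.value, 4), 0.0359)
  # hand arithmetic: 1.0 / sqrt(0.09 + 0.16) = 2
  t2 <- or_equality_test(2.0, 0.3, 1.0, 0.4)
  expect_equal(unname(t2$statistic), 2)
  # equal odds ratios: one-sided p is exactly one half
  t3 <- or_equality_test(1.5, 0.2, 1.5, 0.3)
  expect_equal(unname(t3$statistic), 0)
  expect_equal(t3$p.value, 0.5)
  # log-scale variant differs in general
  t4 <- or_equality_test(3.24, 0.340, 2.55, 0.177, scale = "log")
  expect_false(isTRUE(all.equal(t4$statistic, t1$statistic)))
  expect_error(or_equality_test(-1, 0.1, 2, 0.1), "positive")
  expect_error(or_equality_test(1, 0, 2, 0), "zero")
})

test_that("confidence bounds reconstruct as estimate +/- 1.96 SE", {
  reconstruct <- function(est, se) round(est + c(-1, 1) * qnorm(0.975) * se, 6)
  expect_equal(reconstruct(0.008331, 0.000073), c(0.008188, 0.008474))
  expect_equal(reconstruct(-0.001771, 0.000004), c(-0.001779, -0.001763))
})

test_that("logistic model recovers a known wealth effect on delivery", {
  g <- 1.2
  pop <- generate_population(
    population_config(n_clusters = 460, wealth_gradient_delivery = g,
                      seed = 19))
  fit <- fit_delivery_model(pop, adjusted = TRUE, wealth_as = "rank",
                            covariates = c("wealth_rank", "education",
                                           "residence"))
  beta <- coef(fit)
  se <- sqrt(diag(vcov(fit$fits$joint)))
  expect_lt(abs(beta[["wealth_rank"]] - g), 3 * se[["wealth_rank"]])
})

test_that("logistic fit reports reference-level and per-level odds ratios", {
  pop <- generate_population(small_config(seed = 23))
  fit <- fit_delivery_model(pop, adjusted = TRUE)
  tab <- fit$table
  ref <- tab[tab$covariate == "wealth_quintile" & tab$level == "poorest", ]
  expect_equal(ref$or, 1)
  rich <- tab[tab$covariate == "wealth_quintile" & tab$level == "richest", ]
  expect_gt(rich$or, 1)             # positive gradient by construction
  expect_true(all(tab$lo <= tab$or & tab$or <= tab$hi, na.rm = TRUE))
  # unadjusted: one model per covariate, same table schema
  un <- fit_delivery_model(pop, adjusted = FALSE)
  expect_equal(names(un$table), names(tab))
  expect_false(un$table$adjusted[1])
})

test_that("constant outcome raises a degenerate-fit error", {
  pop <- generate_population(small_config(seed = 29))
  pop$delivered_in_facility <- 1L
  expect_error(fit_delivery_model(pop), "constant|separation")
})

test_that("odds-ratio confidence intervals cover the null for an unrelated covariate", {
  set.seed(47)
  cover <- 0L
  reps <- 100L
  for (i in seq_len(reps)) {
    n <- 500L
    d <- data.frame(
      delivered_in_facility = rbinom(n, 1, 0.4),
      noise = factor(sample(c("a", "b"), n, TRUE)))
    fit <- fit_delivery_model(d, adjusted = TRUE, wealth_as = "none",
                              covariates = "noise")
    row <- fit$table[fit$table$level == "b", ]
    cover <- cover + (row$lo <= 1 && 1 <= row$hi)
  }
  expect_gte(cover / reps, 0.89)
})
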