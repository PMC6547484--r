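test_that("fractional ranks are weighted mid-ranks", {
  expect_equal(fractional_rank(1:4), c(0.125, 0.375, 0.625, 0.875))
  # hand cumulative sums: 0.4/2, 0.4+0.05, 0.5+0.1, 0.7+0.15
  expect_equal(fractional_rank(1:4, c(0.4, 0.1, 0.2, 0.3)),
               c(0.20, 0.45, 0.60, 0.85))
  expect_equal(fractional_rank(7), 0.5)
  # original record order is preserved
  expect_equal(fractional_rank(c(3, 1, 2)), c(0.8333333, 0.1666667, 0.5),
               tolerance = 1e-6)
})

test_that("tied wealth scores share the midpoint of their weight span", {
  r <- fractional_rank(c(1, 2, 2, 3), c(0.25, 0.25, 0.25, 0.25))
  expect_equal(r, c(0.125, 0.5, 0.5, 0.875))
  # invariance to record order within the tied block, unequal weights
  r1 <- fractional_rank(c(1, 2, 2, 3), c(0.1, 0.1, 0.3, 0.5))
  r2 <- fractional_rank(c(1, 2, 2, 3), c(0.1, 0.3, 0.1, 0.5))
  expect_equal(r1[2], r1[3])
  expect_equal(sort(r1), sort(r2))
})

test_that("ranks and weights are validated", {
  expect_error(fractional_rank(numeric(0)), "empty")
  expect_error(fractional_rank(1:3, c(1, -1, 1)), "positive")
  expect_error(ranked_outcome(1:3, wealth = 1:3, weights = 1:2), "length")
  expect_error(ranked_outcome(1:3, ranks = c(0, 0.5, 0.7)), "strictly")
})

test_that("concentration curve accumulates outcome shares", {
  ro <- ranked_outcome(1:5, wealth = 1:5)
  cc <- concentration_curve(ro)
  expect_equal(cc$p, seq(0, 1, by = 0.2))
  expect_equal(cc$L, c(0, 1, 3, 6, 10, 15) / 15)
  # constant outcome: curve is the line of equality
  flat <- concentration_curve(ranked_outcome(rep(2, 10), wealth = 1:10))
  expect_equal(flat$L, flat$p)
  # all outcome mass on the richest individual
  ext <- concentration_curve(ranked_outcome(c(0, 0, 0, 1), wealth = 1:4))
  expect_equal(ext$L, c(0, 0, 0, 0, 1))
})

test_that("quintile-grouped curve has five interior points", {
  ro <- ranked_outcome(1:10, wealth = 1:10)
  cc <- concentration_curve(ro, grouping = "quintile")
  expect_equal(nrow(cc), 6L)
  expect_equal(cc$p, seq(0, 1, by = 0.2))
  expect_equal(cc$L, c(0, cumsum(c(3, 7, 11, 15, 19)) / 55))
})

test_that("the three estimation routes agree on the worked example", {
  ro <- ranked_outcome(1:5, wealth = 1:5)
  # hand arithmetic: 2 * cov_w(h, r) / mu = 2 * 0.4 / 3 = 4/15
  expect_equal(ci_covariance(ro)$estimate, 4 / 15)
  reg <- suppressWarnings(ci_regression(ro))
  expect_equal(reg$estimate, 4 / 15)
  expect_equal(ci_area(concentration_curve(ro))$estimate, 4 / 15)
})

test_that("regression and covariance routes are algebraically identical", {
  set.seed(424)
  for (i in 1:25) {
    ro <- random_ranked(sample(5:300, 1))
    expect_equal(ci_regression(ro)$estimate, ci_covariance(ro)$estimate,
                 tolerance = 1e-10)
  }
})

test_that("curve-area route converges to the covariance route", {
  set.seed(77)
  for (n in c(100, 1000, 10000)) {
    ro <- random_ranked(n)
    a <- ci_area(concentration_curve(ro))$estimate
    b <- ci_covariance(ro)$estimate
    expect_lt(abs(a - b), 2 / n)
  }
})

test_that("index obeys sign, bound and invariance properties", {
  set.seed(99)
  for (i in 1:10) {
    n <- sample(10:200, 1)
    h <- stats::rpois(n, 3)
    wealth <- stats::rnorm(n)
    w <- stats::runif(n, 0.5, 2)
    if (sum(h) == 0) h[1] <- 1
    ro <- ranked_outcome(h, wealth = wealth, weights = w)
    est <- ci_covariance(ro)$estimate
    expect_lte(abs(est), 1)
    # wealth-order reversal flips the sign
    flip <- ci_covariance(ranked_outcome(h, wealth = -wealth, weights = w))
    expect_equal(flip$estimate, -est, tolerance = 1e-12)
    # invariant to weight rescaling and positive outcome rescaling
    resc <- ci_covariance(ranked_outcome(3.7 * h, wealth = wealth,
                                         weights = 10 * w))
    expect_equal(resc$estimate, est, tolerance = 1e-12)
    # permutation of record order
    p <- sample(n)
    perm <- ci_covariance(ranked_outcome(h[p], wealth = wealth[p],
                                         weights = w[p]))
    expect_equal(perm$estimate, est, tolerance = 1e-12)
  }
})

test_that("constant outcome yields a zero index", {
  ro <- ranked_outcome(rep(4, 20), wealth = rnorm(20))
  expect_equal(ci_covariance(ro)$estimate, 0)
  expect_equal(suppressWarnings(ci_regression(ro))$estimate, 0,
               tolerance = 1e-12)
})

test_that("degenerate inputs are rejected", {
  expect_error(ci_covariance(ranked_outcome(c(0, 0), wealth = 1:2)),
               "not positive")
  expect_error(ci_regression(ranked_outcome(1:3, wealth = c(1, 1, 1))),
               "degenerate rank variance")
  expect_error(concentration_curve(ranked_outcome(c(0, 0), wealth = 1:2)),
               "not positive")
})

test_that("dominance classifies curve pairs", {
  ro <- ranked_outcome(1:5, wealth = 1:5)
  ca <- concentration_curve(ro)
  expect_equal(dominance(ca, ca), "coincide")
  # closer to equality dominates
  cb <- concentration_curve(ranked_outcome(c(1, 1, 1, 1, 2), wealth = 1:5))
  expect_equal(dominance(cb, ca), "a_dominates")
  expect_equal(dominance(ca, cb), "b_dominates")
  # constructed single-crossing pair
  cx <- concentration_curve(ranked_outcome(c(0.2, 3, 2, 1, 1), wealth = 1:5))
  expect_equal(dominance(cx, ca), "cross")
})

test_that("concindex fitting function wraps the estimators", {
  d <- data.frame(visits = c(1, 2, 3, 4, 5), wealth = 1:5,
                  wt = c(1, 1, 1, 1, 1))
  fit <- suppressWarnings(concindex(visits ~ wealth, d))
  expect_s3_class(fit, "concindex")
  expect_equal(unname(coef(fit)), 4 / 15)
  expect_equal(fit$method, "regression")
  expect_false(fit$adjusted)
  carea <- concindex(visits ~ wealth, d, method = "area")
  expect_equal(carea$estimate, 4 / 15)
  expect_true(is.na(carea$se))
  expect_error(confint(carea), "regression")
  # weights as a column name
  fit2 <- suppressWarnings(concindex(visits ~ wealth, d, weights = "wt"))
  expect_equal(fit2$estimate, fit$estimate)
})

test_that("concindex summary and confint are normal-theory", {
  set.seed(5)
  d <- data.frame(h = rpois(400, 4), wealth = rnorm(400))
  fit <- concindex(h ~ wealth, d)
  s <- summary(fit)
  expect_equal(s$z, fit$estimate / fit$se)
  expect_equal(unname(confint(fit)[1, ]),
               fit$estimate + c(-1, 1) * qnorm(0.975) * fit$se)
  expect_equal(length(residuals(fit)), 400L)
})
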