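test_that("configuration validation names the offending field", {
  expect_error(population_config(urban_fraction = 1.4), "urban_fraction")
  expect_error(population_config(n_clusters = 0), "n_clusters")
  expect_error(population_config(wealth_gradient_anc = Inf),
               "wealth_gradient_anc")
  expect_error(population_config(
    covariate_prevalences = list(education = c(none = 0.5, primary = 0.2,
                                               secondary = 0.2,
                                               higher = 0.2))),
    "covariate_prevalences\\$education")
  expect_error(population_config(baseline_rates = list(anc = -1, pnc = 0.5,
                                                       delivery = 0.3)),
               "baseline_rates\\$anc")
})

test_that("identical seed and config reproduce the record stream", {
  cfg <- small_config(seed = 42)
  expect_identical(generate_population(cfg), generate_population(cfg))
  # a different seed changes the draw
  expect_false(identical(generate_population(cfg),
                         generate_population(small_config(seed = 43))))
})

test_that("generated records satisfy the record contract", {
  pop <- generate_population(small_config(seed = 8))
  expect_true(all(pop$sampling_weight > 0))
  expect_equal(mean(pop$sampling_weight), 1, tolerance = 1e-12)
  expect_true(all(pop$anc_visits >= 0))
  expect_true(all(unlist(pop[, c("pnc_post_delivery", "pnc_pre_discharge",
                                 "pnc_week_after", "pnc_six_weeks")])
                  %in% 0:1))
  expect_true(all(pop$delivered_in_facility %in% 0:1))
  expect_equal(anyNA(pop), FALSE)
  # urban clusters are wealthier on average (the built-in confounder)
  expect_gt(mean(pop$wealth_score[pop$residence == "urban"]),
            mean(pop$wealth_score[pop$residence == "rural"]))
})

test_that("weighted covariate proportions match the configured prevalences", {
  cfg <- population_config(n_clusters = 1200, seed = 5)
  pop <- generate_population(cfg)
  w <- pop$sampling_weight / sum(pop$sampling_weight)
  for (cov in c("education", "religion", "occupation")) {
    target <- cfg$covariate_prevalences[[cov]]
    got <- tapply(w, pop[[cov]], sum, default = 0)
    for (lv in names(target)) {
      mc_se <- sqrt(target[[lv]] * (1 - target[[lv]]) / nrow(pop)) *
        sqrt(1 + stats::var(w * nrow(pop)))   # weight design effect
      expect_lt(abs(got[[lv]] - target[[lv]]), 3 * mc_se + 1e-3)
    }
  }
})

test_that("a zero gradient yields no concentration and a positive one a rich-poor gap", {
  flat <- generate_population(
    population_config(n_clusters = 1200, wealth_gradient_anc = 0, seed = 9,
                      covariate_effects = FALSE))
  est <- anc_estimate(flat)
  expect_lt(abs(est$estimate), 3 * est$se + 0.005)

  pop <- generate_population(
    population_config(n_clusters = 600, wealth_gradient_delivery = 1.5,
                      seed = 10))
  q <- assign_quintiles(pop$wealth_score, pop$sampling_weight)
  w <- pop$sampling_weight
  rate <- function(lv) weighted.mean(pop$delivered_in_facility[q == lv],
                                     w[q == lv])
  expect_gt(rate("richest"), rate("poorest"))
})

test_that("gradient calibration hits and signs its target", {
  cal_cfg <- population_config(n_clusters = 800, seed = 21)
  g0 <- calibrate_gradient_to_ci(0, homogeneous_config(seed = 21,
                                                       n_clusters = 800))
  expect_lt(abs(g0), 0.05)
  g_neg <- calibrate_gradient_to_ci(-0.05, cal_cfg)
  expect_lt(g_neg, 0)
  g_pos <- calibrate_gradient_to_ci(0.10, cal_cfg, tol = 0.003)
  fresh <- population_config(n_clusters = 1500, seed = 77,
                             wealth_gradient_anc = g_pos)
  est <- anc_estimate(generate_population(fresh))
  expect_lt(abs(est$estimate - 0.10), 0.015)
  expect_error(calibrate_gradient_to_ci(0.9, cal_cfg, bounds = c(-1, 1)),
               "unreachable")
})

test_that("records and configuration round-trip through flat files", {
  cfg <- small_config(seed = 2)
  pop <- generate_population(cfg)
  tmp <- tempfile(fileext = ".tsv")
  write_population(pop, tmp)
  back <- read_population(tmp)
  expect_equal(back, pop)
  tmpc <- tempfile(fileext = ".yaml")
  write_config(cfg, tmpc)
  cfg2 <- read_config(tmpc)
  expect_equal(unclass(cfg2), unclass(cfg))
  expect_equal(generate_population(cfg2), pop)
  unlink(c(tmp, tmpc))
})
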