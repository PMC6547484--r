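#' Configuration for the synthetic DHS-like survey generator
#'
#' Describes a two-stage cluster-sampled household survey of women of
#' reproductive age: enumeration areas (EAs) are drawn from urban and rural
#' strata, a fixed number of households is sampled within each listed EA,
#' and each sampled household contributes an eligible woman with some
#' probability. Sampling weights are the inverse selection probabilities of
#' the two stages, normalized to mean one. Outcomes (ANC visit count, the
#' four postnatal-review components, institutional delivery) are drawn from
#' generalized-linear models whose linear predictors contain a configurable
#' wealth-rank gradient plus modest covariate effects, so the wealth-related
#' inequity of every outcome is known by construction.
#'
#' @param n_clusters number of sampled EAs (survey design: 353, of which
#'   145 urban).
#' @param households_per_cluster households listed per EA (85) — the
#'   denominator of the within-EA selection probability.
#' @param households_sampled households sampled per EA (22).
#' @param urban_fraction fraction of sampled EAs that are urban (145/353).
#' @param frame_clusters named vector `c(urban =, rural =)` of EA counts in
#'   the sampling frame; urban EAs are oversampled relative to the frame, so
#'   the weights down-weight urban respondents to roughly 30% of the
#'   weighted population.
#' @param eligible_prob probability a sampled household contributes one
#'   woman with a birth in the recall window.
#' @param covariate_prevalences named list of per-level proportions for
#'   `education`, `occupation`, `ethnicity`, `religion`, `age_band`; each
#'   must sum to one. Defaults mimic a West-African DHS profile (about
#'   70% no education, 80% Muslim).
#' @param wealth_gradient_anc,wealth_gradient_pnc,wealth_gradient_delivery
#'   effect of the centred fractional wealth rank on the linear predictor of
#'   each outcome (log scale for the ANC count, log-odds for the
#'   postnatal-review components and facility delivery).
#' @param baseline_rates named list: `anc` (mean visit count at the rank
#'   midpoint), `pnc` (probability each review component is attended),
#'   `delivery` (facility-delivery probability).
#' @param urban_wealth_shift additive urban shift of the log-normal wealth
#'   score.
#' @param covariate_effects logical; include the built-in covariate effects
#'   (education, residence) in the outcome models. Disable for a
#'   homogeneous population in which outcomes depend on wealth rank only.
#' @param n_children_mean mean of the Poisson number of children.
#' @param survey_year year label stamped on the records.
#' @param seed root seed; per-cluster substreams are derived from it so the
#'   first clusters are unchanged when `n_clusters` grows.
#' @return validated object of class `population_config`.
#' @export
population_config <- function(n_clusters = 353,
                              households_per_cluster = 85,
                              households_sampled = 22,
                              urban_fraction = 145 / 353,
                              frame_clusters = c(urban = 3000, rural = 7000),
                              eligible_prob = 0.5,
                              covariate_prevalences = NULL,
                              wealth_gradient_anc = 0.3,
                              wealth_gradient_pnc = 0.5,
                              wealth_gradient_delivery = 1.0,
                              baseline_rates = list(anc = 4.3, pnc = 0.55,
                                                    delivery = 0.35),
                              urban_wealth_shift = 1.5,
                              covariate_effects = TRUE,
                              n_children_mean = 2.7,
                              survey_year = 2008,
                              seed = 1L) {
  defaults <- list(
    education = c(none = 0.70, primary = 0.13, secondary = 0.15,
                  higher = 0.02),
    occupation = c(yes = 0.74, no = 0.26),
    ethnicity = c(group_A = 0.44, group_B = 0.40, other = 0.16),
    religion = c(christianity = 0.19, islam = 0.80, other = 0.01),
    age_band = c(`15-19` = 0.09, `20-24` = 0.21, `25-29` = 0.24,
                 `30-34` = 0.19, `35-39` = 0.16, `40-44` = 0.06,
                 `45-49` = 0.05)
  )
  if (is.null(covariate_prevalences)) covariate_prevalences <- defaults
  for (nm in names(defaults)) {
    if (is.null(covariate_prevalences[[nm]]))
      covariate_prevalences[[nm]] <- defaults[[nm]]
  }
  cfg <- list(
    n_clusters = check_count(n_clusters, "n_clusters"),
    households_per_cluster = check_count(households_per_cluster,
                                         "households_per_cluster"),
    households_sampled = check_count(households_sampled, "households_sampled"),
    urban_fraction = check_prob(urban_fraction, "urban_fraction"),
    frame_clusters = frame_clusters,
    eligible_prob = check_prob(eligible_prob, "eligible_prob"),
    covariate_prevalences = covariate_prevalences,
    wealth_gradient_anc = check_real(wealth_gradient_anc,
                                     "wealth_gradient_anc"),
    wealth_gradient_pnc = check_real(wealth_gradient_pnc,
                                     "wealth_gradient_pnc"),
    wealth_gradient_delivery = check_real(wealth_gradient_delivery,
                                          "wealth_gradient_delivery"),
    baseline_rates = baseline_rates,
    urban_wealth_shift = check_real(urban_wealth_shift, "urban_wealth_shift"),
    covariate_effects = isTRUE(covariate_effects),
    n_children_mean = check_real(n_children_mean, "n_children_mean"),
    survey_year = check_real(survey_year, "survey_year"),
    seed = check_count(seed, "seed")
  )
  if (cfg$households_sampled > cfg$households_per_cluster)
    stop_field("households_sampled",
               "cannot exceed households_per_cluster")
  if (length(frame_clusters) != 2L ||
      !all(c("urban", "rural") %in% names(frame_clusters)) ||
      any(frame_clusters < 1))
    stop_field("frame_clusters",
               "must be a named vector c(urban =, rural =) of positive counts")
  for (nm in names(cfg$covariate_prevalences)) {
    p <- cfg$covariate_prevalences[[nm]]
    if (any(p < 0) || any(p > 1) || abs(sum(p) - 1) > 1e-8)
      stop_field(paste0("covariate_prevalences$", nm),
                 "levels must be proportions summing to 1")
  }
  br <- cfg$baseline_rates
  if (!all(c("anc", "pnc", "delivery") %in% names(br)))
    stop_field("baseline_rates", "must name anc, pnc and delivery")
  if (br$anc <= 0) stop_field("baseline_rates$anc", "must be positive")
  check_prob(br$pnc, "baseline_rates$pnc")
  check_prob(br$delivery, "baseline_rates$delivery")
  structure(cfg, class = "population_config")
}

#' @export
print.population_config <- function(x, ...) {
  cat("Synthetic survey configuration\n")
  cat(sprintf("  clusters: %d (%.0f%% urban), %d/%d households sampled\n",
              x$n_clusters, 100 * x$urban_fraction, x$households_sampled,
              x$households_per_cluster))
  cat(sprintf("  wealth gradients: ANC %.3f, PNC %.3f, delivery %.3f\n",
              x$wealth_gradient_anc, x$wealth_gradient_pnc,
              x$wealth_gradient_delivery))
  cat(sprintf("  year %d, seed %d\n", as.integer(x$survey_year), x$seed))
  invisible(x)
}

#' Generate a synthetic two-stage cluster-sampled survey
#'
#' Draws enumeration areas, households and women per the configuration and
#' returns one row per woman with design variables (cluster id, stratum,
#' sampling weight), a continuous wealth score, sociodemographic covariates,
#' and the three maternal-health outcomes. The same configuration and seed
#' always reproduce the identical data frame.
#'
#' @param config a [population_config()].
#' @return data frame with one row per woman: `record_id`, `cluster_id`,
#'   `survey_year`, `sampling_weight`, `wealth_score`, `residence`,
#'   `education`, `occupation`, `ethnicity`, `religion`, `age_band`,
#'   `n_children`, `anc_visits`, `pnc_post_delivery`, `pnc_pre_discharge`,
#'   `pnc_week_after`, `pnc_six_weeks`, `delivered_in_facility`.
#' @export
generate_population <- function(config) {
  stopifnot(inherits(config, "population_config"))
  cfg <- config
  n_urban <- round(cfg$n_clusters * cfg$urban_fraction)
  stratum <- rep(c("urban", "rural"),
                 c(n_urban, cfg$n_clusters - n_urban))
  # EA selection probability per stratum (EAs sampled / EAs in frame);
  # household stage is households_sampled / households_per_cluster
  p_ea <- c(urban = n_urban / cfg$frame_clusters[["urban"]],
            rural = (cfg$n_clusters - n_urban) / cfg$frame_clusters[["rural"]])
  p_hh <- cfg$households_sampled / cfg$households_per_cluster
  old <- rng_snapshot()
  on.exit(rng_restore(old))
  set.seed(cfg$seed)
  cluster_seeds <- sample.int(.Machine$integer.max - 1L, cfg$n_clusters)
  prev <- cfg$covariate_prevalences
  pieces <- vector("list", cfg$n_clusters)
  for (k in seq_len(cfg$n_clusters)) {
    set.seed(cluster_seeds[k])
    urb <- stratum[k] == "urban"
    n_w <- stats::rbinom(1L, cfg$households_sampled, cfg$eligible_prob)
    if (n_w == 0L) next
    pieces[[k]] <- list(
      cluster_id = rep.int(k, n_w),
      wealth_score = stats::rlnorm(n_w) +
        if (urb) cfg$urban_wealth_shift else 0,
      education = sample(names(prev$education), n_w, TRUE, prev$education),
      occupation = sample(names(prev$occupation), n_w, TRUE,
                          prev$occupation),
      ethnicity = sample(names(prev$ethnicity), n_w, TRUE, prev$ethnicity),
      religion = sample(names(prev$religion), n_w, TRUE, prev$religion),
      age_band = sample(names(prev$age_band), n_w, TRUE, prev$age_band),
      n_children = stats::rpois(n_w, cfg$n_children_mean),
      # reserved uniform draws: outcome models consume these after the
      # population-level wealth rank is known, so each woman's outcome
      # depends only on her own stream plus her rank
      u_anc = stats::runif(n_w),
      u_del = stats::runif(n_w),
      u_p1 = stats::runif(n_w),
      u_p2 = stats::runif(n_w),
      u_p3 = stats::runif(n_w),
      u_p4 = stats::runif(n_w)
    )
  }
  pieces <- pieces[!vapply(pieces, is.null, logical(1))]
  if (length(pieces) == 0L)
    stop("generated population is empty; increase n_clusters or eligible_prob",
         call. = FALSE)
  pull <- function(fld) unlist(lapply(pieces, `[[`, fld), use.names = FALSE)
  cluster_id <- pull("cluster_id")
  out <- data.frame(
    cluster_id = cluster_id,
    survey_year = as.integer(cfg$survey_year),
    sampling_weight = unname(1 / (p_ea[stratum[cluster_id]] * p_hh)),
    wealth_score = pull("wealth_score"),
    residence = factor(stratum[cluster_id], levels = c("urban", "rural")),
    education = factor(pull("education"), levels = names(prev$education)),
    occupation = factor(pull("occupation"),
                        levels = names(prev$occupation)),
    ethnicity = factor(pull("ethnicity"), levels = names(prev$ethnicity)),
    religion = factor(pull("religion"), levels = names(prev$religion)),
    age_band = factor(pull("age_band"), levels = names(prev$age_band)),
    n_children = pull("n_children"),
    u_anc = pull("u_anc"), u_del = pull("u_del"),
    u_p1 = pull("u_p1"), u_p2 = pull("u_p2"),
    u_p3 = pull("u_p3"), u_p4 = pull("u_p4"),
    stringsAsFactors = FALSE
  )
  out$record_id <- seq_len(nrow(out))
  out$sampling_weight <- out$sampling_weight / mean(out$sampling_weight)

  # wealth rank across the whole weighted sample, centred at 0
  rank_c <- fractional_rank(out$wealth_score, out$sampling_weight) - 0.5

  # modest covariate effects; residence is the built-in confounder because
  # it also shifts the wealth distribution
  edu_num <- as.integer(out$education) - 1L    # 0..3
  rural <- as.integer(out$residence == "rural")
  eff_anc <- if (cfg$covariate_effects) 0.05 * edu_num - 0.08 * rural else 0
  eff_bin <- if (cfg$covariate_effects) 0.15 * edu_num - 0.25 * rural else 0

  br <- cfg$baseline_rates
  lam <- exp(log(br$anc) + cfg$wealth_gradient_anc * rank_c + eff_anc)
  out$anc_visits <- stats::qpois(out$u_anc, lam)
  p_pnc <- stats::plogis(stats::qlogis(br$pnc) +
                           cfg$wealth_gradient_pnc * rank_c + eff_bin)
  comps <- c("pnc_post_delivery", "pnc_pre_discharge", "pnc_week_after",
             "pnc_six_weeks")
  us <- c("u_p1", "u_p2", "u_p3", "u_p4")
  for (j in seq_along(comps)) {
    out[[comps[j]]] <- as.integer(out[[us[j]]] < p_pnc)
  }
  p_del <- stats::plogis(stats::qlogis(br$delivery) +
                           cfg$wealth_gradient_delivery * rank_c + eff_bin)
  out$delivered_in_facility <- as.integer(out$u_del < p_del)
  out[c("u_anc", "u_del", us)] <- NULL
  cols <- c("record_id", "cluster_id", "survey_year", "sampling_weight",
            "wealth_score", "residence", "education", "occupation",
            "ethnicity", "religion", "age_band", "n_children", "anc_visits",
            "pnc_post_delivery", "pnc_pre_discharge", "pnc_week_after",
            "pnc_six_weeks", "delivered_in_facility")
  out[, cols]
}

rng_snapshot <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

rng_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Find the wealth gradient that produces a target concentration index
#'
#' Monotone bisection over the wealth-gradient parameter of one outcome: at
#' each candidate gradient a large population is generated under the given
#' configuration (fixed seed, so the search sees a smooth monotone curve)
#' and its concentration index is measured with the covariance formula; the
#' bracket is narrowed until the achieved index is within `tol` of
#' `target_ci`.
#'
#' @param target_ci desired concentration index, `|target_ci| < 1`.
#' @param config a [population_config()]; its `n_clusters` is used as the
#'   calibration sample size, so configure a generously sized population.
#' @param outcome which outcome's gradient to calibrate: `"anc"` (visit
#'   count), `"pnc"` (number of reviews), or `"delivery"`.
#' @param bounds search interval for the gradient.
#' @param tol absolute tolerance on the achieved concentration index.
#' @param max_iter bisection iteration cap.
#' @return the calibrated gradient (a single number).
#' @export
calibrate_gradient_to_ci <- function(target_ci, config, outcome = "anc",
                                     bounds = c(-6, 6), tol = 0.002,
                                     max_iter = 60L) {
  stopifnot(inherits(config, "population_config"))
  if (!is.finite(target_ci) || abs(target_ci) >= 1)
    stop("`target_ci` must satisfy |target_ci| < 1", call. = FALSE)
  outcome <- match.arg(outcome, c("anc", "pnc", "delivery"))
  field <- paste0("wealth_gradient_", outcome)
  measure <- function(g) {
    cfg <- config
    cfg[[field]] <- g
    pop <- generate_population(cfg)
    h <- switch(outcome,
                anc = pop$anc_visits,
                pnc = pop$pnc_post_delivery + pop$pnc_pre_discharge +
                  pop$pnc_week_after + pop$pnc_six_weeks,
                delivery = pop$delivered_in_facility)
    ro <- ranked_outcome(h, wealth = pop$wealth_score,
                         weights = pop$sampling_weight)
    ci_covariance(ro)$estimate
  }
  lo <- bounds[1]; hi <- bounds[2]
  f_lo <- measure(lo); f_hi <- measure(hi)
  if ((f_lo - target_ci) * (f_hi - target_ci) > 0)
    stop(sprintf(
      "target_ci %.4f unreachable: achievable range on [%.1f, %.1f] is [%.4f, %.4f]",
      target_ci, lo, hi, min(f_lo, f_hi), max(f_lo, f_hi)), call. = FALSE)
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    f_mid <- measure(mid)
    if (abs(f_mid - target_ci) < tol) return(mid)
    if ((f_lo - target_ci) * (f_mid - target_ci) <= 0) {
      hi <- mid; f_hi <- f_mid
    } else {
      lo <- mid; f_lo <- f_mid
    }
  }
  (lo + hi) / 2
}

#' Write and read survey records and configurations
#'
#' Records round-trip through a tab-separated flat file with a header row;
#' configurations through a YAML file. `read_population()` restores column
#' classes (factors with their level order) so a written file reloads to an
#' identical data frame.
#'
#' @param records data frame from [generate_population()].
#' @param path file path.
#' @rdname survey-io
#' @export
write_population <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname survey-io
#' @export
read_population <- function(path) {
  out <- utils::read.delim(path, stringsAsFactors = FALSE)
  out$residence <- factor(out$residence, levels = c("urban", "rural"))
  out$education <- factor(out$education,
                          levels = c("none", "primary", "secondary", "higher"))
  out$occupation <- factor(out$occupation, levels = c("yes", "no"))
  out$ethnicity <- factor(out$ethnicity,
                          levels = c("group_A", "group_B", "other"))
  out$religion <- factor(out$religion,
                         levels = c("christianity", "islam", "other"))
  out$age_band <- factor(out$age_band,
                         levels = c("15-19", "20-24", "25-29", "30-34",
                                    "35-39", "40-44", "45-49"))
  out
}

#' @param config a [population_config()].
#' @rdname survey-io
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "population_config"))
  x <- unclass(config)
  x$frame_clusters <- as.list(x$frame_clusters)
  x$covariate_prevalences <- lapply(x$covariate_prevalences, as.list)
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' @rdname survey-io
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$frame_clusters <- unlist(x$frame_clusters)
  x$covariate_prevalences <- lapply(x$covariate_prevalences, unlist)
  do.call(population_config, x)
}
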