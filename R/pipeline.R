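#' Run the full inequity analysis for one survey
#'
#' Orchestrates one survey round end-to-end: simulate (or accept) the
#' records, derive the analysis variables (ANC category, postnatal-review
#' count and completeness, weighted wealth quintiles), estimate unadjusted
#' and covariate-standardized concentration indices for the ANC visit count
#' and the postnatal-review count, build their concentration curves, and fit
#' the adjusted and unadjusted logistic models for institutional delivery.
#'
#' @param config a [population_config()]; ignored when `data` is supplied
#'   except as metadata.
#' @param data optional pre-generated/ingested record data frame in the
#'   layout of [generate_population()].
#' @param controls one-sided formula of standardization controls.
#' @param grouping concentration-curve construction.
#' @param out optional directory; when given, curve files (two-column TSV),
#'   the estimate table, the odds-ratio table, the records and a YAML run
#'   manifest are written there.
#' @return object of class `survey_bundle`: list with `records`,
#'   `estimates` (data frame: outcome, adjusted, method, estimate, se, n),
#'   `curves` (named list of [concentration_curve()]s), `delivery`
#'   (adjusted and unadjusted [fit_delivery_model()] results), `manifest`.
#' @export
run_survey_analysis <- function(config = population_config(),
                                data = NULL,
                                controls = ~ education + occupation +
                                  residence + ethnicity + religion +
                                  age_band + n_children,
                                grouping = c("individual", "quintile"),
                                out = NULL) {
  grouping <- match.arg(grouping)
  stage <- "simulate"
  result <- tryCatch({
    if (is.null(data)) data <- generate_population(config)
    if (nrow(data) == 0L) stop("no records to analyse", call. = FALSE)

    stage <- "recode"
    data$anc_category <- recode_anc(data$anc_visits)
    pnc_cols <- c("pnc_post_delivery", "pnc_pre_discharge",
                  "pnc_week_after", "pnc_six_weeks")
    data$pnc_status <- recode_pnc(data[, pnc_cols])
    data$pnc_reviews <- rowSums(data[, pnc_cols])
    warn <- character(0)
    data$wealth_quintile <- withCallingHandlers(
      assign_quintiles(data$wealth_score, data$sampling_weight),
      warning = function(w) {
        warn <<- c(warn, conditionMessage(w))
        invokeRestart("muffleWarning")
      })

    stage <- "estimate"
    outcomes <- c(anc = "anc_visits", pnc = "pnc_reviews")
    estimates <- list()
    curves <- list()
    for (nm in names(outcomes)) {
      form <- stats::as.formula(paste(outcomes[[nm]], "~ wealth_score"))
      unadj <- concindex(form, data, weights = sampling_weight,
                         grouping = grouping)
      adj <- concindex(form, data, weights = sampling_weight,
                       grouping = grouping, adjust = controls)
      estimates[[nm]] <- data.frame(
        outcome = nm,
        adjusted = c(FALSE, TRUE),
        method = c(unadj$method, adj$method),
        estimate = c(unadj$estimate, adj$estimate),
        se = c(unadj$se, adj$se),
        n = c(unadj$n, adj$n))
      curves[[paste0(nm, "_unadjusted")]] <- unadj$curve
      curves[[paste0(nm, "_adjusted")]] <- adj$curve
    }
    estimates <- do.call(rbind, estimates)
    rownames(estimates) <- NULL

    stage <- "delivery_model"
    delivery <- list(
      adjusted = fit_delivery_model(data, adjusted = TRUE),
      unadjusted = fit_delivery_model(data, adjusted = FALSE))

    manifest <- list(
      survey_year = as.integer(config$survey_year),
      seed = config$seed,
      n_records = nrow(data),
      n_clusters = length(unique(data$cluster_id)),
      grouping = grouping,
      controls = all.vars(controls),
      warnings = warn,
      config = unclass(config))
    list(records = data, estimates = estimates, curves = curves,
         delivery = delivery, manifest = manifest)
  }, error = function(e) {
    stop(sprintf("pipeline stage `%s` failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  bundle <- structure(result, class = "survey_bundle")
  if (!is.null(out)) write_bundle(bundle, out)
  bundle
}

#' @export
print.survey_bundle <- function(x, ...) {
  cat(sprintf("Survey bundle: year %d, %d records in %d clusters\n",
              x$manifest$survey_year, x$manifest$n_records,
              x$manifest$n_clusters))
  print(x$estimates, row.names = FALSE)
  invisible(x)
}

write_bundle <- function(bundle, out) {
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(bundle$estimates, file.path(out, "estimates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (nm in names(bundle$curves)) {
    utils::write.table(as.data.frame(bundle$curves[[nm]]),
                       file.path(out, paste0("curve_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  for (side in c("adjusted", "unadjusted")) {
    utils::write.table(bundle$delivery[[side]]$table,
                       file.path(out, paste0("odds_ratios_", side, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_population(bundle$records, file.path(out, "records.tsv"))
  man <- bundle$manifest
  man$config$frame_clusters <- as.list(man$config$frame_clusters)
  man$config$covariate_prevalences <-
    lapply(man$config$covariate_prevalences, as.list)
  yaml::write_yaml(man, file.path(out, "manifest.yaml"), precision = 15)
  invisible(out)
}

rich_poor_or <- function(delivery_fit) {
  tab <- delivery_fit$table
  row <- tab[tab$covariate == "wealth_quintile" & tab$level == "richest", ]
  if (nrow(row) != 1L)
    stop("no richest-quintile odds ratio in the delivery fit", call. = FALSE)
  list(or = row$or, se = row$se)
}

#' Compare two analysed survey rounds
#'
#' Produces the between-survey comparison tables: a z test for the change
#' in each concentration index (unadjusted and standardized), the dominance
#' classification of each pair of concentration curves, and the equality
#' test for the rich-poor (richest vs poorest) institutional-delivery odds
#' ratios.
#'
#' @param bundle_a,bundle_b [run_survey_analysis()] bundles with identical
#'   outcome definitions.
#' @param sided sidedness of the concentration-index difference test.
#' @return object of class `survey_comparison`: list with `index_tests`
#'   (data frame), `dominance` (data frame) and `or_tests` (data frame).
#' @export
compare_surveys <- function(bundle_a, bundle_b, sided = c("two", "one")) {
  sided <- match.arg(sided)
  stopifnot(inherits(bundle_a, "survey_bundle"),
            inherits(bundle_b, "survey_bundle"))
  ka <- sort(unique(bundle_a$estimates$outcome))
  kb <- sort(unique(bundle_b$estimates$outcome))
  if (!identical(ka, kb))
    stop("bundles have different outcome sets: ",
         paste(union(setdiff(ka, kb), setdiff(kb, ka)), collapse = ", "),
         call. = FALSE)

  rows <- list()
  for (nm in ka) {
    for (adj in c(FALSE, TRUE)) {
      ea <- bundle_a$estimates[bundle_a$estimates$outcome == nm &
                                 bundle_a$estimates$adjusted == adj, ]
      eb <- bundle_b$estimates[bundle_b$estimates$outcome == nm &
                                 bundle_b$estimates$adjusted == adj, ]
      tst <- ci_difference_test(list(estimate = ea$estimate, se = ea$se),
                                list(estimate = eb$estimate, se = eb$se),
                                sided = sided)
      rows[[length(rows) + 1L]] <- data.frame(
        outcome = nm, adjusted = adj,
        estimate_a = ea$estimate, se_a = ea$se,
        estimate_b = eb$estimate, se_b = eb$se,
        statistic = unname(tst$statistic), p_value = tst$p.value,
        sign_reversal = sign(ea$estimate) != sign(eb$estimate))
    }
  }
  index_tests <- do.call(rbind, rows)

  dom <- do.call(rbind, lapply(names(bundle_a$curves), function(nm) {
    data.frame(curve = nm,
               dominance = dominance(bundle_a$curves[[nm]],
                                     bundle_b$curves[[nm]]))
  }))

  or_rows <- lapply(c("unadjusted", "adjusted"), function(side) {
    oa <- rich_poor_or(bundle_a$delivery[[side]])
    ob <- rich_poor_or(bundle_b$delivery[[side]])
    tst <- or_equality_test(oa$or, oa$se, ob$or, ob$se)
    data.frame(model = side, or_a = oa$or, se_a = oa$se,
               or_b = ob$or, se_b = ob$se,
               statistic = unname(tst$statistic), p_value = tst$p.value)
  })
  structure(
    list(index_tests = index_tests, dominance = dom,
         or_tests = do.call(rbind, or_rows)),
    class = "survey_comparison"
  )
}

#' @export
print.survey_comparison <- function(x, ...) {
  cat("Concentration-index change tests\n")
  print(x$index_tests, row.names = FALSE, digits = 4)
  cat("\nCurve dominance (a vs b)\n")
  print(x$dominance, row.names = FALSE)
  cat("\nRich-poor odds-ratio equality tests\n")
  print(x$or_tests, row.names = FALSE, digits = 4)
  invisible(x)
}
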