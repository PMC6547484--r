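#' Recode antenatal-care visit counts into analysis categories
#'
#' Three categories: `none` (0 visits), `up_to_four` (1-4), and
#' `more_than_four` (5+). Whether exactly four visits falls in the middle or
#' upper category is genuinely ambiguous in survey practice (the WHO focused
#' ANC benchmark is "four or more"); the default reads "more than four"
#' literally, and `four_in_upper = TRUE` switches to the WHO-style split
#' (1-3 vs 4+).
#'
#' @param anc_visits non-negative integer vector of visit counts.
#' @param four_in_upper place exactly-4 visits in `more_than_four`.
#' @return factor with levels `none`, `up_to_four`, `more_than_four`.
#' @export
recode_anc <- function(anc_visits, four_in_upper = FALSE) {
  if (any(!is.finite(anc_visits)) || any(anc_visits < 0) ||
      any(anc_visits != round(anc_visits)))
    stop("`anc_visits` must be non-negative integers", call. = FALSE)
  cut_at <- if (four_in_upper) 4 else 5
  lev <- c("none", "up_to_four", "more_than_four")
  out <- ifelse(anc_visits == 0, lev[1L],
                ifelse(anc_visits < cut_at, lev[2L], lev[3L]))
  factor(out, levels = lev)
}

#' Recode the four postnatal-review components into complete/incomplete
#'
#' A postnatal-care episode is `complete` only if all four recommended
#' reviews were attended (immediately post-delivery, before discharge, a
#' week after discharge, six weeks post-delivery); missing any one makes it
#' `incomplete`.
#'
#' @param pnc_components a matrix/data frame with four binary columns, or a
#'   length-4 vector for a single record.
#' @return factor with levels `incomplete`, `complete`.
#' @export
recode_pnc <- function(pnc_components) {
  m <- if (is.null(dim(pnc_components))) {
    matrix(pnc_components, nrow = 1)
  } else {
    as.matrix(pnc_components)
  }
  if (ncol(m) != 4L)
    stop("`pnc_components` must have exactly four components", call. = FALSE)
  if (any(!m %in% c(0, 1)))
    stop("`pnc_components` must be binary (0/1)", call. = FALSE)
  factor(ifelse(rowSums(m) == 4L, "complete", "incomplete"),
         levels = c("incomplete", "complete"))
}

#' Assign weighted wealth quintiles
#'
#' Sorts records by wealth score and cuts the cumulative normalized weight at
#' 0.2, 0.4, 0.6 and 0.8, so each quintile carries (up to one record's
#' weight) a fifth of the weighted population. A block of tied scores is
#' assigned as a unit to the quintile containing the midpoint of its
#' cumulative-weight span, making the assignment independent of record order.
#'
#' @param wealth_score numeric wealth index values.
#' @param weights positive sampling weights (default equal).
#' @return factor with levels `poorest`, `poorer`, `middle`, `richer`,
#'   `richest`, in the original record order. If all scores are tied a
#'   single-quintile degenerate result is returned with a warning.
#' @export
assign_quintiles <- function(wealth_score, weights = NULL) {
  n <- length(wealth_score)
  if (n < 5L)
    stop("at least 5 records are needed to form quintiles", call. = FALSE)
  lev <- c("poorest", "poorer", "middle", "richer", "richest")
  if (length(unique(wealth_score)) == 1L) {
    warning("all wealth scores identical: quintiles are degenerate",
            call. = FALSE)
    return(factor(rep(lev[1L], n), levels = lev))
  }
  r <- fractional_rank(wealth_score, weights)
  q <- findInterval(r, c(0.2, 0.4, 0.6, 0.8)) + 1L
  factor(lev[q], levels = lev)
}

#' Keep the most recent birth per woman
#'
#' For inputs holding one row per birth, keeps the row with the maximum
#' birth date (or order index) within each woman id, mirroring the usual
#' eligibility rule that only the latest birth in the recall window is
#' analysed.
#'
#' @param records data frame.
#' @param id column name identifying the woman.
#' @param birth_order column name whose maximum marks the most recent birth
#'   (a date, a birth index, ...).
#' @return the filtered data frame, one row per woman.
#' @export
most_recent_birth <- function(records, id = "record_id",
                              birth_order = "birth_date") {
  stopifnot(is.data.frame(records), id %in% names(records),
            birth_order %in% names(records))
  keep <- records[[birth_order]] ==
    stats::ave(records[[birth_order]], records[[id]], FUN = max)
  out <- records[keep, , drop = FALSE]
  # in the (unusual) event of tied dates keep the last row per woman
  out[!duplicated(out[[id]], fromLast = TRUE), , drop = FALSE]
}
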