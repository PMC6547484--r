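#' Weighted fractional ranks in the wealth distribution
#'
#' Computes the weighted mid-rank of each observation in the living-standards
#' ordering: with normalized weights \eqn{w_i} in ascending wealth order,
#' \eqn{r_i = \sum_{j<i} w_j + w_i/2}, so each individual sits at the centre
#' of its own weight mass and \eqn{r_i \in (0, 1)}. Tied wealth scores all
#' receive the midpoint of the tied block's cumulative-weight span (the
#' weight-weighted average of the within-block mid-ranks), which makes the
#' result invariant to the ordering of records within a tie.
#'
#' @param wealth numeric vector of living-standard scores (any monotone
#'   index; only the ordering and ties matter).
#' @param weights positive sampling weights, recycled to `length(wealth)`
#'   if scalar. Need not be pre-normalized.
#' @return numeric vector of fractional ranks in `(0, 1)`, in the original
#'   record order.
#' @examples
#' fractional_rank(c(3, 1, 2, 4))            # equal weights
#' fractional_rank(1:4, c(0.4, 0.1, 0.2, 0.3))
#' @export
fractional_rank <- function(wealth, weights = NULL) {
  n <- length(wealth)
  if (n == 0L) stop("`wealth` is empty", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) == 1L) weights <- rep(weights, n)
  if (length(weights) != n)
    stop("`weights` must match `wealth` in length", call. = FALSE)
  if (any(!is.finite(wealth)))
    stop("`wealth` must be finite", call. = FALSE)
  if (any(!is.finite(weights)) || any(weights <= 0))
    stop("`weights` must be positive and finite", call. = FALSE)
  w <- weights / sum(weights)
  ord <- order(wealth)
  ws <- w[ord]
  r <- cumsum(ws) - ws / 2
  # ties: midpoint of the tied block's cumulative-weight span
  ties <- stats::ave(seq_len(n), wealth[ord], FUN = length)
  if (any(ties > 1L)) {
    cum <- cumsum(ws)
    lo <- stats::ave(cum - ws, wealth[ord], FUN = min)
    hi <- stats::ave(cum, wealth[ord], FUN = max)
    r <- (lo + hi) / 2
  }
  out <- numeric(n)
  out[ord] <- r
  out
}

#' Bundle an outcome with weights and fractional wealth ranks
#'
#' Constructs the container on which all concentration-index estimators
#' operate: outcome values `h`, weights normalized to sum to one, fractional
#' ranks `r` in the wealth ordering, and the weighted mean `mu` of `h`.
#'
#' @param h non-negative outcome values (counts, indicators, or predicted
#'   values; predicted values from an identity-link standardization may be
#'   negative and are accepted with a warning-free pass-through as long as
#'   their weighted mean is positive).
#' @param wealth living-standard scores used for ranking. Alternatively pass
#'   precomputed ranks via `ranks`.
#' @param weights positive sampling weights (default equal).
#' @param ranks optional precomputed fractional ranks; overrides `wealth`.
#' @return an object of class `ranked_outcome`: a list with elements `h`,
#'   `w` (normalized weights), `r`, `mu`, `n`.
#' @export
ranked_outcome <- function(h, wealth = NULL, weights = NULL, ranks = NULL) {
  n <- length(h)
  if (n == 0L) stop("`h` is empty", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n)
    stop("`weights` must match `h` in length", call. = FALSE)
  if (any(!is.finite(h)))
    stop("`h` must be finite", call. = FALSE)
  if (any(!is.finite(weights)) || any(weights <= 0))
    stop("`weights` must be positive and finite", call. = FALSE)
  if (is.null(ranks)) {
    if (is.null(wealth))
      stop("supply either `wealth` or `ranks`", call. = FALSE)
    r <- fractional_rank(wealth, weights)
  } else {
    if (length(ranks) != n)
      stop("`ranks` must match `h` in length", call. = FALSE)
    if (any(ranks <= 0) || any(ranks >= 1))
      stop("`ranks` must lie strictly in (0, 1)", call. = FALSE)
    r <- as.numeric(ranks)
  }
  w <- weights / sum(weights)
  mu <- sum(w * h)
  structure(
    list(h = as.numeric(h), w = w, r = r, mu = mu, n = n,
         wealth = if (is.null(wealth)) NULL else as.numeric(wealth)),
    class = "ranked_outcome"
  )
}

#' @export
print.ranked_outcome <- function(x, ...) {
  cat("Ranked outcome: n =", x$n,
      " weighted mean =", format(x$mu, digits = 6), "\n")
  invisible(x)
}
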