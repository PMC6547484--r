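## Internal weighted-moment helpers. Weights are treated as sampling
## (probability) weights throughout: means and variances are plug-in
## estimators with weights normalized to sum to one, no Bessel correction.

wmean <- function(x, w) sum(w * x) / sum(w)

wvar <- function(x, w) {
  w <- w / sum(w)
  m <- sum(w * x)
  sum(w * (x - m)^2)
}

wcov <- function(x, y, w) {
  w <- w / sum(w)
  sum(w * (x - sum(w * x)) * (y - sum(w * y)))
}

stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

check_prob <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0 || x > 1)
    stop_field(field, "must be a single proportion in [0, 1]")
  x
}

check_count <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 1 ||
      x != round(x))
    stop_field(field, "must be a positive integer")
  as.integer(x)
}

check_real <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_field(field, "must be a single finite number")
  as.numeric(x)
}
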