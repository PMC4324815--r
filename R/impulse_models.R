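#' Model variants
#'
#' The three impulse-response systems models relating daily training
#' impulses to performance:
#' * `ONE_COMP` — a single positive (adaptation) first-order component.
#' * `TWO_COMP` — the classic Banister fitness-fatigue model: positive
#'   adaptation minus negative fatigue component.
#' * `THREE_COMP` — fatigue gain itself responds to accumulated training
#'   through a further first-order filter.
#' @export
MODEL_VARIANTS <- c("ONE_COMP", "TWO_COMP", "THREE_COMP")

#' Parameters of one rat's impulse-response model
#'
#' Bundles the subject-specific intercept and gain factors with the time
#' constants (shared across a cohort when fitted jointly). Gains have units
#' of W per J (s^-1); time constants are in days.
#'
#' @param variant one of `"ONE_COMP"`, `"TWO_COMP"`, `"THREE_COMP"`.
#' @param p0 initial performance in W.
#' @param k1 gain of the positive (adaptation) component, s^-1.
#' @param tau1 time constant of the positive component, days.
#' @param k2 gain of the negative (fatigue) component, s^-1 (`TWO_COMP`).
#' @param tau2 time constant of the negative component, days.
#' @param k2_0 initial fatigue gain, s^-1 (`THREE_COMP`).
#' @param k3 gain of the filter driving the fatigue gain (`THREE_COMP`).
#' @param tau3 time constant of that filter, days (`THREE_COMP`).
#' @param third_component_sign `"plus"` (default) lets the fatigue gain grow
#'   with accumulated training, `k2(i) = k2_0 + dk2(i)`; `"minus"` uses
#'   `k2(i) = max(k2_0 - dk2(i), 0)`. See the methods vignette for why both
#'   conventions ship.
#' @return object of class `model_params`.
#' @export
model_params <- function(variant, p0, k1, tau1,
                         k2 = NULL, tau2 = NULL,
                         k2_0 = NULL, k3 = NULL, tau3 = NULL,
                         third_component_sign = c("plus", "minus")) {
  variant <- match.arg(variant, MODEL_VARIANTS)
  third_component_sign <- match.arg(third_component_sign)
  need <- switch(variant,
    ONE_COMP = list(p0 = p0, k1 = k1, tau1 = tau1),
    TWO_COMP = list(p0 = p0, k1 = k1, tau1 = tau1, k2 = k2, tau2 = tau2),
    THREE_COMP = list(p0 = p0, k1 = k1, tau1 = tau1, k2_0 = k2_0,
                      tau2 = tau2, k3 = k3, tau3 = tau3))
  for (nm in names(need)) {
    v <- need[[nm]]
    if (is.null(v) || !is.numeric(v) || length(v) != 1 || !is.finite(v))
      stop(sprintf("%s requires scalar numeric '%s'", variant, nm),
           call. = FALSE)
  }
  for (nm in intersect(names(need), c("tau1", "tau2", "tau3")))
    if (need[[nm]] <= 0)
      stop(nm, " must be > 0", call. = FALSE)
  for (nm in intersect(names(need), c("k1", "k2", "k2_0", "k3")))
    if (need[[nm]] < 0)
      stop(nm, " must be >= 0", call. = FALSE)
  structure(c(list(variant = variant), need,
              list(third_component_sign = third_component_sign)),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  vals <- x[setdiff(names(x), c("variant", "third_component_sign"))]
  cat(sprintf("<model_params %s> %s\n", x$variant,
              paste(sprintf("%s=%.4g", names(vals), unlist(vals)),
                    collapse = ", ")))
  invisible(x)
}

check_variant <- function(params, expected) {
  if (!inherits(params, "model_params"))
    stop("params must be a model_params object", call. = FALSE)
  if (params$variant != expected)
    stop(sprintf("params are for %s, not %s", params$variant, expected),
         call. = FALSE)
}

# Same-day-inclusive first-order filter: D(i) = sum_{j=1}^{i} w_j
# exp(-(i-j)/tau). Evaluated in closed form as
# exp(-i/tau) * cumsum(w_j exp(j/tau)); all terms are positive so the
# rescaling loses no relative precision. The sequential recursion is kept
# as a fallback when the exponent range would overflow.
decay_filter_inclusive <- function(w, tau) {
  n <- length(w)
  if (n / tau < 600) {
    e <- exp(seq_len(n) / tau)
    cumsum(w * e) / e
  } else {
    a <- numeric(n)
    d <- exp(-1 / tau)
    prev <- 0
    for (i in seq_len(n)) {
      prev <- d * prev + w[i]
      a[i] <- prev
    }
    a
  }
}

# Exclusive filter used by the convolution sums (same-day training does not
# affect same-day performance): A(n) = sum_{i=1}^{n-1} w_i exp(-(n-i)/tau)
# = exp(-1/tau) * D(n-1); A(1) = 0.
decay_filter <- function(w, tau) {
  n <- length(w)
  if (n == 1) return(0)
  c(0, exp(-1 / tau) * decay_filter_inclusive(w, tau)[-n])
}

# Lag-weighted exclusive filter F(n) = sum_{i=1}^{n-1} (n-i) w_i
# exp(-(n-i)/tau): the derivative of decay_filter with respect to tau is
# F/tau^2. Closed form like the plain filter, with the cross term
# n * D - inclusive-cumsum of i * w_i.
decay_filter_lagweighted <- function(w, tau) {
  n <- length(w)
  i <- seq_len(n)
  e <- exp(i / tau)
  cw <- cumsum(w * e)
  ciw <- cumsum(i * w * e)
  f_incl <- (i * cw - ciw) / e          # sum_{j<=n} (n-j) w_j e^{-(n-j)/tau}
  if (n == 1) return(0)
  d <- exp(-1 / tau)
  # F(n) = d * (F(n-1)_incl + D(n-1)): shift the inclusive versions
  c(0, d * (f_incl[-n] + (cw / e)[-n]))
}

# Inclusive counterpart sum_{j<=n} (n-j) w_j exp(-(n-j)/tau): derivative
# of decay_filter_inclusive with respect to tau is this / tau^2.
decay_filter_lagweighted_inclusive <- function(w, tau) {
  n <- length(w)
  i <- seq_len(n)
  e <- exp(i / tau)
  (i * cumsum(w * e) - cumsum(i * w * e)) / e
}

series_w <- function(series) {
  if (!inherits(series, "training_series"))
    stop("series must be a training_series", call. = FALSE)
  series$w
}

#' Forward simulation of the systems models
#'
#' Predict daily performance from a daily training-impulse series under one
#' of the three model variants. Predictions are made on every calendar day
#' `n = 1..n_days`; only strictly earlier days' training enters day `n`'s
#' prediction, so `p_hat(1) = p0` always.
#'
#' `predict_1comp`: `p_hat(n) = p0 + k1 * sum_{i<n} w_i exp(-(n-i)/tau1)`.
#'
#' `predict_2comp` subtracts a second, fatigue component with gain `k2` and
#' time constant `tau2`.
#'
#' `predict_3comp` lets the fatigue gain `k2(i)` at the day the impulse was
#' applied vary with accumulated training (see [k2_series()]).
#'
#' All three use O(n) exponential-filter recursions; [predict_direct()] is
#' the O(n^2) direct-summation evaluator kept as an independent oracle.
#'
#' @param params a `model_params` of the matching variant.
#' @param series a `training_series`.
#' @return numeric vector of predicted performance (W), one per day.
#' @seealso [predict_direct()], [k2_series()]
#' @export
predict_1comp <- function(params, series) {
  check_variant(params, "ONE_COMP")
  w <- series_w(series)
  params$p0 + params$k1 * decay_filter(w, params$tau1)
}

#' @rdname predict_1comp
#' @export
predict_2comp <- function(params, series) {
  check_variant(params, "TWO_COMP")
  w <- series_w(series)
  params$p0 + params$k1 * decay_filter(w, params$tau1) -
    params$k2 * decay_filter(w, params$tau2)
}

#' Time course of the fatigue gain in the three-component model
#'
#' The fatigue gain applied to the impulse of day `i` is driven by a
#' first-order filter of all training up to and including day `i`:
#' `dk2(i) = k3 * sum_{j<=i} w_j exp(-(i-j)/tau3)`, combined with the
#' initial gain according to the configured sign convention.
#'
#' @inheritParams predict_1comp
#' @return data.frame with columns `day`, `dk2`, `k2`.
#' @export
k2_series <- function(params, series) {
  check_variant(params, "THREE_COMP")
  w <- series_w(series)
  dk2 <- params$k3 * decay_filter_inclusive(w, params$tau3)
  k2 <- if (params$third_component_sign == "plus") params$k2_0 + dk2
        else pmax(params$k2_0 - dk2, 0)
  data.frame(day = seq_along(w), dk2 = dk2, k2 = k2)
}

#' @rdname predict_1comp
#' @export
predict_3comp <- function(params, series) {
  check_variant(params, "THREE_COMP")
  w <- series_w(series)
  g <- k2_series(params, series)$k2 * w
  params$p0 + params$k1 * decay_filter(w, params$tau1) -
    decay_filter(g, params$tau2)
}

#' @rdname predict_1comp
#' @export
predict_performance <- function(params, series) {
  switch(params$variant,
         ONE_COMP = predict_1comp(params, series),
         TWO_COMP = predict_2comp(params, series),
         THREE_COMP = predict_3comp(params, series))
}

#' Direct-summation evaluator (test oracle)
#'
#' Evaluates the model by the O(n^2) convolution sums exactly as written,
#' without the recursive filters. Slow but transparent; the recursive
#' evaluators are checked against it.
#'
#' @inheritParams predict_1comp
#' @return numeric vector of predicted performance (W), one per day.
#' @export
predict_direct <- function(params, series) {
  w <- series_w(series)
  n_days <- length(w)
  p <- rep(params$p0, n_days)
  if (params$variant == "THREE_COMP") {
    dk2 <- vapply(seq_len(n_days), function(i) {
      j <- seq_len(i)
      params$k3 * sum(w[j] * exp(-(i - j) / params$tau3))
    }, numeric(1))
    k2i <- if (params$third_component_sign == "plus") params$k2_0 + dk2
           else pmax(params$k2_0 - dk2, 0)
  }
  for (n in seq_len(n_days)) {
    if (n == 1) next
    i <- seq_len(n - 1)
    pos <- params$k1 * sum(w[i] * exp(-(n - i) / params$tau1))
    neg <- switch(params$variant,
      ONE_COMP = 0,
      TWO_COMP = params$k2 * sum(w[i] * exp(-(n - i) / params$tau2)),
      THREE_COMP = sum(k2i[i] * w[i] * exp(-(n - i) / params$tau2)))
    p[n] <- params$p0 + pos - neg
  }
  p
}

#' Write predicted performance as tidy CSV
#'
#' @param predictions numeric vector of daily predictions, or a named list
#'   of them (one element per rat).
#' @param path file path.
#' @export
write_predictions <- function(predictions, path) {
  if (!is.list(predictions)) predictions <- list(rat = predictions)
  rows <- Map(function(id, p)
    data.frame(rat_id = id, day = seq_along(p), p_hat_watts = p),
    names(predictions), predictions)
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Serialize / restore model parameters as JSON
#'
#' @param params a `model_params`.
#' @param path file path.
#' @export
write_model_params <- function(params, path) {
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model_params
#' @export
read_model_params <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(model_params, x)
}
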