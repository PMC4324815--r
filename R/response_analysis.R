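#' Response characteristics of a single training bout
#'
#' For the two-component model, the response of performance to one unit
#' training impulse is `h(t) = k1 exp(-t/tau1) - k2 exp(-t/tau2)`. When the
#' fatigue gain exceeds the adaptation gain (`k2 > k1`) and fatigue decays
#' faster (`tau1 > tau2`), performance first dips below baseline, recovers
#' at
#' \deqn{t_n = \frac{\tau_1\tau_2}{\tau_1-\tau_2}\ln(k_2/k_1),}
#' and peaks at
#' \deqn{t_g = \frac{\tau_1\tau_2}{\tau_1-\tau_2}\ln\!\left(\frac{\tau_1 k_2}{\tau_2 k_1}\right)}
#' with maximal gain per unit of training
#' \deqn{p_g = k_1 e^{-t_g/\tau_1} - k_2 e^{-t_g/\tau_2}.}
#'
#' Parameter combinations for which a quantity is non-physical (negative
#' log argument, or a negative time — e.g. the response never dips below
#' baseline when `k2 < k1` with `tau1 > tau2`) yield `NA` for that quantity
#' with its `defined` flag `FALSE`, never an error, so cohort summaries can
#' skip them.
#'
#' @param k1,tau1 adaptation gain (s^-1) and time constant (days), > 0.
#' @param k2,tau2 fatigue gain (s^-1) and time constant (days), > 0;
#'   `tau2 != tau1`.
#' @return list of class `response_characteristics`: `tn`, `tg` (days),
#'   `pg` (W per unit training), and logical `defined` flags.
#' @examples
#' response_characteristics(k1 = 0.0186, tau1 = 5.31,
#'                          k2 = 0.0200, tau2 = 4.3)
#' @export
response_characteristics <- function(k1, tau1, k2, tau2) {
  vals <- c(k1 = k1, tau1 = tau1, k2 = k2, tau2 = tau2)
  if (any(!is.finite(vals) | vals <= 0))
    stop("all of k1, tau1, k2, tau2 must be finite and > 0", call. = FALSE)
  if (tau1 == tau2)
    stop("tau1 must differ from tau2 (formulas are singular)",
         call. = FALSE)
  cc <- tau1 * tau2 / (tau1 - tau2)
  tn <- cc * log(k2 / k1)
  tg <- cc * log(tau1 * k2 / (tau2 * k1))
  tn_ok <- is.finite(tn) && tn >= 0
  tg_ok <- is.finite(tg) && tg >= 0 && (!tn_ok || tg >= tn)
  pg <- if (tg_ok) k1 * exp(-tg / tau1) - k2 * exp(-tg / tau2) else NA_real_
  pg_ok <- tg_ok && is.finite(pg) && pg >= 0
  structure(list(tn = if (tn_ok) tn else NA_real_,
                 tg = if (tg_ok) tg else NA_real_,
                 pg = if (pg_ok) pg else NA_real_,
                 defined = c(tn = tn_ok, tg = tg_ok, pg = pg_ok)),
            class = "response_characteristics")
}

#' @export
print.response_characteristics <- function(x, ...) {
  fmt <- function(v, u) if (is.na(v)) "undefined" else sprintf("%.4g %s", v, u)
  cat(sprintf("tn = %s, tg = %s, pg = %s\n", fmt(x$tn, "d"), fmt(x$tg, "d"),
              fmt(x$pg, "W")))
  invisible(x)
}

#' Positive/negative influence decomposition of training on performance
#'
#' The impulse applied on day `i` contributes
#' `E(i, n) = k1 w_i exp(-(n-i)/tau1) - k2 w_i exp(-(n-i)/tau2)` to the
#' model performance of day `n`. Each `(i, n)` term is classified by its
#' own sign; the negative terms sum to the fatigue influence `in(n) <= 0`
#' and the positive ones to the adaptation influence `ip(n) >= 0`, so that
#' `ip(n) + in(n) = p_hat(n) - p0` exactly.
#'
#' @param params a `TWO_COMP` [model_params()].
#' @param series a [training_series()].
#' @return data.frame with columns `day`, `in_n` (W, <= 0), `ip_n` (W, >= 0).
#' @export
influence_decomposition <- function(params, series) {
  check_variant(params, "TWO_COMP")
  w <- series_w(series)
  n_days <- length(w)
  in_n <- numeric(n_days)
  ip_n <- numeric(n_days)
  for (n in seq_len(n_days)) {
    if (n == 1) next
    i <- seq_len(n - 1)
    e <- params$k1 * w[i] * exp(-(n - i) / params$tau1) -
         params$k2 * w[i] * exp(-(n - i) / params$tau2)
    in_n[n] <- sum(e[e < 0])
    ip_n[n] <- sum(e[e > 0])
  }
  data.frame(day = seq_len(n_days), in_n = in_n, ip_n = ip_n)
}

#' Cohort summaries of response characteristics and influences
#'
#' `cohort_response_characteristics` evaluates [response_characteristics()]
#' at each rat's fitted gains (with the shared time constants) and reports
#' per-rat values plus the cohort mean and SD of each defined quantity —
#' means of per-rat values, not formulas evaluated at mean parameters.
#'
#' `cohort_influence_summary` evaluates [influence_decomposition()] for
#' each rat and returns the per-day mean and standard error of the mean
#' across rats of the positive and negative influences.
#'
#' @param fit a `TWO_COMP` `ffm_fit`.
#' @param cohort the `ffm_cohort` the fit was produced on.
#' @return `cohort_response_characteristics`: list with `per_rat`
#'   (data.frame rat_id, k1, k2, tn, tg, pg) and `summary` (data.frame
#'   quantity, mean, sd, n_defined). `cohort_influence_summary`: data.frame
#'   day, ip_mean, ip_sem, in_mean, in_sem.
#' @export
cohort_response_characteristics <- function(fit) {
  stopifnot(inherits(fit, "ffm_fit"))
  if (fit$variant != "TWO_COMP")
    stop("response characteristics are defined for the TWO_COMP fit",
         call. = FALSE)
  tau1 <- fit$shared[["tau1"]]; tau2 <- fit$shared[["tau2"]]
  per <- do.call(rbind, lapply(seq_len(nrow(fit$per_rat)), function(r) {
    row <- fit$per_rat[r, ]
    rc <- if (row$k1 > 0 && row$k2 > 0)
      response_characteristics(row$k1, tau1, row$k2, tau2)
    else list(tn = NA_real_, tg = NA_real_, pg = NA_real_)
    data.frame(rat_id = row$rat_id, k1 = row$k1, k2 = row$k2,
               tn = rc$tn, tg = rc$tg, pg = rc$pg)
  }))
  summ <- do.call(rbind, lapply(c("tn", "tg", "pg"), function(q) {
    v <- per[[q]][!is.na(per[[q]])]
    data.frame(quantity = q,
               mean = if (length(v)) mean(v) else NA_real_,
               sd = if (length(v) > 1) stats::sd(v) else NA_real_,
               n_defined = length(v))
  }))
  list(per_rat = per, summary = summ)
}

#' @rdname cohort_response_characteristics
#' @export
cohort_influence_summary <- function(fit, cohort) {
  stopifnot(inherits(fit, "ffm_fit"), inherits(cohort, "ffm_cohort"))
  if (fit$variant != "TWO_COMP")
    stop("influence decomposition is defined for the TWO_COMP fit",
         call. = FALSE)
  infl <- lapply(seq_len(cohort$R), function(r)
    influence_decomposition(fit$params_per_rat[[r]], cohort$rats[[r]]))
  ip <- sapply(infl, `[[`, "ip_n")
  im <- sapply(infl, `[[`, "in_n")
  if (is.null(dim(ip))) { ip <- matrix(ip, ncol = 1); im <- matrix(im, ncol = 1) }
  sem <- function(m) if (ncol(m) > 1)
    apply(m, 1, stats::sd) / sqrt(ncol(m)) else rep(NA_real_, nrow(m))
  data.frame(day = infl[[1]]$day,
             ip_mean = rowMeans(ip), ip_sem = sem(ip),
             in_mean = rowMeans(im), in_sem = sem(im))
}

#' Plot cohort influence curves
#'
#' Convenience base-graphics plot of the per-day cohort mean positive and
#' negative influences with SEM whiskers.
#'
#' @param summary output of [cohort_influence_summary()].
#' @param ... passed to [graphics::matplot()].
#' @export
plot_influences <- function(summary, ...) {
  graphics::matplot(summary$day, cbind(summary$ip_mean, summary$in_mean),
                    type = "l", lty = 1, col = c("forestgreen", "firebrick"),
                    xlab = "day", ylab = "influence on performance (W)", ...)
  if (!all(is.na(summary$ip_sem))) {
    graphics::arrows(summary$day, summary$ip_mean - summary$ip_sem,
                     summary$day, summary$ip_mean + summary$ip_sem,
                     length = 0.02, angle = 90, code = 3,
                     col = "forestgreen")
    graphics::arrows(summary$day, summary$in_mean - summary$in_sem,
                     summary$day, summary$in_mean + summary$in_sem,
                     length = 0.02, angle = 90, code = 3, col = "firebrick")
  }
  graphics::abline(h = 0, lty = 3)
  graphics::legend("topleft", c("positive (ip)", "negative (in)"), lty = 1,
                   col = c("forestgreen", "firebrick"), bty = "n")
  invisible(summary)
}
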