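#' Default progressive-load climbing protocol
#'
#' Additional load as a percentage of current body mass for each of 19
#' sessions over 4 training weeks (5 sessions/week): sessions 1-5 at 50%,
#' 6 at 80%, 7-8 at 100%, 9-13 at 120%, 14-16 at 130%, 17-18 at 140% and
#' 19 at 150%.
#'
#' @return data.frame with columns `session`, `load_pct`.
#' @export
default_protocol <- function() {
  data.frame(session = 1:19,
             load_pct = c(rep(50, 5), 80, rep(100, 2), rep(120, 5),
                          rep(130, 3), rep(140, 2), 150))
}

#' Default population parameters of the generating model
#'
#' Two-component truth with shared time constants `tau1` = 5.31 d and
#' `tau2` = 4.3 d; per-rat gains drawn from independent normals with mean
#' (SD) 0.0186 (0.0134) s^-1 for `k1` and 0.0200 (0.0157) s^-1 for `k2`,
#' truncated at zero.
#'
#' @param variant generating model variant.
#' @return list understood by [generate_cohort()].
#' @export
default_true_params <- function(variant = "TWO_COMP") {
  variant <- match.arg(variant, MODEL_VARIANTS)
  base <- list(variant = variant, tau1 = 5.31,
               k1_mean = 0.0186, k1_sd = 0.0134, k_correlation = 0)
  if (variant %in% c("TWO_COMP", "THREE_COMP"))
    base <- c(base, list(tau2 = 4.3, k2_mean = 0.0200, k2_sd = 0.0157))
  if (variant == "THREE_COMP")
    base <- c(base, list(tau3 = 10, k3_mean = 2e-6, k3_sd = 1e-6))
  base
}

#' Design of a synthetic rat cohort
#'
#' Describes the study design the generator emulates: cohort size, initial
#' body masses, body-mass growth, the progressive-load protocol, the
#' training calendar, the generating ("true") model parameters, and the
#' observation-noise level.
#'
#' @param n_rats number of animals (default 11).
#' @param initial_mass_mean,initial_mass_sd initial body mass (kg),
#'   defaults 0.277 and 0.015.
#' @param mass_gain_per_day linear body-mass growth (kg/day, default 0.002).
#' @param protocol data.frame `session`, `load_pct` (percent of current
#'   body mass); default [default_protocol()].
#' @param repetitions climbs per session (default 10).
#' @param climb_height m per climb (default 1).
#' @param days_per_week consecutive training days per week (default 5).
#' @param true_params generating model parameters, see
#'   [default_true_params()].
#' @param p0_climb_time_range plausible per-climb time (s) of a 50%-load
#'   session, used to draw each rat's initial performance.
#' @param noise_sd SD of additive Gaussian observation noise on performance
#'   (W). The default 0.1 is the largest level at which the plausibility
#'   constraints do not materially distort which animals survive the
#'   redraw step; see the methods vignette for the calibration reasoning.
#' @param climb_time_band plausibility band (s) for the implied per-climb
#'   time; rats implying times outside it are redrawn.
#' @param max_retries redraw attempts per rat before generation fails.
#' @return list of class `cohort_design`.
#' @export
cohort_design <- function(n_rats = 11L,
                          initial_mass_mean = 0.277,
                          initial_mass_sd = 0.015,
                          mass_gain_per_day = 0.002,
                          protocol = default_protocol(),
                          repetitions = 10L,
                          climb_height = 1,
                          days_per_week = 5L,
                          true_params = default_true_params(),
                          p0_climb_time_range = c(8, 14),
                          noise_sd = 0.1,
                          climb_time_band = c(2, 40),
                          max_retries = 50L) {
  stopifnot(n_rats >= 1, initial_mass_mean > 0, initial_mass_sd >= 0,
            mass_gain_per_day >= 0, nrow(protocol) >= 1,
            all(c("session", "load_pct") %in% names(protocol)),
            repetitions >= 1, climb_height > 0, noise_sd >= 0,
            length(climb_time_band) == 2, climb_time_band[1] > 0)
  if (is.unsorted(protocol$load_pct))
    stop("protocol load percentages must be non-decreasing", call. = FALSE)
  structure(list(n_rats = as.integer(n_rats),
                 initial_mass_mean = initial_mass_mean,
                 initial_mass_sd = initial_mass_sd,
                 mass_gain_per_day = mass_gain_per_day,
                 protocol = protocol, repetitions = as.integer(repetitions),
                 climb_height = climb_height,
                 days_per_week = as.integer(days_per_week),
                 true_params = true_params,
                 p0_climb_time_range = p0_climb_time_range,
                 noise_sd = noise_sd, climb_time_band = climb_time_band,
                 max_retries = as.integer(max_retries)),
            class = "cohort_design")
}

rtrunc_norm <- function(n, mean, sd, lower = 0) {
  if (sd == 0) return(rep(mean, n))
  out <- stats::rnorm(n, mean, sd)
  for (tries in 1:1000) {
    bad <- out <= lower
    if (!any(bad)) break
    out[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  pmax(out, lower + 1e-12)
}

draw_rat_truth <- function(tp, p0) {
  rho <- if (is.null(tp$k_correlation)) 0 else tp$k_correlation
  # correlated standard normals, redrawn jointly until both gains are
  # positive: a genuine truncated (not clamped) bivariate draw
  for (i in 1:1000) {
    z1 <- stats::rnorm(1)
    z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(1)
    k1 <- tp$k1_mean + tp$k1_sd * z1
    k2 <- if (is.null(tp$k2_mean)) 1 else tp$k2_mean + tp$k2_sd * z2
    if (k1 > 0 && k2 > 0) break
  }
  k1 <- max(k1, 1e-12)
  k2 <- max(k2, 1e-12)
  switch(tp$variant,
    ONE_COMP = model_params("ONE_COMP", p0 = p0, k1 = k1, tau1 = tp$tau1),
    TWO_COMP = model_params("TWO_COMP", p0 = p0, k1 = k1, tau1 = tp$tau1,
                            k2 = k2, tau2 = tp$tau2),
    THREE_COMP = model_params("THREE_COMP", p0 = p0, k1 = k1,
                              tau1 = tp$tau1, k2_0 = k2,
                              tau2 = tp$tau2,
                              k3 = rtrunc_norm(1, tp$k3_mean, tp$k3_sd),
                              tau3 = tp$tau3))
}

#' Generate a synthetic rat cohort
#'
#' Emulates the ladder-climbing study design: per rat, an initial body mass
#' is drawn and grown linearly; each session's additional load is the
#' protocol percentage of that day's mass; daily training work follows from
#' [training_work()]; true per-rat model parameters are drawn around the
#' population means; observed performance is the true model's prediction
#' plus Gaussian noise on session days. Session climb times are backed out
#' as `TW / p_obs`, and a rat whose implied per-climb time leaves the
#' plausibility band (or whose noisy performance is non-positive) is
#' redrawn.
#'
#' Regenerating with the same seed reproduces the cohort bit-for-bit.
#'
#' @param design a [cohort_design()].
#' @param seed integer seed.
#' @return list of class `synthetic_cohort`: `cohort` (an `ffm_cohort`),
#'   `truth` (per-rat `model_params`), `sessions` (a `climb_sessions`
#'   table for all rats), `design`, `seed`.
#' @export
generate_cohort <- function(design = cohort_design(), seed = 1L) {
  stopifnot(inherits(design, "cohort_design"))
  local_seed(seed, {
    cal <- training_calendar(nrow(design$protocol), design$days_per_week)
    rats <- vector("list", design$n_rats)
    truth <- vector("list", design$n_rats)
    sess_rows <- vector("list", design$n_rats)
    for (r in seq_len(design$n_rats)) {
      id <- sprintf("rat%02d", r)
      ok <- FALSE
      for (attempt in seq_len(design$max_retries)) {
        m0 <- rtrunc_norm(1, design$initial_mass_mean,
                          design$initial_mass_sd, lower = 0.05)
        mass <- m0 + design$mass_gain_per_day * (cal$session_day - 1)
        load <- design$protocol$load_pct / 100 * mass
        sess <- climb_sessions(rat_id = id, day = cal$session_day,
                               body_mass = mass, load_mass = load,
                               climb_height = design$climb_height,
                               repetitions = design$repetitions,
                               total_time = 1)   # placeholder, set below
        tw <- training_work(sess)
        w <- numeric(cal$n_days)
        w[cal$session_day] <- tw
        t_climb <- stats::runif(1, design$p0_climb_time_range[1],
                                design$p0_climb_time_range[2])
        p0 <- 1.5 * m0 * STANDARD_GRAVITY * design$climb_height / t_climb
        pars <- draw_rat_truth(design$true_params, p0)
        series0 <- training_series(id, w, n_days = cal$n_days)
        p_clean <- predict_performance(pars, series0)[cal$session_day]
        p_obs <- p_clean + stats::rnorm(length(p_clean), 0, design$noise_sd)
        if (any(p_obs <= 0)) next
        per_climb <- tw / (p_obs * design$repetitions)
        if (any(per_climb < design$climb_time_band[1] |
                per_climb > design$climb_time_band[2])) next
        sess$total_time <- tw / p_obs
        rats[[r]] <- training_series(id, w,
                                     measured_days = cal$session_day,
                                     p_obs = p_obs, n_days = cal$n_days)
        truth[[r]] <- pars
        sess_rows[[r]] <- sess
        ok <- TRUE
        break
      }
      if (!ok)
        stop(sprintf(
          "could not generate a plausible rat after %d attempts (rat %s); noise_sd or climb_time_band make the design infeasible",
          design$max_retries, id), call. = FALSE)
    }
    names(truth) <- vapply(rats, `[[`, character(1), "rat_id")
    structure(list(cohort = cohort_data(rats), truth = truth,
                   sessions = validate_climb_sessions(
                     do.call(rbind, sess_rows)),
                   design = design, seed = as.integer(seed)),
              class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d rats x %d sessions, %s truth, noise_sd = %g W, seed = %d\n",
              x$design$n_rats, nrow(x$design$protocol),
              x$design$true_params$variant, x$design$noise_sd, x$seed))
  invisible(x)
}

#' Parameter-recovery experiment
#'
#' Generates `n_replicates` cohorts from the design, fits the generating
#' variant to each, and records the relative errors of the recovered
#' shared time constants and the cohort-mean gains, the fit R^2, and (when
#' `compare = TRUE`) the one- vs two-component nested F test decision.
#' Individual fit failures are recorded, not fatal.
#'
#' @param design a [cohort_design()].
#' @param n_replicates number of replicate cohorts.
#' @param seed integer seed; per-replicate seeds are derived from it.
#' @param config a [fit_config()] used for every fit.
#' @param compare also fit the one- and two-component models and run the
#'   nested F test (requires a `TWO_COMP` or `ONE_COMP` truth).
#' @param alpha significance level for the recorded rejection decision.
#' @return data.frame, one row per replicate: recovered and true time
#'   constants with relative errors, mean relative gain errors, `r2`,
#'   and with `compare` the nested `f`, `p_value` and `reject`.
#' @export
recovery_experiment <- function(design = cohort_design(), n_replicates = 5L,
                                seed = 1L, config = fit_config(),
                                compare = FALSE, alpha = 0.05) {
  stopifnot(n_replicates >= 1)
  rep_seeds <- local_seed(seed, sample.int(.Machine$integer.max - 1,
                                           n_replicates))
  variant <- design$true_params$variant
  rows <- lapply(seq_len(n_replicates), function(i) {
    out <- data.frame(replicate = i, seed = rep_seeds[i])
    syn <- generate_cohort(design, seed = rep_seeds[i])
    fit <- tryCatch(fit_model(syn$cohort, variant, config),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      out$error <- conditionMessage(fit)
      return(out)
    }
    for (nm in names(fit$shared)) {
      truth <- design$true_params[[nm]]
      out[[paste0(nm, "_true")]] <- truth
      out[[paste0(nm, "_hat")]] <- unname(fit$shared[[nm]])
      out[[paste0(nm, "_rel_err")]] <- abs(fit$shared[[nm]] - truth) / truth
    }
    for (g in gain_names(variant)) {
      k_true <- vapply(syn$truth, function(p)
        p[[if (g == "k2_0") "k2_0" else g]], numeric(1))
      k_hat <- fit$per_rat[[g]]
      out[[paste0(g, "_mean_rel_err")]] <-
        mean(abs(k_hat - k_true) / pmax(k_true, 1e-12))
    }
    out$r2 <- goodness_of_fit(fit, syn$cohort)$r2
    if (compare) {
      f1 <- if (variant == "ONE_COMP") fit
            else fit_model(syn$cohort, "ONE_COMP", config)
      t1 <- unname(f1$shared[1])
      f2 <- if (variant == "TWO_COMP") {
        # the truth fit already searched the random starts; the comparison
        # fit only needs the nested warm starts plus that optimum
        cfg2 <- config
        cfg2$n_starts <- 2L
        fit_model(syn$cohort, "TWO_COMP", cfg2,
                  extra_starts = rbind(c(t1, t1 * 0.75), c(t1, t1 * 1.25),
                                       fit$shared))
      } else fit_model(syn$cohort, "TWO_COMP", config,
                       extra_starts = rbind(c(t1, t1 * 0.75),
                                            c(t1, t1 * 1.25)))
      ct <- compare_nested(f1, f2)
      out$f_12 <- ct$f
      out$p_12 <- ct$p_value
      out$reject_12 <- ct$p_value < alpha
    }
    out
  })
  nm <- unique(unlist(lapply(rows, names)))
  do.call(rbind, lapply(rows, function(r) {
    r[setdiff(nm, names(r))] <- NA
    r[nm]
  }))
}
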