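#' Cohort container
#'
#' Bundles one [training_series()] per rat for joint fitting.
#'
#' @param rats list of `training_series` (one per rat, unique `rat_id`s).
#' @return object of class `ffm_cohort` with elements `rats`, `R` (number
#'   of rats), `N_per_rat`, and `N` (total measured performances).
#' @export
cohort_data <- function(rats) {
  if (inherits(rats, "training_series")) rats <- list(rats)
  if (!length(rats) || !all(vapply(rats, inherits, logical(1),
                                   "training_series")))
    stop("rats must be a non-empty list of training_series", call. = FALSE)
  ids <- vapply(rats, `[[`, character(1), "rat_id")
  if (anyDuplicated(ids)) stop("duplicate rat_id in cohort", call. = FALSE)
  names(rats) <- ids
  n_per <- vapply(rats, function(s) length(s$measured_days), integer(1))
  structure(list(rats = rats, R = length(rats), N_per_rat = n_per,
                 N = sum(n_per)),
            class = "ffm_cohort")
}

#' @export
print.ffm_cohort <- function(x, ...) {
  cat(sprintf("<ffm_cohort> %d rats, %d measured performances (%s per rat)\n",
              x$R, x$N, paste(unique(x$N_per_rat), collapse = "/")))
  invisible(x)
}

#' Pooled residual sum of squares
#'
#' RSS of the cohort fit: squared differences between observed and model
#' performance summed over all rats and all measured days. This is the
#' objective the joint fit minimises.
#'
#' @param cohort an `ffm_cohort`.
#' @param params_per_rat list of `model_params`, one per rat, all of the
#'   same variant and with identical shared time constants.
#' @return pooled RSS in W^2.
#' @export
pooled_rss <- function(cohort, params_per_rat) {
  stopifnot(inherits(cohort, "ffm_cohort"))
  if (length(params_per_rat) != cohort$R)
    stop("need one model_params per rat", call. = FALSE)
  variants <- vapply(params_per_rat, `[[`, character(1), "variant")
  if (length(unique(variants)) != 1)
    stop("all rats must use the same model variant", call. = FALSE)
  shared <- intersect(c("tau1", "tau2", "tau3"), names(params_per_rat[[1]]))
  for (nm in shared) {
    taus <- vapply(params_per_rat, `[[`, numeric(1), nm)
    if (diff(range(taus)) > 1e-12 * max(taus))
      stop("shared time constant ", nm, " differs across rats", call. = FALSE)
  }
  sum(vapply(seq_len(cohort$R), function(r) {
    s <- cohort$rats[[r]]
    p_hat <- predict_performance(params_per_rat[[r]], s)
    sum((s$p_obs - p_hat[s$measured_days])^2)
  }, numeric(1)))
}

#' Fitting configuration
#'
#' @param n_starts multistart count for the outer time-constant search.
#' @param seed integer seed for drawing starts.
#' @param tau_bounds length-2 bounds (days) for every time constant.
#' @param gain_bounds length-2 bounds (s^-1) for every gain factor.
#' @param p0_upper_mult upper bound on `p0` as a multiple of the largest
#'   observed performance (lower bound is 0).
#' @param rel_tol relative objective-change convergence tolerance.
#' @param step_tol parameter-step convergence tolerance.
#' @param third_component_sign sign convention for the three-component
#'   model's fatigue gain; see [model_params()].
#' @param count_intercepts_in_df if `TRUE`, per-rat intercepts count toward
#'   model degrees of freedom; default `FALSE` (gain factors plus shared
#'   time constants only).
#' @return list of class `fit_config`.
#' @export
fit_config <- function(n_starts = 25L, seed = 1L,
                       tau_bounds = c(0.5, 60),
                       gain_bounds = c(0, 1),
                       p0_upper_mult = 10,
                       rel_tol = 1e-10, step_tol = 1e-8,
                       third_component_sign = c("plus", "minus"),
                       count_intercepts_in_df = FALSE) {
  third_component_sign <- match.arg(third_component_sign)
  stopifnot(n_starts >= 1, length(tau_bounds) == 2,
            tau_bounds[1] > 0, diff(tau_bounds) > 0,
            length(gain_bounds) == 2, gain_bounds[1] >= 0,
            diff(gain_bounds) > 0, p0_upper_mult > 0)
  structure(list(n_starts = as.integer(n_starts), seed = as.integer(seed),
                 tau_bounds = tau_bounds, gain_bounds = gain_bounds,
                 p0_upper_mult = p0_upper_mult, rel_tol = rel_tol,
                 step_tol = step_tol,
                 third_component_sign = third_component_sign,
                 count_intercepts_in_df = count_intercepts_in_df),
            class = "fit_config")
}

#' @rdname fit_config
#' @param path file path for the JSON round-trip helpers.
#' @param config a `fit_config`.
#' @export
write_fit_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname fit_config
#' @export
read_fit_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(fit_config))
  unknown <- setdiff(names(x), known)
  if (length(unknown))
    stop("unknown fit_config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(fit_config, x)
}

n_tau <- function(variant) switch(variant, ONE_COMP = 1L, TWO_COMP = 2L,
                                  THREE_COMP = 3L)
n_gains <- function(variant) n_tau(variant)
tau_names <- function(variant) paste0("tau", seq_len(n_tau(variant)))
gain_names <- function(variant) switch(variant,
  ONE_COMP = "k1", TWO_COMP = c("k1", "k2"),
  THREE_COMP = c("k1", "k2_0", "k3"))

# Design matrix of the per-rat linear subproblem at fixed time constants.
# Columns multiply (p0, gains...): the model is linear in these, which is
# what makes variable projection possible. All days; subset to measured
# days before solving.
model_design_matrix <- function(variant, series, tau,
                                third_component_sign = "plus") {
  model_design_matrix_w(variant, series$w, tau, third_component_sign)
}

model_design_matrix_w <- function(variant, w, tau,
                                  third_component_sign = "plus") {
  a1 <- decay_filter(w, tau[1])
  switch(variant,
    ONE_COMP = cbind(p0 = 1, k1 = a1),
    TWO_COMP = cbind(p0 = 1, k1 = a1, k2 = -decay_filter(w, tau[2])),
    THREE_COMP = {
      d <- decay_filter_inclusive(w, tau[3])
      s <- if (third_component_sign == "plus") 1 else -1
      cbind(p0 = 1, k1 = a1, k2_0 = -decay_filter(w, tau[2]),
            k3 = -s * decay_filter(w * d, tau[2]))
    })
}

# Box-constrained linear least squares for the tiny (<= 4 column) per-rat
# subproblem, on the normal equations. Plain solve when it lands inside
# the box; otherwise exact active-set enumeration: every assignment of
# each coordinate to {free, at lower, at upper} is solved and the feasible
# minimiser taken. The optimum's active set is among the 3^p assignments,
# so this is exact for the convex QP, and — unlike iterative fallbacks —
# leaves the profiled objective smooth for the outer optimizer.
active_set_table <- local({
  cache <- list()
  function(p) {
    key <- as.character(p)
    if (is.null(cache[[key]])) {
      m <- as.matrix(expand.grid(rep(list(0:2), p)))
      cache[[key]] <<- m[order(rowSums(m != 0)), , drop = FALSE]
    }
    cache[[key]]
  }
})

bounded_ls_normal <- function(xtx, xty, lower, upper) {
  xty <- drop(xty)
  p <- length(xty)
  # equilibrate to unit diagonal: the components' filter columns can be
  # nearly collinear (tau1 ~ tau2), and raw normal equations then lose
  # most of their precision
  d <- sqrt(diag(xtx))
  d[!is.finite(d) | d <= 0] <- 1
  A <- xtx / tcrossprod(d)
  r <- xty / d
  lo <- lower * d
  up <- upper * d

  z <- tryCatch(drop(solve(A, r)), error = function(e) NULL)
  if (!is.null(z) && all(z >= lo & z <= up))
    return(unname(z / d))

  combos <- active_set_table(p)
  kkt_tol <- 1e-9 * max(abs(r), 1)
  best <- NULL
  best_q <- Inf
  for (k in seq_len(nrow(combos))) {
    st <- combos[k, ]
    b <- ifelse(st == 1, lo, up)   # placeholder for free slots too
    free <- st == 0
    if (any(free)) {
      rhs <- r[free]
      if (any(!free)) rhs <- rhs - drop(A[free, !free, drop = FALSE] %*%
                                          b[!free])
      bf <- tryCatch(drop(solve(A[free, free, drop = FALSE], rhs)),
                     error = function(e) NULL)
      if (is.null(bf)) next
      # an ill-conditioned solve may overshoot the box slightly; keep the
      # clipped point as a candidate rather than discarding the active set
      b[free] <- pmin(pmax(bf, lo[free]), up[free])
      exact <- all(bf >= lo[free] - 1e-9) && all(bf <= up[free] + 1e-9)
    } else exact <- TRUE
    g <- drop(A %*% b) - r
    if (exact && all(g[st == 1] >= -kkt_tol) && all(g[st == 2] <= kkt_tol))
      return(unname(b / d))     # KKT point of a convex QP: global optimum
    q <- sum(b * g) - sum(b * r)
    if (is.null(best) || q < best_q) {
      best_q <- q
      best <- b
    }
  }
  if (is.null(best)) best <- pmin(pmax(rep(0, p), lo), up)
  # cyclic coordinate-descent polish: monotone on the convex objective,
  # cleans up clipped candidates along badly conditioned directions
  for (sweep in 1:200) {
    delta <- 0
    for (j in 1:p) {
      if (A[j, j] <= 0) next
      bj <- (r[j] - sum(A[j, -j] * best[-j])) / A[j, j]
      bj <- min(max(bj, lo[j]), up[j])
      delta <- max(delta, abs(bj - best[j]))
      best[j] <- bj
    }
    if (delta < 1e-13 * max(1, max(abs(best)))) break
  }
  unname(best / d)
}

bounded_ls <- function(X, y, lower, upper) {
  bounded_ls_normal(crossprod(X), crossprod(X, y), lower, upper)
}

# Closures computing the pooled RSS profiled over the per-rat linear
# parameters, together with its exact gradient in the time constants.
# At the inner optimum the envelope theorem gives
#   d RSS / d tau_m = -2 sum_r r' (dX/dtau_m) beta,
# with the residuals r and coefficients beta held at their optimum, so no
# finite differencing of the inner solve is needed. The per-rat
# observation blocks are precomputed once; objective and gradient share
# one evaluation memoized on tau.
make_profiled_objective <- function(variant, cohort, lower, upper, sign) {
  rats <- lapply(cohort$rats, function(s)
    list(w = s$w, md = s$measured_days, y = s$p_obs,
         yty = sum(s$p_obs^2)))
  s3 <- if (sign == "plus") 1 else -1
  last_tau <- NULL
  last <- NULL

  evaluate <- function(tau) {
    total <- 0
    grad <- numeric(length(tau))
    for (s in rats) {
      w <- s$w; md <- s$md
      a1 <- decay_filter(w, tau[1])
      X <- switch(variant,
        ONE_COMP = cbind(1, a1[md]),
        TWO_COMP = cbind(1, a1[md], -decay_filter(w, tau[2])[md]),
        THREE_COMP = {
          v <- w * decay_filter_inclusive(w, tau[3])
          cbind(1, a1[md], -decay_filter(w, tau[2])[md],
                -s3 * decay_filter(v, tau[2])[md])
        })
      xtx <- crossprod(X)
      xty <- crossprod(X, s$y)
      beta <- bounded_ls_normal(xtx, xty, lower, upper)
      r <- s$y - drop(X %*% beta)
      total <- total + sum(r * r)
      grad[1] <- grad[1] -
        2 * beta[2] * sum(r * decay_filter_lagweighted(w, tau[1])[md]) /
        tau[1]^2
      if (variant == "TWO_COMP")
        grad[2] <- grad[2] +
          2 * beta[3] * sum(r * decay_filter_lagweighted(w, tau[2])[md]) /
          tau[2]^2
      if (variant == "THREE_COMP") {
        v <- w * decay_filter_inclusive(w, tau[3])
        grad[2] <- grad[2] + 2 / tau[2]^2 *
          sum(r * (beta[3] * decay_filter_lagweighted(w, tau[2])[md] +
                   s3 * beta[4] * decay_filter_lagweighted(v, tau[2])[md]))
        dv <- w * decay_filter_lagweighted_inclusive(w, tau[3]) / tau[3]^2
        grad[3] <- grad[3] +
          2 * s3 * beta[4] * sum(r * decay_filter(dv, tau[2])[md])
      }
    }
    list(rss = total, grad = grad)
  }

  memo <- function(tau) {
    if (is.null(last_tau) || !identical(tau, last_tau)) {
      last <<- evaluate(tau)
      last_tau <<- tau
    }
    last
  }
  list(obj = function(tau) memo(tau)$rss,
       grad = function(tau) memo(tau)$grad)
}

# Profile out the linear parameters: pooled RSS at fixed time constants.
profiled_rss <- function(tau, variant, cohort, lower, upper, sign) {
  make_profiled_objective(variant, cohort, lower, upper, sign)$obj(tau)
}

#' Fit a systems model jointly to a cohort
#'
#' Minimises the pooled residual sum of squares ([pooled_rss()]) with time
#' constants common to all rats and intercept and gain factors specific to
#' each rat (the mixed-effects structure of the joint fit). Because the
#' model is linear in the intercept and gains at fixed time constants, the
#' linear parameters are profiled out by per-rat bounded least squares
#' inside a bounded multistart quasi-Newton search over the time constants
#' (variable projection). Starts are drawn log-uniformly within
#' `tau_bounds` under the configured seed; the lowest-RSS start wins, ties
#' broken by start order.
#'
#' @param cohort an `ffm_cohort`.
#' @param variant model variant, see [MODEL_VARIANTS].
#' @param config a [fit_config()].
#' @param extra_starts optional matrix (or vector) of additional
#'   time-constant start points, one row per start — used to warm-start a
#'   richer model from a poorer model's solution so that nested fits can
#'   only improve.
#' @return object of class `ffm_fit`: fitted `shared` time constants,
#'   `per_rat` parameter table, `rss`, per-rat `predictions` (full daily
#'   series), `df`, `n_obs`, `converged`, multistart diagnostics in
#'   `starts`, and identifiability `warnings`.
#' @examples
#' coh <- generate_cohort(cohort_design(n_rats = 4, noise_sd = 0), seed = 7)
#' fit <- fit_model(coh$cohort, "TWO_COMP", fit_config(n_starts = 5))
#' fit$shared
#' @export
fit_model <- function(cohort, variant, config = fit_config(),
                      extra_starts = NULL) {
  stopifnot(inherits(cohort, "ffm_cohort"))
  variant <- match.arg(variant, MODEL_VARIANTS)
  if (!inherits(config, "fit_config")) stop("config must be a fit_config",
                                            call. = FALSE)
  p_rat <- 1L + n_gains(variant)          # per-rat linear parameters
  if (any(cohort$N_per_rat < p_rat))
    stop(sprintf(
      "underdetermined: rat(s) %s have fewer measured days than the %d free parameters per rat",
      paste(names(cohort$rats)[cohort$N_per_rat < p_rat], collapse = ", "),
      p_rat), call. = FALSE)

  nt <- n_tau(variant)
  p_max <- max(unlist(lapply(cohort$rats, `[[`, "p_obs")))
  lower <- c(0, rep(config$gain_bounds[1], n_gains(variant)))
  upper <- c(config$p0_upper_mult * p_max,
             rep(config$gain_bounds[2], n_gains(variant)))
  sign <- config$third_component_sign
  obj <- make_profiled_objective(variant, cohort, lower, upper, sign)

  lb <- log(config$tau_bounds[1]); ub <- log(config$tau_bounds[2])
  starts <- local_seed(config$seed, {
    matrix(exp(stats::runif(config$n_starts * nt, lb, ub)),
           ncol = nt)
  })
  if (!is.null(extra_starts)) {
    extra_starts <- matrix(as.numeric(extra_starts), ncol = nt)
    extra_starts[] <- pmin(pmax(extra_starts, config$tau_bounds[1]),
                           config$tau_bounds[2])
    starts <- rbind(starts, extra_starts)
  }

  runs <- lapply(seq_len(nrow(starts)), function(i) {
    res <- tryCatch(
      stats::nlminb(starts[i, ], obj$obj, gradient = obj$grad,
                    lower = rep(config$tau_bounds[1], nt),
                    upper = rep(config$tau_bounds[2], nt),
                    control = list(rel.tol = config$rel_tol,
                                   x.tol = config$step_tol,
                                   iter.max = 500, eval.max = 1000)),
      error = function(e) NULL)
    if (is.null(res))
      return(list(tau = starts[i, ], rss = Inf, converged = FALSE))
    list(tau = res$par, rss = res$objective, converged = res$convergence == 0)
  })
  rss_all <- vapply(runs, `[[`, numeric(1), "rss")
  if (!any(is.finite(rss_all)))
    stop("no optimizer start converged; per-start diagnostics attached",
         call. = FALSE)
  best <- which.min(rss_all)            # which.min takes the first minimum
  tau_hat <- runs[[best]]$tau
  names(tau_hat) <- tau_names(variant)

  warnings <- character()
  per_rat <- do.call(rbind, lapply(seq_len(cohort$R), function(r) {
    s <- cohort$rats[[r]]
    X <- model_design_matrix(variant, s, tau_hat, sign)[s$measured_days, ,
                                                        drop = FALSE]
    if (qr(X)$rank < ncol(X))
      warnings <<- c(warnings, sprintf(
        "rat %s: design rank-deficient at the solution; gains not uniquely identified",
        s$rat_id))
    beta <- bounded_ls(X, s$p_obs, lower, upper)
    out <- as.data.frame(as.list(beta))
    names(out) <- c("p0", gain_names(variant))
    cbind(data.frame(rat_id = s$rat_id), out)
  }))
  rownames(per_rat) <- NULL

  params_list <- lapply(seq_len(cohort$R), function(r)
    make_rat_params(variant, per_rat[r, ], tau_hat, sign))
  predictions <- lapply(seq_len(cohort$R), function(r)
    predict_performance(params_list[[r]], cohort$rats[[r]]))
  names(predictions) <- names(cohort$rats)
  rss <- pooled_rss(cohort, params_list)

  structure(list(
    variant = variant, shared = tau_hat, per_rat = per_rat,
    params_per_rat = params_list, rss = rss, predictions = predictions,
    df = model_df(variant, cohort$R,
                  count_intercepts = config$count_intercepts_in_df),
    n_obs = cohort$N, converged = runs[[best]]$converged,
    n_starts = nrow(starts), best_start = best,
    starts = data.frame(start = seq_along(runs),
                        rss = rss_all,
                        converged = vapply(runs, `[[`, logical(1),
                                           "converged")),
    warnings = warnings, config = config), class = "ffm_fit")
}

make_rat_params <- function(variant, row, tau, sign) {
  switch(variant,
    ONE_COMP = model_params("ONE_COMP", p0 = row$p0, k1 = row$k1,
                            tau1 = tau[[1]]),
    TWO_COMP = model_params("TWO_COMP", p0 = row$p0, k1 = row$k1,
                            tau1 = tau[[1]], k2 = row$k2, tau2 = tau[[2]]),
    THREE_COMP = model_params("THREE_COMP", p0 = row$p0, k1 = row$k1,
                              tau1 = tau[[1]], k2_0 = row$k2_0,
                              tau2 = tau[[2]], k3 = row$k3, tau3 = tau[[3]],
                              third_component_sign = sign))
}

#' @export
print.ffm_fit <- function(x, ...) {
  cat(sprintf("<ffm_fit %s> %d rats, N = %d\n", x$variant,
              nrow(x$per_rat), x$n_obs))
  cat("  shared: ", paste(sprintf("%s = %.3f d", names(x$shared), x$shared),
                          collapse = ", "), "\n", sep = "")
  cat(sprintf("  RSS = %.5g W^2, df = %d, best of %d starts%s\n", x$rss,
              x$df, x$n_starts,
              if (length(x$warnings)) sprintf(" (%d warning(s))",
                                              length(x$warnings)) else ""))
  invisible(x)
}

#' Serialize a fit
#'
#' Writes the fitted shared constants, per-rat parameters, RSS and
#' multistart diagnostics as JSON, and optionally the per-rat parameter
#' table as CSV.
#'
#' @param fit an `ffm_fit`.
#' @param path JSON output path.
#' @param csv_path optional CSV path for the per-rat parameter table.
#' @export
write_fit_result <- function(fit, path, csv_path = NULL) {
  out <- list(variant = fit$variant, shared = as.list(fit$shared),
              per_rat = fit$per_rat, rss = fit$rss, df = fit$df,
              n_obs = fit$n_obs, converged = fit$converged,
              n_starts = fit$n_starts, best_start = fit$best_start,
              starts = fit$starts, warnings = fit$warnings)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  if (!is.null(csv_path))
    utils::write.csv(fit$per_rat, csv_path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Evaluate an expression under a temporary RNG seed, restoring the caller's
# RNG state afterwards.
local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
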