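#' Model degrees of freedom
#'
#' Free-parameter count under the convention used for the cohort fits: one
#' gain factor per rat per component plus the shared time constants, so
#' `C * n_rats + C` for a model with `C` components. Per-rat intercepts are
#' excluded by default; set `count_intercepts` to include them.
#'
#' For an 11-rat cohort this gives 12, 24 and 36 for the one-, two- and
#' three-component models.
#'
#' @param variant model variant, see [MODEL_VARIANTS].
#' @param n_rats number of rats in the cohort.
#' @param count_intercepts include the per-rat intercepts in the count.
#' @return integer degrees of freedom.
#' @export
model_df <- function(variant, n_rats, count_intercepts = FALSE) {
  variant <- match.arg(variant, MODEL_VARIANTS)
  stopifnot(n_rats >= 1)
  C <- n_gains(variant)
  df <- C * n_rats + n_tau(variant)
  if (count_intercepts) df <- df + n_rats
  as.integer(df)
}

#' Goodness-of-fit diagnostics for a cohort fit
#'
#' Computes the coefficient of determination about the pooled grand mean of
#' all observed performances, its df-adjusted version, the overall-fit
#' F ratio with (df, N - df - 1) degrees of freedom, and the residual mean
#' square:
#' \deqn{R^2 = 1 - RSS/SS_{tot}, \quad
#'       Adj.R^2 = 1 - (1 - R^2)\frac{N-1}{N-df-1},}
#' \deqn{F = \frac{R^2/df}{(1-R^2)/(N-df-1)}, \quad
#'       MSE = \frac{RSS}{N-df-1}.}
#'
#' @param fit an `ffm_fit` produced on `cohort`, or a list with elements
#'   `rss`, `df`, `n_obs` (so printed statistics can be re-derived from
#'   reported RSS/R^2 values via [gof_from_r2()]).
#' @param cohort the `ffm_cohort` the fit was produced on.
#' @param per_rat_centering centre the total sum of squares per rat instead
#'   of about the pooled grand mean.
#' @return list of class `fit_diagnostics`: `r2`, `adj_r2`, `f_ratio`,
#'   `df_model`, `df_resid`, `p_value`, `mse`, `rmse`.
#' @export
goodness_of_fit <- function(fit, cohort, per_rat_centering = FALSE) {
  stopifnot(inherits(cohort, "ffm_cohort"))
  p_all <- unlist(lapply(cohort$rats, `[[`, "p_obs"))
  ss_tot <- if (per_rat_centering) {
    sum(vapply(cohort$rats, function(s) sum((s$p_obs - mean(s$p_obs))^2),
               numeric(1)))
  } else sum((p_all - mean(p_all))^2)
  r2 <- 1 - fit$rss / ss_tot
  gof_from_r2(r2, fit$df, fit$n_obs, rss = fit$rss)
}

#' @rdname goodness_of_fit
#' @param r2 coefficient of determination.
#' @param df model degrees of freedom.
#' @param n_obs total number of observations N.
#' @param rss optional RSS, used for `mse`/`rmse` when available.
#' @export
gof_from_r2 <- function(r2, df, n_obs, rss = NA_real_) {
  df_resid <- n_obs - df - 1
  if (df_resid <= 0)
    stop("no residual degrees of freedom: N <= df + 1", call. = FALSE)
  adj_r2 <- 1 - (1 - r2) * (n_obs - 1) / df_resid
  f_ratio <- (r2 / df) / ((1 - r2) / df_resid)
  structure(list(r2 = r2, adj_r2 = adj_r2, f_ratio = f_ratio,
                 df_model = as.integer(df), df_resid = as.integer(df_resid),
                 p_value = stats::pf(f_ratio, df, df_resid,
                                     lower.tail = FALSE),
                 mse = rss / df_resid, rmse = sqrt(rss / df_resid)),
            class = "fit_diagnostics")
}

#' @export
print.fit_diagnostics <- function(x, ...) {
  cat(sprintf("R2 = %.3f, Adj.R2 = %.3f, F(%d, %d) = %.2f, p = %.3g\n",
              x$r2, x$adj_r2, x$df_model, x$df_resid, x$f_ratio, x$p_value))
  if (is.finite(x$mse))
    cat(sprintf("residual MSE = %.4g W^2 (RMSE %.4g W)\n", x$mse, x$rmse))
  invisible(x)
}

#' Nested-model F-ratio test
#'
#' Tests whether the extra components of the larger model significantly
#' reduce the residual variation:
#' \deqn{F = \frac{(RSS_s - RSS_l)/(df_l - df_s)}{RSS_l/(N - df_l - 1)}}
#' referred to an F distribution with `(df_l - df_s, N - df_l - 1)` degrees
#' of freedom.
#'
#' @param fit_small,fit_large `ffm_fit`s (or lists with `rss`, `df`,
#'   `n_obs`) of nested variants on the same cohort.
#' @return list of class `nested_test`: `f`, `df1`, `df2`, `p_value`, plus
#'   the two RSS values.
#' @export
compare_nested <- function(fit_small, fit_large) {
  if (fit_small$n_obs != fit_large$n_obs)
    stop("fits are not on the same observations", call. = FALSE)
  if (fit_small$df >= fit_large$df)
    stop("fit_small must have fewer degrees of freedom", call. = FALSE)
  if (fit_large$rss > fit_small$rss * (1 + 1e-12))
    stop("larger model has larger RSS; nested fitting failed (warm-start the richer model)",
         call. = FALSE)
  df1 <- fit_large$df - fit_small$df
  df2 <- fit_large$n_obs - fit_large$df - 1
  f <- ((fit_small$rss - fit_large$rss) / df1) / (fit_large$rss / df2)
  f <- max(f, 0)   # guard tiny negative from the tolerance above
  structure(list(f = f, df1 = as.integer(df1), df2 = as.integer(df2),
                 p_value = stats::pf(f, df1, df2, lower.tail = FALSE),
                 rss_small = fit_small$rss, rss_large = fit_large$rss),
            class = "nested_test")
}

#' @export
print.nested_test <- function(x, ...) {
  cat(sprintf("nested F(%d, %d) = %.3f, p = %.4g (RSS %.5g -> %.5g)\n",
              x$df1, x$df2, x$f, x$p_value, x$rss_small, x$rss_large))
  invisible(x)
}

#' Shapiro-Wilk normality check
#'
#' Thin wrapper around [stats::shapiro.test()] used to check the normality
#' of the model inputs (training loads) and outputs (performances).
#'
#' @param values numeric vector, 3 to 5000 values with nonzero variance.
#' @return list with `w` (test statistic) and `p_value`.
#' @export
normality_check <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 3 || length(values) > 5000)
    stop("normality check needs between 3 and 5000 finite values",
         call. = FALSE)
  if (stats::sd(values) == 0)
    stop("normality check undefined for a constant sequence", call. = FALSE)
  ht <- stats::shapiro.test(values)
  list(w = unname(ht$statistic), p_value = ht$p.value)
}

#' Model-comparison table for the three variants
#'
#' Fits all three variants to a cohort (each richer model warm-started from
#' the poorer model's time constants so nested fits can only improve) and
#' assembles a comparison table: one row of goodness-of-fit statistics per
#' variant plus one row per pairwise nested F test.
#'
#' @param cohort an `ffm_cohort`.
#' @param config a [fit_config()].
#' @return list with `fits` (named list of `ffm_fit`), `table` (data.frame
#'   with columns `model`, `r2`, `adj_r2`, `f_ratio`, `df_model`,
#'   `df_resid`, `p_value`, `mse`) and `nested` (data.frame of pairwise
#'   tests).
#' @export
model_comparison_table <- function(cohort, config = fit_config()) {
  fits <- fit_all_variants(cohort, config)
  gofs <- lapply(fits, goodness_of_fit, cohort = cohort)
  tab <- do.call(rbind, Map(function(nm, g)
    data.frame(model = nm, r2 = g$r2, adj_r2 = g$adj_r2,
               f_ratio = g$f_ratio, df_model = g$df_model,
               df_resid = g$df_resid, p_value = g$p_value, mse = g$mse),
    names(gofs), gofs))
  rownames(tab) <- NULL
  pairs <- list(c("ONE_COMP", "TWO_COMP"), c("TWO_COMP", "THREE_COMP"))
  nested <- do.call(rbind, lapply(pairs, function(pr) {
    ct <- compare_nested(fits[[pr[1]]], fits[[pr[2]]])
    data.frame(smaller = pr[1], larger = pr[2], f = ct$f, df1 = ct$df1,
               df2 = ct$df2, p_value = ct$p_value)
  }))
  list(fits = fits, table = tab, nested = nested)
}

#' @rdname model_comparison_table
#' @export
fit_all_variants <- function(cohort, config = fit_config()) {
  f1 <- fit_model(cohort, "ONE_COMP", config)
  t1 <- unname(f1$shared[1])
  f2 <- fit_model(cohort, "TWO_COMP", config,
                  extra_starts = rbind(c(t1, t1 * 0.75), c(t1, t1 * 1.25)))
  t2 <- unname(f2$shared)
  f3 <- fit_model(cohort, "THREE_COMP", config,
                  extra_starts = rbind(c(t2, t2[2]), c(t2, t2[1])))
  list(ONE_COMP = f1, TWO_COMP = f2, THREE_COMP = f3)
}
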