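test_that("pooled RSS accumulates squared residuals over measured days", {
  # one rat, one measured day, p = 1, p_hat = 0.5 under a null model
  s <- training_series("r", w = rep(0, 3), measured_days = 2, p_obs = 1)
  coh <- cohort_data(list(s))
  pars <- list(model_params("ONE_COMP", p0 = 0.5, k1 = 0, tau1 = 1))
  expect_equal(pooled_rss(coh, pars), 0.25)

  # predictions equal to observations give zero
  pars0 <- list(model_params("ONE_COMP", p0 = 1, k1 = 0, tau1 = 1))
  expect_equal(pooled_rss(coh, pars0), 0)
})

test_that("pooled RSS matches brute-force accumulation on a random cohort", {
  set.seed(21)
  rats <- lapply(1:3, function(r) {
    w <- random_impulse_train(15)
    md <- sort(sample(2:15, 6))
    training_series(paste0("r", r), w, measured_days = md,
                    p_obs = runif(6, 0.3, 1.5))
  })
  coh <- cohort_data(rats)
  pars <- lapply(1:3, function(r)
    model_params("TWO_COMP", p0 = runif(1, 0, 1), k1 = runif(1, 0, 0.05),
                 tau1 = 6.1, k2 = runif(1, 0, 0.05), tau2 = 3.3))
  brute <- sum(unlist(lapply(1:3, function(r) {
    ph <- predict_direct(pars[[r]], rats[[r]])
    (rats[[r]]$p_obs - ph[rats[[r]]$measured_days])^2
  })))
  expect_equal(pooled_rss(coh, pars), brute, tolerance = 1e-12)
})

test_that("pooled RSS rejects inconsistent shared time constants", {
  s <- training_series("r", rep(0, 3), measured_days = 2, p_obs = 1)
  s2 <- training_series("q", rep(0, 3), measured_days = 2, p_obs = 1)
  coh <- cohort_data(list(s, s2))
  pars <- list(model_params("ONE_COMP", 1, 0, tau1 = 5),
               model_params("ONE_COMP", 1, 0, tau1 = 6))
  expect_error(pooled_rss(coh, pars), "tau1")
  mixed <- list(model_params("ONE_COMP", 1, 0, tau1 = 5),
                model_params("TWO_COMP", 1, 0, tau1 = 5, k2 = 0,
                             tau2 = 4))
  expect_error(pooled_rss(coh, mixed), "variant")
})

test_that("box-constrained inner solver matches a general-purpose optimizer", {
  set.seed(17)
  for (i in 1:40) {
    X <- cbind(1, matrix(rnorm(60), 20, 3))
    y <- rnorm(20, sd = 2)
    lo <- rep(0, 4)
    up <- c(5, 1, 1, 1)
    b <- fitnessfatigue:::bounded_ls_normal(crossprod(X), crossprod(X, y),
                                            lo, up)
    expect_true(all(b >= lo - 1e-12) && all(b <= up + 1e-12))
    f <- function(b) sum((y - X %*% b)^2)
    ref <- stats::optim(pmin(pmax(drop(qr.solve(X, y)), lo), up), f,
                        lower = lo, upper = up, method = "L-BFGS-B")
    expect_lte(f(b), ref$value + 1e-8)
  }
})

test_that("a noiseless two-component cohort is recovered to within 1%", {
  syn <- generate_cohort(cohort_design(n_rats = 6, noise_sd = 0), seed = 3)
  fit <- fit_model(syn$cohort, "TWO_COMP", fit_config(n_starts = 8))
  expect_lt(abs(fit$shared[["tau1"]] - 5.31) / 5.31, 0.01)
  expect_lt(abs(fit$shared[["tau2"]] - 4.3) / 4.3, 0.01)
  p2 <- sum(unlist(lapply(syn$cohort$rats, `[[`, "p_obs"))^2)
  expect_lt(fit$rss, 1e-6 * p2)
  # reported RSS is self-consistent with the returned parameters
  expect_equal(fit$rss, pooled_rss(syn$cohort, fit$params_per_rat),
               tolerance = 1e-10)
})

test_that("an all-rest cohort pins p0 and flags unidentifiable gains", {
  s <- training_series("r", w = rep(0, 8), measured_days = c(2, 4, 6),
                       p_obs = rep(0.7, 3))
  fit <- fit_model(cohort_data(list(s)), "ONE_COMP",
                   fit_config(n_starts = 3))
  expect_equal(fit$per_rat$p0, 0.7, tolerance = 1e-8)
  expect_equal(fit$rss, 0, tolerance = 1e-12)
  expect_true(length(fit$warnings) > 0)
})

test_that("underdetermined cohorts are refused with a clear error", {
  s <- training_series("r", w = c(10, 0, 10, 0), measured_days = c(1, 3),
                       p_obs = c(0.5, 0.6))
  expect_error(fit_model(cohort_data(list(s)), "TWO_COMP", fit_config()),
               "underdetermined")
})

test_that("the fit does not depend on rat ordering", {
  syn <- generate_cohort(cohort_design(n_rats = 4), seed = 8)
  cfg <- fit_config(n_starts = 4)
  fit_fwd <- fit_model(syn$cohort, "TWO_COMP", cfg)
  fit_rev <- fit_model(cohort_data(rev(syn$cohort$rats)), "TWO_COMP", cfg)
  expect_equal(fit_rev$rss, fit_fwd$rss, tolerance = 1e-8)
  expect_equal(fit_rev$shared, fit_fwd$shared, tolerance = 1e-6)
})

test_that("recovered time constants converge to truth as noise shrinks", {
  errs <- sapply(c(0, 0.02), function(sg) {
    syn <- generate_cohort(cohort_design(n_rats = 6, noise_sd = sg),
                           seed = 19)
    fit <- fit_model(syn$cohort, "TWO_COMP", fit_config(n_starts = 6),
                     extra_starts = c(5.31, 4.3))
    max(abs(fit$shared - c(5.31, 4.3)) / c(5.31, 4.3))
  })
  expect_lt(errs[1], 1e-4)
  expect_lt(errs[2], 0.25)
})

test_that("fit configuration round-trips and rejects unknown keys", {
  cfg <- fit_config(n_starts = 7, seed = 42, tau_bounds = c(1, 30),
                    third_component_sign = "minus")
  path <- withr::local_tempfile(fileext = ".json")
  write_fit_config(cfg, path)
  expect_equal(read_fit_config(path), cfg)
  bad <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(n_starts = 3, optimizer = "simplex"), bad,
                       auto_unbox = TRUE)
  expect_error(read_fit_config(bad), "optimizer")
})

test_that("profiled objective equals RSS of the assembled parameters", {
  syn <- generate_cohort(cohort_design(n_rats = 3), seed = 31)
  coh <- syn$cohort
  pm <- max(unlist(lapply(coh$rats, `[[`, "p_obs")))
  lo <- c(0, 0, 0)
  up <- c(10 * pm, 1, 1)
  tau <- c(5.31, 4.3)
  val <- fitnessfatigue:::profiled_rss(tau, "TWO_COMP", coh, lo, up, "plus")
  # reassemble the inner solutions and recompute through the model itself
  pars <- lapply(coh$rats, function(s) {
    X <- fitnessfatigue:::model_design_matrix("TWO_COMP", s,
                                              tau)[s$measured_days, ]
    b <- fitnessfatigue:::bounded_ls(X, s$p_obs, lo, up)
    model_params("TWO_COMP", p0 = b[1], k1 = b[2], tau1 = tau[1],
                 k2 = b[3], tau2 = tau[2])
  })
  expect_equal(val, pooled_rss(coh, pars), tolerance = 1e-10)
})
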