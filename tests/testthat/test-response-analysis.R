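test_that("response characteristics match the closed-form expressions", {
  rc <- response_characteristics(k1 = 0.0186, tau1 = 5.31, k2 = 0.0200,
                                 tau2 = 4.3)
  expect_equal(rc$tn, 5.31 * 4.3 / (5.31 - 4.3) * log(0.02 / 0.0186))
  expect_equal(round(rc$tn, 3), 1.641)
  expect_equal(round(rc$tg, 2), 6.41)
  expect_equal(round(rc$pg, 5), 0.00106)
  expect_true(all(rc$defined))

  # equal gains: the response never dips below baseline, tn = 0
  rc0 <- response_characteristics(k1 = 0.02, tau1 = 5.31, k2 = 0.02,
                                  tau2 = 4.3)
  expect_equal(rc0$tn, 0)
  expect_true(rc0$defined[["tn"]])
})

test_that("non-physical parameter combinations are flagged, not thrown", {
  # k2 < k1 with tau1 > tau2: no dip, tn formula would be negative
  rc <- response_characteristics(k1 = 0.03, tau1 = 5.31, k2 = 0.01,
                                 tau2 = 4.3)
  expect_true(is.na(rc$tn))
  expect_false(rc$defined[["tn"]])

  expect_error(response_characteristics(0.02, 5, 0.02, 5), "tau1")
  expect_error(response_characteristics(-0.02, 5, 0.02, 4), "> 0")
})

test_that("tn and tg agree with a densely simulated unit-impulse response", {
  set.seed(61)
  for (i in 1:12) {
    tau1 <- runif(1, 3, 15)
    tau2 <- tau1 * runif(1, 0.35, 0.9)
    k1 <- runif(1, 0.005, 0.04)
    k2 <- k1 * runif(1, 1.05, 2.5)
    rc <- response_characteristics(k1, tau1, k2, tau2)
    t_grid <- seq(0.005, 300, by = 0.005)
    h <- k1 * exp(-t_grid / tau1) - k2 * exp(-t_grid / tau2)
    tn_grid <- t_grid[which(h > 0)[1]]
    tg_grid <- t_grid[which.max(h)]
    expect_lt(abs(rc$tn - tn_grid), 0.0051)
    expect_lt(abs(rc$tg - tg_grid), 0.0051)
    expect_equal(rc$pg, max(h), tolerance = 1e-6)
  }
})

test_that("pg scales linearly with a common gain factor", {
  rc <- response_characteristics(0.0186, 5.31, 0.0200, 4.3)
  rc3 <- response_characteristics(3 * 0.0186, 5.31, 3 * 0.0200, 4.3)
  expect_equal(rc3$pg, 3 * rc$pg)
  expect_equal(rc3$tn, rc$tn)   # times are gain-ratio properties
  expect_equal(rc3$tg, rc$tg)
})

test_that("influence terms sum exactly to the modeled performance change", {
  set.seed(77)
  for (i in 1:8) {
    s <- impulse_series(random_impulse_train(26))
    p <- model_params("TWO_COMP", p0 = runif(1, 0, 1),
                      k1 = runif(1, 0, 0.05), tau1 = runif(1, 2, 20),
                      k2 = runif(1, 0, 0.05), tau2 = runif(1, 2, 20))
    infl <- influence_decomposition(p, s)
    expect_true(all(infl$in_n <= 0))
    expect_true(all(infl$ip_n >= 0))
    expect_equal(infl$ip_n + infl$in_n, predict_2comp(p, s) - p$p0,
                 tolerance = 1e-10)
  }
})

test_that("influence decomposition degenerates correctly", {
  s <- impulse_series(c(40, 0, 40, 0, 0, 0))
  p <- model_params("TWO_COMP", p0 = 0.4, k1 = 0.02, tau1 = 5, k2 = 0,
                    tau2 = 4)
  infl <- influence_decomposition(p, s)
  expect_equal(infl$in_n, rep(0, 6))
  expect_equal(infl$ip_n, predict_2comp(p, s) - 0.4)

  s0 <- impulse_series(rep(0, 6))
  infl0 <- influence_decomposition(p, s0)
  expect_equal(infl0$ip_n, rep(0, 6))
  expect_equal(infl0$in_n, rep(0, 6))

  p1 <- model_params("ONE_COMP", 0, 1, 1)
  expect_error(influence_decomposition(p1, s), "ONE_COMP")
})

# Minimal hand-built TWO_COMP fit object for summary-level functions.
fake_fit <- function(params_list) {
  per_rat <- do.call(rbind, lapply(params_list, function(p)
    data.frame(rat_id = "x", p0 = p$p0, k1 = p$k1, k2 = p$k2)))
  per_rat$rat_id <- paste0("r", seq_along(params_list))
  structure(list(variant = "TWO_COMP",
                 shared = c(tau1 = params_list[[1]]$tau1,
                            tau2 = params_list[[1]]$tau2),
                 per_rat = per_rat, params_per_rat = params_list),
            class = "ffm_fit")
}

test_that("cohort influence summary averages rats with SEM", {
  s <- impulse_series(c(10, 0, 0, 0))
  tau1 <- 5; tau2 <- 2
  # choose gains so each rat's ip on day 2 is exactly 1 and 3
  k_for <- function(target) target / (10 * exp(-1 / tau1))
  mk <- function(k1) model_params("TWO_COMP", p0 = 0, k1 = k1, tau1 = tau1,
                                  k2 = 0, tau2 = tau2)
  fit <- fake_fit(list(mk(k_for(1)), mk(k_for(3))))
  coh <- cohort_data(list(training_series("r1", s$w, 2, 1),
                          training_series("r2", s$w, 2, 3)))
  summ <- cohort_influence_summary(fit, coh)
  expect_equal(summ$ip_mean[2], 2)
  expect_equal(summ$ip_sem[2], 1)

  # identical rats: zero SEM everywhere
  fit_same <- fake_fit(list(mk(0.02), mk(0.02)))
  summ_same <- cohort_influence_summary(fit_same, coh)
  expect_equal(summ_same$ip_sem, rep(0, 4))

  # single rat: SEM undefined
  fit1 <- fake_fit(list(mk(0.02)))
  coh1 <- cohort_data(list(training_series("r1", s$w, 2, 1)))
  expect_true(all(is.na(cohort_influence_summary(fit1, coh1)$ip_sem)))
})

test_that("cohort response characteristics are means of per-rat values", {
  tau1 <- 5.31; tau2 <- 4.3
  mk <- function(k1, k2) model_params("TWO_COMP", p0 = 0.4, k1 = k1,
                                      tau1 = tau1, k2 = k2, tau2 = tau2)
  fit <- fake_fit(list(mk(0.0186, 0.0200), mk(0.010, 0.025)))
  rc <- cohort_response_characteristics(fit)
  expect_equal(nrow(rc$per_rat), 2)
  tn_each <- sapply(1:2, function(r)
    response_characteristics(rc$per_rat$k1[r], tau1, rc$per_rat$k2[r],
                             tau2)$tn)
  expect_equal(rc$summary$mean[rc$summary$quantity == "tn"],
               mean(tn_each))
  # a rat with k2 < k1 contributes no tn but is not fatal
  fit2 <- fake_fit(list(mk(0.0186, 0.0200), mk(0.03, 0.01)))
  rc2 <- cohort_response_characteristics(fit2)
  expect_equal(rc2$summary$n_defined[rc2$summary$quantity == "tn"], 1)
})

test_that("influences on default synthetic cohorts follow the expected shape", {
  syn <- generate_cohort(cohort_design(), seed = 1)
  # use the true parameters directly: the qualitative shape is a property
  # of the generating model, not of any particular fit
  fit <- fake_fit(syn$truth)
  summ <- cohort_influence_summary(fit, syn$cohort)
  # positive influence accumulates over the program
  expect_gt(summ$ip_mean[26], summ$ip_mean[10])
  expect_gt(summ$ip_mean[10], summ$ip_mean[2])
  # negative influence relaxes toward zero across each weekend gap
  # (days 6-7, 13-14, 20-21 are rest; compare end of week vs after rest)
  expect_gt(summ$in_mean[8], summ$in_mean[6])   # in is negative: closer to 0
  expect_gt(summ$in_mean[15], summ$in_mean[13])
  expect_gt(summ$in_mean[22], summ$in_mean[20])
})
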