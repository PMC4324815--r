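test_that("single-impulse responses match their closed forms", {
  s <- impulse_series(c(1, 0, 0, 0, 0, 0))
  p1 <- model_params("ONE_COMP", p0 = 0, k1 = 1, tau1 = 1)
  expect_equal(predict_1comp(p1, s)[2], exp(-1))
  expect_equal(predict_1comp(p1, s)[1], 0)   # day 1 sees no training

  s10 <- impulse_series(c(10, 0, 0, 0, 0, 0))
  p2 <- model_params("TWO_COMP", p0 = 0, k1 = 2, tau1 = 5, k2 = 1,
                     tau2 = 2)
  expect_equal(predict_2comp(p2, s10)[6], 20 * exp(-1) - 10 * exp(-2.5))
})

test_that("no training means performance stays at p0", {
  s <- impulse_series(rep(0, 15))
  expect_equal(predict_1comp(model_params("ONE_COMP", 0.4, 0.02, 5), s),
               rep(0.4, 15))
  expect_equal(predict_3comp(
    model_params("THREE_COMP", p0 = 0.4, k1 = 0.02, tau1 = 5,
                 k2_0 = 0.02, tau2 = 4, k3 = 1e-5, tau3 = 8), s),
    rep(0.4, 15))
})

test_that("the variants nest exactly", {
  set.seed(41)
  s <- impulse_series(random_impulse_train(30))
  base <- list(p0 = 0.4, k1 = 0.02, tau1 = 5.3)
  p1 <- do.call(model_params, c(variant = "ONE_COMP", base))
  p2 <- do.call(model_params, c(variant = "TWO_COMP", base,
                                list(k2 = 0, tau2 = 4.3)))
  expect_equal(predict_2comp(p2, s), predict_1comp(p1, s))

  p2b <- do.call(model_params, c(variant = "TWO_COMP", base,
                                 list(k2 = 0.015, tau2 = 4.3)))
  for (sign in c("plus", "minus")) {
    p3 <- do.call(model_params, c(variant = "THREE_COMP", base,
                                  list(k2_0 = 0.015, tau2 = 4.3, k3 = 0,
                                       tau3 = 9,
                                       third_component_sign = sign)))
    expect_equal(predict_3comp(p3, s), predict_2comp(p2b, s))
  }

  # exact cancellation when both components coincide
  pc <- model_params("TWO_COMP", p0 = 0.4, k1 = 0.02, tau1 = 5,
                     k2 = 0.02, tau2 = 5)
  expect_equal(predict_2comp(pc, s), rep(0.4, 30))
})

test_that("recursive evaluators agree with the direct-summation oracle", {
  set.seed(7)
  for (i in 1:10) {
    s <- impulse_series(random_impulse_train(sample(5:40, 1)))
    p2 <- model_params("TWO_COMP", p0 = runif(1, 0, 1),
                       k1 = runif(1, 0, 0.05), tau1 = runif(1, 0.6, 30),
                       k2 = runif(1, 0, 0.05), tau2 = runif(1, 0.6, 30))
    expect_equal(predict_2comp(p2, s), predict_direct(p2, s),
                 tolerance = 1e-12)
    p3 <- model_params("THREE_COMP", p0 = runif(1, 0, 1),
                       k1 = runif(1, 0, 0.05), tau1 = runif(1, 0.6, 30),
                       k2_0 = runif(1, 0, 0.05), tau2 = runif(1, 0.6, 30),
                       k3 = runif(1, 0, 1e-4), tau3 = runif(1, 0.6, 30),
                       third_component_sign = sample(c("plus", "minus"), 1))
    expect_equal(predict_3comp(p3, s), predict_direct(p3, s),
                 tolerance = 1e-12)
  }
})

test_that("the fatigue-gain filter follows its closed form and recursion", {
  p3 <- model_params("THREE_COMP", p0 = 0, k1 = 0.02, tau1 = 5,
                     k2_0 = 0.02, tau2 = 4, k3 = 1e-4, tau3 = 6)
  W <- 50
  s <- impulse_series(c(W, rep(0, 9)))
  ks <- k2_series(p3, s)
  i <- 1:10
  expect_equal(ks$dk2, 1e-4 * W * exp(-(i - 1) / 6))
  expect_equal(ks$k2, 0.02 + ks$dk2)

  p0k3 <- model_params("THREE_COMP", p0 = 0, k1 = 0.02, tau1 = 5,
                       k2_0 = 0.02, tau2 = 4, k3 = 0, tau3 = 6)
  expect_equal(k2_series(p0k3, s)$k2, rep(0.02, 10))

  # brute-force summation equivalence on random input
  set.seed(13)
  sr <- impulse_series(random_impulse_train(25))
  ksr <- k2_series(p3, sr)
  brute <- sapply(1:25, function(n)
    1e-4 * sum(sr$w[1:n] * exp(-(n - (1:n)) / 6)))
  expect_equal(ksr$dk2, brute, tolerance = 1e-12)
})

test_that("the minus sign convention floors the fatigue gain at zero", {
  p3 <- model_params("THREE_COMP", p0 = 0, k1 = 0.02, tau1 = 5,
                     k2_0 = 0.001, tau2 = 4, k3 = 1e-3, tau3 = 6,
                     third_component_sign = "minus")
  s <- impulse_series(c(100, rep(0, 5)))
  ks <- k2_series(p3, s)
  expect_true(all(ks$k2 >= 0))
  expect_equal(ks$k2[1], 0)   # 0.001 - 0.1 floored
})

test_that("two-component response is linear in the impulse train", {
  set.seed(3)
  s <- impulse_series(random_impulse_train(20))
  s2 <- impulse_series(2.5 * s$w)
  p <- reference_gain_params()
  expect_equal(predict_2comp(p, s2) - p$p0,
               2.5 * (predict_2comp(p, s) - p$p0))
})

test_that("predictions are causal in the training inputs", {
  set.seed(5)
  w <- random_impulse_train(20)
  p <- reference_gain_params()
  base <- predict_2comp(p, impulse_series(w))
  for (n in c(5, 12)) {
    w2 <- w
    w2[n] <- w[n] + 50
    bumped <- predict_2comp(p, impulse_series(w2))
    expect_equal(bumped[1:n], base[1:n])
    expect_false(isTRUE(all.equal(bumped[n + 1], base[n + 1])))
  }
})

test_that("variant mismatches and invalid parameters are rejected", {
  s <- impulse_series(c(1, 0))
  p1 <- model_params("ONE_COMP", 0, 1, 1)
  expect_error(predict_2comp(p1, s), "ONE_COMP")
  expect_error(k2_series(p1, s), "ONE_COMP")
  expect_error(model_params("TWO_COMP", 0, 1, 1), "k2")
  expect_error(model_params("ONE_COMP", 0, 1, tau1 = -2), "tau1")
  expect_error(model_params("ONE_COMP", 0, k1 = -1, tau1 = 2), "k1")
})

test_that("model parameters round-trip through JSON", {
  p <- model_params("THREE_COMP", p0 = 0.41, k1 = 0.021, tau1 = 5.31,
                    k2_0 = 0.02, tau2 = 4.3, k3 = 3.1e-6, tau3 = 11,
                    third_component_sign = "minus")
  path <- withr::local_tempfile(fileext = ".json")
  write_model_params(p, path)
  expect_equal(read_model_params(path), p)
})
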