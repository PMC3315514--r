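test_that("gradient weights follow the -2*delta..+2*delta linspace", {
  expect_equal(gradient_weights(7, 0), rep(0, 7))
  expect_equal(gradient_weights(5, 0.1), c(-0.2, -0.1, 0, 0.1, 0.2))
  expect_equal(mean(abs(gradient_weights(5, 0.1))), 0.12)

  w <- gradient_weights(130, 0.025)
  expect_equal(w[1], -0.05)
  expect_equal(w[130], 0.05)
  expect_lt(abs(mean(abs(w)) - 0.025), 2 * 0.025 / 129)

  # symmetry: zero-sum and reversal antisymmetry
  expect_equal(sum(w), 0)
  expect_equal(rev(w), -w)
  expect_error(gradient_weights(2, 0.1), class = "coref_validation_error")
})

test_that("simulate_pair hits the target population correlation", {
  d0 <- simulate_pair(10000, r_x = 0, seed = 1)
  expect_lt(abs(cor(d0$x1, d0$x2)), 0.05)
  d4 <- simulate_pair(100000, r_x = 0.4, seed = 2)
  expect_lt(abs(cor(d4$x1, d4$x2) - 0.4), 0.01)
  expect_equal(sd(d4$x1), 10, tolerance = 0.02)
  expect_error(simulate_pair(100, r_x = 1), class = "coref_validation_error")
})

test_that("the literal delta-mixing baseline has the analytic correlation", {
  # cor = delta / sqrt(delta^2 + (1-delta)^2); at delta = 0.1 that is 0.1104
  d <- simulate_bivariate_pair(100000, delta = 0.1, seed = 3)
  expect_lt(abs(cor(d$x1, d$x2) - 0.1 / sqrt(0.01 + 0.81)), 0.01)
  d0 <- simulate_bivariate_pair(10000, delta = 0, seed = 4)
  expect_lt(abs(cor(d0$x1, d0$x2)), 0.05)
  expect_error(simulate_bivariate_pair(100, delta = 1),
               class = "coref_validation_error")
})

test_that("identical specs give bit-identical datasets", {
  spec <- coref_spec(n = 50, k = 20, delta = 0.1, r_x = 0.2,
                     n_noise_vars = 5, include_x1_in_y = TRUE, seed = 77)
  a <- simulate_coref_data(spec)
  b <- simulate_coref_data(spec)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_identical(attr(a, "weights"), gradient_weights(20, 0.1))
})

test_that("contamination columns are appended as specified", {
  d <- simulate_coref_data(coref_spec(n = 30, k = 10, delta = 0.05,
                                      n_noise_vars = 4,
                                      include_x1_in_y = TRUE,
                                      include_x2_in_y = TRUE, seed = 5))
  refs <- setdiff(names(d), c("x1", "x2"))
  expect_length(refs, 10 + 4 + 2)
  # x1/x2 included verbatim as the last two reference columns
  expect_equal(d$Y015, d$x1)
  expect_equal(d$Y016, d$x2)
})

test_that("null mode gives reference data independent of the test variables", {
  # r(x1, Y_i)*sqrt(n-2)/sqrt(1-r^2) is t(n-2) under independence
  d <- simulate_coref_data(coref_spec(n = 500, k = 130, delta = 0.1,
                                      mode = "null", seed = 6))
  r <- correlation_profile(d, "x1")$estimate
  tstat <- r * sqrt(498) / sqrt(1 - r^2)
  ks <- stats::ks.test(tstat, stats::pt, df = 498)
  expect_gt(ks$p.value, 0.01)
})

test_that("both_informative correlations track the closed-form mixture value", {
  spec <- coref_spec(n = 100000, k = 130, delta = 0.1, seed = 8)
  d <- simulate_coref_data(spec)
  w <- attr(d, "weights")
  # var(Y_i)/sigma^2 = 2*w^2*(1+r_x) + (1-2|w|)^2 with r_x = 0
  theo <- w / sqrt(2 * w^2 + (1 - 2 * abs(w))^2)
  emp <- correlation_profile(d, "x1", setdiff(names(d), c("x1", "x2")))$estimate
  expect_lt(max(abs(emp - theo)), 0.01)
})

test_that("sigma cancels from all correlation-level quantities", {
  s1 <- coref_spec(n = 60, k = 20, delta = 0.1, r_x = 0.2, sigma = 1, seed = 9)
  s10 <- coref_spec(n = 60, k = 20, delta = 0.1, r_x = 0.2, sigma = 10, seed = 9)
  d1 <- simulate_coref_data(s1)
  d10 <- simulate_coref_data(s10)
  expect_equal(coref_coefficient(d1, "x1", "x2"),
               coref_coefficient(d10, "x1", "x2"))
})

test_that("invalid spec parameters are rejected", {
  expect_error(coref_spec(n = 3, k = 10), class = "coref_validation_error")
  expect_error(coref_spec(n = 50, k = 2), class = "coref_validation_error")
  expect_error(coref_spec(n = 50, delta = 0.3), class = "coref_validation_error")
  expect_error(coref_spec(n = 50, r_x = 0.99), class = "coref_validation_error")
  # delta = 0.25 zeroes the noise weight at the gradient endpoints
  expect_error(simulate_coref_data(coref_spec(n = 50, k = 10, delta = 0.25)),
               "non-positive", class = "coref_validation_error")
})
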