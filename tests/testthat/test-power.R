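test_that("PCA-regression p matches a hand-coded OLS F-test on a fixture", {
  set.seed(15)
  n <- 12
  Y <- matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, paste0("y", 1:6)))
  x <- 0.8 * Y[, 1] - 0.5 * Y[, 4] + rnorm(n, 0, 0.5)
  d <- dplyr::bind_cols(tibble::tibble(x = x), tibble::as_tibble(Y))
  p_pkg <- pca_regression_test(d, "x", paste0("y", 1:6), n_components = 3)
  scores <- prcomp(scale(Y), center = FALSE)$x[, 1:3]
  p_oracle <- oracle_ols_f_p(x, scores)
  expect_equal(p_pkg, p_oracle, tolerance = 1e-10)
})

test_that("a test variable lying in the retained PC span gives p near 0", {
  set.seed(16)
  n <- 200
  base <- rnorm(n)
  # Y built so PC1 is dominated by the shared component: x = Y's backbone
  Y <- sapply(1:20, function(j) base + rnorm(n, 0, 0.3))
  colnames(Y) <- paste0("y", 1:20)
  d <- dplyr::bind_cols(tibble::tibble(x = base), tibble::as_tibble(Y))
  expect_lt(pca_regression_test(d, "x", n_components = 1), 1e-10)
})

test_that("PCA regression is calibrated under independence", {
  rej <- vapply(seq_len(500), function(i) {
    d <- simulate_coref_data(coref_spec(n = 200, k = 130, mode = "null",
                                        seed = 30000 + i))
    pca_regression_test(d, "x1", setdiff(names(d), c("x1", "x2")),
                        n_components = 10) < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.02)
  expect_lte(mean(rej), 0.08)
})

test_that("n_components beyond the data dimensions is an error", {
  d <- simulate_coref_data(coref_spec(n = 20, k = 10, seed = 1))
  refs <- setdiff(names(d), c("x1", "x2"))
  expect_error(pca_regression_test(d, "x1", refs, n_components = 10),
               class = "coref_validation_error")
  expect_error(pca_regression_test(d, "x1", refs, n_components = 0),
               class = "coref_validation_error")
})

test_that("bivariate regression p matches the textbook t-test on the fixture", {
  d <- fixture5()
  # frozen: r = 0.8, t = r*sqrt(3)/sqrt(1-r^2), two-sided p with 3 df
  expect_equal(bivariate_regression_test(d, "x1", "x2"), 0.104088038661828,
               tolerance = 1e-12)
  d$x2 <- d$x1
  expect_lt(suppressWarnings(bivariate_regression_test(d, "x1", "x2")), 1e-12)
})

test_that("bivariate regression is calibrated under independence", {
  rej <- vapply(seq_len(500), function(i) {
    d <- simulate_pair(200, r_x = 0, seed = 40000 + i)
    bivariate_regression_test(d, "x1", "x2") < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.02)
  expect_lte(mean(rej), 0.08)
})

test_that("run_power_condition tabulates power and median R_C consistently", {
  res <- run_power_condition(coref_spec(n = 50, k = 15, delta = 0.1),
                             n_sims = 10, n_perm = 100, seed = 3)
  expect_s3_class(res, "coref_power")
  expect_equal(nrow(res), 1L)
  expect_equal(res$power, mean(res$p_values[[1]] < 0.05))
  expect_equal(res$median_rc, median(res$rc_values[[1]]))
  expect_length(res$p_values[[1]], 10)

  one <- run_power_condition(coref_spec(n = 30, k = 10, delta = 0),
                             n_sims = 1, n_perm = 50, seed = 4)
  expect_true(one$power %in% c(0, 1))
})

test_that("run_power_condition is reproducible and method-aware", {
  spec <- coref_spec(n = 40, k = 12, delta = 0.1)
  a <- run_power_condition(spec, n_sims = 5, n_perm = 100, seed = 8)
  b <- run_power_condition(spec, n_sims = 5, n_perm = 100, seed = 8)
  expect_identical(a$p_values, b$p_values)

  pca <- run_power_condition(coref_spec(n = 60, k = 15, delta = 0.1),
                             method = "pca_regression_10", n_sims = 5, seed = 9)
  expect_true(is.na(pca$median_rc))
  biv <- run_power_condition(coref_spec(n = 60, k = 15, delta = 0.1),
                             method = "bivariate_regression", n_sims = 5,
                             seed = 10)
  expect_true(all(biv$p_values[[1]] >= 0 & biv$p_values[[1]] <= 1))
})

test_that("coreferentiality and PCA regression have comparable power", {
  co <- run_power_condition(coref_spec(n = 200, k = 130, delta = 0.05),
                            n_sims = 50, n_perm = 1000, seed = 21)
  pca <- run_power_condition(coref_spec(n = 200, k = 130, delta = 0.05),
                             method = "pca_regression_10", n_sims = 50,
                             seed = 22)
  expect_lte(abs(co$power - pca$power), 0.15)
})

test_that("run_power_grid validates input and binds tidy rows", {
  expect_error(run_power_grid(tibble::tibble()), class = "coref_validation_error")
  expect_error(run_power_grid(tibble::tibble(n = 50, bogus = 1), seed = 1),
               "bogus", class = "coref_validation_error")
  grid <- tidyr::expand_grid(n = c(30, 50), delta = c(0, 0.1), k = 10)
  res <- run_power_grid(grid, n_sims = 3, n_perm = 50, seed = 2)
  expect_equal(nrow(res), 4L)
  expect_true(all(res$power >= 0 & res$power <= 1))
  res2 <- run_power_grid(grid, n_sims = 3, n_perm = 50, seed = 2)
  expect_identical(res$power, res2$power)
  expect_s3_class(autoplot(res), "ggplot")
  expect_s3_class(plot_power(res, x = "n", colour = "delta"), "ggplot")
})
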