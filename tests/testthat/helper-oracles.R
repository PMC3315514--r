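# Independent oracles: textbook formulas coded without the package's
# matrix engine, used to freeze expected values for the small fixtures.

# Pearson r by the raw-sums textbook formula.
oracle_pearson <- function(x, y) {
  n <- length(x)
  (n * sum(x * y) - sum(x) * sum(y)) /
    sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
}

oracle_profile <- function(x, Y) {
  vapply(seq_len(ncol(Y)), function(j) oracle_pearson(x, Y[, j]), numeric(1))
}

oracle_rc <- function(x1, x2, Y) {
  oracle_pearson(oracle_profile(x1, Y), oracle_profile(x2, Y))
}

# All permutations of 1..n by filtering the n^n index grid — deliberately
# different from the package's recursive generator.
oracle_all_perms <- function(n) {
  g <- as.matrix(expand.grid(rep(list(seq_len(n)), n)))
  g[apply(g, 1L, function(r) length(unique(r)) == n), , drop = FALSE]
}

# Exact two-tailed permutation p over all n! joint reshuffles, with the
# same last-ulp tie tolerance as the package so float noise cannot decide
# whether the observed statistic counts as reached.
oracle_exhaustive_p <- function(x1, x2, Y) {
  rc_obs <- oracle_rc(x1, x2, Y)
  perms <- oracle_all_perms(length(x1))
  rcs <- apply(perms, 1L, function(ix) oracle_rc(x1[ix], x2[ix], Y))
  mean(abs(rcs) >= abs(rc_obs) - 1e-12)
}

# A generic continuous 5-sample, 4-reference fixture for permutation
# oracles (fixture5's observed R_C is exactly 1 with a 20% tie mass at
# |R_C| = 1 across permutations, so it exercises tie handling instead).
fixture_gauss5 <- function() {
  tibble::tibble(
    x1 = c(0.3735462, 1.1836433, -0.8356286, 1.5952808, 0.3295078),
    x2 = c(-0.8204684, 0.4874291, 0.7383247, 0.5757814, -0.3053884),
    y_a = c(1.5117812, 0.3898432, -0.6212406, -2.2146999, 1.1249309),
    y_b = c(-0.0449336, -0.0161903, 0.9438362, 0.8212212, 0.5939013),
    y_c = c(0.9189774, 0.7821363, 0.0745650, -1.9893517, 0.6198257),
    y_d = c(-0.0561287, -0.1557955, -1.4707524, -0.4781501, 0.4179416)
  )
}

# Overall F-test of an OLS regression of y on columns of X, by the normal
# equations — independent of lm().
oracle_ols_f_p <- function(y, X) {
  n <- length(y)
  Xd <- cbind(1, X)
  beta <- solve(crossprod(Xd), crossprod(Xd, y))
  fitted <- drop(Xd %*% beta)
  sse <- sum((y - fitted)^2)
  sst <- sum((y - mean(y))^2)
  p <- ncol(X)
  f <- ((sst - sse) / p) / (sse / (n - p - 1))
  pf(f, p, n - p - 1, lower.tail = FALSE)
}

# The 5-sample, 3-reference fixture used across the core tests.
fixture5 <- function() {
  tibble::tibble(
    x1 = c(1, 2, 3, 4, 5),
    x2 = c(2, 1, 3, 5, 4),
    y_a = c(2, 1, 4, 3, 5),
    y_b = c(5, 4, 3, 2, 1),
    y_c = c(1, 3, 2, 5, 4)
  )
}
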