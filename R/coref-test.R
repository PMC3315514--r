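# The permutation significance test for coreferentiality.

# All n! permutations of 1..n as an n x n! index matrix. Only used for the
# exhaustive mode, which is capped at n = 8 (40320 permutations).
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, n, n * ncol(sub))
  col <- 0L
  for (pos in seq_len(n)) { # insert the value n at every position
    for (j in seq_len(ncol(sub))) {
      col <- col + 1L
      out[, col] <- append(sub[, j], n, after = pos - 1L)
    }
  }
  out
}

# m uniform random permutations of 1..n as an n x m index matrix.
random_permutations <- function(n, m) {
  vapply(seq_len(m), function(i) sample.int(n), integer(n))
}

#' Permutation test for coreferentiality
#'
#' Tests the null hypothesis that the coefficient of coreferentiality R_C of
#' `x1` and `x2` with respect to the reference set equals its no-association
#' expectation R_C0. The null distribution is generated by parallel
#' reshuffling: the same random permutation of the sample indices is applied
#' jointly to `x1` and `x2` while the reference data stay in place, which
#' preserves both the direct correlation r(x1, x2) and the internal
#' structure of Y. Note that R_C0 is therefore not 0 in general — for
#' directly correlated test variables it defaults to r(x1, x2).
#'
#' The reported p-value is two-tailed: the proportion of permutations whose
#' absolute R_C reaches the observed absolute value. With
#' `p_rule = "add_one"` (default) the observed statistic is counted in the
#' numerator and denominator, `p = (1 + #\{|R_C^perm| >= |R_C^obs|\}) /
#' (n_perm + 1)`, which guarantees `p > 0`. `p_rule = "strict"` is the
#' strict-exceedance proportion `#\{|R_C^perm| > |R_C^obs|\} / n_perm`.
#' Ties have measure zero for continuous data, so the two differ only by
#' the add-one correction.
#'
#' For small samples the null can be enumerated exactly: with
#' `exhaustive = "auto"` all N! permutations are used when N <= 6, and
#' `exhaustive = "always"` allows N up to 8. The exhaustive p-value is the
#' exact proportion of permutations (identity included) reaching the
#' observed absolute R_C, so it is always positive.
#'
#' @inheritParams coref_coefficient
#' @param n_perm Number of random permutations (ignored when the null is
#'   enumerated exhaustively). Default 1000.
#' @param seed Seed for the permutation draws; identical seed and inputs
#'   give bit-identical results. `NULL` uses (and advances) the session RNG.
#' @param p_rule Counting rule for the empirical p-value, see Details.
#' @param exhaustive `"auto"`, `"never"`, or `"always"`.
#' @param keep_null Keep the full vector of permutation R_C values in the
#'   result (needed for [autoplot()]).
#' @return An object of class `coref_test`: a list with elements `r_c`,
#'   `p_value`, `n_perm`, `r_x1x2`, `null_mean`, `null_sd`, `null_q025`,
#'   `null_q975`, `null_rc` (if kept), `exhaustive`, `method`, `p_rule`,
#'   `seed`, `n`, `k`, `x1`, `x2`. Has [tidy()], [glance()] and
#'   [autoplot()] methods.
#' @examples
#' d <- simulate_coref_data(coref_spec(n = 100, k = 50, delta = 0.1, seed = 1))
#' fit <- coref_test(d, "x1", "x2", n_perm = 200, seed = 2)
#' fit
#' glance(fit)
#' @export
coref_test <- function(data, x1, x2, ref = NULL,
                       n_perm = 1000L, seed = NULL,
                       method = c("pearson", "spearman"),
                       p_rule = c("add_one", "strict"),
                       exhaustive = c("auto", "never", "always"),
                       keep_null = TRUE) {
  method <- match.arg(method)
  p_rule <- match.arg(p_rule)
  exhaustive <- match.arg(exhaustive)
  check_seed(seed)
  if (!is.numeric(n_perm) || length(n_perm) != 1L || n_perm < 1) {
    stop_validation("`n_perm` must be a positive integer.")
  }
  n_perm <- as.integer(n_perm)

  parts <- resolve_columns(data, x1, x2, ref)
  x1v <- parts$x1
  x2v <- parts$x2
  n <- length(x1v)
  r_x1x2 <- cor(parts$x1, parts$x2)

  Y <- parts$Y
  if (method == "spearman") {
    x1v <- rank(x1v)
    x2v <- rank(x2v)
    Y <- rank_cols(Y)
  }
  Y_std <- std_cols(Y)

  P_obs <- profile_engine(Y_std, std_cols(cbind(x1v, x2v)))
  rc_obs <- unname(colwise_cor(P_obs[, 1L, drop = FALSE],
                               P_obs[, 2L, drop = FALSE]))

  use_exhaustive <- switch(exhaustive,
    auto = n <= 6L,
    never = FALSE,
    always = {
      if (n > 8L) {
        stop_validation(paste0(
          "Exhaustive enumeration is limited to N <= 8 (", n,
          "! permutations would be required)."
        ))
      }
      TRUE
    }
  )

  idx <- if (use_exhaustive) {
    all_permutations(n)
  } else {
    with_seed(seed, random_permutations(n, n_perm))
  }
  m <- ncol(idx)

  X1p <- std_cols(matrix(x1v[idx], n, m))
  X2p <- std_cols(matrix(x2v[idx], n, m))
  null_rc <- colwise_cor(profile_engine(Y_std, X1p),
                         profile_engine(Y_std, X2p))

  # tolerance-aware tie counting: recomputation noise at the last ulp must
  # not decide whether the observed statistic counts as reached
  eps <- 1e-12
  n_ge <- sum(abs(null_rc) >= abs(rc_obs) - eps)
  n_gt <- sum(abs(null_rc) > abs(rc_obs) + eps)
  p_value <- if (use_exhaustive) {
    if (p_rule == "strict") n_gt / m else n_ge / m
  } else {
    if (p_rule == "strict") n_gt / m else (1 + n_ge) / (m + 1)
  }

  out <- structure(list(
    r_c = rc_obs,
    p_value = p_value,
    n_perm = m,
    r_x1x2 = unname(r_x1x2),
    null_mean = mean(null_rc),
    null_sd = sd(null_rc),
    null_q025 = unname(quantile(null_rc, 0.025)),
    null_q975 = unname(quantile(null_rc, 0.975)),
    null_rc = if (keep_null) null_rc,
    exhaustive = use_exhaustive,
    method = method,
    p_rule = p_rule,
    seed = seed,
    n = n,
    k = ncol(Y),
    x1 = parts$x1_name,
    x2 = parts$x2_name
  ), class = "coref_test")
  out
}

#' @export
print.coref_test <- function(x, ...) {
  cat("Coreferentiality permutation test\n")
  cat(sprintf("  %s vs %s against k = %d reference variables (N = %d)\n",
              x$x1, x$x2, x$k, x$n))
  cat(sprintf("  R_C = %.4f   r(%s,%s) = %.4f\n", x$r_c, x$x1, x$x2, x$r_x1x2))
  cat(sprintf("  p = %.4g   (%s, %s, %s)\n", x$p_value,
              if (x$exhaustive) sprintf("exhaustive, %d permutations", x$n_perm)
              else sprintf("%d random permutations", x$n_perm),
              x$method, x$p_rule))
  cat(sprintf("  null R_C: mean %.4f, sd %.4f, 95%% [%.4f, %.4f]\n",
              x$null_mean, x$null_sd, x$null_q025, x$null_q975))
  invisible(x)
}

#' Tidy a coreferentiality test
#'
#' @param x A `coref_test` object.
#' @param ... Unused.
#' @return `tidy()` gives a one-row tibble with `estimate` (R_C) and
#'   `p.value`; `glance()` adds the null-distribution summary and the test
#'   configuration.
#' @export
tidy.coref_test <- function(x, ...) {
  tibble::tibble(estimate = x$r_c, p.value = x$p_value)
}

#' @rdname tidy.coref_test
#' @export
glance.coref_test <- function(x, ...) {
  tibble::tibble(
    r_c = x$r_c, p_value = x$p_value, r_x1x2 = x$r_x1x2,
    n_perm = x$n_perm, exhaustive = x$exhaustive,
    null_mean = x$null_mean, null_sd = x$null_sd,
    null_q025 = x$null_q025, null_q975 = x$null_q975,
    n = x$n, k = x$k, method = x$method, p_rule = x$p_rule
  )
}

#' Plot the permutation null distribution of a coreferentiality test
#'
#' Histogram of the permutation R_C values with the observed coefficient
#' marked. The null centers near r(x1, x2), not 0, when the test variables
#' are directly correlated.
#'
#' @param object A `coref_test` fitted with `keep_null = TRUE`.
#' @param bins Number of histogram bins.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.coref_test <- function(object, bins = 40, ...) {
  if (is.null(object$null_rc)) {
    stop_validation("Refit with `keep_null = TRUE` to plot the null distribution.")
  }
  df <- tibble::tibble(null_rc = object$null_rc)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$null_rc)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$r_c, colour = "red") +
    ggplot2::labs(
      x = expression(R[C] ~ "under parallel reshuffling"),
      y = "permutations",
      title = sprintf("Observed R_C = %.3f, p = %.4g", object$r_c, object$p_value)
    )
}
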