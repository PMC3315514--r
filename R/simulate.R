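# Synthetic data with the generative structure of the power study:
# Gaussian test variables, reference variables built as gradient-weighted
# linear mixtures of the test variables and fresh Gaussian noise.

#' Gradient of mixing weights
#'
#' The k reference variables receive individual degrees of determination on
#' a linear gradient from `-2 * delta` to `+2 * delta` (endpoints
#' inclusive), so the average absolute weight is approximately `delta`. The
#' weights sum to zero and the reversed gradient equals its negation.
#'
#' @param k Number of reference variables (>= 3).
#' @param delta Average absolute degree of determination, >= 0.
#' @return Numeric vector of length `k`.
#' @examples
#' gradient_weights(5, 0.1) # -0.2 -0.1 0.0 0.1 0.2
#' @export
gradient_weights <- function(k, delta) {
  if (!is.numeric(k) || length(k) != 1L || k < 3) {
    stop_validation("`k` must be a single integer >= 3.")
  }
  if (!is.numeric(delta) || length(delta) != 1L || delta < 0) {
    stop_validation("`delta` must be a single number >= 0.")
  }
  seq(-2 * delta, 2 * delta, length.out = as.integer(k))
}

#' Simulate a pair of test variables with a defined correlation
#'
#' Draws `x1 ~ N(0, sigma^2)` and sets
#' `x2 = r_x * x1 + sqrt(1 - r_x^2) * e` with independent
#' `e ~ N(0, sigma^2)`, so the population correlation of the pair is
#' exactly `r_x` and both marginals have standard deviation `sigma`.
#'
#' @param n Sample size (>= 4).
#' @param r_x Target population correlation, `|r_x| < 1`.
#' @param sigma Marginal standard deviation (default 10; correlations are
#'   invariant to it).
#' @param seed RNG seed (`NULL` uses the session RNG).
#' @return A tibble with columns `x1` and `x2`.
#' @examples
#' simulate_pair(5, r_x = 0.4, seed = 1)
#' @export
simulate_pair <- function(n, r_x = 0, sigma = 10, seed = NULL) {
  check_seed(seed)
  if (!is.numeric(n) || length(n) != 1L || n < 4) {
    stop_validation("`n` must be a single integer >= 4.")
  }
  if (!is.numeric(r_x) || length(r_x) != 1L || abs(r_x) >= 1) {
    stop_validation("`r_x` must satisfy |r_x| < 1.")
  }
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0) {
    stop_validation("`sigma` must be a positive number.")
  }
  n <- as.integer(n)
  with_seed(seed, {
    x1 <- rnorm(n, 0, sigma)
    e <- rnorm(n, 0, sigma)
    tibble::tibble(x1 = x1, x2 = r_x * x1 + sqrt(1 - r_x^2) * e)
  })
}

#' Simulate a bivariate pair by literal delta-mixing
#'
#' The baseline construction for comparing against simple bivariate
#' regression: `x2 = delta * x1 + (1 - delta) * e`. Unlike
#' [simulate_pair()], the mixing weights are applied literally (no
#' unit-variance scaling), so the implied population correlation is
#' `delta / sqrt(delta^2 + (1 - delta)^2)`.
#'
#' @inheritParams simulate_pair
#' @param delta Mixing weight of `x1`, in `[0, 1)`.
#' @return A tibble with columns `x1` and `x2`.
#' @export
simulate_bivariate_pair <- function(n, delta, sigma = 10, seed = NULL) {
  check_seed(seed)
  if (!is.numeric(n) || length(n) != 1L || n < 4) {
    stop_validation("`n` must be a single integer >= 4.")
  }
  if (!is.numeric(delta) || length(delta) != 1L || delta < 0 || delta >= 1) {
    stop_validation("`delta` must be in [0, 1).")
  }
  n <- as.integer(n)
  with_seed(seed, {
    x1 <- rnorm(n, 0, sigma)
    e <- rnorm(n, 0, sigma)
    tibble::tibble(x1 = x1, x2 = delta * x1 + (1 - delta) * e)
  })
}

#' Specification of one simulated coreferentiality dataset
#'
#' Collects the generative parameters for [simulate_coref_data()]: the
#' sample size, number of gradient-weighted reference variables, average
#' degree of determination `delta`, the direct correlation `r_x` of the
#' test-variable pair, the generative mode, and the contamination options
#' (appended pure-noise reference columns, or the test variables themselves
#' included verbatim in the reference set).
#'
#' Modes:
#' \describe{
#'   \item{`both_informative`}{`Y_i = w_i*x1 + w_i*x2 + (1 - 2|w_i|)*E_i`;
#'     the same weight multiplies both test variables, so both contribute
#'     with equal weight and the noise coefficient stays positive for
#'     `delta < 0.25`.}
#'   \item{`bystander`}{`Y_i = w_i*x1 + (1 - |w_i|)*E_i`; only `x1`
#'     influences the reference data, `x2` relates to them only through its
#'     direct correlation `r_x` with `x1`.}
#'   \item{`null`}{`Y_i = E_i`, independent of both test variables
#'     regardless of `delta`.}
#' }
#'
#' @param n Sample size (>= 4).
#' @param k Number of gradient-weighted reference variables (default 130).
#' @param delta Average absolute degree of determination, in `[0, 0.25]`.
#' @param r_x Direct correlation of `x1` and `x2`, in `[0, 0.95]`.
#' @param mode `"both_informative"`, `"bystander"`, or `"null"`.
#' @param n_noise_vars Number of appended independent-noise reference
#'   columns (>= 0).
#' @param include_x1_in_y,include_x2_in_y Append `x1` / `x2` verbatim as
#'   extra reference columns (the correlation-outlier contamination).
#' @param sigma Base standard deviation of all Gaussian draws (default 10).
#' @param seed RNG seed; identical specs give bit-identical datasets.
#' @return An object of class `coref_spec` (a validated list).
#' @export
coref_spec <- function(n, k = 130L, delta = 0, r_x = 0,
                       mode = c("both_informative", "bystander", "null"),
                       n_noise_vars = 0L,
                       include_x1_in_y = FALSE, include_x2_in_y = FALSE,
                       sigma = 10, seed = NULL) {
  mode <- match.arg(mode)
  check_seed(seed)
  if (!is.numeric(n) || length(n) != 1L || n < 4) {
    stop_validation("`n` must be a single integer >= 4.")
  }
  if (!is.numeric(k) || length(k) != 1L || k < 3) {
    stop_validation("`k` must be a single integer >= 3.")
  }
  if (!is.numeric(delta) || length(delta) != 1L || delta < 0 || delta > 0.25) {
    stop_validation(
      "`delta` must be in [0, 0.25] so that the gradient endpoints 2*delta keep the noise weights positive."
    )
  }
  if (!is.numeric(r_x) || length(r_x) != 1L || r_x < 0 || r_x > 0.95) {
    stop_validation("`r_x` must be in [0, 0.95].")
  }
  if (!is.numeric(n_noise_vars) || length(n_noise_vars) != 1L || n_noise_vars < 0) {
    stop_validation("`n_noise_vars` must be a non-negative integer.")
  }
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0) {
    stop_validation("`sigma` must be a positive number.")
  }
  structure(list(
    n = as.integer(n), k = as.integer(k), delta = delta, r_x = r_x,
    mode = mode, n_noise_vars = as.integer(n_noise_vars),
    include_x1_in_y = isTRUE(include_x1_in_y),
    include_x2_in_y = isTRUE(include_x2_in_y),
    sigma = sigma, seed = seed
  ), class = "coref_spec")
}

#' @export
print.coref_spec <- function(x, ...) {
  cat("coref_spec:",
      sprintf("n = %d, k = %d, delta = %g, r_x = %g, mode = %s", x$n, x$k,
              x$delta, x$r_x, x$mode), "\n")
  if (x$n_noise_vars > 0 || x$include_x1_in_y || x$include_x2_in_y) {
    cat(sprintf("  contamination: %d noise columns%s%s\n", x$n_noise_vars,
                if (x$include_x1_in_y) ", x1 in Y" else "",
                if (x$include_x2_in_y) ", x2 in Y" else ""))
  }
  cat(sprintf("  sigma = %g, seed = %s\n", x$sigma,
              if (is.null(x$seed)) "NULL" else format(x$seed)))
  invisible(x)
}

#' Simulate one coreferentiality dataset
#'
#' Generates the test-variable pair with [simulate_pair()] and builds each
#' reference column as the mode-specific linear mixture of the test
#' variables and a fresh Gaussian noise column (see [coref_spec()]).
#' Contamination columns are appended after the informative ones:
#' first `n_noise_vars` pure-noise columns, then `x1` and/or `x2` verbatim
#' if requested.
#'
#' @param spec A [coref_spec()].
#' @return A tibble with columns `x1`, `x2`, and reference columns
#'   `Y001`, `Y002`, ... (informative first, then contamination). The
#'   gradient weights of the informative columns are attached as attribute
#'   `"weights"` and the generating spec as attribute `"spec"`.
#' @examples
#' d <- simulate_coref_data(coref_spec(n = 50, k = 10, delta = 0.1, seed = 1))
#' attr(d, "weights")
#' @export
simulate_coref_data <- function(spec) {
  if (!inherits(spec, "coref_spec")) {
    stop_validation("`spec` must be a coref_spec object.")
  }
  w <- gradient_weights(spec$k, spec$delta)
  noise_coef <- switch(spec$mode,
    both_informative = 1 - 2 * abs(w),
    bystander = 1 - abs(w),
    null = rep(1, spec$k)
  )
  if (any(noise_coef <= 0)) {
    stop_validation(paste0(
      "delta = ", spec$delta, " makes some noise coefficients non-positive ",
      "in mode '", spec$mode, "'."
    ))
  }

  with_seed(spec$seed, {
    pair <- simulate_pair(spec$n, spec$r_x, spec$sigma, seed = NULL)
    E <- matrix(rnorm(spec$n * spec$k, 0, spec$sigma), spec$n, spec$k)
    signal <- switch(spec$mode,
      both_informative = outer(pair$x1, w) + outer(pair$x2, w),
      bystander = outer(pair$x1, w),
      null = 0
    )
    Y <- signal + sweep(E, 2L, noise_coef, "*")
    if (spec$n_noise_vars > 0L) {
      Y <- cbind(Y, matrix(rnorm(spec$n * spec$n_noise_vars, 0, spec$sigma),
                           spec$n, spec$n_noise_vars))
    }
    if (spec$include_x1_in_y) Y <- cbind(Y, pair$x1)
    if (spec$include_x2_in_y) Y <- cbind(Y, pair$x2)
    colnames(Y) <- sprintf("Y%03d", seq_len(ncol(Y)))

    out <- dplyr::bind_cols(pair, tibble::as_tibble(Y))
    attr(out, "weights") <- w
    attr(out, "spec") <- spec
    out
  })
}
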