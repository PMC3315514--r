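# Monte-Carlo power study and the two regression baselines.

#' PCA-score multiple regression test
#'
#' The multiple-regression baseline: principal components are derived from
#' the standardized reference variables (correlation-matrix PCA, since the
#' simulated Y variances differ along the weight gradient), the test
#' variable is regressed on the leading `n_components` score vectors by
#' ordinary least squares, and the overall F-test p-value of that
#' regression is returned.
#'
#' @inheritParams correlation_profile
#' @param n_components Number of leading principal components to retain
#'   (must be below `min(N - 2, k)`).
#' @return A single p-value.
#' @export
pca_regression_test <- function(data, x, ref = NULL, n_components = 10L) {
  parts <- resolve_columns(data, x, NULL, ref, require_x2 = FALSE)
  n <- length(parts$x1)
  k <- ncol(parts$Y)
  if (!is.numeric(n_components) || length(n_components) != 1L || n_components < 1) {
    stop_validation("`n_components` must be a positive integer.")
  }
  n_components <- as.integer(n_components)
  if (n_components >= min(n - 2L, k)) {
    stop_validation(paste0(
      "`n_components` = ", n_components, " is too large for N = ", n,
      " and k = ", k, " (need n_components < min(N - 2, k))."
    ))
  }
  scores <- prcomp(scale(parts$Y), center = FALSE, scale. = FALSE)$x[, seq_len(n_components), drop = FALSE]
  fit <- lm(parts$x1 ~ scores)
  fs <- summary(fit)$fstatistic
  unname(pf(fs[1L], fs[2L], fs[3L], lower.tail = FALSE))
}

#' Bivariate linear-regression test
#'
#' The classic two-variable baseline: ordinary least-squares regression of
#' `x2` on `x1`; returns the two-sided p-value of the slope (equivalent to
#' the Pearson correlation t-test).
#'
#' @inheritParams coref_coefficient
#' @return A single p-value.
#' @export
bivariate_regression_test <- function(data, x1, x2) {
  if (!is.data.frame(data) || !all(c(x1, x2) %in% names(data))) {
    stop_validation("`data` must contain columns `x1` and `x2` as named.")
  }
  x1v <- validate_test_vector(data[[x1]], x1)
  x2v <- validate_test_vector(data[[x2]], x2)
  if (length(x1v) != length(x2v)) {
    stop_validation("`x1` and `x2` must have the same length.")
  }
  fit <- lm(x2v ~ x1v)
  unname(summary(fit)$coefficients["x1v", "Pr(>|t|)"])
}

power_methods <- c("coreferentiality", "pca_regression_10",
                   "pca_regression_50", "bivariate_regression")

#' Estimate power for one simulated condition
#'
#' Simulates `n_sims` independent datasets from `spec` (with per-replicate
#' seeds derived deterministically from `seed`), applies the chosen test to
#' each, and tabulates the power (fraction of replicates with
#' `p < alpha`) and the median observed coreferentiality coefficient.
#'
#' Methods:
#' \describe{
#'   \item{`coreferentiality`}{[coref_test()] of `x1` vs `x2` against the
#'     simulated reference columns, `n_perm` permutations.}
#'   \item{`pca_regression_10` / `pca_regression_50`}{[pca_regression_test()]
#'     of `x1` on 10 resp. 50 PC scores of the reference columns (the
#'     two-variable bookkeeping uses the first test variable's own
#'     regression).}
#'   \item{`bivariate_regression`}{ignores the reference set entirely:
#'     each replicate draws a pair by literal delta-mixing
#'     ([simulate_bivariate_pair()] with `spec$delta`) and tests the slope.}
#' }
#'
#' @param spec A [coref_spec()] describing the generative condition; its
#'   `seed` field is ignored in favour of the derived per-replicate seeds.
#' @param method One of `"coreferentiality"`, `"pca_regression_10"`,
#'   `"pca_regression_50"`, `"bivariate_regression"`.
#' @param n_sims Number of replicate datasets (default 100).
#' @param n_perm Permutations per coreferentiality test (default 1000).
#' @param alpha Significance level (default 0.05).
#' @param seed Master seed for the whole condition.
#' @return A one-row tibble (class `coref_power`) with the condition
#'   parameters, `power`, `median_rc`, and list-columns `p_values`,
#'   `rc_values`, `seeds`.
#' @examples
#' run_power_condition(coref_spec(n = 50, k = 20, delta = 0.1),
#'                     n_sims = 5, n_perm = 100, seed = 1)
#' @export
run_power_condition <- function(spec, method = "coreferentiality",
                                n_sims = 100L, n_perm = 1000L,
                                alpha = 0.05, seed = NULL) {
  if (!inherits(spec, "coref_spec")) {
    stop_validation("`spec` must be a coref_spec object.")
  }
  method <- match.arg(method, power_methods)
  if (!is.numeric(n_sims) || length(n_sims) != 1L || n_sims < 1) {
    stop_validation("`n_sims` must be a positive integer.")
  }
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    stop_validation("`alpha` must be in (0, 1).")
  }
  n_sims <- as.integer(n_sims)
  check_seed(seed)

  # two independent deterministic seed streams: data generation and
  # permutation draws
  seeds <- derive_seeds(seed, 2L * n_sims)
  data_seeds <- seeds[seq_len(n_sims)]
  test_seeds <- seeds[n_sims + seq_len(n_sims)]

  one_rep <- function(i) {
    if (method == "bivariate_regression") {
      d <- simulate_bivariate_pair(spec$n, spec$delta, spec$sigma,
                                   seed = data_seeds[i])
      return(c(p = bivariate_regression_test(d, "x1", "x2"), rc = NA_real_))
    }
    spec_i <- spec
    spec_i$seed <- data_seeds[i]
    d <- simulate_coref_data(spec_i)
    ref <- setdiff(names(d), c("x1", "x2"))
    if (method == "coreferentiality") {
      fit <- coref_test(d, "x1", "x2", ref, n_perm = n_perm,
                        seed = test_seeds[i], exhaustive = "never",
                        keep_null = FALSE)
      c(p = fit$p_value, rc = fit$r_c)
    } else {
      ncomp <- if (method == "pca_regression_10") 10L else 50L
      c(p = pca_regression_test(d, "x1", ref, n_components = ncomp),
        rc = NA_real_)
    }
  }

  res <- vapply(seq_len(n_sims), one_rep, c(p = 0, rc = 0))
  p_values <- unname(res["p", ])
  rc_values <- unname(res["rc", ])

  out <- tibble::tibble(
    method = method,
    n = spec$n, k = spec$k, delta = spec$delta, r_x = spec$r_x,
    mode = spec$mode, n_noise_vars = spec$n_noise_vars,
    include_x1_in_y = spec$include_x1_in_y,
    include_x2_in_y = spec$include_x2_in_y,
    n_sims = n_sims, n_perm = as.integer(n_perm), alpha = alpha,
    power = mean(p_values < alpha),
    median_rc = if (all(is.na(rc_values))) NA_real_ else median(rc_values),
    p_values = list(p_values),
    rc_values = list(rc_values),
    seeds = list(data_seeds)
  )
  class(out) <- c("coref_power", class(out))
  out
}

#' Run a grid of power conditions
#'
#' Takes a data frame with one row per condition (any of the columns `n`,
#' `k`, `delta`, `r_x`, `mode`, `n_noise_vars`, `include_x1_in_y`,
#' `include_x2_in_y`, `sigma`, `method`, `n_sims`, `n_perm`, `alpha`;
#' missing columns fall back to the defaults of [coref_spec()] and
#' [run_power_condition()]), runs every condition with a per-condition seed
#' derived from `seed`, and binds the results into one tidy table. Results
#' are independent of the order in which conditions are evaluated.
#'
#' @param grid A data frame of conditions; `tidyr::expand_grid()` is a
#'   convenient way to build one.
#' @param n_sims,n_perm,alpha Defaults for conditions that do not carry
#'   their own columns.
#' @param seed Master seed.
#' @return A `coref_power` tibble with one row per condition.
#' @examples
#' grid <- tidyr::expand_grid(n = c(50, 100), delta = c(0, 0.1), k = 20)
#' run_power_grid(grid, n_sims = 3, n_perm = 50, seed = 1)
#' @export
run_power_grid <- function(grid, n_sims = 100L, n_perm = 1000L,
                           alpha = 0.05, seed = NULL) {
  if (!is.data.frame(grid) || nrow(grid) == 0L) {
    stop_validation("`grid` must be a data frame with at least one row.")
  }
  check_seed(seed)
  cond_seeds <- derive_seeds(seed, nrow(grid))

  spec_fields <- c("n", "k", "delta", "r_x", "mode", "n_noise_vars",
                   "include_x1_in_y", "include_x2_in_y", "sigma")
  unknown <- setdiff(names(grid),
                     c(spec_fields, "method", "n_sims", "n_perm", "alpha"))
  if (length(unknown) > 0L) {
    stop_validation(paste0("Unknown grid column(s): ",
                           paste(unknown, collapse = ", "), "."))
  }

  rows <- purrr::map(seq_len(nrow(grid)), function(i) {
    row <- as.list(grid[i, , drop = FALSE])
    spec <- do.call(coref_spec, row[intersect(names(row), spec_fields)])
    run_power_condition(
      spec,
      method = if ("method" %in% names(row)) row$method else "coreferentiality",
      n_sims = if ("n_sims" %in% names(row)) row$n_sims else n_sims,
      n_perm = if ("n_perm" %in% names(row)) row$n_perm else n_perm,
      alpha = if ("alpha" %in% names(row)) row$alpha else alpha,
      seed = cond_seeds[i]
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("coref_power", class(out))
  out
}

#' Plot a power table
#'
#' Line plot of power (or median R_C) against a chosen condition variable,
#' one line per level of a grouping variable — the shape of the study's
#' power figures.
#'
#' @param object A `coref_power` tibble from [run_power_condition()] or
#'   [run_power_grid()].
#' @param x Name of the column on the horizontal axis (default `"delta"`).
#' @param colour Name of the grouping column (default `"n"`).
#' @param y `"power"` or `"median_rc"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.coref_power <- function(object, x = "delta", colour = "n",
                                 y = c("power", "median_rc"), ...) {
  y <- match.arg(y)
  df <- as.data.frame(object)
  df[[colour]] <- factor(df[[colour]])
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[x]], y = .data[[y]],
                                   colour = .data[[colour]],
                                   group = .data[[colour]])) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(
      y = if (y == "power") sprintf("power (fraction of tests p < %g)",
                                    object$alpha[1L])
          else expression("median " * R[C]),
      colour = colour
    )
}

#' @rdname autoplot.coref_power
#' @param results A `coref_power` tibble.
#' @export
plot_power <- function(results, x = "delta", colour = "n",
                       y = c("power", "median_rc"), ...) {
  autoplot.coref_power(results, x = x, colour = colour, y = y, ...)
}
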