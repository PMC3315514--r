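# Bystander-control diagnostic.
#
# A significant coreferentiality test does not by itself distinguish the
# case where both test variables relate to Y from the case where only x1
# does and x2 merely correlates with x1 ("bystander" coreferentiality).
# The control asks: would an artificial x2', correlated with x1 exactly as
# strongly as the real x2 but otherwise pure noise, reach the observed
# |R_C| as often?

#' Bystander-control test for an observed coreferentiality
#'
#' Simulates `n_sim` artificial secondary test variables
#' `x2' = r * z1 + sqrt(1 - r^2) * e`, where `r` is the observed
#' correlation of `x1` and `x2`, `z1` the standardized `x1` and `e` fresh
#' standard Gaussian noise, so each `x2'` is correlated with `x1` like the
#' real `x2` but carries no information of its own. For each replicate the
#' absolute coreferentiality coefficient of `(x1, x2')` against the
#' reference set is computed; the reported `bystander_p` is the (add-one
#' corrected) fraction of replicates reaching or exceeding the observed
#' `|R_C|`. A small `bystander_p` means the observed coreferentiality is
#' not explained by `x2` merely echoing `x1`.
#'
#' @inheritParams coref_test
#' @param test Optionally, the `coref_test` result for the same data; its
#'   observed `r_c` is reused. If `NULL`, R_C is computed from `data`.
#' @param n_sim Number of simulated bystander variables.
#' @return An object of class `coref_bystander`: a list with
#'   `bystander_p`, `r_c_obs`, `r_x1x2`, `n_sim`, `seed`, and the vector
#'   `null_abs_rc` of simulated `|R_C|` values. Has a [tidy()] method.
#' @examples
#' d <- simulate_coref_data(coref_spec(n = 100, k = 50, delta = 0.1, seed = 1))
#' bystander_control(d, "x1", "x2", n_sim = 200, seed = 2)
#' @export
bystander_control <- function(data, x1, x2, ref = NULL, test = NULL,
                              n_sim = 1000L, seed = NULL,
                              method = c("pearson", "spearman")) {
  method <- match.arg(method)
  check_seed(seed)
  if (!is.numeric(n_sim) || length(n_sim) != 1L || n_sim < 1) {
    stop_validation("`n_sim` must be a positive integer.")
  }
  n_sim <- as.integer(n_sim)

  parts <- resolve_columns(data, x1, x2, ref)
  n <- length(parts$x1)
  r <- unname(cor(parts$x1, parts$x2))
  if (abs(r) >= 1 - 1e-12) {
    stop_validation(
      "x1 and x2 are perfectly correlated; the bystander construction is degenerate."
    )
  }

  rc_obs <- if (!is.null(test)) {
    if (!inherits(test, "coref_test")) {
      stop_validation("`test` must be a coref_test object (or NULL).")
    }
    test$r_c
  } else {
    coref_coefficient(data, x1, x2, ref, method = method)
  }

  z1 <- (parts$x1 - mean(parts$x1)) / sd(parts$x1)
  X2sim <- with_seed(seed, {
    E <- matrix(rnorm(n * n_sim), n, n_sim)
    r * z1 + sqrt(1 - r^2) * E
  })

  x1v <- parts$x1
  Y <- parts$Y
  if (method == "spearman") {
    x1v <- rank(x1v)
    X2sim <- rank_cols(X2sim)
    Y <- rank_cols(Y)
  }
  Y_std <- std_cols(Y)
  P1 <- profile_engine(Y_std, std_cols(cbind(x1v)))
  P2 <- profile_engine(Y_std, std_cols(X2sim))
  null_abs <- abs(colwise_cor(P1[, rep(1L, n_sim), drop = FALSE], P2))

  structure(list(
    bystander_p = (1 + sum(null_abs >= abs(rc_obs) - 1e-12)) / (n_sim + 1),
    r_c_obs = rc_obs,
    r_x1x2 = r,
    n_sim = n_sim,
    seed = seed,
    method = method,
    null_abs_rc = null_abs
  ), class = "coref_bystander")
}

#' @export
print.coref_bystander <- function(x, ...) {
  cat("Bystander-control test\n")
  cat(sprintf("  observed R_C = %.4f with r(x1,x2) = %.4f\n", x$r_c_obs, x$r_x1x2))
  cat(sprintf("  bystander p = %.4g over %d simulated bystander variables\n",
              x$bystander_p, x$n_sim))
  cat("  (small p: the coreferentiality exceeds what a pure bystander x2 would give)\n")
  invisible(x)
}

#' @export
tidy.coref_bystander <- function(x, ...) {
  tibble::tibble(
    estimate = x$r_c_obs, r_x1x2 = x$r_x1x2,
    bystander_p = x$bystander_p, n_sim = x$n_sim
  )
}
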