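# Correlation profiles and the coefficient of coreferentiality.
#
# The engine works on column-standardized matrices so that the profile of a
# whole block of (permuted) test vectors against Y is a single crossprod.

# Standardize columns to mean 0, rms 1/(sqrt(n-1)) units: crossprod of two
# such matrices is their Pearson correlation matrix.
std_cols <- function(M) {
  M <- sweep(M, 2L, colMeans(M), "-")
  ss <- sqrt(colSums(M^2))
  sweep(M, 2L, ss, "/")
}

rank_cols <- function(M) {
  apply(M, 2L, rank)
}

# Pearson correlations of each column of X (n x m) with each column of
# Y (n x k): k x m matrix. Both already standardized with std_cols().
profile_engine <- function(Y_std, X_std) {
  crossprod(Y_std, X_std)
}

# Column-wise Pearson correlation between two matrices of matched shape
# (k x m): one correlation per column pair. Used to turn pairs of
# correlation profiles into coreferentiality coefficients.
colwise_cor <- function(A, B) {
  A <- sweep(A, 2L, colMeans(A), "-")
  B <- sweep(B, 2L, colMeans(B), "-")
  num <- colSums(A * B)
  den <- sqrt(colSums(A^2) * colSums(B^2))
  if (any(den == 0)) {
    stop_validation(paste0(
      "Degenerate correlation profile (all k profile entries identical): ",
      "the coreferentiality coefficient is undefined."
    ))
  }
  num / den
}

#' Correlation profile of one variable against the reference set
#'
#' Computes the Pearson (or Spearman) correlation of one test variable with
#' every reference variable, returning the profile in reference-column
#' order. The correlation of two such profiles is the coefficient of
#' coreferentiality (see [coref_coefficient()]).
#'
#' @param data A data frame with one row per sample.
#' @param x Name of the test-variable column.
#' @param ref Character vector of reference-column names, or `NULL` to use
#'   all remaining numeric columns.
#' @param method `"pearson"` (default) or `"spearman"` (ranks first, then
#'   Pearson machinery).
#' @return A tibble with columns `term` (reference variable) and `estimate`
#'   (correlation), one row per reference variable.
#' @examples
#' d <- tibble::tibble(x = rnorm(20), a = rnorm(20), b = rnorm(20), c = rnorm(20))
#' correlation_profile(d, "x")
#' @export
correlation_profile <- function(data, x, ref = NULL,
                                method = c("pearson", "spearman")) {
  method <- match.arg(method)
  parts <- resolve_columns(data, x, NULL, ref, require_x2 = FALSE)
  xv <- parts$x1
  Y <- parts$Y
  if (method == "spearman") {
    xv <- rank(xv)
    Y <- rank_cols(Y)
  }
  r <- drop(profile_engine(std_cols(Y), std_cols(cbind(xv))))
  tibble::tibble(term = colnames(parts$Y), estimate = unname(r))
}

#' Coefficient of coreferentiality
#'
#' The coefficient of coreferentiality R_C of two test variables with
#' respect to a reference set Y is the Pearson correlation between their two
#' correlation profiles: the k-vector of correlations of `x1` with each Y
#' column, against the matching k-vector for `x2`. It measures whether the
#' two variables parallel each other in their relatedness to the reference
#' data, not whether they correlate directly.
#'
#' @inheritParams correlation_profile
#' @param x1,x2 Names of the two test-variable columns.
#' @return A single number in \[-1, 1\].
#' @seealso [coref_test()] for the permutation significance test.
#' @examples
#' d <- simulate_coref_data(coref_spec(n = 100, k = 20, delta = 0.1, seed = 1))
#' coref_coefficient(d, "x1", "x2")
#' @export
coref_coefficient <- function(data, x1, x2, ref = NULL,
                              method = c("pearson", "spearman")) {
  method <- match.arg(method)
  parts <- resolve_columns(data, x1, x2, ref)
  x1v <- parts$x1
  x2v <- parts$x2
  Y <- parts$Y
  if (method == "spearman") {
    x1v <- rank(x1v)
    x2v <- rank(x2v)
    Y <- rank_cols(Y)
  }
  P <- profile_engine(std_cols(Y), std_cols(cbind(x1v, x2v)))
  unname(colwise_cor(P[, 1L, drop = FALSE], P[, 2L, drop = FALSE]))
}
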