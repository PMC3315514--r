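# Input validation shared by every user-facing entry point.
#
# Error conditions carry classes so the CLI can map them to exit codes:
#   coref_validation_error -> 2, coref_io_error -> 3.

stop_validation <- function(msg, ...) {
  abort(msg, class = "coref_validation_error", ...)
}

stop_io <- function(msg, ...) {
  abort(msg, class = "coref_io_error", ...)
}

# Resolve x1/x2/ref column names against `data` and return validated
# numeric pieces: x1, x2 vectors and Y matrix (samples x k).
# `ref = NULL` means all remaining numeric columns.
resolve_columns <- function(data, x1, x2, ref = NULL,
                            require_x2 = TRUE, min_n = 4L, min_k = 3L) {
  if (!is.data.frame(data)) {
    stop_validation("`data` must be a data frame.")
  }
  if (!is.character(x1) || length(x1) != 1L) {
    stop_validation("`x1` must be a single column name.")
  }
  if (require_x2 && (!is.character(x2) || length(x2) != 1L)) {
    stop_validation("`x2` must be a single column name.")
  }
  test_cols <- c(x1, if (require_x2) x2)
  missing_cols <- setdiff(test_cols, names(data))
  if (length(missing_cols) > 0L) {
    stop_validation(paste0(
      "Column(s) not found in `data`: ",
      paste(missing_cols, collapse = ", "), "."
    ))
  }
  if (require_x2 && identical(x1, x2)) {
    stop_validation("`x1` and `x2` must name different columns.")
  }
  if (is.null(ref)) {
    numeric_cols <- names(data)[vapply(data, is.numeric, logical(1))]
    ref <- setdiff(numeric_cols, test_cols)
  } else {
    missing_ref <- setdiff(ref, names(data))
    if (length(missing_ref) > 0L) {
      stop_validation(paste0(
        "Reference column(s) not found in `data`: ",
        paste(missing_ref, collapse = ", "), "."
      ))
    }
    overlap <- intersect(ref, test_cols)
    if (length(overlap) > 0L) {
      stop_validation(paste0(
        "Reference columns must not include the test variables (",
        paste(overlap, collapse = ", "),
        "); pass them explicitly through the force option of read_coref_data() ",
        "if this is really intended."
      ))
    }
  }
  if (length(ref) < min_k) {
    stop_validation(paste0(
      "At least ", min_k, " reference variables are required; got ",
      length(ref), ". A correlation of two correlation profiles is ",
      "degenerate below k = 3."
    ))
  }

  x1v <- validate_test_vector(data[[x1]], x1, min_n = min_n)
  x2v <- NULL
  if (require_x2) {
    x2v <- validate_test_vector(data[[x2]], x2, min_n = min_n)
  }
  Y <- validate_reference_matrix(data[ref], n = length(x1v))

  list(x1 = x1v, x2 = x2v, Y = Y, x1_name = x1,
       x2_name = if (require_x2) x2, ref = ref)
}

validate_test_vector <- function(x, name, min_n = 4L) {
  if (!is.numeric(x)) {
    stop_validation(paste0("Column `", name, "` must be numeric."))
  }
  if (length(x) < min_n) {
    stop_validation(paste0(
      "At least ", min_n, " samples are required; `", name, "` has ",
      length(x), "."
    ))
  }
  if (anyNA(x) || !all(is.finite(x))) {
    bad <- which(!is.finite(x))
    stop_validation(paste0(
      "Column `", name, "` contains missing or non-finite values (rows ",
      paste(head(bad, 5L), collapse = ", "),
      if (length(bad) > 5L) ", ..." else "",
      "). Complete rows are required: pairwise deletion would distort the ",
      "permutation scheme."
    ))
  }
  if (sd(x) == 0) {
    stop_validation(paste0(
      "Column `", name, "` has zero variance; correlations are undefined."
    ))
  }
  as.numeric(x)
}

validate_reference_matrix <- function(df, n) {
  not_num <- names(df)[!vapply(df, is.numeric, logical(1))]
  if (length(not_num) > 0L) {
    stop_validation(paste0(
      "Reference column(s) not numeric: ", paste(not_num, collapse = ", "), "."
    ))
  }
  Y <- as.matrix(df)
  storage.mode(Y) <- "double"
  if (nrow(Y) != n) {
    stop_validation(paste0(
      "Reference data have ", nrow(Y), " rows but the test variables have ",
      n, "; sample ordering must match."
    ))
  }
  bad <- !is.finite(Y)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop_validation(paste0(
      "Reference data contain missing or non-finite values (first at row ",
      idx[1L], ", column `", colnames(Y)[idx[2L]], "`)."
    ))
  }
  sds <- apply(Y, 2L, sd)
  if (any(sds == 0)) {
    stop_validation(paste0(
      "Reference column(s) with zero variance: ",
      paste(colnames(Y)[sds == 0], collapse = ", "), "."
    ))
  }
  Y
}

check_seed <- function(seed) {
  if (is.null(seed)) return(invisible(NULL))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop_validation("`seed` must be a single finite number or NULL.")
  }
  invisible(NULL)
}

# Evaluate `expr` under `seed` without disturbing the caller's RNG state.
# seed = NULL uses (and advances) the session RNG.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic per-replicate seed stream: draw n seeds under the master
# seed so that any replicate can be rerun in isolation and results do not
# depend on scheduling.
derive_seeds <- function(master_seed, n) {
  with_seed(master_seed, sample.int(.Machine$integer.max - 1L, n))
}
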