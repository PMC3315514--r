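# Tabular input with cell-level validation, and result serialization.

# 17 significant digits round-trip IEEE doubles exactly; readr's default
# formatting does not guarantee that, so doubles are pre-formatted.
write_tsv_precise <- function(df, path) {
  df <- as.data.frame(df)
  for (nm in names(df)) {
    if (is.double(df[[nm]])) df[[nm]] <- sprintf("%.17g", df[[nm]])
  }
  readr::write_tsv(df, path, quote = "none")
}

infer_delim <- function(path, delim = NULL) {
  if (!is.null(delim)) return(delim)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    csv = ",",
    tsv = "\t",
    txt = "\t",
    stop_io(paste0(
      "Cannot infer the delimiter from extension '.", ext,
      "'; pass `delim` explicitly."
    ))
  )
}

#' Read and validate a coreferentiality input table
#'
#' Reads a delimited file (one row per sample, one named column per
#' variable), checks every cell, and returns the validated pieces for
#' [coref_test()]. Non-numeric or empty cells are hard errors reported
#' with their row/column coordinates; constant columns are hard errors
#' naming the column. Reference columns that duplicate a test variable
#' value-for-value are dropped with a warning unless
#' `force_include_x_in_ref = TRUE` — including a test variable in the
#' reference set creates a correlation outlier that can destroy the power
#' of the test.
#'
#' @param path Path to a `.csv` (comma) or `.tsv`/`.txt` (tab) file.
#' @param x1,x2 Names of the two test-variable columns.
#' @param ref Character vector of reference-column names, or `NULL` for
#'   all remaining columns.
#' @param delim Field delimiter, overriding the extension-based choice.
#' @param force_include_x_in_ref Keep reference columns that duplicate a
#'   test variable, and allow `ref` to name `x1`/`x2` themselves (their
#'   values are then copied into extra reference columns `<name>.ref`).
#' @return A list with elements `data` (tibble), `x1`, `x2`, `ref`
#'   (character vector of the retained reference columns).
#' @export
read_coref_data <- function(path, x1, x2, ref = NULL, delim = NULL,
                            force_include_x_in_ref = FALSE) {
  if (!file.exists(path)) {
    stop_io(paste0("Input file not found: ", path))
  }
  delim <- infer_delim(path, delim)
  raw <- tryCatch(
    readr::read_delim(path, delim = delim,
                      col_types = readr::cols(.default = readr::col_character()),
                      progress = FALSE),
    error = function(e) stop_io(paste0("Failed to read ", path, ": ",
                                       conditionMessage(e)))
  )
  if (nrow(raw) == 0L) stop_validation("Input table has no data rows.")

  # cell-level numeric parse with coordinates on failure
  parsed <- purrr::imap(raw, function(col, name) {
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num))
    if (length(bad) > 0L) {
      stop_validation(paste0(
        "Non-numeric or empty cell at row ", bad[1L], ", column `", name,
        "` (value: ",
        if (is.na(col[bad[1L]])) "<empty>" else paste0("'", col[bad[1L]], "'"),
        ")."
      ))
    }
    num
  })
  data <- tibble::as_tibble(parsed)

  for (nm in c(x1, x2)) {
    if (!nm %in% names(data)) {
      stop_validation(paste0("Column `", nm, "` not found in ", path, "."))
    }
  }
  if (identical(x1, x2)) {
    stop_validation("`x1` and `x2` must name different columns.")
  }

  if (is.null(ref)) {
    ref <- setdiff(names(data), c(x1, x2))
  } else {
    missing_ref <- setdiff(ref, names(data))
    if (length(missing_ref) > 0L) {
      stop_validation(paste0("Reference column(s) not found: ",
                             paste(missing_ref, collapse = ", "), "."))
    }
  }

  # explicit request to use the test variables themselves as reference
  overlap <- intersect(ref, c(x1, x2))
  if (length(overlap) > 0L) {
    if (!force_include_x_in_ref) {
      stop_validation(paste0(
        "Reference columns include the test variable(s) ",
        paste(overlap, collapse = ", "),
        "; use `force_include_x_in_ref = TRUE` if this is really intended."
      ))
    }
    warn(paste0(
      "Including the test variable(s) ", paste(overlap, collapse = ", "),
      " in the reference set: this creates correlation outliers and can ",
      "abolish the power of the coreferentiality test."
    ))
    for (nm in overlap) {
      data[[paste0(nm, ".ref")]] <- data[[nm]]
    }
    ref <- c(setdiff(ref, overlap), paste0(overlap, ".ref"))
  }

  # reference columns duplicating a test variable value-for-value
  dup <- ref[vapply(ref, function(nm) {
    identical(data[[nm]], data[[x1]]) || identical(data[[nm]], data[[x2]])
  }, logical(1))]
  dup <- setdiff(dup, paste0(overlap, ".ref"))
  if (length(dup) > 0L) {
    if (force_include_x_in_ref) {
      warn(paste0(
        "Reference column(s) duplicating a test variable retained under ",
        "force_include_x_in_ref: ", paste(dup, collapse = ", "), "."
      ))
    } else {
      warn(paste0(
        "Dropping reference column(s) that duplicate a test variable ",
        "value-for-value: ", paste(dup, collapse = ", "),
        " (use `force_include_x_in_ref = TRUE` to keep them)."
      ))
      ref <- setdiff(ref, dup)
    }
  }

  # full structural validation (dimensions, finiteness, variance)
  resolve_columns(data, x1, x2,
                  if (force_include_x_in_ref) NULL else ref,
                  require_x2 = TRUE)
  if (force_include_x_in_ref) {
    validate_reference_matrix(data[ref], n = nrow(data))
  }

  list(data = data, x1 = x1, x2 = x2, ref = ref)
}

#' Write a result to disk
#'
#' `coref_test` and `coref_bystander` results are written as JSON (full
#' numeric precision, decimal points regardless of locale); `coref_power`
#' tables as TSV with one row per condition and the documented scalar
#' columns (`method`, `n`, `k`, `delta`, `r_x`, `mode`, `n_noise_vars`,
#' `include_x1_in_y`, `include_x2_in_y`, `n_sims`, `n_perm`, `alpha`,
#' `power`, `median_rc`). Reading a written result back reproduces all
#' numeric fields exactly.
#'
#' @param x A `coref_test`, `coref_bystander`, or `coref_power` object.
#' @param path Destination file.
#' @param null_path Optional path for the full permutation null
#'   distribution of a `coref_test` (one-column TSV `null_rc`).
#' @return `path`, invisibly.
#' @seealso [read_coref_result()]
#' @export
write_coref_result <- function(x, path, null_path = NULL) {
  wrap_io <- function(expr) {
    tryCatch(expr, error = function(e) {
      if (inherits(e, "coref_io_error")) stop(e)
      stop_io(paste0("Failed to write ", path, ": ", conditionMessage(e)))
    })
  }
  if (inherits(x, "coref_test")) {
    rec <- list(
      r_c = x$r_c, p_value = x$p_value, n_perm = x$n_perm,
      r_x1x2 = x$r_x1x2, seed = x$seed,
      null_mean = x$null_mean, null_sd = x$null_sd,
      null_q025 = x$null_q025, null_q975 = x$null_q975
    )
    wrap_io(jsonlite::write_json(rec, path, auto_unbox = TRUE,
                                 digits = I(17), null = "null"))
    if (!is.null(null_path)) {
      if (is.null(x$null_rc)) {
        stop_validation("No null distribution stored; refit with `keep_null = TRUE`.")
      }
      wrap_io(write_tsv_precise(tibble::tibble(null_rc = x$null_rc), null_path))
    }
  } else if (inherits(x, "coref_bystander")) {
    rec <- list(
      r_c_obs = x$r_c_obs, bystander_p = x$bystander_p,
      r_x1x2 = x$r_x1x2, n_sim = x$n_sim, seed = x$seed
    )
    wrap_io(jsonlite::write_json(rec, path, auto_unbox = TRUE,
                                 digits = I(17), null = "null"))
  } else if (inherits(x, "coref_power") || is.data.frame(x)) {
    keep <- intersect(
      c("method", "n", "k", "delta", "r_x", "mode", "n_noise_vars",
        "include_x1_in_y", "include_x2_in_y", "n_sims", "n_perm", "alpha",
        "power", "median_rc"),
      names(x)
    )
    wrap_io(write_tsv_precise(as.data.frame(x)[, keep, drop = FALSE], path))
  } else {
    stop_validation("Don't know how to write an object of this class.")
  }
  invisible(path)
}

#' Read a result written by [write_coref_result()]
#'
#' @param path A `.json` (single test) or `.tsv` (power table) file.
#' @return A named list (JSON) or tibble (TSV).
#' @export
read_coref_result <- function(path) {
  if (!file.exists(path)) stop_io(paste0("Result file not found: ", path))
  if (tolower(tools::file_ext(path)) == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    # parse cells with base strtod: correctly rounded, so full-precision
    # numbers written by write_tsv_precise() round-trip bit-exactly
    raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                           col_types = readr::cols(.default = readr::col_character()))
    tibble::as_tibble(purrr::map(raw, function(col) {
      if (all(col %in% c("TRUE", "FALSE"))) return(as.logical(col))
      num <- suppressWarnings(as.numeric(col))
      if (anyNA(num)) col else num
    }))
  }
}
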