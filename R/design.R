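#' Construct a design table
#'
#' The central container for a designed experiment: a runs-by-factors matrix
#' of coded levels, zero or more dummy (error-estimation) columns, and one or
#' more response columns in real units. Replicate groups -- sets of runs with
#' identical coded rows, e.g. the replicated center points of a Box-Behnken
#' design -- are detected automatically and drive the pure-error computation
#' in [anova_quadratic()].
#'
#' @param coded Data frame or matrix of coded levels (factors and any dummy
#'   columns), one row per run.
#' @param responses Data frame of response columns (same number of rows).
#' @param dummy_columns Character vector naming the columns of `coded` that
#'   are dummy factors (carry no real variable; used for error estimation).
#' @param factors Optional named list of [factor_spec()] objects for the
#'   non-dummy columns, enabling real-unit decoding and level validation.
#' @param run_ids Run identifiers, default `1:nrow`.
#' @param response_units Optional named character vector of units.
#' @return An object of class `"design_table"`.
#' @export
design_table <- function(coded, responses, dummy_columns = character(),
                         factors = NULL, run_ids = NULL,
                         response_units = NULL) {
  coded <- as.data.frame(coded)
  responses <- as.data.frame(responses)
  if (nrow(coded) != nrow(responses)) {
    stop("coded matrix and responses disagree on number of runs", call. = FALSE)
  }
  if (ncol(responses) < 1L) stop("at least one response column is required",
                                 call. = FALSE)
  if (!all(vapply(coded, is.numeric, logical(1)))) {
    bad <- names(coded)[!vapply(coded, is.numeric, logical(1))]
    stop("non-numeric coded column(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (!all(dummy_columns %in% names(coded))) {
    stop("dummy column(s) not present in design: ",
         paste(setdiff(dummy_columns, names(coded)), collapse = ", "),
         call. = FALSE)
  }
  if (is.null(run_ids)) run_ids <- seq_len(nrow(coded))
  if (anyDuplicated(run_ids)) stop("duplicate run ids", call. = FALSE)

  factor_cols <- setdiff(names(coded), dummy_columns)
  if (!is.null(factors)) {
    for (nm in intersect(names(factors), factor_cols)) {
      lev <- factors[[nm]]$levels
      off <- !vapply(coded[[nm]], function(v) any(abs(v - lev) < 1e-8),
                     logical(1))
      if (any(off)) {
        stop("column ", nm, ": coded value(s) ",
             paste(unique(coded[[nm]][off]), collapse = ", "),
             " not among declared levels {",
             paste(lev, collapse = ", "), "}", call. = FALSE)
      }
    }
  }

  key <- apply(coded, 1L, paste, collapse = "\r")
  replicate_groups <- split(run_ids, key)
  names(replicate_groups) <- NULL

  structure(
    list(run_ids = run_ids, coded = coded, responses = responses,
         dummy_columns = dummy_columns, factor_columns = factor_cols,
         factors = factors, response_units = response_units,
         replicate_groups = replicate_groups),
    class = "design_table"
  )
}

#' @export
print.design_table <- function(x, ...) {
  nrep <- sum(lengths(x$replicate_groups) > 1L)
  cat(sprintf("Design table: %d runs, %d factors (%s)%s, responses: %s\n",
              nrow(x$coded), length(x$factor_columns),
              paste(x$factor_columns, collapse = ", "),
              if (length(x$dummy_columns))
                paste0(", dummies: ", paste(x$dummy_columns, collapse = ", "))
              else "",
              paste(names(x$responses), collapse = ", ")))
  if (nrep) cat(sprintf("  %d replicated coded point(s); largest group n = %d\n",
                        nrep, max(lengths(x$replicate_groups))))
  invisible(x)
}

#' Extract a response column, with checking
#' @keywords internal
#' @noRd
get_response <- function(table, response_name) {
  stopifnot(inherits(table, "design_table"))
  if (!response_name %in% names(table$responses)) {
    stop("unknown response '", response_name, "'; available: ",
         paste(names(table$responses), collapse = ", "), call. = FALSE)
  }
  table$responses[[response_name]]
}

#' Generate a Box-Behnken design
#'
#' Three-level response-surface design: for every pair of factors the four
#' (+/-1, +/-1) combinations with all other factors at 0, plus `n_center`
#' replicated center runs. For 4 factors this gives the classical 24 + 5
#' = 29-run layout.
#'
#' @param k Number of factors (>= 3).
#' @param n_center Number of center-point replicates.
#' @param names Factor column names, default `X1..Xk`.
#' @return Data frame of coded levels, one row per run.
#' @export
bbd_design <- function(k, n_center = 5L, names = paste0("X", seq_len(k))) {
  stopifnot(k >= 3L, n_center >= 0L, length(names) == k)
  pairs <- utils::combn(k, 2L)
  pm <- as.matrix(expand.grid(c(-1, 1), c(-1, 1)))
  rows <- lapply(seq_len(ncol(pairs)), function(p) {
    block <- matrix(0, 4L, k)
    block[, pairs[, p]] <- pm
    block
  })
  out <- do.call(rbind, c(rows, list(matrix(0, n_center, k))))
  colnames(out) <- names
  as.data.frame(out)
}
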