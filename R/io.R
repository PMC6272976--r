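#' Path to a packaged example file
#'
#' @param file File name under the package's `extdata/`; with no argument,
#'   lists the available files.
#' @return Full path (or character vector of file names).
#' @examples
#' fermkin_example()
#' fermkin_example("bbd_table4.csv")
#' @export
fermkin_example <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "fermkin")))
  }
  path <- system.file("extdata", file, package = "fermkin")
  if (path == "") stop("no packaged file '", file, "'", call. = FALSE)
  path
}

#' Read a run configuration
#'
#' A structured YAML sidecar describing a design CSV: factor centers and
#' halfwidths, whether the factor columns are stored in real or coded
#' units, the dummy columns, and the response columns with units.
#'
#' @param path YAML file path.
#' @return A validated configuration list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  need <- c("units", "responses", "factors")
  missing <- setdiff(need, names(cfg))
  if (length(missing)) stop("config lacks field(s): ",
                            paste(missing, collapse = ", "), call. = FALSE)
  if (!cfg$units %in% c("real", "coded")) {
    stop("config units must be 'real' or 'coded'", call. = FALSE)
  }
  for (nm in names(cfg$factors)) {
    f <- cfg$factors[[nm]]
    if (is.null(f$center) || is.null(f$halfwidth)) {
      stop("factor '", nm, "' needs center and halfwidth", call. = FALSE)
    }
  }
  if (is.null(cfg$dummy_columns)) cfg$dummy_columns <- character()
  cfg
}

#' Read a design CSV into a design table
#'
#' Reads a CSV whose header carries factor columns (real or coded units,
#' per the config) then response columns, builds [factor_spec()]s from the
#' config, encodes real-unit columns onto the coded scale, and returns a
#' [design_table()] with replicate groups detected. Parallel
#' standard-deviation columns named in the config are carried along but
#' never used by fitting.
#'
#' @param path CSV file path.
#' @param config A configuration list from [read_run_config()], or the path
#'   to the YAML file.
#' @return A [design_table()].
#' @examples
#' pb <- read_design_csv(fermkin_example("pb_table2.csv"),
#'                       fermkin_example("pb_table2.yaml"))
#' @export
read_design_csv <- function(path, config) {
  if (is.character(config)) config <- read_run_config(config)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- tryCatch(utils::read.csv(path, check.names = FALSE),
                  error = function(e) {
                    stop("parse error: ", path, ": ", conditionMessage(e),
                         call. = FALSE)
                  })
  if (nrow(raw) == 0L || ncol(raw) == 0L) {
    stop("parse error: ", path, " contains no data rows", call. = FALSE)
  }

  fac_names <- names(config$factors)
  resp_names <- names(config$responses)
  dummy <- as.character(config$dummy_columns)
  needed <- c(fac_names, resp_names, dummy)
  missing <- setdiff(needed, names(raw))
  if (length(missing)) {
    stop("parse error: column(s) missing from ", basename(path), ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (nm in needed) {
    if (!is.numeric(raw[[nm]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(raw[[nm]]))))[1L]
      stop("parse error: non-numeric value in column '", nm, "', row ",
           bad, call. = FALSE)
    }
  }

  run_col <- config$run_column
  run_ids <- if (!is.null(run_col) && run_col %in% names(raw)) {
    if (anyDuplicated(raw[[run_col]])) {
      stop("parse error: duplicate run id in column '", run_col, "'",
           call. = FALSE)
    }
    raw[[run_col]]
  } else NULL

  specs <- lapply(fac_names, function(nm) {
    f <- config$factors[[nm]]
    factor_spec(nm, center = f$center, halfwidth = f$halfwidth,
                levels = if (!is.null(f$levels)) f$levels else c(-1, 0, 1),
                label = if (!is.null(f$label)) f$label else nm)
  })
  names(specs) <- fac_names

  coded <- raw[, c(fac_names, dummy), drop = FALSE]
  if (config$units == "real") {
    for (nm in fac_names) coded[[nm]] <- encode_levels(specs[[nm]], coded[[nm]])
  }
  # snap float fuzz from real-unit encoding onto exact declared levels
  for (nm in fac_names) {
    lev <- specs[[nm]]$levels
    near <- lev[apply(abs(outer(coded[[nm]], lev, "-")), 1L, which.min)]
    coded[[nm]] <- ifelse(abs(coded[[nm]] - near) < 1e-6, near, coded[[nm]])
  }

  responses <- raw[, resp_names, drop = FALSE]
  sd_cols <- config$sd_columns
  if (!is.null(sd_cols)) {
    for (nm in names(sd_cols)) {
      if (sd_cols[[nm]] %in% names(raw)) {
        responses[[sd_cols[[nm]]]] <- raw[[sd_cols[[nm]]]]
      }
    }
  }

  design_table(coded, responses, dummy_columns = dummy, factors = specs,
               run_ids = run_ids,
               response_units = unlist(config$responses))
}

#' Serialize an analysis result
#'
#' Writes a result object -- a [pb_effects()] table, an
#' [anova_quadratic()] table, an [optimize_quadratic()] point, a
#' [fit_quadratic()] or kinetic fit -- as JSON (full structure) or TSV
#' (tabular part). Numbers are written at full precision; any display
#' rounding is left to the reader.
#'
#' @param results A result object from an analysis function.
#' @param path Output file; with `NULL` the serialized text is returned
#'   invisibly instead of written.
#' @param format `"json"` or `"tsv"`.
#' @return The file path (or the serialized text), invisibly.
#' @export
write_report <- function(results, path = NULL, format = c("json", "tsv")) {
  format <- match.arg(format)
  if (format == "json") {
    payload <- report_payload(results)
    txt <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                            pretty = TRUE, na = "null")
  } else {
    tab <- report_table(results)
    con <- textConnection("txt_out", "w", local = TRUE)
    utils::write.table(format(tab, digits = 17, scientific = FALSE,
                              trim = TRUE),
                       con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
    txt <- paste(txt_out, collapse = "\n")
  }
  if (is.null(path)) return(invisible(txt))
  writeLines(as.character(txt), path)
  invisible(path)
}

#' Re-read a TSV report written by [write_report()]
#'
#' @param path TSV file path.
#' @return Data frame with numeric columns restored.
#' @export
read_report_tsv <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE)
  for (nm in names(tab)) {
    num <- suppressWarnings(as.numeric(tab[[nm]]))
    if (!all(is.na(num) != is.na(tab[[nm]]))) {
      if (all(is.na(tab[[nm]]) | !is.na(num))) tab[[nm]] <- num
    }
  }
  tab
}

report_payload <- function(results) {
  if (inherits(results, "pb_result")) {
    list(type = "pb_result", response = results$response,
         error = results$error, error_df = results$error_df,
         error_estimate = results$error_estimate, t_limit = results$t_limit,
         effects = results$effects)
  } else if (inherits(results, "anova_table")) {
    list(type = "anova_table", response = attr(results, "response"),
         table = as.data.frame(results))
  } else if (inherits(results, "optimum_point")) {
    list(type = "optimum_point", response = results$response,
         sense = results$sense,
         coded_location = as.list(results$coded_location),
         real_location = as.list(results$real_location),
         predicted_response = results$predicted_response,
         on_boundary = results$on_boundary)
  } else if (inherits(results, "quadratic_fit")) {
    list(type = "quadratic_fit", response = results$response,
         coefficients = as.list(results$coefficients), R2 = results$R2,
         n_runs = results$n_runs, n_params = results$n_params)
  } else if (inherits(results, "kinetic_fit")) {
    list(type = "kinetic_fit", params = unclass(results$params),
         R2 = results$R2, residual_sse = results$residual_sse,
         converged = results$converged)
  } else if (is.data.frame(results) || is.list(results)) {
    results
  } else {
    stop("usage error: don't know how to serialize a ",
         paste(class(results), collapse = "/"), call. = FALSE)
  }
}

report_table <- function(results) {
  if (inherits(results, "pb_result")) {
    results$effects
  } else if (inherits(results, "anova_table")) {
    as.data.frame(results)
  } else if (inherits(results, "optimum_point")) {
    data.frame(factor = names(results$coded_location),
               coded = as.numeric(results$coded_location),
               real = if (is.null(results$real_location)) NA_real_
                      else as.numeric(results$real_location))
  } else if (is.data.frame(results)) {
    results
  } else {
    stop("usage error: no tabular form for a ",
         paste(class(results), collapse = "/"), call. = FALSE)
  }
}
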