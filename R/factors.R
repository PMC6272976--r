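#' Define a design factor and its coded scale
#'
#' A factor spec maps one medium component or process variable between its
#' real units (e.g. g/L) and the dimensionless coded scale used in design of
#' experiments, where the design levels sit at -1, 0, +1 (or just -1, +1 for
#' a two-level screening design). Coded 0 corresponds to `center`; one coded
#' unit corresponds to `halfwidth` real units.
#'
#' @param name Factor name (column name in design tables).
#' @param center Real-unit value mapped to coded 0.
#' @param halfwidth Real units per coded unit; must be strictly positive.
#' @param levels Coded levels used by the design, default `c(-1, 0, 1)`.
#' @param label Optional human-readable label with units.
#' @return An object of class `"factor_spec"`.
#' @examples
#' carr <- factor_spec("X1", center = 2, halfwidth = 1)
#' encode_levels(carr, c(1, 2, 3))   # -1 0 1
#' decode_levels(carr, -0.24)        # 1.76
#' @export
factor_spec <- function(name, center, halfwidth, levels = c(-1, 0, 1),
                        label = name) {
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(center), length(center) == 1L, is.finite(center),
            is.numeric(halfwidth), length(halfwidth) == 1L)
  if (!is.finite(halfwidth) || halfwidth <= 0) {
    stop("invalid factor spec '", name, "': halfwidth must be > 0",
         call. = FALSE)
  }
  structure(
    list(name = name, center = center, halfwidth = halfwidth,
         levels = sort(unique(as.numeric(levels))), label = label),
    class = "factor_spec"
  )
}

#' @export
print.factor_spec <- function(x, ...) {
  cat(sprintf("Factor %s [%s]: center %g, halfwidth %g, coded levels {%s}\n",
              x$name, x$label, x$center, x$halfwidth,
              paste(x$levels, collapse = ", ")))
  invisible(x)
}

#' Convert between real units and coded units
#'
#' `encode_levels()` maps real-unit values onto the coded scale,
#' `coded = (real - center) / halfwidth`; `decode_levels()` is its exact
#' inverse. Both are vectorized.
#'
#' @param spec A [factor_spec()].
#' @param real_values,coded_values Numeric vectors.
#' @return Numeric vector of the same length.
#' @export
encode_levels <- function(spec, real_values) {
  stopifnot(inherits(spec, "factor_spec"), is.numeric(real_values))
  (real_values - spec$center) / spec$halfwidth
}

#' @rdname encode_levels
#' @export
decode_levels <- function(spec, coded_values) {
  stopifnot(inherits(spec, "factor_spec"), is.numeric(coded_values))
  spec$center + coded_values * spec$halfwidth
}
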