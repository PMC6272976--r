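#' Polynomial meta-model of a kinetic parameter over operating conditions
#'
#' Fits a user-declared polynomial in the operating conditions -- stirring
#' speed `RS` (r/min), temperature `T` (degrees C) and inoculum size `IS`
#' (mL) -- to a kinetic parameter (e.g. `mu_m`, `X0`, `Xm`, `alpha`,
#' `beta`) estimated at each condition. The term list must be declared
#' explicitly because typical one-factor-at-a-time condition grids cannot
#' identify a full quadratic with interactions: 9 such points cannot support
#' the 10-term model, and this function refuses to return a silent
#' minimum-norm solution in that case.
#'
#' @param conditions Data frame with numeric columns `RS`, `T`, `IS`
#'   (strictly positive), one row per condition point.
#' @param values Numeric parameter values, one per condition.
#' @param terms Character vector of polynomial terms over the condition
#'   variables: a variable name (`"RS"`), a squared term (`"RS^2"` or
#'   `"RS2"`), or an interaction (`"RS:T"`). The intercept is always
#'   included and need not be listed.
#' @param allow_underdetermined If `TRUE`, a rank-deficient or
#'   under-determined system is solved in the minimum-norm sense (via the
#'   pseudoinverse) with a warning instead of an error.
#' @return Object of class `"param_surface"`: `coefficients` (named, led by
#'   `(Intercept)`), `terms`, `rank`, `n_points`, `n_terms`, `R2`,
#'   `underdetermined` flag; use `predict()` on a new conditions data frame.
#' @examples
#' grid <- expand.grid(RS = c(80, 130, 200), T = c(10, 20, 30), IS = 2:4)
#' vals <- 1 + 0.01 * grid$RS - 0.002 * grid$T^2
#' fit <- fit_param_surface(grid, vals, terms = c("RS", "T^2"))
#' fit$coefficients
#' @export
fit_param_surface <- function(conditions, values, terms,
                              allow_underdetermined = FALSE) {
  conditions <- as.data.frame(conditions)
  vars <- c("RS", "T", "IS")
  missing <- setdiff(vars, names(conditions))
  if (length(missing)) stop("conditions lack column(s): ",
                            paste(missing, collapse = ", "), call. = FALSE)
  if (any(as.matrix(conditions[vars]) <= 0)) {
    stop("condition values must be strictly positive", call. = FALSE)
  }
  stopifnot(is.numeric(values), length(values) == nrow(conditions),
            is.character(terms), length(terms) >= 1L)

  X <- surface_model_matrix(conditions, terms)
  n <- nrow(X); p <- ncol(X)
  qrX <- qr(X)
  underdetermined <- n < p || qrX$rank < p
  if (underdetermined && !allow_underdetermined) {
    stop(sprintf(
      "underdetermined meta-model: %d points, %d terms, rank %d; declare fewer terms or set allow_underdetermined = TRUE for a minimum-norm fit",
      n, p, qrX$rank), call. = FALSE)
  }
  if (underdetermined) {
    warning(sprintf(
      "rank-deficient system (%d points, %d terms, rank %d): minimum-norm coefficients returned; they are not unique",
      n, p, qrX$rank))
    sv <- svd(X)
    pos <- sv$d > max(dim(X)) * .Machine$double.eps * sv$d[1L]
    cf <- sv$v[, pos, drop = FALSE] %*%
      ((t(sv$u[, pos, drop = FALSE]) %*% values) / sv$d[pos])
    cf <- stats::setNames(drop(cf), colnames(X))
  } else {
    cf <- stats::setNames(qr.coef(qrX, values), colnames(X))
  }
  fitted <- drop(X %*% cf)
  sse <- sum((values - fitted)^2)
  sst <- sum((values - mean(values))^2)
  structure(
    list(coefficients = cf, terms = terms, rank = qrX$rank,
         n_points = n, n_terms = p,
         R2 = if (sst > 0) 1 - sse / sst else NA_real_,
         residual_sse = sse, underdetermined = underdetermined,
         fitted = fitted),
    class = "param_surface"
  )
}

# Columns for declared polynomial terms over RS, T, IS; intercept first.
surface_model_matrix <- function(conditions, terms) {
  vars <- c("RS", "T", "IS")
  cols <- lapply(terms, function(tm) {
    tm0 <- gsub(" ", "", tm)
    if (grepl(":", tm0, fixed = TRUE)) {
      pair <- strsplit(tm0, ":", fixed = TRUE)[[1L]]
      if (length(pair) != 2L || !all(pair %in% vars)) {
        stop("unknown interaction term '", tm, "'", call. = FALSE)
      }
      conditions[[pair[1L]]] * conditions[[pair[2L]]]
    } else {
      sq <- sub("(\\^2|2)$", "", tm0)
      if (tm0 %in% vars) {
        conditions[[tm0]]
      } else if (sq %in% vars && tm0 != sq) {
        conditions[[sq]]^2
      } else {
        stop("unknown term '", tm, "'; use e.g. \"RS\", \"T^2\", \"RS:T\"",
             call. = FALSE)
      }
    }
  })
  X <- cbind(1, do.call(cbind, cols))
  colnames(X) <- c("(Intercept)", gsub(" ", "", terms))
  X
}

#' @export
print.param_surface <- function(x, ...) {
  cat(sprintf("Parameter meta-model: %d term(s) + intercept on %d points (rank %d%s)\n",
              x$n_terms - 1L, x$n_points, x$rank,
              if (x$underdetermined) ", UNDERDETERMINED" else ""))
  print(signif(x$coefficients, 6))
  if (!is.na(x$R2)) cat(sprintf("  R2 = %.4f\n", x$R2))
  invisible(x)
}

#' @export
predict.param_surface <- function(object, newdata, ...) {
  X <- surface_model_matrix(as.data.frame(newdata), object$terms)
  drop(X %*% object$coefficients)
}
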