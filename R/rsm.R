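#' Fit a full second-order response-surface model in coded variables
#'
#' Ordinary least squares of the response on the coded model matrix
#' `[1, Xi, Xi^2, Xi*Xj (i<j)]` -- for k factors, `1 + 2k + k(k-1)/2`
#' coefficients (15 for the four-factor case). The fit is done on the coded
#' scale so the intercept is the predicted response at the design center.
#'
#' @param table A [design_table()] with coded factor columns.
#' @param response_name Response column to fit.
#' @return Object of class `"quadratic_fit"`: `intercept`, named vectors
#'   `linear`, `quadratic` and `interaction` (names like `"X1:X2"`), `R2`,
#'   `residuals`, `fitted_values`, `n_params`, `n_runs`, the underlying
#'   `lm` object, the factor names and (if present) the factor specs for
#'   real-unit decoding.
#' @seealso [anova_quadratic()], [optimize_quadratic()]
#' @examples
#' bbd <- read_design_csv(fermkin_example("bbd_table4.csv"),
#'                        fermkin_example("bbd_table4.yaml"))
#' fit <- fit_quadratic(bbd, "EA")
#' fit$intercept   # predicted response at the center point
#' @export
fit_quadratic <- function(table, response_name) {
  stopifnot(inherits(table, "design_table"))
  y <- get_response(table, response_name)
  fac <- table$factor_columns
  k <- length(fac)
  n_params <- 1L + 2L * k + (k * (k - 1L)) %/% 2L
  if (nrow(table$coded) <= n_params) {
    stop("design has ", nrow(table$coded), " runs but the quadratic model has ",
         n_params, " parameters", call. = FALSE)
  }

  X <- quadratic_model_matrix(table$coded[, fac, drop = FALSE])
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("singular design: collinear model column(s) ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }

  dat <- as.data.frame(X[, -1L, drop = FALSE], check.names = FALSE)
  dat[[response_name]] <- y
  fml <- stats::as.formula(paste0(
    "`", response_name, "` ~ ",
    paste0("`", colnames(X)[-1L], "`", collapse = " + ")))
  lmfit <- stats::lm(fml, data = dat)

  beta <- stats::coef(lmfit)
  names(beta) <- colnames(X)   # strip backticks
  lin <- beta[fac]
  quad <- beta[paste0(fac, "^2")]
  names(quad) <- fac
  inter_names <- colnames(X)[grep(":", colnames(X), fixed = TRUE)]
  inter <- beta[inter_names]

  ss_res <- sum(stats::resid(lmfit)^2)
  ss_tot <- sum((y - mean(y))^2)

  structure(
    list(intercept = unname(beta[1L]), linear = lin, quadratic = quad,
         interaction = inter, coefficients = beta,
         R2 = 1 - ss_res / ss_tot,
         residuals = unname(stats::resid(lmfit)),
         fitted_values = unname(stats::fitted(lmfit)),
         n_params = n_params, n_runs = nrow(table$coded),
         response = response_name, factor_names = fac,
         factors = table$factors, lm = lmfit),
    class = "quadratic_fit"
  )
}

# Model matrix [1 | linear | squared | pairwise interactions] on coded columns.
quadratic_model_matrix <- function(coded) {
  coded <- as.data.frame(coded)
  fac <- names(coded)
  k <- length(fac)
  X <- cbind(`(Intercept)` = rep(1, nrow(coded)), as.matrix(coded))
  sq <- as.matrix(coded)^2
  colnames(sq) <- paste0(fac, "^2")
  X <- cbind(X, sq)
  if (k >= 2L) {
    for (i in seq_len(k - 1L)) {
      for (j in (i + 1L):k) {
        v <- coded[[i]] * coded[[j]]
        X <- cbind(X, v)
        colnames(X)[ncol(X)] <- paste0(fac[i], ":", fac[j])
      }
    }
  }
  X
}

#' @export
print.quadratic_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Second-order model of '%s' on %d coded factors (%d runs, %d params)\n",
              x$response, length(x$factor_names), x$n_runs, x$n_params))
  cat(sprintf("  R2 = %.4f\n", x$R2))
  print(round(x$coefficients, digits))
  invisible(x)
}

#' @export
predict.quadratic_fit <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)
  missing <- setdiff(object$factor_names, names(newdata))
  if (length(missing)) stop("newdata lacks coded column(s): ",
                            paste(missing, collapse = ", "), call. = FALSE)
  X <- quadratic_model_matrix(newdata[, object$factor_names, drop = FALSE])
  drop(X %*% object$coefficients[colnames(X)])
}

#' ANOVA with lack-of-fit decomposition for a response-surface fit
#'
#' Decomposes the total (corrected) sum of squares into per-term, model and
#' residual components, and splits the residual into lack-of-fit and pure
#' error using the replicate groups of the design (runs sharing an identical
#' coded row, typically the center points). Per-term sums of squares are
#' partial (drop-one) SS on the coded basis; on an orthogonal or
#' near-orthogonal design such as a Box-Behnken these coincide with
#' sequential SS for the linear and interaction terms.
#'
#' Identities guaranteed by construction: `SS(model) + SS(residual) =
#' SS(total)` and `SS(lack-of-fit) + SS(pure error) = SS(residual)`, with
#' degrees of freedom additive likewise.
#'
#' @param fit A [fit_quadratic()] result.
#' @param table The [design_table()] the fit came from.
#' @return Object of class `"anova_table"`: a data frame with columns
#'   `source`, `df`, `SS`, `MS`, `F`, `p`. Without replicated runs the
#'   lack-of-fit split is omitted with a warning.
#' @export
anova_quadratic <- function(fit, table) {
  stopifnot(inherits(fit, "quadratic_fit"), inherits(table, "design_table"))
  y <- get_response(table, fit$response)
  X <- quadratic_model_matrix(table$coded[, fit$factor_names, drop = FALSE])
  n <- length(y)

  ss_tot <- sum((y - mean(y))^2)
  ss_res <- sum(fit$residuals^2)
  ss_mod <- ss_tot - ss_res
  df_mod <- fit$n_params - 1L
  df_res <- n - fit$n_params
  ms_res <- ss_res / df_res

  term_names <- colnames(X)[-1L]
  rss_full <- ss_res
  term_ss <- vapply(term_names, function(nm) {
    Xr <- X[, setdiff(colnames(X), nm), drop = FALSE]
    sum(stats::lm.fit(Xr, y)$residuals^2) - rss_full
  }, numeric(1))

  term_kind <- ifelse(grepl(":", term_names, fixed = TRUE), "interaction",
                      ifelse(grepl("\\^2$", term_names), "quadratic", "factor"))
  rows <- data.frame(
    source = term_names, kind = term_kind, df = 1L, SS = term_ss,
    stringsAsFactors = FALSE)
  rows$MS <- rows$SS
  rows$F <- rows$MS / ms_res
  rows$p <- stats::pf(rows$F, 1L, df_res, lower.tail = FALSE)

  model_row <- data.frame(source = "Model", kind = "model", df = df_mod,
                          SS = ss_mod, MS = ss_mod / df_mod,
                          F = (ss_mod / df_mod) / ms_res,
                          p = stats::pf((ss_mod / df_mod) / ms_res,
                                        df_mod, df_res, lower.tail = FALSE))
  resid_row <- data.frame(source = "Residual", kind = "residual", df = df_res,
                          SS = ss_res, MS = ms_res, F = NA_real_, p = NA_real_)

  rep_groups <- Filter(function(g) length(g) > 1L, table$replicate_groups)
  if (length(rep_groups) == 0L) {
    warning("no replicated runs: lack-of-fit / pure-error split unavailable")
    lof_rows <- NULL
  } else {
    idx <- match(unlist(rep_groups), table$run_ids)
    grp <- rep(seq_along(rep_groups), lengths(rep_groups))
    ss_pe <- sum(unlist(tapply(y[idx], grp, function(v) (v - mean(v))^2)))
    df_pe <- sum(lengths(rep_groups) - 1L)
    ss_lof <- ss_res - ss_pe
    df_lof <- df_res - df_pe
    ms_pe <- ss_pe / df_pe
    f_lof <- (ss_lof / df_lof) / ms_pe
    lof_rows <- data.frame(
      source = c("Lack of fit", "Pure error"),
      kind = c("lack-of-fit", "pure-error"),
      df = c(df_lof, df_pe), SS = c(ss_lof, ss_pe),
      MS = c(ss_lof / df_lof, ms_pe),
      F = c(f_lof, NA_real_),
      p = c(stats::pf(f_lof, df_lof, df_pe, lower.tail = FALSE), NA_real_))
  }
  total_row <- data.frame(source = "Total", kind = "total", df = n - 1L,
                          SS = ss_tot, MS = NA_real_, F = NA_real_,
                          p = NA_real_)

  tab <- rbind(rows, model_row, resid_row, lof_rows, total_row)
  rownames(tab) <- NULL
  structure(tab, class = c("anova_table", "data.frame"),
            response = fit$response)
}

#' @export
print.anova_table <- function(x, ...) {
  cat("Response-surface ANOVA for '", attr(x, "response"), "'\n", sep = "")
  out <- as.data.frame(x)
  out$SS <- signif(out$SS, 7)
  out$MS <- signif(out$MS, 6)
  out$F <- signif(out$F, 5)
  out$p <- signif(out$p, 4)
  print(out, row.names = FALSE)
  invisible(x)
}

#' Optimize a fitted quadratic surface over a coded box
#'
#' Writes the fitted surface as `Y(x) = b0 + g'x + x'Hx` (with `H[i,i] =
#' beta_ii` and `H[i,j] = beta_ij / 2`) and solves the stationary condition
#' `g + 2Hx = 0`. If the Hessian has the right definiteness for the
#' requested sense and the stationary point lies inside the box, that
#' interior optimum is returned directly; otherwise a deterministic
#' multi-start box-constrained search (L-BFGS-B from a 3^k grid of starts
#' plus the clipped stationary point) is used and `on_boundary` is flagged
#' when the optimum sits on a box face.
#'
#' @param fit A [fit_quadratic()] result.
#' @param box Coded bounds: either a length-2 vector applied to every
#'   factor (default `c(-1, 1)`) or a 2-row matrix with one column per factor.
#' @param sense `"max"` (default) or `"min"`.
#' @return Object of class `"optimum_point"`: `coded_location`,
#'   `real_location` (decoded when factor specs are available),
#'   `predicted_response`, `on_boundary`, `hessian_eigenvalues`.
#' @export
optimize_quadratic <- function(fit, box = c(-1, 1), sense = c("max", "min")) {
  stopifnot(inherits(fit, "quadratic_fit"))
  sense <- match.arg(sense)
  k <- length(fit$factor_names)
  if (is.matrix(box)) {
    stopifnot(nrow(box) == 2L, ncol(box) == k)
    lower <- box[1L, ]; upper <- box[2L, ]
  } else {
    stopifnot(length(box) == 2L)
    lower <- rep(box[1L], k); upper <- rep(box[2L], k)
  }
  if (any(lower >= upper)) stop("box lower bounds must be below upper bounds",
                                call. = FALSE)

  g <- unname(fit$linear)
  H <- diag(unname(fit$quadratic), k)
  for (nm in names(fit$interaction)) {
    ij <- match(strsplit(nm, ":", fixed = TRUE)[[1L]], fit$factor_names)
    H[ij[1L], ij[2L]] <- H[ij[2L], ij[1L]] <- fit$interaction[[nm]] / 2
  }
  fval <- function(x) fit$intercept + sum(g * x) + drop(t(x) %*% H %*% x)
  grad <- function(x) g + 2 * drop(H %*% x)
  ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values

  definite <- if (sense == "max") all(ev < 0) else all(ev > 0)
  x_best <- NULL
  if (definite) {
    x_stat <- drop(solve(-2 * H, g))
    if (all(x_stat >= lower - 1e-10) && all(x_stat <= upper + 1e-10)) {
      x_best <- pmin(pmax(x_stat, lower), upper)
    }
  }

  if (is.null(x_best)) {
    sgn <- if (sense == "max") -1 else 1
    starts <- as.matrix(expand.grid(rep(list(c(-0.9, 0, 0.9)), k)))
    starts <- sweep(sweep(starts, 2L, (upper - lower) / 2, "*"),
                    2L, (upper + lower) / 2, "+")
    x_stat_cl <- tryCatch(pmin(pmax(drop(solve(-2 * H, g)), lower), upper),
                          error = function(e) NULL)
    if (!is.null(x_stat_cl)) starts <- rbind(starts, x_stat_cl)
    best <- NULL
    for (s in seq_len(nrow(starts))) {
      o <- stats::optim(starts[s, ], fn = function(x) sgn * fval(x),
                        gr = function(x) sgn * grad(x),
                        method = "L-BFGS-B", lower = lower, upper = upper)
      if (is.null(best) || o$value < best$value - 1e-12) best <- o
    }
    x_best <- best$par
  }

  on_boundary <- any(abs(x_best - lower) < 1e-6 | abs(x_best - upper) < 1e-6)
  coded <- stats::setNames(as.numeric(x_best), fit$factor_names)
  real <- if (!is.null(fit$factors)) {
    stats::setNames(vapply(fit$factor_names, function(nm)
      decode_levels(fit$factors[[nm]], coded[[nm]]), numeric(1)),
      fit$factor_names)
  } else NULL

  structure(
    list(coded_location = coded, real_location = real,
         predicted_response = fval(x_best), on_boundary = on_boundary,
         sense = sense, response = fit$response,
         hessian_eigenvalues = ev),
    class = "optimum_point"
  )
}

#' @export
print.optimum_point <- function(x, ...) {
  cat(sprintf("%s of '%s': predicted %.6g%s\n",
              if (x$sense == "max") "Maximum" else "Minimum",
              x$response, x$predicted_response,
              if (x$on_boundary) " (on box boundary)" else ""))
  cat("  coded: ", paste(sprintf("%s = %.4g", names(x$coded_location),
                                 x$coded_location), collapse = ", "), "\n")
  if (!is.null(x$real_location)) {
    cat("  real:  ", paste(sprintf("%s = %.4g", names(x$real_location),
                                   x$real_location), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Relative error of a model prediction against an observation
#'
#' `|observed - predicted| / |predicted|`, the verification statistic used
#' to compare a predicted optimum against a confirmation experiment.
#'
#' @param predicted Nonzero predicted value.
#' @param observed Observed value.
#' @return Nonnegative numeric vector.
#' @examples
#' relative_error(267.851, 266.84)   # ~0.0038
#' @export
relative_error <- function(predicted, observed) {
  stopifnot(is.numeric(predicted), is.numeric(observed))
  if (any(predicted == 0)) {
    stop("relative error undefined for predicted == 0", call. = FALSE)
  }
  abs(observed - predicted) / abs(predicted)
}
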