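#' Plackett-Burman effect estimation
#'
#' Estimates the main effect of every factor (real and dummy) of a two-level
#' screening design as the difference between the mean response at the high
#' (+1) and low (-1) coded levels. In a balanced orthogonal two-level design
#' the effect equals twice the ordinary-least-squares coefficient of the
#' main-effects model, so the coefficient is reported as `effect / 2`.
#'
#' The experimental error is estimated from the dummy columns -- factors that
#' carry no real variable, whose apparent effects reflect noise alone:
#' `SE_effect = sqrt(sum(effect_dummy^2) / n_dummies)`, with `n_dummies`
#' degrees of freedom. Each real factor's `t = effect / SE_effect` is
#' compared against `t_limit` (default: two-sided 5% Student-t quantile on
#' the error df). Alternatively `error = "residual"` uses the residual mean
#' square of the main-effects regression, an approach some DOE software
#' reports; the two agree when the dummies are the only unassigned columns.
#'
#' @param table A [design_table()] whose coded columns are all two-level
#'   +/-1 and balanced.
#' @param response_name Name of the response column to analyse.
#' @param error `"dummy"` (default) or `"residual"`.
#' @param t_limit Significance cutoff on |t|; default `qt(0.975, error_df)`.
#'   Set explicitly to reproduce thresholds quoted by other software.
#' @return Object of class `"pb_result"`: a data frame `effects` with one
#'   row per factor (`factor`, `coefficient`, `effect`, `t_value`,
#'   `p_value`, `significant`, `is_dummy`), plus `error_estimate` (the SE of
#'   an effect), `error_df`, `t_limit`, `error` and `response`.
#' @examples
#' pb <- read_design_csv(fermkin_example("pb_table2.csv"),
#'                       fermkin_example("pb_table2.yaml"))
#' pb_effects(pb, "EA")
#' @export
pb_effects <- function(table, response_name, error = c("dummy", "residual"),
                       t_limit = NULL) {
  stopifnot(inherits(table, "design_table"))
  error <- match.arg(error)
  y <- get_response(table, response_name)
  cols <- names(table$coded)

  eff <- vapply(cols, function(nm) {
    x <- table$coded[[nm]]
    lv <- sort(unique(x))
    if (length(lv) != 2L || !isTRUE(all.equal(lv, c(-1, 1))) ||
        sum(x > 0) != sum(x < 0)) {
      stop("column ", nm, " is not a balanced two-level +/-1 column",
           call. = FALSE)
    }
    mean(y[x > 0]) - mean(y[x < 0])
  }, numeric(1))
  coefs <- eff / 2
  is_dummy <- cols %in% table$dummy_columns

  if (error == "dummy") {
    n_dum <- sum(is_dummy)
    if (n_dum == 0L) {
      warning("no dummy columns: error estimate unavailable, t and p omitted")
      se <- NA_real_
      df <- NA_integer_
    } else {
      se <- sqrt(sum(eff[is_dummy]^2) / n_dum)
      df <- n_dum
    }
  } else {
    X <- as.matrix(table$coded[, !is_dummy, drop = FALSE])
    fit <- stats::lm.fit(cbind(1, X), y)
    df <- length(y) - fit$rank
    if (df < 1L) stop("no residual degrees of freedom for error = 'residual'",
                      call. = FALSE)
    ms <- sum(fit$residuals^2) / df
    # var(effect) = 4 * var(coef) = 4 * MS / n for a balanced +/-1 column
    se <- sqrt(4 * ms / length(y))
  }

  if (is.finite(se) && se > 0) {
    t_val <- eff / se
    p_val <- 2 * stats::pt(abs(t_val), df = df, lower.tail = FALSE)
  } else {
    t_val <- rep(NA_real_, length(eff))
    p_val <- rep(NA_real_, length(eff))
  }
  if (is.null(t_limit)) {
    t_limit <- if (is.finite(se)) stats::qt(0.975, df) else NA_real_
  }

  res <- data.frame(
    factor = cols, coefficient = coefs, effect = eff,
    t_value = t_val, p_value = p_val,
    significant = !is.na(t_val) & abs(t_val) > t_limit,
    is_dummy = is_dummy,
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(
    list(effects = res, error_estimate = se, error_df = df,
         t_limit = t_limit, error = error, response = response_name),
    class = "pb_result"
  )
}

#' @export
print.pb_result <- function(x, digits = 4, ...) {
  cat(sprintf("Plackett-Burman screening of '%s' (%s error, df = %s, |t| > %s)\n",
              x$response, x$error, format(x$error_df),
              format(round(x$t_limit, 5))))
  df <- x$effects
  df$coefficient <- round(df$coefficient, digits)
  df$effect <- round(df$effect, digits)
  df$t_value <- round(df$t_value, digits)
  df$p_value <- signif(df$p_value, 3)
  print(df, row.names = FALSE)
  invisible(x)
}
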