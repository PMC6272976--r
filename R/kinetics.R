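#' Logistic growth parameters
#'
#' Parameter container for the logistic growth model
#' `dX/dt = mu_m * X * (1 - X/Xm)` with inoculum `X0 = X(0)`: sigmoidal
#' growth from `X0` to the carrying capacity `Xm` at maximum specific rate
#' `mu_m` (1/h). Biomass is measured as optical density at 600 nm.
#'
#' @param X0 Initial biomass (> 0).
#' @param Xm Maximum biomass (> X0).
#' @param mu_m Maximum specific growth rate, 1/h (> 0).
#' @return Object of class `"logistic_params"`.
#' @export
logistic_params <- function(X0, Xm, mu_m) {
  stopifnot(is.numeric(X0), is.numeric(Xm), is.numeric(mu_m))
  if (!(X0 > 0)) stop("invalid params: X0 must be > 0", call. = FALSE)
  if (!(Xm > X0)) stop("invalid params: need 0 < X0 < Xm", call. = FALSE)
  if (!(mu_m > 0)) stop("invalid params: mu_m must be > 0", call. = FALSE)
  structure(list(X0 = X0, Xm = Xm, mu_m = mu_m), class = "logistic_params")
}

#' @export
print.logistic_params <- function(x, ...) {
  cat(sprintf("Logistic growth: X0 = %g, Xm = %g (OD600), mu_m = %g /h\n",
              x$X0, x$Xm, x$mu_m))
  invisible(x)
}

#' Closed-form logistic growth curve
#'
#' Evaluates `X(t) = X0*Xm*exp(mu_m*t) / (Xm - X0 + X0*exp(mu_m*t))`, the
#' solution of the logistic ODE, in the overflow-safe equivalent form
#' `Xm / (1 + ((Xm - X0)/X0) * exp(-mu_m*t))` so that large `mu_m * t`
#' saturates at `Xm` instead of overflowing.
#'
#' @param p A [logistic_params()] object.
#' @param t Time(s) in hours, >= 0.
#' @return Biomass at each `t`; `X(0) == X0` exactly.
#' @export
logistic_curve <- function(p, t) {
  stopifnot(inherits(p, "logistic_params"), is.numeric(t), all(t >= 0))
  p$Xm / (1 + ((p$Xm - p$X0) / p$X0) * exp(-p$mu_m * t))
}

#' Logistic growth rate at a given biomass
#'
#' `dX/dt = mu_m * X * (1 - X/Xm)`: zero at `X = 0` and `X = Xm`, maximal
#' (`mu_m * Xm / 4`) at the half-capacity point `X = Xm/2`.
#'
#' @param p A [logistic_params()] object.
#' @param X Biomass value(s), normally in `[0, Xm]`.
#' @return Growth rate dX/dt. Values of `X > Xm` give a negative rate and a
#'   warning: the decline phase is outside the model's scope.
#' @export
logistic_rate <- function(p, X) {
  stopifnot(inherits(p, "logistic_params"), is.numeric(X), all(X >= 0))
  if (any(X > p$Xm)) {
    warning("X > Xm: negative rate returned; decline phase is outside the logistic model")
  }
  p$mu_m * X * (1 - X / p$Xm)
}

#' Fit the logistic growth model to a biomass time series
#'
#' Nonlinear least squares (Levenberg-Marquardt) of the closed-form logistic
#' curve to observed biomass. Starting values follow the standard
#' linearization: `Xm` from the observed maximum, `X0` from the first
#' positive observation, and `mu_m` from the slope of
#' `log(y / (Xm0 - y))` against `t`.
#'
#' @param t Time in hours (strictly increasing) or a data frame with
#'   columns `t` and `y`.
#' @param y Biomass observations (OD600); omit when `t` is a data frame.
#' @param cutoff Optional time cutoff (h); observations after it (e.g. the
#'   decline phase, which the logistic model does not represent) are dropped
#'   before fitting.
#' @return Object of class `"kinetic_fit"`: `params` ([logistic_params()]),
#'   `R2`, `residual_sse`, `converged`, `n_iter`, `fitted`, `residuals`.
#' @export
fit_logistic <- function(t, y = NULL, cutoff = NULL) {
  ser <- as_time_series(t, y)
  if (!is.null(cutoff)) ser <- ser[ser$t <= cutoff, , drop = FALSE]
  t <- ser$t; y <- ser$y
  if (length(t) < 4L) stop("need at least 4 points to fit", call. = FALSE)

  Xm0 <- max(y)
  X00 <- y[y > 0][1L]
  ok <- y > 0 & y < Xm0
  mu0 <- if (sum(ok) >= 2L) {
    z <- log(y[ok] / (Xm0 - y[ok]))
    max(stats::coef(stats::lm(z ~ t[ok]))[2L], 1e-3)
  } else 0.1

  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ Xm / (1 + ((Xm - X0) / X0) * exp(-mu_m * t)),
      start = list(X0 = X00, Xm = Xm0 * 1.02, mu_m = mu0),
      lower = c(X0 = 1e-10, Xm = 1e-10, mu_m = 1e-8),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)

  if (inherits(fit, "error")) {
    return(structure(list(params = NULL, R2 = NA_real_,
                          residual_sse = NA_real_, converged = FALSE,
                          n_iter = NA_integer_,
                          message = conditionMessage(fit)),
                     class = "kinetic_fit"))
  }
  cf <- stats::coef(fit)
  sse <- sum(stats::resid(fit)^2)
  structure(
    list(params = logistic_params(cf[["X0"]], cf[["Xm"]], cf[["mu_m"]]),
         R2 = 1 - sse / sum((y - mean(y))^2),
         residual_sse = sse, converged = fit$convInfo$isConv,
         n_iter = fit$convInfo$finIter,
         fitted = as.numeric(stats::fitted(fit)),
         residuals = as.numeric(stats::resid(fit)), t = t, y = y),
    class = "kinetic_fit"
  )
}

#' Luedeking-Piret production parameters
#'
#' `alpha` is the growth-associated yield (product per unit biomass) and
#' `beta` the non-growth-associated specific production rate (product per
#' unit biomass per hour) of `dP/dt = alpha * dX/dt + beta * X`. The Gaden
#' fermentation type follows from which coefficients are nonzero; see
#' [classify_gaden()].
#'
#' @param alpha Growth-associated coefficient (U/mL per OD600).
#' @param beta Non-growth-associated coefficient (U/mL per OD600 per h).
#' @param tol Zero-tolerance used for the Gaden classification.
#' @return Object of class `"lp_params"` with a `gaden_type` field.
#' @export
lp_params <- function(alpha, beta, tol = 0.005) {
  stopifnot(is.numeric(alpha), is.numeric(beta))
  structure(list(alpha = alpha, beta = beta,
                 gaden_type = classify_gaden(alpha, beta, tol = tol)),
            class = "lp_params")
}

#' @export
print.lp_params <- function(x, ...) {
  cat(sprintf("Luedeking-Piret: alpha = %g, beta = %g (Gaden type %s)\n",
              x$alpha, x$beta,
              if (is.na(x$gaden_type)) "undefined" else x$gaden_type))
  invisible(x)
}

#' Gaden classification of a fermentation
#'
#' Type I (growth-associated): `alpha != 0, beta == 0`; type II (partially
#' growth-associated): both nonzero; type III (non-growth-associated):
#' `alpha == 0, beta != 0`. Zero is tested as `|x| <= tol` in each
#' parameter's native units; the default 0.005 treats a coefficient
#' reported as 0.000 to three decimals as zero.
#'
#' @param alpha,beta Luedeking-Piret coefficients (an [lp_params()] object
#'   may be passed as `alpha`).
#' @param tol Nonnegative zero-tolerance.
#' @return `"I"`, `"II"` or `"III"`; `NA` with a warning when both
#'   coefficients are below tolerance (no production).
#' @examples
#' classify_gaden(458.271, 0.000)   # "I"
#' classify_gaden(95.433, 42.558)   # "II"
#' @export
classify_gaden <- function(alpha, beta = NULL, tol = 0.005) {
  if (inherits(alpha, "lp_params")) {
    beta <- alpha$beta; alpha <- alpha$alpha
  }
  stopifnot(is.numeric(alpha), is.numeric(beta), tol >= 0)
  a <- abs(alpha) > tol
  b <- abs(beta) > tol
  if (!a && !b) {
    warning("both alpha and beta below tolerance: no production, type undefined")
    return(NA_character_)
  }
  if (a && !b) "I" else if (a && b) "II" else "III"
}

#' Integrated Luedeking-Piret product curve
#'
#' Closed form of product concentration along a logistic growth trajectory:
#' `P(t) = alpha * X(t) + (beta * Xm / mu_m) * log((Xm - X0 +
#' X0*exp(mu_m*t)) / Xm) + P0`. The logarithm is evaluated in log-space so
#' large `mu_m * t` cannot overflow. With `P0 = 0` (default) the curve
#' starts at `P(0) = alpha * X0`.
#'
#' @param p A [logistic_params()] object (growth).
#' @param q An [lp_params()] object (production).
#' @param t Time(s) in hours, >= 0.
#' @param P0 Optional additive baseline product level, default 0.
#' @return Product concentration (U/mL) at each `t`.
#' @export
lp_product <- function(p, q, t, P0 = 0) {
  stopifnot(inherits(p, "logistic_params"), inherits(q, "lp_params"),
            is.numeric(t), all(t >= 0))
  # log((Xm - X0 + X0 e^{mu t}) / Xm) = logsumexp(log((Xm-X0)/Xm),
  #                                               mu t + log(X0/Xm))
  la <- log((p$Xm - p$X0) / p$Xm)
  lb <- p$mu_m * t + log(p$X0 / p$Xm)
  m <- pmax(la, lb)
  log_term <- m + log(exp(la - m) + exp(lb - m))
  q$alpha * logistic_curve(p, t) + (q$beta * p$Xm / p$mu_m) * log_term + P0
}

#' Fit the Luedeking-Piret model given fitted growth parameters
#'
#' Two-stage estimation: with the logistic growth parameters fixed, the
#' integrated product curve is linear in `(alpha, beta)`, so the
#' coefficients are obtained by linear least squares on the regressors
#' `X(t)` and `(Xm/mu_m) * log((Xm - X0 + X0*exp(mu_m*t))/Xm)`. This is
#' deterministic and avoids the local minima of a joint 5-parameter
#' nonlinear fit.
#'
#' @param growth A [logistic_params()] or a converged [fit_logistic()]
#'   result.
#' @param t Time in hours, or a data frame with columns `t` and `y`.
#' @param P Product observations (U/mL); omit when `t` is a data frame.
#' @param estimate_P0 If `TRUE`, also estimate an additive baseline
#'   (intercept); default `FALSE`, matching a curve through
#'   `P(0) = alpha * X0`.
#' @param tol Zero-tolerance passed to [classify_gaden()].
#' @param cutoff Optional time cutoff (h) excluding the decline phase.
#' @return Object of class `"kinetic_fit"` whose `params` is an
#'   [lp_params()]; includes `R2`, `residual_sse`, `P0`.
#' @export
fit_lp <- function(growth, t, P = NULL, estimate_P0 = FALSE, tol = 0.005,
                   cutoff = NULL) {
  if (inherits(growth, "kinetic_fit")) {
    if (!isTRUE(growth$converged)) stop("growth fit did not converge",
                                        call. = FALSE)
    growth <- growth$params
  }
  stopifnot(inherits(growth, "logistic_params"))
  ser <- as_time_series(t, P)
  if (!is.null(cutoff)) ser <- ser[ser$t <= cutoff, , drop = FALSE]
  t <- ser$t; P <- ser$y
  if (length(t) < 4L) stop("need at least 4 points to fit", call. = FALSE)

  x1 <- logistic_curve(growth, t)
  la <- log((growth$Xm - growth$X0) / growth$Xm)
  lb <- growth$mu_m * t + log(growth$X0 / growth$Xm)
  m <- pmax(la, lb)
  x2 <- (growth$Xm / growth$mu_m) * (m + log(exp(la - m) + exp(lb - m)))

  X <- if (estimate_P0) cbind(1, x1, x2) else cbind(x1, x2)
  qrX <- qr(X)
  if (qrX$rank < ncol(X) || diff(range(x1)) < 1e-4 * mean(abs(x1))) {
    stop("unidentifiable parameters: biomass trajectory is flat or regressors collinear",
         call. = FALSE)
  }
  cf <- qr.coef(qrX, P)
  fitted <- drop(X %*% cf)
  sse <- sum((P - fitted)^2)
  k <- if (estimate_P0) 1L else 0L
  params <- lp_params(alpha = unname(cf[k + 1L]), beta = unname(cf[k + 2L]),
                      tol = tol)
  structure(
    list(params = params, P0 = if (estimate_P0) unname(cf[1L]) else 0,
         R2 = 1 - sse / sum((P - mean(P))^2),
         residual_sse = sse, converged = TRUE, n_iter = 1L,
         fitted = fitted, residuals = P - fitted, t = t, y = P),
    class = "kinetic_fit"
  )
}

#' @export
print.kinetic_fit <- function(x, ...) {
  if (!isTRUE(x$converged)) {
    cat("Kinetic fit: DID NOT CONVERGE",
        if (!is.null(x$message)) paste0(" (", x$message, ")"), "\n", sep = "")
    return(invisible(x))
  }
  print(x$params)
  cat(sprintf("  R2 = %.4f, SSE = %.4g, n = %d\n", x$R2, x$residual_sse,
              length(x$y)))
  invisible(x)
}

# Accept either (t, y) vectors or a two-column data frame.
as_time_series <- function(t, y) {
  if (is.data.frame(t)) {
    stopifnot(all(c("t", "y") %in% names(t)))
    ser <- data.frame(t = t$t, y = t$y)
  } else {
    stopifnot(is.numeric(t), is.numeric(y), length(t) == length(y))
    ser <- data.frame(t = t, y = y)
  }
  if (any(diff(ser$t) <= 0)) stop("time must be strictly increasing",
                                  call. = FALSE)
  ser
}
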