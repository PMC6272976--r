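#' Simulate a noisy batch fermentation
#'
#' Generates biomass and product time series with the structure the kinetic
#' models assume: logistic growth plus integrated Luedeking-Piret
#' production, each corrupted by additive homoscedastic Gaussian noise. The
#' default sampling grid is every 4 h over a 72 h batch, matching typical
#' shake-flask sampling. Default noise levels (`sd` 0.01 OD600 for biomass,
#' 3 U/mL for product) are on the scale of replicate spreads seen in such
#' assays.
#'
#' @param growth A [logistic_params()] truth.
#' @param production An [lp_params()] truth.
#' @param times Sampling times in hours, default `seq(0, 72, by = 4)`.
#' @param noise_sd Length-2 numeric `c(biomass, product)` Gaussian sd (>= 0).
#' @param seed Integer seed; mandatory whenever any `noise_sd > 0` so every
#'   stochastic draw is reproducible.
#' @param P0 Baseline product level passed to [lp_product()].
#' @return List with data frames `biomass` and `product`, each with columns
#'   `t` (h) and `y`.
#' @examples
#' truth_g <- logistic_params(X0 = 0.016, Xm = 0.655, mu_m = 0.214)
#' truth_p <- lp_params(alpha = 330.606, beta = 16.432)
#' sim <- simulate_fermentation(truth_g, truth_p, seed = 1)
#' @export
simulate_fermentation <- function(growth, production,
                                  times = seq(0, 72, by = 4),
                                  noise_sd = c(biomass = 0.01, product = 3),
                                  seed = NULL, P0 = 0) {
  stopifnot(inherits(growth, "logistic_params"),
            inherits(production, "lp_params"),
            is.numeric(times), length(noise_sd) == 2L)
  if (any(noise_sd < 0)) stop("invalid spec: noise_sd must be >= 0",
                              call. = FALSE)
  if (any(noise_sd > 0) && is.null(seed)) {
    stop("invalid spec: a seed is required for stochastic simulation",
         call. = FALSE)
  }
  x <- logistic_curve(growth, times)
  p <- lp_product(growth, production, times, P0 = P0)
  if (any(noise_sd > 0)) {
    with_seed(seed, {
      x <- x + stats::rnorm(length(times), 0, noise_sd[[1L]])
      p <- p + stats::rnorm(length(times), 0, noise_sd[[2L]])
    })
  }
  list(biomass = data.frame(t = times, y = x),
       product = data.frame(t = times, y = p))
}

#' Simulate responses on a designed experiment
#'
#' Evaluates a declared quadratic surface at every run of a coded design
#' and adds Gaussian noise, producing a [design_table()] ready for
#' [fit_quadratic()]. Replicated runs (identical coded rows) share the same
#' truth mean and differ only through noise, so the pure-error structure of
#' a real replicated design is reproduced.
#'
#' @param design Coded design: a data frame of coded columns or a
#'   [design_table()] whose coded factor columns are used.
#' @param coefficients Named numeric vector of surface coefficients in
#'   [fit_quadratic()] naming: `"(Intercept)"`, factor names, `"X1^2"`
#'   style squared terms, `"X1:X2"` style interactions. Every name must
#'   correspond to a column the design can form.
#' @param noise_sd Gaussian response sd (>= 0). The default 5.9 is on the
#'   scale of the center-point replicate spread of the packaged
#'   enzyme-activity table.
#' @param seed Integer seed; mandatory when `noise_sd > 0`.
#' @param response_name Name for the generated response column.
#' @param factors Optional factor specs passed through to the result.
#' @return A [design_table()] with the simulated response.
#' @export
simulate_doe <- function(design, coefficients, noise_sd = 5.9, seed = NULL,
                         response_name = "Y", factors = NULL) {
  if (inherits(design, "design_table")) {
    if (is.null(factors)) factors <- design$factors
    design <- design$coded[, design$factor_columns, drop = FALSE]
  }
  design <- as.data.frame(design)
  stopifnot(is.numeric(coefficients), !is.null(names(coefficients)))
  if (length(noise_sd) != 1L || noise_sd < 0) {
    stop("invalid spec: noise_sd must be a single value >= 0", call. = FALSE)
  }
  if (noise_sd > 0 && is.null(seed)) {
    stop("invalid spec: a seed is required for stochastic simulation",
         call. = FALSE)
  }
  X <- quadratic_model_matrix(design)
  unknown <- setdiff(names(coefficients), colnames(X))
  if (length(unknown)) {
    stop("invalid spec: coefficient name(s) not formable from the design: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  mu <- drop(X[, names(coefficients), drop = FALSE] %*% coefficients)
  y <- if (noise_sd > 0) {
    with_seed(seed, mu + stats::rnorm(length(mu), 0, noise_sd))
  } else mu
  responses <- stats::setNames(data.frame(y), response_name)
  design_table(design, responses, factors = factors)
}

# Evaluate `expr` under a fixed seed without disturbing the caller's RNG.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
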