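test_that("logistic closed form honours its boundary behaviour", {
  p <- logistic_params(X0 = 0.016, Xm = 0.655, mu_m = 0.214)
  expect_identical(logistic_curve(p, 0), p$X0)
  expect_equal(logistic_curve(p, 1e4), p$Xm, tolerance = 1e-12)
  # no overflow at extreme mu*t
  expect_true(is.finite(logistic_curve(logistic_params(0.01, 1, 5), 1e5)))

  # strictly increasing and bounded in (X0, Xm) for several parameter sets
  t <- seq(0, 72, by = 0.5)
  for (p in list(p, logistic_params(0.007, 0.504, 0.255),
                 logistic_params(0.1, 0.2, 0.05))) {
    x <- logistic_curve(p, t)
    expect_true(all(diff(x) > 0))
    expect_true(all(x >= p$X0 & x <= p$Xm))
  }
  expect_error(logistic_params(0.7, 0.655, 0.2), "X0 < Xm")
  expect_error(logistic_params(0, 0.655, 0.2), "X0")
})

test_that("logistic rate: zero at capacity, maximal at half capacity", {
  p <- logistic_params(0.02, 0.5, 0.2)
  expect_equal(logistic_rate(p, p$Xm), 0)
  expect_equal(logistic_rate(p, p$Xm / 2), p$mu_m * p$Xm / 4)
  X <- seq(0.01, p$Xm, by = 0.005)
  expect_equal(which.max(logistic_rate(p, X)),
               which.min(abs(X - p$Xm / 2)))
  expect_warning(r <- logistic_rate(p, 0.6), "decline")
  expect_lt(r, 0)
})

test_that("closed-form curve satisfies the growth ODE (finite-difference oracle)", {
  p <- logistic_params(0.016, 0.655, 0.214)
  t <- seq(0.5, 60, by = 0.5)
  h <- 1e-5
  num <- (logistic_curve(p, t + h) - logistic_curve(p, t - h)) / (2 * h)
  ana <- logistic_rate(p, logistic_curve(p, t))
  expect_equal(num, ana, tolerance = 1e-6)
})

test_that("integrated product curve equals quadrature of the rate equation", {
  skip_if_not_installed("deSolve")
  cases <- list(
    list(g = logistic_params(0.016, 0.655, 0.214),
         q = lp_params(330.606, 16.432)),
    list(g = logistic_params(0.009, 0.329, 0.198),
         q = lp_params(458.271, 0)),
    list(g = logistic_params(0.02, 0.5, 0.3), q = lp_params(0, 5)))
  for (cs in cases) {
    g <- cs$g; q <- cs$q
    rhs <- function(t, y, parms) {
      dX <- g$mu_m * y[1] * (1 - y[1] / g$Xm)
      list(c(dX, q$alpha * dX + q$beta * y[1]))
    }
    t <- seq(0, 72, by = 2)
    sol <- deSolve::ode(y = c(X = g$X0, P = q$alpha * g$X0), times = t,
                        func = rhs, parms = NULL, rtol = 1e-10, atol = 1e-12)
    expect_equal(lp_product(g, q, t), unname(sol[, "P"]), tolerance = 1e-6)
  }
})

test_that("product curve limits: null production and growth-associated limit", {
  g <- logistic_params(0.016, 0.655, 0.214)
  t <- seq(0, 72, by = 4)
  none <- suppressWarnings(lp_params(0, 0))
  expect_equal(lp_product(g, none, t), rep(0, length(t)))
  a_only <- lp_params(300, 0)
  expect_equal(lp_product(g, a_only, t), 300 * logistic_curve(g, t))
  # P0 shifts the whole curve additively
  expect_equal(lp_product(g, a_only, t, P0 = 7),
               300 * logistic_curve(g, t) + 7)
})

test_that("noiseless growth series is recovered exactly", {
  truth <- logistic_params(0.02, 0.5, 0.2)
  t <- seq(0, 72, by = 4)
  fit <- fit_logistic(t, logistic_curve(truth, t))
  expect_true(fit$converged)
  expect_equal(fit$params$X0, truth$X0, tolerance = 1e-6)
  expect_equal(fit$params$Xm, truth$Xm, tolerance = 1e-6)
  expect_equal(fit$params$mu_m, truth$mu_m, tolerance = 1e-6)
  expect_equal(fit$R2, 1, tolerance = 1e-10)
})

test_that("simulate-then-fit recovers growth parameters within 10% under noise", {
  truth <- logistic_params(0.02, 0.5, 0.2)
  sim <- simulate_fermentation(truth, lp_params(300, 20),
                               times = seq(0, 72, length.out = 19),
                               noise_sd = c(0.01, 2), seed = 11)
  fit <- fit_logistic(sim$biomass)
  expect_true(fit$converged)
  expect_lt(abs(fit$params$Xm - truth$Xm) / truth$Xm, 0.1)
  expect_lt(abs(fit$params$mu_m - truth$mu_m) / truth$mu_m, 0.1)
})

test_that("recovery bias shrinks as noise shrinks", {
  truth <- logistic_params(0.02, 0.5, 0.2)
  t <- seq(0, 72, by = 4)
  err <- vapply(c(0.02, 0.005, 0.0005), function(sd) {
    sim <- simulate_fermentation(truth, lp_params(300, 20), times = t,
                                 noise_sd = c(sd, 1), seed = 303)
    f <- fit_logistic(sim$biomass)
    abs(f$params$mu_m - truth$mu_m) / truth$mu_m
  }, numeric(1))
  expect_true(all(diff(err) < 0))
  expect_lt(err[3], 0.01)
})

test_that("two-stage product fit recovers alpha and beta", {
  g <- logistic_params(0.02, 0.5, 0.2)
  t <- seq(0, 72, by = 4)

  # exact type-I series: beta estimated as numerically zero
  P1 <- 300 * logistic_curve(g, t)
  f1 <- fit_lp(g, t, P1)
  expect_equal(f1$params$alpha, 300, tolerance = 1e-8)
  expect_equal(f1$params$beta, 0, tolerance = 1e-8)
  expect_identical(f1$params$gaden_type, "I")

  # noisy round trip within 10%
  truth_q <- lp_params(300, 20)
  sim <- simulate_fermentation(g, truth_q, times = t,
                               noise_sd = c(0.01, 2), seed = 19)
  fg <- fit_logistic(sim$biomass)
  fp <- fit_lp(fg, sim$product)
  expect_lt(abs(fp$params$alpha - 300) / 300, 0.1)
  expect_lt(abs(fp$params$beta - 20) / 20, 0.1)
  expect_identical(fp$params$gaden_type, "II")
})

test_that("constraining beta to zero never beats the unconstrained fit", {
  g <- logistic_params(0.02, 0.5, 0.2)
  t <- seq(0, 72, by = 4)
  set.seed(5)
  for (rep in 1:5) {
    P <- lp_product(g, lp_params(runif(1, 50, 400), runif(1, 0, 40)), t) +
      rnorm(length(t), 0, 3)
    full <- fit_lp(g, t, P)
    x1 <- logistic_curve(g, t)
    sse_b0 <- sum(lm(P ~ 0 + x1)$residuals^2)  # alpha-only oracle
    expect_lte(full$residual_sse, sse_b0 + 1e-9)
  }
})

test_that("flat biomass makes the product fit unidentifiable", {
  g <- logistic_params(0.49999, 0.5, 0.2)  # essentially no growth
  t <- seq(0, 72, by = 4)
  expect_error(fit_lp(g, t, rep(3, length(t))), "nidentifiable|collinear")
})

test_that("Gaden classification follows the zero-tolerance rule", {
  expect_identical(classify_gaden(458.271, 0.000), "I")
  expect_identical(classify_gaden(95.433, 42.558), "II")
  expect_identical(classify_gaden(0, 5), "III")
  expect_identical(classify_gaden(0.004, 5, tol = 0.005), "III")
  expect_identical(classify_gaden(lp_params(106.824, 46.014)), "II")
  expect_warning(res <- classify_gaden(0.001, 0.002), "no production")
  expect_true(is.na(res))
})

test_that("every packaged condition's (alpha, beta) classifies as reported", {
  t6 <- table6_fixture()
  types <- mapply(classify_gaden, t6$alpha, t6$beta)
  expect_identical(unname(types[t6$condition == "T" & t6$level == 10]), "I")
  expect_true(all(types[!(t6$condition == "T" & t6$level == 10)] == "II"))
})

test_that("parameter meta-models recover a declared sparse polynomial exactly", {
  grid <- expand.grid(RS = c(80, 130, 200), T = c(10, 20, 30), IS = c(2, 3, 4))
  truth <- c(`(Intercept)` = 0.1, RS = 0.002, `T^2` = -0.0005, `RS:IS` = 1e-4)
  vals <- truth[1] + truth[2] * grid$RS + truth[3] * grid$T^2 +
    truth[4] * grid$RS * grid$IS
  fit <- fit_param_surface(grid, vals, terms = c("RS", "T^2", "RS:IS"))
  expect_false(fit$underdetermined)
  expect_equal(fit$coefficients, truth, tolerance = 1e-10)
  expect_equal(fit$R2, 1, tolerance = 1e-12)
  expect_equal(predict(fit, grid), unname(vals), tolerance = 1e-10)

  # constant values -> intercept-only structure
  cfit <- fit_param_surface(grid, rep(0.2, nrow(grid)), terms = c("RS", "T"))
  expect_equal(unname(cfit$coefficients),c(0.2, 0, 0), tolerance = 1e-12)
})

test_that("one-factor-at-a-time condition grids cannot support a full quadratic", {
  t6 <- table6_fixture()
  base <- list(RS = 130, T = 30, IS = 3)
  conds <- data.frame(
    RS = ifelse(t6$condition == "RS", t6$level, base$RS),
    T = ifelse(t6$condition == "T", t6$level, base$T),
    IS = ifelse(t6$condition == "IS", t6$level, base$IS))
  full <- c("RS", "T", "IS", "RS:T", "RS:IS", "T:IS",
            "RS^2", "T^2", "IS^2")
  expect_error(fit_param_surface(conds, t6$mu_m, terms = full),
               "underdetermined")
  expect_warning(fit <- fit_param_surface(conds, t6$mu_m, terms = full,
                                          allow_underdetermined = TRUE),
                 "rank-deficient")
  expect_lt(fit$rank, fit$n_terms)
})
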