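test_that("quadratic refit of the packaged BBD table matches the published model", {
  bbd <- bbd_fixture()
  ea <- fit_quadratic(bbd, "EA")
  expect_equal(ea$intercept, 266.19, tolerance = 0.005)
  expect_equal(unname(ea$linear["X1"]), -11.23, tolerance = 0.005)
  expect_equal(unname(ea$interaction["X3:X4"]), -44.73, tolerance = 0.005)
  expect_equal(ea$R2, 0.9689, tolerance = 0.001)
  expect_equal(ea$n_params, 15L)
  expect_equal(ea$n_runs, 29L)

  bm <- fit_quadratic(bbd, "BM")
  # published values are printed to 2 and 3 decimals respectively
  expect_equal(bm$intercept, 0.52, tolerance = 0.005 / 0.52)
  expect_equal(unname(bm$linear["X2"]), -0.018, tolerance = 0.0005 / 0.018)

  # predictions at the coded origin equal the intercept
  origin <- as.data.frame(as.list(setNames(rep(0, 4), ea$factor_names)))
  expect_equal(unname(predict(ea, origin)), ea$intercept)

  # residuals orthogonal to every model-matrix column
  X <- cbind(1, as.matrix(bbd$coded), as.matrix(bbd$coded)^2)
  expect_lt(max(abs(crossprod(X, ea$residuals))), 1e-8)
})

test_that("a noiseless quadratic response is recovered to machine precision", {
  truth <- ea_surface_truth()
  des <- bbd_design(4)
  tab <- simulate_doe(des, truth, noise_sd = 0)
  fit <- fit_quadratic(tab, "Y")
  expect_equal(fit$coefficients[names(truth)], truth, tolerance = 1e-12)
  expect_equal(fit$R2, 1, tolerance = 1e-12)
  expect_lt(sum(fit$residuals^2), 1e-18)

  # also on a 3-factor design with a different sparse truth
  truth3 <- c("(Intercept)" = 5, A = 2, "B^2" = -3, "A:C" = 0.5,
              B = 0, C = 0, "A^2" = 0, "C^2" = 0, "A:B" = 0, "B:C" = 0)
  tab3 <- simulate_doe(bbd_design(3, names = c("A", "B", "C")), truth3,
                       noise_sd = 0)
  fit3 <- fit_quadratic(tab3, "Y")
  expect_equal(fit3$coefficients[names(truth3)], truth3, tolerance = 1e-12)
})

test_that("rank-deficient designs raise an error naming collinear columns", {
  des <- bbd_design(4)
  des$X4 <- des$X3  # duplicate column -> collinear interactions/quadratics
  tab <- design_table(des, data.frame(Y = rnorm(nrow(des))))
  expect_error(fit_quadratic(tab, "Y"), "singular design")
})

test_that("ANOVA decomposition sums exactly and matches the fit's R2", {
  bbd <- bbd_fixture()
  for (resp in c("EA", "BM")) {
    fit <- fit_quadratic(bbd, resp)
    a <- anova_quadratic(fit, bbd)
    ss <- setNames(a$SS, a$source)
    df <- setNames(a$df, a$source)

    expect_equal(ss[["Model"]] + ss[["Residual"]], ss[["Total"]])
    expect_equal(ss[["Lack of fit"]] + ss[["Pure error"]], ss[["Residual"]])
    expect_equal(df[["Model"]] + df[["Residual"]], df[["Total"]])
    expect_equal(df[["Lack of fit"]] + df[["Pure error"]], df[["Residual"]])
    expect_equal(fit$R2, 1 - ss[["Residual"]] / ss[["Total"]])
  }
})

test_that("ANOVA reproduces the published sums of squares for enzyme activity", {
  bbd <- bbd_fixture()
  a <- anova_quadratic(fit_quadratic(bbd, "EA"), bbd)
  ss <- setNames(a$SS, a$source)
  expect_equal(ss[["Model"]], 49077.94, tolerance = 0.005)
  # pure error oracle: within-group squared deviations of the five
  # center replicates 270.32, 271.85, 269.09, 260.33, 259.36
  ctr <- c(270.32, 271.85, 269.09, 260.33, 259.36)
  expect_equal(ss[["Pure error"]], sum((ctr - mean(ctr))^2))
  expect_equal(ss[["Pure error"]], 138.43, tolerance = 0.005)
  expect_equal(setNames(a$df, a$source)[["Pure error"]], 4L)
})

test_that("noiseless responses give zero residual SS; no replicates drops the split", {
  des <- bbd_design(4, n_center = 1)  # no replicated rows
  tab <- simulate_doe(des, ea_surface_truth(), noise_sd = 0)
  fit <- fit_quadratic(tab, "Y")
  expect_warning(a <- anova_quadratic(fit, tab), "no replicated runs")
  expect_false(any(a$source %in% c("Lack of fit", "Pure error")))
  expect_equal(a$SS[a$source == "Residual"], 0, tolerance = 1e-18)
})

test_that("interior optimum of a concave surface matches the closed form", {
  # symmetric bowl: maximum at the origin with value b0
  bowl <- c("(Intercept)" = 10, X1 = 0, X2 = 0, X3 = 0, X4 = 0,
            "X1^2" = -1, "X2^2" = -1, "X3^2" = -1, "X4^2" = -1,
            "X1:X2" = 0, "X1:X3" = 0, "X1:X4" = 0, "X2:X3" = 0,
            "X2:X4" = 0, "X3:X4" = 0)
  fit <- fit_quadratic(simulate_doe(bbd_design(4), bowl, noise_sd = 0), "Y")
  opt <- optimize_quadratic(fit)
  expect_equal(unname(opt$coded_location), rep(0, 4), tolerance = 1e-8)
  expect_equal(opt$predicted_response, 10)
  expect_false(opt$on_boundary)

  # random negative-definite surfaces: optimum equals -(2H)^{-1} g (oracle)
  set.seed(7)
  for (rep in 1:5) {
    A <- matrix(rnorm(16), 4)
    H <- -(crossprod(A) + diag(4) * 0.5)
    g <- rnorm(4, sd = 0.3)
    cf <- c("(Intercept)" = 1, setNames(g, paste0("X", 1:4)),
            setNames(diag(H), paste0("X", 1:4, "^2")),
            setNames(2 * H[upper.tri(H)][c(1, 2, 4, 3, 5, 6)] * NA, NULL))
    # build interaction coefficients explicitly (H[i,j] -> beta_ij = 2 H[i,j])
    inter <- c("X1:X2" = 2 * H[1, 2], "X1:X3" = 2 * H[1, 3],
               "X1:X4" = 2 * H[1, 4], "X2:X3" = 2 * H[2, 3],
               "X2:X4" = 2 * H[2, 4], "X3:X4" = 2 * H[3, 4])
    cf <- c(cf[!is.na(cf)], inter)
    fit <- fit_quadratic(simulate_doe(bbd_design(4), cf, noise_sd = 0), "Y")
    x_star <- solve(-2 * H, g)
    opt <- optimize_quadratic(fit, box = c(-5, 5))
    expect_equal(unname(opt$coded_location), as.numeric(x_star),
                 tolerance = 1e-6)
  }
})

test_that("saddle surfaces fall back to a boundary maximum", {
  saddle <- c("(Intercept)" = 0, X1 = 0, X2 = 0, X3 = 0, X4 = 0,
              "X1^2" = 1, "X2^2" = -1, "X3^2" = -1, "X4^2" = -1,
              "X1:X2" = 0, "X1:X3" = 0, "X1:X4" = 0, "X2:X3" = 0,
              "X2:X4" = 0, "X3:X4" = 0)
  fit <- fit_quadratic(simulate_doe(bbd_design(4), saddle, noise_sd = 0), "Y")
  opt <- optimize_quadratic(fit)
  expect_true(opt$on_boundary)
  expect_equal(opt$predicted_response, 1, tolerance = 1e-6)  # X1 = +/-1
})

test_that("optimum of the packaged EA surface dominates every design run", {
  bbd <- bbd_fixture()
  fit <- fit_quadratic(bbd, "EA")
  opt <- optimize_quadratic(fit)
  expect_gte(opt$predicted_response, max(fit$fitted_values) - 1e-9)
  expect_true(all(abs(opt$coded_location) <= 1 + 1e-9))
  # decoded location available because the fixture carries factor specs
  expect_named(opt$real_location, c("X1", "X2", "X3", "X4"))
})

test_that("relative error behaves as the verification statistic", {
  expect_equal(relative_error(267.851, 266.84), 0.0038, tolerance = 0.01)
  expect_lt(relative_error(267.851, 266.84), 0.02)
  expect_equal(relative_error(0.521281, 0.519), 0.0044, tolerance = 0.01)
  expect_equal(relative_error(5, 5), 0)
  expect_error(relative_error(0, 1), "undefined")
})
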