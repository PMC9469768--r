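pc <- published_coefficients()

test_that("noiseless data regenerate each published coefficient set", {
  d1 <- rows_from_coefficients(pc$linear_sum)
  m1 <- fit_linear_sum(d1)
  expect_lt(max(abs(m1$coefficients[names(pc$linear_sum)] - pc$linear_sum)),
            1e-6)
  d2 <- rows_from_coefficients(pc$multiple_rg)
  m2 <- fit_multiple_rg(d2)
  expect_lt(max(abs(m2$coefficients[names(pc$multiple_rg)] - pc$multiple_rg)),
            1e-6)
  d3 <- rows_from_coefficients(pc$polynomial_sq)
  m3 <- fit_polynomial_sq(d3)
  expect_lt(max(abs(m3$coefficients[names(pc$polynomial_sq)] -
                      pc$polynomial_sq)), 1e-5)
})

test_that("noisy polynomial fits recover the generating coefficients within CI", {
  d <- rows_from_coefficients(pc$polynomial_sq, n = 100, seed = 8,
                              noise_sd = 0.05)
  m <- fit_polynomial_sq(d)
  td <- tidy(m)
  for (term in names(pc$polynomial_sq)) {
    row <- td[td$term == if (term == "(Intercept)") "(Intercept)" else term, ]
    expect_lt(abs(row$estimate - pc$polynomial_sq[term]), 4 * row$std.error)
  }
})

test_that("degenerate designs raise typed fitting errors", {
  d <- tibble::tibble(r = c(100, 120, 140), g = c(50, 30, 10),
                      b = c(30, 30, 30), concentration = c(1, 2, 3))
  expect_error(fit_linear_sum(d), "rank|constant|collinear")  # constant sum
  d2 <- tibble::tibble(r = runif(10, 0, 255))
  d2$g <- d2$r
  d2$b <- runif(10)
  d2$concentration <- runif(10)
  expect_error(fit_multiple_rg(d2), "rank|collinear")
  d3 <- rows_from_coefficients(pc$polynomial_sq, n = 20)
  d3$b <- 100
  expect_error(fit_polynomial_sq(d3), "rank|collinear")
  expect_error(fit_linear_sum(d[1:2, ]), "at least")
})

test_that("an exactly linear calibration interpolates its points with flagged fit quality", {
  d <- tibble::tibble(r = c(100, 150, 120), g = c(100, 150, 120),
                      b = c(100, 150, 120),
                      concentration = 4 - 0.005 * c(300, 450, 360))
  m <- fit_linear_sum(d)
  expect_lt(max(abs(predict_concentration(m, d) - d$concentration)), 1e-9)
  expect_true(residual_diagnostics(m)$degenerate)
})

test_that("prediction evaluates the printed polynomial literally", {
  pm <- published_model("polynomial_sq")
  expect_equal(predict_concentration(pm, tibble::tibble(r = 0, g = 0, b = 0)),
               10.86)
  # hand evaluation at (150, 60, 120)
  hand <- 1.086e1 + 6.2720e-2 * 150 - 6.242e-2 * 60 - 1.3970e-1 * 120 +
    1.297e-4 * 150^2 + 4.526e-4 * 60^2 - 1.626e-4 * 120^2
  expect_equal(predict_concentration(pm, tibble::tibble(r = 150, g = 60,
                                                        b = 120)), hand)
  # RGB sum at which the linear model crosses zero
  lm0 <- published_model("linear_sum")
  sum0 <- 3.7360509 / 0.0070353
  third <- sum0 / 3
  expect_lt(abs(predict_concentration(
    lm0, tibble::tibble(r = third, g = third, b = third))), 1e-9)
  expect_error(predict_concentration(lm0, tibble::tibble(x = 1)), "lacks")
})

test_that("training residuals average to zero after any family fit", {
  d <- rows_from_coefficients(pc$polynomial_sq, n = 50, seed = 3,
                              noise_sd = 0.2)
  for (f in list(fit_linear_sum, fit_multiple_rg, fit_polynomial_sq)) {
    m <- f(d)
    res <- d$concentration - predict_concentration(m, d)
    expect_lt(abs(mean(res)), 1e-9)
  }
})

test_that("backward stepwise matches an independent stepwise oracle and lowers AIC", {
  for (seed in c(2, 5)) {
    d <- rows_from_coefficients(pc$polynomial_sq, n = 200, seed = seed,
                                noise_sd = 0.05)
    mine <- backward_stepwise_aic(d)
    da <- chlorosnap:::augment_rgb(d)
    full <- lm(concentration ~ r + g + b + r2 + g2 + b2, data = da)
    ref <- stats::step(full, direction = "backward", trace = 0)
    expect_setequal(mine$terms, attr(terms(ref), "term.labels"))
    expect_lte(AIC(mine$fit), AIC(full))
    tr <- attr(mine, "trace")
    expect_identical(tr$removed[1], "<none>")
  }
})

test_that("stepwise keeps real structure and can prune an absent blue channel", {
  d_full <- rows_from_coefficients(pc$polynomial_sq, n = 500, seed = 30,
                                   noise_sd = 0.05)
  m_full <- backward_stepwise_aic(d_full)
  expect_setequal(m_full$terms, c("r", "g", "b", "r2", "g2", "b2"))
  cf_nob <- pc$polynomial_sq[c("(Intercept)", "r", "g", "r2", "g2")]
  d_nob <- rows_from_coefficients(cf_nob, n = 500, seed = 31, noise_sd = 0.05)
  m_nob <- backward_stepwise_aic(d_nob)
  expect_false(any(c("b", "b2") %in% m_nob$terms))
  # a single informative regressor reduces to the simple fit
  d1 <- rows_from_coefficients(pc$linear_sum, n = 60, seed = 4)
  m1 <- backward_stepwise_aic(d1, full_terms = "rgb_sum")
  expect_identical(m1$terms, "rgb_sum")
  expect_equal(unname(m1$coefficients["rgb_sum"]),
               unname(pc$linear_sum["rgb_sum"]), tolerance = 1e-6)
})

test_that("a fit without a true green effect reports an insignificant green term", {
  ps <- vapply(1:20, function(seed) {
    d <- withr::with_seed(seed, {
      d <- tibble::tibble(r = runif(80, 90, 200), g = runif(80, 90, 200),
                          b = runif(80, 90, 200))
      d$concentration <- 2 - 0.01 * d$r + rnorm(80, 0, 0.1)
      d
    })
    td <- tidy(fit_multiple_rg(d))
    td$p.value[td$term == "g"]
  }, numeric(1))
  expect_gt(mean(ps > 0.05), 0.8)
  expect_gt(mean(ps), 0.2)
})

test_that("residual diagnostics flag degeneracy and detect curvature", {
  d <- rows_from_coefficients(pc$linear_sum, n = 30, seed = 6)
  m <- fit_linear_sum(d)
  diag0 <- residual_diagnostics(m)
  expect_true(diag0$degenerate)
  # strongly curved residuals are non-normal
  d2 <- withr::with_seed(11, {
    s <- seq(300, 600, length.out = 150)
    tibble::tibble(r = s / 3, g = s / 3, b = s / 3,
                   concentration = 5 - 0.005 * s + 2e-5 * (s - 450)^2 +
                     rnorm(150, 0, 0.01))
  })
  m2 <- fit_linear_sum(d2)
  diag2 <- residual_diagnostics(m2)
  expect_lt(diag2$shapiro_p, 0.05)
  expect_false(is.null(diag2$residuals_fitted))
  # normal residuals keep the nominal type-I rate
  rej <- vapply(1:200, function(seed) {
    d3 <- withr::with_seed(seed + 500, {
      tibble::tibble(r = runif(97, 90, 200), g = runif(97, 90, 200),
                     b = runif(97, 90, 200),
                     concentration = 1 + 0.01 * (runif(97, 90, 200)) +
                       rnorm(97))
    })
    residual_diagnostics(fit_linear_sum(d3))$shapiro_p < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.01)
  expect_lt(mean(rej), 0.12)
})

test_that("calibration models survive a JSON round trip", {
  d <- rows_from_coefficients(pc$polynomial_sq, n = 40, seed = 12)
  m <- fit_polynomial_sq(d)
  path <- withr::local_tempfile(fileext = ".json")
  write_calibration_json(m, path)
  m2 <- read_calibration_json(path)
  samp <- tibble::tibble(r = 150, g = 120, b = 140)
  expect_equal(predict_concentration(m2, samp),
               predict_concentration(m, samp), tolerance = 1e-10)
})
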