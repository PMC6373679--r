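tab <- tumor_reference_data()

test_that("the BPA power law reproduces the published coefficients", {
  fit <- fit_power_law(tab$xnc, tab$d0_bpa)
  expect_equal(printed(fit$a, 4), 0.1341)
  expect_equal(printed(fit$b, 3), -1.586)
  expect_equal(printed(fit$r_squared, 4), 0.9721)
  expect_equal(fit$n, 5L)
})

test_that("the BSH linear model reproduces the published coefficients", {
  keep <- tab$name != "B16-BL6"
  fit <- fit_linear(tab$xcs[keep], tab$d0_bsh[keep])
  expect_equal(printed(fit$slope, 4), 0.0122)
  expect_equal(printed(fit$intercept, 4), -0.1319)
  expect_equal(printed(fit$r_squared, 4), 0.9795)

  full <- fit_linear(tab$xcs, tab$d0_bsh)
  expect_lt(full$r_squared, fit$r_squared)
})

test_that("exact data are recovered exactly", {
  x <- c(0.5, 1, 2, 4)
  pw <- fit_power_law(x, 2 / x)
  expect_equal(pw$a, 2, tolerance = 1e-12)
  expect_equal(pw$b, -1, tolerance = 1e-12)
  expect_equal(pw$r_squared, 1)

  cst <- fit_power_law(x, rep(0.7, 4))
  expect_equal(cst$b, 0, tolerance = 1e-12)
  expect_equal(cst$a, 0.7, tolerance = 1e-12)

  lin <- fit_linear(x, x)
  expect_equal(coef(lin), c(slope = 1, intercept = 0), tolerance = 1e-12)
  expect_equal(lin$r_squared, 1)
})

test_that("degenerate and out-of-domain inputs are rejected", {
  expect_error(fit_power_law(c(1, 2), c(1, 2)), class = "abebnct_domain_error")
  expect_error(fit_power_law(c(-1, 1, 2), c(1, 1, 1)),
               class = "abebnct_domain_error")
  expect_error(fit_linear(c(1, 1, 1), c(1, 2, 3)), "zero variance",
               class = "abebnct_domain_error")
  expect_error(fit_linear(1:2, 1:2), class = "abebnct_domain_error")
})

test_that("predictions evaluate the fitted forms", {
  models <- fit_d0_models(tab)
  expect_equal(predict_d0(models$bpa, 1), models$bpa$a)
  expect_equal(printed(predict_d0(models$bpa, 1), 4), 0.1341)
  expect_equal(predict_d0(models$bpa, 0.508), 0.392, tolerance = 2e-3)
  expect_equal(predict_d0(models$bsh, 74.5), 0.777, tolerance = 3e-3)
  expect_error(predict_d0(models$bpa, 0), class = "abebnct_domain_error")
  expect_warning(d0 <- predict_d0(models$bsh, 5), "validity")
  expect_true(attr(d0, "out_of_validity"))
})

test_that("the power fit is equivariant under predictor rescaling", {
  set.seed(77)
  for (i in 1:15) {
    x <- runif(5, 0.1, 3)
    y <- 0.2 * x^runif(1, -2, 1) * exp(rnorm(5, 0, 0.1))
    c_scale <- runif(1, 0.1, 10)
    f1 <- fit_power_law(x, y)
    f2 <- fit_power_law(c_scale * x, y)
    expect_equal(f2$b, f1$b, tolerance = 1e-10)
    expect_equal(f2$a, f1$a * c_scale^(-f1$b), tolerance = 1e-8)
    expect_equal(f2$r_squared, f1$r_squared, tolerance = 1e-10)
  }
})

test_that("fit_linear matches the closed-form OLS oracle", {
  set.seed(99)
  for (i in 1:15) {
    x <- runif(6, 10, 300)
    y <- 0.01 * x + rnorm(6, 0, 0.2)
    fit <- fit_linear(x, y)
    oracle <- ols_oracle(x, y)
    expect_equal(fit$slope, oracle$slope, tolerance = 1e-10)
    expect_equal(fit$intercept, oracle$intercept, tolerance = 1e-10)
    expect_equal(fit$r_squared, oracle$r_squared, tolerance = 1e-10)
  }
})

test_that("fits are invariant to pair order", {
  perm <- c(4, 1, 5, 2, 3)
  f1 <- fit_power_law(tab$xnc, tab$d0_bpa)
  f2 <- fit_power_law(tab$xnc[perm], tab$d0_bpa[perm])
  expect_equal(f1$r_squared, f2$r_squared, tolerance = 1e-12)
  expect_equal(coef(f1), coef(f2), tolerance = 1e-12)
})

test_that("model round trips refit to the same coefficients", {
  models <- fit_d0_models(tab)
  x <- c(0.2, 0.35, 0.5, 0.65)
  refit <- fit_power_law(x, predict_d0(models$bpa, x))
  expect_equal(refit$a, models$bpa$a, tolerance = 1e-8)
  expect_equal(refit$b, models$bpa$b, tolerance = 1e-8)

  xs <- c(60, 100, 140, 180)
  refit_l <- fit_linear(xs, predict_d0(models$bsh, xs))
  expect_equal(refit_l$slope, models$bsh$slope, tolerance = 1e-8)
  expect_equal(refit_l$intercept, models$bsh$intercept, tolerance = 1e-8)
})

test_that("form comparison exposes unnatural extrapolations at N/C = 1", {
  rep <- compare_approximations(tab$xnc, tab$d0_bpa, at = 1)
  expect_setequal(rep$form, c("linear", "quadratic", "exponential",
                              "logarithmic", "power"))
  pw <- rep[rep$form == "power", ]
  expect_gt(pw$r_squared, 0.97)
  expect_gt(pw$d0_at_ref, 0)
  others <- rep[rep$form != "power", ]
  expect_true(any(others$d0_at_ref <= 0 |
                    others$d0_at_ref > 2 * max(tab$d0_bpa)))
})

test_that("form comparison ranks exact generating forms first", {
  x <- c(0.3, 0.5, 0.8, 1.2, 2)
  rep_pw <- compare_approximations(x, 0.5 * x^-1.3)
  expect_equal(rep_pw$form[1], "power")
  expect_equal(rep_pw$r_squared[1], 1)
  expect_true(all(rep_pw$r_squared[1] >= rep_pw$r_squared[-1]))

  rep_lin <- compare_approximations(x, 2 * x + 1)
  expect_equal(rep_lin[rep_lin$form == "linear", "r_squared"], 1)
})
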