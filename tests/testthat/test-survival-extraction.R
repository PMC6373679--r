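test_that("fit_exponential recovers a noiseless exponential exactly", {
  phi <- c(0, 5e12, 1e13)
  fit <- fit_exponential(survival_curve(phi, exp(-2e-13 * phi)))
  expect_equal(fit$slope_k, 2e-13, tolerance = 1e-12)
  expect_equal(fit$ln_intercept, 0, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$n_points, 3L)
})

test_that("two-point fit matches the hand-computed slope", {
  fit <- fit_exponential(survival_curve(c(1e12, 2e12), c(0.8187, 0.6703)))
  hand <- (log(0.8187) - log(0.6703)) / 1e12
  expect_equal(fit$slope_k, hand, tolerance = 1e-12)
  expect_equal(fit$slope_k, 2.000e-13, tolerance = 1e-3)
})

test_that("constant survival gives zero slope and a defined r-squared", {
  fit <- fit_exponential(survival_curve(c(0, 1e12, 2e12), c(1, 1, 1)))
  expect_equal(fit$slope_k, 0)
  expect_equal(fit$r_squared, 1)
})

test_that("curve construction enforces its invariants", {
  expect_error(survival_curve(c(1e12, 1e12), c(0.9, 0.8)),
               "distinct fluence", class = "abebnct_domain_error")
  expect_error(survival_curve(c(0, 1e12), c(1, 0)),
               "fluence 1e\\+12", class = "abebnct_domain_error")
  expect_error(survival_curve(c(0, 1e12), c(1, -0.1)),
               class = "abebnct_domain_error")
  expect_error(survival_curve(c(0, 1e12), colonies = c(50, 0),
                              plated = c(100, 100)),
               "zero colonies", class = "abebnct_domain_error")
  expect_error(survival_curve(c(0, 1e12), c(1, 0.5), drug = "BPA"),
               class = "abebnct_domain_error")
  expect_error(survival_curve(c(0, 1e12), c(1, 0.5),
                              condition = "beam_plus_boron", drug = "BPA",
                              boron_ppm = 0),
               class = "abebnct_domain_error")
})

test_that("surviving fractions derive from counts via the plating efficiency", {
  cv <- survival_curve(c(0, 1e12), colonies = c(60, 30),
                       plated = c(100, 100))
  # control PE = 0.6 from the zero-fluence point
  expect_equal(cv$surviving_fraction, c(1, 0.5))
  expect_error(
    survival_curve(c(1e12, 2e12), colonies = c(30, 20), plated = c(100, 100),
                   condition = "beam_plus_boron", drug = "BSH",
                   boron_ppm = 10),
    "plating_efficiency", class = "abebnct_schema_error")
})

test_that("subtract_beam takes the slope difference and flags degeneracy", {
  expect_equal(subtract_beam(list(slope_k = 3e-13), list(slope_k = 1e-13)),
               5e12)
  expect_equal(subtract_beam(list(slope_k = 1e-13), list(slope_k = 0)), 1e13)
  expect_error(subtract_beam(list(slope_k = 1e-13), list(slope_k = 1e-13)),
               "no detectable boron effect", class = "abebnct_domain_error")
  expect_error(subtract_beam(list(slope_k = 1e-13), list(slope_k = 2e-13)),
               class = "abebnct_domain_error")
})

test_that("phi0_to_d0 applies the kerma conversion and is bilinear", {
  expect_equal(phi0_to_d0(5e12, 25), 8.666, tolerance = 1e-3)
  expect_equal(phi0_to_d0(1e13, 10), 6.933, tolerance = 1e-12)
  expect_error(phi0_to_d0(1e13, 0), class = "abebnct_domain_error")
  expect_error(phi0_to_d0(-1, 10), class = "abebnct_domain_error")
  set.seed(11)
  for (i in 1:20) {
    phi0 <- runif(1, 1e11, 1e13)
    ppm <- runif(1, 1, 60)
    expect_equal(phi0_to_d0(phi0, 2 * ppm), 2 * phi0_to_d0(phi0, ppm))
    expect_equal(phi0_to_d0(2 * phi0, ppm), 2 * phi0_to_d0(phi0, ppm))
  }
})

test_that("extraction inverts the generating parameters in closed form", {
  pair <- make_noiseless_pair(k_beam = 1e-13, k_boron = 4e-13,
                              boron_ppm = 20)
  bc <- extract_boron_component(pair$beam, pair$boron)
  expect_equal(bc$d0, 6.933e-14 * 20 / 4e-13, tolerance = 1e-12)
  expect_equal(bc$phi0, 1 / 4e-13, tolerance = 1e-12)
})

test_that("a boron curve identical to the control is rejected", {
  phi <- c(0, 5e11, 1e12)
  beam <- survival_curve(phi, exp(-1e-13 * phi))
  boron <- survival_curve(phi, exp(-1e-13 * phi),
                          condition = "beam_plus_boron", drug = "BPA",
                          boron_ppm = 10)
  expect_error(extract_boron_component(beam, boron),
               class = "abebnct_domain_error")
})

test_that("noiseless extraction is exact to 1e-10 relative over random configs", {
  set.seed(2024)
  for (i in 1:25) {
    k_beam <- runif(1, 0, 2e-12)
    d0 <- runif(1, 0.2, 2)
    ppm <- runif(1, 5, 50)
    k_boron <- 6.933e-14 * ppm / d0
    pair <- make_noiseless_pair(k_beam, k_boron, ppm,
                                fluences = seq(0, 3 / (k_beam + k_boron),
                                               length.out = 5),
                                shoulder_beam = runif(1, -0.2, 0),
                                shoulder_boron = runif(1, -0.2, 0))
    bc <- extract_boron_component(pair$beam, pair$boron)
    expect_lt(abs(bc$d0 - d0) / d0, 1e-10)
  }
})

test_that("a single noisy experiment recovers D0 within 5 percent", {
  sim <- simulate_survival_experiment(seed = 20240501, n_plated = 1e5,
                                      d0_true = 0.35)
  bc <- extract_boron_component(sim$beam, sim$boron)
  expect_lt(abs(bc$d0 - 0.35) / 0.35, 0.05)
})

test_that("point order cannot change extraction output bits", {
  phi <- c(0, 5e11, 1e12, 2e12, 3e12)
  sf_beam <- exp(-1.3e-13 * phi)
  sf_boron <- exp(-6.2e-13 * phi)
  perm <- c(3, 1, 5, 2, 4)
  a <- extract_boron_component(
    survival_curve(phi, sf_beam),
    survival_curve(phi, sf_boron, condition = "beam_plus_boron",
                   drug = "BSH", boron_ppm = 30))
  b <- extract_boron_component(
    survival_curve(phi[perm], sf_beam[perm]),
    survival_curve(phi[perm], sf_boron[perm],
                   condition = "beam_plus_boron", drug = "BSH",
                   boron_ppm = 30))
  expect_identical(a, b)
})
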