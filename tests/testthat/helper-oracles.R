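# Shared helpers and independent oracles.

# Noiseless curve pair with known slopes and intercept shoulders.
make_noiseless_pair <- function(k_beam, k_boron, boron_ppm,
                                fluences = c(0, 2e11, 5e11, 8e11, 1.2e12),
                                shoulder_beam = 0, shoulder_boron = 0) {
  beam <- survival_curve(fluences,
                         pmin(1, exp(shoulder_beam - k_beam * fluences)))
  boron <- survival_curve(fluences,
                          pmin(1, exp(shoulder_boron -
                                        (k_beam + k_boron) * fluences)),
                          condition = "beam_plus_boron", drug = "BPA",
                          boron_ppm = boron_ppm)
  list(beam = beam, boron = boron)
}

# Two-pass closed-form simple OLS, independent of lm().
ols_oracle <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  sxy <- sum((x - mx) * (y - my))
  slope <- sxy / sxx
  intercept <- my - slope * mx
  res <- y - intercept - slope * x
  r2 <- 1 - sum(res^2) / sum((y - my)^2)
  list(slope = slope, intercept = intercept, r_squared = r2)
}

# Rounding to printed decimals, half away from zero (matching how published
# coefficients are typically displayed).
printed <- function(x, digits) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Binary disc stamped into a logical matrix (pixel-centre convention).
disc_mask <- function(size, cx, cy, r) {
  xs <- matrix(seq_len(size) - 0.5, size, size, byrow = TRUE)
  ys <- matrix(seq_len(size) - 0.5, size, size)
  (xs - cx)^2 + (ys - cy)^2 <= r^2
}
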