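#' Clonogenic survival curve against thermal neutron fluence
#'
#' Builds a validated survival curve for one irradiation condition. Surviving
#' fractions can be given directly or derived from colony counts as
#' `colonies / (plated * plating_efficiency)`. Points are stored sorted by
#' fluence so that the order in which they were supplied can never influence
#' downstream numerical results.
#'
#' @param fluence Thermal neutron fluence at each point, n/cm^2, finite and
#'   non-negative.
#' @param surviving_fraction Surviving fraction at each point, in (0, 1].
#'   Mutually exclusive with `colonies`/`plated`.
#' @param colonies,plated Colony counts and cells plated per point; used to
#'   derive the surviving fraction when `surviving_fraction` is not given.
#'   A point with zero colonies is rejected (its log-survival is undefined).
#' @param plating_efficiency Fraction of unirradiated plated cells forming
#'   colonies. When counts are supplied without it, it is taken from this
#'   curve's zero-fluence point if the curve is a beam-only control;
#'   otherwise it must be supplied (typically from the matching control).
#' @param condition `"beam_only"` (neutron beam without boron carrier) or
#'   `"beam_plus_boron"`.
#' @param drug Boron carrier: `"none"`, `"BPA"` or `"BSH"`. Must be `"none"`
#'   for beam-only curves.
#' @param boron_ppm Tumour 10B concentration in ppm; 0 for beam-only curves,
#'   strictly positive for beam-plus-boron curves.
#'
#' @return An object of class `"survival_curve"`: a list with elements
#'   `fluence`, `surviving_fraction`, `condition`, `drug`, `boron_ppm` and
#'   (when derived from counts) `plating_efficiency`.
#' @examples
#' sc <- survival_curve(c(0, 5e11, 1e12), exp(-2e-13 * c(0, 5e11, 1e12)))
#' fit_exponential(sc)
#' @seealso [fit_exponential()], [extract_boron_component()]
#' @export
survival_curve <- function(fluence, surviving_fraction = NULL,
                           colonies = NULL, plated = NULL,
                           plating_efficiency = NULL,
                           condition = c("beam_only", "beam_plus_boron"),
                           drug = c("none", "BPA", "BSH"),
                           boron_ppm = 0) {
  condition <- match.arg(condition)
  drug <- match.arg(drug)
  if (!is.numeric(fluence) || length(fluence) == 0) {
    stop_schema("'fluence' must be a non-empty numeric vector")
  }
  if (any(!is.finite(fluence)) || any(fluence < 0)) {
    stop_domain("all fluences must be finite and non-negative")
  }
  if (!is_scalar_number(boron_ppm) || boron_ppm < 0) {
    stop_domain("'boron_ppm' must be a single non-negative number")
  }
  if (condition == "beam_only") {
    if (drug != "none" || boron_ppm != 0) {
      stop_domain("a beam-only curve must have drug = 'none' and boron_ppm = 0")
    }
  } else if (boron_ppm <= 0) {
    stop_domain("a beam-plus-boron curve requires boron_ppm > 0")
  }

  if (is.null(surviving_fraction)) {
    if (is.null(colonies) || is.null(plated)) {
      stop_schema("supply either 'surviving_fraction' or both 'colonies' and 'plated'")
    }
    if (length(colonies) != length(fluence) || length(plated) != length(fluence)) {
      stop_schema("'colonies' and 'plated' must match the length of 'fluence'")
    }
    if (any(colonies < 0) || any(plated <= 0)) {
      stop_domain("colony counts must be >= 0 and cells plated > 0")
    }
    bad <- which(colonies == 0)
    if (length(bad)) {
      stop_domain(sprintf(
        "point %d (fluence %g) has zero colonies; its log-survival is undefined",
        bad[1], fluence[bad[1]]))
    }
    if (is.null(plating_efficiency)) {
      if (condition == "beam_only" && any(fluence == 0)) {
        i0 <- which(fluence == 0)[1]
        plating_efficiency <- colonies[i0] / plated[i0]
      } else {
        stop_schema(paste("'plating_efficiency' is required when deriving surviving",
                          "fractions for a curve without a zero-fluence control point"))
      }
    }
    if (!is_scalar_number(plating_efficiency) ||
        plating_efficiency <= 0 || plating_efficiency > 1) {
      stop_domain("'plating_efficiency' must be a single number in (0, 1]")
    }
    surviving_fraction <- colonies / (plated * plating_efficiency)
  } else if (length(surviving_fraction) != length(fluence)) {
    stop_schema("'surviving_fraction' must match the length of 'fluence'")
  }

  bad <- which(!is.finite(surviving_fraction) | surviving_fraction <= 0)
  if (length(bad)) {
    stop_domain(sprintf(
      "point %d (fluence %g) has surviving fraction %g; must be in (0, 1]",
      bad[1], fluence[bad[1]], surviving_fraction[bad[1]]))
  }
  if (length(unique(fluence)) < 2) {
    stop_domain("a survival curve needs at least 2 distinct fluence values")
  }

  ord <- order(fluence, surviving_fraction)
  structure(
    list(fluence = fluence[ord],
         surviving_fraction = surviving_fraction[ord],
         condition = condition, drug = drug, boron_ppm = boron_ppm,
         plating_efficiency = plating_efficiency),
    class = "survival_curve")
}

#' @export
print.survival_curve <- function(x, ...) {
  cat(sprintf("Clonogenic survival curve (%s%s, %g ppm 10B), %d points\n",
              x$condition,
              if (x$drug != "none") paste0(" + ", x$drug) else "",
              x$boron_ppm, length(x$fluence)))
  print(data.frame(fluence_n_per_cm2 = x$fluence,
                   surviving_fraction = x$surviving_fraction))
  invisible(x)
}

#' Fit an exponential survival curve
#'
#' Ordinary least squares of \eqn{\ln SF} on fluence with a free intercept:
#' \eqn{SF = \exp(c - k\varphi)}. The intercept is not forced through
#' \eqn{SF = 1} at \eqn{\varphi = 0} because measured control curves are
#' often shouldered; only slopes enter the boron-component subtraction, so
#' the intercept never reaches \eqn{\varphi_0}. The fit is unweighted on the
#' log scale.
#'
#' @param curve A [survival_curve()].
#' @return An object of class `"survival_fit"` with elements `slope_k` (the
#'   negated regression slope, per n/cm^2; positive for decaying survival),
#'   `ln_intercept`, `r_squared` (computed on the log scale; defined as 1
#'   for the degenerate constant-survival case), `n_points`, and the curve
#'   metadata. Methods: `print`, `summary`, `coef`, `residuals`, `plot`.
#' @examples
#' phi <- c(0, 5e12, 1e13)
#' fit_exponential(survival_curve(phi, exp(-2e-13 * phi)))
#' @export
fit_exponential <- function(curve) {
  if (!inherits(curve, "survival_curve")) {
    stop_schema("'curve' must be a survival_curve object")
  }
  phi <- curve$fluence
  lsf <- log(curve$surviving_fraction)
  fit <- stats::lm(lsf ~ phi)
  r2 <- rsq(lsf, unname(stats::fitted(fit)))
  structure(
    list(slope_k = -unname(stats::coef(fit)[2]),
         ln_intercept = unname(stats::coef(fit)[1]),
         r_squared = r2,
         n_points = length(phi),
         condition = curve$condition, drug = curve$drug,
         boron_ppm = curve$boron_ppm,
         fluence = phi, ln_sf = lsf,
         fitted_ln_sf = unname(stats::fitted(fit))),
    class = "survival_fit")
}

#' @export
print.survival_fit <- function(x, ...) {
  cat(sprintf("Exponential survival fit (%s): SF = exp(%.4g - %.4g * fluence)\n",
              x$condition, x$ln_intercept, x$slope_k))
  cat(sprintf("  slope k = %.6g per n/cm^2,  R^2 (log scale) = %.4f,  n = %d\n",
              x$slope_k, x$r_squared, x$n_points))
  invisible(x)
}

#' @export
summary.survival_fit <- function(object, ...) {
  print(object)
  cat(sprintf("  1/e fluence of this curve: %.4g n/cm^2\n", 1 / object$slope_k))
  invisible(object)
}

#' @export
coef.survival_fit <- function(object, ...) {
  c(slope_k = object$slope_k, ln_intercept = object$ln_intercept)
}

#' @export
residuals.survival_fit <- function(object, ...) {
  object$ln_sf - object$fitted_ln_sf
}

#' @export
plot.survival_fit <- function(x, ...) {
  graphics::plot(x$fluence, exp(x$ln_sf), log = "y",
                 xlab = "Thermal neutron fluence (n/cm^2)",
                 ylab = "Surviving fraction",
                 main = sprintf("Exponential survival fit (%s)", x$condition), ...)
  graphics::lines(x$fluence, exp(x$fitted_ln_sf), col = "firebrick")
  invisible(x)
}

#' Isolate the boron-only slope and its 1/e fluence
#'
#' The boron-neutron component is the difference between the beam-plus-boron
#' and beam-only log-survival slopes: the beam-only control absorbs every
#' non-capture component (thermal/epithermal/fast neutron and gamma), so the
#' subtracted line decays with \eqn{k_B = k_{total} - k_{beam}} and
#' \eqn{\varphi_0 = 1/k_B} is the fluence reducing it by \eqn{e^{-1}}.
#'
#' @param fit_boron [fit_exponential()] result for the beam-plus-boron curve.
#' @param fit_beam [fit_exponential()] result for the beam-only control.
#' @return `phi0`, the 1/e fluence of the subtracted line, n/cm^2.
#' @examples
#' subtract_beam(list(slope_k = 3e-13), list(slope_k = 1e-13)) # 5e12
#' @export
subtract_beam <- function(fit_boron, fit_beam) {
  k_b <- fit_boron$slope_k - fit_beam$slope_k
  if (!is.finite(k_b) || k_b <= 0) {
    stop_domain(paste("no detectable boron effect: survival with boron is not",
                      "steeper than with the beam alone (k_total <= k_beam)"))
  }
  1 / k_b
}

#' Convert a 1/e fluence to the boron-neutron D0
#'
#' `d0 = phi0 * kerma * boron_ppm`: the boron-neutron dose delivered over the
#' fluence that reduces the subtracted survival line by 1/e.
#'
#' @param phi0 1/e fluence of the boron-only survival line, n/cm^2, > 0.
#' @param boron_ppm Tumour 10B concentration, ppm, > 0.
#' @param kerma Fluence-and-concentration-to-dose coefficient, Gy cm^2 per
#'   ppm; defaults to [boron_kerma_coefficient].
#' @return D0 of the boron-neutron dose, Gy.
#' @examples
#' phi0_to_d0(5e12, 25) # 8.666 Gy
#' @export
phi0_to_d0 <- function(phi0, boron_ppm, kerma = boron_kerma_coefficient) {
  if (!is_scalar_number(phi0) || phi0 <= 0) {
    stop_domain("'phi0' must be a single positive number")
  }
  if (!is_scalar_number(boron_ppm) || boron_ppm <= 0) {
    stop_domain("the boron-neutron dose is undefined without 10B: 'boron_ppm' must be > 0")
  }
  if (!is_scalar_number(kerma) || kerma <= 0) {
    stop_domain("'kerma' must be a single positive number")
  }
  phi0 * kerma * boron_ppm
}

#' Extract the boron-neutron dose component from a curve pair
#'
#' Full extraction chain: fit both curves exponentially
#' ([fit_exponential()]), subtract the beam-only slope ([subtract_beam()]),
#' and convert the resulting \eqn{\varphi_0} to D0 ([phi0_to_d0()]) using the
#' boron curve's 10B concentration.
#'
#' @param beam_curve Beam-only control [survival_curve()].
#' @param boron_curve Beam-plus-boron [survival_curve()].
#' @inheritParams phi0_to_d0
#' @return An object of class `"boron_component"`: `phi0` (n/cm^2), `d0`
#'   (Gy), `boron_ppm`, `kerma_coefficient`, and both component fits
#'   (`fit_beam`, `fit_boron`) for provenance. Methods: `print`, `summary`,
#'   `coef`, `plot`.
#' @examples
#' phi <- c(0, 5e11, 1e12, 2e12)
#' beam <- survival_curve(phi, exp(-1e-13 * phi))
#' boron <- survival_curve(phi, exp(-5e-13 * phi),
#'                         condition = "beam_plus_boron", drug = "BPA",
#'                         boron_ppm = 20)
#' extract_boron_component(beam, boron)
#' @export
extract_boron_component <- function(beam_curve, boron_curve,
                                    kerma = boron_kerma_coefficient) {
  if (!inherits(beam_curve, "survival_curve") ||
      beam_curve$condition != "beam_only") {
    stop_schema("'beam_curve' must be a survival_curve with condition 'beam_only'")
  }
  if (!inherits(boron_curve, "survival_curve") ||
      boron_curve$condition != "beam_plus_boron") {
    stop_schema("'boron_curve' must be a survival_curve with condition 'beam_plus_boron'")
  }
  fit_beam <- fit_exponential(beam_curve)
  fit_boron <- fit_exponential(boron_curve)
  phi0 <- subtract_beam(fit_boron, fit_beam)
  d0 <- phi0_to_d0(phi0, boron_curve$boron_ppm, kerma)
  structure(
    list(phi0 = phi0, d0 = d0, boron_ppm = boron_curve$boron_ppm,
         kerma_coefficient = kerma, drug = boron_curve$drug,
         fit_beam = fit_beam, fit_boron = fit_boron),
    class = "boron_component")
}

#' @export
print.boron_component <- function(x, ...) {
  cat("Boron-neutron dose component\n")
  cat(sprintf("  drug: %s, tumour 10B: %g ppm\n", x$drug, x$boron_ppm))
  cat(sprintf("  slope k_beam  = %.6g per n/cm^2 (R^2 = %.4f)\n",
              x$fit_beam$slope_k, x$fit_beam$r_squared))
  cat(sprintf("  slope k_total = %.6g per n/cm^2 (R^2 = %.4f)\n",
              x$fit_boron$slope_k, x$fit_boron$r_squared))
  cat(sprintf("  phi0 = %.6g n/cm^2\n", x$phi0))
  cat(sprintf("  D0   = %.4g Gy  (kerma %.4g Gy cm^2/ppm)\n",
              x$d0, x$kerma_coefficient))
  invisible(x)
}

#' @export
summary.boron_component <- function(object, ...) {
  print(object)
  cat(sprintf("  ABE factor (1/D0): %.4g\n", 1 / object$d0))
  invisible(object)
}

#' @export
coef.boron_component <- function(object, ...) {
  c(phi0 = object$phi0, d0 = object$d0)
}

#' @export
plot.boron_component <- function(x, ...) {
  fb <- x$fit_beam; ft <- x$fit_boron
  rng <- range(c(fb$fluence, ft$fluence))
  sf <- c(exp(fb$ln_sf), exp(ft$ln_sf))
  graphics::plot(NA, xlim = rng, ylim = range(sf), log = "y",
                 xlab = "Thermal neutron fluence (n/cm^2)",
                 ylab = "Surviving fraction",
                 main = "Boron-neutron component extraction", ...)
  graphics::points(fb$fluence, exp(fb$ln_sf), pch = 1)
  graphics::lines(fb$fluence, exp(fb$fitted_ln_sf), lty = 2)
  graphics::points(ft$fluence, exp(ft$ln_sf), pch = 16)
  graphics::lines(ft$fluence, exp(ft$fitted_ln_sf))
  k_b <- 1 / x$phi0
  graphics::curve(exp(-k_b * x), from = rng[1], to = rng[2], add = TRUE,
                  col = "firebrick")
  graphics::legend("bottomleft",
                   legend = c("beam only", "beam + boron", "subtracted (boron only)"),
                   lty = c(2, 1, 1), pch = c(1, 16, NA),
                   col = c("black", "black", "firebrick"), bty = "n")
  invisible(x)
}
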