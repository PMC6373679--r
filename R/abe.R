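#' Absolute biological effectiveness factor
#'
#' The ABE factor of a tumour whose boron-neutron survival curve has
#' characteristic dose D0 is `1 / d0` (Gy/D0; numerically per Gy, treated as
#' unitless since D0 itself is in Gy). Unlike RBE or CBE it references the
#' tumour's own measured radiosensitivity, not an X-ray standard.
#'
#' @param d0 Boron-neutron D0, Gy, > 0.
#' @return The ABE factor.
#' @examples
#' abe_factor(0.35) # 2.857
#' @export
abe_factor <- function(d0) {
  if (!is.numeric(d0) || any(!is.finite(d0)) || any(d0 <= 0)) {
    stop_domain("'d0' must be positive")
  }
  1 / d0
}

#' ABE dose and implied survival for a physical boron-neutron dose
#'
#' `abe_dose = physical_dose * abe_factor = physical_dose / d0`, in
#' Gy-equivalents: the number of 1/e reductions the dose produces on the
#' tumour's own exponential survival curve. The implied surviving fraction
#' is `exp(-abe_dose)` (the "e to the minus ABE dose" convention, with the
#' ABE dose expressed in Gy-equivalents).
#'
#' @param physical_dose Physical boron-neutron dose, Gy, >= 0.
#' @param d0 Boron-neutron D0 of the tumour, Gy, > 0.
#' @return An object of class `"abe_result"`: `d0`, `abe_factor`,
#'   `physical_dose`, `abe_dose`, `implied_survival`.
#' @examples
#' abe_dose(2.3, 0.91) # ABE dose 2.53, survival 0.080
#' @export
abe_dose <- function(physical_dose, d0) {
  if (!is_scalar_number(physical_dose) || physical_dose < 0) {
    stop_domain("'physical_dose' must be a single non-negative number")
  }
  if (!is_scalar_number(d0) || d0 <= 0) {
    stop_domain("'d0' must be a single positive number")
  }
  fac <- abe_factor(d0)
  ad <- physical_dose * fac
  structure(
    list(d0 = d0, abe_factor = fac, physical_dose = physical_dose,
         abe_dose = ad, implied_survival = exp(-ad)),
    class = "abe_result")
}

#' @export
print.abe_result <- function(x, ...) {
  cat("ABE dose result\n")
  if (!is.null(x$predicted_from)) {
    cat(sprintf("  D0 predicted from %s (%s model): %.4g Gy\n",
                x$predicted_from, x$drug, x$d0))
  } else {
    cat(sprintf("  D0: %.4g Gy\n", x$d0))
  }
  cat(sprintf("  ABE factor:       %.4g\n", x$abe_factor))
  cat(sprintf("  physical dose:    %.4g Gy\n", x$physical_dose))
  cat(sprintf("  ABE dose:         %.4g Gy-equivalents\n", x$abe_dose))
  cat(sprintf("  implied survival: %.4g\n", x$implied_survival))
  invisible(x)
}

#' Predict the ABE dose of a tumour from slide morphometry
#'
#' Routes the morphometric predictor to the drug-appropriate model — N/C
#' ratio through the power-law model for BPA (intracellular carrier), or
#' cell-size index through the linear model for BSH (extracellular carrier)
#' — then converts the physical dose via [abe_dose()].
#'
#' @param indices A [compute_indices()] result, or any list with `xnc`
#'   and/or `xcs`.
#' @param drug `"BPA"` or `"BSH"`.
#' @param physical_dose Physical boron-neutron dose, Gy.
#' @param models List with elements `bpa` and `bsh` as returned by
#'   [fit_d0_models()]; defaults to models fitted to the packaged reference
#'   table.
#' @return An [abe_dose()] result, augmented with `drug`, `predictor`,
#'   `predicted_from`. A BSH prediction with D0 <= 0 signals an
#'   out-of-validity error (the linear model does not extend there).
#' @examples
#' predict_abe_from_slide(list(xnc = 0.508), "BPA", physical_dose = 1)
#' @export
predict_abe_from_slide <- function(indices, drug = c("BPA", "BSH"),
                                   physical_dose, models = fit_d0_models()) {
  drug <- match.arg(drug)
  if (drug == "BPA") {
    if (is.null(indices$xnc)) {
      stop_schema("BPA prediction requires the N/C ratio 'xnc'")
    }
    if (is.null(models$bpa)) stop_schema("no BPA model supplied")
    d0 <- predict_d0(models$bpa, indices$xnc)
    predictor <- c(xnc = indices$xnc)
  } else {
    if (is.null(indices$xcs)) {
      stop_schema("BSH prediction requires the cell-size index 'xcs'")
    }
    if (is.null(models$bsh)) stop_schema("no BSH model supplied")
    d0 <- withCallingHandlers(
      predict_d0(models$bsh, indices$xcs),
      warning = function(w) invokeRestart("muffleWarning"))
    if (d0 <= 0) {
      stop_domain(sprintf(
        "predicted D0 = %.4g Gy at xcs = %g is outside the linear model's validity",
        d0, indices$xcs))
    }
    predictor <- c(xcs = indices$xcs)
  }
  out <- abe_dose(physical_dose, as.numeric(d0))
  out$drug <- drug
  out$predictor <- predictor
  out$predicted_from <- names(predictor)
  out
}
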