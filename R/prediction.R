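#' Fit a power-law radiosensitivity model
#'
#' Fits \eqn{y = a x^b} by ordinary least squares of \eqn{\ln y} on
#' \eqn{\ln x}: `a = exp(intercept)`, `b = slope`. This is the model linking
#' the boron-neutron D0 under BPA to the nucleocytoplasmic ratio. The
#' reported \eqn{R^2} is the squared correlation on the ln-ln scale (the
#' scale on which the fit is performed), recorded in the model metadata.
#'
#' @param x Predictor values, > 0 (e.g. N/C ratios).
#' @param y Response values, > 0 (e.g. D0 in Gy).
#' @return An object of class `"power_law_fit"`: `a`, `b`, `r_squared`, `n`.
#'   Methods: `print`, `coef` (named `a`, `b`), `predict`, `residuals`
#'   (ln scale), `plot`.
#' @examples
#' tab <- tumor_reference_data()
#' fit_power_law(tab$xnc, tab$d0_bpa) # a = 0.1341, b = -1.586
#' @export
fit_power_law <- function(x, y) {
  check_pairs(x, y, min_n = 3)
  if (any(x <= 0) || any(y <= 0)) {
    stop_domain("power-law fitting requires strictly positive x and y")
  }
  lx <- log(x); ly <- log(y)
  fit <- stats::lm(ly ~ lx)
  r2 <- rsq(ly, unname(stats::fitted(fit)))
  structure(
    list(a = exp(unname(stats::coef(fit)[1])),
         b = unname(stats::coef(fit)[2]),
         r_squared = r2, n = length(x),
         r_squared_scale = "ln-ln",
         x = x, y = y),
    class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("Power-law model: D0 = %.4g * x^(%.4g)   [R^2 = %.4f on the %s scale, n = %d]\n",
              x$a, x$b, x$r_squared, x$r_squared_scale, x$n))
  invisible(x)
}

#' @export
coef.power_law_fit <- function(object, ...) c(a = object$a, b = object$b)

#' @export
residuals.power_law_fit <- function(object, ...) {
  log(object$y) - (log(object$a) + object$b * log(object$x))
}

#' @export
predict.power_law_fit <- function(object, newdata, ...) {
  predict_d0(object, newdata)
}

#' @export
plot.power_law_fit <- function(x, ...) {
  graphics::plot(x$x, x$y, xlab = "predictor", ylab = "D0 (Gy)",
                 main = "Power-law D0 model", ...)
  xx <- seq(min(x$x), max(x$x), length.out = 200)
  graphics::lines(xx, x$a * xx^x$b, col = "firebrick")
  invisible(x)
}

#' Fit a linear radiosensitivity model
#'
#' Ordinary least squares of D0 on a morphometric predictor; the model
#' linking the boron-neutron D0 under BSH to the cell-size index. \eqn{R^2}
#' is the squared Pearson correlation.
#'
#' @param x Predictor values (e.g. cell-size index, um^2).
#' @param y Response values (D0, Gy).
#' @param exclusions Character vector of record names excluded before the
#'   fit when `names(x)` is set (a named exclusion list, never automated
#'   outlier detection). Stored in the result.
#' @return An object of class `"linear_d0_fit"`: `slope`, `intercept`,
#'   `r_squared`, `n`, `exclusions`. Methods: `print`, `coef`, `predict`,
#'   `residuals`, `plot`.
#' @examples
#' tab <- tumor_reference_data()
#' keep <- tab$name != "B16-BL6"
#' fit_linear(tab$xcs[keep], tab$d0_bsh[keep]) # 0.0122 x - 0.1319
#' @export
fit_linear <- function(x, y, exclusions = character()) {
  if (length(exclusions) && !is.null(names(x))) {
    keep <- !(names(x) %in% exclusions)
    x <- x[keep]
    y <- y[keep]
  }
  check_pairs(x, y, min_n = 3)
  if (stats::var(x) == 0) {
    stop_domain("predictor has zero variance; the slope is undefined")
  }
  fit <- stats::lm(y ~ x)
  r2 <- rsq(y, unname(stats::fitted(fit)))
  structure(
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r_squared = r2, n = length(x),
         exclusions = exclusions,
         x = unname(x), y = unname(y)),
    class = "linear_d0_fit")
}

#' @export
print.linear_d0_fit <- function(x, ...) {
  cat(sprintf("Linear model: D0 = %.4g * x + (%.4g)   [R^2 = %.4f, n = %d%s]\n",
              x$slope, x$intercept, x$r_squared, x$n,
              if (length(x$exclusions))
                paste0(", excluded: ", paste(x$exclusions, collapse = ", "))
              else ""))
  invisible(x)
}

#' @export
coef.linear_d0_fit <- function(object, ...) {
  c(slope = object$slope, intercept = object$intercept)
}

#' @export
residuals.linear_d0_fit <- function(object, ...) {
  object$y - (object$intercept + object$slope * object$x)
}

#' @export
predict.linear_d0_fit <- function(object, newdata, ...) {
  predict_d0(object, newdata)
}

#' @export
plot.linear_d0_fit <- function(x, ...) {
  graphics::plot(x$x, x$y, xlab = "predictor", ylab = "D0 (Gy)",
                 main = "Linear D0 model", ...)
  graphics::abline(x$intercept, x$slope, col = "firebrick")
  invisible(x)
}

check_pairs <- function(x, y, min_n) {
  if (!is.numeric(x) || !is.numeric(y) || length(x) != length(y)) {
    stop_schema("'x' and 'y' must be numeric vectors of equal length")
  }
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop_domain("'x' and 'y' must be finite")
  }
  if (length(x) < min_n) {
    stop_domain(sprintf("at least %d pairs are required", min_n))
  }
}

#' Predict D0 from a fitted model
#'
#' Evaluates a [fit_power_law()] or [fit_linear()] model at new predictor
#' values. A linear-model prediction that is not positive lies outside the
#' model's range of validity: the value is returned with attribute
#' `out_of_validity = TRUE` and a warning.
#'
#' @param model A `"power_law_fit"` or `"linear_d0_fit"`.
#' @param x Predictor value(s); must be > 0 for the power model.
#' @return Predicted D0, Gy.
#' @examples
#' m <- fit_power_law(c(0.3, 0.4, 0.5), c(0.9, 0.55, 0.4))
#' predict_d0(m, 0.45)
#' @export
predict_d0 <- function(model, x) {
  UseMethod("predict_d0")
}

#' @export
predict_d0.power_law_fit <- function(model, x) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    stop_domain("the power-law model is defined for x > 0 only")
  }
  model$a * x^model$b
}

#' @export
predict_d0.linear_d0_fit <- function(model, x) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop_domain("'x' must be finite")
  }
  d0 <- model$intercept + model$slope * x
  if (any(d0 <= 0)) {
    warning("predicted D0 <= 0: outside the linear model's range of validity",
            call. = FALSE)
    attr(d0, "out_of_validity") <- TRUE
  }
  d0
}

#' Fit the two default D0-prediction models from a tumour table
#'
#' BPA: power law of `d0_bpa` on the N/C ratio, all records. BSH: linear
#' model of `d0_bsh` on the cell-size index, with B16-BL6 melanoma excluded
#' by default (its extracellular BSH microdistribution deviates from the
#' linear relation the other lines follow).
#'
#' @param records Data frame with columns `name`, `d0_bpa`, `d0_bsh`, `xnc`,
#'   `xcs` (see [tumor_reference_data()]).
#' @param bsh_exclude Named exclusion list for the BSH fit.
#' @param bpa_exclude Named exclusion list for the BPA fit (default none).
#' @return List with elements `bpa` (power_law_fit) and `bsh`
#'   (linear_d0_fit).
#' @export
fit_d0_models <- function(records = tumor_reference_data(),
                          bsh_exclude = "B16-BL6",
                          bpa_exclude = character()) {
  need <- c("name", "d0_bpa", "d0_bsh", "xnc", "xcs")
  if (!all(need %in% names(records))) {
    stop_schema(paste("'records' must have columns",
                      paste(need, collapse = ", ")))
  }
  keep_bpa <- !(records$name %in% bpa_exclude)
  bpa <- fit_power_law(records$xnc[keep_bpa], records$d0_bpa[keep_bpa])
  xs <- stats::setNames(records$xcs, records$name)
  bsh <- fit_linear(xs, stats::setNames(records$d0_bsh, records$name),
                    exclusions = bsh_exclude)
  list(bpa = bpa, bsh = bsh)
}

#' Compare functional forms for the D0 relationship
#'
#' Refits the same pairs under five forms — linear, exponential
#' (\eqn{y = a e^{bx}}), logarithmic (\eqn{y = a + b \ln x}), power
#' (\eqn{y = a x^b}) and quadratic polynomial — reporting each form's
#' \eqn{R^2} (on the scale the form is fitted on) and its predicted D0 at a
#' reference predictor value. The reference point (default `at = 1`, i.e. a
#' nucleus filling the cell when the predictor is the N/C ratio) exposes
#' forms that extrapolate to negative or implausibly large D0 there, the
#' argument for preferring the power form for the BPA model.
#'
#' @param x,y Pairs, at least 4.
#' @param at Reference predictor value for the extrapolation column.
#' @return A data frame of class `"approximation_report"`, one row per form,
#'   ordered by decreasing `r_squared`: `form`, `r_squared`, `d0_at_ref`,
#'   `note` (fitting scale or a reason the form was skipped).
#' @export
compare_approximations <- function(x, y, at = 1.0) {
  check_pairs(x, y, min_n = 4)
  rows <- list()
  add <- function(form, r2, pred, note) {
    rows[[length(rows) + 1]] <<- data.frame(
      form = form, r_squared = r2, d0_at_ref = pred, note = note)
  }

  f_lin <- stats::lm(y ~ x)
  add("linear", rsq(y, unname(stats::fitted(f_lin))),
      unname(stats::coef(f_lin)[1] + stats::coef(f_lin)[2] * at), "y scale")

  f_quad <- stats::lm(y ~ x + I(x^2))
  add("quadratic", rsq(y, unname(stats::fitted(f_quad))),
      unname(sum(stats::coef(f_quad) * c(1, at, at^2))), "y scale")

  if (all(y > 0)) {
    f_exp <- stats::lm(log(y) ~ x)
    add("exponential", rsq(log(y), unname(stats::fitted(f_exp))),
        exp(unname(stats::coef(f_exp)[1] + stats::coef(f_exp)[2] * at)),
        "ln y scale")
  } else {
    add("exponential", NA_real_, NA_real_, "skipped: non-positive y")
  }

  if (all(x > 0)) {
    f_log <- stats::lm(y ~ log(x))
    add("logarithmic", rsq(y, unname(stats::fitted(f_log))),
        unname(stats::coef(f_log)[1] + stats::coef(f_log)[2] * log(at)),
        "y scale")
  } else {
    add("logarithmic", NA_real_, NA_real_, "skipped: non-positive x")
  }

  if (all(x > 0) && all(y > 0)) {
    pw <- fit_power_law(x, y)
    add("power", pw$r_squared, pw$a * at^pw$b, "ln-ln scale")
  } else {
    add("power", NA_real_, NA_real_, "skipped: non-positive x or y")
  }

  out <- do.call(rbind, rows)
  out <- out[order(out$r_squared, decreasing = TRUE, na.last = TRUE), ]
  rownames(out) <- NULL
  class(out) <- c("approximation_report", "data.frame")
  attr(out, "at") <- at
  out
}

#' @export
print.approximation_report <- function(x, ...) {
  cat(sprintf("Functional-form comparison (reference predictor x = %g):\n",
              attr(x, "at")))
  print.data.frame(x, digits = 4)
  invisible(x)
}
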