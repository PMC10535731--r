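#' Percent viability from alamarBlue absorbance pairs
#'
#' Converts a test-well absorbance pair (570 nm, 600 nm) and a negative
#' control pair (medium plus reagent, no cells) into percent viability via
#' the reagent manufacturer's equation
#' \deqn{100 (c_1 A_1 - c_2 A_2) / (c_3 N_2 - c_4 N_1)}
#' with default coefficients `c = (117216, 80586, 155677, 14652)`. `A1`/`A2`
#' are the test well at 570/600 nm, `N1`/`N2` the negative control at
#' 570/600 nm. The raw scale is preserved: values may exceed 100 or fall
#' below 0; any clipping is a display decision, not done here.
#'
#' @param a570_test,a600_test test-well absorbances at 570 and 600 nm.
#' @param a570_negctrl,a600_negctrl negative-control absorbances.
#' @param config a [run_config()] supplying `viability_coefficients`.
#' @return percent viability (vectorized over the test pair).
#' @examples
#' compute_viability(0.5, 0.3, 0.1, 0.2)  # ~116.05
#' @export
compute_viability <- function(a570_test, a600_test, a570_negctrl, a600_negctrl,
                              config = run_config()) {
  cf <- config$viability_coefficients
  den <- cf[3] * a600_negctrl - cf[4] * a570_negctrl
  if (any(!is.finite(den)) || any(abs(den) < 1e-8 * cf[3]))
    abort_radsyn("degenerate negative control: denominator is zero or near zero",
                 "radsyn_degenerate_control_error")
  100 * (cf[1] * a570_test - cf[2] * a600_test) / den
}

#' Build a dose-viability curve from plate wells
#'
#' Negative-control absorbances are averaged into a single reference pair;
#' every test well is converted with [compute_viability()]; wells are then
#' grouped by dose into per-dose mean, standard error, and replicate count,
#' sorted by ascending dose.
#'
#' @param wells data frame in the `viability` schema (see [read_assay_table()]).
#' @param config a [run_config()].
#' @return data frame of class `radsyn_curve` with columns `dose_um`,
#'   `mean_viability`, `se_viability`, `n`.
#' @export
build_viability_curve <- function(wells, config = run_config()) {
  wells <- validate_assay_table(wells, "viability")
  nc <- wells[wells$is_negative_control, , drop = FALSE]
  test <- wells[!wells$is_negative_control, , drop = FALSE]
  if (nrow(nc) == 0L)
    abort_radsyn("no negative-control well", "radsyn_validation_error")
  if (length(unique(test$dose_um)) < 2L)
    abort_radsyn("need at least 2 distinct doses to build a curve",
                 "radsyn_validation_error")
  n1 <- mean(nc$a570); n2 <- mean(nc$a600)
  v <- compute_viability(test$a570, test$a600, n1, n2, config)
  agg <- split(v, test$dose_um)
  doses <- as.numeric(names(agg))
  ord <- order(doses)
  out <- data.frame(
    dose_um = doses[ord],
    mean_viability = vapply(agg, mean, numeric(1))[ord],
    se_viability = vapply(agg, function(x)
      if (length(x) > 1L) stats::sd(x) / sqrt(length(x)) else 0, numeric(1))[ord],
    n = vapply(agg, length, integer(1))[ord],
    row.names = NULL
  )
  class(out) <- c("radsyn_curve", "data.frame")
  out
}

#' Estimate IC50 from a dose-viability curve
#'
#' Two estimators:
#'
#' * `log_interp` locates the first downward crossing of 50% viability by
#'   linear interpolation of mean viability against `log10(dose)` between the
#'   bracketing doses. Dose 0 cannot enter the interpolation (log of zero)
#'   and is dropped with the normalization anchor role it plays elsewhere.
#' * `four_pl` fits a 4-parameter logistic
#'   \deqn{v(d) = bottom + (top - bottom) / (1 + (d / ic50)^{hill})}
#'   by Levenberg-Marquardt least squares and returns the fitted midpoint.
#'   The fit constrains `top` to \[80, 120\]%, `bottom` to \[0, 50\]% and
#'   `hill > 0`, initialized from the curve extremes and the interpolated
#'   crossing, which keeps 7-point curves away from degenerate optima.
#'
#' @param curve output of [build_viability_curve()] (or any data frame with
#'   `dose_um` and `mean_viability`).
#' @param method `"log_interp"` or `"four_pl"`.
#' @return IC50 in the dose units of the curve (scalar).
#' @examples
#' curve <- data.frame(dose_um = c(50, 100), mean_viability = c(60, 40))
#' estimate_ic50(curve)  # ~70.71
#' @export
estimate_ic50 <- function(curve, method = c("log_interp", "four_pl")) {
  method <- match.arg(method)
  cv <- curve[curve$dose_um > 0, , drop = FALSE]
  cv <- cv[order(cv$dose_um), , drop = FALSE]
  if (method == "log_interp") return(.ic50_log_interp(cv))
  if (nrow(cv) < 4L)
    abort_radsyn("four_pl needs at least 4 nonzero doses", "radsyn_fit_error")
  .ic50_four_pl(cv)
}

.ic50_log_interp <- function(cv) {
  v <- cv$mean_viability
  d <- cv$dose_um
  # first index where the curve moves from >= 50 down to < 50
  cross <- which(v[-length(v)] >= 50 & v[-1] < 50)
  if (v[1] < 50 || length(cross) == 0L) {
    exact <- which(v == 50)
    if (length(exact)) return(d[exact[1]])
    abort_radsyn("viability never crosses 50% within the dose range",
                 "radsyn_not_estimable_error")
  }
  i <- cross[1]
  f <- (v[i] - 50) / (v[i] - v[i + 1])
  10^(log10(d[i]) + f * (log10(d[i + 1]) - log10(d[i])))
}

.ic50_four_pl <- function(cv) {
  d <- cv$dose_um; v <- cv$mean_viability
  start_mid <- tryCatch(.ic50_log_interp(cv), error = function(e) stats::median(d))
  start <- c(top = max(min(max(v), 120), 80), bottom = min(max(min(v), 0), 50),
             ic50 = start_mid, hill = 1)
  resid_fn <- function(p)
    v - (p[["bottom"]] + (p[["top"]] - p[["bottom"]]) / (1 + (d / p[["ic50"]])^p[["hill"]]))
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = start, fn = resid_fn,
      lower = c(top = 80, bottom = 0, ic50 = min(d) / 100, hill = 1e-3),
      upper = c(top = 120, bottom = 50, ic50 = max(d) * 100, hill = 20),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e)
      abort_radsyn(paste0("4PL fit failed: ", conditionMessage(e)), "radsyn_fit_error"))
  if (!fit$info %in% 1:4)
    abort_radsyn(paste0("4PL fit did not converge: ", fit$message), "radsyn_fit_error")
  unname(fit$par[["ic50"]])
}
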