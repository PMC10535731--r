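#' Run configuration for the analysis pipeline
#'
#' Bundles the constants every stage shares: the growth-time volume threshold,
#' the ellipsoid volume constant, the four manufacturer coefficients of the
#' alamarBlue viability equation, the significance tiers, and the precision
#' mode.
#'
#' `precision_mode` selects between `"full"` (all arithmetic at double
#' precision) and `"printed"` (ratios and rates computed from intermediates
#' rounded the way published tables round them: whole-percent inhibition
#' rates, two-decimal time ratios). `"printed"` exists to reproduce published
#' tables bit-for-bit; `"full"` is the honest default for new data.
#'
#' @param growth_threshold_mm3 tumor volume threshold defining growth time
#'   (mm^3, default 400).
#' @param volume_constant multiplier in `V = c * L * W * H` (default 0.523 as
#'   conventionally printed; `4 * pi / 24` is the exact ellipsoid constant).
#' @param precision_mode `"full"` or `"printed"`.
#' @param viability_coefficients numeric length-4 vector `c(c1, c2, c3, c4)`
#'   of the manufacturer's absorbance equation (see [compute_viability()]).
#' @param significance_thresholds strictly decreasing p-value cutoffs for the
#'   one/two/three-glyph annotation tiers.
#' @param seed integer seed recorded for provenance.
#' @return an object of class `radsyn_config` (a named list).
#' @examples
#' cfg <- run_config(precision_mode = "printed")
#' cfg$growth_threshold_mm3
#' @export
run_config <- function(growth_threshold_mm3 = 400,
                       volume_constant = 0.523,
                       precision_mode = c("full", "printed"),
                       viability_coefficients = c(117216, 80586, 155677, 14652),
                       significance_thresholds = c(0.05, 0.01, 0.001),
                       seed = 1L) {
  precision_mode <- match.arg(precision_mode)
  if (!is_number(growth_threshold_mm3) || growth_threshold_mm3 <= 0)
    abort_radsyn("growth_threshold_mm3 must be a positive number", "radsyn_config_error")
  if (!is_number(volume_constant) || volume_constant <= 0)
    abort_radsyn("volume_constant must be > 0", "radsyn_config_error")
  if (length(viability_coefficients) != 4L || !all(is.finite(viability_coefficients)))
    abort_radsyn("viability_coefficients must be 4 finite numbers", "radsyn_config_error")
  if (any(diff(significance_thresholds) >= 0))
    abort_radsyn("significance_thresholds must be strictly decreasing", "radsyn_config_error")
  structure(list(
    growth_threshold_mm3 = growth_threshold_mm3,
    volume_constant = volume_constant,
    precision_mode = precision_mode,
    viability_coefficients = as.numeric(viability_coefficients),
    significance_thresholds = as.numeric(significance_thresholds),
    seed = as.integer(seed)
  ), class = "radsyn_config")
}

#' Read a run configuration from a JSON file
#'
#' @param path JSON file whose keys mirror the arguments of [run_config()].
#' @return a `radsyn_config` object.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort_radsyn(paste0("config file not found: ", path), "radsyn_io_error")
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(run_config))
  do.call(run_config, raw[intersect(names(raw), known)])
}

#' @export
print.radsyn_config <- function(x, ...) {
  cat("<radsyn_config>\n")
  cat("  growth threshold:", x$growth_threshold_mm3, "mm^3\n")
  cat("  volume constant :", x$volume_constant, "\n")
  cat("  precision mode  :", x$precision_mode, "\n")
  cat("  significance    :", paste(x$significance_thresholds, collapse = " / "), "\n")
  cat("  seed            :", x$seed, "\n")
  invisible(x)
}
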