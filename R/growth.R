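#' Ellipsoid tumor volume from caliper dimensions
#'
#' `V = c * L * W * H` with the conventional constant `c = 0.523`, i.e. the
#' ellipsoid formula `(4/3) pi (L/2)(W/2)(H/2)` with its constant truncated to
#' three decimals. Pass `volume_constant = 4 * pi / 24` in the config for the
#' exact ellipsoid constant (~0.5236).
#'
#' @param length_mm,width_mm,height_mm caliper dimensions in mm (>= 0).
#' @param config a [run_config()] supplying `volume_constant`.
#' @return volume in mm^3 (vectorized).
#' @examples
#' tumor_volume(10, 10, 10)  # 523
#' @export
tumor_volume <- function(length_mm, width_mm, height_mm, config = run_config()) {
  if (any(c(length_mm, width_mm, height_mm) < 0, na.rm = TRUE))
    abort_radsyn("caliper dimensions must be >= 0", "radsyn_validation_error")
  config$volume_constant * length_mm * width_mm * height_mm
}

#' Split a caliper table into per-animal tumor trajectories
#'
#' Computes volumes from dimensions where needed (rows supplying
#' `volume_mm3` directly are kept as-is) and returns one trajectory per
#' animal with days sorted ascending.
#'
#' @param caliper data frame in the `caliper` schema.
#' @param config a [run_config()].
#' @return named list of data frames (`animal_id`, `group`, `day`,
#'   `volume_mm3`), one per animal.
#' @export
tumor_trajectories <- function(caliper, config = run_config()) {
  caliper <- validate_assay_table(caliper, "caliper")
  vol <- if ("volume_mm3" %in% names(caliper)) caliper$volume_mm3 else rep(NA_real_, nrow(caliper))
  need <- is.na(vol)
  if (any(need)) {
    if (!all(c("length_mm", "width_mm", "height_mm") %in% names(caliper)))
      abort_radsyn("caliper rows without volume_mm3 need all three dimensions",
                   "radsyn_schema_error")
    vol[need] <- tumor_volume(caliper$length_mm[need], caliper$width_mm[need],
                              caliper$height_mm[need], config)
  }
  df <- data.frame(animal_id = as.character(caliper$animal_id),
                   group = as.character(caliper$group),
                   day = caliper$day, volume_mm3 = vol)
  lapply(split(df, df$animal_id), function(tr) {
    tr <- tr[order(tr$day), ]
    rownames(tr) <- NULL
    tr
  })
}

#' Time for a tumor to reach a volume threshold
#'
#' Returns the day at which the trajectory first reaches `threshold_mm3`.
#' Between measurement days the crossing is located by linear interpolation
#' of `ln(volume)` against day within the first bracketing interval —
#' tumor growth is near-exponential at small volumes, so the log scale is the
#' natural interpolant. If the first observation is already at or above the
#' threshold its day is returned. A trajectory that never reaches the
#' threshold is censored: `NA` with attribute `censored = TRUE`.
#'
#' @param days measurement days, strictly increasing.
#' @param volumes_mm3 tumor volumes (mm^3).
#' @param threshold_mm3 volume threshold (default 400 mm^3).
#' @return growth time in days, or `NA` (censored).
#' @examples
#' growth_time(c(7, 14), c(200, 800))  # 10.5
#' @export
growth_time <- function(days, volumes_mm3, threshold_mm3 = 400) {
  if (length(days) < 2L && max(volumes_mm3) < threshold_mm3)
    abort_radsyn("need >= 2 time points for growth-time interpolation",
                 "radsyn_validation_error")
  if (any(diff(days) <= 0))
    abort_radsyn("days must be strictly increasing", "radsyn_validation_error")
  if (volumes_mm3[1] >= threshold_mm3) return(days[1])
  hit <- which(volumes_mm3 >= threshold_mm3)
  if (length(hit) == 0L) {
    res <- NA_real_
    attr(res, "censored") <- TRUE
    return(res)
  }
  i <- hit[1]
  v0 <- volumes_mm3[i - 1]; v1 <- volumes_mm3[i]
  if (v0 <= 0 || v1 <= 0)
    abort_radsyn("bracketing volumes must be > 0 for log interpolation",
                 "radsyn_validation_error")
  days[i - 1] + (days[i] - days[i - 1]) *
    (log(threshold_mm3) - log(v0)) / (log(v1) - log(v0))
}

#' Group-level growth-time summaries (delay, time-ratio rate, enhancement)
#'
#' For each group: mean growth time over uncensored animals, delay versus the
#' control mean, and the time-ratio inhibition rate (group mean / control
#' mean). For the combination group, one combination enhancement ratio per
#' single-agent group: combination rate / single-agent rate.
#'
#' In `precision_mode = "printed"` the time-ratio rates are rounded to two
#' decimals before the enhancement ratios are formed, and the ratios rounded
#' to two decimals — the convention under which published tables such as
#' "2.78 / 1.33 = 2.09" are internally consistent. In `"full"` mode nothing
#' is rounded.
#'
#' Censored animals (threshold never reached) are excluded from group means
#' with a warning.
#'
#' @param trajectories list from [tumor_trajectories()].
#' @param config a [run_config()] supplying `growth_threshold_mm3` and
#'   `precision_mode`.
#' @return data frame with one row per group: `group`, `n`, `n_censored`,
#'   `mean_growth_time`, `delay_time`, `time_ratio_rate`,
#'   `enhancement_vs_drug`, `enhancement_vs_radiation`.
#' @export
growth_summaries <- function(trajectories, config = run_config()) {
  per_animal <- do.call(rbind, lapply(trajectories, function(tr) {
    gt <- growth_time(tr$day, tr$volume_mm3, config$growth_threshold_mm3)
    data.frame(animal_id = tr$animal_id[1], group = tr$group[1],
               growth_time = as.numeric(gt),
               censored = isTRUE(attr(gt, "censored")))
  }))
  if (any(per_animal$censored))
    warning(sum(per_animal$censored),
            " animal(s) never reached the threshold; excluded from group means")
  usable <- per_animal[!per_animal$censored, , drop = FALSE]
  if (!"control" %in% usable$group)
    abort_radsyn("control group with >= 1 uncensored animal required",
                 "radsyn_validation_error")
  grp <- split(usable$growth_time, usable$group)
  grp <- grp[lengths(grp) > 0]
  means <- vapply(grp, mean, numeric(1))
  ctrl <- means[["control"]]
  printed <- config$precision_mode == "printed"
  rate <- means / ctrl
  if (printed) rate <- round_half_away(rate, 2)
  out <- data.frame(
    group = names(means),
    n = vapply(grp, length, integer(1)),
    n_censored = vapply(names(means), function(g)
      sum(per_animal$censored[per_animal$group == g]), integer(1)),
    mean_growth_time = unname(means),
    delay_time = unname(means - ctrl),
    time_ratio_rate = unname(rate),
    row.names = NULL
  )
  out$enhancement_vs_drug <- NA_real_
  out$enhancement_vs_radiation <- NA_real_
  if ("combination" %in% out$group) {
    i <- match("combination", out$group)
    er <- function(single) {
      j <- match(single, out$group)
      if (is.na(j)) return(NA_real_)
      r <- out$time_ratio_rate[i] / out$time_ratio_rate[j]
      if (printed) round_half_away(r, 2) else r
    }
    out$enhancement_vs_drug[i] <- er("drug")
    out$enhancement_vs_radiation[i] <- er("radiation")
  }
  ord <- order(match(out$group, .radsyn_groups))
  out <- out[ord, ]
  rownames(out) <- NULL
  out
}

#' Volume-based tumor growth inhibition rate
#'
#' `(1 - treated / control) * 100` on group mean volumes at a stated day.
#' In printed mode the result is rounded to the nearest whole percent,
#' half away from zero. A treated mean exceeding the control yields a
#' negative rate (growth promotion), which is allowed.
#'
#' Note this is a different quantity from the time-ratio rate of
#' [growth_summaries()]; the two are never interchanged.
#'
#' @param group_mean_volume treated-group mean volume (mm^3).
#' @param control_mean_volume control-group mean volume (mm^3, > 0).
#' @param config a [run_config()].
#' @return inhibition rate in percent.
#' @examples
#' volume_inhibition_rate(490, 2200, run_config(precision_mode = "printed"))  # 78
#' @export
volume_inhibition_rate <- function(group_mean_volume, control_mean_volume,
                                   config = run_config()) {
  if (any(control_mean_volume <= 0))
    abort_radsyn("control mean volume must be > 0", "radsyn_validation_error")
  rate <- (1 - group_mean_volume / control_mean_volume) * 100
  if (config$precision_mode == "printed") round_half_away(rate, 0) else rate
}

#' Bliss-expected inhibition rate of a combination
#'
#' For single-agent inhibition rates `r_a`, `r_b` (as fractions), the Bliss
#' independence expectation for the combination is
#' `r_a + r_b - r_a * r_b` — equivalently `1 - (1 - r_a)(1 - r_b)`. Inputs
#' and output are percentages; printed mode rounds the inputs to whole
#' percent before combining and the output to whole percent after.
#'
#' @param rate_a,rate_b single-agent inhibition rates in percent, in
#'   \[0, 100\].
#' @param config a [run_config()].
#' @return expected combination inhibition rate in percent.
#' @examples
#' bliss_expected_rate(33, 54, run_config(precision_mode = "printed"))  # 69
#' @export
bliss_expected_rate <- function(rate_a, rate_b, config = run_config()) {
  if (any(c(rate_a, rate_b) < 0) || any(c(rate_a, rate_b) > 100))
    abort_radsyn("rates must lie in [0, 100] percent", "radsyn_validation_error")
  printed <- config$precision_mode == "printed"
  if (printed) {
    rate_a <- round_half_away(rate_a, 0)
    rate_b <- round_half_away(rate_b, 0)
  }
  ra <- rate_a / 100; rb <- rate_b / 100
  expected <- (ra + rb - ra * rb) * 100
  if (printed) round_half_away(expected, 0) else expected
}

#' Combination index from observed and Bliss-expected inhibition rates
#'
#' `CI = (1 - observed/100) / (1 - expected/100)`. CI < 1 indicates
#' synergism, CI = 1 additivity, CI > 1 antagonism. Printed mode rounds the
#' index to two decimals.
#'
#' @param observed_rate combination-group inhibition rate in percent.
#' @param expected_rate Bliss-expected rate in percent, < 100.
#' @param config a [run_config()].
#' @return list with `ci` and `classification`.
#' @examples
#' combination_index(78, 69, run_config(precision_mode = "printed"))$ci  # 0.71
#' @export
combination_index <- function(observed_rate, expected_rate, config = run_config()) {
  if (any(expected_rate >= 100))
    abort_radsyn("expected rate of 100% makes the combination index undefined",
                 "radsyn_validation_error")
  ci <- (1 - observed_rate / 100) / (1 - expected_rate / 100)
  if (config$precision_mode == "printed") ci <- round_half_away(ci, 2)
  classification <- ifelse(ci < 1, "synergism", ifelse(ci > 1, "antagonism", "additivity"))
  list(ci = ci, classification = classification)
}

#' Volume-based inhibition summary with Bliss expectation and CI
#'
#' Runs the volume-based chain at a stated evaluation day: group mean volumes
#' (trajectories must contain a measurement at `day`; the group mean is taken
#' over animals measured on that day), per-group inhibition rates versus
#' control, the Bliss-expected rate for the combination from the drug-alone
#' and radiation-alone rates, and the combination index.
#'
#' @param trajectories list from [tumor_trajectories()].
#' @param day evaluation day (e.g. 26).
#' @param config a [run_config()].
#' @return data frame, one row per group: `group`, `n`, `mean_volume_mm3`,
#'   `inhibition_rate`, `expected_rate`, `combination_index`.
#' @export
inhibition_summaries <- function(trajectories, day, config = run_config()) {
  rows <- do.call(rbind, lapply(trajectories, function(tr) {
    i <- match(day, tr$day)
    if (is.na(i)) return(NULL)
    data.frame(group = tr$group[1], volume = tr$volume_mm3[i])
  }))
  if (is.null(rows) || !"control" %in% rows$group)
    abort_radsyn(sprintf("no control-group measurement at day %s", day),
                 "radsyn_validation_error")
  grp <- split(rows$volume, rows$group)
  grp <- grp[lengths(grp) > 0]
  means <- vapply(grp, mean, numeric(1))
  out <- data.frame(group = names(means),
                    n = vapply(grp, length, integer(1)),
                    mean_volume_mm3 = unname(means),
                    row.names = NULL)
  out$inhibition_rate <- ifelse(
    out$group == "control", NA_real_,
    volume_inhibition_rate(out$mean_volume_mm3, means[["control"]], config))
  out$expected_rate <- NA_real_
  out$combination_index <- NA_real_
  singles <- c(drug = "drug", radiation = "radiation")
  if ("combination" %in% out$group &&
      all(singles %in% out$group)) {
    i <- match("combination", out$group)
    ra <- out$inhibition_rate[match("drug", out$group)]
    rb <- out$inhibition_rate[match("radiation", out$group)]
    if (ra >= 0 && rb >= 0) {
      out$expected_rate[i] <- bliss_expected_rate(ra, rb, config)
      out$combination_index[i] <-
        combination_index(out$inhibition_rate[i], out$expected_rate[i], config)$ci
    }
  }
  ord <- order(match(out$group, .radsyn_groups))
  out <- out[ord, ]
  rownames(out) <- NULL
  out
}
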