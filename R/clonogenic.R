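#' Plating efficiency from untreated clonogenic plates
#'
#' PE is the pooled ratio of total colonies to total cells plated over the
#' untreated (0 Gy, 0 uM) replicates. Pooling the counts (ratio of totals)
#' rather than averaging per-replicate ratios is the minimum-variance choice
#' for Poisson-distributed colony counts.
#'
#' @param records data frame in the `clonogenic` schema.
#' @return plating efficiency in (0, 1].
#' @examples
#' rec <- data.frame(radiation_gy = 0, drug_um = 0, cells_plated = c(200, 200),
#'                   colonies = c(90, 110), replicate = 1:2)
#' plating_efficiency(rec)  # 0.5
#' @export
plating_efficiency <- function(records) {
  records <- validate_assay_table(records, "clonogenic")
  untreated <- records[records$radiation_gy == 0 & records$drug_um == 0, , drop = FALSE]
  if (nrow(untreated) == 0L)
    abort_radsyn("no untreated (0 Gy, 0 uM) record to estimate plating efficiency",
                 "radsyn_validation_error")
  total_col <- sum(untreated$colonies)
  if (total_col == 0L)
    abort_radsyn("zero colonies in all untreated plates; surviving fractions undefined",
                 "radsyn_validation_error")
  total_col / sum(untreated$cells_plated)
}

#' Surviving fractions per treatment condition
#'
#' For each `(radiation_gy, drug_um)` condition, per-replicate surviving
#' fractions `SF = colonies / (cells_plated * PE)` are averaged, with a
#' standard error when replicated. Conditions are labelled `radiation_only`,
#' `drug_only`, `combination`, or `untreated`. `sf = 0` rows (no colonies)
#' are kept but flagged `below_detection`; log-domain fitting excludes them.
#'
#' @param records data frame in the `clonogenic` schema.
#' @param pe plating efficiency, typically from [plating_efficiency()]; taken
#'   from the same records when omitted.
#' @return data frame with columns `radiation_gy`, `drug_um`, `condition`,
#'   `sf`, `se_sf`, `n`, `below_detection`.
#' @export
surviving_fractions <- function(records, pe = plating_efficiency(records)) {
  records <- validate_assay_table(records, "clonogenic")
  if (!is_number(pe) || pe <= 0)
    abort_radsyn("plating efficiency must be > 0", "radsyn_validation_error")
  sf_rep <- records$colonies / (records$cells_plated * pe)
  key <- paste(records$radiation_gy, records$drug_um, sep = "\r")
  agg <- split(sf_rep, key)
  first <- !duplicated(key)
  out <- data.frame(
    radiation_gy = records$radiation_gy[first],
    drug_um = records$drug_um[first],
    sf = vapply(agg, mean, numeric(1))[unique(key)],
    se_sf = vapply(agg, function(x)
      if (length(x) > 1L) stats::sd(x) / sqrt(length(x)) else 0, numeric(1))[unique(key)],
    n = vapply(agg, length, integer(1))[unique(key)],
    row.names = NULL
  )
  out$condition <- ifelse(out$radiation_gy > 0 & out$drug_um > 0, "combination",
                   ifelse(out$radiation_gy > 0, "radiation_only",
                   ifelse(out$drug_um > 0, "drug_only", "untreated")))
  out$below_detection <- out$sf == 0
  out[order(out$drug_um, out$radiation_gy), ]
}

#' Classify one dose level by the Bliss multiplicativity criterion
#'
#' Under Bliss independence two independently acting agents satisfy
#' `SF_observed = SF_radiation * SF_drug`. The verdict is `synergism` when
#' the observed combined surviving fraction falls below
#' `(1 - tolerance) * SF_r * SF_c`, `antagonism` when it exceeds
#' `(1 + tolerance) * SF_r * SF_c`, and `additivity` otherwise. The default
#' tolerance is 0: plain comparison of the stored numbers, which is how
#' published synergy tables are read.
#'
#' @param sf_r surviving fraction under radiation alone, in (0, 1].
#' @param sf_c surviving fraction under drug alone, in (0, 1].
#' @param sf_observed surviving fraction under the combination, in (0, 1].
#' @param radiation_gy optional dose label carried into the output.
#' @param tolerance relative dead band around the Bliss product (default 0).
#' @return one-row data frame (`radiation_gy`, `sf_r`, `sf_c`,
#'   `bliss_product`, `sf_observed`, `verdict`); vectorized over its inputs.
#' @examples
#' classify_bliss(0.26, 0.5, 0.06)  # synergism (product 0.13)
#' @export
classify_bliss <- function(sf_r, sf_c, sf_observed, radiation_gy = NA_real_,
                           tolerance = 0) {
  vals <- c(sf_r, sf_c, sf_observed)
  if (any(!is.finite(vals)) || any(vals <= 0) || any(vals > 1))
    abort_radsyn("surviving fractions must lie in (0, 1]", "radsyn_validation_error")
  if (tolerance < 0)
    abort_radsyn("tolerance must be >= 0", "radsyn_validation_error")
  product <- sf_r * sf_c
  verdict <- ifelse(sf_observed < (1 - tolerance) * product, "synergism",
             ifelse(sf_observed > (1 + tolerance) * product, "antagonism",
                    "additivity"))
  data.frame(radiation_gy = radiation_gy, sf_r = sf_r, sf_c = sf_c,
             bliss_product = product, sf_observed = sf_observed,
             verdict = verdict)
}

#' Synergy table from clonogenic records
#'
#' Runs the whole clonogenic chain: plating efficiency, surviving fractions,
#' then per-radiation-dose Bliss classification of the combination arm
#' against radiation-alone and drug-alone.
#'
#' @inheritParams surviving_fractions
#' @param tolerance passed to [classify_bliss()].
#' @return data frame, one row per radiation dose present in both the
#'   radiation-alone and combination arms.
#' @export
synergy_table <- function(records, tolerance = 0) {
  sf <- surviving_fractions(records)
  drug <- sf[sf$condition == "drug_only", , drop = FALSE]
  if (nrow(drug) == 0L)
    abort_radsyn("no drug-only (0 Gy, drug > 0) condition present",
                 "radsyn_validation_error")
  sf_c <- drug$sf[1]
  rad <- sf[sf$condition == "radiation_only", , drop = FALSE]
  comb <- sf[sf$condition == "combination", , drop = FALSE]
  doses <- intersect(rad$radiation_gy, comb$radiation_gy)
  if (length(doses) == 0L)
    abort_radsyn("no radiation dose shared by radiation-alone and combination arms",
                 "radsyn_validation_error")
  doses <- sort(doses)
  sf_r <- rad$sf[match(doses, rad$radiation_gy)]
  sf_rc <- comb$sf[match(doses, comb$radiation_gy)]
  classify_bliss(sf_r, sf_c, sf_rc, radiation_gy = doses, tolerance = tolerance)
}

#' Infer the drug-only surviving fraction from a published synergy row
#'
#' Synergy tables sometimes print the radiation-alone fraction and the Bliss
#' product but not the drug-alone fraction itself; it is recoverable as
#' `product / SF_r`. This helper documents that inference.
#'
#' @param sf_r printed radiation-alone surviving fraction(s).
#' @param bliss_product printed product column.
#' @return implied drug-only surviving fraction(s).
#' @export
infer_drug_sf <- function(sf_r, bliss_product) {
  if (any(sf_r <= 0)) abort_radsyn("sf_r must be > 0", "radsyn_validation_error")
  bliss_product / sf_r
}

#' Fit the linear-quadratic survival model
#'
#' Least-squares fit of `ln SF = -alpha * D - beta * D^2` through the origin,
#' with both coefficients clipped at zero. Points with `sf = 0` are excluded
#' (log undefined); at least 3 positive-SF dose levels are required.
#'
#' When the surviving fractions derive from colony counts, pass the counts
#' (or any quantity proportional to them) as `weights`: the sampling variance
#' of `ln SF` under Poisson counting is approximately `1 / colonies`, so
#' weighting by counts is the inverse-variance fit and stops the scarce
#' high-dose colonies from dominating the log-scale regression.
#'
#' @param radiation_gy radiation doses (Gy).
#' @param sf surviving fractions at those doses.
#' @param weights optional non-negative regression weights (e.g. colony
#'   counts); `NULL` for ordinary least squares.
#' @return list with elements `alpha` (1/Gy) and `beta` (1/Gy^2).
#' @export
fit_lq <- function(radiation_gy, sf, weights = NULL) {
  keep <- is.finite(sf) & sf > 0 & is.finite(radiation_gy)
  if (!is.null(weights)) keep <- keep & is.finite(weights) & weights > 0
  d <- radiation_gy[keep]; s <- sf[keep]
  w <- if (is.null(weights)) rep(1, length(d)) else weights[keep]
  if (length(unique(d)) < 3L)
    abort_radsyn("LQ fit needs >= 3 dose levels with sf > 0", "radsyn_fit_error")
  y <- log(s)
  fit <- stats::lm(y ~ 0 + I(-d) + I(-d^2), weights = w)
  co <- stats::coef(fit)
  list(alpha = max(unname(co[1]), 0), beta = max(unname(co[2]), 0))
}

#' Evaluate the linear-quadratic model
#'
#' @param dose_gy radiation dose(s) in Gy.
#' @param alpha,beta LQ coefficients (1/Gy, 1/Gy^2).
#' @return surviving fraction `exp(-alpha * D - beta * D^2)`.
#' @export
lq_survival <- function(dose_gy, alpha, beta) {
  exp(-alpha * dose_gy - beta * dose_gy^2)
}

#' Cell-culture doubling time
#'
#' `T_d = (t - t0) * ln 2 / (ln N - ln N0)` over a window of the exponential
#' growth phase.
#'
#' @param times hours post-seeding, strictly increasing.
#' @param counts viable cell counts, positive.
#' @param window length-2 index pair `(i0, i)` selecting `t0` and `t`;
#'   defaults to the first and last point.
#' @return doubling time in the units of `times`.
#' @examples
#' doubling_time(c(12, 48), c(1e5, 8e5))  # 12
#' @export
doubling_time <- function(times, counts, window = c(1L, length(times))) {
  if (any(diff(times) <= 0))
    abort_radsyn("times must be strictly increasing", "radsyn_validation_error")
  if (any(counts <= 0))
    abort_radsyn("counts must be positive", "radsyn_validation_error")
  i0 <- window[1]; i1 <- window[2]
  t0 <- times[i0]; t1 <- times[i1]
  n0 <- counts[i0]; n1 <- counts[i1]
  if (!(t1 > t0) || !(n1 > n0))
    abort_radsyn("window must have increasing time and count", "radsyn_validation_error")
  (t1 - t0) * log(2) / (log(n1) - log(n0))
}
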