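#' Simulation configuration with known ground truth
#'
#' Collects every generator parameter in one object so that simulated
#' datasets carry their own truth for parameter-recovery and calibration
#' tests. The defaults describe a plausible radiosensitizer study in a
#' syngeneic colon-carcinoma model:
#'
#' * clonogenic survival follows the linear-quadratic model
#'   `SF(D) = exp(-alpha D - beta D^2)` with `alpha = 0.2` /Gy and
#'   `beta = 0.06` /Gy^2 (surviving fractions of roughly 0.53, 0.17, 0.035
#'   and 0.004 at 2/4/6/8 Gy), a drug-only surviving fraction of 0.5 at the
#'   working concentration, and a multiplicative Bliss `interaction` on the
#'   combination (1 = Bliss-null; < 1 = synergy; the realized combination
#'   SF is `SF(D) * drug_sf * interaction`);
#' * viability follows a 4-parameter logistic with midpoint 75 uM and Hill
#'   slope 2 over the 7-point dose panel 0-100 uM, rendered as 570/600 nm
#'   absorbance pairs by inverting the manufacturer's equation around fixed
#'   negative-control and 600 nm baselines;
#' * tumors grow as Gompertz curves `V(t) = v0 exp((a/b)(1 - e^(-bt)))`
#'   from 100 mm^3 at treatment start, calibrated so the control arm reaches
#'   about 2200 mm^3 on day 26; single-agent arms scale the growth
#'   coefficient `a` by `group_multipliers` (defaults reach about 1000 and
#'   1500 mm^3), and the combination multiplier is derived so that day-26
#'   volume inhibition deviates from the Bliss expectation exactly by
#'   `interaction`;
#' * animals are measured twice weekly, with multiplicative lognormal
#'   measurement noise of coefficient of variation `volume_noise_cv`.
#'
#' One master `seed` drives a separate pseudo-random stream per assay, so
#' adding draws to one simulator does not perturb another's output.
#'
#' @param seed master integer seed.
#' @param lq_alpha,lq_beta LQ coefficients (1/Gy, 1/Gy^2), both >= 0.
#' @param drug_sf drug-only surviving fraction in (0, 1].
#' @param interaction multiplicative deviation from Bliss (> 0).
#' @param pe plating efficiency in (0, 1].
#' @param n_plated cells plated per dish.
#' @param replicates dishes per condition.
#' @param radiation_doses Gy panel for the clonogenic grid.
#' @param drug_dose_um working drug concentration (uM).
#' @param viability_doses uM panel for the plate.
#' @param viability_4pl named vector `c(top, bottom, ic50, hill)` in percent
#'   / percent / uM / dimensionless.
#' @param absorbance_noise_sd Gaussian noise sd on absorbances.
#' @param negctrl_a570,negctrl_a600 negative-control absorbances.
#' @param a600_baseline fixed 600 nm test-well baseline.
#' @param wells_per_dose replicate wells per dose.
#' @param gompertz named vector `c(v0, a, b)`: mm^3, 1/day, 1/day.
#' @param group_multipliers named vector with elements `radiation` and
#'   `drug`: multipliers on the Gompertz `a`.
#' @param eval_day day the volume-based endpoints are read (default 26).
#' @param measurement_days caliper schedule (days post-treatment).
#' @param volume_noise_cv lognormal measurement CV (fraction).
#' @param n_animals animals per group.
#' @param cohort_effects data frame `analyte, group, mean, sd` of cohort
#'   ground truth; see [default_cohort_effects()].
#' @return an object of class `radsyn_simconfig` (named list).
#' @export
simulation_config <- function(seed = 1L,
                              lq_alpha = 0.2, lq_beta = 0.06,
                              drug_sf = 0.5, interaction = 1,
                              pe = 0.7, n_plated = 500L, replicates = 3L,
                              radiation_doses = c(0, 2, 4, 6, 8),
                              drug_dose_um = 75,
                              viability_doses = c(0, 1, 20, 50, 75, 85, 100),
                              viability_4pl = c(top = 100, bottom = 0, ic50 = 75, hill = 2),
                              absorbance_noise_sd = 0.01,
                              negctrl_a570 = 0.05, negctrl_a600 = 0.25,
                              a600_baseline = 0.15,
                              wells_per_dose = 3L,
                              gompertz = c(v0 = 100, a = 0.2124556, b = 0.05),
                              group_multipliers = c(radiation = 0.7449290, drug = 0.8761077),
                              eval_day = 26,
                              measurement_days = c(0, 3, 7, 10, 14, 17, 21, 24, 26),
                              volume_noise_cv = 0.2,
                              n_animals = 6L,
                              cohort_effects = default_cohort_effects()) {
  if (lq_alpha < 0 || lq_beta < 0 || (lq_alpha == 0 && lq_beta == 0))
    abort_radsyn("lq_alpha/lq_beta must be >= 0 and not both 0", "radsyn_config_error")
  if (drug_sf <= 0 || drug_sf > 1 || pe <= 0 || pe > 1)
    abort_radsyn("drug_sf and pe must lie in (0, 1]", "radsyn_config_error")
  if (interaction <= 0)
    abort_radsyn("interaction must be > 0", "radsyn_config_error")
  if (gompertz[["b"]] <= 0)
    abort_radsyn("Gompertz b must be > 0 (use a small b for near-exponential growth)",
                 "radsyn_config_error")
  if (absorbance_noise_sd < 0 || volume_noise_cv < 0)
    abort_radsyn("noise parameters must be >= 0", "radsyn_config_error")
  structure(as.list(environment()), class = "radsyn_simconfig")
}

# internal: one deterministic RNG stream per assay, derived from the master seed
.seed_stream <- function(config, stream) {
  offset <- c(clonogenic = 1001L, viability = 2002L, tumor = 3003L, cohort = 4004L)[[stream]]
  set.seed((as.integer(config$seed) %% 1000000L) * 1000L + offset)
}

#' Simulate a clonogenic assay
#'
#' Generates the full dose grid `radiation_doses x {0, drug_dose_um}`. True
#' surviving fractions are LQ for radiation alone, `drug_sf` for drug alone,
#' and `SF(D) * drug_sf * interaction` for the combination. Colony counts are
#' `Poisson(n_plated * pe * SF)` (or the rounded expectation with
#' `sampling = "expected"`, the noiseless mode).
#'
#' @param config a [simulation_config()].
#' @param sampling `"poisson"` (default) or `"expected"`.
#' @return data frame in the `clonogenic` schema, with the generating truth
#'   attached as attribute `truth`.
#' @export
simulate_clonogenic <- function(config = simulation_config(),
                                sampling = c("poisson", "expected")) {
  sampling <- match.arg(sampling)
  .seed_stream(config, "clonogenic")
  grid <- expand.grid(radiation_gy = config$radiation_doses,
                      drug_um = c(0, config$drug_dose_um),
                      replicate = seq_len(config$replicates))
  sf_true <- with(grid, {
    sfr <- lq_survival(radiation_gy, config$lq_alpha, config$lq_beta)
    ifelse(drug_um > 0 & radiation_gy > 0, sfr * config$drug_sf * config$interaction,
    ifelse(drug_um > 0, config$drug_sf, sfr))
  })
  mu <- config$n_plated * config$pe * sf_true
  if (any(mu > config$n_plated))
    abort_radsyn("expected colony count exceeds cells plated; lower pe or SF",
                 "radsyn_config_error")
  colonies <- if (sampling == "poisson") stats::rpois(nrow(grid), mu) else round(mu)
  out <- data.frame(radiation_gy = grid$radiation_gy, drug_um = grid$drug_um,
                    cells_plated = config$n_plated,
                    colonies = pmin(colonies, config$n_plated),
                    replicate = grid$replicate)
  attr(out, "truth") <- list(alpha = config$lq_alpha, beta = config$lq_beta,
                             drug_sf = config$drug_sf, interaction = config$interaction,
                             pe = config$pe, sf_true = sf_true)
  out
}

#' Simulate an alamarBlue viability plate
#'
#' True viability comes from the 4PL at each panel dose. The negative-control
#' pair and the test-well 600 nm baseline are fixed; the 570 nm absorbance is
#' obtained by inverting the manufacturer's viability equation, so the
#' noiseless plate passed through [compute_viability()] returns the 4PL
#' values exactly. Gaussian noise of sd `absorbance_noise_sd` is then added
#' to both test-well absorbances.
#'
#' @param config a [simulation_config()].
#' @param run_cfg a [run_config()] supplying the viability coefficients.
#' @return data frame in the `viability` schema with attribute `truth`.
#' @export
simulate_viability_plate <- function(config = simulation_config(),
                                     run_cfg = run_config()) {
  .seed_stream(config, "viability")
  p <- config$viability_4pl
  if (p[["ic50"]] < min(config$viability_doses[config$viability_doses > 0]) ||
      p[["ic50"]] > max(config$viability_doses))
    warning("4PL midpoint lies outside the dose span; IC50 will not be estimable")
  doses <- rep(config$viability_doses, each = config$wells_per_dose)
  v_true <- p[["bottom"]] + (p[["top"]] - p[["bottom"]]) /
    (1 + (doses / p[["ic50"]])^p[["hill"]])
  cf <- run_cfg$viability_coefficients
  den <- cf[3] * config$negctrl_a600 - cf[4] * config$negctrl_a570
  a600 <- rep(config$a600_baseline, length(doses))
  a570 <- (v_true / 100 * den + cf[2] * a600) / cf[1]
  if (config$absorbance_noise_sd > 0) {
    a570 <- a570 + stats::rnorm(length(a570), 0, config$absorbance_noise_sd)
    a600 <- a600 + stats::rnorm(length(a600), 0, config$absorbance_noise_sd)
  }
  test <- data.frame(
    well_id = sprintf("D%02d_r%d", rep(seq_along(config$viability_doses),
                                       each = config$wells_per_dose),
                      rep(seq_len(config$wells_per_dose),
                          length(config$viability_doses))),
    dose_um = doses, a570 = a570, a600 = a600, is_negative_control = FALSE)
  nc <- data.frame(well_id = "NC_1", dose_um = 0,
                   a570 = config$negctrl_a570, a600 = config$negctrl_a600,
                   is_negative_control = TRUE)
  out <- rbind(test, nc)
  attr(out, "truth") <- list(viability_4pl = p, viability_true = v_true)
  out
}

#' Simulate tumor-growth trajectories for a five-group study
#'
#' Gompertz growth per animal with group-specific multipliers on the growth
#' coefficient. The combination multiplier is derived in closed form so that
#' the expected day-`eval_day` volume satisfies
#' `V_comb / V_ctrl = (V_rad / V_ctrl) * (V_drug / V_ctrl) * interaction`,
#' i.e. the volume-based combination index equals `interaction` exactly in
#' the noiseless limit. Measurement noise is multiplicative lognormal with
#' mean 1 and CV `volume_noise_cv`. Caliper triplets are emitted by
#' factoring each volume into length >= width >= height at aspect ratios
#' 1 : 0.8 : 0.6 perturbed by +/-10%, rescaled so the recorded dimensions
#' reproduce the volume exactly under the configured volume constant.
#'
#' @param config a [simulation_config()].
#' @param run_cfg a [run_config()] (volume constant used for the caliper
#'   factoring).
#' @return data frame in the `caliper` schema (groups control / radiation /
#'   drug / combination) with attribute `truth` carrying the multipliers and
#'   expected day-`eval_day` volumes.
#' @export
simulate_tumor_growth <- function(config = simulation_config(),
                                  run_cfg = run_config()) {
  .seed_stream(config, "tumor")
  g <- config$gompertz
  Td <- config$eval_day
  shape <- (1 - exp(-g[["b"]] * Td)) / g[["b"]]  # integral factor at eval day
  ln_ctrl <- g[["a"]] * shape                    # ln(V_ctrl(T) / v0)
  m <- c(control = 1,
         radiation = config$group_multipliers[["radiation"]],
         drug = config$group_multipliers[["drug"]])
  v_T <- g[["v0"]] * exp(m * ln_ctrl)
  v_comb_T <- v_T[["control"]] *
    (v_T[["radiation"]] / v_T[["control"]]) *
    (v_T[["drug"]] / v_T[["control"]]) * config$interaction
  m <- c(m, combination = log(v_comb_T / g[["v0"]]) / ln_ctrl)
  rows <- list()
  for (grp in names(m)) {
    for (i in seq_len(config$n_animals)) {
      tt <- config$measurement_days
      v <- g[["v0"]] * exp(m[[grp]] * g[["a"]] *
                             (1 - exp(-g[["b"]] * tt)) / g[["b"]])
      if (config$volume_noise_cv > 0) {
        s2 <- log(1 + config$volume_noise_cv^2)
        v <- v * stats::rlnorm(length(v), -s2 / 2, sqrt(s2))
      }
      dims <- .factor_volume(v, run_cfg$volume_constant)
      rows[[paste(grp, i)]] <- data.frame(
        animal_id = sprintf("%s_%02d", grp, i), group = grp, day = tt,
        length_mm = dims$L, width_mm = dims$W, height_mm = dims$H)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "truth") <- list(multipliers = m, expected_volumes = c(v_T, combination = v_comb_T),
                             interaction = config$interaction, eval_day = Td)
  out
}

# internal: factor volumes into caliper triplets with jittered aspect ratios
.factor_volume <- function(v, constant) {
  n <- length(v)
  r1 <- 1 * stats::runif(n, 0.9, 1.1)
  r2 <- 0.8 * stats::runif(n, 0.9, 1.1)
  r3 <- 0.6 * stats::runif(n, 0.9, 1.1)
  s <- (v / (constant * r1 * r2 * r3))^(1 / 3)
  list(L = r1 * s, W = r2 * s, H = r3 * s)
}

#' Default ground-truth table for the cohort simulator
#'
#' Group means and standard deviations for the immune and toxicity readouts:
#' spleen index, CD4+/CD8+ T-lymphocyte percentages, cytokines (IL-12,
#' IL-18, IFN-gamma in pg/mL), body weight and serum biochemistry. Values
#' describe a tumor-bearing mouse cohort in which the tumor elevates the
#' spleen index and depresses T-lymphocyte fractions, and treatment partially
#' restores both.
#'
#' @return data frame with columns `analyte`, `group`, `mean`, `sd`.
#' @export
default_cohort_effects <- function() {
  groups <- c("normal", "control", "radiation", "drug", "combination")
  tbl <- list(
    spleen_index = list(mean = c(0.0040, 0.0075, 0.0070, 0.0055, 0.0050), cv = 0.10),
    CD4_percent  = list(mean = c(24.1, 13.6, 18.6, 21.9, 24.8), cv = 0.15),
    CD8_percent  = list(mean = c(17.1, 11.5, 13.6, 17.8, 20.5), cv = 0.15),
    IL12         = list(mean = c(60, 55, 90, 100, 120), cv = 0.20),
    IL18         = list(mean = c(200, 190, 210, 260, 300), cv = 0.20),
    IFNg         = list(mean = c(15, 14, 22, 25, 32), cv = 0.20),
    body_weight_g = list(mean = c(22, 23, 22, 22, 22), cv = 0.07),
    ALP = list(mean = c(170, 163, 195, 190, 193), cv = 0.15),
    ALB = list(mean = c(2.4, 2.3, 2.4, 2.1, 2.5), cv = 0.10),
    ALT = list(mean = c(45, 46, 54, 26, 47), cv = 0.30),
    AST = list(mean = c(180, 251, 187, 129, 165), cv = 0.40),
    BUN = list(mean = c(25, 33, 30, 31, 30), cv = 0.15),
    CRE = list(mean = c(0.45, 0.5, 0.5, 0.4, 0.4), cv = 0.20)
  )
  do.call(rbind, lapply(names(tbl), function(a)
    data.frame(analyte = a, group = groups, mean = tbl[[a]]$mean,
               sd = tbl[[a]]$mean * tbl[[a]]$cv)))
}

#' Simulate an animal cohort with immune and toxicity readouts
#'
#' Per-animal values are drawn from normal distributions truncated at zero
#' (negative draws are redrawn) with the group means and standard deviations
#' of `config$cohort_effects`. Spleen weights are reconstructed from the
#' drawn spleen index and body weight so the animal table is internally
#' consistent.
#'
#' @param config a [simulation_config()].
#' @return list with `animals` (the `animal` schema, biochemistry included)
#'   and `measurements` (long data frame `animal_id, group, analyte, value`
#'   for the non-biochemistry analytes), plus attribute `truth`.
#' @export
simulate_cohort <- function(config = simulation_config()) {
  .seed_stream(config, "cohort")
  eff <- config$cohort_effects
  if (any(eff$sd < 0))
    abort_radsyn("cohort effect sds must be >= 0", "radsyn_config_error")
  groups <- unique(eff$group)
  n <- config$n_animals
  ids <- unlist(lapply(groups, function(g) sprintf("%s_%02d", g, seq_len(n))))
  gvec <- rep(groups, each = n)
  draw <- function(analyte) {
    out <- numeric(length(ids))
    for (g in groups) {
      row <- eff[eff$analyte == analyte & eff$group == g, ]
      x <- stats::rnorm(n, row$mean, row$sd)
      while (any(x < 0)) x[x < 0] <- stats::rnorm(sum(x < 0), row$mean, row$sd)
      out[gvec == g] <- x
    }
    out
  }
  vals <- lapply(stats::setNames(unique(eff$analyte), unique(eff$analyte)), draw)
  animals <- data.frame(
    animal_id = ids, group = gvec,
    body_weight_g = vals$body_weight_g,
    spleen_weight_g = vals$spleen_index * vals$body_weight_g,
    alp = vals$ALP, alb = vals$ALB, alt = vals$ALT,
    ast = vals$AST, bun = vals$BUN, cre = vals$CRE)
  meas_analytes <- c("spleen_index", "CD4_percent", "CD8_percent",
                     "IL12", "IL18", "IFNg")
  measurements <- do.call(rbind, lapply(meas_analytes, function(a)
    data.frame(animal_id = ids, group = gvec, analyte = a, value = vals[[a]])))
  res <- list(animals = animals, measurements = measurements)
  attr(res, "truth") <- eff
  res
}
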