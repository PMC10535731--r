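test_that("every simulator is byte-deterministic under a fixed seed", {
  cfg <- simulation_config(seed = 99)
  expect_identical(simulate_clonogenic(cfg), simulate_clonogenic(cfg))
  expect_identical(simulate_viability_plate(cfg), simulate_viability_plate(cfg))
  expect_identical(simulate_tumor_growth(cfg), simulate_tumor_growth(cfg))
  expect_identical(simulate_cohort(cfg), simulate_cohort(cfg))
})

test_that("assays draw from independent named streams", {
  a <- simulation_config(seed = 4)
  b <- simulation_config(seed = 4, wells_per_dose = 6)  # extra viability draws
  expect_identical(simulate_clonogenic(a), simulate_clonogenic(b))
  expect_identical(simulate_tumor_growth(a), simulate_tumor_growth(b))
})

test_that("noiseless Bliss-null clonogenic data classify as additive", {
  cfg <- simulation_config(seed = 1, interaction = 1, n_plated = 200000L,
                           replicates = 1L)
  rec <- simulate_clonogenic(cfg, sampling = "expected")
  tab <- synergy_table(rec, tolerance = 0.01)
  expect_true(all(tab$verdict == "additivity"))
})

test_that("constructed synergy is detected at every dose", {
  cfg <- simulation_config(seed = 1, interaction = 0.5, n_plated = 200000L,
                           replicates = 1L)
  rec <- simulate_clonogenic(cfg, sampling = "expected")
  tab <- synergy_table(rec, tolerance = 0.01)
  expect_true(all(tab$verdict == "synergism"))
})

test_that("clonogenic truth attribute matches the generating model", {
  cfg <- simulation_config(seed = 2)
  rec <- simulate_clonogenic(cfg, sampling = "expected")
  sf <- surviving_fractions(rec)
  rad <- sf[sf$condition == "radiation_only", ]
  expect_equal(rad$sf, lq_survival(rad$radiation_gy, cfg$lq_alpha, cfg$lq_beta),
               tolerance = 0.05)
})

test_that("noiseless tumor growth with interaction 1 yields CI exactly 1", {
  cfg <- simulation_config(seed = 10, volume_noise_cv = 0, interaction = 1)
  trajs <- tumor_trajectories(simulate_tumor_growth(cfg))
  out <- inhibition_summaries(trajs, cfg$eval_day, run_config())
  expect_equal(out$combination_index[out$group == "combination"], 1,
               tolerance = 1e-9)
})

test_that("the interaction parameter is recovered as the noiseless CI", {
  cfg <- simulation_config(seed = 10, volume_noise_cv = 0, interaction = 0.7)
  trajs <- tumor_trajectories(simulate_tumor_growth(cfg))
  out <- inhibition_summaries(trajs, cfg$eval_day, run_config())
  expect_equal(out$combination_index[out$group == "combination"], 0.7,
               tolerance = 1e-9)
})

test_that("group-arm calibration reaches the intended day-26 volumes", {
  cfg <- simulation_config(seed = 10, volume_noise_cv = 0)
  truth <- attr(simulate_tumor_growth(cfg), "truth")
  expect_equal(unname(truth$expected_volumes["control"]), 2200, tolerance = 0.01)
  expect_equal(unname(truth$expected_volumes["radiation"]), 1000, tolerance = 0.01)
  expect_equal(unname(truth$expected_volumes["drug"]), 1500, tolerance = 0.01)
})

test_that("caliper factoring preserves volume under the configured constant", {
  cfg <- simulation_config(seed = 6, volume_noise_cv = 0)
  cal <- simulate_tumor_growth(cfg)
  v <- tumor_volume(cal$length_mm, cal$width_mm, cal$height_mm)
  g <- cfg$gompertz
  m <- attr(cal, "truth")$multipliers[cal$group]
  v_true <- g[["v0"]] * exp(m * g[["a"]] * (1 - exp(-g[["b"]] * cal$day)) / g[["b"]])
  expect_equal(v, unname(v_true), tolerance = 1e-9)
  # dimensions ordered length >= width >= height on average aspect 1:0.8:0.6
  expect_true(mean(cal$length_mm > cal$height_mm) > 0.99)
})

test_that("with true CI 0.7 at n = 6 the estimate detects synergy in most runs", {
  ci <- vapply(1:200, function(s) {
    cfg <- simulation_config(seed = s, interaction = 0.7, volume_noise_cv = 0.2)
    trajs <- tumor_trajectories(simulate_tumor_growth(cfg))
    out <- inhibition_summaries(trajs, cfg$eval_day, run_config())
    out$combination_index[out$group == "combination"]
  }, numeric(1))
  expect_gte(mean(ci < 1), 0.8)
})

test_that("cohort simulator returns configured means when sd is zero", {
  eff <- default_cohort_effects()
  eff$sd <- 0
  cfg <- simulation_config(seed = 3, cohort_effects = eff, n_animals = 3L)
  coh <- simulate_cohort(cfg)
  cd4 <- coh$measurements[coh$measurements$analyte == "CD4_percent", ]
  s <- summarize_groups(cd4$value, cd4$group, "CD4_percent")
  truth <- eff[eff$analyte == "CD4_percent", ]
  expect_equal(s$mean[match(truth$group, s$group)], truth$mean)
})

test_that("simulated cohorts recover their programmed group means", {
  cfg <- simulation_config(seed = 8, n_animals = 6L)
  coh <- simulate_cohort(cfg)
  eff <- attr(coh, "truth")
  for (a in c("CD4_percent", "spleen_index")) {
    m <- coh$measurements[coh$measurements$analyte == a, ]
    s <- summarize_groups(m$value, m$group, a)
    tr <- eff[eff$analyte == a, ]
    tr <- tr[match(s$group, tr$group), ]
    # within 4 standard errors of the generating mean
    expect_true(all(abs(s$mean - tr$mean) < 4 * tr$sd / sqrt(6)))
  }
  expect_true(all(coh$measurements$value >= 0))
  expect_true(all(coh$animals$spleen_weight_g < coh$animals$body_weight_g))
})

test_that("programmed relative spleen index is recovered from the cohort", {
  cfg <- simulation_config(seed = 12, n_animals = 30L)
  coh <- simulate_cohort(cfg)
  rsi <- relative_spleen_index(coh$animals)
  # programmed truth: control mean index 0.0075 vs normal 0.0040
  expect_equal(rsi$rsi[rsi$group == "control"], 0.0075 / 0.0040, tolerance = 0.1)
})

test_that("invalid simulation configurations are rejected", {
  expect_error(simulation_config(lq_alpha = 0, lq_beta = 0),
               class = "radsyn_config_error")
  expect_error(simulation_config(interaction = 0), class = "radsyn_config_error")
  expect_error(simulation_config(gompertz = c(v0 = 100, a = 0.2, b = 0)),
               class = "radsyn_config_error")
  expect_error(simulation_config(drug_sf = 1.5), class = "radsyn_config_error")
  expect_error(simulation_config(volume_noise_cv = -0.1),
               class = "radsyn_config_error")
})
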