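test_that("ellipsoid volume follows the caliper formula", {
  expect_equal(tumor_volume(10, 10, 10), 523)
  expect_equal(tumor_volume(10, 0, 10), 0)
  exact <- run_config(volume_constant = 4 * pi / 24)
  expect_equal(tumor_volume(10, 10, 10, exact), 4 / 3 * pi * 5^3, tolerance = 1e-12)
  expect_error(tumor_volume(-1, 2, 3), class = "radsyn_validation_error")
})

test_that("growth time interpolates log-linearly and flags censoring", {
  expect_equal(growth_time(c(0, 7), c(450, 900)), 0)  # already past threshold
  expect_equal(growth_time(c(7, 14), c(200, 800)), 10.5)
  cens <- growth_time(c(0, 7, 14), c(100, 150, 200))
  expect_true(is.na(cens))
  expect_true(attr(cens, "censored"))
})

test_that("growth time is monotone non-decreasing in the threshold", {
  days <- c(0, 3, 7, 10, 14)
  vols <- c(120, 180, 350, 600, 1100)
  ths <- seq(150, 1000, by = 50)
  gts <- vapply(ths, function(th) growth_time(days, vols, th), numeric(1))
  expect_true(all(diff(gts) >= 0))
})

test_that("printed-mode growth summaries reproduce rounded-ratio arithmetic", {
  trajs <- tumor_trajectories(make_growth_fixture())
  out <- growth_summaries(trajs, printed_cfg())
  # rows ordered control, radiation, drug, combination
  expect_equal(out$mean_growth_time, c(9, 16, 12, 25))
  expect_equal(out$delay_time, c(0, 7, 3, 16))
  expect_equal(out$time_ratio_rate, c(1.00, 1.78, 1.33, 2.78))
  comb <- out[out$group == "combination", ]
  expect_equal(comb$enhancement_vs_drug, 2.09)       # 2.78 / 1.33
  expect_equal(comb$enhancement_vs_radiation, 1.56)  # 2.78 / 1.78
})

test_that("full-precision growth summaries stay within 0.02 of printed values", {
  trajs <- tumor_trajectories(make_growth_fixture())
  out <- growth_summaries(trajs, run_config(precision_mode = "full"))
  comb <- out[out$group == "combination", ]
  expect_equal(comb$time_ratio_rate, 2.78, tolerance = 0.02 / 2.78)
  expect_equal(comb$enhancement_vs_drug, 2.09, tolerance = 0.02 / 2.09)
  expect_equal(comb$enhancement_vs_radiation, 1.56, tolerance = 0.02 / 1.56)
})

test_that("control compared with itself gives zero delay and unit rate", {
  ctrl <- tumor_trajectories(do.call(rbind, lapply(1:3, function(i)
    make_trajectory(paste0("c", i), "control", 9))))
  out <- growth_summaries(ctrl, printed_cfg())
  expect_equal(out$delay_time, 0)
  expect_equal(out$time_ratio_rate, 1)
})

test_that("censored animals are excluded from group means with a warning", {
  trajs <- tumor_trajectories(rbind(
    make_trajectory("c1", "control", 9),
    make_trajectory("d1", "drug", 12),
    data.frame(animal_id = "d2", group = "drug", day = c(0, 20),
               volume_mm3 = c(100, 150))))
  expect_warning(out <- growth_summaries(trajs, run_config()), "never reached")
  expect_equal(out$mean_growth_time[out$group == "drug"], 12)
  expect_equal(out$n_censored[out$group == "drug"], 1L)
})

test_that("volume inhibition rate matches the day-26 published arithmetic", {
  p <- printed_cfg()
  expect_equal(volume_inhibition_rate(490, 2200, p), 78)
  expect_equal(volume_inhibition_rate(1000, 1000, p), 0)
  # growth promotion: negative rate allowed
  expect_lt(volume_inhibition_rate(1200, 1000, p), 0)
  expect_error(volume_inhibition_rate(100, 0), class = "radsyn_validation_error")
})

test_that("Bliss expected rate is symmetric and algebraically consistent", {
  p <- printed_cfg()
  expect_equal(bliss_expected_rate(33, 54, p), 69)
  expect_equal(bliss_expected_rate(0, 40), 40)
  expect_equal(bliss_expected_rate(100, 37), 100)
  expect_error(bliss_expected_rate(105, 20), class = "radsyn_validation_error")
  full <- run_config()
  set.seed(11)
  for (i in 1:25) {
    ra <- runif(1, 0, 100); rb <- runif(1, 0, 100)
    expect_equal(bliss_expected_rate(ra, rb, full), bliss_expected_rate(rb, ra, full),
                 tolerance = 1e-12)
    expect_equal(bliss_expected_rate(ra, rb, full),
                 (1 - (1 - ra / 100) * (1 - rb / 100)) * 100, tolerance = 1e-9)
  }
})

test_that("combination index reproduces the published value and classifies", {
  p <- printed_cfg()
  res <- combination_index(78, 69, p)
  expect_equal(res$ci, 0.71)
  expect_equal(res$classification, "synergism")
  expect_equal(combination_index(50, 50)$ci, 1)
  expect_equal(combination_index(50, 50)$classification, "additivity")
  anti <- combination_index(50, 75)
  expect_equal(anti$ci, 2)
  expect_equal(anti$classification, "antagonism")
  expect_error(combination_index(90, 100), class = "radsyn_validation_error")
  # full precision differs from the printed CI by far less than 0.02
  full <- combination_index(78, bliss_expected_rate(33, 54, run_config()))$ci
  expect_equal(full, 0.71, tolerance = 0.02 / 0.71)
})

test_that("inhibition summaries chain volumes to expected rate and CI", {
  p <- printed_cfg()
  trajs <- tumor_trajectories(make_volume_fixture())
  out <- inhibition_summaries(trajs, 26, p)
  expect_equal(out$inhibition_rate[out$group == "radiation"], 55)
  expect_equal(out$inhibition_rate[out$group == "drug"], 32)
  comb <- out[out$group == "combination", ]
  expect_equal(comb$inhibition_rate, 78)
  expect_equal(comb$expected_rate, 69)
  expect_equal(comb$combination_index, 0.71)
})
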