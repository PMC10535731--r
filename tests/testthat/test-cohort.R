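test_that("spleen index is the weight ratio with guarded degenerate cases", {
  expect_equal(spleen_index(0.1, 20), 0.005)
  expect_equal(spleen_index(0, 20), 0)
  expect_warning(idx <- spleen_index(20, 20), "degenerate")
  expect_equal(idx, 1)
  expect_error(spleen_index(0.1, 0), class = "radsyn_validation_error")
})

test_that("relative spleen index anchors the normal group at exactly 1", {
  set.seed(5)
  for (i in 1:10) {
    animals <- data.frame(
      animal_id = sprintf("a%d", 1:9),
      group = rep(c("normal", "control", "drug"), each = 3),
      body_weight_g = runif(9, 18, 25),
      spleen_weight_g = runif(9, 0.05, 0.3))
    rsi <- relative_spleen_index(animals)
    expect_identical(rsi$rsi[rsi$group == "normal"], 1)
  }
  no_normal <- data.frame(animal_id = c("a", "b"), group = "control",
                          body_weight_g = c(20, 21), spleen_weight_g = c(0.1, 0.1))
  expect_error(relative_spleen_index(no_normal), "normal group")
})

test_that("a group with doubled mean index has RSI 2", {
  animals <- data.frame(
    animal_id = sprintf("a%d", 1:4),
    group = rep(c("normal", "control"), each = 2),
    body_weight_g = 20,
    spleen_weight_g = c(0.1, 0.1, 0.2, 0.2))
  rsi <- relative_spleen_index(animals)
  expect_equal(rsi$rsi[rsi$group == "control"], 2)
})

test_that("group summaries report mean and standard error", {
  out <- summarize_groups(c(10, 14), c("control", "control"))
  expect_equal(out$mean, 12)
  expect_equal(out$se, 2)  # sd = 2*sqrt(2), se = sd/sqrt(2)
  expect_equal(summarize_groups(rep(7, 4), rep("g", 4))$se, 0)
  single <- summarize_groups(5, "g")
  expect_true(is.na(single$se))
})

test_that("significance annotation agrees with the pooled-t closed form", {
  # independent oracle: pooled-variance two-sample t and its p-value by hand
  pooled_p <- function(x, y) {
    nx <- length(x); ny <- length(y)
    sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
    tstat <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
    2 * pt(-abs(tstat), nx + ny - 2)
  }
  set.seed(13)
  for (i in 1:20) {
    x <- rnorm(sample(3:8, 1), mean = runif(1, 0, 5))
    y <- rnorm(sample(3:8, 1), mean = runif(1, 0, 5))
    ann <- annotate_comparisons(c(x, y),
                                rep(c("drug", "control"), c(length(x), length(y))))
    expect_equal(ann$p_value, pooled_p(x, y), tolerance = 1e-10)
  }
})

test_that("glyph tiers follow the thresholds and are monotone in p", {
  cfg <- run_config()
  tier <- function(p) strrep("*", sum(p < cfg$significance_thresholds))
  expect_equal(tier(0.03), "*")
  expect_equal(tier(0.0005), "***")
  ps <- sort(runif(50))
  glyphs <- nchar(vapply(ps, tier, character(1)))
  expect_true(all(diff(glyphs) <= 0))  # smaller p never fewer glyphs

  # identical groups annotate as non-significant with empty symbol
  same <- annotate_comparisons(rep(c(1, 2, 3), 2),
                               rep(c("drug", "control"), each = 3))
  expect_equal(same$p_value, 1)
  expect_equal(same$symbol, "")

  # zero within-group variance with different means: p ~ 0, three glyphs
  sep <- annotate_comparisons(c(1, 1, 1, 9, 9, 9),
                              rep(c("control", "drug"), each = 3))
  expect_lt(sep$p_value, 1e-3)
  expect_equal(sep$symbol, "***")
})

test_that("each reference family uses its own glyph", {
  set.seed(21)
  vals <- c(rnorm(4, 0), rnorm(4, 10), rnorm(4, 20))
  grp <- rep(c("control", "radiation", "drug"), each = 4)
  ann <- annotate_comparisons(vals, grp, references = c("control", "radiation", "drug"))
  expect_true(all(grepl("^\\*+$", ann$symbol[ann$reference == "control"])))
  expect_true(all(grepl("^#+$", ann$symbol[ann$reference == "radiation"])))
  expect_true(all(grepl("^\\$+$", ann$symbol[ann$reference == "drug"])))
})

test_that("reference-range flags use inclusive boundaries", {
  ranges <- data.frame(analyte = c("ALP", "BUN"), low = c(62, 18),
                       high = c(209, 29), units = c("U/L", "mg/dL"))
  out <- flag_reference_ranges(c(ALP = 163, BUN = 33), ranges)
  expect_equal(out$flag, c("within", "above"))
  expect_equal(flag_reference_ranges(c(ALP = 209), ranges)$flag, "within")
  expect_equal(flag_reference_ranges(c(ALP = 62), ranges)$flag, "within")
  expect_warning(unk <- flag_reference_ranges(c(XYZ = 5), ranges), "no reference range")
  expect_true(is.na(unk$flag))
})
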