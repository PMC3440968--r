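test_that("repeat integration: background subtraction with floor, mean, CV, counts", {
  spots <- data.frame(probe_id = "mir-a", spot_index = 1:3, channel = "Cy3",
                      raw_signal = c(130, 110, 120))
  chip <- chip_data("c1", 20, 10, spots)
  integ <- integrate_repeats(chip)
  expect_equal(integ$integrated_signal, 100)          # mean(110, 90, 100)
  expect_equal(integ$repeat_cv, 0.1)                  # sd/mean, sample s.d.
  expect_equal(integ$n_repeats, 3L)
  expect_equal(integ$n_repeats_above, 3L)             # all > 3 * 10

  below <- chip_data("c2", 200, 10,
                     transform(spots, raw_signal = c(10, 20, 30)))
  integ <- integrate_repeats(below)
  expect_equal(integ$integrated_signal, 0)
  expect_equal(integ$repeat_cv, 0)
  expect_equal(integ$n_repeats_above, 0L)
})

test_that("detection call implements the three-condition rule with its boundaries", {
  # signal > 3 x background sd (strict), CV < 0.5 (strict),
  # >= 50% of repeats above level (inclusive)
  expect_true(detection_call(100, 0.2, 4L, 4L, 10))
  expect_false(detection_call(100, 0.6, 4L, 4L, 10))   # CV rule
  expect_false(detection_call(100, 0.2, 4L, 4L, 40))   # 100 <= 120
  expect_false(detection_call(120, 0.2, 4L, 4L, 40))   # exactly 3 x sd fails
  expect_false(detection_call(100, 0.5, 4L, 4L, 10))   # CV exactly 0.5 fails
  expect_true(detection_call(100, 0.2, 4L, 2L, 10))    # exactly 50% passes
  expect_false(detection_call(100, 0.2, 4L, 1L, 10))   # 25% fails
})

test_that("detection call is monotone in integrated signal", {
  withr::local_seed(1)
  for (i in 1:200) {
    sd_bg <- runif(1, 1, 50)
    cv <- runif(1, 0, 1)
    n <- 4L
    n_above <- sample(0:4, 1)
    sig <- sort(runif(2, 0, 300))
    low <- detection_call(sig[1], cv, n, n_above, sd_bg)
    high <- detection_call(sig[2], cv, n, n_above, sd_bg)
    expect_false(low && !high)
  }
})

test_that("LOWESS reproduces a line exactly and is constant on constants", {
  x <- seq(0, 10, length.out = 50)
  y <- 2 * x + 1
  for (span in c(0.2, 0.5, 1)) {
    expect_lt(max(abs(lowess_smooth(x, y, span = span) - y)), 1e-9)
  }
  expect_equal(lowess_smooth(x, rep(3.5, 50)), rep(3.5, 50))
  # degenerate x: mean of y everywhere
  expect_equal(lowess_smooth(rep(1, 10), 1:10), rep(5.5, 10))
})

test_that("robust LOWESS shrugs off a gross outlier, matching the reference smoother", {
  set.seed(7)
  x <- seq(0, 2 * pi, length.out = 60)
  y <- sin(x)
  y_dirty <- y
  y_dirty[30] <- y_dirty[30] + 5
  fit <- lowess_smooth(x, y_dirty, span = 0.3, iterations = 3)
  clean_fit <- lowess_smooth(x, y, span = 0.3, iterations = 3)
  expect_lt(abs(fit[30] - clean_fit[30]), 0.1)
  # independent reference: the classic Cleveland smoother in stats
  ref <- lowess(x, y_dirty, f = 0.3, iter = 3, delta = 0)
  expect_lt(max(abs(fit - ref$y)), 0.1)
})

test_that("a linear dye bias is removed to numerical precision", {
  cfg <- clean_config(seed = 4, dye_bias_amplitude = 0.6)
  design <- simulate_design(cfg)
  sim <- simulate_chips(design, cfg)
  for (chip in sim$chips[1:2]) {
    integ <- integrate_repeats(chip)
    norm <- normalize_chip(integ)
    wide <- split(norm$log2_value, norm$channel)
    m <- wide$Cy5 - wide$Cy3
    expect_lt(max(abs(m)), 1e-6)
  }
})

test_that("without dye bias the within-chip correction is a no-op up to centering", {
  cfg <- clean_config(seed = 6)
  design <- simulate_design(cfg)
  sim <- simulate_chips(design, cfg)
  chip <- sim$chips[[1]]
  integ <- integrate_repeats(chip)
  norm <- normalize_chip(integ)
  raw <- log2(integ$integrated_signal)
  expect_equal(norm$log2_value[norm$channel == "Cy3"],
               raw[integ$channel == "Cy3"], tolerance = 1e-9)
})

test_that("normalization is idempotent on noise-free data and medians sit at 0", {
  cfg <- clean_config(seed = 8, dye_bias_amplitude = 0.5,
                      frac_gender_effect = 0.1)
  design <- simulate_design(cfg)
  sim <- simulate_chips(design, cfg)
  chip <- sim$chips[[1]]
  integ <- integrate_repeats(chip)
  once <- normalize_chip(integ)
  # re-feed the corrected values as a fresh integration result
  integ2 <- integ
  ord <- order(integ$channel, integ$probe_id)
  stopifnot(identical(integ$probe_id[ord][integ$channel[ord] == "Cy3"],
                      once$probe_id[once$channel == "Cy3"]))
  integ2$integrated_signal[ord] <- 2^once$log2_value
  twice <- normalize_chip(integ2)
  expect_equal(twice$log2_value, once$log2_value, tolerance = 1e-6)

  mat <- build_expression_matrix(sim$chips, design)
  meds <- apply(mat$values, 2, median, na.rm = TRUE)
  expect_equal(unname(meds), rep(0, ncol(mat$values)), tolerance = 1e-9)
})

test_that("planted two-fold effects survive normalization within 0.1 log2", {
  cfg <- sim_config(seed = 10, n_probes = 100L, n_confirmed = 80L,
                    n_predicted = 20L, frac_gender_effect = 0.05,
                    frac_treatment_effect = 0, effect_size_log2 = 1,
                    noise_sd_log2 = 0.02, background_sd = 5)
  design <- simulate_design(cfg)
  sim <- simulate_chips(design, cfg)
  mat <- build_expression_matrix(sim$chips, design)
  res <- run_contrasts(mat, "gender_within_treatment")
  for (trt in cfg$treatments) {
    eff <- sim$truth$gender_effect[, trt]
    planted <- names(eff)[eff != 0]
    r <- res[res$contrast == paste0("F_vs_M:", trt), ]
    got <- r$log2_ratio[match(planted, r$probe_id)]
    expect_equal(got, unname(eff[planted]), tolerance = 0.1)
  }
})

test_that("chips with too few co-detected probes fall back to median-only normalization", {
  spots <- data.frame(probe_id = rep(sprintf("m%02d", 1:12), each = 2),
                      spot_index = rep(1:2, 12),
                      channel = "Cy3",
                      raw_signal = 500)
  spots5 <- transform(spots, channel = "Cy5",
                      raw_signal = c(rep(500, 8), rep(0, 16)))
  chip <- chip_data("sparse", 100, 10, rbind(spots, spots5))
  integ <- integrate_repeats(chip)
  expect_warning(norm <- normalize_chip(integ), "co-detected")
  expect_equal(sum(!is.na(norm$log2_value[norm$channel == "Cy5"])), 4)
})
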