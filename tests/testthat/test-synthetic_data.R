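test_that("design layout: one sample per gender x treatment x replicate, paired on chips", {
  design <- simulate_design(sim_config())
  expect_equal(nrow(design), 2 * 6 * 2)           # 24 samples
  expect_equal(length(unique(design$chip_id)), 12) # 12 chips
  # each chip carries exactly one Cy3 and one Cy5 sample of one condition
  for (chip in unique(design$chip_id)) {
    rows <- design[design$chip_id == chip, ]
    expect_setequal(rows$channel, c("Cy3", "Cy5"))
    expect_equal(length(unique(rows$gender)), 1)
    expect_equal(length(unique(rows$treatment)), 1)
  }
})

test_that("default condition set has the six study treatments, control first", {
  trts <- default_treatments()
  expect_length(trts, 6)
  expect_equal(trts[1], "control")
  expect_setequal(trts, c("control", "PE_fed", "saline_inj", "PGN_inj",
                          "heat", "hunger"))
})

test_that("invalid configurations are rejected naming the offending field", {
  expect_error(sim_config(n_bio_replicates = 1), "n_bio_replicates")
  expect_error(sim_config(n_confirmed = 100, n_predicted = 100,
                          n_probes = 150), "n_confirmed")
  expect_error(sim_config(noise_sd_log2 = -1), "noise_sd_log2")
  expect_error(sim_config(frac_gender_effect = 1.5), "frac_gender_effect")
  expect_error(sim_config(treatments = c("a", "a")), "treatments")
})

test_that("annotation catalogue has the confirmed/predicted split and miRBase-style ids", {
  ann <- simulate_annotation(sim_config())
  expect_equal(nrow(ann), 455)
  expect_equal(sum(ann$status == "confirmed"), 386)
  expect_equal(sum(ann$status == "predicted"), 69)
  expect_false(anyDuplicated(ann$probe_id) > 0)
  expect_true(all(grepl("^C_", ann$probe_id[ann$status == "predicted"])))
  expect_true(all(grepl("-miR-", ann$probe_id)))
})

test_that("identical configs produce byte-identical study files", {
  cfg <- small_config(seed = 11, frac_gender_effect = 0.1)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_study(cfg, d1)
  simulate_study(cfg, d2)
  f1 <- sort(list.files(d1, recursive = TRUE))
  expect_gt(length(f1), 3)
  expect_identical(f1, sort(list.files(d2, recursive = TRUE)))
  for (f in f1) {
    expect_identical(readBin(file.path(d1, f), "raw", 2e6),
                     readBin(file.path(d2, f), "raw", 2e6),
                     info = f)
  }
})

test_that("null simulation: no planted effects, no noise -> all within-chip log2 ratios are 0", {
  cfg <- clean_config()
  design <- simulate_design(cfg)
  sim <- simulate_chips(design, cfg)
  for (chip in sim$chips[1:3]) {
    integ <- integrate_repeats(chip)
    wide <- split(integ$integrated_signal, integ$channel)
    expect_equal(log2(wide$Cy5) - log2(wide$Cy3), rep(0, cfg$n_probes),
                 tolerance = 1e-12)
  }
})

test_that("planted gender effect plumbs through to the female-vs-male ratio", {
  cfg <- clean_config(seed = 3, frac_gender_effect = 0.1,
                      effect_size_log2 = 1)
  design <- simulate_design(cfg)
  sim <- simulate_chips(design, cfg)
  mat <- build_expression_matrix(sim$chips, design)
  res <- run_contrasts(mat, "gender_within_treatment")
  for (trt in cfg$treatments) {
    eff <- sim$truth$gender_effect[, trt]
    r <- res[res$contrast == paste0("F_vs_M:", trt), ]
    got <- r$log2_ratio[match(names(eff), r$probe_id)]
    # median centering can add a tiny common offset; the planted +/-1
    # must survive essentially unchanged
    expect_equal(got[eff != 0], eff[eff != 0], tolerance = 0.05,
                 ignore_attr = TRUE)
  }
})

test_that("qPCR truth: zero noise recovers planted folds exactly; the normalizer is flat", {
  cfg <- clean_config(seed = 5)
  design <- simulate_design(cfg)
  qp <- simulate_qpcr(design, cfg)
  folds <- relative_fold(qp$ct, design)
  key <- paste(folds$gene, folds$gender, folds$treatment)
  tkey <- paste(qp$truth$gene, qp$truth$gender, qp$truth$treatment)
  expect_equal(folds$fold, qp$truth$fold[match(key, tkey)],
               tolerance = 1e-9)
  # 18S against itself: delta-Ct is identically zero per sample
  ct18 <- qp$ct[qp$ct$gene == "18S", ]
  per_sample <- tapply(ct18$ct, ct18$sample_id, mean)
  expect_equal(as.vector(per_sample - per_sample), rep(0, length(per_sample)))
})

test_that("qPCR recovery with Ct noise 0.1 stays within 20% of planted truth", {
  cfg <- small_config(seed = 9, ct_noise_sd = 0.1)
  design <- simulate_design(cfg)
  qp <- simulate_qpcr(design, cfg)
  folds <- relative_fold(qp$ct, design)
  key <- paste(folds$gene, folds$gender, folds$treatment)
  tkey <- paste(qp$truth$gene, qp$truth$gender, qp$truth$treatment)
  truth <- qp$truth$fold[match(key, tkey)]
  expect_true(all(abs(folds$fold / truth - 1) < 0.2))
})

test_that("full-pipeline null simulation keeps the t-test's type-I error near 5%", {
  # binomial band 0.05 +/- 3 * sqrt(0.05 * 0.95 / n) over pooled seeds
  ps <- c()
  for (seed in 1:3) {
    cfg <- sim_config(seed = seed, n_probes = 100L, n_confirmed = 80L,
                      n_predicted = 20L, frac_gender_effect = 0,
                      frac_treatment_effect = 0, dye_bias_amplitude = 0)
    design <- simulate_design(cfg)
    sim <- simulate_chips(design, cfg)
    mat <- build_expression_matrix(sim$chips, design)
    res <- run_contrasts(mat, "gender_within_treatment")
    ps <- c(ps, res$p[!is.na(res$p)])
  }
  rate <- mean(ps < 0.05)
  band <- 3 * sqrt(0.05 * 0.95 / 100)   # per-probe binomial band
  expect_lt(abs(rate - 0.05), band)
})

test_that("planted-effect recovery at the stated operating point (effect 1.5, noise 0.2)", {
  cfg <- sim_config(seed = 21, noise_sd_log2 = 0.2, effect_size_log2 = 1.5,
                    frac_gender_effect = 0.15)
  design <- simulate_design(cfg)
  sim <- simulate_chips(design, cfg)
  mat <- build_expression_matrix(sim$chips, design)
  res <- run_contrasts(mat, "gender_within_treatment")
  planted <- recovered <- 0
  for (trt in cfg$treatments) {
    eff <- sim$truth$gender_effect[, trt]
    truth_set <- names(eff)[eff != 0]
    r <- res[res$contrast == paste0("F_vs_M:", trt), ]
    found <- r$probe_id[r$class %in% c("up", "down")]
    planted <- planted + length(truth_set)
    recovered <- recovered + sum(truth_set %in% found)
  }
  expect_gte(recovered / planted, 0.9)
})
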