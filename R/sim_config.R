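#' Default stressor treatments
#'
#' The condition labels of the crossed gender-by-stressor layout the
#' simulator emulates: an untreated control, feeding with an
#' entomopathogenic bacterium, a sham saline injection, peptidoglycan
#' injection, mild heat shock and starvation.
#'
#' @return Character vector of six treatment labels; `"control"` is first
#'   and acts as the calibrator/reference condition throughout.
#' @export
default_treatments <- function() {
  c("control", "PE_fed", "saline_inj", "PGN_inj", "heat", "hunger")
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator: chip content
#' (number of probes, confirmed/predicted split, repeating spots per
#' probe), experimental layout (treatments, biological replicates per
#' gender-by-treatment cell), and the signal model (log2 baseline
#' distribution, per-spot log2 noise, additive raw-scale background,
#' intensity-dependent Cy5 dye bias, and the planted log2 effects that
#' define ground truth).
#'
#' @param seed Integer seed driving all randomness.
#' @param n_probes Number of distinct mature miRNA probes on a chip.
#' @param n_confirmed,n_predicted Split of `n_probes` into confirmed and
#'   computationally predicted sequences; must sum to `n_probes`.
#' @param n_repeats_per_probe Repeating spots per probe and channel.
#' @param treatments Ordered character vector of condition labels; the
#'   first entry is the control/reference.
#' @param n_bio_replicates Biological replicates (pools) per
#'   gender-by-treatment cell; must be an even number >= 2 because each
#'   pair of replicates is co-hybridized on one two-colour chip.
#' @param baseline_log2_mean,baseline_log2_sd Distribution of per-probe
#'   baseline expression on the log2 intensity scale.
#' @param noise_sd_log2 Per-spot log2-normal measurement noise s.d.
#' @param background_mean,background_sd Additive raw-scale background;
#'   both statistics are recorded in each chip file so the 3 x s.d.
#'   detection rule is computable downstream.
#' @param dye_bias_amplitude Slope amplitude of the intensity-dependent
#'   dye bias applied to the Cy5 channel only (log2 M-offset per 3
#'   baseline s.d. of log2 intensity). The curve is linear in log2
#'   intensity, so LOWESS normalization can remove it exactly.
#' @param frac_treatment_effect Fraction of probes planted with a
#'   treatment effect in each non-control treatment.
#' @param frac_gender_effect Fraction of probes planted with a gender
#'   effect (female minus male) in a random subset of treatments.
#' @param effect_size_log2 Magnitude of every planted log2 effect.
#' @param ct_noise_sd Technical-replicate Ct noise s.d. (cycles) for the
#'   simulated qPCR panel.
#'
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(seed = 1L,
                       n_probes = 455L,
                       n_confirmed = 386L,
                       n_predicted = 69L,
                       n_repeats_per_probe = 4L,
                       treatments = default_treatments(),
                       n_bio_replicates = 2L,
                       baseline_log2_mean = 10,
                       baseline_log2_sd = 1.5,
                       noise_sd_log2 = 0.1,
                       background_mean = 100,
                       background_sd = 30,
                       dye_bias_amplitude = 0.4,
                       frac_treatment_effect = 0.10,
                       frac_gender_effect = 0.15,
                       effect_size_log2 = 1.5,
                       ct_noise_sd = 0.1) {
  cfg <- list(
    seed = as.integer(seed),
    n_probes = as.integer(n_probes),
    n_confirmed = as.integer(n_confirmed),
    n_predicted = as.integer(n_predicted),
    n_repeats_per_probe = as.integer(n_repeats_per_probe),
    treatments = as.character(treatments),
    n_bio_replicates = as.integer(n_bio_replicates),
    baseline_log2_mean = as.numeric(baseline_log2_mean),
    baseline_log2_sd = as.numeric(baseline_log2_sd),
    noise_sd_log2 = as.numeric(noise_sd_log2),
    background_mean = as.numeric(background_mean),
    background_sd = as.numeric(background_sd),
    dye_bias_amplitude = as.numeric(dye_bias_amplitude),
    frac_treatment_effect = as.numeric(frac_treatment_effect),
    frac_gender_effect = as.numeric(frac_gender_effect),
    effect_size_log2 = as.numeric(effect_size_log2),
    ct_noise_sd = as.numeric(ct_noise_sd)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  fail <- function(field, why) {
    stop(sprintf("invalid sim_config: field '%s' %s", field, why),
         call. = FALSE)
  }
  if (is.na(cfg$seed)) fail("seed", "must be an integer")
  if (cfg$n_probes < 1L) fail("n_probes", "must be >= 1")
  if (cfg$n_confirmed < 0L) fail("n_confirmed", "must be >= 0")
  if (cfg$n_predicted < 0L) fail("n_predicted", "must be >= 0")
  if (cfg$n_confirmed + cfg$n_predicted != cfg$n_probes)
    fail("n_confirmed", "plus n_predicted must equal n_probes")
  if (cfg$n_repeats_per_probe < 1L)
    fail("n_repeats_per_probe", "must be >= 1")
  if (length(cfg$treatments) < 1L || anyDuplicated(cfg$treatments))
    fail("treatments", "must be a non-empty set of unique labels")
  if (cfg$n_bio_replicates < 2L)
    fail("n_bio_replicates", "must be >= 2 (t-tests need two replicates)")
  if (cfg$n_bio_replicates %% 2L != 0L)
    fail("n_bio_replicates", "must be even (replicates are co-hybridized in pairs)")
  for (f in c("baseline_log2_sd", "noise_sd_log2", "background_sd",
              "ct_noise_sd")) {
    if (cfg[[f]] < 0) fail(f, "must be >= 0")
  }
  for (f in c("frac_treatment_effect", "frac_gender_effect")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) fail(f, "must lie in [0, 1]")
  }
  invisible(cfg)
}

#' Probe annotation for a simulated chip
#'
#' Builds the probe catalogue: miRBase-style species-prefixed identifiers
#' for confirmed mature miRNAs and `C_`-prefixed identifiers for
#' computationally predicted ones. Deterministic given the config (no
#' random draws), so identical configs give identical catalogues.
#'
#' @param config A [sim_config()].
#' @return A data.frame with columns `probe_id` and
#'   `status` (`"confirmed"` or `"predicted"`).
#' @export
simulate_annotation <- function(config) {
  validate_sim_config(config)
  prefixes <- c("tca", "dme", "bmo", "dpu", "ame", "aga", "cqu")
  conf <- if (config$n_confirmed > 0L) {
    i <- seq_len(config$n_confirmed)
    sprintf("%s-miR-%d%s",
            prefixes[(i - 1L) %% length(prefixes) + 1L],
            100L + i,
            ifelse(i %% 9L == 0L, "*", ""))
  } else character(0)
  pred <- if (config$n_predicted > 0L) {
    j <- seq_len(config$n_predicted)
    sprintf("C_tca-miR-%d%s", 500L + j, ifelse(j %% 7L == 0L, "*", ""))
  } else character(0)
  data.frame(
    probe_id = c(conf, pred),
    status = rep(c("confirmed", "predicted"),
                 c(config$n_confirmed, config$n_predicted)),
    stringsAsFactors = FALSE
  )
}
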