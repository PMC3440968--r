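#' Simulate the experimental design table
#'
#' Lays out one sample per gender x treatment x biological replicate.
#' Replicates of the same gender-by-treatment cell are co-hybridized in
#' pairs on one two-colour chip: the odd replicate of a pair is labelled
#' Cy3, the even one Cy5.
#'
#' @param config A [sim_config()].
#' @return A design data.frame with columns `sample_id`, `chip_id`,
#'   `channel`, `gender` (`"F"`/`"M"`), `treatment`, `replicate`.
#' @export
simulate_design <- function(config) {
  validate_sim_config(config)
  genders <- c("F", "M")
  rows <- list()
  k <- 0L
  for (g in genders) {
    for (trt in config$treatments) {
      for (r in seq_len(config$n_bio_replicates)) {
        pair <- (r - 1L) %/% 2L + 1L
        chip <- sprintf("chip_%s_%s_%d", g, trt, pair)
        k <- k + 1L
        rows[[k]] <- data.frame(
          sample_id = sprintf("%s_%s_r%d", g, trt, r),
          chip_id = chip,
          channel = if (r %% 2L == 1L) "Cy3" else "Cy5",
          gender = g,
          treatment = trt,
          replicate = r,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  design <- do.call(rbind, rows)
  validate_design(design, treatments = config$treatments)
  design
}

# Plant per-probe ground truth. Called under the config's seed so chips
# and truth stay in sync.
plant_truth <- function(config, probe_ids) {
  n <- config$n_probes
  ntrt <- length(config$treatments)
  baseline <- stats::rnorm(n, config$baseline_log2_mean,
                           config$baseline_log2_sd)
  trt_eff <- matrix(0, n, ntrt, dimnames = list(probe_ids, config$treatments))
  gen_eff <- matrix(0, n, ntrt, dimnames = list(probe_ids, config$treatments))

  non_control <- setdiff(config$treatments, config$treatments[1L])
  n_trt_probes <- round(config$frac_treatment_effect * n)
  for (trt in non_control) {
    if (n_trt_probes > 0L) {
      idx <- sample.int(n, n_trt_probes)
      trt_eff[idx, trt] <- sample(c(-1, 1), n_trt_probes, replace = TRUE) *
        config$effect_size_log2
    }
  }

  n_gen_probes <- round(config$frac_gender_effect * n)
  if (n_gen_probes > 0L) {
    idx <- sample.int(n, n_gen_probes)
    for (i in idx) {
      sgn <- sample(c(-1, 1), 1L)
      affected <- stats::runif(ntrt) < 0.6
      if (!any(affected)) affected[sample.int(ntrt, 1L)] <- TRUE
      gen_eff[i, affected] <- sgn * config$effect_size_log2
    }
  }

  list(baseline = stats::setNames(baseline, probe_ids),
       treatment_effect = trt_eff,
       gender_effect = gen_eff)
}

# Intensity-dependent dye bias on the log2 scale, linear in log2
# intensity so a local-linear smoother removes it without residual.
dye_bias <- function(log2_intensity, config) {
  s <- max(config$baseline_log2_sd, 1e-8)
  config$dye_bias_amplitude * (log2_intensity - config$baseline_log2_mean) /
    (3 * s)
}

#' Simulate spot-level two-colour chips with planted truth
#'
#' For every chip in the design and both channels, each probe receives
#' `n_repeats_per_probe` spots. A spot's pre-background signal is
#' `2^(baseline + treatment effect + gender effect + N(0, noise_sd_log2))`;
#' on the Cy5 channel the exponent additionally gets a dye-bias offset
#' linear in log2 intensity. Additive background `N(background_mean,
#' background_sd)` (floored at zero) is then added on the raw scale, and
#' the generating background mean and s.d. are recorded per chip.
#'
#' @param design Design table from [simulate_design()].
#' @param config The same [sim_config()].
#' @return A list with `chips` (list of [chip_data()] objects, one per
#'   chip), `annotation` (probe catalogue) and `truth` (the planted
#'   ground truth: per-probe baseline, per probe-by-treatment treatment
#'   and gender log2 effects).
#' @export
simulate_chips <- function(design, config) {
  validate_sim_config(config)
  validate_design(design, treatments = config$treatments)
  annotation <- simulate_annotation(config)
  probe_ids <- annotation$probe_id

  set.seed(config$seed)
  truth <- plant_truth(config, probe_ids)

  chips <- list()
  for (chip_id in unique(design$chip_id)) {
    chan_rows <- design[design$chip_id == chip_id, , drop = FALSE]
    spot_list <- list()
    for (ci in seq_len(nrow(chan_rows))) {
      smp <- chan_rows[ci, ]
      e <- truth$baseline +
        truth$treatment_effect[, smp$treatment] +
        (if (smp$gender == "F") truth$gender_effect[, smp$treatment] else 0)
      nrep <- config$n_repeats_per_probe
      l <- rep(e, each = nrep) +
        stats::rnorm(length(e) * nrep, 0, config$noise_sd_log2)
      if (smp$channel == "Cy5") l <- l + dye_bias(l, config)
      bg <- pmax(stats::rnorm(length(l), config$background_mean,
                              config$background_sd), 0)
      spot_list[[ci]] <- data.frame(
        probe_id = rep(probe_ids, each = nrep),
        spot_index = rep(seq_len(nrep), times = length(probe_ids)),
        channel = smp$channel,
        raw_signal = 2^l + bg,
        stringsAsFactors = FALSE
      )
    }
    chips[[chip_id]] <- chip_data(
      chip_id = chip_id,
      background_mean = config$background_mean,
      background_sd = config$background_sd,
      spots = do.call(rbind, spot_list)
    )
  }
  list(chips = chips, annotation = annotation, truth = truth)
}

#' Panel of immune- and stress-response genes for the simulated qPCR assay
#'
#' Three antibacterial defensins, the antifungal protein thaumatin, a
#' cytochrome P450 and three heat-shock proteins, mirroring the effector
#' genes used to monitor immune and stress responses in the beetle study
#' design, plus the 18S rRNA normalizer.
#'
#' @return Character vector of eight target gene names (the normalizer
#'   `"18S"` is not included).
#' @export
qpcr_gene_panel <- function() {
  c("defensin1", "defensin2", "defensin3", "thaumatin",
    "cyp450", "hsp27", "hsp63", "hsp90")
}

#' Simulate a qPCR Ct table with planted fold truth
#'
#' Per target gene, gender and non-control treatment, a true fold change
#' relative to the same-gender control is planted (no change with
#' probability 0.45, otherwise `2^U(-1.5, 3)`). Ct values follow
#' `Ct = ct_ref - log2(relative expression) + sample offset + noise`:
#' the per-sample offset emulates RNA-loading differences and cancels in
#' the delta-Ct normalization against the constant 18S normalizer. Three
#' technical replicates are drawn per gene and sample.
#'
#' @param design Design table from [simulate_design()].
#' @param config The same [sim_config()]; `ct_noise_sd` sets the
#'   technical Ct noise.
#' @param genes Target genes; defaults to [qpcr_gene_panel()].
#' @return A list with `ct` (data.frame `sample_id`, `gene`,
#'   `tech_replicate`, `ct`) and `truth` (data.frame `gene`, `gender`,
#'   `treatment`, `fold` of true fold differences vs the same-gender
#'   control).
#' @export
simulate_qpcr <- function(design, config, genes = qpcr_gene_panel()) {
  validate_sim_config(config)
  validate_design(design, treatments = config$treatments)
  set.seed((config$seed + 1234567L) %% 2147483647L)

  control <- config$treatments[1L]
  ct_ref <- stats::setNames(stats::runif(length(genes), 18, 24), genes)

  cells <- expand.grid(gene = genes, gender = c("F", "M"),
                       treatment = config$treatments,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  changed <- cells$treatment != control & stats::runif(nrow(cells)) >= 0.45
  log2fold <- ifelse(changed, stats::runif(nrow(cells), -1.5, 3), 0)
  cells$fold <- 2^log2fold

  sample_offset <- stats::setNames(
    stats::rnorm(nrow(design), 0, 0.3), design$sample_id)

  n_tech <- 3L
  rows <- vector("list", nrow(design))
  for (si in seq_len(nrow(design))) {
    smp <- design[si, ]
    key <- paste(cells$gender, cells$treatment)
    sel <- cells[key == paste(smp$gender, smp$treatment), , drop = FALSE]
    folds <- stats::setNames(sel$fold, sel$gene)
    all_genes <- c(genes, "18S")
    mean_ct <- c(ct_ref - log2(folds[genes]),
                 "18S" = 10) + sample_offset[[smp$sample_id]]
    rows[[si]] <- data.frame(
      sample_id = smp$sample_id,
      gene = rep(all_genes, each = n_tech),
      tech_replicate = rep(seq_len(n_tech), times = length(all_genes)),
      ct = rep(mean_ct, each = n_tech) +
        stats::rnorm(length(all_genes) * n_tech, 0, config$ct_noise_sd),
      stringsAsFactors = FALSE
    )
  }
  list(ct = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       truth = cells)
}

#' Write a complete simulated study to disk
#'
#' Generates the design, annotation, chip files, qPCR Ct table and truth
#' tables for one configuration and writes them in the package's TSV
#' dialects. Identical configurations produce byte-identical files.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if missing); chip files go to
#'   `dir/chips/`.
#' @return Invisibly, a list with the in-memory `design`, `chips`,
#'   `annotation`, `truth`, `ct` and `ct_truth`, plus `paths` of all
#'   files written.
#' @export
simulate_study <- function(config, dir) {
  validate_sim_config(config)
  dir.create(file.path(dir, "chips"), recursive = TRUE, showWarnings = FALSE)
  design <- simulate_design(config)
  sim <- simulate_chips(design, config)
  qp <- simulate_qpcr(design, config)

  paths <- list(
    design = file.path(dir, "design.tsv"),
    annotation = file.path(dir, "annotation.tsv"),
    ct = file.path(dir, "ct.tsv"),
    truth_effects = file.path(dir, "truth_effects.tsv"),
    truth_qpcr = file.path(dir, "truth_qpcr.tsv"),
    chips = file.path(dir, "chips",
                      paste0(names(sim$chips), ".tsv"))
  )
  write_tsv_plain(design, paths$design)
  write_tsv_plain(sim$annotation, paths$annotation)
  write_tsv_plain(format_num_cols(qp$ct, "ct"), paths$ct)
  write_tsv_plain(format_num_cols(truth_effects_table(sim$truth),
                                  c("baseline_log2", "treatment_log2",
                                    "gender_log2")),
                  paths$truth_effects)
  write_tsv_plain(format_num_cols(qp$truth, "fold"), paths$truth_qpcr)
  for (i in seq_along(sim$chips)) {
    write_chip(sim$chips[[i]], paths$chips[[i]])
  }
  invisible(list(design = design, chips = sim$chips,
                 annotation = sim$annotation, truth = sim$truth,
                 ct = qp$ct, ct_truth = qp$truth, paths = paths))
}

# Long-format view of the planted effect truth.
truth_effects_table <- function(truth) {
  probes <- names(truth$baseline)
  trts <- colnames(truth$treatment_effect)
  data.frame(
    probe_id = rep(probes, times = length(trts)),
    treatment = rep(trts, each = length(probes)),
    baseline_log2 = rep(unname(truth$baseline), times = length(trts)),
    treatment_log2 = as.vector(truth$treatment_effect),
    gender_log2 = as.vector(truth$gender_effect),
    stringsAsFactors = FALSE
  )
}
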