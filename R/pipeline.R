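#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end run. All thresholds are
#' surfaced here so study-faithful and exploratory runs differ only in
#' configuration, never in code.
#'
#' @param seed Integer seed for the simulation stage.
#' @param sim A [sim_config()]; its own seed is overridden by `seed`.
#' @param span,iterations LOWESS parameters for normalization.
#' @param alpha Per-test significance level in (0, 1).
#' @param gender_fold,treatment_fold Fold-change thresholds (>= 1) for
#'   the two contrast families; the defaults (2 and 1) mirror the
#'   study's reporting rules.
#' @param p_adjust Multiple-testing method (see [stats::p.adjust()]);
#'   `"none"` for study-faithful runs.
#' @param normalizer,calibrator qPCR normalizer gene and calibrator
#'   condition.
#' @param out_dir Output directory for the report bundle.
#' @return Validated list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(seed = 1L,
                            sim = sim_config(seed = seed),
                            span = 0.3, iterations = 3L,
                            alpha = 0.05,
                            gender_fold = 2, treatment_fold = 1,
                            p_adjust = "none",
                            normalizer = "18S", calibrator = "control",
                            out_dir = "mirray_out") {
  cfg <- list(seed = as.integer(seed), sim = sim, span = span,
              iterations = as.integer(iterations), alpha = alpha,
              gender_fold = gender_fold, treatment_fold = treatment_fold,
              p_adjust = p_adjust, normalizer = normalizer,
              calibrator = calibrator, out_dir = out_dir)
  cfg$sim$seed <- cfg$seed
  validate_sim_config(cfg$sim)
  if (!is.numeric(cfg$alpha) || cfg$alpha <= 0 || cfg$alpha >= 1)
    stop("invalid pipeline_config: field 'alpha' must lie in (0, 1)",
         call. = FALSE)
  for (f in c("gender_fold", "treatment_fold")) {
    if (cfg[[f]] < 1)
      stop("invalid pipeline_config: field '", f, "' must be >= 1",
           call. = FALSE)
  }
  if (cfg$span <= 0 || cfg$span > 1)
    stop("invalid pipeline_config: field 'span' must lie in (0, 1]",
         call. = FALSE)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Load a pipeline configuration from YAML
#'
#' Any field of [pipeline_config()] or of its `sim` sub-config may be
#' set; omitted fields keep their defaults.
#'
#' @param path YAML file.
#' @return A `"pipeline_config"`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim_args <- y$sim
  y$sim <- NULL
  if (!is.null(y$seed) && !is.null(sim_args)) sim_args$seed <- y$seed
  sim <- do.call(sim_config, if (is.null(sim_args)) list() else sim_args)
  do.call(pipeline_config, c(y, list(sim = sim)))
}

#' Run the full analysis pipeline
#'
#' simulate -> preprocess -> per-miRNA contrasts (gender within
#' treatment and treatment vs control) -> gender/Venn summary ->
#' average-linkage clustering of the gender log2-ratio profiles ->
#' per-miRNA two-factor ANOVA -> delta-delta-Ct qPCR folds. All outputs
#' plus a JSON run manifest (parameters, package version, file digests)
#' are written to `config$out_dir`. Deterministic given the seed.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with every intermediate object (`study`,
#'   `matrix`, `gender_results`, `treatment_results`, `summary`,
#'   `tree`, `anova`, `folds`, `manifest`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  study <- stage("simulate", simulate_study(config$sim,
                                            file.path(out, "input")))
  mat <- stage("preprocess", build_expression_matrix(
    study$chips, study$design, span = config$span,
    iterations = config$iterations))
  write_expression_matrix(mat, file.path(out, "matrix.tsv"),
                          file.path(out, "detection.tsv"))

  gender_res <- stage("diffexpr", run_contrasts(
    mat, "gender_within_treatment", alpha = config$alpha,
    fold_threshold = config$gender_fold, p_adjust = config$p_adjust))
  treat_res <- stage("diffexpr", run_contrasts(
    mat, "treatment_vs_control", alpha = config$alpha,
    fold_threshold = config$treatment_fold, p_adjust = config$p_adjust))
  write_results(gender_res, file.path(out, "results_gender.tsv"))
  write_results(treat_res, file.path(out, "results_treatment.tsv"))

  summ <- stage("summarize", summarize_gender(gender_res,
                                              config$sim$n_probes))
  write_results(summ$table, file.path(out, "table1.tsv"))
  write_results(summ$venn, file.path(out, "venn.tsv"))
  write_results(regulation_counts(treat_res),
                file.path(out, "regulation_counts.tsv"))

  # cluster the gender-specific probes over their per-treatment
  # log2(F/M) profiles
  tree <- NULL
  if (length(summ$union) >= 2L) {
    ratios <- stats::reshape(
      gender_res[gender_res$probe_id %in% summ$union,
                 c("probe_id", "contrast", "log2_ratio")],
      idvar = "probe_id", timevar = "contrast", direction = "wide")
    rm_mat <- as.matrix(ratios[, -1L, drop = FALSE])
    rownames(rm_mat) <- ratios$probe_id
    colnames(rm_mat) <- sub("^log2_ratio\\.", "", colnames(rm_mat))
    keep <- rowSums(!is.na(rm_mat)) > 0
    rm_mat <- rm_mat[keep, , drop = FALSE]
    if (nrow(rm_mat) >= 2L) {
      tree <- stage("cluster",
                    average_linkage(euclidean_distances(rm_mat)))
      write_newick(tree, file.path(out, "tree.nwk"))
      writeLines(leaf_order(tree), file.path(out, "order.txt"))
      ordered <- data.frame(probe_id = rownames(rm_mat)[tree$order],
                            signif(rm_mat[tree$order, , drop = FALSE], 6),
                            check.names = FALSE)
      write_results(ordered, file.path(out, "matrix_ordered.tsv"))
    }
  }

  anova_res <- stage("anova", run_anova(mat))
  write_results(anova_res, file.path(out, "anova.tsv"))

  folds <- stage("qpcr", relative_fold(
    study$ct, study$design, normalizer = config$normalizer,
    calibrator = config$calibrator))
  write_results(folds, file.path(out, "folds.tsv"))

  manifest <- build_manifest(config, out)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(study = study, matrix = mat,
                 gender_results = gender_res, treatment_results = treat_res,
                 summary = summ, tree = tree, anova = anova_res,
                 folds = folds, manifest = manifest))
}

build_manifest <- function(config, out) {
  files <- sort(setdiff(
    list.files(out, recursive = TRUE),
    "manifest.json"))
  digests <- as.vector(tools::md5sum(file.path(out, files)))
  params <- unclass(config)
  params$sim <- unclass(params$sim)
  list(
    package = "mirray",
    version = as.character(utils::packageVersion("mirray")),
    parameters = params,
    files = stats::setNames(as.list(digests), files)
  )
}
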