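#' Read a qPCR Ct table
#'
#' @param path TSV with columns `sample_id`, `gene`, `tech_replicate`,
#'   `ct` (cycles, > 0).
#' @return Validated data.frame.
#' @export
read_ct <- function(path) {
  ct <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "gene", "tech_replicate", "ct")
  miss <- setdiff(need, names(ct))
  if (length(miss))
    stop("Ct table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(ct$ct)) || any(ct$ct <= 0))
    stop("Ct values must be finite and > 0", call. = FALSE)
  ct
}

#' Calibrator-relative fold differences (delta-delta-Ct)
#'
#' Standard relative quantification with a fixed amplification
#' efficiency: per biological sample, `dCt = mean Ct(gene) - mean
#' Ct(normalizer)` over technical replicates; per gene, gender and
#' treatment, each sample's `ddCt = dCt - mean dCt` over the same-gender
#' calibrator samples, and the per-sample fold is `efficiency^(-ddCt)`.
#' The reported fold is the mean over biological replicates with its
#' s.d.; a condition is flagged induced when the fold is strictly above
#' 2 ("above the twofold of the controls", so exactly 2 is not
#' induced). Calibrators are gender-matched: female conditions are
#' referred to the female calibrator, male to male.
#'
#' @param ct Ct table as from [read_ct()] / [simulate_qpcr()].
#' @param design Design table mapping `sample_id` to `gender`,
#'   `treatment`, `replicate`.
#' @param normalizer Endogenous control gene, default `"18S"`; required
#'   in every sample.
#' @param calibrator Reference condition, default `"control"`; required
#'   for both genders.
#' @param efficiency Amplification efficiency (fold per cycle),
#'   default 2.
#' @return data.frame with `gene`, `gender`, `treatment`, `fold`, `sd`
#'   (NA with a single biological replicate), `n_replicates`, `induced`.
#' @export
relative_fold <- function(ct, design, normalizer = "18S",
                          calibrator = "control", efficiency = 2) {
  stopifnot(efficiency > 1)
  samples <- unique(ct$sample_id)
  miss_design <- setdiff(samples, design$sample_id)
  if (length(miss_design))
    stop("Ct table has sample(s) absent from the design: ",
         paste(miss_design, collapse = ", "), call. = FALSE)

  # mean Ct per (sample, gene) over technical replicates
  key <- paste(ct$sample_id, ct$gene, sep = "\t")
  mean_ct <- tapply(ct$ct, key, mean)

  norm_key <- paste(samples, normalizer, sep = "\t")
  no_norm <- samples[!norm_key %in% names(mean_ct)]
  if (length(no_norm))
    stop("normalizer gene '", normalizer, "' missing for sample(s): ",
         paste(no_norm, collapse = ", "), call. = FALSE)
  norm_ct <- stats::setNames(as.vector(mean_ct[norm_key]), samples)

  genes <- setdiff(unique(ct$gene), normalizer)
  meta <- design[match(samples, design$sample_id), ]
  for (g in c("F", "M")) {
    if (!any(meta$gender == g & meta$treatment == calibrator))
      stop("no calibrator ('", calibrator, "') samples for gender ", g,
           call. = FALSE)
  }

  out <- list()
  k <- 0L
  for (gene in genes) {
    gkey <- paste(samples, gene, sep = "\t")
    have <- gkey %in% names(mean_ct)
    dct <- stats::setNames(as.vector(mean_ct[gkey]) - norm_ct, samples)
    for (gdr in c("F", "M")) {
      cal_samples <- samples[meta$gender == gdr &
                               meta$treatment == calibrator & have]
      if (!length(cal_samples))
        stop("gene '", gene, "': no calibrator measurements for gender ",
             gdr, call. = FALSE)
      cal_dct <- mean(dct[cal_samples])
      for (trt in unique(meta$treatment)) {
        grp <- samples[meta$gender == gdr & meta$treatment == trt & have]
        if (!length(grp)) next
        folds <- efficiency^(-(dct[grp] - cal_dct))
        k <- k + 1L
        out[[k]] <- data.frame(
          gene = gene, gender = gdr, treatment = trt,
          fold = mean(folds),
          sd = if (length(folds) > 1L) stats::sd(folds) else NA_real_,
          n_replicates = length(folds),
          induced = mean(folds) > 2,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
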