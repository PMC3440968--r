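#' Pooled-variance two-sample t-test
#'
#' Two-sided pooled-variance t-test with `df = nA + nB - 2`; the p-value
#' comes from the t distribution tail (evaluated through the regularized
#' incomplete beta function). Conventions for degenerate inputs: zero
#' pooled variance with equal means gives `t = 0, p = 1`; zero pooled
#' variance with unequal means gives `t = +/-Inf, p = 0`. Groups with
#' fewer than two non-missing values make the comparison untestable
#' (`testable = FALSE`, no p reported).
#'
#' @param a,b Numeric vectors (NAs dropped).
#' @return List with `t`, `df`, `p`, `testable`.
#' @export
two_sample_t <- function(a, b) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  na <- length(a)
  nb <- length(b)
  if (na < 2L || nb < 2L) {
    return(list(t = NA_real_, df = NA_integer_, p = NA_real_,
                testable = FALSE))
  }
  df <- na + nb - 2L
  sp2 <- ((na - 1L) * stats::var(a) + (nb - 1L) * stats::var(b)) / df
  delta <- mean(a) - mean(b)
  if (sp2 <= 0) {
    if (delta == 0) {
      return(list(t = 0, df = df, p = 1, testable = TRUE))
    }
    return(list(t = sign(delta) * Inf, df = df, p = 0, testable = TRUE))
  }
  t <- delta / sqrt(sp2 * (1 / na + 1 / nb))
  p <- 2 * stats::pt(-abs(t), df)
  list(t = t, df = df, p = p, testable = TRUE)
}

#' Per-miRNA contrasts on the expression matrix
#'
#' Two contrast families mirror the study design. In
#' `"gender_within_treatment"` mode every treatment is tested female
#' minus male; in `"treatment_vs_control"` mode every non-control
#' treatment is tested against the control within each gender. A probe
#' enters a contrast only if it is detectable in at least 50% of the
#' samples of at least one of the two groups; otherwise its class is
#' `"undetected"` and no p-value is reported. Classes: `"up"` if
#' `p < alpha` and `log2_ratio >= log2(fold_threshold)`, `"down"`
#' symmetric, else `"ns"`.
#'
#' @param mat An `"expr_matrix"` from [build_expression_matrix()].
#' @param mode `"gender_within_treatment"` or `"treatment_vs_control"`.
#' @param alpha Significance level (default 0.05).
#' @param fold_threshold Minimum fold change; defaults to 2 for gender
#'   contrasts and 1 (no fold filter) for treatment contrasts, matching
#'   the study's reporting rules.
#' @param p_adjust Multiple-testing correction passed to
#'   [stats::p.adjust()] within each contrast; `"none"` (default) for
#'   study-faithful runs.
#' @return data.frame with columns `probe_id`, `contrast`, `log2_ratio`,
#'   `t`, `df`, `p`, `class`.
#' @export
run_contrasts <- function(mat, mode = c("gender_within_treatment",
                                        "treatment_vs_control"),
                          alpha = 0.05, fold_threshold = NULL,
                          p_adjust = "none") {
  mode <- match.arg(mode)
  design <- mat$design
  treatments <- unique(design$treatment)
  if (is.null(fold_threshold)) {
    fold_threshold <- if (mode == "gender_within_treatment") 2 else 1
  }
  stopifnot(alpha > 0, alpha < 1, fold_threshold >= 1)

  pairs <- list()
  if (mode == "gender_within_treatment") {
    for (trt in treatments) {
      pairs[[paste0("F_vs_M:", trt)]] <- list(
        g1 = design$sample_id[design$treatment == trt & design$gender == "F"],
        g2 = design$sample_id[design$treatment == trt & design$gender == "M"])
    }
  } else {
    control <- treatments[1L]
    for (trt in setdiff(treatments, control)) {
      for (g in c("F", "M")) {
        pairs[[sprintf("%s_vs_%s:%s", trt, control, g)]] <- list(
          g1 = design$sample_id[design$treatment == trt & design$gender == g],
          g2 = design$sample_id[design$treatment == control &
                                  design$gender == g])
      }
    }
  }

  out <- list()
  for (cname in names(pairs)) {
    g1 <- pairs[[cname]]$g1
    g2 <- pairs[[cname]]$g2
    if (!length(g1) || !length(g2))
      stop("contrast '", cname, "': a group has no samples", call. = FALSE)
    v1 <- mat$values[, g1, drop = FALSE]
    v2 <- mat$values[, g2, drop = FALSE]
    d1 <- rowMeans(mat$detection[, g1, drop = FALSE])
    d2 <- rowMeans(mat$detection[, g2, drop = FALSE])
    testable_det <- d1 >= 0.5 | d2 >= 0.5

    n <- nrow(mat$values)
    res <- data.frame(
      probe_id = rownames(mat$values),
      contrast = cname,
      log2_ratio = NA_real_, t = NA_real_, df = NA_integer_, p = NA_real_,
      class = "undetected", stringsAsFactors = FALSE)
    for (i in seq_len(n)) {
      if (!testable_det[i]) next
      tt <- two_sample_t(v1[i, ], v2[i, ])
      if (!tt$testable) next
      res$log2_ratio[i] <- mean(v1[i, ], na.rm = TRUE) -
        mean(v2[i, ], na.rm = TRUE)
      res$t[i] <- tt$t
      res$df[i] <- tt$df
      res$p[i] <- tt$p
      res$class[i] <- "ns"
    }
    ok <- res$class != "undetected"
    padj <- res$p
    padj[ok] <- stats::p.adjust(res$p[ok], method = p_adjust)
    lfc <- log2(fold_threshold)
    res$class[ok & padj < alpha & res$log2_ratio >= lfc] <- "up"
    res$class[ok & padj < alpha & res$log2_ratio <= -lfc] <- "down"
    out[[cname]] <- res
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

# Percentage of total probes, rounded to the nearest integer for report
# display (raw values retained alongside wherever tables are emitted).
gender_pct <- function(n, n_total) round(100 * n / n_total)

#' Gender-specific summary: per-treatment sets, percentages, Venn regions
#'
#' From gender-mode contrast results, collects per treatment the set of
#' gender-specific probes (class `"up"` = higher in females, `"down"` =
#' higher in males), their counts and percentages of all probes on the
#' chip, the Venn region counts over the per-treatment sets, the overall
#' union, and the core set gender-specific under every treatment.
#'
#' @param results data.frame from [run_contrasts()] in
#'   `"gender_within_treatment"` mode, covering every treatment.
#' @param n_total Total number of probes on the chip (> 0).
#' @return List of class `"gender_summary"`: `table` (per-treatment
#'   counts and percentages, raw and display-rounded), `sets` (named
#'   list of per-treatment probe-id sets), `venn` (data.frame of region
#'   membership pattern and count over all non-empty region patterns),
#'   `union`, `core`, `pct_total_raw`, `pct_total` (rounded).
#' @export
summarize_gender <- function(results, n_total) {
  if (n_total <= 0) stop("n_total must be > 0", call. = FALSE)
  trts <- sub("^F_vs_M:", "", unique(results$contrast))
  if (any(trts == unique(results$contrast)))
    stop("summarize_gender expects gender-mode contrasts (F_vs_M:<treatment>)",
         call. = FALSE)

  sets <- list()
  up_f <- list()
  up_m <- list()
  for (trt in trts) {
    r <- results[results$contrast == paste0("F_vs_M:", trt), ]
    up_f[[trt]] <- r$probe_id[r$class == "up"]
    up_m[[trt]] <- r$probe_id[r$class == "down"]
    sets[[trt]] <- c(up_f[[trt]], up_m[[trt]])
  }

  tab <- data.frame(
    treatment = trts,
    n_specific = vapply(sets, length, 0L),
    n_up_f = vapply(up_f, length, 0L),
    n_up_m = vapply(up_m, length, 0L),
    stringsAsFactors = FALSE, row.names = NULL)
  tab$pct_total_raw <- 100 * tab$n_specific / n_total
  tab$pct_up_f_raw <- 100 * tab$n_up_f / n_total
  tab$pct_up_m_raw <- 100 * tab$n_up_m / n_total
  tab$pct_total <- gender_pct(tab$n_specific, n_total)
  tab$pct_up_f <- gender_pct(tab$n_up_f, n_total)
  tab$pct_up_m <- gender_pct(tab$n_up_m, n_total)

  all_ids <- sort(unique(unlist(sets, use.names = FALSE)))
  membership <- vapply(sets, function(s) all_ids %in% s,
                       logical(length(all_ids)))
  if (length(all_ids) == 1L) membership <- matrix(membership, nrow = 1L,
                                                  dimnames = list(NULL, trts))
  pattern <- apply(membership, 1L, function(row)
    paste(trts[row], collapse = "&"))
  venn <- as.data.frame(table(pattern), stringsAsFactors = FALSE)
  names(venn) <- c("regions", "count")
  venn <- venn[order(-venn$count, venn$regions), , drop = FALSE]
  rownames(venn) <- NULL

  core <- if (length(all_ids)) all_ids[rowSums(membership) == length(trts)]
          else character(0)

  structure(list(
    table = tab, sets = sets, venn = venn, union = all_ids, core = core,
    n_total = n_total,
    pct_total_raw = 100 * length(all_ids) / n_total,
    pct_total = gender_pct(length(all_ids), n_total)
  ), class = "gender_summary")
}

#' @export
print.gender_summary <- function(x, ...) {
  cat(sprintf(
    "<gender_summary> %d/%d probes gender-specific overall (%d%%), core %d\n",
    length(x$union), x$n_total, x$pct_total, length(x$core)))
  print(x$table[, c("treatment", "n_specific", "pct_total", "pct_up_f",
                    "pct_up_m")], row.names = FALSE)
  invisible(x)
}

#' Regulation counts per treatment contrast
#'
#' Tallies up/down/ns/undetected classes per contrast, the study-style
#' summary of differential expression upon each stressor.
#'
#' @param results data.frame from [run_contrasts()].
#' @return data.frame `contrast`, `n_up`, `n_down`, `n_ns`,
#'   `n_undetected`.
#' @export
regulation_counts <- function(results) {
  tab <- table(results$contrast,
               factor(results$class,
                      levels = c("up", "down", "ns", "undetected")))
  data.frame(contrast = rownames(tab),
             n_up = as.integer(tab[, "up"]),
             n_down = as.integer(tab[, "down"]),
             n_ns = as.integer(tab[, "ns"]),
             n_undetected = as.integer(tab[, "undetected"]),
             stringsAsFactors = FALSE, row.names = NULL)
}
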