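#' Balanced two-factor fixed-effects ANOVA for one probe
#'
#' Classical decomposition from cell means for a balanced full-factorial
#' gender x treatment design with replicate measurements:
#' `SS_total = SS_gender + SS_treatment + SS_interaction + SS_residual`,
#' `F = MS_effect / MS_residual`, p from the F-distribution tail
#' (computed through the regularized incomplete beta function). Under
#' balance the type-I and type-III decompositions coincide. When every
#' value is equal all sums of squares are 0 and each F is reported as 0
#' with p = 1. Unbalanced or incomplete designs are rejected.
#'
#' @param values Numeric vector of log2 intensities, no missing values.
#' @param gender Factor/character of `"F"`/`"M"` per value.
#' @param treatment Factor/character of treatment labels per value.
#' @return One-row data.frame: per term (`gender`, `treatment`,
#'   `interaction`, `residual`) the sum of squares `ss_*` and degrees of
#'   freedom `df_*`, plus `f_*` and `p_*` for the three effect terms.
#' @export
two_way_anova <- function(values, gender, treatment) {
  if (anyNA(values)) stop("values must not contain NA", call. = FALSE)
  gender <- factor(gender)
  treatment <- factor(treatment)
  n <- length(values)
  stopifnot(length(gender) == n, length(treatment) == n)

  cells <- table(gender, treatment)
  if (any(cells == 0L)) {
    idx <- which(cells == 0L, arr.ind = TRUE)[1L, ]
    stop(sprintf("empty design cell: gender=%s, treatment=%s",
                 rownames(cells)[idx[1L]], colnames(cells)[idx[2L]]),
         call. = FALSE)
  }
  if (length(unique(as.vector(cells))) != 1L)
    stop("unbalanced design: unequal replication across cells",
         call. = FALSE)
  r <- as.vector(cells)[1L]
  if (r < 2L) stop("need >= 2 replicates per cell", call. = FALSE)

  a <- nlevels(gender)
  b <- nlevels(treatment)
  grand <- mean(values)
  m_g <- tapply(values, gender, mean)
  m_t <- tapply(values, treatment, mean)
  m_gt <- tapply(values, list(gender, treatment), mean)

  ss_g <- b * r * sum((m_g - grand)^2)
  ss_t <- a * r * sum((m_t - grand)^2)
  ss_i <- r * sum((sweep(sweep(m_gt, 1L, m_g), 2L, m_t) + grand)^2)
  ss_r <- sum((values - m_gt[cbind(gender, treatment)])^2)

  df_g <- a - 1L
  df_t <- b - 1L
  df_i <- df_g * df_t
  df_r <- n - a * b

  ms_r <- ss_r / df_r
  fp <- function(ss, df) {
    if (ss <= 0 && ms_r <= 0) return(c(0, 1))
    if (ms_r <= 0) return(c(Inf, 0))
    f <- (ss / df) / ms_r
    c(f, stats::pf(f, df, df_r, lower.tail = FALSE))
  }
  g <- fp(ss_g, df_g)
  t_ <- fp(ss_t, df_t)
  i <- fp(ss_i, df_i)

  data.frame(
    ss_gender = ss_g, ss_treatment = ss_t, ss_interaction = ss_i,
    ss_residual = ss_r,
    df_gender = df_g, df_treatment = df_t, df_interaction = df_i,
    df_residual = df_r,
    f_gender = g[1L], f_treatment = t_[1L], f_interaction = i[1L],
    p_gender = g[2L], p_treatment = t_[2L], p_interaction = i[2L]
  )
}

#' Per-miRNA two-factor ANOVA over an expression matrix
#'
#' Applies [two_way_anova()] probe by probe using the gender and
#' treatment factors of the design. Probes with missing log2 values
#' (nonpositive integrated signal somewhere) cannot form a balanced
#' table and are reported with `tested = FALSE` and NA statistics rather
#' than silently reweighted.
#'
#' @param mat An `"expr_matrix"`.
#' @return data.frame with `probe_id`, `tested`, and the
#'   [two_way_anova()] columns.
#' @export
run_anova <- function(mat) {
  design <- mat$design
  g <- design$gender[match(colnames(mat$values), design$sample_id)]
  trt <- design$treatment[match(colnames(mat$values), design$sample_id)]
  rows <- vector("list", nrow(mat$values))
  template <- two_way_anova(as.numeric(seq_along(g)), g, trt)
  na_row <- template
  na_row[1L, ] <- NA
  for (i in seq_len(nrow(mat$values))) {
    v <- mat$values[i, ]
    if (anyNA(v)) {
      rows[[i]] <- cbind(data.frame(probe_id = rownames(mat$values)[i],
                                    tested = FALSE,
                                    stringsAsFactors = FALSE), na_row)
    } else {
      rows[[i]] <- cbind(data.frame(probe_id = rownames(mat$values)[i],
                                    tested = TRUE,
                                    stringsAsFactors = FALSE),
                         two_way_anova(v, g, trt))
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
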