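#' Integrate repeating spots of one chip
#'
#' Per probe and channel: the per-chip background mean is subtracted from
#' each spot with a floor at zero; the integrated signal is the mean of
#' the floored values; the repeat CV is the sample s.d. over the floored
#' spot values divided by their mean (0 if the mean is 0); and
#' `n_repeats_above` counts spots whose floored signal exceeds 3 x the
#' chip's background s.d.
#'
#' @param chip A [chip_data()] object.
#' @return data.frame with one row per (probe_id, channel):
#'   `integrated_signal`, `repeat_cv`, `n_repeats`, `n_repeats_above`,
#'   plus `chip_id`.
#' @export
integrate_repeats <- function(chip) {
  validate_chip_data(chip)
  sp <- chip$spots
  if (!nrow(sp)) stop("chip '", chip$chip_id, "': no spots", call. = FALSE)
  floored <- pmax(sp$raw_signal - chip$background_mean, 0)
  key <- factor(paste(sp$probe_id, sp$channel, sep = "\t"))
  thr <- 3 * chip$background_sd

  agg <- function(f) as.vector(tapply(floored, key, f))
  means <- agg(mean)
  sds <- agg(function(v) if (length(v) > 1L) stats::sd(v) else 0)
  n <- agg(length)
  n_above <- as.vector(tapply(floored > thr, key, sum))

  ids <- do.call(rbind, strsplit(levels(key), "\t", fixed = TRUE))
  data.frame(
    chip_id = chip$chip_id,
    probe_id = ids[, 1L],
    channel = ids[, 2L],
    integrated_signal = means,
    repeat_cv = ifelse(means > 0, sds / means, 0),
    n_repeats = as.integer(n),
    n_repeats_above = as.integer(n_above),
    stringsAsFactors = FALSE
  )
}

#' Detection call for an integrated probe
#'
#' A probe is detectable on a chip/channel when all three conditions
#' hold: integrated signal strictly above 3 x the chip background s.d.;
#' repeat CV strictly below 0.5; and at least 50% of the repeating spots
#' individually above the 3 x s.d. detection level.
#'
#' @param integrated_signal Background-subtracted integrated signal.
#' @param repeat_cv CV over the repeating spots.
#' @param n_repeats,n_repeats_above Spot counts from
#'   [integrate_repeats()].
#' @param background_sd The chip's background s.d.
#' @return Logical vector of detection calls (vectorized over probes).
#' @export
detection_call <- function(integrated_signal, repeat_cv, n_repeats,
                           n_repeats_above, background_sd) {
  (integrated_signal > 3 * background_sd) &
    (repeat_cv < 0.5) &
    (n_repeats_above / n_repeats >= 0.5)
}

#' Locally weighted scatterplot smoother (LOWESS)
#'
#' Classic robust locally weighted linear regression: for each point, a
#' weighted least-squares line is fitted over the `ceiling(span * n)`
#' nearest x-neighbours (ties between equidistant neighbours broken by
#' lower index) with tricube weights, then `iterations` robustifying
#' passes down-weight residual outliers by bisquare weights of
#' `residual / (6 * median |residual|)`.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @param span Neighbourhood fraction in (0, 1].
#' @param iterations Number of robustifying passes (0 = plain fit).
#' @return Fitted values at the input `x`, in input order. If all `x`
#'   are equal the fit degenerates to `mean(y)` everywhere.
#' @export
lowess_smooth <- function(x, y, span = 0.3, iterations = 3L) {
  n <- length(x)
  stopifnot(length(y) == n, n >= 3L, span > 0, span <= 1)
  if (diff(range(x)) == 0) return(rep(mean(y), n))
  r <- max(2L, ceiling(span * n))
  robw <- rep(1, n)
  fit <- numeric(n)
  for (pass in 0:iterations) {
    for (i in seq_len(n)) {
      d <- abs(x - x[i])
      nb <- order(d, seq_len(n))[seq_len(r)]
      h <- d[nb[r]]
      w <- if (h > 0) (1 - pmin(d[nb] / h, 1)^3)^3 else rep(1, r)
      w <- w * robw[nb]
      if (sum(w) <= 0) {
        fit[i] <- mean(y[nb])
        next
      }
      xw <- x[nb]
      yw <- y[nb]
      sw <- sum(w)
      xbar <- sum(w * xw) / sw
      ybar <- sum(w * yw) / sw
      sxx <- sum(w * (xw - xbar)^2)
      if (sxx > 1e-12 * sw * max(1, xbar^2)) {
        beta <- sum(w * (xw - xbar) * (yw - ybar)) / sxx
        fit[i] <- ybar + beta * (x[i] - xbar)
      } else {
        fit[i] <- ybar
      }
    }
    if (pass == iterations) break
    res <- y - fit
    s <- stats::median(abs(res))
    if (s <= 0) break
    robw <- pmax(1 - (res / (6 * s))^2, 0)^2
  }
  fit
}

#' Within-chip MA-LOWESS dye-bias correction
#'
#' For probes with positive integrated signal in both channels, computes
#' `M = log2(Cy5) - log2(Cy3)` and `A = (log2(Cy5) + log2(Cy3)) / 2`,
#' fits `lowess_smooth(A, M)`, and removes the fitted trend
#' symmetrically (`Cy5 - fit/2`, `Cy3 + fit/2` on the log2 scale).
#' Probes positive in a single channel keep their uncorrected log2
#' value; nonpositive integrated signals become `NA`. With fewer than
#' 10 co-positive probes the LOWESS step is skipped with a warning and
#' only the (downstream) median centering normalizes the chip.
#'
#' @param integrated Output of [integrate_repeats()] for one chip.
#' @param span,iterations Passed to [lowess_smooth()].
#' @return data.frame `probe_id`, `channel`, `log2_value` for the chip.
#' @export
normalize_chip <- function(integrated, span = 0.3, iterations = 3L) {
  cy3 <- integrated[integrated$channel == "Cy3", ]
  cy5 <- integrated[integrated$channel == "Cy5", ]
  probes <- sort(unique(integrated$probe_id))
  s3 <- cy3$integrated_signal[match(probes, cy3$probe_id)]
  s5 <- cy5$integrated_signal[match(probes, cy5$probe_id)]
  l3 <- ifelse(!is.na(s3) & s3 > 0, log2(s3), NA_real_)
  l5 <- ifelse(!is.na(s5) & s5 > 0, log2(s5), NA_real_)

  both <- which(!is.na(l3) & !is.na(l5))
  if (length(both) >= 10L) {
    m <- l5[both] - l3[both]
    a <- (l5[both] + l3[both]) / 2
    f <- lowess_smooth(a, m, span = span, iterations = iterations)
    l5[both] <- l5[both] - f / 2
    l3[both] <- l3[both] + f / 2
  } else {
    warning("chip '", integrated$chip_id[1L], "': only ", length(both),
            " co-detected probes; skipping LOWESS, median centering only",
            call. = FALSE)
  }
  rbind(
    data.frame(probe_id = probes, channel = "Cy3", log2_value = l3,
               co_positive = seq_along(probes) %in% both,
               stringsAsFactors = FALSE),
    data.frame(probe_id = probes, channel = "Cy5", log2_value = l5,
               co_positive = seq_along(probes) %in% both,
               stringsAsFactors = FALSE)
  )
}

#' Build the normalized expression matrix for a study
#'
#' Runs [integrate_repeats()], [detection_call()] and [normalize_chip()]
#' on every chip, maps chip channels to samples through the design, and
#' median-centers each sample's log2 values across chips (median taken
#' over the probes that were positive in both channels of the sample's
#' chip, which then sits exactly at 0).
#'
#' @param chips Named list of [chip_data()] objects.
#' @param design Design table matching the chips.
#' @param span,iterations LOWESS parameters.
#' @return An object of class `"expr_matrix"`: list with `values`
#'   (probe x sample matrix of normalized log2 intensities, `NA` where
#'   the integrated signal was nonpositive), `detection` (logical matrix
#'   of detection calls), and `design`.
#' @export
build_expression_matrix <- function(chips, design, span = 0.3,
                                    iterations = 3L) {
  validate_design(design)
  miss <- setdiff(design$chip_id, names(chips))
  if (length(miss))
    stop("design references missing chip(s): ",
         paste(unique(miss), collapse = ", "), call. = FALSE)

  probe_ids <- sort(unique(chips[[design$chip_id[1L]]]$spots$probe_id))
  values <- matrix(NA_real_, length(probe_ids), nrow(design),
                   dimnames = list(probe_ids, design$sample_id))
  detect <- matrix(FALSE, length(probe_ids), nrow(design),
                   dimnames = list(probe_ids, design$sample_id))

  for (chip_id in unique(design$chip_id)) {
    chip <- chips[[chip_id]]
    integ <- integrate_repeats(chip)
    integ$detectable <- detection_call(
      integ$integrated_signal, integ$repeat_cv, integ$n_repeats,
      integ$n_repeats_above, chip$background_sd)
    norm <- normalize_chip(integ, span = span, iterations = iterations)
    for (si in which(design$chip_id == chip_id)) {
      chan <- design$channel[si]
      nc <- norm[norm$channel == chan, ]
      v <- nc$log2_value[match(probe_ids, nc$probe_id)]
      ctr <- stats::median(v[nc$co_positive[match(probe_ids, nc$probe_id)]],
                           na.rm = TRUE)
      if (is.na(ctr)) ctr <- 0
      values[, si] <- v - ctr
      ic <- integ[integ$channel == chan, ]
      detect[, si] <- ic$detectable[match(probe_ids, ic$probe_id)] %in% TRUE
    }
  }
  structure(list(values = values, detection = detect, design = design),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf(
    "<expr_matrix> %d probes x %d samples; %.1f%% detected, %.1f%% missing\n",
    nrow(x$values), ncol(x$values), 100 * mean(x$detection),
    100 * mean(is.na(x$values))))
  invisible(x)
}

#' Write / read an expression matrix
#'
#' The matrix TSV has probes as rows and samples as columns; the parallel
#' detection TSV holds 0/1 flags in the same layout.
#'
#' @param mat An `"expr_matrix"`.
#' @param values_path,detection_path Output paths.
#' @return Invisibly `values_path`.
#' @export
write_expression_matrix <- function(mat, values_path, detection_path) {
  df <- data.frame(probe_id = rownames(mat$values),
                   as.data.frame(signif(mat$values, 6)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_plain(format_num_cols(df, setdiff(names(df), "probe_id")),
                  values_path)
  dd <- data.frame(probe_id = rownames(mat$detection),
                   as.data.frame(mat$detection * 1L),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_plain(dd, detection_path)
  invisible(values_path)
}

#' @rdname write_expression_matrix
#' @param design The design table the matrix belongs to.
#' @export
read_expression_matrix <- function(values_path, detection_path, design) {
  v <- utils::read.delim(values_path, check.names = FALSE,
                         stringsAsFactors = FALSE)
  d <- utils::read.delim(detection_path, check.names = FALSE,
                         stringsAsFactors = FALSE)
  values <- as.matrix(v[, -1L, drop = FALSE])
  rownames(values) <- v$probe_id
  detect <- as.matrix(d[, -1L, drop = FALSE]) == 1L
  rownames(detect) <- d$probe_id
  structure(list(values = values, detection = detect, design = design),
            class = "expr_matrix")
}
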