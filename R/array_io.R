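#' Spot-level data for one two-colour chip
#'
#' Container for the raw measurements of a single hybridized chip:
#' per-chip background statistics plus one row per spot. Every probe must
#' appear with the same number of repeating spots in each channel.
#'
#' @param chip_id Chip label.
#' @param background_mean,background_sd Per-chip additive background
#'   statistics on the raw intensity scale (`background_sd >= 0`).
#' @param spots data.frame with columns `probe_id`, `spot_index`,
#'   `channel` (`"Cy3"`/`"Cy5"`), `raw_signal` (>= 0).
#' @return An object of class `"chip_data"`.
#' @export
chip_data <- function(chip_id, background_mean, background_sd, spots) {
  obj <- list(chip_id = as.character(chip_id),
              background_mean = as.numeric(background_mean),
              background_sd = as.numeric(background_sd),
              spots = spots)
  class(obj) <- "chip_data"
  validate_chip_data(obj)
  obj
}

validate_chip_data <- function(chip) {
  if (is.na(chip$background_sd) || chip$background_sd < 0)
    stop("chip '", chip$chip_id, "': background_sd must be >= 0",
         call. = FALSE)
  need <- c("probe_id", "spot_index", "channel", "raw_signal")
  miss <- setdiff(need, names(chip$spots))
  if (length(miss))
    stop("chip '", chip$chip_id, "': spots lack column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  bad_chan <- setdiff(unique(chip$spots$channel), c("Cy3", "Cy5"))
  if (length(bad_chan))
    stop("chip '", chip$chip_id, "': unknown channel(s) ",
         paste(bad_chan, collapse = ", "), call. = FALSE)
  if (any(chip$spots$raw_signal < 0))
    stop("chip '", chip$chip_id, "': raw_signal must be >= 0",
         call. = FALSE)
  counts <- table(chip$spots$probe_id, chip$spots$channel)
  if (length(unique(as.vector(counts))) > 1L)
    stop("chip '", chip$chip_id,
         "': probes must have the same number of repeating spots per channel",
         call. = FALSE)
  invisible(chip)
}

#' @export
print.chip_data <- function(x, ...) {
  cat(sprintf("<chip_data> %s: %d spots, %d probes, background %.4g +/- %.4g\n",
              x$chip_id, nrow(x$spots), length(unique(x$spots$probe_id)),
              x$background_mean, x$background_sd))
  invisible(x)
}

# --- chip TSV dialect -------------------------------------------------
# Header lines "#key<TAB>value" for chip_id, background_mean,
# background_sd, then a tab-separated spot table. UTF-8, LF endings.

#' Write a chip file
#'
#' @param chip A [chip_data()] object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_chip <- function(chip, path) {
  validate_chip_data(chip)
  con <- file(path, open = "wb")
  on.exit(close(con))
  hdr <- c(sprintf("#chip_id\t%s", chip$chip_id),
           sprintf("#background_mean\t%s", num_fmt(chip$background_mean)),
           sprintf("#background_sd\t%s", num_fmt(chip$background_sd)),
           "probe_id\tspot_index\tchannel\traw_signal")
  body <- sprintf("%s\t%d\t%s\t%s",
                  chip$spots$probe_id,
                  as.integer(chip$spots$spot_index),
                  chip$spots$channel,
                  num_fmt(chip$spots$raw_signal))
  writeLines(c(hdr, body), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read a chip file
#'
#' Accepts the chip TSV dialect written by [write_chip()]. Channel names
#' are matched case-insensitively and normalized to `"Cy3"`/`"Cy5"`;
#' malformed rows are rejected with their line number.
#'
#' @param path Path to a chip TSV file.
#' @return A [chip_data()] object.
#' @export
read_chip <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  is_hdr <- startsWith(lines, "#")
  hdr <- lines[is_hdr]
  kv <- strsplit(sub("^#", "", hdr), "\t", fixed = TRUE)
  keys <- vapply(kv, `[`, "", 1L)
  vals <- vapply(kv, function(x) if (length(x) >= 2L) x[2L] else NA_character_, "")
  for (need in c("chip_id", "background_mean", "background_sd")) {
    if (!need %in% keys || is.na(vals[match(need, keys)]))
      stop("chip file '", path, "': missing header '#", need, "'",
           call. = FALSE)
  }
  meta <- stats::setNames(vals, keys)

  body <- lines[!is_hdr]
  body_lineno <- which(!is_hdr)
  if (length(body) < 1L)
    stop("chip file '", path, "': no spot table", call. = FALSE)
  header_cols <- strsplit(body[1L], "\t", fixed = TRUE)[[1L]]
  need_cols <- c("probe_id", "spot_index", "channel", "raw_signal")
  if (!identical(header_cols, need_cols))
    stop("chip file '", path, "': spot table header must be ",
         paste(need_cols, collapse = "\t"), call. = FALSE)
  rows <- strsplit(body[-1L], "\t", fixed = TRUE)
  nf <- lengths(rows)
  if (any(nf != 4L))
    stop("chip file '", path, "': malformed row at line ",
         body_lineno[-1L][which(nf != 4L)[1L]], call. = FALSE)
  m <- matrix(unlist(rows), ncol = 4L, byrow = TRUE)
  sig <- suppressWarnings(as.numeric(m[, 4L]))
  idx <- suppressWarnings(as.integer(m[, 2L]))
  if (anyNA(sig))
    stop("chip file '", path, "': non-numeric raw_signal at line ",
         body_lineno[-1L][which(is.na(sig))[1L]], call. = FALSE)
  if (anyNA(idx))
    stop("chip file '", path, "': non-integer spot_index at line ",
         body_lineno[-1L][which(is.na(idx))[1L]], call. = FALSE)
  chan <- normalize_channel(m[, 3L])
  if (anyNA(chan))
    stop("chip file '", path, "': unknown channel at line ",
         body_lineno[-1L][which(is.na(chan))[1L]], call. = FALSE)
  if (any(sig < 0))
    stop("chip file '", path, "': negative raw_signal at line ",
         body_lineno[-1L][which(sig < 0)[1L]], call. = FALSE)
  chip_data(
    chip_id = meta[["chip_id"]],
    background_mean = as.numeric(meta[["background_mean"]]),
    background_sd = as.numeric(meta[["background_sd"]]),
    spots = data.frame(probe_id = m[, 1L], spot_index = idx,
                       channel = chan, raw_signal = sig,
                       stringsAsFactors = FALSE)
  )
}

normalize_channel <- function(x) {
  out <- c(cy3 = "Cy3", cy5 = "Cy5")[tolower(x)]
  unname(out)
}

#' Read all chip files of a directory
#'
#' @param dir Directory containing `*.tsv` chip files.
#' @return Named list of [chip_data()] objects, keyed by chip_id.
#' @export
read_chip_dir <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.tsv$", full.names = TRUE))
  if (!length(files)) stop("no chip files (*.tsv) in '", dir, "'",
                           call. = FALSE)
  chips <- lapply(files, read_chip)
  names(chips) <- vapply(chips, `[[`, "", "chip_id")
  if (anyDuplicated(names(chips)))
    stop("duplicate chip_id across files in '", dir, "'", call. = FALSE)
  chips
}

# --- design / annotation ----------------------------------------------

validate_design <- function(design, treatments = NULL) {
  need <- c("sample_id", "chip_id", "channel", "gender", "treatment",
            "replicate")
  miss <- setdiff(need, names(design))
  if (length(miss))
    stop("design lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(design$sample_id))
    stop("design: duplicate sample_id", call. = FALSE)
  key <- paste(design$chip_id, design$channel)
  if (anyDuplicated(key))
    stop("design: duplicate (chip_id, channel) pair: ",
         key[anyDuplicated(key)], call. = FALSE)
  if (!all(design$gender %in% c("F", "M")))
    stop("design: gender must be 'F' or 'M'", call. = FALSE)
  if (!all(design$channel %in% c("Cy3", "Cy5")))
    stop("design: channel must be 'Cy3' or 'Cy5'", call. = FALSE)
  if (!is.null(treatments)) {
    bad <- setdiff(unique(design$treatment), treatments)
    if (length(bad))
      stop("design: unknown treatment label(s) ",
           paste(bad, collapse = ", "), "; allowed: ",
           paste(treatments, collapse = ", "), call. = FALSE)
  }
  invisible(design)
}

#' Read a design table
#'
#' @param path Design TSV with columns `sample_id`, `chip_id`, `channel`,
#'   `gender`, `treatment`, `replicate`.
#' @param treatments Optional vector of allowed treatment labels; unknown
#'   labels are rejected with the allowed set in the message.
#' @return Validated design data.frame.
#' @export
read_design <- function(path, treatments = NULL) {
  design <- utils::read.delim(path, stringsAsFactors = FALSE)
  design$channel <- normalize_channel(design$channel)
  validate_design(design, treatments = treatments)
  design
}

#' Read a probe annotation table
#'
#' @param path Annotation TSV with columns `probe_id` and `status`
#'   (`confirmed` or `predicted`).
#' @return data.frame with those two columns.
#' @export
read_annotation <- function(path) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("probe_id", "status") %in% names(ann)))
    stop("annotation must have columns probe_id, status", call. = FALSE)
  bad <- setdiff(unique(ann$status), c("confirmed", "predicted"))
  if (length(bad))
    stop("annotation: unknown status ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(ann$probe_id))
    stop("annotation: duplicate probe_id", call. = FALSE)
  ann
}

# --- generic writers --------------------------------------------------

num_fmt <- function(x) {
  out <- sprintf("%.6g", x)
  out[is.na(x)] <- "NA"
  out
}

format_num_cols <- function(df, cols) {
  for (cl in intersect(cols, names(df))) df[[cl]] <- num_fmt(df[[cl]])
  df
}

write_tsv_plain <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  lines <- c(paste(names(df), collapse = "\t"),
             do.call(paste, c(lapply(df, as.character), sep = "\t")))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Write a results table
#'
#' Writes any results data.frame in a diffable form: fixed column order
#' as given, numeric columns rendered with 6 significant digits, tabs,
#' LF endings.
#'
#' @param table data.frame of results.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_results <- function(table, path) {
  num_cols <- names(table)[vapply(table, is.numeric, TRUE) &
                             !vapply(table, is.integer, TRUE)]
  write_tsv_plain(format_num_cols(table, num_cols), path)
}

# --- Newick export ----------------------------------------------------

newick_quote <- function(label) {
  ok <- grepl("^[A-Za-z0-9_.|*-]+$", label)
  ifelse(ok, label, paste0("'", gsub("'", "''", label), "'"))
}

#' Write a cluster tree as Newick
#'
#' Serializes a tree from [average_linkage()] (an `hclust`-compatible
#' merge structure). Branch lengths are merge-height differences, so the
#' tree is ultrametric: every leaf sits at distance `max(height)` from
#' the root. Labels containing characters outside `[A-Za-z0-9_.|*-]` are
#' single-quoted.
#'
#' @param tree An `hclust`-like object (`merge`, `height`, `labels`).
#' @param path Output path.
#' @return Invisibly, the Newick string written.
#' @export
write_newick <- function(tree, path) {
  stopifnot(!is.null(tree$merge), !is.null(tree$height))
  labels <- tree$labels
  if (is.null(labels)) labels <- as.character(seq_len(nrow(tree$merge) + 1L))
  node_str <- function(id, parent_h) {
    if (id < 0L) {
      sprintf("%s:%s", newick_quote(labels[-id]), num_fmt(parent_h))
    } else {
      h <- tree$height[id]
      sprintf("(%s,%s):%s",
              node_str(tree$merge[id, 1L], h),
              node_str(tree$merge[id, 2L], h),
              num_fmt(parent_h - h))
    }
  }
  root <- nrow(tree$merge)
  h <- tree$height[root]
  nwk <- sprintf("(%s,%s);",
                 node_str(tree$merge[root, 1L], h),
                 node_str(tree$merge[root, 2L], h))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(nwk, con, sep = "\n", useBytes = TRUE)
  invisible(nwk)
}
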