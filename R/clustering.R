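#' Pairwise Euclidean distances with missing-value rescaling
#'
#' `d(i, j) = sqrt(sum_k (x_ik - x_jk)^2)` over the dimensions
#' non-missing in both rows, rescaled by `sqrt(D / D_used)` so rows with
#' different missingness stay comparable (D = total number of columns).
#' A pair of rows sharing no observed dimension is an error naming both
#' rows.
#'
#' @param m Numeric matrix (rows are the objects to cluster); may
#'   contain `NA`.
#' @return A `dist` object (lower triangle, `Size` attribute, labels
#'   from rownames).
#' @export
euclidean_distances <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) < 2L) stop("need at least 2 rows", call. = FALSE)
  d_total <- ncol(m)
  w <- !is.na(m)
  x0 <- m
  x0[!w] <- 0
  p <- x0 * x0
  wn <- w * 1
  term1 <- p %*% t(wn)
  cross <- x0 %*% t(x0)
  d2 <- term1 + t(term1) - 2 * cross
  used <- wn %*% t(wn)

  labs <- rownames(m)
  if (is.null(labs)) labs <- as.character(seq_len(nrow(m)))
  bad <- which(used == 0 & upper.tri(used), arr.ind = TRUE)
  if (nrow(bad))
    stop("rows '", labs[bad[1L, 1L]], "' and '", labs[bad[1L, 2L]],
         "' share no observed dimension", call. = FALSE)

  d2 <- pmax(d2, 0)  # guard tiny negatives from cross-product round-off
  dm <- sqrt(d2 * d_total / used)
  stats::as.dist(dm)
}

#' Average-linkage (UPGMA-style) agglomerative clustering
#'
#' Repeatedly merges the pair of clusters with the smallest average
#' inter-cluster distance, where the cluster-cluster distance is the
#' arithmetic mean of all member pairwise distances (maintained by the
#' Lance-Williams size-weighted update). Ties are broken by the
#' lexicographically smallest pair of cluster indices, clusters being
#' numbered in creation order (leaves 1..n in input order, then merged
#' clusters). Average linkage is monotone, so merge heights never
#' decrease.
#'
#' @param d A `dist` object, e.g. from [euclidean_distances()].
#' @return An `hclust`-compatible object (class `c("mirray_tree",
#'   "hclust")`): `merge`, `height`, `order` (left-to-right leaf
#'   traversal), `labels`, `method = "average"`.
#' @export
average_linkage <- function(d) {
  n <- attr(d, "Size")
  if (is.null(n) || n < 2L) stop("need a dist over >= 2 objects",
                                 call. = FALSE)
  labs <- attr(d, "Labels")
  dm <- as.matrix(d)
  diag(dm) <- Inf

  # bookkeeping per active cluster: creation id, hclust code, size, order
  active <- seq_len(n)           # creation ids of active clusters
  code <- -seq_len(n)            # hclust merge codes
  size <- rep(1L, n)
  ords <- as.list(seq_len(n))
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  next_id <- n

  for (step in seq_len(n - 1L)) {
    k <- length(active)
    # smallest distance; near-ties (relative 1e-8) -> smallest (i, j) in
    # creation order. Rows/columns of dm are kept in creation order of
    # the active clusters.
    mn <- min(dm)
    tol <- 1e-8 * (1 + mn)
    cand <- which(dm <= mn + tol, arr.ind = TRUE)
    cand <- cand[cand[, 2L] < cand[, 1L], , drop = FALSE]  # (col, row) = (i, j)
    pick <- order(cand[, 2L], cand[, 1L])[1L]
    i <- cand[pick, 2L]; j <- cand[pick, 1L]
    merge[step, ] <- c(code[i], code[j])
    height[step] <- dm[i, j]
    new_ord <- c(ords[[i]], ords[[j]])
    new_size <- size[i] + size[j]
    # Lance-Williams average-linkage update against all other clusters
    newd <- (size[i] * dm[i, ] + size[j] * dm[j, ]) / new_size
    keep <- setdiff(seq_len(k), c(i, j))
    dm <- dm[keep, keep, drop = FALSE]
    dm <- rbind(cbind(dm, newd[keep]), c(newd[keep], Inf))
    next_id <- next_id + 1L
    active <- c(active[keep], next_id)
    code <- c(code[keep], step)
    size <- c(size[keep], new_size)
    ords <- c(ords[keep], list(new_ord))
  }
  structure(list(merge = merge, height = height, order = ords[[1L]],
                 labels = labs, method = "average",
                 dist.method = "euclidean",
                 call = match.call()),
            class = c("mirray_tree", "hclust"))
}

#' Left-to-right leaf order of a cluster tree
#'
#' @param tree Result of [average_linkage()].
#' @return Character vector of leaf labels in dendrogram order (indices
#'   as character if the tree is unlabelled).
#' @export
leaf_order <- function(tree) {
  labs <- tree$labels
  if (is.null(labs)) labs <- as.character(seq_along(tree$order))
  labs[tree$order]
}
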