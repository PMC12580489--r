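# Chemometric stage: z-score standardization, PCA, Ward-criterion
# agglomerative clustering, and the k-cluster cut.
#
# Conventions (both flagged in output metadata because published protocols
# rarely state them):
#   * z-score uses the population (divide-by-n) standard deviation;
#   * Ward merge heights are the objective increase
#     dESS(A,B) = |A||B| / (|A|+|B|) * ||centroid(A) - centroid(B)||^2,
#     with ties broken by the smallest lexicographic cluster-index pair.
#     stats::hclust("ward.D" on squared Euclidean distances) yields exactly
#     twice these heights.

#' Z-score standardization (population sd)
#'
#' Centers each column to mean 0 and scales to population standard
#' deviation 1 (divide by n, not n-1).
#'
#' @param x numeric matrix or all-numeric data frame (molecules x
#'   descriptors).
#' @return numeric matrix with attributes `center` and `scale`.
#' @export
zscore <- function(x) {
  x <- as.matrix(x)
  if (!is.numeric(x) || anyNA(x))
    dmaq2_stop("dmaq2_type_error", "zscore needs a complete numeric matrix")
  mu <- colMeans(x)
  sdev <- sqrt(colMeans(sweep(x, 2, mu)^2))
  if (any(sdev == 0))
    dmaq2_stop("dmaq2_constant_column", "constant column(s): %s",
               paste(colnames(x)[sdev == 0], collapse = ", "))
  z <- sweep(sweep(x, 2, mu), 2, sdev, "/")
  attr(z, "center") <- mu
  attr(z, "scale") <- sdev
  z
}

#' Principal component analysis of standardized descriptors
#'
#' Eigendecomposition of the correlation matrix (the covariance of z-scored
#' data), components sorted by decreasing eigenvalue.  Loading signs are
#' fixed deterministically: the largest-magnitude entry of each loading
#' column is made positive.
#'
#' @param z standardized matrix from [zscore()] (rows >= 2).
#' @return list of class `dmaq2_pca`: `loadings` (descriptors x components,
#'   orthonormal columns), `scores` (= z %*% loadings),
#'   `explained_variance_ratio`.
#' @export
pca <- function(z) {
  z <- as.matrix(z)
  if (nrow(z) < 2L) dmaq2_stop("dmaq2_type_error", "PCA needs >= 2 rows")
  if (anyNA(z)) dmaq2_stop("dmaq2_type_error", "PCA input has missing values")
  n <- nrow(z)
  covm <- crossprod(z) / n          # population covariance of z-scores
  eg <- eigen(covm, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  V <- eg$vectors
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  rownames(V) <- colnames(z)
  colnames(V) <- paste0("PC", seq_len(ncol(V)))
  scores <- z %*% V
  structure(list(
    loadings = V,
    scores = scores,
    explained_variance_ratio = ev / sum(ev)
  ), class = "dmaq2_pca")
}

# dESS between two clusters given centroids and sizes
ward_delta <- function(c1, c2, n1, n2) {
  n1 * n2 / (n1 + n2) * sum((c1 - c2)^2)
}

#' Ward-criterion agglomerative hierarchical clustering
#'
#' Greedy agglomeration in Euclidean descriptor space: at each step the
#' pair of clusters whose merger least increases the total within-cluster
#' sum of squares (dESS) is joined; the merge height recorded is that dESS
#' increase.  Ties break toward the smallest lexicographic pair of current
#' cluster indices, making the dendrogram fully deterministic.
#'
#' @param x numeric matrix (observations x variables), typically z-scored
#'   descriptors; duplicate rows are allowed (zero-height merges).
#' @param labels leaf labels (default rownames or 1..n).
#' @return list of class `dmaq2_dendrogram`: `merges` data frame
#'   (`a`, `b`, `height`, `size`; negative entries denote leaves, positive
#'   entries earlier merges, as in [stats::hclust()]), `labels`, `n`.
#' @export
ward_hca <- function(x, labels = NULL) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 2L) dmaq2_stop("dmaq2_type_error", "clustering needs >= 2 rows")
  if (is.null(labels)) labels <- rownames(x)
  if (is.null(labels)) labels <- as.character(seq_len(n))

  # cluster slots: leaves occupy 1..n, merges fill n+1 .. 2n-1
  cent <- rbind(x, matrix(NA_real_, n - 1L, ncol(x)))
  size <- c(rep(1L, n), integer(n - 1L))
  alive <- c(rep(TRUE, n), rep(FALSE, n - 1L))

  merges <- data.frame(a = integer(n - 1L), b = integer(n - 1L),
                       height = numeric(n - 1L), size = integer(n - 1L))
  idx_of <- c(-seq_len(n), seq_len(n - 1L))  # hclust-style id per slot

  for (step in seq_len(n - 1L)) {
    live <- which(alive)                     # ascending slot order
    best <- NULL
    best_d <- Inf
    # visit pairs in lexicographic (i, j) order; strict '<' keeps the
    # lexicographically smallest pair among ties
    for (ii in seq_len(length(live) - 1L)) {
      for (jj in (ii + 1L):length(live)) {
        i <- live[ii]; j <- live[jj]
        d <- ward_delta(cent[i, ], cent[j, ], size[i], size[j])
        if (d < best_d) {
          best_d <- d
          best <- c(i, j)
        }
      }
    }
    i <- best[1]; j <- best[2]
    new <- n + step
    cent[new, ] <- (size[i] * cent[i, ] + size[j] * cent[j, ]) / (size[i] + size[j])
    size[new] <- size[i] + size[j]
    alive[c(i, j)] <- FALSE
    alive[new] <- TRUE
    merges$a[step] <- idx_of[i]
    merges$b[step] <- idx_of[j]
    merges$height[step] <- best_d
    merges$size[step] <- size[new]
  }
  structure(list(merges = merges, labels = labels, n = n),
            class = "dmaq2_dendrogram")
}

#' @export
print.dmaq2_dendrogram <- function(x, ...) {
  cat(sprintf("<dmaq2_dendrogram> %d leaves, %d Ward merges, max height %.4g\n",
              x$n, nrow(x$merges), max(x$merges$height)))
  invisible(x)
}

#' Convert a Ward dendrogram to an hclust object
#'
#' Heights are the dESS merge increases; `stats::hclust`'s `ward.D` on
#' squared Euclidean distances produces twice these heights, so rescale
#' before numerical comparison across conventions.
#'
#' @param d a [ward_hca()] result.
#' @return an object of class `hclust` (plottable with `plot()`).
#' @export
as_hclust <- function(d) {
  m <- cbind(d$merges$a, d$merges$b)
  structure(list(
    merge = m, height = d$merges$height,
    order = hclust_leaf_order(m, d$n),
    labels = d$labels, method = "ward-dESS",
    call = match.call(), dist.method = "euclidean"
  ), class = "hclust")
}

# leaf order by left-to-right traversal of the merge tree
hclust_leaf_order <- function(merge, n) {
  walk <- function(node) {
    if (node < 0) return(-node)
    c(walk(merge[node, 1]), walk(merge[node, 2]))
  }
  walk(nrow(merge))
}

#' Cut a Ward dendrogram into k clusters
#'
#' Undoes the last `k - 1` merges; labels are renumbered 1..k in order of
#' first leaf occurrence, so the labelling is stable across runs.
#'
#' @param d a [ward_hca()] result.
#' @param k number of clusters, `1 <= k <= n`.
#' @return integer vector of cluster labels, one per leaf, named by leaf
#'   label.
#' @export
cut_clusters <- function(d, k) {
  n <- d$n
  if (k < 1L || k > n) dmaq2_stop("dmaq2_type_error", "k must be in 1..%d", n)
  lab <- -seq_len(n)          # cluster id per leaf; start as own leaf
  # replay all but the last k-1 merges
  keep <- n - k
  assign_id <- lab
  for (step in seq_len(keep)) {
    a <- d$merges$a[step]; b <- d$merges$b[step]
    assign_id[assign_id %in% c(a, b)] <- step
  }
  # renumber by first occurrence
  first <- unique(assign_id)
  out <- match(assign_id, first)
  names(out) <- d$labels
  out
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same items;
#' 1 means identical partitions (up to label permutation), ~0 means
#' chance-level agreement.
#'
#' @param a,b cluster label vectors of equal length.
#' @return scalar ARI.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b))
    dmaq2_stop("dmaq2_type_error", "label vectors differ in length")
  tab <- table(a, b)
  n <- length(a)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)   # degenerate: single cluster both
  (sum_ij - expected) / (max_index - expected)
}
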