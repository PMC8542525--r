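#' K-means clustering of accessions by ancestry-ratio vectors
#'
#' Runs Lloyd-style k-means (via \code{\link[stats]{kmeans}}) on the
#' rows of Q with \code{n_init} seeded random restarts, keeping the
#' assignment with the lowest within-cluster sum of squares (equivalently
#' the highest BCTSS ratio).
#'
#' @param Q n x K numeric matrix of feature vectors (ancestry ratios) or
#'   an \code{admixture_fit}.
#' @param k number of clusters, 1 <= k <= n.
#' @param n_init number of random restarts.
#' @param seed integer seed.
#' @return object of class \code{cluster_assignment}: list with
#'   \code{labels} (integer 1..k per accession), \code{k},
#'   \code{centroids}, \code{bctss}, and empty \code{support} fields to
#'   be filled by \code{\link{bootstrap_support}}.
#' @export
kmeans_cluster <- function(Q, k, n_init = 20L, seed = 1L) {
  if (inherits(Q, "admixture_fit")) Q <- Q$Q
  Q <- as.matrix(Q)
  n <- nrow(Q)
  stopifnot(k >= 1, k <= n)
  set.seed(seed)
  if (k == 1L) {
    labels <- rep(1L, n)
    cent <- matrix(colMeans(Q), 1)
  } else if (k == n) {
    labels <- seq_len(n)        # every point its own centroid
    cent <- Q
  } else {
    km <- safe_kmeans(Q, k, n_init)
    labels <- km$cluster
    cent <- km$centers
  }
  new_cluster_assignment(labels, k, cent, bctss_ratio(Q, labels))
}

# kmeans that tolerates duplicated rows (bootstrap resamples): failed
# random starts (duplicate initial centers, empty clusters) are retried.
safe_kmeans <- function(x, k, n_init, iter.max = 300L) {
  best <- NULL
  attempts <- 0L
  while (n_init > 0L && attempts < 10L * n_init) {
    attempts <- attempts + 1L
    km <- tryCatch(
      suppressWarnings(stats::kmeans(x, centers = k, nstart = 1L,
                                     iter.max = iter.max)),
      error = function(e) NULL)
    if (is.null(km)) next
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    n_init <- n_init - 1L
  }
  if (is.null(best))
    stop("k-means failed: fewer than k distinct points")
  best
}

new_cluster_assignment <- function(labels, k, centroids, bctss,
                                   support = NULL, n_boot = 0L, seed = NA) {
  structure(list(labels = as.integer(labels), k = as.integer(k),
                 centroids = centroids, bctss = bctss,
                 support = support, n_boot = n_boot, seed = seed),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("cluster_assignment: k = %d, n = %d, BCTSS ratio %.3f\n",
              x$k, length(x$labels), x$bctss))
  print(table(cluster = x$labels))
  if (!is.null(x$support)) {
    cat(sprintf("bootstrap support (%d replicates):\n", x$n_boot))
    print(round(x$support, 3))
  }
  invisible(x)
}

#' Between-cluster / total sum-of-squares ratio
#'
#' BCTSS = (TSS - WSS)/TSS, where TSS is the total sum of squared
#' distances to the grand mean and WSS the within-cluster sum of squared
#' distances to cluster centroids.  0 for a single cluster (the
#' single-cluster reference), approaching 1 for perfectly separated
#' clusters; defined as 0 when TSS = 0 (all rows identical).
#'
#' @param Q n x K feature matrix.
#' @param labels cluster label per row.
#' @return a number in [0, 1].
#' @export
bctss_ratio <- function(Q, labels) {
  Q <- as.matrix(Q)
  stopifnot(length(labels) == nrow(Q))
  tss <- sum(sweep(Q, 2, colMeans(Q))^2)
  if (tss == 0) return(0)
  wss <- 0
  for (c in unique(labels)) {
    rows <- Q[labels == c, , drop = FALSE]
    wss <- wss + sum(sweep(rows, 2, colMeans(rows))^2)
  }
  (tss - wss) / tss
}

#' Choose the number of clusters by the BCTSS elbow
#'
#' Computes the BCTSS ratio for each k in \code{k_range} (plus flanking
#' values for context) and picks the largest k whose marginal gain
#' bctss(k) - bctss(k-1) is still significant, i.e. at least
#' \code{min_gain} of the total sum of squares; the next split's gain
#' falls below that bar, which is where the curve flattens into its
#' elbow.  A split that stops explaining at least 2% of total variance
#' (the default bar) is treated as noise; for ancestry-ratio vectors,
#' real subpopulations - including an admixed group sitting between two
#' ancestors - each explain well over that share.  If no candidate
#' clears the bar the smallest k is returned.  The full curve is always
#' emitted so the choice can be overridden.
#'
#' @param Q n x K feature matrix or \code{admixture_fit}.
#' @param k_range contiguous integer candidates, min >= 2.
#' @param n_init,seed passed to \code{\link{kmeans_cluster}}.
#' @param min_gain smallest BCTSS gain (fraction of total sum of
#'   squares) still considered a real split.
#' @return list with \code{k} (the choice), \code{curve} (data.frame of
#'   k, bctss and gain including the flanking k values) and
#'   \code{assignments} (the per-k clusterings).
#' @export
select_k_elbow <- function(Q, k_range = 2:8, n_init = 20L, seed = 1L,
                           min_gain = 0.02) {
  if (inherits(Q, "admixture_fit")) Q <- Q$Q
  k_range <- sort(unique(as.integer(k_range)))
  stopifnot(min(k_range) >= 2, all(diff(k_range) == 1))
  ks <- c(min(k_range) - 1L, k_range)
  if (max(k_range) + 1L <= nrow(Q)) ks <- c(ks, max(k_range) + 1L)
  fits <- lapply(ks, function(k)
    kmeans_cluster(Q, k, n_init = n_init, seed = stage_seed(seed, k)))
  names(fits) <- ks
  b <- vapply(fits, `[[`, 0, "bctss")
  gain <- c(NA, diff(b))
  ok <- which(ks %in% k_range & !is.na(gain) & gain >= min_gain)
  best_k <- if (length(ok)) max(ks[ok]) else min(k_range)
  list(k = best_k,
       curve = data.frame(k = ks, bctss = b, gain = gain),
       assignments = fits)
}

#' Bootstrap support of a reference clustering
#'
#' Clusterwise stability: for each bootstrap replicate, n accessions are
#' resampled with replacement and re-clustered by k-means at the
#' reference k; each reference cluster is then matched to the replicate
#' cluster with maximal Jaccard similarity, computed on the resampled
#' accession multiset, and that Jaccard value is recorded.  A cluster's
#' support is its mean recorded Jaccard across replicates.  Replicates
#' in which a reference cluster has no resampled members are skipped for
#' that cluster (the count is tracked).
#'
#' @param Q n x K feature matrix or \code{admixture_fit}.
#' @param reference a \code{cluster_assignment} to assess.
#' @param n_boot number of bootstrap replicates (the analysis default is
#'   10000).
#' @param n_init k-means restarts within each replicate.
#' @param seed integer seed.
#' @param resample_fun function of n returning the resampled accession
#'   indices; defaults to sampling with replacement (override for
#'   diagnostics, e.g. an identity resample).
#' @return the \code{reference} object with \code{support} (per-cluster
#'   mean Jaccard), \code{support_n} (replicates contributing per
#'   cluster), \code{n_boot} and \code{seed} filled in.
#' @export
bootstrap_support <- function(Q, reference, n_boot = 10000L, n_init = 5L,
                              seed = 1L,
                              resample_fun = function(n)
                                sample.int(n, n, replace = TRUE)) {
  if (inherits(Q, "admixture_fit")) Q <- Q$Q
  Q <- as.matrix(Q)
  stopifnot(inherits(reference, "cluster_assignment"), n_boot >= 1)
  n <- nrow(Q)
  k <- reference$k
  ref <- reference$labels
  acc <- numeric(k)
  cnt <- integer(k)
  set.seed(seed)
  for (b in seq_len(n_boot)) {
    idx <- resample_fun(n)
    rep_labels <- if (k == 1L) rep(1L, length(idx)) else
      safe_kmeans(Q[idx, , drop = FALSE], k, n_init,
                  iter.max = 100L)$cluster
    ref_b <- ref[idx]
    for (cl in seq_len(k)) {
      in_ref <- ref_b == cl
      if (!any(in_ref)) next
      jac <- vapply(seq_len(k), function(rc) {
        in_rep <- rep_labels == rc
        sum(in_ref & in_rep) / sum(in_ref | in_rep)
      }, 0)
      acc[cl] <- acc[cl] + max(jac)
      cnt[cl] <- cnt[cl] + 1L
    }
  }
  support <- ifelse(cnt > 0, acc / cnt, NA_real_)
  out <- reference
  out$support <- support
  out$support_n <- cnt
  out$n_boot <- as.integer(n_boot)
  out$seed <- seed
  out
}
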