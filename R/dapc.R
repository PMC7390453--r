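#' PCA reduction of a complete dosage matrix
#'
#' Centres (and optionally scales) the imputed dosage matrix and projects it
#' onto leading principal components — the dimension-reduction step ahead of
#' k-means cluster search and discriminant analysis.
#'
#' @param gm a [genotype_matrix()] with no missing calls (see
#'   [impute_missing()]).
#' @param n_pcs number of components to keep; overrides `variance_kept`.
#' @param variance_kept keep the smallest number of PCs explaining at least
#'   this fraction of variance (default 0.9), capped at `max_pc_frac` of the
#'   sample count.
#' @param scale divide loci by their standard deviation. Default FALSE.
#' @param max_pc_frac cap on n_pcs as a fraction of n samples; default 1/3.
#'   Ignored when `n_pcs` is given explicitly.
#' @return matrix of PC scores (samples x components) with attribute
#'   `explained` (per-component variance fractions).
#' @export
pca_reduce <- function(gm, n_pcs = NULL, variance_kept = 0.9, scale = FALSE,
                       max_pc_frac = 1/3) {
  X <- gm$calls
  if (anyNA(X)) stop("pca_reduce needs complete data; run impute_missing() first")
  keep <- which(apply(X, 2, stats::var) > 0)
  p <- stats::prcomp(X[, keep, drop = FALSE], center = TRUE, scale. = scale)
  expl <- p$sdev^2 / sum(p$sdev^2)
  rank <- sum(p$sdev > 1e-10 * p$sdev[1])
  if (is.null(n_pcs)) {
    n_pcs <- which(cumsum(expl) >= variance_kept)[1]
    n_pcs <- min(n_pcs, max(1L, floor(nrow(X) * max_pc_frac)), rank)
  } else if (n_pcs > rank) {
    stop("n_pcs exceeds matrix rank (", rank, ")")
  }
  scores <- p$x[, seq_len(n_pcs), drop = FALSE]
  attr(scores, "explained") <- expl[seq_len(n_pcs)]
  scores
}

#' Scan cluster numbers with k-means and information criteria
#'
#' For each K in 1..K_max, runs k-means with `n_starts` restarts (best
#' within-cluster sum of squares kept) and scores the partition with
#' BIC = n ln(WSS/n) + K ln(n) and AIC = n ln(WSS/n) + 2K. The K with the
#' lowest value of each criterion is reported; raw WSS is kept so any other
#' criterion can be recomputed.
#'
#' @param scores PC score matrix from [pca_reduce()].
#' @param K_max largest cluster number to try (<= n samples).
#' @param n_starts k-means restarts per K; default 100.
#' @param seed integer seed.
#' @return list of class `cluster_scan`: data.frame `scan` (K, WSS, BIC,
#'   AIC), `K_bic`, `K_aic`, `assignments` (integer vector at `K_bic`),
#'   `assignments_aic`, `n_pcs`.
#' @export
find_clusters <- function(scores, K_max = 10, n_starts = 100, seed = NULL) {
  scores <- as.matrix(scores)
  n <- nrow(scores)
  if (K_max > n) stop("K_max exceeds number of samples")
  tot <- sum(scale(scores, scale = FALSE)^2)
  if (tot < 1e-12) stop("degenerate scores: all samples identical")
  with_seed(seed, {
    wss <- numeric(K_max)
    parts <- vector("list", K_max)
    wss[1] <- tot
    parts[[1]] <- rep(1L, n)
    for (K in seq_len(K_max)[-1]) {
      if (K >= n) {
        km <- stats::kmeans(scores, centers = n, iter.max = 100)
      } else {
        km <- stats::kmeans(scores, centers = K, nstart = n_starts,
                            iter.max = 100)
      }
      wss[K] <- km$tot.withinss
      parts[[K]] <- km$cluster
    }
    K <- seq_len(K_max)
    # WSS = 0 (perfect fit) would put ln at -Inf; floor at a tiny fraction
    wss_safe <- pmax(wss, 1e-12 * tot)
    bic <- n * log(wss_safe / n) + K * log(n)
    aic <- n * log(wss_safe / n) + 2 * K
    structure(list(
      scan = data.frame(K = K, WSS = wss, BIC = bic, AIC = aic),
      K_bic = K[which.min(bic)],
      K_aic = K[which.min(aic)],
      assignments = parts[[K[which.min(bic)]]],
      assignments_aic = parts[[K[which.min(aic)]]],
      n_pcs = ncol(scores)
    ), class = "cluster_scan")
  })
}

#' Discriminant-space assignment of samples to clusters
#'
#' Fits linear discriminant axes (maximising between- over within-cluster
#' variance) to the PC scores with the scanned cluster labels, then assigns
#' each sample to the cluster with the nearest centroid in discriminant
#' space. Membership probabilities are inverse-squared-distance weights to
#' the centroids, so a sample sitting on a centroid gets probability 1 and
#' a sample equidistant from two centroids 0.5/0.5.
#'
#' @param scores PC score matrix.
#' @param clusters integer cluster labels (e.g. `cluster_scan$assignments`).
#' @param n_discriminants number of discriminant axes; default
#'   `min(K - 1, ncol(scores))`.
#' @return list: `membership` (samples x clusters probability matrix, rows
#'   sum to 1), `assigned` (integer vector), `axes` (discriminant
#'   projections of the samples).
#' @export
dapc_assign <- function(scores, clusters, n_discriminants = NULL) {
  scores <- as.matrix(scores)
  K <- length(unique(clusters))
  n <- nrow(scores)
  if (K == 1L) {
    return(list(membership = matrix(1, n, 1,
                                    dimnames = list(rownames(scores), "1")),
                assigned = rep(1L, n), axes = scores[, 1, drop = FALSE]))
  }
  if (is.null(n_discriminants)) n_discriminants <- min(K - 1L, ncol(scores))
  fit <- MASS::lda(scores, grouping = factor(clusters))
  ld <- as.matrix(scores) %*% fit$scaling[, seq_len(n_discriminants), drop = FALSE]
  cent <- apply(ld, 2, function(col) tapply(col, clusters, mean))
  cent <- matrix(cent, nrow = K)
  d2 <- outer(rowSums(ld^2), rowSums(cent^2), "+") - 2 * ld %*% t(cent)
  d2 <- pmax(d2, 0)
  eps <- 1e-12 * max(d2)
  w <- 1 / (d2 + eps)
  membership <- w / rowSums(w)
  colnames(membership) <- sort(unique(clusters))
  rownames(membership) <- rownames(scores)
  list(membership = membership,
       assigned = max.col(membership),
       axes = ld)
}
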