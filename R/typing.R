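## Graph-based clustering of co-twin pairs on their discordance profiles,
## 2-D embedding for reporting, centroid-rule UPV type assignment, and the
## hierarchical heat-map ordering.

## shared-nearest-neighbor graph with Jaccard edge weights; neighbor sets
## include self plus the k nearest others (Euclidean)
.snnGraph <- function(X, k, prune = 1 / 15) {
  n <- nrow(X)
  dm <- as.matrix(dist(X))
  nb <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    ord <- order(dm[i, ])  # ties broken by row index (stable)
    nb[i, ord[seq_len(k + 1)]] <- TRUE  # self sits at distance 0
    nb[i, i] <- TRUE
  }
  inter <- tcrossprod(nb * 1)
  uni <- (k + 1) * 2 - inter
  J <- inter / uni
  diag(J) <- 0
  J[J < prune] <- 0
  igraph::graph_from_adjacency_matrix(J, mode = "max", weighted = TRUE,
                                      diag = FALSE)
}

.louvain <- function(g, resolution, seed) {
  withSeed(seed, igraph::cluster_louvain(g, resolution = resolution))
}

#' Cluster co-twin pairs on trait discordances
#'
#' Traits are standardized (z-score per trait), a k-nearest-neighbor graph
#' (Euclidean) is converted to a shared-nearest-neighbor graph with Jaccard
#' edge weights, and communities are found by modularity (Louvain) at the
#' given resolution. The observed modularity is compared against a null
#' reference to guard against claiming structure in unstructured data. The
#' default null is a moment-matched Gaussian parametric bootstrap: replicate
#' data are drawn from a single multivariate normal with the observed mean
#' and covariance, then re-standardized, re-graphed and re-clustered. This
#' preserves the correlation structure that BMI orientation and derived
#' (summed) traits induce even without any cluster structure, while
#' destroying multimodality; a column-permutation null
#' (\code{null_method = "permute"}) and a degree-preserving edge-rewiring
#' null (\code{"rewire"}) are also available. If the observed modularity
#' does not exceed the null (p > 0.05), the partition is flagged unstable
#' and the number of stable clusters is reported as 1.
#'
#' @param D a \linkS4class{DiscordanceMatrix} with no missing cells
#' @param k_neighbors neighbors for the kNN graph (default 20, capped at
#'   n_pairs/3)
#' @param resolution Louvain resolution (default 0.8)
#' @param seed integer
#' @param n_null null replicates for the structure test (default 49; 0 skips)
#' @param null_method "gaussian" (default), "permute" or "rewire"
#' @param prune SNN Jaccard pruning threshold (default 1/15)
#' @return a \linkS4class{UPVClustering} (types unset; see
#'   \code{\link{assignClusterTypes}})
#' @export
clusterCotwinPairs <- function(D, k_neighbors = 20, resolution = 0.8,
                               seed = 1L, n_null = 49,
                               null_method = c("gaussian", "permute",
                                               "rewire"),
                               prune = 1 / 15) {
  null_method <- match.arg(null_method)
  X <- discordanceValues(D)
  stopIfNot1(!anyNA(X), "discordance matrix has missing cells")
  n <- nrow(X)
  k <- min(k_neighbors, max(2L, floor(n / 3)))
  if (n < k_neighbors + 1) stop("insufficient pairs", call. = FALSE)
  Z <- zscoreCols(X, warn = FALSE)
  g <- .snnGraph(Z, k, prune)
  cl <- .louvain(g, resolution, childSeed(seed, "louvain"))
  labels <- setNames(as.integer(igraph::membership(cl)), rownames(X))
  mod <- igraph::modularity(cl)

  nullMod <- rep(NA_real_, n_null)
  if (n_null > 0) {
    chS <- if (null_method == "gaussian") {
      S <- cov(Z)
      chol(S + diag(1e-8 * mean(diag(S)), ncol(S)))
    }
    for (b in seq_len(n_null)) {
      if (null_method == "gaussian") {
        Zb <- withSeed(childSeed(seed, paste0("null", b)),
                       matrix(rnorm(n * ncol(Z)), n) %*% chS)
        gb <- .snnGraph(zscoreCols(Zb, warn = FALSE), k, prune)
      } else if (null_method == "permute") {
        Zb <- withSeed(childSeed(seed, paste0("null", b)),
                       apply(Z, 2, sample))
        gb <- .snnGraph(Zb, k, prune)
      } else {
        gb <- withSeed(childSeed(seed, paste0("null", b)),
                       igraph::rewire(g, igraph::keeping_degseq(
                         niter = igraph::ecount(g) * 10)))
        igraph::E(gb)$weight <- igraph::E(g)$weight
      }
      nullMod[b] <- igraph::modularity(
        .louvain(gb, resolution, childSeed(seed, paste0("nullcl", b))))
    }
  }
  p <- if (n_null > 0) (1 + sum(nullMod >= mod)) / (n_null + 1) else NA_real_
  nClusters <- length(unique(labels))
  nStable <- if (!is.na(p) && p > 0.05) 1L else nClusters
  cent <- .clusterCentroids(labels, X)
  new("UPVClustering", labels = labels, types = character(0),
      embedding = matrix(numeric(0), 0, 2),
      centroids = cent,
      parameters = list(k_neighbors = k, resolution = resolution,
                        seed = seed, modularity = mod,
                        null_modularity = nullMod, structure_p = p,
                        n_stable_clusters = nStable,
                        null_method = null_method))
}

.clusterCentroids <- function(labels, X) {
  cls <- sort(unique(labels))
  cent <- t(vapply(cls, function(cl)
    colMeans(X[labels == cl, , drop = FALSE]), numeric(ncol(X))))
  rownames(cent) <- as.character(cls)
  colnames(cent) <- colnames(X)
  cent
}

#' Embed co-twin pairs in two dimensions
#'
#' UMAP on the standardized discordance matrix, deterministic given the
#' seed. The embedding is for reporting only; cluster membership is never
#' read off it.
#'
#' @param D a \linkS4class{DiscordanceMatrix}
#' @param n_neighbors,min_dist UMAP parameters
#' @param seed integer
#' @return matrix pair x 2
#' @export
embedPairs <- function(D, n_neighbors = 15, min_dist = 0.1, seed = 1L) {
  X <- discordanceValues(D)
  stopIfNot1(!anyNA(X), "discordance matrix has missing cells")
  if (n_neighbors >= nrow(X))
    stop("n_neighbors must be smaller than the number of pairs",
         call. = FALSE)
  Z <- zscoreCols(X, warn = FALSE)
  emb <- withSeed(childSeed(seed, "umap"),
                  uwot::umap(Z, n_neighbors = n_neighbors,
                             min_dist = min_dist, n_threads = 1,
                             n_sgd_threads = 1))
  rownames(emb) <- rownames(X)
  colnames(emb) <- c("umap1", "umap2")
  emb
}

#' Assign UPV types to pair clusters
#'
#' Per cluster, compute the mean fat-trait discordance (m_fat), the mean
#' lean-trait discordance (m_lean) and the mean absolute discordance over
#' all traits (m_abs). The cluster with minimal m_abs is Concordant. A
#' remaining cluster is TypeB when m_fat > 0 and m_lean >= tau_lean
#' (coordinated fat and lean gain), TypeA when m_fat > 0 and m_lean <= 0
#' (fat gain with lean reduction), Intermediate when m_fat > 0 and
#' 0 < m_lean < tau_lean, and Unassigned otherwise.
#'
#' @param clustering a \linkS4class{UPVClustering}
#' @param D the \linkS4class{DiscordanceMatrix} used to cluster
#' @param fat_traits,lean_traits trait name tags
#' @param tau_lean lean threshold; default half the cohort s.d. of lean
#'   discordances
#' @return the clustering with types filled in
#' @export
assignClusterTypes <- function(clustering, D, fat_traits, lean_traits,
                               tau_lean = NULL) {
  if (missing(fat_traits) || missing(lean_traits) ||
      !length(fat_traits) || !length(lean_traits))
    stop("fat/lean trait tags are required", call. = FALSE)
  X <- discordanceValues(D)
  stopIfNot1(all(fat_traits %in% colnames(X)), "unknown fat traits")
  stopIfNot1(all(lean_traits %in% colnames(X)), "unknown lean traits")
  labels <- clusterLabels(clustering)
  X <- X[names(labels), , drop = FALSE]
  if (is.null(tau_lean))
    tau_lean <- 0.5 * sd(as.vector(X[, lean_traits]))
  cent <- .clusterCentroids(labels, X)
  mFat <- rowMeans(cent[, fat_traits, drop = FALSE])
  mLean <- rowMeans(cent[, lean_traits, drop = FALSE])
  mAbs <- vapply(rownames(cent), function(cl)
    mean(abs(X[labels == as.integer(cl), , drop = FALSE])), 0)
  types <- setNames(rep("Unassigned", nrow(cent)), rownames(cent))
  conc <- names(which.min(mAbs))
  types[conc] <- "Concordant"
  for (cl in setdiff(names(types), conc)) {
    f <- mFat[[cl]]; l <- mLean[[cl]]
    types[cl] <- if (f > 0 && l >= tau_lean) "TypeB"
    else if (f > 0 && l <= 0) "TypeA"
    else if (f > 0 && l > 0 && l < tau_lean) "Intermediate"
    else "Unassigned"
  }
  ## TypeB designates the single coordinated-overgrowth cluster: when
  ## several qualify, keep the one with the largest lean centroid and
  ## demote the rest to Intermediate
  bs <- names(types)[types == "TypeB"]
  if (length(bs) > 1) {
    keepB <- bs[which.max(mLean[bs])]
    types[setdiff(bs, keepB)] <- "Intermediate"
  }
  clustering@types <- types
  clustering@centroids <- cent
  clustering@parameters$tau_lean <- tau_lean
  clustering
}

#' Hierarchical heat-map ordering of a discordance matrix
#'
#' Rows are z-scaled (constant rows become zeros with a warning), then rows
#' and columns are clustered hierarchically with Euclidean distance and
#' complete linkage.
#'
#' @param D a \linkS4class{DiscordanceMatrix} or numeric matrix
#' @param scale_rows z-scale rows before clustering (default TRUE)
#' @return list(row_order, col_order, scaled, row_heights, col_heights,
#'   row_hclust, col_hclust)
#' @export
heatmapOrder <- function(D, scale_rows = TRUE) {
  X <- if (is(D, "DiscordanceMatrix")) discordanceValues(D) else D
  stopIfNot1(!anyNA(X), "missing cells")
  S <- if (scale_rows) zscoreRows(X) else X
  hr <- if (nrow(S) >= 2) hclust(dist(S), method = "complete") else NULL
  hc <- if (ncol(S) >= 2) hclust(dist(t(S)), method = "complete") else NULL
  list(row_order = if (is.null(hr)) rownames(X) else rownames(X)[hr$order],
       col_order = if (is.null(hc)) colnames(X) else colnames(X)[hc$order],
       scaled = S,
       row_heights = if (is.null(hr)) numeric(0) else hr$height,
       col_heights = if (is.null(hc)) numeric(0) else hc$height,
       row_hclust = hr, col_hclust = hc)
}
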