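## Population stratification on a gene signature: saturation-point k-means,
## bootstrap Jaccard stability, the UPV-B median-rank score, and PC-based
## variance attribution.

.checkSignatureGenes <- function(expr, genes, hard = TRUE) {
  miss <- setdiff(genes, rownames(expr))
  if (length(miss)) {
    msg <- paste0("signature genes absent from expression: ",
                  paste(head(miss, 10), collapse = ", "),
                  if (length(miss) > 10) " ...")
    if (hard || length(miss) == length(genes)) stop(msg, call. = FALSE)
    warning(msg, "; excluded")
  }
  intersect(genes, rownames(expr))
}

#' Stratify individuals on a gene signature
#'
#' Individuals are k-means clustered (25 restarts, deterministic given the
#' seed) on z-scored signature-gene expression for k = 1..k_max. The chosen
#' k is the saturation point of the within-cluster dispersion curve: the
#' smallest k whose relative WSS drop to k+1 falls below
#' \code{saturation_threshold}. Per-cluster stability is the mean Jaccard
#' similarity against \code{n_boot} bootstrap reclusterings (clusters matched
#' by maximal Jaccard). Cluster ids are renumbered by ascending mean UPV-B
#' rank so that cluster 1 is the most light-like. When phenotypes are
#' supplied, individuals are ordered by BMI within cluster.
#'
#' @param expr genes x individuals matrix
#' @param signature a \linkS4class{GeneSignature}
#' @param k_max maximum k (default 10)
#' @param n_boot bootstrap replicates (default 100; 0 reports stability NA)
#' @param seed integer
#' @param saturation_threshold relative WSS-drop threshold (default 0.1)
#' @param nstart k-means restarts (default 25)
#' @param bmi optional named BMI vector for within-cluster ordering
#' @return a \linkS4class{StratificationResult}
#' @export
stratifyIndividuals <- function(expr, signature, k_max = 10, n_boot = 100,
                                seed = 1L, saturation_threshold = 0.1,
                                nstart = 25, bmi = NULL) {
  stopIfNot1(length(signatureGenes(signature)) > 0, "signature is empty")
  genes <- .checkSignatureGenes(expr, signatureGenes(signature), hard = TRUE)
  n <- ncol(expr)
  stopIfNot1(n >= k_max * 3, "need at least 3*k_max individuals")
  X <- t(zscoreRows(expr[genes, , drop = FALSE], warn = FALSE))

  wss <- numeric(k_max)
  fits <- vector("list", k_max)
  for (k in seq_len(k_max)) {
    if (k == 1) {
      wss[k] <- sum(scale(X, scale = FALSE)^2)
      fits[[k]] <- rep(1L, n)
    } else {
      km <- withSeed(childSeed(seed, paste0("km", k)),
                     kmeans(X, centers = k, nstart = nstart,
                            iter.max = 50))
      wss[k] <- km$tot.withinss
      fits[[k]] <- km$cluster
    }
  }
  rel <- (wss[-k_max] - wss[-1]) / wss[-k_max]
  sat <- which(rel < saturation_threshold)
  chosen <- if (length(sat)) min(sat) else k_max
  cl <- setNames(as.integer(fits[[chosen]]), colnames(expr))

  stability <- rep(NA_real_, chosen)
  if (n_boot > 0 && chosen > 1) {
    acc <- matrix(0, n_boot, chosen)
    for (b in seq_len(n_boot)) {
      idx <- withSeed(childSeed(seed, paste0("boot", b)),
                      unique(sample.int(n, n, replace = TRUE)))
      kmb <- withSeed(childSeed(seed, paste0("bootkm", b)),
                      kmeans(X[idx, , drop = FALSE], centers = chosen,
                             nstart = max(5, nstart %/% 5), iter.max = 50))
      for (c0 in seq_len(chosen)) {
        orig <- intersect(which(cl == c0), idx)
        jac <- vapply(seq_len(chosen), function(cb) {
          bootm <- idx[kmb$cluster == cb]
          u <- length(union(orig, bootm))
          if (u == 0) 0 else length(intersect(orig, bootm)) / u
        }, 0)
        acc[b, c0] <- max(jac)
      }
    }
    stability <- colMeans(acc)
  } else if (chosen == 1) {
    stability <- 1
  }

  rk <- upvbRank(expr, signature)
  meanRank <- tapply(rk[names(cl)], cl, mean)
  remap <- setNames(seq_along(meanRank), names(sort(meanRank)))
  cl <- setNames(as.integer(remap[as.character(cl)]), names(cl))
  stability <- stability[as.integer(names(sort(meanRank)))]

  ordering <- names(cl)
  if (!is.null(bmi)) {
    ordering <- unlist(lapply(seq_len(chosen), function(c0) {
      ids <- names(cl)[cl == c0]
      ids[order(bmi[ids])]
    }), use.names = FALSE)
  } else {
    ordering <- names(sort(cl))
  }

  new("StratificationResult", cluster = cl, k = as.integer(chosen),
      wss = wss, stability = as.numeric(stability), upvbRank = rk,
      hdacScore = setNames(numeric(0), character(0)), ordering = ordering)
}

#' UPV-B median-rank score
#'
#' For each signature gene, individuals are ranked 1..n by expression
#' (average ranks on ties); ranks of down-regulated genes are reflected
#' (n+1-rank) so that a high rank always means a heavy-like profile. The
#' score is the median rank across signature genes.
#'
#' @param expr genes x individuals matrix
#' @param signature a \linkS4class{GeneSignature}
#' @param reflect_down reflect ranks of down_in_heavy genes (default TRUE)
#' @return named numeric score per individual, in [1, n]
#' @export
upvbRank <- function(expr, signature, reflect_down = TRUE) {
  stopIfNot1(length(signatureGenes(signature)) > 0, "signature is empty")
  stopIfNot1(ncol(expr) >= 2, "need at least 2 individuals")
  genes <- .checkSignatureGenes(expr, signatureGenes(signature), hard = FALSE)
  dirs <- signatureDirections(signature)[genes]
  n <- ncol(expr)
  R <- t(apply(expr[genes, , drop = FALSE], 1, rank))
  if (reflect_down && any(dirs == "down_in_heavy")) {
    dn <- dirs == "down_in_heavy"
    R[dn, ] <- n + 1 - R[dn, ]
  }
  setNames(apply(R, 2, median), colnames(expr))
}

#' Variance attribution to signature-associated principal components
#'
#' PCA on centered expression with genes as variables. The per-PC
#' association with a gene set is the mean, over set genes, of the gene
#' contributions to that PC (squared loadings; contributions sum to 1 per
#' PC). PCs are sorted by descending association and the inflection index
#' of the sorted curve is the maximal discrete second difference
#' (kneedle-style); the cumulative explained-variance fraction of the
#' selected PCs is reported against all PCs. A flat association curve is
#' reported as uninformative.
#'
#' @param expr genes x individuals matrix (n >= 3 individuals)
#' @param gene_set character vector, subset of rownames(expr)
#' @return list(selected_pcs, cumulative_variance_fraction, association,
#'   contributions, variance_fraction, uninformative)
#' @export
pcSignatureContribution <- function(expr, gene_set) {
  stopIfNot1(ncol(expr) >= 3, "need at least 3 individuals")
  miss <- setdiff(gene_set, rownames(expr))
  stopIfNot1(length(miss) == 0,
             paste("gene_set members absent from expression:",
                   paste(head(miss, 5), collapse = ", ")))
  pca <- prcomp(t(expr), center = TRUE, scale. = FALSE)
  ## numerically zero-variance PCs span null-space directions (e.g. exact
  ## collinearity) and would otherwise dominate the association curve
  keep <- pca$sdev^2 > 1e-12 * max(pca$sdev^2)
  contrib <- pca$rotation[, keep, drop = FALSE]^2  # columns sum to 1
  assoc <- colMeans(contrib[gene_set, , drop = FALSE])
  varFrac <- pca$sdev[keep]^2 / sum(pca$sdev^2)
  ord <- order(assoc, decreasing = TRUE)
  s <- assoc[ord]
  spread <- max(s) - min(s)
  if (!is.finite(spread) || spread < 1e-12 * max(abs(s), 1e-300)) {
    return(list(selected_pcs = character(0),
                cumulative_variance_fraction = NA_real_,
                association = assoc, contributions = contrib,
                variance_fraction = varFrac, uninformative = TRUE))
  }
  m <- length(s)
  nSel <- if (m < 3) 1L else {
    d2 <- s[3:m] - 2 * s[2:(m - 1)] + s[1:(m - 2)]  # curvature at 2..m-1
    which.max(d2)                                    # elbow index - 1
  }
  sel <- names(s)[seq_len(nSel)]
  list(selected_pcs = sel,
       cumulative_variance_fraction = sum(varFrac[ord[seq_len(nSel)]]),
       association = assoc, contributions = contrib,
       variance_fraction = varFrac, uninformative = FALSE)
}
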