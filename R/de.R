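## Paired moderated differential expression (heavy - light) and derivation
## of the cluster-specific gene signature.
##
## The moderated t construction shrinks gene-wise residual variances toward
## a pooled prior estimated from the gene-wise variance distribution by
## moment matching on the log-variance scale (the scaled inverse chi-square
## empirical-Bayes construction), then refers effect / shrunken s.e. to a t
## distribution with residual + prior degrees of freedom.

## Newton inversion of the trigamma function (monotone decreasing on (0,Inf))
trigammaInverse <- function(x) {
  vapply(x, function(xi) {
    if (!is.finite(xi)) return(if (xi > 0) 1e-7 else Inf)
    if (xi <= 0) return(Inf)
    if (xi > 1e7) return(1 / sqrt(xi))
    if (xi < 1e-6) return(1 / xi)
    y <- 0.5 + 1 / xi
    for (iter in 1:50) {
      tri <- trigamma(y)
      dif <- tri * (1 - tri / xi) / psigamma(y, 2)
      y <- y + dif
      if (-dif / y < 1e-8) break
    }
    y
  }, 0)
}

## moment-matched scaled-F fit of gene-wise variances: returns prior df and
## prior variance such that s^2 ~ s0^2 F(df, df0)
.fitVariancePrior <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0
  if (sum(ok) < 2) return(list(df_prior = 0, var_prior = mean(s2[ok], na.rm = TRUE)))
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- var(e) - trigamma(df / 2)
  if (is.finite(evar) && evar > 0) {
    df_prior <- 2 * trigammaInverse(evar)
    var_prior <- exp(emean + digamma(df_prior / 2) - log(df_prior / 2))
  } else {
    ## no excess spread beyond chi-square sampling noise: variances look
    ## exchangeable, so the prior is the pooled (arithmetic mean) variance
    df_prior <- Inf
    var_prior <- mean(s2[ok])
  }
  list(df_prior = df_prior, var_prior = var_prior)
}

#' Paired moderated differential expression per pair cluster
#'
#' For each cluster of co-twin pairs, paired log-expression differences
#' (heavy - light) are fit per gene against an intercept plus centered
#' pair-level covariates. Gene-wise residual variances are moderated by
#' empirical-Bayes shrinkage toward a pooled prior (moment matching on the
#' log-variance scale); moderated t statistics and p-values use residual +
#' prior degrees of freedom, with Benjamini-Hochberg adjustment within each
#' cluster.
#'
#' @param expr genes x individuals log2 expression matrix
#' @param orient orientation data.frame (pair, light, heavy)
#' @param pair_clusters named vector, pair -> cluster label
#' @param covariates optional data.frame of pair-level covariates with
#'   rownames = pair IDs (e.g. age)
#' @param prior_df "auto" (estimate; default), or a number; 0 gives the
#'   ordinary paired t-test
#' @param min_pairs clusters with fewer pairs are skipped (default 3)
#' @return named list of data.frames (gene, cluster, effect, t, p, padj,
#'   n_pairs), one per cluster
#' @export
pairedModeratedDE <- function(expr, orient, pair_clusters, covariates = NULL,
                              prior_df = "auto", min_pairs = 3) {
  stopIfNot1(is.matrix(expr) && !is.null(rownames(expr)),
             "expr must be a named genes x individuals matrix")
  keep <- orient$light %in% colnames(expr) & orient$heavy %in% colnames(expr)
  orient <- orient[keep, , drop = FALSE]
  orient <- orient[orient$pair %in% names(pair_clusters), , drop = FALSE]
  out <- list()
  for (cl in sort(unique(as.character(pair_clusters[orient$pair])))) {
    o <- orient[as.character(pair_clusters[orient$pair]) == cl, ,
                drop = FALSE]
    n <- nrow(o)
    if (n < min_pairs) {
      warning("cluster '", cl, "' skipped: fewer than ", min_pairs, " pairs")
      next
    }
    Y <- t(expr[, o$heavy, drop = FALSE] - expr[, o$light, drop = FALSE])
    X <- matrix(1, n, 1)
    if (!is.null(covariates)) {
      cv <- covariates[o$pair, , drop = FALSE]
      cv <- as.matrix(cv)
      cv <- sweep(cv, 2, colMeans(cv), "-")
      cv <- cv[, apply(cv, 2, function(v) var(v) > 0), drop = FALSE]
      if (ncol(cv)) X <- cbind(X, cv)
    }
    p <- ncol(X)
    dfRes <- n - p
    stopIfNot1(dfRes >= 1, paste0("cluster '", cl,
                                  "' has no residual degrees of freedom"))
    qrX <- qr(X)
    B <- qr.coef(qrX, Y)
    res <- Y - X %*% B
    s2 <- colSums(res^2) / dfRes
    effect <- B[1, ]
    c11 <- chol2inv(qr.R(qrX))[1, 1]

    if (identical(prior_df, "auto")) {
      pr <- .fitVariancePrior(s2, dfRes)
    } else {
      pr <- list(df_prior = as.numeric(prior_df),
                 var_prior = mean(s2[is.finite(s2) & s2 > 0]))
    }
    d0 <- pr$df_prior; s02 <- pr$var_prior
    s2post <- if (is.infinite(d0)) rep(s02, length(s2)) else
      if (d0 == 0) s2 else (d0 * s02 + dfRes * s2) / (d0 + dfRes)
    se <- sqrt(s2post * c11)
    tstat <- ifelse(se > 0, effect / se,
                    ifelse(effect == 0, 0, sign(effect) * Inf))
    ## total df capped at the pooled residual df across genes: with an
    ## infinite prior the information cannot exceed what all genes supply
    dfTot <- min(dfRes + d0, dfRes * nrow(expr))
    pval <- 2 * pt(-abs(tstat), df = dfTot)
    pval[tstat == 0] <- 1
    out[[cl]] <- data.frame(gene = rownames(expr), cluster = cl,
                            effect = unname(effect), t = unname(tstat),
                            p = unname(pval),
                            padj = p.adjust(pval, "BH"), n_pairs = n,
                            row.names = NULL)
    attr(out[[cl]], "prior") <- pr
  }
  out
}

#' Derive the cluster-specific (Type-B) gene signature
#'
#' Candidate genes have p < alpha in the target cluster and p >= alpha in
#' every other cluster (the specificity filter). Candidates are k-means
#' clustered on their absolute per-cluster effect profiles, and the gene
#' cluster whose centroid maximizes |target effect| / (1 + mean |other
#' effect|) is returned; directions come from the sign of the target-cluster
#' effect.
#'
#' @param de_tables list from \code{\link{pairedModeratedDE}}; must include
#'   the target cluster
#' @param alpha p-value cutoff (default 0.001)
#' @param target name of the target cluster (default "TypeB")
#' @param gene_kmeans_k k for the gene-level k-means (default 2)
#' @param seed integer
#' @return a \linkS4class{GeneSignature} (empty, with a warning, when no
#'   candidates survive)
#' @export
deriveTypeBSignature <- function(de_tables, alpha = 0.001, target = "TypeB",
                                 gene_kmeans_k = 2, seed = 1L) {
  stopIfNot1(target %in% names(de_tables),
             paste0("no DE table for target cluster '", target, "'"))
  others <- setdiff(names(de_tables), target)
  stopIfNot1(length(others) > 0, "need DE tables for non-target clusters")
  tt <- de_tables[[target]]
  genes <- tt$gene
  pmat <- vapply(de_tables, function(d) d$p[match(genes, d$gene)],
                 numeric(length(genes)))
  emat <- vapply(de_tables, function(d) d$effect[match(genes, d$gene)],
                 numeric(length(genes)))
  rownames(pmat) <- rownames(emat) <- genes
  cand <- pmat[, target] < alpha &
    apply(pmat[, others, drop = FALSE] >= alpha, 1, all)
  cand <- cand & !is.na(cand)
  emptySig <- function(msg, nCand = 0) {
    warning(msg)
    new("GeneSignature", genes = character(0),
        direction = setNames(character(0), character(0)), alpha = alpha,
        sourceCluster = target,
        provenance = list(n_candidates = nCand, gene_kmeans_k = gene_kmeans_k))
  }
  if (!any(cand)) return(emptySig("empty candidate set; empty signature"))
  prof <- abs(emat[cand, , drop = FALSE])
  k <- min(gene_kmeans_k, nrow(prof))
  ## stats::kmeans needs strictly more (distinct) points than centers;
  ## tiny candidate sets skip the profile clustering and are kept whole
  if (k >= 2 && nrow(prof) > k && nrow(unique(prof)) > k) {
    km <- withSeed(childSeed(seed, "genekm"),
                   kmeans(prof, centers = k, nstart = 10))
    score <- km$centers[, target] /
      (1 + rowMeans(km$centers[, others, drop = FALSE]))
    ## keep every gene cluster scoring close to the best: when the
    ## candidate cloud is homogeneous, a forced k-way split must not
    ## discard half the signature; genuine background profiles score
    ## far below the winner
    pick <- which(score >= 0.5 * max(score))
    sel <- rownames(prof)[km$cluster %in% pick]
  } else {
    sel <- rownames(prof)
  }
  dir <- ifelse(emat[sel, target] < 0, "down_in_heavy", "up_in_heavy")
  new("GeneSignature", genes = sel, direction = setNames(dir, sel),
      alpha = alpha, sourceCluster = target,
      provenance = list(n_candidates = sum(cand), gene_kmeans_k = k,
                        kmeans_used = k >= 2))
}
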