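## Correlation and variance-heterogeneity statistics linking expression
## discordance, phenotypic discordance, insulin and BMI, including the
## quantile-split mixture analysis used for small validation cohorts.

#' Spearman correlation map between expression and trait discordances
#'
#' Per gene x trait, Spearman's rho and its p-value (exact enumeration for
#' n <= 9, t-approximation otherwise), reported alongside -log10(p). With
#' cluster labels, the same analysis is repeated within each cluster and
#' the per-gene mean p-value over all traits is reported per cluster (the
#' mean rho is also emitted).
#'
#' @param geneD expression \linkS4class{DiscordanceMatrix} (genes as columns)
#' @param traitD trait \linkS4class{DiscordanceMatrix}
#' @param cluster_labels optional named vector, pair -> cluster
#' @return list of class "CorrelationMap": rho, p, neglog10p (genes x
#'   traits), and with labels cluster_mean_p / cluster_mean_rho (genes x
#'   clusters)
#' @export
discordanceSpearman <- function(geneD, traitD, cluster_labels = NULL) {
  G <- discordanceValues(geneD)
  T <- discordanceValues(traitD)
  shared <- intersect(rownames(G), rownames(T))
  stopIfNot1(length(shared) >= 4, "need at least 4 shared pairs")
  G <- G[shared, , drop = FALSE]; T <- T[shared, , drop = FALSE]

  corOne <- function(x, y) {
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 3 || sd(x[ok]) == 0 || sd(y[ok]) == 0)
      return(c(NA_real_, NA_real_))
    ct <- suppressWarnings(cor.test(x[ok], y[ok], method = "spearman",
                                    exact = sum(ok) <= 9))
    c(unname(ct$estimate), ct$p.value)
  }
  runMap <- function(Gm, Tm) {
    rho <- p <- matrix(NA_real_, ncol(Gm), ncol(Tm),
                       dimnames = list(colnames(Gm), colnames(Tm)))
    for (j in seq_len(ncol(Tm))) {
      res <- vapply(seq_len(ncol(Gm)),
                    function(i) corOne(Gm[, i], Tm[, j]), numeric(2))
      rho[, j] <- res[1, ]; p[, j] <- res[2, ]
    }
    list(rho = rho, p = p)
  }
  full <- runMap(G, T)
  if (anyNA(full$rho))
    warning("undefined correlations (constant columns) set missing")
  out <- list(rho = full$rho, p = full$p, neglog10p = -log10(full$p))
  if (!is.null(cluster_labels)) {
    cls <- sort(unique(as.character(cluster_labels[shared])))
    mp <- mr <- matrix(NA_real_, ncol(G), length(cls),
                       dimnames = list(colnames(G), cls))
    for (cl in cls) {
      idx <- shared[as.character(cluster_labels[shared]) == cl]
      if (length(idx) < 4) next
      sub <- runMap(G[idx, , drop = FALSE], T[idx, , drop = FALSE])
      mp[, cl] <- rowMeans(sub$p, na.rm = TRUE)
      mr[, cl] <- rowMeans(sub$rho, na.rm = TRUE)
    }
    out$cluster_mean_p <- mp
    out$cluster_mean_rho <- mr
  }
  class(out) <- "CorrelationMap"
  out
}

#' Per-group ordinary least squares fit
#'
#' @param y,x numeric vectors
#' @param groups grouping vector (same length)
#' @return data.frame (group, n, slope, intercept, r_squared, p); groups
#'   with fewer than 3 points or zero x-variance are skipped
#' @export
groupLinearFit <- function(y, x, groups) {
  rows <- list()
  for (g in sort(unique(as.character(groups)))) {
    idx <- which(as.character(groups) == g & is.finite(x) & is.finite(y))
    if (length(idx) < 3 || var(x[idx]) == 0) {
      warning("group '", g, "' skipped (n < 3 or zero x-variance)")
      next
    }
    fit <- lm(y[idx] ~ x[idx])
    sm <- summary(fit)
    rows[[g]] <- data.frame(group = g, n = length(idx),
                            slope = unname(coef(fit)[2]),
                            intercept = unname(coef(fit)[1]),
                            r_squared = sm$r.squared,
                            p = unname(coef(sm)[2, 4]))
  }
  rbindRows(rows, data.frame(group = character(), n = integer(),
                             slope = numeric(), intercept = numeric(),
                             r_squared = numeric(), p = numeric()))
}

#' Residual adjustment of one variable on another
#'
#' OLS residuals of y on x (e.g. serum insulin adjusted on BMI).
#'
#' @param y,x numeric vectors
#' @return residuals, named as y
#' @export
adjustOn <- function(y, x) {
  ok <- is.finite(x) & is.finite(y)
  out <- rep(NA_real_, length(y))
  out[ok] <- unname(resid(lm(y[ok] ~ x[ok])))
  names(out) <- names(y)
  out
}

#' Variance homogeneity tests
#'
#' Bartlett's chi-square test or Levene's test (one-way ANOVA on
#' mean-centered absolute deviations).
#'
#' @param values numeric vector
#' @param groups grouping vector
#' @param method "bartlett" or "levene"
#' @return list(statistic, p, df, method)
#' @export
varianceHomogeneity <- function(values, groups,
                                method = c("bartlett", "levene")) {
  method <- match.arg(method)
  groups <- factor(groups)
  stopIfNot1(nlevels(groups) >= 2, "need at least 2 groups")
  ns <- tapply(values, groups, length)
  stopIfNot1(all(ns >= 2), "need at least 2 values per group")
  if (method == "bartlett") {
    v <- tapply(values, groups, var)
    if (any(v == 0))
      stop("Bartlett statistic undefined: a group has zero variance",
           call. = FALSE)
    bt <- bartlett.test(values, groups)
    list(statistic = unname(bt$statistic), p = bt$p.value,
         df = unname(bt$parameter), method = "bartlett")
  } else {
    adev <- abs(values - ave(values, groups))
    fit <- lm(adev ~ groups)
    an <- anova(fit)
    list(statistic = an$`F value`[1], p = an$`Pr(>F)`[1],
         df = unname(an$Df), method = "levene")
  }
}

#' Quantile-split mixture analysis of pair discordances
#'
#' Pairs are split at the median of their mean expression level (with an
#' odd pair count, the median pair goes to the low half). A one-dimensional
#' Gaussian mixture is fit to absolute discordances, choosing among one
#' component and two components (shared or free variances) by BIC; pairs
#' are assigned concordant (lower-mean component) or discordant by maximum
#' posterior, and proportions are tabulated per half.
#'
#' @param pair_gene_level named numeric, pair -> mean expression level
#' @param pair_discordance named numeric, pair -> discordance
#' @param seed integer
#' @param n_restarts EM restarts (default 10)
#' @return list(split, assignment, proportions, fit, G)
#' @export
quantileSplitMixture <- function(pair_gene_level, pair_discordance,
                                 seed = 1L, n_restarts = 10) {
  pairs <- intersect(names(pair_gene_level), names(pair_discordance))
  stopIfNot1(length(pairs) >= 6, "need at least 6 pairs")
  v <- pair_gene_level[pairs]
  ord <- order(v, pairs)
  nLow <- ceiling(length(pairs) / 2)
  split <- setNames(rep("high", length(pairs)), pairs)
  split[pairs[ord[seq_len(nLow)]]] <- "low"

  y <- abs(pair_discordance[pairs])
  fits <- list()
  fits[["G1"]] <- fitMixtureEM(y, G = 1)
  if (sd(y) > 0) {
    fits[["G2_shared"]] <- tryCatch(
      fitMixtureEM(y, G = 2, cov_model = "equal-spherical",
                   n_restarts = n_restarts, seed = seed),
      error = function(e) NULL)
    fits[["G2_free"]] <- tryCatch(
      fitMixtureEM(y, G = 2, cov_model = "free",
                   n_restarts = n_restarts, seed = seed),
      error = function(e) NULL)
  }
  fits <- Filter(Negate(is.null), fits)
  best <- fits[[which.min(vapply(fits, mixtureBIC, 0))]]
  if (best@G == 1) {
    assignment <- setNames(rep("concordant", length(pairs)), pairs)
  } else {
    lowComp <- which.min(best@means[1, ])
    comp <- max.col(posteriors(best))
    assignment <- setNames(ifelse(comp == lowComp, "concordant",
                                  "discordant"), pairs)
  }
  proportions <- table(half = split, assignment = assignment)
  list(split = split, assignment = assignment, proportions = proportions,
       fit = best, G = best@G)
}
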