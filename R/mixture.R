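## Gaussian finite mixture modeling of body-composition data: EM with
## kmeans++-style restarts, BIC model selection (-2 logL + npar log n,
## smaller is better), a closed-form single-component reference model for
## WT animals, and supervised-reference morph classification in which the
## reference component is held fixed.

.asMatrix <- function(data) {
  if (is.null(dim(data))) matrix(data, ncol = 1) else as.matrix(data)
}

.logdmvnorm <- function(X, mean, cov) {
  d <- ncol(X)
  ch <- tryCatch(chol(cov), error = function(e) NULL)
  if (is.null(ch)) return(rep(-Inf, nrow(X)))
  logdet <- 2 * sum(log(diag(ch)))
  ctr <- sweep(X, 2, mean, "-")
  q <- colSums(backsolve(ch, t(ctr), transpose = TRUE)^2)
  -0.5 * (d * log(2 * pi) + logdet + q)
}

.kmeansppCenters <- function(X, G) {
  n <- nrow(X)
  centers <- matrix(NA_real_, G, ncol(X))
  idx <- sample.int(n, 1)
  centers[1, ] <- X[idx, ]
  if (G > 1) {
    d2 <- rowSums(sweep(X, 2, centers[1, ], "-")^2)
    for (g in 2:G) {
      p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      idx <- sample.int(n, 1, prob = p)
      centers[g, ] <- X[idx, ]
      d2 <- pmin(d2, rowSums(sweep(X, 2, centers[g, ], "-")^2))
    }
  }
  centers
}

.nparMixture <- function(G, d, cov_model, fixed_first = FALSE) {
  free <- if (fixed_first) G - 1 else G
  meanPar <- free * d
  covPar <- if (cov_model == "equal-spherical") 1
  else free * d * (d + 1) / 2
  if (fixed_first && cov_model == "equal-spherical" && G == 1) covPar <- 0
  (G - 1) + meanPar + covPar
}

## core EM; component 1 can be held fixed at supplied parameters
.emFit <- function(X, G, cov_model, init_centers, fixed_first = NULL,
                   tol = 1e-8, max_iter = 500) {
  n <- nrow(X); d <- ncol(X)
  scale0 <- mean(diag(cov(X))) + 1e-12
  means <- init_centers
  covs <- replicate(G, cov(X) / G + diag(1e-6 * scale0, d),
                    simplify = FALSE)
  w <- rep(1 / G, G)
  if (!is.null(fixed_first)) {
    means[1, ] <- fixed_first$mean
    covs[[1]] <- fixed_first$cov
  }
  ll <- -Inf; trace <- numeric(0)
  for (iter in seq_len(max_iter)) {
    logd <- vapply(seq_len(G), function(g)
      .logdmvnorm(X, means[g, ], covs[[g]]) + log(w[g]), numeric(n))
    m <- apply(logd, 1, max)
    if (any(!is.finite(m))) return(NULL)
    lse <- m + log(rowSums(exp(logd - m)))
    llNew <- sum(lse)
    R <- exp(logd - lse)
    nk <- colSums(R)
    if (any(nk < 1e-8)) return(NULL)
    w <- nk / n
    gFrom <- if (is.null(fixed_first)) 1 else 2
    if (gFrom <= G) {
      for (g in gFrom:G) means[g, ] <- colSums(R[, g] * X) / nk[g]
    }
    if (cov_model == "equal-spherical") {
      ## shared spherical variance over the components being estimated
      est <- gFrom:G
      ss <- 0
      for (g in est) {
        ctr <- sweep(X, 2, means[g, ], "-")
        ss <- ss + sum(R[, g] * rowSums(ctr^2))
      }
      sig2 <- ss / (sum(nk[est]) * d)
      if (!is.finite(sig2) || sig2 < 1e-12 * scale0) return(NULL)
      for (g in est) covs[[g]] <- diag(sig2, d)
    } else if (gFrom <= G) {
      for (g in gFrom:G) {
        ctr <- sweep(X, 2, means[g, ], "-")
        S <- crossprod(sqrt(R[, g]) * ctr) / nk[g]
        ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
        if (min(ev) < 1e-10 * scale0) return(NULL)
        covs[[g]] <- S
      }
    }
    trace <- c(trace, llNew)
    if (is.finite(ll) && abs(llNew - ll) < tol * (1 + abs(llNew))) {
      ll <- llNew
      break
    }
    ll <- llNew
  }
  logd <- vapply(seq_len(G), function(g)
    .logdmvnorm(X, means[g, ], covs[[g]]) + log(w[g]), numeric(n))
  m <- apply(logd, 1, max)
  lse <- m + log(rowSums(exp(logd - m)))
  list(weights = w, means = means, covs = covs, logLik = sum(lse),
       posteriors = exp(logd - lse), trace = trace)
}

.mkFit <- function(res, G, d, cov_model, n, fixed_first = FALSE,
                   info = list()) {
  npar <- .nparMixture(G, d, cov_model, fixed_first)
  new("GaussianMixtureFit", G = as.integer(G), dimension = as.integer(d),
      weights = res$weights, means = t(res$means),
      covariances = res$covs, covModel = cov_model, logLik = res$logLik,
      bic = -2 * res$logLik + npar * log(n), posteriors = res$posteriors,
      llTrace = res$trace, info = info)
}

#' Fit a Gaussian mixture by EM
#'
#' EM from kmeans++-style initializations across restarts; the best
#' log-likelihood is kept. The log-likelihood is non-decreasing across
#' iterations (exposed in the \code{llTrace} slot). Runs whose components
#' degenerate (vanishing weight or variance) are discarded and restarted;
#' an error is raised if every restart degenerates. For G = 1 the
#' closed-form maximum-likelihood moments are returned directly.
#'
#' @param data numeric vector (1-D) or n x d matrix
#' @param G component count
#' @param cov_model "free" (default) or "equal-spherical"
#' @param n_restarts restarts (default 10)
#' @param seed integer
#' @param tol relative log-likelihood convergence tolerance (default 1e-8)
#' @param max_iter maximum EM iterations (default 500)
#' @return a \linkS4class{GaussianMixtureFit}
#' @export
fitMixtureEM <- function(data, G, cov_model = c("free", "equal-spherical"),
                         n_restarts = 10, seed = 1L, tol = 1e-8,
                         max_iter = 500) {
  cov_model <- match.arg(cov_model)
  X <- .asMatrix(data)
  n <- nrow(X); d <- ncol(X)
  stopIfNot1(n >= G * (d + 1), "too few observations for requested G")
  if (G == 1) {
    mu <- colMeans(X)
    S <- crossprod(sweep(X, 2, mu, "-")) / n
    if (cov_model == "equal-spherical") S <- diag(mean(diag(S)), d)
    info <- list()
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < 1e-10 * (mean(diag(S)) + 1e-300)) {
      S <- S + diag(1e-6 * (sum(diag(S)) + 1e-12), d)
      info$ridged <- TRUE
      warning("singular covariance; ridge added")
    }
    ll <- sum(.logdmvnorm(X, mu, S))
    res <- list(weights = 1, means = matrix(mu, 1), covs = list(S),
                logLik = ll, posteriors = matrix(1, n, 1), trace = ll)
    return(.mkFit(res, 1, d, cov_model, n, info = info))
  }
  best <- NULL
  for (r in seq_len(n_restarts)) {
    ctrs <- withSeed(childSeed(seed, paste0("init", r)),
                     .kmeansppCenters(X, G))
    res <- .emFit(X, G, cov_model, ctrs, tol = tol, max_iter = max_iter)
    if (!is.null(res) && (is.null(best) || res$logLik > best$logLik))
      best <- res
  }
  if (is.null(best))
    stop("all EM restarts degenerated (variance collapse); ",
         "data may not support G = ", G, call. = FALSE)
  .mkFit(best, G, d, cov_model, n, info = list(n_restarts = n_restarts))
}

#' Fit the single-component WT reference model
#'
#' Closed-form single-Gaussian fit (sample moments) over the selected
#' traits, default the 2-D fat/lean body composition. A singular covariance
#' is ridged (1e-6 of the trace) and flagged.
#'
#' @param wt_data numeric vector or matrix of WT animals (n >= 3)
#' @return a \linkS4class{GaussianMixtureFit} with G = 1
#' @export
fitReferenceModel <- function(wt_data) {
  X <- .asMatrix(wt_data)
  stopIfNot1(nrow(X) >= 3, "need at least 3 WT animals")
  fitMixtureEM(X, G = 1)
}

#' Classify mutant morphs against a fixed WT reference component
#'
#' A G-component mixture is fit to the mutant data with component 1 held
#' fixed at the reference parameters (only the mixing weights and the free
#' components' parameters are estimated). Animals are labelled by maximum
#' posterior: component 1 is the light (WT-like) morph; free components are
#' labelled by ascending total mean mass (heavy for G = 2; obese then heavy
#' for G = 3). Bimodality evidence is the BIC comparison against the
#' fixed-reference single-component model; when the free fit does not beat
#' it (or collapses onto the reference) "no separation" is reported and all
#' animals are labelled light.
#'
#' @param reference a G = 1 \linkS4class{GaussianMixtureFit}
#' @param mutant_data numeric vector or matrix (n >= 6)
#' @param G total components including the reference (default 2; use 3 for
#'   double mutants)
#' @param cov_model,n_restarts,seed,tol,max_iter EM controls
#' @param morph_names labels; default light/heavy (G=2) or
#'   light/obese/heavy (G=3) in ascending order of total mean
#' @return list(labels, posteriors, fit, null_bic, delta_bic, separated)
#' @export
classifyMorphs <- function(reference, mutant_data, G = 2,
                           cov_model = c("free", "equal-spherical"),
                           n_restarts = 10, seed = 1L, tol = 1e-8,
                           max_iter = 500, morph_names = NULL) {
  cov_model <- match.arg(cov_model)
  stopIfNot1(is(reference, "GaussianMixtureFit") && reference@G == 1L,
             "reference must be a single-component fit")
  X <- .asMatrix(mutant_data)
  n <- nrow(X); d <- ncol(X)
  stopIfNot1(n >= 6, "need at least 6 mutant animals")
  stopIfNot1(d == reference@dimension, "dimension mismatch with reference")
  fixed <- list(mean = reference@means[, 1], cov = reference@covariances[[1]])
  if (is.null(morph_names))
    morph_names <- if (G <= 2) c("light", "heavy")
  else c("light", "obese", "heavy")

  ## fixed-reference single-component null: no free parameters
  ll0 <- sum(.logdmvnorm(X, fixed$mean, fixed$cov))
  bic0 <- -2 * ll0

  best <- NULL
  refLd <- .logdmvnorm(X, fixed$mean, fixed$cov)
  for (r in seq_len(n_restarts)) {
    ctrs <- withSeed(childSeed(seed, paste0("cls", r)), {
      ## seed free components among low-reference-density points
      lowIdx <- order(refLd)[seq_len(max(G - 1, ceiling(n / 2)))]
      ctrs <- matrix(NA_real_, G, d)
      ctrs[1, ] <- fixed$mean
      pick <- sample(lowIdx, G - 1)
      ctrs[2:G, ] <- X[pick, , drop = FALSE]
      ctrs
    })
    res <- .emFit(X, G, cov_model, ctrs, fixed_first = fixed,
                  tol = tol, max_iter = max_iter)
    if (!is.null(res) && (is.null(best) || res$logLik > best$logLik))
      best <- res
  }
  if (is.null(best)) {
    fit <- NULL
    separated <- FALSE
    deltaBic <- -Inf
    labels <- setNames(rep(morph_names[1], n), rownames(X))
    post <- matrix(1, n, 1)
  } else {
    fit <- .mkFit(best, G, d, cov_model, n, fixed_first = TRUE,
                  info = list(reference_fixed = TRUE))
    deltaBic <- bic0 - fit@bic
    ## collapse: every free mean within a small Mahalanobis radius of the
    ## reference
    free <- 2:G
    collapse <- all(vapply(free, function(g)
      mahalanobis(t(fit@means[, g]), fixed$mean, fixed$cov) < 0.25, TRUE))
    separated <- deltaBic > 0 && !collapse
    if (separated) {
      ord <- order(colSums(fit@means[, free, drop = FALSE]))
      lab <- character(G)
      lab[1] <- morph_names[1]
      lab[free[ord]] <- morph_names[2:G]
      comp <- max.col(fit@posteriors)
      labels <- setNames(lab[comp], rownames(X))
      post <- fit@posteriors
    } else {
      labels <- setNames(rep(morph_names[1], n), rownames(X))
      post <- fit@posteriors
    }
  }
  list(labels = labels, posteriors = post, fit = fit, null_bic = bic0,
       delta_bic = deltaBic, separated = separated)
}
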