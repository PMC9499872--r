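#' Accessors for TwinCohort
#'
#' @param x a \linkS4class{TwinCohort}
#' @param traits optional character vector; defaults to the cohort's
#'   morphometric panel (\code{metadata(x)$traitNames})
#' @param ... unused
#' @return \code{traitMatrix}: individuals x traits numeric matrix;
#'   \code{pairIds}: named character, individual -> pair; \code{zygosity}:
#'   named character, pair -> MZ/DZ; \code{truthGroups}: planted pair groups
#'   or NULL; \code{truthRoles}: planted gene roles or NULL;
#'   \code{exprsMatrix}: genes x individuals log2 expression.
#' @name TwinCohort-accessors
NULL

#' @rdname TwinCohort-accessors
#' @export
setMethod("traitMatrix", "TwinCohort", function(x, traits = NULL, ...) {
  cd <- as.data.frame(SummarizedExperiment::colData(x))
  if (is.null(traits)) traits <- S4Vectors::metadata(x)$traitNames
  stopIfNot1(all(traits %in% colnames(cd)),
             "requested traits absent from cohort phenotypes")
  m <- as.matrix(cd[, traits, drop = FALSE])
  rownames(m) <- cd$individual
  m
})

#' @rdname TwinCohort-accessors
#' @export
setMethod("pairIds", "TwinCohort", function(x) {
  cd <- SummarizedExperiment::colData(x)
  setNames(as.character(cd$pair), cd$individual)
})

#' @rdname TwinCohort-accessors
#' @export
setMethod("zygosity", "TwinCohort", function(x) {
  cd <- SummarizedExperiment::colData(x)
  z <- tapply(as.character(cd$zygosity), as.character(cd$pair),
              function(v) v[1])
  setNames(as.character(z), names(z))
})

#' @rdname TwinCohort-accessors
#' @export
setMethod("truthGroups", "TwinCohort", function(x)
  S4Vectors::metadata(x)$truth$group)

#' @rdname TwinCohort-accessors
#' @export
setMethod("truthRoles", "TwinCohort", function(x) {
  rd <- SummarizedExperiment::rowData(x)
  if ("role" %in% colnames(rd)) setNames(as.character(rd$role), rownames(x))
  else NULL
})

#' @rdname TwinCohort-accessors
#' @export
setMethod("exprsMatrix", "TwinCohort", function(x) {
  stopIfNot1("exprs" %in% SummarizedExperiment::assayNames(x),
             "cohort has no expression assay")
  SummarizedExperiment::assay(x, "exprs")
})

setMethod("show", "TwinCohort", function(object) {
  cd <- SummarizedExperiment::colData(object)
  z <- table(zygosity(object))
  cat("TwinCohort:", ncol(object), "individuals,",
      length(unique(cd$pair)), "pairs (",
      paste(names(z), z, sep = "=", collapse = ", "), ")\n")
  tn <- S4Vectors::metadata(object)$traitNames
  cat("  traits:", length(tn), "| genes:", nrow(object), "\n")
  if (!is.null(truthGroups(object)))
    cat("  planted truth groups present\n")
})

#' Accessors for DiscordanceMatrix
#' @param x a \linkS4class{DiscordanceMatrix}
#' @name DiscordanceMatrix-accessors
NULL

#' @rdname DiscordanceMatrix-accessors
#' @export
setMethod("discordanceValues", "DiscordanceMatrix", function(x) x@values)

#' @rdname DiscordanceMatrix-accessors
#' @export
setMethod("orientation", "DiscordanceMatrix", function(x) x@orientation)

setMethod("show", "DiscordanceMatrix", function(object) {
  cat("DiscordanceMatrix:", nrow(object@values), "pairs x",
      ncol(object@values), "features (log base", object@logBase, ")\n")
})

#' Accessors for UPVClustering
#' @param x a \linkS4class{UPVClustering}
#' @name UPVClustering-accessors
NULL

#' @rdname UPVClustering-accessors
#' @export
setMethod("clusterLabels", "UPVClustering", function(x) x@labels)

#' @rdname UPVClustering-accessors
#' @export
setMethod("clusterTypes", "UPVClustering", function(x) x@types)

#' @rdname UPVClustering-accessors
#' @export
setMethod("pairEmbedding", "UPVClustering", function(x) x@embedding)

setMethod("show", "UPVClustering", function(object) {
  tab <- table(object@labels)
  cat("UPVClustering:", length(object@labels), "pairs in",
      length(tab), "clusters\n")
  if (length(object@types)) {
    for (cl in names(tab))
      cat(sprintf("  cluster %s: n=%d type=%s\n", cl, tab[[cl]],
                  if (cl %in% names(object@types)) object@types[[cl]] else "?"))
  }
  p <- object@parameters
  if (!is.null(p$structure_p))
    cat(sprintf("  structure p=%.3f; stable clusters: %d\n",
                p$structure_p, p$n_stable_clusters))
})

#' Accessors for GeneSignature
#' @param x a \linkS4class{GeneSignature}
#' @name GeneSignature-accessors
NULL

#' @rdname GeneSignature-accessors
#' @export
setMethod("signatureGenes", "GeneSignature", function(x) x@genes)

#' @rdname GeneSignature-accessors
#' @export
setMethod("signatureDirections", "GeneSignature", function(x) x@direction)

setMethod("show", "GeneSignature", function(object) {
  cat("GeneSignature:", length(object@genes), "genes (",
      sum(object@direction == "up_in_heavy"), "up,",
      sum(object@direction == "down_in_heavy"), "down ) specific to",
      object@sourceCluster, "at alpha =", object@alpha, "\n")
})

#' Accessors for GaussianMixtureFit
#' @param x a \linkS4class{GaussianMixtureFit}
#' @name GaussianMixtureFit-accessors
NULL

#' @rdname GaussianMixtureFit-accessors
#' @export
setMethod("posteriors", "GaussianMixtureFit", function(x) x@posteriors)

#' @rdname GaussianMixtureFit-accessors
#' @export
setMethod("mixtureBIC", "GaussianMixtureFit", function(x) x@bic)

setMethod("show", "GaussianMixtureFit", function(object) {
  cat(sprintf("GaussianMixtureFit: G=%d, d=%d, %s covariances\n",
              object@G, object@dimension, object@covModel))
  cat("  weights:", round(object@weights, 3), "\n")
  cat(sprintf("  logLik=%.2f BIC=%.2f\n", object@logLik, object@bic))
})

setMethod("show", "StratificationResult", function(object) {
  cat("StratificationResult: k =", object@k, "over",
      length(object@cluster), "individuals\n")
  if (!all(is.na(object@stability)))
    cat("  stability:", round(object@stability, 2), "\n")
})
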