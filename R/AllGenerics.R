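#' @rdname TwinCohort-accessors
#' @export
setGeneric("traitMatrix", function(x, ...) standardGeneric("traitMatrix"))

#' @rdname TwinCohort-accessors
#' @export
setGeneric("pairIds", function(x) standardGeneric("pairIds"))

#' @rdname TwinCohort-accessors
#' @export
setGeneric("zygosity", function(x) standardGeneric("zygosity"))

#' @rdname TwinCohort-accessors
#' @export
setGeneric("truthGroups", function(x) standardGeneric("truthGroups"))

#' @rdname TwinCohort-accessors
#' @export
setGeneric("truthRoles", function(x) standardGeneric("truthRoles"))

#' @rdname TwinCohort-accessors
#' @export
setGeneric("exprsMatrix", function(x) standardGeneric("exprsMatrix"))

#' @rdname DiscordanceMatrix-accessors
#' @export
setGeneric("discordanceValues", function(x) standardGeneric("discordanceValues"))

#' @rdname DiscordanceMatrix-accessors
#' @export
setGeneric("orientation", function(x) standardGeneric("orientation"))

#' @rdname UPVClustering-accessors
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))

#' @rdname UPVClustering-accessors
#' @export
setGeneric("clusterTypes", function(x) standardGeneric("clusterTypes"))

#' @rdname UPVClustering-accessors
#' @export
setGeneric("pairEmbedding", function(x) standardGeneric("pairEmbedding"))

#' @rdname GeneSignature-accessors
#' @export
setGeneric("signatureGenes", function(x) standardGeneric("signatureGenes"))

#' @rdname GeneSignature-accessors
#' @export
setGeneric("signatureDirections", function(x) standardGeneric("signatureDirections"))

#' @rdname GaussianMixtureFit-accessors
#' @export
setGeneric("posteriors", function(x) standardGeneric("posteriors"))

#' @rdname GaussianMixtureFit-accessors
#' @export
setGeneric("mixtureBIC", function(x) standardGeneric("mixtureBIC"))
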