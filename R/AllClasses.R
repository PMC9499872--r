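#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' TwinCohort: a twin cohort with phenotypes and expression
#'
#' Extends \linkS4class{SummarizedExperiment}: the assay \code{"exprs"} holds
#' log2-normalized expression (genes x individuals; columns of individuals
#' without expression are \code{NA}), \code{colData} holds individual-level
#' phenotypes (\code{individual}, \code{pair}, \code{zygosity}, \code{sex},
#' \code{age}, the morphometric traits, and \code{insulin}), and
#' \code{rowData} may carry planted gene roles for synthetic cohorts.
#' \code{metadata} slots used: \code{traitNames} (the morphometric panel),
#' \code{fatTraits}/\code{leanTraits} (tags used for type assignment), and
#' \code{truth} (planted per-pair groups for synthetic cohorts).
#'
#' @export
setClass("TwinCohort", contains = "SummarizedExperiment")

setValidity("TwinCohort", function(object) {
  cd <- SummarizedExperiment::colData(object)
  req <- c("individual", "pair", "zygosity")
  if (!all(req %in% colnames(cd)))
    return(paste("colData must contain:", paste(req, collapse = ", ")))
  tab <- table(cd$pair)
  if (any(tab != 2L))
    return(paste("every pair must have exactly 2 individuals; offending:",
                 paste(names(tab)[tab != 2L], collapse = ", ")))
  if (!all(cd$zygosity %in% c("MZ", "DZ")))
    return("zygosity must be MZ or DZ")
  tn <- S4Vectors::metadata(object)$traitNames
  if (!is.null(tn)) {
    miss <- setdiff(tn, colnames(cd))
    if (length(miss)) return(paste("traits missing from colData:",
                                   paste(miss, collapse = ", ")))
    for (t in intersect(tn, colnames(cd))) {
      v <- cd[[t]]
      if (any(is.finite(v) & v <= 0) &&
          t %in% c("bmi", "height", "weight"))
        return(paste("trait", t, "must be positive"))
    }
  }
  ## co-twins share age and sex
  if (all(c("age", "sex") %in% colnames(cd))) {
    sp <- split(seq_len(nrow(cd)), cd$pair)
    for (idx in sp) {
      if (length(unique(cd$age[idx])) > 1L || length(unique(cd$sex[idx])) > 1L)
        return("co-twins must share age and sex")
    }
  }
  TRUE
})

#' DiscordanceMatrix: pair x trait (or gene) log-scale discordances
#'
#' Rows are co-twin pairs, columns traits or genes; values are
#' log(heavy) - log(light) on the recorded base. The orientation maps each
#' pair to its (light, heavy) individuals; swapping a pair's orientation
#' negates its row.
#'
#' @slot values numeric matrix, pairs x features
#' @slot orientation data.frame with columns pair, light, heavy, tie
#' @slot logBase "e" or "2"
#' @slot rejects data.frame (pair, feature, reason) of excluded cells/pairs
#' @export
setClass("DiscordanceMatrix",
         representation(values = "matrix", orientation = "data.frame",
                        logBase = "character", rejects = "data.frame"),
         prototype(rejects = data.frame(pair = character(),
                                        feature = character(),
                                        reason = character())))

setValidity("DiscordanceMatrix", function(object) {
  if (!object@logBase %in% c("e", "2")) return("logBase must be 'e' or '2'")
  if (!all(c("pair", "light", "heavy") %in% colnames(object@orientation)))
    return("orientation needs columns pair, light, heavy")
  if (!all(rownames(object@values) %in% object@orientation$pair))
    return("orientation missing for some rows")
  TRUE
})

#' UPVClustering: pair clusters, types and embedding
#'
#' @slot labels named integer vector, pair -> cluster id
#' @slot types named character vector, cluster id -> UPV type
#' @slot embedding numeric matrix pair x 2 (may have 0 rows)
#' @slot centroids cluster x trait mean discordance matrix
#' @slot parameters list (k_neighbors, resolution, seed, modularity,
#'   null_modularity, structure_p, n_stable_clusters)
#' @export
setClass("UPVClustering",
         representation(labels = "integer", types = "character",
                        embedding = "matrix", centroids = "matrix",
                        parameters = "list"))

setValidity("UPVClustering", function(object) {
  if (is.null(names(object@labels))) return("labels must be named by pair")
  if (length(object@types) &&
      !all(object@types %in% c("Concordant", "TypeA", "TypeB",
                               "Intermediate", "Unassigned")))
    return("unknown cluster type label")
  TRUE
})

#' GeneSignature: directional gene list with derivation provenance
#'
#' @slot genes character vector (unique)
#' @slot direction named character, gene -> up_in_heavy / down_in_heavy
#' @slot alpha numeric, the DE p-value cutoff used
#' @slot sourceCluster character, the pair cluster the signature is specific to
#' @slot provenance list (candidate count, k used in gene k-means, etc.)
#' @export
setClass("GeneSignature",
         representation(genes = "character", direction = "character",
                        alpha = "numeric", sourceCluster = "character",
                        provenance = "list"))

setValidity("GeneSignature", function(object) {
  if (anyDuplicated(object@genes)) return("duplicate genes in signature")
  if (length(object@genes) && !identical(sort(names(object@direction)),
                                         sort(object@genes)))
    return("every gene needs a direction")
  if (length(object@direction) &&
      !all(object@direction %in% c("up_in_heavy", "down_in_heavy")))
    return("directions must be up_in_heavy or down_in_heavy")
  TRUE
})

#' GaussianMixtureFit: finite Gaussian mixture with posteriors
#'
#' BIC is computed as -2 logL + npar log(n): smaller is better.
#'
#' @slot G integer component count
#' @slot dimension integer (1 or 2)
#' @slot weights numeric, sums to 1
#' @slot means dimension x G matrix
#' @slot covariances list of dimension x dimension matrices
#' @slot covModel "equal-spherical" or "free"
#' @slot logLik numeric
#' @slot bic numeric
#' @slot posteriors n x G matrix, rows sum to 1
#' @slot llTrace numeric, per-iteration log-likelihood of the winning run
#' @slot info list (restarts used, convergence, flags such as ridged)
#' @export
setClass("GaussianMixtureFit",
         representation(G = "integer", dimension = "integer",
                        weights = "numeric", means = "matrix",
                        covariances = "list", covModel = "character",
                        logLik = "numeric", bic = "numeric",
                        posteriors = "matrix", llTrace = "numeric",
                        info = "list"),
         prototype(llTrace = numeric(), info = list()))

setValidity("GaussianMixtureFit", function(object) {
  if (abs(sum(object@weights) - 1) > 1e-8) return("weights must sum to 1")
  if (any(object@weights <= 0)) return("weights must be positive")
  if (nrow(object@posteriors) &&
      max(abs(rowSums(object@posteriors) - 1)) > 1e-8)
    return("posterior rows must sum to 1")
  TRUE
})

#' StratificationResult: population stratification on a signature
#'
#' @slot cluster named integer, individual -> cluster (1..k)
#' @slot k integer chosen by the WSS saturation rule
#' @slot wss numeric within-cluster dispersion curve over k = 1..k_max
#' @slot stability per-cluster mean bootstrap Jaccard (NA when n_boot = 0)
#' @slot upvbRank named numeric median-rank score per individual
#' @slot hdacScore named numeric (may be empty)
#' @slot ordering character, individuals ordered by cluster then BMI
#' @export
setClass("StratificationResult",
         representation(cluster = "integer", k = "integer", wss = "numeric",
                        stability = "numeric", upvbRank = "numeric",
                        hdacScore = "numeric", ordering = "character"))
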