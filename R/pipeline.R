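## Pipeline orchestrator: discordance -> typing -> DE/signature ->
## stratification -> enrichment -> association, with a content-hash
## manifest enabling partial reruns.

#' Pipeline configuration
#'
#' Collects the per-stage parameters with the package defaults. Any field
#' can be overridden; the full configuration is echoed into the manifest.
#'
#' @param phenotypes,expression,truth input paths (alternatively pass a
#'   cohort object to \code{\link{runPipeline}})
#' @param gene_sets GMT path or a list of gene sets
#' @param out_dir output directory
#' @param seed global seed fanned out deterministically to every
#'   randomized stage
#' @param ... overrides for: k_neighbors, resolution, n_null, alpha,
#'   gene_kmeans_k, k_max, n_boot, n_perm, padj_cutoff, de_covariates,
#'   n_neighbors, min_dist, max_assoc_genes
#' @return list of class "PipelineConfig"
#' @export
pipelineConfig <- function(phenotypes = NULL, expression = NULL,
                           truth = NULL, gene_sets = NULL,
                           out_dir = "upv_out", seed = 1L, ...) {
  cfg <- list(phenotypes = phenotypes, expression = expression,
              truth = truth, gene_sets = gene_sets, out_dir = out_dir,
              seed = as.integer(seed),
              k_neighbors = 20, resolution = 0.8, n_null = 49,
              n_neighbors = 15, min_dist = 0.1,
              alpha = 0.001, gene_kmeans_k = 2,
              k_max = 10, n_boot = 100,
              n_perm = 2000, padj_cutoff = 0.01,
              de_covariates = "age",
              max_assoc_genes = 200)
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  stopIfNot1(length(bad) == 0,
             paste("unknown config fields:", paste(bad, collapse = ", ")))
  cfg[names(dots)] <- dots
  class(cfg) <- "PipelineConfig"
  cfg
}

.hashObj <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE),
             f)
  unname(tools::md5sum(f))
}

.hashFiles <- function(paths) {
  h <- tools::md5sum(paths)
  setNames(unname(h), basename(paths))
}

#' Run the full UPV analysis pipeline
#'
#' Stages run in order (discordance, typing, signature, stratification,
#' enrichment, association); each stage's outputs are written to the output
#' directory and recorded in manifest.json with content hashes and the
#' parameters used. On rerun, a stage is skipped when its parameter/input
#' hash matches the manifest and its outputs are intact; a corrupted or
#' missing intermediate invalidates that stage and everything downstream.
#'
#' @param config a \code{\link{pipelineConfig}}
#' @param cohort optional \linkS4class{TwinCohort}; when NULL the cohort is
#'   read from the configured paths
#' @return list with the stage results and the manifest
#' @export
runPipeline <- function(config, cohort = NULL) {
  stopIfNot1(inherits(config, "PipelineConfig"), "need a PipelineConfig")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manPath <- file.path(config$out_dir, "manifest.json")
  manifest <- if (file.exists(manPath))
    jsonlite::read_json(manPath, simplifyVector = TRUE) else list()
  if (is.null(manifest$stages)) manifest$stages <- list()

  if (is.null(cohort)) {
    stopIfNot1(!is.null(config$phenotypes), "no cohort and no phenotype path")
    cohort <- readCohort(config$phenotypes, config$expression, config$truth)
  }
  md <- S4Vectors::metadata(cohort)
  fatT <- md$fatTraits; leanT <- md$leanTraits
  results <- list()
  state <- new.env(parent = emptyenv())
  state$upstreamKey <- ""

  stage <- function(name, params, outputs, run, load) {
    key <- .hashObj(list(params = params, upstream = state$upstreamKey))
    rec <- manifest$stages[[name]]
    paths <- file.path(config$out_dir, outputs)
    intact <- !is.null(rec) && identical(rec$key, key) &&
      all(file.exists(paths)) &&
      identical(unname(unlist(rec$outputs)), unname(.hashFiles(paths)))
    if (intact) {
      message("stage '", name, "': up to date, skipped")
      out <- load(paths)
    } else {
      out <- tryCatch(run(paths), error = function(e)
        stop("pipeline aborted at stage '", name, "': ",
             conditionMessage(e), call. = FALSE))
      manifest$stages[[name]] <<- list(
        key = key, params = params,
        outputs = as.list(.hashFiles(paths)))
      jsonlite::write_json(manifest, manPath, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
    }
    ## chain on the produced content so downstream stages are invalidated
    ## whenever an upstream stage's outputs change
    state$upstreamKey <- .hashObj(list(key = key,
                                       outputs = .hashFiles(paths)))
    out
  }

  ## -- discordance ---------------------------------------------------------
  results$discordance <- stage(
    "discordance",
    params = list(seed = config$seed),
    outputs = c("orientation.tsv", "discordance_traits.tsv"),
    run = function(paths) {
      orient <- assignReference(cohort)
      D <- traitDiscordance(cohort, orient)
      mz <- names(zygosity(cohort))[zygosity(cohort) == "MZ"]
      Dmz <- .newDiscordance(
        discordanceValues(D)[rownames(discordanceValues(D)) %in% mz, ,
                             drop = FALSE],
        orientation(D), D@logBase)
      .writeTsv(orient[, c("pair", "light", "heavy")], paths[1])
      .writeTsv(discordanceValues(Dmz), paths[2], rownames_as = "pair")
      list(orient = orient, D = D, Dmz = Dmz)
    },
    load = function(paths) {
      orient <- read.table(paths[1], sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
      v <- read.table(paths[2], sep = "\t", header = TRUE, row.names = 1,
                      check.names = FALSE)
      Dmz <- .newDiscordance(as.matrix(v), orient, "e")
      full <- assignReference(cohort)
      list(orient = full, D = traitDiscordance(cohort, full), Dmz = Dmz)
    })

  ## -- typing --------------------------------------------------------------
  results$typing <- stage(
    "typing",
    params = config[c("k_neighbors", "resolution", "n_null", "n_neighbors",
                      "min_dist", "seed")],
    outputs = c("clusters.tsv", "embedding.tsv", "heatmap_order.json"),
    run = function(paths) {
      Dmz <- results$discordance$Dmz
      clu <- clusterCotwinPairs(Dmz, k_neighbors = config$k_neighbors,
                                resolution = config$resolution,
                                seed = config$seed, n_null = config$n_null)
      clu <- assignClusterTypes(clu, Dmz, fat_traits = fatT,
                                lean_traits = leanT)
      emb <- embedPairs(Dmz, n_neighbors = config$n_neighbors,
                        min_dist = config$min_dist, seed = config$seed)
      clu@embedding <- emb
      hm <- heatmapOrder(Dmz)
      lab <- clusterLabels(clu)
      .writeTsv(data.frame(pair = names(lab), cluster = lab,
                           type = clusterTypes(clu)[as.character(lab)]),
                paths[1])
      .writeTsv(data.frame(pair = rownames(emb), emb), paths[2])
      jsonlite::write_json(list(row_order = hm$row_order,
                                col_order = hm$col_order),
                           paths[3], auto_unbox = TRUE)
      list(clustering = clu, heatmap = hm)
    },
    load = function(paths) {
      tab <- read.table(paths[1], sep = "\t", header = TRUE,
                        stringsAsFactors = FALSE)
      emb <- read.table(paths[2], sep = "\t", header = TRUE, row.names = 1)
      lab <- setNames(as.integer(tab$cluster), tab$pair)
      types <- tapply(tab$type, as.character(tab$cluster),
                      function(v) v[1])
      clu <- new("UPVClustering", labels = lab,
                 types = setNames(as.character(types), names(types)),
                 embedding = as.matrix(emb),
                 centroids = .clusterCentroids(
                   lab, discordanceValues(results$discordance$Dmz)),
                 parameters = list())
      list(clustering = clu, heatmap = NULL)
    })

  ## -- signature (paired DE + specificity filter) --------------------------
  results$signature <- stage(
    "signature",
    params = config[c("alpha", "gene_kmeans_k", "de_covariates", "seed")],
    outputs = c("signature.tsv", "de_tables.tsv"),
    run = function(paths) {
      clu <- results$typing$clustering
      lab <- clusterLabels(clu)
      types <- clusterTypes(clu)
      pairType <- setNames(types[as.character(lab)], names(lab))
      covariates <- NULL
      if ("age" %in% config$de_covariates) {
        cd <- SummarizedExperiment::colData(cohort)
        age <- tapply(cd$age, as.character(cd$pair), function(v) v[1])
        covariates <- data.frame(age = as.numeric(age),
                                 row.names = names(age))
      }
      de <- pairedModeratedDE(exprsMatrix(cohort),
                              results$discordance$orient,
                              pairType, covariates = covariates)
      sig <- if ("TypeB" %in% names(de))
        deriveTypeBSignature(de, alpha = config$alpha,
                             gene_kmeans_k = config$gene_kmeans_k,
                             seed = config$seed)
      else {
        warning("no TypeB cluster; empty signature")
        new("GeneSignature", genes = character(0),
            direction = setNames(character(0), character(0)),
            alpha = config$alpha, sourceCluster = "TypeB",
            provenance = list())
      }
      .writeTsv(data.frame(gene = signatureGenes(sig),
                           direction = unname(signatureDirections(
                             sig)[signatureGenes(sig)])), paths[1])
      .writeTsv(do.call(rbind, c(lapply(de, function(d) {
        d$leading <- NULL; d
      }), list(make.row.names = FALSE))), paths[2])
      list(de = de, signature = sig)
    },
    load = function(paths) {
      st <- read.table(paths[1], sep = "\t", header = TRUE,
                       stringsAsFactors = FALSE)
      det <- read.table(paths[2], sep = "\t", header = TRUE,
                        stringsAsFactors = FALSE)
      de <- split(det, det$cluster)
      sig <- new("GeneSignature", genes = st$gene,
                 direction = setNames(st$direction, st$gene),
                 alpha = config$alpha, sourceCluster = "TypeB",
                 provenance = list(restored = TRUE))
      list(de = de, signature = sig)
    })

  ## -- stratification ------------------------------------------------------
  results$stratification <- stage(
    "stratification",
    params = config[c("k_max", "n_boot", "seed")],
    outputs = "strata.tsv",
    run = function(paths) {
      sig <- results$signature$signature
      if (!length(signatureGenes(sig))) {
        warning("empty signature; stratification skipped")
        .writeTsv(data.frame(individual = character(), cluster = integer(),
                             upvb_rank = numeric()), paths[1])
        return(NULL)
      }
      cd <- SummarizedExperiment::colData(cohort)
      bmi <- setNames(cd$bmi, cd$individual)
      strat <- stratifyIndividuals(exprsMatrix(cohort), sig,
                                   k_max = config$k_max,
                                   n_boot = config$n_boot,
                                   seed = config$seed, bmi = bmi)
      .writeTsv(data.frame(individual = names(strat@cluster),
                           cluster = strat@cluster,
                           upvb_rank = strat@upvbRank[names(strat@cluster)]),
                paths[1])
      strat
    },
    load = function(paths) {
      tab <- read.table(paths[1], sep = "\t", header = TRUE,
                        stringsAsFactors = FALSE)
      if (!nrow(tab)) return(NULL)
      new("StratificationResult",
          cluster = setNames(as.integer(tab$cluster), tab$individual),
          k = length(unique(tab$cluster)), wss = numeric(),
          stability = NA_real_,
          upvbRank = setNames(tab$upvb_rank, tab$individual),
          hdacScore = setNames(numeric(0), character(0)),
          ordering = tab$individual)
    })

  ## -- enrichment ----------------------------------------------------------
  results$enrichment <- stage(
    "enrichment",
    params = config[c("n_perm", "padj_cutoff", "seed")],
    outputs = c("enrichment.tsv", "hdac_signature.gmt"),
    run = function(paths) {
      sets <- config$gene_sets
      if (is.character(sets)) sets <- readGmt(sets)
      de <- results$signature$de
      if (is.null(sets) || !"TypeB" %in% names(de)) {
        warning("no gene sets or no TypeB DE table; enrichment skipped")
        .writeTsv(data.frame(), paths[1]); writeGmt(list(), paths[2])
        return(NULL)
      }
      tb <- de[["TypeB"]]
      ranked <- setNames(tb$t, tb$gene)
      enr <- prerankedEnrichment(ranked, sets, n_perm = config$n_perm,
                                 seed = config$seed)
      hdac <- deriveHdacSignature(enr, padj_cutoff = config$padj_cutoff)
      score <- if (length(hdac$genes))
        signatureScore(exprsMatrix(cohort), hdac) else NULL
      .writeTsv(enr[, setdiff(colnames(enr), "leading_edge")], paths[1])
      writeGmt(list(hdac), paths[2])
      list(enrichment = enr, hdac_signature = hdac, hdac_score = score)
    },
    load = function(paths) {
      enr <- read.table(paths[1], sep = "\t", header = TRUE,
                        stringsAsFactors = FALSE)
      hd <- readGmt(paths[2])
      hdac <- if (length(hd)) hd[[1]] else NULL
      score <- if (!is.null(hdac) && length(hdac$genes))
        signatureScore(exprsMatrix(cohort), hdac) else NULL
      list(enrichment = enr, hdac_signature = hdac, hdac_score = score)
    })

  ## -- association ---------------------------------------------------------
  results$association <- stage(
    "association",
    params = config["max_assoc_genes"],
    outputs = c("group_fits.tsv", "correlation_map.tsv"),
    run = function(paths) {
      cd <- SummarizedExperiment::colData(cohort)
      clu <- results$typing$clustering
      lab <- clusterLabels(clu)
      types <- clusterTypes(clu)
      indType <- setNames(types[as.character(lab[as.character(cd$pair)])],
                          cd$individual)
      fits <- if ("insulin" %in% colnames(cd))
        groupLinearFit(cd$insulin, cd$bmi, indType)
      else data.frame()
      .writeTsv(fits, paths[1])
      cm <- NULL
      if (nrow(cohort) > 0) {
        orient <- results$discordance$orient
        eD <- expressionDiscordance(cohort, orient)
        ev <- discordanceValues(eD)
        keepG <- head(order(-apply(ev, 2, var)), config$max_assoc_genes)
        eD2 <- .newDiscordance(ev[, keepG, drop = FALSE], orient,
                               eD@logBase)
        cm <- discordanceSpearman(eD2, results$discordance$Dmz,
                                  cluster_labels = lab)
        .writeTsv(as.data.frame(cm$neglog10p), paths[2],
                  rownames_as = "gene")
      } else .writeTsv(data.frame(), paths[2])
      list(group_fits = fits, correlation_map = cm)
    },
    load = function(paths) {
      list(group_fits = read.table(paths[1], sep = "\t", header = TRUE,
                                   stringsAsFactors = FALSE),
           correlation_map = NULL)
    })

  results$manifest <- jsonlite::read_json(manPath, simplifyVector = TRUE)
  invisible(results)
}
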