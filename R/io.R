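## Readers and writers: GMT gene-set collections, cohort phenotype and
## expression TSVs with a truth sidecar, discordance matrices, and mouse
## colony tables. All TSVs are tab-delimited UTF-8 with a header row and
## "." decimal.

.writeTsv <- function(d, path, rownames_as = NULL) {
  if (!is.null(rownames_as)) {
    d <- cbind(setNames(data.frame(rownames(d)), rownames_as),
               as.data.frame(d))
  }
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
}

#' Read a GMT gene-set file
#'
#' Each line: set name, description, member genes (tab-delimited).
#' Duplicate members within a set are de-duplicated with a warning.
#'
#' @param path file path
#' @return list of \code{list(name, description, genes)}
#' @export
readGmt <- function(path) {
  stopIfNot1(file.exists(path), paste("no such file:", path))
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop("GMT parse error at line ", i, ": fewer than 3 fields",
           call. = FALSE)
    genes <- f[-(1:2)]
    if (anyDuplicated(genes)) {
      warning("duplicate members in set '", f[1], "' (line ", i,
              "); de-duplicated")
      genes <- unique(genes)
    }
    out[[i]] <- list(name = f[1], description = f[2], genes = genes)
  }
  out
}

#' Write a GMT gene-set file
#' @param sets list of \code{list(name, description, genes)}
#' @param path file path
#' @export
writeGmt <- function(sets, path) {
  empty <- vapply(sets, function(s) length(s$genes) == 0, TRUE)
  if (any(empty)) {
    warning(sum(empty), " empty set(s) not written")
    sets <- sets[!empty]
  }
  lines <- vapply(sets, function(s)
    paste(c(s$name, if (is.null(s$description)) "" else s$description,
            s$genes), collapse = "\t"), "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Write a TwinCohort to disk
#'
#' Writes phenotypes.tsv (one row per individual), expression.tsv (genes x
#' individuals) and, when planted truth is present, truth.json.
#'
#' @param cohort a \linkS4class{TwinCohort}
#' @param dir output directory (created if needed)
#' @return named character vector of written paths
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cd <- as.data.frame(SummarizedExperiment::colData(cohort))
  pPath <- file.path(dir, "phenotypes.tsv")
  .writeTsv(cd, pPath)
  paths <- c(phenotypes = pPath)
  ex <- SummarizedExperiment::assay(cohort, "exprs")
  if (nrow(ex) > 0) {
    ePath <- file.path(dir, "expression.tsv")
    .writeTsv(ex, ePath, rownames_as = "gene")
    paths <- c(paths, expression = ePath)
  }
  md <- S4Vectors::metadata(cohort)
  truth <- md$truth
  roles <- truthRoles(cohort)
  if (!is.null(truth) || !is.null(roles)) {
    tPath <- file.path(dir, "truth.json")
    ## named atomic vectors must become lists to keep their names in JSON
    truth <- lapply(truth, function(v)
      if (is.atomic(v) && !is.null(names(v))) as.list(v) else v)
    jsonlite::write_json(list(truth = truth, gene_roles = as.list(roles),
                              traitNames = md$traitNames,
                              fatTraits = md$fatTraits,
                              leanTraits = md$leanTraits),
                         tPath, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, truth = tPath)
  }
  paths
}

#' Read a TwinCohort from phenotype/expression TSVs
#'
#' Required phenotype columns: individual, pair, zygosity, bmi. Individuals
#' missing from the expression matrix are retained with expression flagged
#' absent (NA columns). A pair with a member count other than 2 or a
#' non-numeric trait cell is an error.
#'
#' @param phenotypes_path,expression_path TSV paths (expression optional:
#'   NULL for phenotype-only cohorts)
#' @param truth_path optional truth.json sidecar
#' @param trait_names optional explicit trait panel; default: all numeric
#'   phenotype columns except age and insulin
#' @return a \linkS4class{TwinCohort}
#' @export
readCohort <- function(phenotypes_path, expression_path = NULL,
                       truth_path = NULL, trait_names = NULL) {
  cd <- read.table(phenotypes_path, sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE, check.names = FALSE,
                   encoding = "UTF-8")
  req <- c("individual", "pair", "zygosity", "bmi")
  miss <- setdiff(req, colnames(cd))
  stopIfNot1(length(miss) == 0,
             paste("phenotypes missing required columns:",
                   paste(miss, collapse = ", ")))
  tab <- table(cd$pair)
  bad <- names(tab)[tab != 2]
  if (length(bad))
    stop("pair(s) without exactly 2 members: ",
         paste(bad, collapse = ", "), call. = FALSE)
  meta <- intersect(c("individual", "pair", "zygosity", "sex"), colnames(cd))
  for (cn in setdiff(colnames(cd), meta)) {
    v <- cd[[cn]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      badRow <- which(!is.na(v) & is.na(vn))
      stop("non-numeric value in column '", cn, "', row(s) ",
           paste(head(badRow, 5), collapse = ", "), call. = FALSE)
    }
  }
  rownames(cd) <- cd$individual
  if (!is.null(expression_path)) {
    ex <- read.table(expression_path, sep = "\t", header = TRUE,
                     stringsAsFactors = FALSE, check.names = FALSE,
                     encoding = "UTF-8")
    genes <- ex[[1]]
    ex <- as.matrix(ex[, -1, drop = FALSE])
    rownames(ex) <- genes
    full <- matrix(NA_real_, nrow(ex), nrow(cd),
                   dimnames = list(genes, cd$individual))
    shared <- intersect(colnames(ex), cd$individual)
    full[, shared] <- ex[, shared]
  } else {
    full <- matrix(numeric(0), 0, nrow(cd),
                   dimnames = list(NULL, cd$individual))
  }
  truth <- NULL; roles <- NULL
  fatT <- leanT <- NULL
  if (!is.null(truth_path) && file.exists(truth_path)) {
    tj <- jsonlite::read_json(truth_path, simplifyVector = TRUE)
    truth <- lapply(tj$truth, function(v) if (is.list(v)) unlist(v) else v)
    roles <- tj$gene_roles
    if (is.null(trait_names)) trait_names <- tj$traitNames
    fatT <- tj$fatTraits; leanT <- tj$leanTraits
  }
  if (is.null(trait_names)) {
    numCols <- vapply(cd, is.numeric, TRUE)
    trait_names <- setdiff(colnames(cd)[numCols], c("age", "insulin"))
  }
  rowdat <- if (!is.null(roles) && nrow(full) > 0)
    S4Vectors::DataFrame(role = unlist(roles)[rownames(full)],
                         row.names = rownames(full))
  else NULL
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = full),
    colData = S4Vectors::DataFrame(cd),
    rowData = rowdat)
  obj <- new("TwinCohort", se)
  S4Vectors::metadata(obj)$traitNames <- trait_names
  S4Vectors::metadata(obj)$fatTraits <-
    if (!is.null(fatT)) fatT else grep("^fat_", trait_names, value = TRUE)
  S4Vectors::metadata(obj)$leanTraits <-
    if (!is.null(leanT)) leanT else grep("^lean_", trait_names, value = TRUE)
  if (!is.null(truth)) S4Vectors::metadata(obj)$truth <- truth
  validObject(obj)
  obj
}

#' Write a discordance matrix with its orientation sidecar
#' @param dm a \linkS4class{DiscordanceMatrix}
#' @param path values TSV path
#' @param orientation_path sidecar path (pair, light, heavy)
#' @return invisibly, the two paths
#' @export
writeDiscordance <- function(dm, path,
                             orientation_path = sub("\\.tsv$",
                                                    "_orientation.tsv",
                                                    path)) {
  .writeTsv(discordanceValues(dm), path, rownames_as = "pair")
  .writeTsv(orientation(dm)[, c("pair", "light", "heavy")], orientation_path)
  invisible(c(path, orientation_path))
}

#' Write / read a mouse colony table
#' @param tab data.frame from \code{\link{simulateMouseColony}}
#' @param path TSV path
#' @export
writeMouseColony <- function(tab, path) {
  .writeTsv(tab, path)
  invisible(path)
}

#' @rdname writeMouseColony
#' @export
readMouseColony <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             encoding = "UTF-8")
}
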