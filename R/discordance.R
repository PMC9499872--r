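## Co-twin discordance indices with BMI-ordered heavy/light orientation.
##
## The discordance index of a trait for a pair is the difference of the
## log-transformed values between co-twins, after setting the co-twin with
## the lower reference trait (BMI by default) as the light reference.

#' Orient co-twin pairs by a reference trait
#'
#' For each pair the co-twin with the lower reference value becomes the
#' light reference and the other the heavy co-twin. Ties are broken by the
#' lexicographically smaller individual ID as light and flagged. Pairs with
#' a missing reference value are dropped and listed in the rejects report.
#'
#' @param cohort a \linkS4class{TwinCohort}
#' @param reference_trait column of \code{colData} to order on (default "bmi")
#' @return data.frame (pair, light, heavy, tie) with attribute
#'   \code{"rejects"}: data.frame (pair, reason)
#' @export
assignReference <- function(cohort, reference_trait = "bmi") {
  cd <- as.data.frame(SummarizedExperiment::colData(cohort))
  stopIfNot1(reference_trait %in% colnames(cd),
             paste0("reference trait '", reference_trait, "' absent"))
  sp <- split(cd, cd$pair)
  rows <- list(); rej <- list()
  for (p in names(sp)) {
    d <- sp[[p]]
    v <- d[[reference_trait]]
    if (any(!is.finite(v))) {
      rej[[p]] <- data.frame(pair = p, reason = "missing reference")
      next
    }
    tie <- v[1] == v[2]
    if (tie) {
      ord <- order(d$individual)
    } else {
      ord <- order(v)
    }
    rows[[p]] <- data.frame(pair = p, light = d$individual[ord[1]],
                            heavy = d$individual[ord[2]], tie = tie)
  }
  out <- rbindRows(rows, data.frame(pair = character(), light = character(),
                                    heavy = character(), tie = logical()))
  rejects <- rbindRows(rej, data.frame(pair = character(),
                                       reason = character()))
  if (nrow(rejects))
    warning(nrow(rejects), " pair(s) dropped: missing reference value")
  attr(out, "rejects") <- rejects
  out
}

.newDiscordance <- function(values, orientation, logBase, rejects = NULL) {
  if (is.null(rejects))
    rejects <- data.frame(pair = character(), feature = character(),
                          reason = character())
  new("DiscordanceMatrix", values = values,
      orientation = orientation[orientation$pair %in% rownames(values), ,
                                drop = FALSE],
      logBase = logBase, rejects = rejects)
}

#' Trait discordance matrix
#'
#' \code{d = log(heavy) - log(light)} per pair and trait. Nonpositive trait
#' values make the cell missing (reported); a pair is dropped when more than
#' \code{max_missing_frac} of its cells are missing.
#'
#' @param cohort a \linkS4class{TwinCohort}
#' @param orient orientation data.frame from \code{\link{assignReference}}
#' @param traits trait names; default the cohort panel
#' @param log_base "e" (default) or "2"
#' @param max_missing_frac row-drop threshold (default 0.2)
#' @return a \linkS4class{DiscordanceMatrix}
#' @export
traitDiscordance <- function(cohort, orient, traits = NULL,
                             log_base = c("e", "2"),
                             max_missing_frac = 0.2) {
  log_base <- match.arg(log_base)
  lg <- if (log_base == "e") log else log2
  tm <- traitMatrix(cohort, traits = traits)
  stopIfNot1(all(orient$light %in% rownames(tm)) &&
               all(orient$heavy %in% rownames(tm)),
             "orientation refers to unknown individuals")
  hv <- tm[orient$heavy, , drop = FALSE]
  lt <- tm[orient$light, , drop = FALSE]
  bad <- !(hv > 0 & lt > 0) | !is.finite(hv) | !is.finite(lt)
  hv[bad] <- NA; lt[bad] <- NA
  d <- lg(hv) - lg(lt)
  rownames(d) <- orient$pair
  rej <- NULL
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)
    rej <- data.frame(pair = orient$pair[idx[, 1]],
                      feature = colnames(tm)[idx[, 2]],
                      reason = "nonpositive or missing value")
    warning(nrow(rej), " cell(s) set missing (nonpositive/missing values)")
  }
  frac <- rowMeans(is.na(d))
  drop <- frac > max_missing_frac
  if (any(drop)) {
    rej <- rbind(rej, data.frame(pair = rownames(d)[drop], feature = "*",
                                 reason = "row missingness above threshold"))
    warning(sum(drop), " pair(s) dropped: > ", max_missing_frac * 100,
            "% cells missing")
    d <- d[!drop, , drop = FALSE]
  }
  .newDiscordance(d, orient, log_base, rej)
}

#' Expression discordance matrix
#'
#' Expression is stored log2-normalized, so the discordance is directly
#' \code{heavy - light} (a difference of log-transformed values); the log
#' base is recorded as 2. Pairs with an individual absent from the
#' expression matrix are excluded and reported.
#'
#' @inheritParams traitDiscordance
#' @return a \linkS4class{DiscordanceMatrix} with genes as columns
#' @export
expressionDiscordance <- function(cohort, orient) {
  ex <- exprsMatrix(cohort)
  stopIfNot1(nrow(ex) > 0, "cohort has no expression data")
  ok <- orient$light %in% colnames(ex) & orient$heavy %in% colnames(ex)
  if (any(ok)) {
    noNA <- function(ids) colSums(is.na(ex[, ids, drop = FALSE])) == 0
    ok[ok] <- noNA(orient$light[ok]) & noNA(orient$heavy[ok])
  }
  rej <- NULL
  if (any(!ok)) {
    rej <- data.frame(pair = orient$pair[!ok], feature = "*",
                      reason = "individual absent from expression matrix")
    warning(sum(!ok), " pair(s) excluded: no expression data")
  }
  o <- orient[ok, , drop = FALSE]
  d <- t(ex[, o$heavy, drop = FALSE] - ex[, o$light, drop = FALSE])
  rownames(d) <- o$pair
  .newDiscordance(d, o, "2", rej)
}

#' Height-adjusted traits (FatMI/LeanMI analogues)
#'
#' Replaces every mass trait by mass divided by squared height (the mass
#' index construction behind FatMI and LeanMI), suffixing names with
#' \code{"_hadj"}. BMI and height are left unchanged. Pairs containing an
#' individual with nonpositive height are excluded and reported.
#'
#' @param cohort a \linkS4class{TwinCohort}
#' @param mass_traits traits to adjust; default all panel traits except
#'   height and bmi
#' @return a \linkS4class{TwinCohort} with the adjusted panel
#' @export
heightAdjustedTraits <- function(cohort, mass_traits = NULL) {
  cd <- SummarizedExperiment::colData(cohort)
  stopIfNot1("height" %in% colnames(cd), "height trait absent")
  panel <- S4Vectors::metadata(cohort)$traitNames
  if (is.null(mass_traits)) mass_traits <- setdiff(panel, c("height", "bmi"))
  badInd <- !is.finite(cd$height) | cd$height <= 0
  if (any(badInd)) {
    badPairs <- unique(as.character(cd$pair[badInd]))
    warning(sum(badInd), " individual(s) with nonpositive height; ",
            length(badPairs), " pair(s) excluded")
    cohort <- cohort[, !(as.character(cd$pair) %in% badPairs)]
    cd <- SummarizedExperiment::colData(cohort)
  }
  h2 <- cd$height^2
  newNames <- character(0)
  for (t in mass_traits) {
    nn <- paste0(t, "_hadj")
    SummarizedExperiment::colData(cohort)[[nn]] <- cd[[t]] / h2
    newNames <- c(newNames, nn)
  }
  md <- S4Vectors::metadata(cohort)
  md$traitNames <- c(newNames, intersect(c("height", "bmi"), panel))
  md$fatTraits <- paste0(intersect(md$fatTraits, mass_traits), "_hadj")
  md$leanTraits <- paste0(intersect(md$leanTraits, mass_traits), "_hadj")
  S4Vectors::metadata(cohort) <- md
  cohort
}

#' MZ versus DZ discordance comparison
#'
#' Per trait, a one-sided Wilcoxon rank-sum test of whether MZ absolute
#' discordances are stochastically smaller than DZ absolute discordances.
#'
#' @param mz,dz \linkS4class{DiscordanceMatrix} objects sharing trait columns
#' @param min_pairs traits with fewer non-missing pairs in either group are
#'   skipped with a warning (default 3)
#' @return data.frame (trait, mean_abs_mz, mean_abs_dz, statistic, p)
#' @export
zygosityDiscordanceTest <- function(mz, dz, min_pairs = 3) {
  shared <- intersect(colnames(mz@values), colnames(dz@values))
  stopIfNot1(length(shared) > 0, "no shared trait columns")
  rows <- list()
  skipped <- character(0)
  for (t in shared) {
    a <- abs(mz@values[, t]); a <- a[is.finite(a)]
    b <- abs(dz@values[, t]); b <- b[is.finite(b)]
    if (length(a) < min_pairs || length(b) < min_pairs) {
      skipped <- c(skipped, t)
      next
    }
    wt <- suppressWarnings(wilcox.test(a, b, alternative = "less"))
    rows[[t]] <- data.frame(trait = t, mean_abs_mz = mean(a),
                            mean_abs_dz = mean(b),
                            statistic = unname(wt$statistic), p = wt$p.value)
  }
  if (length(skipped))
    warning("trait(s) skipped (fewer than ", min_pairs, " pairs): ",
            paste(skipped, collapse = ", "))
  rbindRows(rows, data.frame(trait = character(), mean_abs_mz = numeric(),
                             mean_abs_dz = numeric(), statistic = numeric(),
                             p = numeric()))
}
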