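## Synthetic twin cohorts and mouse-colony tables with planted ground truth.
##
## The generator emulates the statistical structure the discordance analysis
## assumes: MZ pairs carrying four planted discordance patterns (concordant,
## Type-A fat-up/lean-down, Type-B fat-up/lean-up, intermediate), DZ pairs
## with inflated discordance variance, expression with a Type-B-specific
## differential gene set (including a down-regulated NNAT-like gene and an
## up-regulated HDAC-responsive set in the heavy co-twin), insulin coupled to
## BMI with a group-specific R-squared, and mouse colonies with unimodal WT,
## bimodal single-mutant and tri-modal double-mutant body composition.

#' Default 35-trait morphometric panel
#'
#' Eight body regions with fat and lean components, regional total masses,
#' upper/lower and appendicular subtotals, plus weight, height and BMI.
#' Only the count (35) and the presence of bmi/height/weight and regional
#' fat/lean masses are fixed; names are configurable through
#' \code{\link{simConfig}}.
#'
#' @return character vector of 35 trait names
#' @export
defaultTraitPanel <- function() {
  regions <- c("head", "trunk", "android", "gynoid",
               "arm_left", "arm_right", "leg_left", "leg_right")
  c(paste0("fat_", regions), "fat_upper", "fat_lower", "fat_appendicular",
    "fat_total",
    paste0("lean_", regions), "lean_upper", "lean_lower", "lean_appendicular",
    "lean_total",
    paste0("mass_", regions),
    "weight", "height", "bmi")
}

#' Simulation configuration for synthetic twin cohorts
#'
#' Defaults are the package's reference study conditions: 40 MZ pairs per
#' planted group (160 total), 40 DZ pairs, the 35-trait panel, log-scale
#' fat/lean effects of 0.35/0.10 in the heavy co-twin, trait noise s.d. 0.06,
#' 2000 genes with 60 planted signature genes (30\% down-regulated, housing
#' the NNAT-like gene) and 40 HDAC-responsive genes shifted by 1.0 log2 units
#' in heavy Type-B co-twins, and insulin coupled to BMI with R-squared 0.5 in
#' the Type-B group versus 0.1 elsewhere.
#'
#' @param n_pairs_per_group named integer vector over
#'   concordant/typeA/typeB/intermediate
#' @param n_dz_pairs DZ pair count (DZ discordances are drawn from the MZ
#'   generative mixture with effects and noise scaled by \code{dz_inflation})
#' @param trait_names trait panel; must contain "bmi" and "height"
#' @param effect_fat,effect_lean log-scale mean discordance of fat/lean
#'   traits in the heavy co-twin (Type-A uses \code{-effect_lean}; the
#'   intermediate group uses half-scale effects)
#' @param noise_sd_traits log-scale s.d. of per-trait discordance noise
#' @param dz_inflation multiplier on DZ effects and noise (default 2)
#' @param n_genes,n_signature_genes,hdac_set_size gene counts
#' @param frac_signature_down fraction of signature genes down-regulated in
#'   the heavy co-twin
#' @param expr_effect log2 shift of signature/HDAC genes in heavy Type-B
#'   co-twins
#' @param expr_noise_sd log2 s.d. of expression noise
#' @param background_axis pair-shared background position (in units of
#'   \code{expr_effect}) of non-Type-B pairs along the signature axis,
#'   emulating the population's molecular strata; 0 disables it
#' @param insulin_bmi_r2 target within-group squared correlation of insulin
#'   with BMI; single value or named over groups (plus "dz")
#' @param seed root seed; per-stream child seeds are derived from it so that
#'   e.g. changing gene counts does not perturb trait draws
#' @return a validated list of class "SimConfig"
#' @export
simConfig <- function(n_pairs_per_group = c(concordant = 40, typeA = 40,
                                            typeB = 40, intermediate = 40),
                      n_dz_pairs = 40,
                      trait_names = defaultTraitPanel(),
                      effect_fat = 0.35, effect_lean = 0.10,
                      noise_sd_traits = 0.06, dz_inflation = 2,
                      n_genes = 2000, n_signature_genes = 60,
                      frac_signature_down = 0.3, hdac_set_size = 40,
                      expr_effect = 1.0, expr_noise_sd = 0.3,
                      background_axis = 0.5,
                      insulin_bmi_r2 = c(concordant = 0.1, typeA = 0.1,
                                         typeB = 0.5, intermediate = 0.1,
                                         dz = 0.1),
                      seed = 1L) {
  cfg <- list(n_pairs_per_group = n_pairs_per_group, n_dz_pairs = n_dz_pairs,
              trait_names = trait_names, effect_fat = effect_fat,
              effect_lean = effect_lean, noise_sd_traits = noise_sd_traits,
              dz_inflation = dz_inflation, n_genes = n_genes,
              n_signature_genes = n_signature_genes,
              frac_signature_down = frac_signature_down,
              hdac_set_size = hdac_set_size, expr_effect = expr_effect,
              expr_noise_sd = expr_noise_sd,
              background_axis = background_axis,
              insulin_bmi_r2 = insulin_bmi_r2, seed = as.integer(seed))
  class(cfg) <- "SimConfig"
  validateSimConfig(cfg)
  cfg
}

validateSimConfig <- function(cfg) {
  groups <- c("concordant", "typeA", "typeB", "intermediate")
  fail <- function(field, why)
    stop("invalid SimConfig field '", field, "': ", why, call. = FALSE)
  if (!all(groups %in% names(cfg$n_pairs_per_group)))
    fail("n_pairs_per_group", "must name concordant, typeA, typeB, intermediate")
  if (any(cfg$n_pairs_per_group <= 0))
    fail("n_pairs_per_group", "all counts must be > 0")
  if (cfg$n_dz_pairs < 0) fail("n_dz_pairs", "must be >= 0")
  if (!all(c("bmi", "height") %in% cfg$trait_names))
    fail("trait_names", "must contain 'bmi' and 'height'")
  if (cfg$noise_sd_traits <= 0) fail("noise_sd_traits", "must be > 0")
  if (cfg$n_genes <= 0) fail("n_genes", "must be > 0")
  if (cfg$n_signature_genes <= 0) fail("n_signature_genes", "must be > 0")
  if (cfg$hdac_set_size <= 0) fail("hdac_set_size", "must be > 0")
  if (cfg$frac_signature_down < 0 || cfg$frac_signature_down > 1)
    fail("frac_signature_down", "must be in [0, 1]")
  if (cfg$expr_noise_sd <= 0) fail("expr_noise_sd", "must be > 0")
  if (any(cfg$insulin_bmi_r2 < 0) || any(cfg$insulin_bmi_r2 > 1))
    fail("insulin_bmi_r2", "must be in [0, 1]")
  if (cfg$dz_inflation < 1) fail("dz_inflation", "must be >= 1")
  invisible(TRUE)
}

## region baselines (kg); a fat-dominant composition keeps Type-A heavy
## co-twins heavier by BMI despite the lean-mass reduction
.regionFat  <- c(head = 0.8, trunk = 12, android = 2.2, gynoid = 4.5,
                 arm_left = 1.5, arm_right = 1.5, leg_left = 4, leg_right = 4)
.regionLean <- c(head = 3.0, trunk = 20, android = 3.0, gynoid = 5.0,
                 arm_left = 2.2, arm_right = 2.2, leg_left = 6.5,
                 leg_right = 6.5)

## assemble the derived panel from primitive region components
.assembleTraits <- function(fat, lean, resid, height) {
  regions <- names(.regionFat)
  upper <- c("head", "trunk", "android", "arm_left", "arm_right")
  lower <- c("gynoid", "leg_left", "leg_right")
  app <- c("arm_left", "arm_right", "leg_left", "leg_right")
  out <- c(setNames(fat, paste0("fat_", regions)),
           fat_upper = sum(fat[upper]), fat_lower = sum(fat[lower]),
           fat_appendicular = sum(fat[app]), fat_total = sum(fat),
           setNames(lean, paste0("lean_", regions)),
           lean_upper = sum(lean[upper]), lean_lower = sum(lean[lower]),
           lean_appendicular = sum(lean[app]), lean_total = sum(lean),
           setNames(fat + lean, paste0("mass_", regions)))
  w <- sum(fat) + sum(lean) + resid
  c(out, weight = w, height = height, bmi = w / height^2)
}

#' Simulate a synthetic twin cohort (phenotypes)
#'
#' Light co-twin traits are drawn from a log-normal baseline with sex-specific
#' location shifts and a pair-level size factor; the heavy co-twin's primitive
#' fat/lean components are the light co-twin's times
#' \code{exp(group effect + noise)}. Derived traits (totals, weight, BMI) are
#' assembled from the components. DZ pairs are drawn from the same generative
#' mixture with effects and noise scaled by \code{dz_inflation}. Insulin is
#' generated as a linear function of BMI with noise solved in closed form
#' from the group's target R-squared. Planted truth labels (pair group and
#' planted-heavy individual) are recorded in \code{metadata(x)$truth}.
#'
#' @param cfg a \code{\link{simConfig}} object
#' @return a \linkS4class{TwinCohort} (expression assay empty; see
#'   \code{\link{simulateExpression}})
#' @export
simulateTwinCohort <- function(cfg) {
  validateSimConfig(cfg)
  groups <- rep(names(cfg$n_pairs_per_group), cfg$n_pairs_per_group)
  zyg <- rep("MZ", length(groups))
  if (cfg$n_dz_pairs > 0) {
    ## DZ pairs carry hidden patterns in the same proportions as MZ
    dzHidden <- withSeed(childSeed(cfg$seed, "dzgroups"),
                         sample(names(cfg$n_pairs_per_group), cfg$n_dz_pairs,
                                replace = TRUE,
                                prob = cfg$n_pairs_per_group))
    groups <- c(groups, dzHidden)
    zyg <- c(zyg, rep("DZ", cfg$n_dz_pairs))
  }
  nPairs <- length(groups)
  pairIdsV <- sprintf("P%03d", seq_len(nPairs))

  effects <- function(group, infl) {
    f <- cfg$effect_fat; l <- cfg$effect_lean
    e <- switch(group,
                concordant = c(0, 0),
                typeA = c(f, -l),
                typeB = c(f, l),
                intermediate = c(f / 2, l / 2))
    e * infl
  }

  rows <- withSeed(childSeed(cfg$seed, "traits"), {
    lapply(seq_len(nPairs), function(i) {
      male <- runif(1) < 0.5
      age <- sample(40:80, 1)
      infl <- if (zyg[i] == "DZ") cfg$dz_inflation else 1
      sexFat <- if (male) 0.8 else 1
      sexLean <- if (male) 1.25 else 1
      hBase <- if (male) 1.78 else 1.63
      size <- exp(rnorm(1, 0, 0.10))
      fatL <- .regionFat * sexFat * size * exp(rnorm(8, 0, 0.12))
      leanL <- .regionLean * sexLean * size * exp(rnorm(8, 0, 0.12))
      residL <- 3.5 * size * exp(rnorm(1, 0, 0.10))
      heightL <- hBase * exp(rnorm(1, 0, 0.03))
      ef <- effects(groups[i], infl)
      ns <- cfg$noise_sd_traits * infl
      fatH <- fatL * exp(ef[1] + rnorm(8, 0, ns))
      leanH <- leanL * exp(ef[2] + rnorm(8, 0, ns))
      residH <- residL * exp(rnorm(1, 0, ns / 2))
      heightH <- heightL * exp(rnorm(1, 0, 0.004))
      list(light = .assembleTraits(fatL, leanL, residL, heightL),
           heavy = .assembleTraits(fatH, leanH, residH, heightH),
           sex = if (male) "M" else "F", age = age)
    })
  })

  ind <- character(2 * nPairs)
  cd <- vector("list", 2 * nPairs)
  heavyOf <- character(nPairs)
  for (i in seq_len(nPairs)) {
    idL <- paste0(pairIdsV[i], "A"); idH <- paste0(pairIdsV[i], "B")
    ind[2 * i - 1] <- idL; ind[2 * i] <- idH
    heavyOf[i] <- idH
    cd[[2 * i - 1]] <- rows[[i]]$light
    cd[[2 * i]] <- rows[[i]]$heavy
  }
  traitTab <- do.call(rbind, cd)
  present <- intersect(cfg$trait_names, colnames(traitTab))
  if (length(present) < length(cfg$trait_names))
    warning("trait panel entries not generated: ",
            paste(setdiff(cfg$trait_names, present), collapse = ", "))
  coldat <- data.frame(individual = ind,
                       pair = rep(pairIdsV, each = 2),
                       zygosity = rep(zyg, each = 2),
                       sex = rep(vapply(rows, `[[`, "", "sex"), each = 2),
                       age = rep(vapply(rows, `[[`, 0, "age"), each = 2),
                       traitTab[, present, drop = FALSE],
                       row.names = ind, check.names = FALSE)

  ## insulin = a*BMI + eps, eps variance solved from the group target R2
  r2 <- cfg$insulin_bmi_r2
  if (length(r2) == 1L) r2 <- setNames(rep(r2, 5),
                                       c("concordant", "typeA", "typeB",
                                         "intermediate", "dz"))
  grpOfInd <- rep(ifelse(zyg == "DZ", "dz", groups), each = 2)
  insulin <- numeric(2 * nPairs)
  withSeed(childSeed(cfg$seed, "insulin"), {
    a <- 1.5
    for (g in unique(grpOfInd)) {
      idx <- which(grpOfInd == g)
      b <- coldat$bmi[idx]
      tgt <- if (g %in% names(r2)) r2[[g]] else 0.1
      ## noise orthogonalized against BMI in-sample and rescaled so the
      ## realized within-group R-squared equals the target exactly
      e0 <- rnorm(length(idx))
      e <- resid(lm(e0 ~ b))
      eps <- if (tgt >= 1) 0 else if (tgt <= 0) e / sd(e) * a * sd(b) * 50
      else e / sd(e) * a * sd(b) * sqrt((1 - tgt) / tgt)
      insulin[idx] <- pmax(20 + a * b + eps, 0.5)
    }
  })
  coldat$insulin <- insulin

  exprs0 <- matrix(numeric(0), nrow = 0, ncol = 2 * nPairs,
                   dimnames = list(NULL, ind))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = exprs0),
    colData = S4Vectors::DataFrame(coldat))
  obj <- new("TwinCohort", se)
  S4Vectors::metadata(obj)$traitNames <- present
  S4Vectors::metadata(obj)$fatTraits <- grep("^fat_", present, value = TRUE)
  S4Vectors::metadata(obj)$leanTraits <- grep("^lean_", present, value = TRUE)
  S4Vectors::metadata(obj)$truth <- list(
    group = setNames(ifelse(zyg == "DZ", "dz", groups), pairIdsV),
    hidden_dz_group = setNames(groups, pairIdsV),
    heavy = setNames(heavyOf, pairIdsV))
  S4Vectors::metadata(obj)$simConfig <- cfg
  validObject(obj)
  obj
}

#' Simulate gene expression for a twin cohort
#'
#' Null genes vary i.i.d. around gene-specific baselines. Signature genes are
#' shifted by \code{+-expr_effect} (sign per planted direction) in heavy
#' co-twins of Type-B pairs only; HDAC genes are shifted \code{+expr_effect}
#' in the same individuals; the designated NNAT-like gene is a down-regulated
#' signature gene. Non-Type-B pairs additionally share a pair-level background
#' position (\code{+-background_axis * expr_effect}) along the signature axis
#' so the population carries the four molecular strata the cohort analysis
#' expects; being pair-shared, it cancels exactly in paired differences and
#' leaves within-cluster differential expression untouched.
#'
#' @param cfg a \code{\link{simConfig}}
#' @param cohort a \linkS4class{TwinCohort} from \code{\link{simulateTwinCohort}}
#' @return the cohort with the \code{"exprs"} assay filled and gene roles in
#'   \code{rowData}
#' @export
simulateExpression <- function(cfg, cohort) {
  validateSimConfig(cfg)
  if (cfg$n_signature_genes + cfg$hdac_set_size > cfg$n_genes)
    stop("invalid SimConfig field 'n_signature_genes': ",
         "n_signature_genes + hdac_set_size exceeds n_genes", call. = FALSE)
  cd <- SummarizedExperiment::colData(cohort)
  stopIfNot1(all(c("pair", "individual") %in% colnames(cd)),
             "cohort pairings absent")
  truth <- S4Vectors::metadata(cohort)$truth
  genes <- sprintf("g%04d", seq_len(cfg$n_genes))

  roles <- withSeed(childSeed(cfg$seed, "roles"), {
    role <- rep("null", cfg$n_genes)
    sig <- sample.int(cfg$n_genes, cfg$n_signature_genes)
    nDown <- round(cfg$frac_signature_down * cfg$n_signature_genes)
    if (cfg$frac_signature_down > 0) nDown <- max(1L, nDown)
    down <- if (nDown > 0) sig[seq_len(nDown)] else integer(0)
    role[sig] <- "signature_up"
    role[down] <- "signature_down"
    hdac <- sample(setdiff(seq_len(cfg$n_genes), sig), cfg$hdac_set_size)
    role[hdac] <- "hdac"
    role
  })
  nnatGene <- if (any(roles == "signature_down"))
    genes[which(roles == "signature_down")[1]] else NA_character_

  ## per-individual position along the signature axis (units of expr_effect)
  grp <- truth$group
  hidden <- truth$hidden_dz_group
  heavy <- truth$heavy
  pairState <- withSeed(childSeed(cfg$seed, "states"), {
    setNames(vapply(names(grp), function(p) {
      if (hidden[[p]] == "typeB" && grp[[p]] != "dz") NA_real_
      else sample(c(-1, 1), 1) * cfg$background_axis
    }, 0), names(grp))
  })
  indState <- vapply(seq_len(nrow(cd)), function(j) {
    p <- as.character(cd$pair[j])
    if (is.na(pairState[[p]])) {
      if (cd$individual[j] == heavy[[p]]) 1 else 0
    } else pairState[[p]]
  }, 0)
  isHeavyB <- indState == 1

  expr <- withSeed(childSeed(cfg$seed, "expression"), {
    base <- runif(cfg$n_genes, 5, 10)
    dir <- ifelse(roles == "signature_down", -1,
                  ifelse(roles == "signature_up", 1, 0))
    m <- matrix(rnorm(cfg$n_genes * nrow(cd), 0, cfg$expr_noise_sd),
                nrow = cfg$n_genes)
    m <- m + base
    ## HDAC-responsive genes ride the same axis, up in heavy-like profiles
    dir[roles == "hdac"] <- 1
    sigIdx <- dir != 0
    m[sigIdx, ] <- m[sigIdx, ] +
      outer(dir[sigIdx] * cfg$expr_effect, indState)
    dimnames(m) <- list(genes, cd$individual)
    m
  })

  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = expr),
    colData = cd,
    rowData = S4Vectors::DataFrame(role = roles, row.names = genes))
  out <- new("TwinCohort", se)
  S4Vectors::metadata(out) <- S4Vectors::metadata(cohort)
  S4Vectors::metadata(out)$truth$nnat_gene <- nnatGene
  S4Vectors::metadata(out)$truth$state <- setNames(indState, cd$individual)
  validObject(out)
  out
}

#' Simulate synthetic gene-set collections for enrichment testing
#'
#' Builds HDAC-like sets enriched for the planted HDAC-responsive genes plus
#' random decoy sets, for exercising preranked enrichment end to end.
#'
#' @param cohort a cohort with planted gene roles
#' @param n_hdac_sets,n_null_sets set counts
#' @param set_size genes per set
#' @param hdac_frac fraction of each HDAC set drawn from planted HDAC genes
#' @param seed integer
#' @return list of gene sets (each \code{list(name, description, genes)})
#' @export
simulateGeneSets <- function(cohort, n_hdac_sets = 3, n_null_sets = 15,
                             set_size = 50, hdac_frac = 0.7, seed = 1L) {
  roles <- truthRoles(cohort)
  stopIfNot1(!is.null(roles), "cohort has no planted gene roles")
  hdac <- names(roles)[roles == "hdac"]
  nulls <- names(roles)[roles == "null"]
  withSeed(childSeed(seed, "genesets"), {
    sets <- list()
    for (i in seq_len(n_hdac_sets)) {
      nh <- min(round(hdac_frac * set_size), length(hdac))
      g <- c(sample(hdac, nh), sample(nulls, set_size - nh))
      sets[[length(sets) + 1L]] <- list(
        name = sprintf("HDAC_RESPONSIVE_%d", i),
        description = "synthetic HDAC-responsive set", genes = g)
    }
    for (i in seq_len(n_null_sets)) {
      sets[[length(sets) + 1L]] <- list(
        name = sprintf("RANDOM_SET_%02d", i),
        description = "synthetic decoy set",
        genes = sample(nulls, set_size))
    }
    sets
  })
}

#' Default mouse-colony mixture parameters
#'
#' WT is unimodal; Nnat-type mutants are bimodal with a large overgrown
#' (heavy) component; Trim28-type mutants are bimodal toward an obese morph;
#' double mutants are tri-modal (light/obese/heavy).
#'
#' @return named list of per-genotype component parameters for
#'   \code{\link{simulateMouseColony}}
#' @export
defaultMouseParams <- function() {
  list(
    WT = list(pi = 1, fat_mean = 10, fat_sd = 1.2,
              lean_mean = 26, lean_sd = 1.5,
              morphs = "light"),
    NnatMut = list(pi = c(0.5, 0.5), fat_mean = c(10, 25), fat_sd = c(1.2, 2),
                   lean_mean = c(26, 33), lean_sd = c(1.5, 2),
                   morphs = c("light", "heavy")),
    Trim28Mut = list(pi = c(0.5, 0.5), fat_mean = c(10, 22),
                     fat_sd = c(1.2, 2), lean_mean = c(26, 27),
                     lean_sd = c(1.5, 1.5),
                     morphs = c("light", "obese")),
    DoubleMut = list(pi = c(0.4, 0.3, 0.3), fat_mean = c(10, 22, 25),
                     fat_sd = c(1.2, 2, 2), lean_mean = c(26, 27, 33),
                     lean_sd = c(1.5, 1.5, 2),
                     morphs = c("light", "obese", "heavy")))
}

#' Simulate a mouse-colony body-composition table
#'
#' @param n_per_genotype animals per genotype (single count or named vector);
#'   0 yields an empty table
#' @param component_params per-genotype list with elements \code{pi} (component
#'   weights summing to 1), \code{fat_mean}, \code{fat_sd}, \code{lean_mean},
#'   \code{lean_sd} (per-component, grams) and optional \code{morphs} labels;
#'   see \code{\link{defaultMouseParams}}. The WT genotype must have exactly
#'   one component.
#' @param seed integer
#' @return data.frame (animal, genotype, fat_mass, lean_mass, truth_morph)
#' @export
simulateMouseColony <- function(n_per_genotype = 60,
                                component_params = defaultMouseParams(),
                                seed = 1L) {
  genos <- names(component_params)
  if (length(n_per_genotype) == 1L)
    n_per_genotype <- setNames(rep(n_per_genotype, length(genos)), genos)
  for (g in genos) {
    p <- component_params[[g]]
    if (abs(sum(p$pi) - 1) > 1e-8)
      stop("invalid component_params for '", g, "': weights must sum to 1",
           call. = FALSE)
    if (any(c(p$fat_sd, p$lean_sd) <= 0))
      stop("invalid component_params for '", g, "': sds must be > 0",
           call. = FALSE)
    if (g == "WT" && length(p$pi) != 1L)
      stop("invalid component_params for 'WT': ",
           "WT must be configured with exactly 1 component", call. = FALSE)
  }
  withSeed(childSeed(seed, "mouse"), {
    out <- lapply(genos, function(g) {
      n <- n_per_genotype[[g]]
      if (n == 0) return(NULL)
      p <- component_params[[g]]
      G <- length(p$pi)
      morphs <- if (!is.null(p$morphs)) p$morphs else
        c("light", "heavy", "obese")[seq_len(G)]
      z <- sample.int(G, n, replace = TRUE, prob = p$pi)
      data.frame(animal = paste0(g, "_", seq_len(n)), genotype = g,
                 fat_mass = pmax(rnorm(n, p$fat_mean[z], p$fat_sd[z]), 0.01),
                 lean_mass = pmax(rnorm(n, p$lean_mean[z], p$lean_sd[z]), 0.01),
                 truth_morph = morphs[z])
    })
    out <- do.call(rbind, out)
    if (is.null(out))
      out <- data.frame(animal = character(), genotype = character(),
                        fat_mass = numeric(), lean_mass = numeric(),
                        truth_morph = character())
    rownames(out) <- NULL
    out
  })
}
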