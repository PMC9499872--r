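test_that("simulation is deterministic given config and seed", {
  cfg <- smallSimConfig(seed = 9)
  a <- simulateExpression(cfg, simulateTwinCohort(cfg))
  b <- simulateExpression(cfg, simulateTwinCohort(cfg))
  expect_identical(as.data.frame(SummarizedExperiment::colData(a)),
                   as.data.frame(SummarizedExperiment::colData(b)))
  expect_identical(exprsMatrix(a), exprsMatrix(b))
  expect_identical(S4Vectors::metadata(a)$truth, S4Vectors::metadata(b)$truth)
})

test_that("every pair, individual and gene carries exactly one truth label", {
  co <- plantedFixture()$cohort
  tg <- truthGroups(co)
  expect_setequal(names(tg), unique(pairIds(co)))
  expect_true(all(tg %in% c("concordant", "typeA", "typeB", "intermediate",
                            "dz")))
  roles <- truthRoles(co)
  expect_length(roles, nrow(co))
  expect_true(all(roles %in% c("signature_up", "signature_down", "hdac",
                               "null")))
  heavy <- S4Vectors::metadata(co)$truth$heavy
  expect_setequal(names(heavy), names(tg))
})

test_that("planted typeB fat-mass discordance matches the configured effect", {
  cfg <- simConfig(n_pairs_per_group = c(concordant = 5, typeA = 5,
                                         typeB = 40, intermediate = 5),
                   n_dz_pairs = 5, seed = 3)
  co <- simulateTwinCohort(cfg)
  tg <- truthGroups(co)
  heavy <- S4Vectors::metadata(co)$truth$heavy
  tm <- traitMatrix(co)
  fatRegions <- paste0("fat_", c("head", "trunk", "android", "gynoid",
                                 "arm_left", "arm_right", "leg_left",
                                 "leg_right"))
  bPairs <- names(tg)[tg == "typeB"]
  pid <- pairIds(co)
  d <- unlist(lapply(bPairs, function(p) {
    ids <- names(pid)[pid == p]
    h <- heavy[[p]]; l <- setdiff(ids, h)
    log(tm[h, fatRegions]) - log(tm[l, fatRegions])
  }))
  se <- cfg$noise_sd_traits / sqrt(length(d))
  expect_lt(abs(mean(d) - cfg$effect_fat), 3 * se)
})

test_that("expected fat discordance increases monotonically in effect_fat", {
  means <- vapply(c(0.1, 0.25, 0.4), function(ef) {
    cfg <- smallSimConfig(seed = 5, effect_fat = ef)
    co <- simulateTwinCohort(cfg)
    orient <- assignReference(co)
    D <- suppressWarnings(traitDiscordance(co, orient))
    tg <- truthGroups(co)
    v <- discordanceValues(D)
    rows <- rownames(v)[tg[rownames(v)] %in% c("typeA", "typeB")]
    mean(v[rows, grep("^fat_", colnames(v))])
  }, 0)
  expect_true(all(diff(means) > 0))
})

test_that("DZ discordance variance dominates MZ at the default inflation", {
  cfg <- smallSimConfig(seed = 6, n_dz_pairs = 60)
  co <- simulateTwinCohort(cfg)
  D <- suppressWarnings(traitDiscordance(co, assignReference(co)))
  v <- discordanceValues(D)
  zy <- zygosity(co)[rownames(v)]
  vMZ <- apply(v[zy == "MZ", ], 2, var)
  vDZ <- apply(v[zy == "DZ", ], 2, var)
  expect_true(all(vDZ >= vMZ))
})

test_that("insulin-BMI coupling hits the per-group target R-squared", {
  co <- plantedFixture()$cohort
  cd <- as.data.frame(SummarizedExperiment::colData(co))
  grp <- truthGroups(co)[as.character(cd$pair)]
  for (g in c("concordant", "typeB")) {
    r2 <- cor(cd$insulin[grp == g], cd$bmi[grp == g])^2
    target <- plantedFixture()$cfg$insulin_bmi_r2[[g]]
    expect_equal(r2, target, tolerance = 0.02)
  }
})

test_that("invalid configurations raise errors naming the field", {
  expect_error(simConfig(noise_sd_traits = 0), "noise_sd_traits")
  expect_error(simConfig(trait_names = c("weight", "height")), "trait_names")
  expect_error(simConfig(frac_signature_down = 1.5), "frac_signature_down")
  expect_error(simConfig(n_pairs_per_group = c(concordant = 0, typeA = 1,
                                               typeB = 1, intermediate = 1)),
               "n_pairs_per_group")
})

test_that("expression planting respects gene budgets and pairings", {
  cfg <- simConfig(n_pairs_per_group = c(concordant = 5, typeA = 5,
                                         typeB = 5, intermediate = 5),
                   n_dz_pairs = 2, n_genes = 40, n_signature_genes = 30,
                   hdac_set_size = 20, seed = 2)
  co <- simulateTwinCohort(cfg)
  expect_error(simulateExpression(cfg, co), "exceeds n_genes")

  fx <- plantedFixture()
  roles <- truthRoles(fx$cohort)
  expect_equal(sum(roles %in% c("signature_up", "signature_down")),
               fx$cfg$n_signature_genes)
  expect_equal(sum(roles == "hdac"), fx$cfg$hdac_set_size)
  nn <- S4Vectors::metadata(fx$cohort)$truth$nnat_gene
  expect_equal(unname(roles[nn]), "signature_down")
})

test_that("identical co-twin expression gives exactly zero discordance", {
  tm <- matrix(c(25, 25, 1.6, 1.6), 2, 2,
               dimnames = list(c("i1", "i2"), c("bmi", "height")))
  ex <- matrix(c(7.25, 7.25), 1, 2, dimnames = list("g1", c("i1", "i2")))
  co <- makeCohort(tm, pair = c("P1", "P1"), expr = ex)
  orient <- suppressWarnings(assignReference(co))
  d <- expressionDiscordance(co, orient)
  expect_identical(unname(discordanceValues(d)[1, 1]), 0)
})

test_that("mouse colony draws match their planted component moments", {
  tab <- simulateMouseColony(150, seed = 11)
  nn <- tab[tab$genotype == "NnatMut", ]
  p <- defaultMouseParams()$NnatMut
  for (i in seq_along(p$morphs)) {
    x <- nn$fat_mass[nn$truth_morph == p$morphs[i]]
    expect_lt(abs(mean(x) - p$fat_mean[i]), 3 * p$fat_sd[i] / sqrt(length(x)))
  }
})

test_that("mouse colony degenerate configurations behave as contracted", {
  expect_identical(nrow(simulateMouseColony(0, seed = 1)), 0L)
  bad <- defaultMouseParams()
  bad$WT$pi <- c(0.5, 0.5); bad$WT$fat_mean <- c(10, 20)
  bad$WT$fat_sd <- c(1, 1); bad$WT$lean_mean <- c(25, 30)
  bad$WT$lean_sd <- c(1, 1)
  expect_error(simulateMouseColony(10, bad, seed = 1), "WT")

  uni <- list(WT = defaultMouseParams()$WT,
              NnatMut = defaultMouseParams()$WT)
  tab <- simulateMouseColony(120, uni, seed = 2)
  y <- tab$fat_mass[tab$genotype == "NnatMut"]
  f1 <- fitMixtureEM(y, 1)
  f2 <- fitMixtureEM(y, 2, seed = 2)
  expect_lt(mixtureBIC(f1), mixtureBIC(f2))
})
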