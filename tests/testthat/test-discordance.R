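mkPairCohort <- function(vals, trait = "weight", bmi = c(24, 31.5)) {
  tm <- cbind(bmi = bmi, height = c(1.6, 1.6))
  if (!is.null(vals)) tm <- cbind(tm, setNames(data.frame(vals), trait))
  tm <- as.matrix(tm)
  rownames(tm) <- c("iA", "iB")
  makeCohort(tm, pair = c("P1", "P1"))
}

test_that("reference assignment picks the lower-BMI co-twin as light", {
  co <- mkPairCohort(c(60, 72))
  o <- assignReference(co)
  expect_identical(o$light, "iA")
  expect_identical(o$heavy, "iB")
  expect_false(o$tie)
})

test_that("BMI ties break lexicographically and are flagged", {
  co <- mkPairCohort(c(60, 72), bmi = c(27, 27))
  o <- assignReference(co)
  expect_identical(o$light, "iA")
  expect_true(o$tie)
})

test_that("pairs with a missing reference land in the rejects report", {
  co <- mkPairCohort(c(60, 72), bmi = c(NA, 31))
  expect_warning(o <- assignReference(co), "missing reference")
  expect_identical(nrow(o), 0L)
  rej <- attr(o, "rejects")
  expect_identical(rej$reason, "missing reference")
  expect_identical(rej$pair, "P1")
})

test_that("trait discordance equals the log ratio heavy/light", {
  co <- mkPairCohort(c(60, 72))
  o <- assignReference(co)
  d <- traitDiscordance(co, o, traits = "weight")
  expect_equal(unname(discordanceValues(d)[1, "weight"]), log(72 / 60),
               tolerance = 1e-12)
  d2 <- traitDiscordance(co, o, traits = "weight", log_base = "2")
  expect_equal(unname(discordanceValues(d2)[1, "weight"]), log2(72 / 60),
               tolerance = 1e-12)
})

test_that("discordance is antisymmetric under orientation swap (exact)", {
  fx <- plantedFixture()
  o <- fx$orient
  oSwap <- o
  oSwap$light <- o$heavy; oSwap$heavy <- o$light
  d1 <- discordanceValues(traitDiscordance(fx$cohort, o))
  d2 <- discordanceValues(traitDiscordance(fx$cohort, oSwap))
  expect_identical(d1, -d2)
})

test_that("discordance is invariant to positive rescaling of a trait", {
  fx <- plantedFixture()
  co2 <- fx$cohort
  SummarizedExperiment::colData(co2)$weight <-
    SummarizedExperiment::colData(co2)$weight * 7.3
  d1 <- discordanceValues(traitDiscordance(fx$cohort, fx$orient))
  d2 <- discordanceValues(traitDiscordance(co2, fx$orient))
  expect_equal(d1, d2, tolerance = 1e-12)
})

test_that("equal co-twins give an all-zero row", {
  co <- mkPairCohort(c(70, 70), bmi = c(26, 27))
  o <- assignReference(co)
  d <- traitDiscordance(co, o, traits = c("weight", "height"))
  expect_equal(unname(discordanceValues(d)[1, ]), c(0, 0))
})

test_that("nonpositive cells go missing and heavy missingness drops rows", {
  tm <- matrix(c(24, 31, 1.6, 1.6, 60, -1), 2, 3,
               dimnames = list(c("iA", "iB"), c("bmi", "height", "weight")))
  co <- makeCohort(tm, pair = c("P1", "P1"))
  o <- assignReference(co)
  expect_warning(
    expect_warning(d <- traitDiscordance(co, o,
                                         traits = c("bmi", "height",
                                                    "weight")),
                   "nonpositive"),
    "dropped")
  expect_identical(nrow(discordanceValues(d)), 0L)
  d2 <- suppressWarnings(traitDiscordance(co, o,
                                          traits = c("bmi", "height",
                                                     "weight"),
                                          max_missing_frac = 0.5))
  expect_identical(nrow(discordanceValues(d2)), 1L)
  expect_true(is.na(discordanceValues(d2)[1, "weight"]))
})

test_that("height adjustment divides mass traits by squared height", {
  tm <- matrix(c(24, 31, 1.6, 1.6, 20, 25), 2, 3,
               dimnames = list(c("iA", "iB"), c("bmi", "height", "fat_total")))
  co <- makeCohort(tm, pair = c("P1", "P1"))
  adj <- heightAdjustedTraits(co)
  cd <- SummarizedExperiment::colData(adj)
  expect_equal(unname(cd$fat_total_hadj[1]), 20 / 1.6^2, tolerance = 1e-12)
  expect_equal(unname(cd$fat_total_hadj[1]), 7.8125)
  expect_true("bmi" %in% S4Vectors::metadata(adj)$traitNames)
})

test_that("equal heights within a pair cancel in adjusted discordances", {
  fx <- plantedFixture()
  co <- fx$cohort
  ## force exactly equal heights within every pair
  cd <- SummarizedExperiment::colData(co)
  h <- ave(cd$height, as.character(cd$pair))
  SummarizedExperiment::colData(co)$height <- h
  adj <- heightAdjustedTraits(co)
  dRaw <- discordanceValues(traitDiscordance(co, fx$orient,
                                             traits = "fat_total"))
  dAdj <- discordanceValues(traitDiscordance(adj, fx$orient,
                                             traits = "fat_total_hadj"))
  expect_equal(unname(dRaw[, 1]), unname(dAdj[, 1]), tolerance = 1e-10)
})

test_that("adjusted discordance equals raw minus twice the height discordance", {
  fx <- plantedFixture()
  adj <- heightAdjustedTraits(fx$cohort)
  dRaw <- discordanceValues(traitDiscordance(fx$cohort, fx$orient,
                                             traits = c("fat_total",
                                                        "height")))
  dAdj <- discordanceValues(traitDiscordance(adj, fx$orient,
                                             traits = "fat_total_hadj"))
  expect_equal(unname(dAdj[, 1]),
               unname(dRaw[, "fat_total"] - 2 * dRaw[, "height"]),
               tolerance = 1e-10)
})

test_that("zero height rejects the pair", {
  tm <- matrix(c(24, 31, 0, 1.6, 20, 25), 2, 3,
               dimnames = list(c("iA", "iB"), c("bmi", "height", "fat_total")))
  co <- makeCohort(tm, pair = c("P1", "P1"))
  expect_warning(adj <- heightAdjustedTraits(co), "nonpositive height")
  expect_identical(ncol(adj), 0L)
})

test_that("MZ/DZ comparison has power when DZ discordance doubles MZ", {
  set.seed(31)
  nTraits <- 40
  pvals <- vapply(seq_len(nTraits), function(i) {
    mzv <- matrix(rnorm(50, 0, 0.05), ncol = 1,
                  dimnames = list(sprintf("m%02d", 1:50), "t"))
    dzv <- matrix(rnorm(50, 0, 0.10), ncol = 1,
                  dimnames = list(sprintf("d%02d", 1:50), "t"))
    o <- function(v) data.frame(pair = rownames(v), light = "x", heavy = "y")
    mz <- new("DiscordanceMatrix", values = mzv, orientation = o(mzv),
              logBase = "e")
    dz <- new("DiscordanceMatrix", values = dzv, orientation = o(dzv),
              logBase = "e")
    zygosityDiscordanceTest(mz, dz)$p
  }, 0)
  expect_gte(mean(pvals < 0.01), 0.95)
})

test_that("MZ/DZ comparison holds its size under the null", {
  set.seed(32)
  pvals <- replicate(400, {
    v <- function(pfx) matrix(rnorm(30, 0, 0.05), ncol = 1,
                              dimnames = list(paste0(pfx, 1:30), "t"))
    mzv <- v("m"); dzv <- v("d")
    o <- function(vv) data.frame(pair = rownames(vv), light = "x",
                                 heavy = "y")
    zygosityDiscordanceTest(
      new("DiscordanceMatrix", values = mzv, orientation = o(mzv),
          logBase = "e"),
      new("DiscordanceMatrix", values = dzv, orientation = o(dzv),
          logBase = "e"))$p
  })
  expect_lt(abs(mean(pvals < 0.05) - 0.05), 0.04)
})

test_that("an empty DZ matrix skips the trait and returns an empty table", {
  v <- matrix(rnorm(10), ncol = 1, dimnames = list(paste0("m", 1:10), "t"))
  o <- data.frame(pair = rownames(v), light = "x", heavy = "y")
  mz <- new("DiscordanceMatrix", values = v, orientation = o, logBase = "e")
  dzv <- v[0, , drop = FALSE]
  dz <- new("DiscordanceMatrix", values = dzv,
            orientation = o[0, ], logBase = "e")
  expect_warning(res <- zygosityDiscordanceTest(mz, dz), "skipped")
  expect_identical(nrow(res), 0L)
})
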