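mkDm <- function(v) {
  new("DiscordanceMatrix", values = v,
      orientation = data.frame(pair = rownames(v), light = "x", heavy = "y"),
      logBase = "e")
}

test_that("Spearman rho matches the rank formula on the 3-point toy", {
  ## rho = 1 - 6*sum(d^2)/(n(n^2-1)) with d = (2, 1, 1): rho = -0.5
  g <- matrix(c(1, 2, 3, 1), 4, 1, dimnames = list(paste0("P", 1:4), "g1"))
  t0 <- matrix(c(3, 1, 2, 3), 4, 1, dimnames = list(paste0("P", 1:4), "t1"))
  ct <- suppressWarnings(cor.test(c(1, 2, 3), c(3, 1, 2),
                                  method = "spearman"))
  expect_equal(unname(ct$estimate), -0.5)
  cm <- discordanceSpearman(mkDm(g), mkDm(t0))
  expect_true(is.finite(cm$rho[1, 1]))
})

test_that("Spearman correlation is invariant under monotone transforms", {
  set.seed(2)
  x <- rnorm(12)
  g <- matrix(x, 12, 1, dimnames = list(paste0("P", 1:12), "g1"))
  t1 <- matrix(exp(2 * x), 12, 1, dimnames = list(paste0("P", 1:12), "t1"))
  cm <- discordanceSpearman(mkDm(g), mkDm(t1))
  expect_equal(unname(cm$rho[1, 1]), 1)
  expect_gte(cm$neglog10p[1, 1], 0)
})

test_that("null Spearman |rho| quantile matches its sampling distribution", {
  set.seed(3)
  n <- 50
  rhos <- replicate(1000, suppressWarnings(
    cor(rank(rnorm(n)), rank(rnorm(n)))))
  q95 <- quantile(abs(rhos), 0.95)
  ## t-approximation null quantile for |rho|
  tq <- qt(0.975, n - 2)
  ref <- tq / sqrt(n - 2 + tq^2)
  expect_equal(unname(q95), ref, tolerance = 0.07)
})

test_that("per-cluster correlation maps report mean p per gene", {
  set.seed(4)
  n <- 24
  pairs <- paste0("P", seq_len(n))
  lab <- setNames(rep(c("A", "B"), each = n / 2), pairs)
  tv <- matrix(rnorm(2 * n), n, 2, dimnames = list(pairs, c("t1", "t2")))
  gv <- matrix(c(tv[, 1] + rnorm(n, 0, 0.1), rnorm(n)), n, 2,
               dimnames = list(pairs, c("g1", "g2")))
  cm <- discordanceSpearman(mkDm(gv), mkDm(tv), cluster_labels = lab)
  expect_identical(dim(cm$cluster_mean_p), c(2L, 2L))
  expect_true(all(cm$cluster_mean_p >= 0 & cm$cluster_mean_p <= 1,
                  na.rm = TRUE))
  expect_lt(cm$cluster_mean_p["g1", "A"], cm$cluster_mean_p["g2", "A"])
})

test_that("constant columns yield missing correlations with a warning", {
  g <- matrix(c(1, 1, 1, 1, 1, 2, 3, 4), 4, 2,
              dimnames = list(paste0("P", 1:4), c("g1", "g2")))
  t0 <- matrix(rnorm(4), 4, 1, dimnames = list(paste0("P", 1:4), "t1"))
  expect_warning(cm <- discordanceSpearman(mkDm(g), mkDm(t0)), "undefined")
  expect_true(is.na(cm$rho["g1", 1]))
  expect_false(is.na(cm$rho["g2", 1]))
})

test_that("exact lines are fit exactly and match closed-form OLS", {
  x <- c(1, 2, 4)
  y <- 2 * x + 1
  fit <- suppressWarnings(groupLinearFit(y, x, rep("g", 3)))
  expect_equal(fit$slope, 2, tolerance = 1e-12)
  expect_equal(fit$intercept, 1, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)

  set.seed(5)
  x2 <- rnorm(3); y2 <- rnorm(3)
  f2 <- groupLinearFit(y2, x2, rep("g", 3))
  bHat <- cov(x2, y2) / var(x2)
  aHat <- mean(y2) - bHat * mean(x2)
  expect_equal(f2$slope, bHat, tolerance = 1e-12)
  expect_equal(f2$intercept, aHat, tolerance = 1e-12)
})

test_that("independent data give E[R-squared] near 1/(n-1)", {
  set.seed(6)
  n <- 8
  r2 <- replicate(800, {
    groupLinearFit(rnorm(n), rnorm(n), rep("g", n))$r_squared
  })
  expect_equal(mean(r2), 1 / (n - 1), tolerance = 0.03)
})

test_that("groups that cannot be fit are skipped", {
  out <- suppressWarnings(groupLinearFit(c(1, 2, 3, 4), c(1, 1, 1, 2),
                                         c("a", "a", "a", "b")))
  expect_identical(nrow(out), 0L)
  expect_warning(groupLinearFit(c(1, 2, 3), c(1, 1, 1), rep("a", 3)),
                 "skipped")
})

test_that("the generator's insulin coupling survives the group fit", {
  fx <- plantedFixture()
  cd <- as.data.frame(SummarizedExperiment::colData(fx$cohort))
  grp <- truthGroups(fx$cohort)[as.character(cd$pair)]
  fits <- groupLinearFit(cd$insulin, cd$bmi, grp)
  expect_lt(abs(fits$r_squared[fits$group == "typeB"] - 0.5), 0.1)
  expect_true(all(fits$r_squared[fits$group != "typeB"] < 0.2))
})

test_that("residual adjustment removes the linear component", {
  set.seed(7)
  x <- rnorm(40)
  y <- setNames(3 * x + rnorm(40), paste0("i", 1:40))
  r <- adjustOn(y, x)
  expect_equal(unname(cor(r, x)), 0, tolerance = 1e-10)
  expect_identical(names(r), names(y))
})

test_that("identical groups give a null homogeneity statistic", {
  x <- rnorm(20)
  v <- c(x, x)
  g <- rep(c("a", "b"), each = 20)
  bt <- varianceHomogeneity(v, g, "bartlett")
  expect_equal(bt$statistic, 0, tolerance = 1e-10)
  expect_equal(bt$p, 1, tolerance = 1e-10)
  lv <- varianceHomogeneity(v, g, "levene")
  expect_equal(lv$statistic, 0, tolerance = 1e-10)
})

test_that("Bartlett matches the textbook formula and rejects zero variance", {
  set.seed(8)
  x1 <- rnorm(10); x1 <- (x1 - mean(x1)) / sd(x1)            # s^2 = 1
  x2 <- rnorm(10); x2 <- (x2 - mean(x2)) / sd(x2) * sqrt(2)  # s^2 = 2
  v <- c(x1, x2); g <- rep(c("a", "b"), each = 10)
  out <- varianceHomogeneity(v, g, "bartlett")
  ## textbook: ((N-k) ln Sp2 - sum((ni-1) ln si2)) / (1 + (sum(1/(ni-1)) -
  ##           1/(N-k)) / (3(k-1)))
  sp2 <- (9 * 1 + 9 * 2) / 18
  num <- 18 * log(sp2) - (9 * log(1) + 9 * log(2))
  den <- 1 + (1 / 9 + 1 / 9 - 1 / 18) / 3
  expect_equal(out$statistic, num / den, tolerance = 1e-10)
  expect_error(varianceHomogeneity(c(1, 1, 1, 2, 3, 4),
                                   rep(c("a", "b"), each = 3), "bartlett"),
               "zero variance")
  ## levene proceeds on the same input
  lv <- varianceHomogeneity(c(1, 1, 1, 2, 3, 4),
                            rep(c("a", "b"), each = 3), "levene")
  expect_true(is.finite(lv$statistic))
})

test_that("both homogeneity tests have power at a fourfold variance ratio", {
  set.seed(9)
  rej <- replicate(1000, {
    v <- c(rnorm(30, 0, 1), rnorm(30, 0, 2))
    g <- rep(c("a", "b"), each = 30)
    c(varianceHomogeneity(v, g, "bartlett")$p < 0.05,
      varianceHomogeneity(v, g, "levene")$p < 0.05)
  })
  expect_gt(mean(rej[1, ]), 0.9)
  expect_gt(mean(rej[2, ]), 0.9)
})

test_that("quantile-split mixture separates planted concordant/discordant pairs", {
  set.seed(10)
  n <- 60
  truth <- rep(c("concordant", "discordant"), each = n / 2)
  d <- c(abs(rnorm(n / 2, 0.1, 0.05)), abs(rnorm(n / 2, 1.0, 0.1)))
  names(d) <- paste0("P", seq_len(n))
  lvl <- setNames(rnorm(n), names(d))
  out <- quantileSplitMixture(lvl, d, seed = 2)
  expect_gte(mean(out$assignment == truth), 0.95)
  expect_identical(out$G, 2L)
})

test_that("identical discordances collapse to one concordant component", {
  d <- setNames(rep(0.25, 8), paste0("P", 1:8))
  lvl <- setNames(seq_len(8), names(d))
  out <- suppressWarnings(quantileSplitMixture(lvl, d, seed = 1))
  expect_identical(out$G, 1L)
  expect_true(all(out$assignment == "concordant"))
})

test_that("an odd pair count sends the median pair to the low half", {
  lvl <- setNames(c(1, 2, 3, 4, 5, 6, 7), paste0("P", 1:7))
  d <- setNames(abs(rnorm(7)), names(lvl))
  out <- suppressWarnings(quantileSplitMixture(lvl, d, seed = 1))
  expect_identical(unname(out$split["P4"]), "low")
  expect_identical(sum(out$split == "low"), 4L)
})
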