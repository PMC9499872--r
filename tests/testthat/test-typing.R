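mkD <- function(v) {
  new("DiscordanceMatrix", values = v,
      orientation = data.frame(pair = rownames(v), light = "x", heavy = "y"),
      logBase = "e")
}

test_that("pair clustering recovers the planted groups", {
  fx <- plantedFixture()
  clu <- clusterCotwinPairs(fx$Dmz, k_neighbors = 10, seed = 1, n_null = 0)
  tg <- truthGroups(fx$cohort)[names(clusterLabels(clu))]
  expect_gte(mclust::adjustedRandIndex(clusterLabels(clu), tg), 0.8)
})

test_that("identical pairs are always co-clustered", {
  set.seed(4)
  v <- rbind(matrix(rnorm(40 * 6), 40, 6),
             matrix(rnorm(40 * 6, 3), 40, 6))
  v[2, ] <- v[1, ]
  rownames(v) <- sprintf("P%02d", 1:80)
  colnames(v) <- paste0("t", 1:6)
  clu <- clusterCotwinPairs(mkD(v), k_neighbors = 10, seed = 2, n_null = 0)
  lab <- clusterLabels(clu)
  expect_identical(lab[["P01"]], lab[["P02"]])
})

test_that("zero-effect cohorts are reported as a single stable cluster", {
  cfg <- smallSimConfig(seed = 8, effect_fat = 0, effect_lean = 0)
  co <- simulateTwinCohort(cfg)
  orient <- assignReference(co)
  D <- traitDiscordance(co, orient)
  mzp <- names(zygosity(co))[zygosity(co) == "MZ"]
  v <- discordanceValues(D)
  Dmz <- mkD(v[rownames(v) %in% mzp, ])
  clu <- clusterCotwinPairs(Dmz, seed = 8, n_null = 29)
  expect_identical(clu@parameters$n_stable_clusters, 1L)
})

test_that("too few pairs is an explicit error", {
  v <- matrix(rnorm(5 * 35), 5, 35,
              dimnames = list(paste0("P", 1:5), paste0("t", 1:35)))
  expect_error(clusterCotwinPairs(mkD(v), k_neighbors = 20), "insufficient")
})

test_that("community detection matches exhaustive modularity search on a two-clique toy", {
  ## two tight point clouds whose SNN graph is two cliques plus weak links
  set.seed(7)
  X <- rbind(matrix(rnorm(5 * 2, 0, 0.05), 5, 2),
             matrix(rnorm(5 * 2, 10, 0.05), 5, 2))
  rownames(X) <- paste0("P", 1:10)
  colnames(X) <- c("a", "b")
  g <- TwinUPV:::.snnGraph(scale(X), k = 4, prune = 0)
  A <- as.matrix(igraph::as_adjacency_matrix(g, attr = "weight"))
  m2 <- sum(A)
  kdeg <- rowSums(A)
  modOf <- function(lab) {
    same <- outer(lab, lab, "==")
    sum((A - outer(kdeg, kdeg) / m2) * same) / m2
  }
  ## exhaustive search over all partitions into at most 3 blocks
  best <- -Inf; bestLab <- NULL
  for (code in 0:(3^9 - 1)) {
    lab <- c(0, (code %/% 3^(0:8)) %% 3)
    q <- modOf(lab)
    if (q > best) { best <- q; bestLab <- lab }
  }
  clu <- clusterCotwinPairs(mkD(X), k_neighbors = 4, seed = 1, n_null = 0,
                            prune = 0)
  lab <- clusterLabels(clu)
  expect_equal(mclust::adjustedRandIndex(lab, bestLab), 1)
  expect_equal(mclust::adjustedRandIndex(lab, rep(1:2, each = 5)), 1)
})

test_that("type assignment follows the centroid rules", {
  v <- rbind(conc = c(0.01, 0.00), A = c(0.30, -0.05),
             B = c(0.35, 0.20), mid = c(0.20, 0.06))
  colnames(v) <- c("fat_x", "lean_x")
  D <- mkD(v)
  clu <- new("UPVClustering",
             labels = setNames(1:4, rownames(v)), types = character(0),
             embedding = matrix(numeric(0), 0, 2),
             centroids = v, parameters = list())
  out <- assignClusterTypes(clu, D, fat_traits = "fat_x",
                            lean_traits = "lean_x", tau_lean = 0.1)
  expect_identical(unname(clusterTypes(out)[as.character(1:4)]),
                   c("Concordant", "TypeA", "TypeB", "Intermediate"))
})

test_that("a single cluster is labelled Concordant and typing is idempotent", {
  v <- matrix(rnorm(20, 0.2, 0.05), 10, 2,
              dimnames = list(paste0("P", 1:10), c("fat_x", "lean_x")))
  D <- mkD(v)
  clu <- new("UPVClustering", labels = setNames(rep(1L, 10), rownames(v)),
             types = character(0), embedding = matrix(numeric(0), 0, 2),
             centroids = matrix(0, 1, 2), parameters = list())
  out <- assignClusterTypes(clu, D, "fat_x", "lean_x")
  expect_identical(unname(clusterTypes(out)), "Concordant")
  out2 <- assignClusterTypes(out, D, "fat_x", "lean_x")
  expect_identical(clusterTypes(out2), clusterTypes(out))
})

test_that("type assignment requires fat/lean tags", {
  fx <- plantedFixture()
  clu <- clusterCotwinPairs(fx$Dmz, seed = 1, n_null = 0)
  expect_error(assignClusterTypes(clu, fx$Dmz, character(0), character(0)),
               "tags")
})

test_that("heat-map ordering reproduces hand-computed complete linkage", {
  v <- matrix(c(0, 1, 10), 3, 1, dimnames = list(c("a", "b", "c"), "t"))
  hm <- heatmapOrder(v, scale_rows = FALSE)
  expect_equal(sort(hm$row_heights), c(1, 10))

  v2 <- rbind(a = c(1, 2, 3), b = c(1, 2, 3), c = c(9, 1, 2))
  colnames(v2) <- paste0("t", 1:3)
  hm2 <- heatmapOrder(v2, scale_rows = FALSE)
  expect_equal(min(hm2$row_heights), 0)
})

test_that("heat-map ordering is invariant to row permutation", {
  set.seed(12)
  v <- matrix(rnorm(60), 10, 6,
              dimnames = list(paste0("P", 1:10), paste0("t", 1:6)))
  hm1 <- heatmapOrder(v)
  perm <- sample(10)
  hm2 <- heatmapOrder(v[perm, ])
  expect_equal(sort(hm1$row_heights), sort(hm2$row_heights))
  expect_identical(hm1$col_order, hm2$col_order)
  d1 <- stats::cophenetic(hm1$row_hclust)
  d2 <- stats::cophenetic(hm2$row_hclust)
  m1 <- as.matrix(d1); m2 <- as.matrix(d2)[rownames(m1), colnames(m1)]
  expect_equal(m1, m2)
})

test_that("constant rows are scaled to zeros with a warning", {
  v <- rbind(a = c(1, 1, 1), b = c(1, 2, 3), c = c(3, 1, 2))
  colnames(v) <- paste0("t", 1:3)
  expect_warning(hm <- heatmapOrder(v), "constant")
  expect_equal(unname(hm$scaled["a", ]), c(0, 0, 0))
})

test_that("embedding is deterministic and separates planted groups", {
  fx <- plantedFixture()
  e1 <- embedPairs(fx$Dmz, seed = 5)
  e2 <- embedPairs(fx$Dmz, seed = 5)
  expect_identical(e1, e2)
  tg <- truthGroups(fx$cohort)[rownames(e1)]
  sil <- cluster::silhouette(as.integer(factor(tg)), dist(e1))
  expect_gt(mean(sil[, "sil_width"]), 0)
  expect_error(embedPairs(fx$Dmz, n_neighbors = nrow(discordanceValues(fx$Dmz))),
               "n_neighbors")
})

test_that("duplicated pairs embed close together", {
  fx <- plantedFixture()
  v <- discordanceValues(fx$Dmz)
  v <- rbind(v, dup1 = v[1, ], dup2 = v[1, ])
  emb <- embedPairs(mkD(v), seed = 3)
  dDup <- sqrt(sum((emb["dup1", ] - emb["dup2", ])^2))
  expect_lt(dDup, median(dist(emb)))
})
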