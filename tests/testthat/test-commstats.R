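test_that("Bray-Curtis matches its defining formula", {
  m <- rbind(x = c(1, 2, 0), y = c(3, 0, 0))
  colnames(m) <- c("a", "b", "c")
  d <- bray_curtis(m)
  expect_equal(as.numeric(d), 1 - 2 * 1 / (3 + 3))
  ident <- rbind(x = c(2, 1), y = c(2, 1))
  expect_equal(as.numeric(bray_curtis(ident)), 0)
  disj <- rbind(x = c(5, 0), y = c(0, 4))
  expect_equal(as.numeric(bray_curtis(disj)), 1)
  expect_error(bray_curtis(rbind(x = c(0, 0), y = c(1, 1))), "all-zero")
})

test_that("Bray-Curtis agrees with the vegan implementation", {
  skip_if_not_installed("vegan")
  set.seed(9)
  m <- matrix(rpois(60, 8), 6, 10,
              dimnames = list(sprintf("s%d", 1:6), sprintf("o%d", 1:10)))
  expect_equal(as.numeric(bray_curtis(m)),
               as.numeric(vegan::vegdist(m, "bray")))
  # relative-abundance normalization removes library-size effects
  m2 <- m
  m2[1, ] <- m[1, ] * 13
  expect_equal(as.numeric(bray_curtis(m2, relative = TRUE)),
               as.numeric(bray_curtis(m, relative = TRUE)))
})

test_that("ANOSIM attains R = 1 under perfect separation", {
  m <- as.matrix(dist(c(0, 0.1, 0.2, 10, 10.1, 10.2)))
  rownames(m) <- colnames(m) <- sprintf("s%d", 1:6)
  res <- anosim(stats::as.dist(m), rep(c("a", "b"), each = 3),
                n_perms = 999, seed = 1)
  expect_equal(res$R, 1)
  expect_true(res$exact)
  expect_equal(res$p, 2 / 20)  # complement labelling ties the partition
  expect_equal(res$band, "distinct")
})

test_that("ANOSIM matches the exhaustive brute-force oracle", {
  for (seed in 1:6) {
    set.seed(seed)
    m <- matrix(runif(36, 0.05, 0.9), 6, 6)
    m <- (m + t(m)) / 2
    diag(m) <- 0
    rownames(m) <- colnames(m) <- sprintf("s%d", 1:6)
    g <- rep(c("a", "b"), each = 3)
    res <- anosim(stats::as.dist(m), g, n_perms = 999, seed = seed)
    oracle <- oracle_anosim_exact(m, g)
    expect_equal(res$R, oracle$R)
    expect_equal(res$p, oracle$p)
    expect_true(res$exact)
  }
})

test_that("ANOSIM agrees with vegan on larger sampled problems", {
  skip_if_not_installed("vegan")
  set.seed(21)
  m <- matrix(rpois(240, 10), 12, 20,
              dimnames = list(sprintf("s%d", 1:12), sprintf("o%d", 1:20)))
  g <- rep(c("a", "b"), each = 6)
  d <- bray_curtis(m)
  expect_equal(anosim(d, g, n_perms = 999, seed = 1)$R,
               as.numeric(vegan::anosim(d, g, permutations = 0)$statistic))
})

test_that("ANOSIM R is invariant under monotone distance transforms", {
  set.seed(5)
  m <- matrix(runif(64, 0.1, 0.9), 8, 8)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  rownames(m) <- colnames(m) <- sprintf("s%d", 1:8)
  g <- rep(c("a", "b"), each = 4)
  r1 <- anosim(stats::as.dist(m), g, n_perms = 99, seed = 1)$R
  r2 <- anosim(stats::as.dist(m^3), g, n_perms = 99, seed = 1)$R
  r3 <- anosim(stats::as.dist(log1p(m)), g, n_perms = 99, seed = 1)$R
  expect_equal(r1, r2)
  expect_equal(r1, r3)
})

test_that("ANOSIM null p-values are approximately uniform", {
  set.seed(33)
  pvals <- replicate(60, {
    m <- matrix(runif(100), 10, 10)
    m <- (m + t(m)) / 2
    diag(m) <- 0
    rownames(m) <- colnames(m) <- sprintf("s%d", 1:10)
    anosim(stats::as.dist(m), rep(c("a", "b"), each = 5),
           n_perms = 199, seed = sample.int(1e6, 1))$p
  })
  # labels carry no information, so p <= 0.05 should occur ~5% of the time
  expect_lte(mean(pvals <= 0.05), 0.15)
  expect_gte(mean(pvals > 0.5), 0.25)
})

test_that("ANOSIM rejects degenerate groupings", {
  m <- as.matrix(dist(1:5))
  rownames(m) <- colnames(m) <- sprintf("s%d", 1:5)
  expect_error(anosim(stats::as.dist(m), c("a", "a", "a", "a", "b"),
                      n_perms = 99), "singleton")
  expect_error(anosim(stats::as.dist(m), rep("a", 5), n_perms = 99),
               "two groups")
})

test_that("SIMPER contributions sum to the pairwise Bray-Curtis", {
  set.seed(13)
  m <- matrix(rpois(80, 6) + 1, 8, 10,
              dimnames = list(sprintf("s%d", 1:8), sprintf("o%d", 1:10)))
  ga <- sprintf("s%d", 1:4)
  gb <- sprintf("s%d", 5:8)
  rel <- m / rowSums(m)
  for (i in ga[1:2]) {
    for (j in gb[1:2]) {
      contrib <- abs(rel[i, ] - rel[j, ]) / sum(rel[i, ] + rel[j, ])
      bc <- 1 - 2 * sum(pmin(rel[i, ], rel[j, ])) /
        (sum(rel[i, ]) + sum(rel[j, ]))
      expect_equal(sum(contrib), bc, tolerance = 1e-12)
    }
  }
  res <- simper(m, ga, gb)
  d <- as.matrix(bray_curtis(rel))
  expect_equal(attr(res, "average_dissimilarity"),
               mean(d[ga, gb]), tolerance = 1e-12)
  expect_equal(sum(res$percent), 100)
  expect_true(all(diff(res$contribution) <= 1e-15))
})

test_that("SIMPER matches a hand-computed pair-average oracle", {
  counts <- matrix(c(6, 2, 2,
                     5, 3, 2,
                     1, 7, 2,
                     2, 6, 2), 4, 3, byrow = TRUE,
                   dimnames = list(c("a1", "a2", "b1", "b2"),
                                   c("o1", "o2", "o3")))
  rel <- counts / rowSums(counts)
  pairs <- expand.grid(i = c("a1", "a2"), j = c("b1", "b2"),
                       stringsAsFactors = FALSE)
  oracle <- colMeans(t(apply(pairs, 1, function(p) {
    abs(rel[p[1], ] - rel[p[2], ]) / sum(rel[p[1], ] + rel[p[2], ])
  })))
  res <- simper(counts, c("a1", "a2"), c("b1", "b2"))
  expect_equal(stats::setNames(res$contribution, res$otu_id),
               sort(oracle, decreasing = TRUE))
  expect_equal(res$otu_id[1], "o1")
})

test_that("SIMPER flags single-OTU differences and degenerate groups", {
  counts <- matrix(c(10, 5, 5, 5,
                     10, 5, 5, 5,
                     2, 5, 5, 5,
                     2, 5, 5, 5), 4, 4, byrow = TRUE,
                   dimnames = list(c("a1", "a2", "b1", "b2"),
                                   sprintf("o%d", 1:4)))
  res <- simper(counts, c("a1", "a2"), c("b1", "b2"), relative = FALSE)
  expect_equal(res$percent[1], 100)
  expect_equal(res$otu_id[1], "o1")
  same <- counts[c(1, 2, 1, 2), ]
  rownames(same) <- c("a1", "a2", "b1", "b2")
  res2 <- simper(same, c("a1", "a2"), c("b1", "b2"))
  expect_true(attr(res2, "degenerate"))
  expect_true(all(is.na(res2$percent)))
  expect_error(simper(counts, character(0), "b1"), "non-empty")
})

test_that("NMDS embeds exactly embeddable configurations with ~zero stress", {
  square <- matrix(c(0, 0, 1, 0, 1, 1, 0, 1), ncol = 2, byrow = TRUE)
  rownames(square) <- sprintf("p%d", 1:4)
  res <- nmds(dist(square), n_restarts = 10, seed = 2)
  expect_lt(res$stress, 0.01)
  expect_true(all(diff(res$stress_trace) <= 1e-12))
})

test_that("NMDS stress decreases monotonically within a run", {
  set.seed(8)
  m <- matrix(runif(100, 0.1, 1), 10, 10)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  rownames(m) <- colnames(m) <- sprintf("s%d", 1:10)
  res <- nmds(stats::as.dist(m), n_restarts = 5, seed = 3)
  expect_true(all(diff(res$stress_trace) <= 1e-12))
  expect_gte(res$stress, 0)
})

test_that("NMDS separates planted clusters like a reference implementation", {
  skip_if_not_installed("MASS")
  set.seed(17)
  pts <- rbind(matrix(rnorm(8, 0, 0.05), 4, 2),
               matrix(rnorm(8, 3, 0.05), 4, 2))
  rownames(pts) <- sprintf("s%d", 1:8)
  d <- dist(pts)
  res <- nmds(d, n_restarts = 10, seed = 4)
  e <- as.matrix(dist(res$points))
  within <- c(e[1:4, 1:4][lower.tri(e[1:4, 1:4])],
              e[5:8, 5:8][lower.tri(e[5:8, 5:8])])
  between <- e[1:4, 5:8]
  expect_gt(min(between), max(within))
  ref <- MASS::isoMDS(d, k = 2, trace = FALSE)
  eref <- as.matrix(dist(ref$points))
  expect_gt(min(eref[1:4, 5:8]), max(c(eref[1:4, 1:4][lower.tri(diag(4))],
                                       eref[5:8, 5:8][lower.tri(diag(4))])))
})
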