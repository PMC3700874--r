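test_that("FASTA round-trip preserves records and parses sample ids", {
  recs <- data.frame(id = c("Chm94B|ATT|c0001", "Chm94B|SUS|c0002"),
                     sample_id = c("Chm94B_ATT", "Chm94B_SUS"),
                     seq = c("ACGTACGT", "ACGTTCGT"),
                     stringsAsFactors = FALSE)
  f <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(recs, f)
  back <- read_fasta(f)
  expect_equal(back, recs)
  # lowercase residues are normalized to uppercase
  writeLines(c(">A|ATT|c1", "acgt"), f)
  expect_equal(read_fasta(f)$seq, "ACGT")
  writeLines(c(">A|ATT|c1", "ACGT", ">A|ATT|c1", "ACGT"), f)
  expect_error(read_fasta(f), "duplicate")
})

test_that("pairwise distances follow the declared conventions", {
  expect_equal(pairwise_distance("ACGT", "ACGT"), 0)
  expect_equal(pairwise_distance("ACGT", "ACGA"), 0.25)
  # gap-gap columns are ignored; gap-base columns count as differences
  expect_equal(pairwise_distance("AC-T", "AC-A"), 1 / 3)
  expect_equal(pairwise_distance("AC-T", "ACGT"), 0.25)
  expect_error(pairwise_distance("ACG", "ACGT"), "equal lengths")
  # symmetry over random pairs, both modes
  set.seed(1)
  for (k in 1:5) {
    a <- paste(sample(c("A", "C", "G", "T"), 30, TRUE), collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), 30, TRUE), collapse = "")
    expect_equal(pairwise_distance(a, b), pairwise_distance(b, a))
    expect_equal(pairwise_distance(a, b, "global"),
                 pairwise_distance(b, a, "global"))
  }
  # global mode scores indels over the alignment length
  expect_equal(pairwise_distance("ACGTACGT", "ACGTACGT", "global"), 0)
  expect_gt(pairwise_distance("ACGTACGT", "ACGACGT", "global"), 0)
})

test_that("degenerate clusterings behave as expected", {
  recs <- data.frame(id = sprintf("s%d", 1:4), sample_id = "A_ATT",
                     seq = rep("ACGTACGTAC", 4), stringsAsFactors = FALSE)
  tab <- cluster_average_neighbor(recs, 0.03)
  expect_equal(ncol(tab$counts), 1)
  expect_equal(sum(tab$counts), 4)
  two <- data.frame(id = c("s1", "s2"), sample_id = "A_ATT",
                    seq = c("AAAAAAAAAA", "AAAAAAAAGG"),  # distance 0.2
                    stringsAsFactors = FALSE)
  expect_equal(ncol(cluster_average_neighbor(two, 0.03)$counts), 2)
  expect_equal(ncol(cluster_average_neighbor(two, 0.5)$counts), 1)
  expect_error(cluster_average_neighbor(two, 1.5), "cutoff")
})

test_that("richness is monotone in the clustering cutoff", {
  recs <- gen_sequences(4, 4, 0.02, 0.2, length = 120, seed = 11)
  d <- distance_matrix(recs)
  k <- vapply(c(0, 0.01, 0.03, 0.1, 0.5, 1),
              function(ct) ncol(cluster_average_neighbor(recs, ct,
                                                         d = d)$counts), 0)
  expect_true(all(diff(k) <= 0))
  # cutoff 0: one OTU per distinct sequence; cutoff 1: a single OTU
  expect_equal(k[1], length(unique(recs$seq)))
  expect_equal(k[length(k)], 1)
})

test_that("average-neighbour clustering matches a brute-force UPGMA oracle", {
  for (seed in 1:8) {
    set.seed(seed)
    n <- sample(6:12, 1)
    ids <- sprintf("s%02d", seq_len(n))
    m <- matrix(runif(n * n, 0.01, 0.4), n, n, dimnames = list(ids, ids))
    m <- (m + t(m)) / 2
    diag(m) <- 0
    cutoff <- runif(1, 0.05, 0.3)
    recs <- data.frame(id = ids, sample_id = "A_ATT", seq = "ACGT",
                       stringsAsFactors = FALSE)
    mine <- attr(cluster_average_neighbor(recs, cutoff,
                                          d = stats::as.dist(m)),
                 "assignments")
    oracle <- oracle_upgma_cut(m, cutoff)
    expect_true(same_partition(mine, oracle), info = paste("seed", seed))
  }
})

test_that("planted sequence clusters are recovered exactly at 97%", {
  recs <- gen_sequences(5, 6, within_divergence = 0.01,
                        between_divergence = 0.10, length = 250, seed = 3)
  tab <- cluster_average_neighbor(recs, 0.03)
  expect_equal(ncol(tab$counts), 5)
  expect_true(same_partition(attr(recs, "truth"),
                             attr(tab, "assignments")[recs$id]))
})

test_that("collector's curves are monotone and end at the pool richness", {
  cc <- collectors_curve(c(a = 7, b = 2, c = 1), seed = 4)
  expect_true(all(diff(cc$richness) >= 0))
  expect_equal(tail(cc$richness, 1), 3)
  expect_equal(collectors_curve(c(one = 5))$richness, rep(1, 5))
  singles <- stats::setNames(rep(1, 6), letters[1:6])
  expect_equal(collectors_curve(singles, seed = 2)$richness, 1:6)
})

test_that("mean collector's curve matches the hypergeometric expectation", {
  counts <- c(12, 6, 4, 2, 1, 1, 1)
  curves <- vapply(1:400, function(s) collectors_curve(counts, seed = s)$richness,
                   numeric(sum(counts)))
  mc <- rowMeans(curves)
  exact <- vapply(seq_len(sum(counts)),
                  function(d) expected_richness(counts, d), 0)
  se <- apply(curves, 1, stats::sd) / sqrt(ncol(curves))
  # depths are strongly correlated along a trajectory, so allow 4 SE for
  # the simultaneous per-depth comparison
  expect_true(all(abs(mc - exact) <= pmax(4 * se, 1e-9)))
})

test_that("subsampling is reproducible and matches rarefaction", {
  tab <- toy_table()
  expect_error(subsample_table(tab, depth = 1000), "exceeds")
  full <- subsample_table(tab, depth = sum(tab$counts))
  expect_equal(sum(full), sum(tab$counts))
  s1 <- subsample_table(tab, depth = 10, seed = 7)
  expect_equal(subsample_table(tab, depth = 10, seed = 7), s1)
  expect_equal(sum(s1), 10)
  # observed richness after subsampling never exceeds the pool's
  expect_lte(length(s1), sum(colSums(tab$counts) > 0))
  # mean richness over 500 seeds vs the closed form (3 SE: a single
  # Monte-Carlo comparison, kept tight but not flaky)
  pool <- colSums(tab$counts)
  depth <- 12
  rich <- vapply(1:500, function(s)
    length(subsample_table(tab, depth = depth, seed = s)), 0)
  se <- stats::sd(rich) / sqrt(length(rich))
  expect_lte(abs(mean(rich) - expected_richness(pool, depth)), 3 * se)
})

test_that("shared-richness accounting matches hand counts", {
  counts <- matrix(c(5, 5, 0,
                     0, 2, 8), nrow = 2, byrow = TRUE,
                   dimnames = list(c("A_ATT", "A_SUS"),
                                   c("Otu001", "Otu002", "Otu003")))
  tab <- otu_table(counts)
  s <- shared_richness(tab, "A_ATT", "A_SUS")
  expect_equal(s$otus_a, 2)
  expect_equal(s$otus_b, 2)
  expect_equal(s$shared_otus, 1)
  expect_equal(s$pct_seqs_in_shared_a, 50)
  expect_equal(s$pct_seqs_in_shared_b, 20)
  # symmetry under swapping groups
  s2 <- shared_richness(tab, "A_SUS", "A_ATT")
  expect_equal(s2$otus_a, s$otus_b)
  expect_equal(s2$pct_seqs_in_shared_a, s$pct_seqs_in_shared_b)
  expect_error(shared_richness(tab, "A_ATT", "A_ATT"), "overlap")
})

test_that("disjoint and identical compositions give 0% and 100% shared", {
  disjoint <- otu_table(matrix(c(5, 0, 0, 7), 2, byrow = TRUE,
                               dimnames = list(c("X_ATT", "X_SUS"),
                                               c("Otu001", "Otu002"))))
  s <- shared_richness(disjoint, "X_ATT", "X_SUS")
  expect_equal(s$shared_otus, 0)
  expect_equal(s$pct_seqs_in_shared_a + s$pct_seqs_in_shared_b, 0)
  same <- otu_table(matrix(c(3, 4, 3, 4), 2, byrow = TRUE,
                           dimnames = list(c("X_ATT", "X_SUS"),
                                           c("Otu001", "Otu002"))))
  s2 <- shared_richness(same, "X_ATT", "X_SUS")
  expect_equal(s2$pct_otus_shared_a, 100)
  expect_equal(s2$pct_seqs_in_shared_b, 100)
})
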