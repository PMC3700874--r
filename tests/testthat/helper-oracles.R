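# Independent oracles used across the suite.  These deliberately take the
# naive route (definition-level double loops, full recomputation from the
# original distance matrix) rather than the package's algorithms.

# ANOSIM R straight from the definition: rank all pairs, average
# between/within ranks.
oracle_anosim_r <- function(dmat, grouping) {
  n <- nrow(dmat)
  pairs <- which(lower.tri(dmat), arr.ind = TRUE)
  r <- rank(dmat[lower.tri(dmat)])
  between <- grouping[pairs[, 1]] != grouping[pairs[, 2]]
  (mean(r[between]) - mean(r[!between])) / (nrow(pairs) / 2)
}

# all C(n, k) two-group label assignments
oracle_anosim_exact <- function(dmat, grouping) {
  n <- nrow(dmat)
  labs <- sort(unique(grouping))
  stopifnot(length(labs) == 2)
  k <- sum(grouping == labs[1])
  combos <- utils::combn(n, k)
  r_all <- apply(combos, 2, function(idx) {
    g <- rep(labs[2], n)
    g[idx] <- labs[1]
    oracle_anosim_r(dmat, g)
  })
  r_obs <- oracle_anosim_r(dmat, grouping)
  list(R = r_obs, p = mean(r_all >= r_obs - 1e-12), null = r_all)
}

# Brute-force UPGMA: cluster-to-cluster distances recomputed every merge
# as the mean over all member pairs of the ORIGINAL distance matrix.
oracle_upgma_cut <- function(dmat, cutoff) {
  ids <- rownames(dmat)
  clusters <- as.list(seq_along(ids))
  repeat {
    if (length(clusters) == 1) break
    best <- NULL
    best_d <- Inf
    for (a in seq_along(clusters)[-length(clusters)]) {
      for (b in seq((a + 1), length(clusters))) {
        dd <- mean(dmat[clusters[[a]], clusters[[b]]])
        if (dd < best_d - 1e-12) {
          best_d <- dd
          best <- c(a, b)
        }
      }
    }
    if (best_d > cutoff) break
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  assign <- integer(length(ids))
  for (k in seq_along(clusters)) assign[clusters[[k]]] <- k
  assign
}

same_partition <- function(a, b) {
  length(unique(paste(a, b))) == length(unique(a)) &&
    length(unique(a)) == length(unique(b))
}

# tiny well fixture for energetics tests
toy_well <- function(so4 = 0.5, ch4 = 10, h2 = 20, dic = 7, ph = 7.5,
                     temp = 14, spc = 700, id = "Toy1") {
  w <- data.frame(
    well_id = id, formation = "unknown", temperature = temp, ph = ph,
    spec_cond = spc,
    so4 = so4, so4_status = ifelse(is.na(so4), "missing", "measured"),
    ch4 = ch4, ch4_status = ifelse(is.na(ch4), "missing", "measured"),
    h2 = h2, h2_status = ifelse(is.na(h2), "missing", "measured"),
    dic = dic, dic_status = ifelse(is.na(dic), "missing", "measured"),
    doc = 1, doc_status = "measured", stringsAsFactors = FALSE)
  class(w) <- c("well_chem", "data.frame")
  w
}

# small deterministic OTU table
toy_table <- function() {
  counts <- matrix(c(5, 5, 0,
                     4, 6, 0,
                     0, 2, 8,
                     1, 0, 9), nrow = 4, byrow = TRUE,
                   dimnames = list(c("W1_ATT", "W2_ATT", "W1_SUS", "W2_SUS"),
                                   c("Otu001", "Otu002", "Otu003")))
  otu_table(counts)
}
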