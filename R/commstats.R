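#' Bray-Curtis dissimilarity matrix
#'
#' d(x, y) = 1 - 2 sum_k min(x_k, y_k) / (sum_k x_k + sum_k y_k) between
#' every pair of sample rows.
#'
#' @param x an `otu_table` or a samples x OTUs numeric matrix.
#' @param relative normalize each sample to relative abundance first.
#' @return a `dist` with entries in \[0, 1\], labelled by sample id.
#' @export
bray_curtis <- function(x, relative = FALSE) {
  m <- if (inherits(x, "otu_table")) x$counts else as.matrix(x)
  if (nrow(m) < 2) stop("need at least two samples")
  zero <- rowSums(m) == 0
  if (any(zero)) {
    stop("all-zero sample(s): ", paste(rownames(m)[zero], collapse = ", "))
  }
  if (relative) m <- m / rowSums(m)
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      d[i, j] <- d[j, i] <-
        1 - 2 * sum(pmin(m[i, ], m[j, ])) / (sum(m[i, ]) + sum(m[j, ]))
    }
  }
  stats::as.dist(d)
}

# R statistic from a distance matrix and a grouping, Clarke's definition:
# mid-ranks of all off-diagonal distances; R = (rB - rW) / (M / 2).
.anosim_r <- function(rank_mat, same_group) {
  rb <- mean(rank_mat[!same_group])
  rw <- mean(rank_mat[same_group])
  M <- length(same_group)  # number of pairs
  (rb - rw) / (M / 2)
}

# all distinct assignments of a label multiset to positions (small n only)
.label_permutations <- function(labels) {
  uniq <- sort(unique(labels))
  counts <- table(factor(labels, levels = uniq))
  out <- list()
  recurse <- function(prefix, remaining) {
    if (sum(remaining) == 0) {
      out[[length(out) + 1]] <<- prefix
      return(invisible())
    }
    for (u in seq_along(uniq)) {
      if (remaining[u] > 0) {
        rem <- remaining
        rem[u] <- rem[u] - 1
        recurse(c(prefix, uniq[u]), rem)
      }
    }
  }
  recurse(character(0), as.vector(counts))
  out
}

#' Analysis of similarity (ANOSIM)
#'
#' Rank-based test contrasting between-group and within-group
#' dissimilarities: R = (mean between-group rank - mean within-group
#' rank) / (M/2), with M = n(n-1)/2 and mid-ranks for ties.  Inference is
#' by permutation of the group labels; when the number of distinct label
#' assignments does not exceed `n_perms` the null distribution is
#' enumerated exhaustively (exact p), otherwise `n_perms` random
#' permutations are drawn and p = (1 + #\{R* >= R\}) / (1 + n_perms).
#'
#' Interpretation bands follow common practice for community data:
#' R > 0.75 "distinct", 0.25--0.75 "overlapping", < 0.25 "indistinct".
#'
#' @param d a `dist` of community dissimilarities.
#' @param grouping vector of group labels, one per sample (>= 2 groups,
#'   each with >= 2 members).
#' @param n_perms number of permutations (>= 99).
#' @param seed RNG seed.
#' @return an `anosim_result` list: `R`, `p`, `n_perms`, `exact`, `band`.
#' @export
anosim <- function(d, grouping, n_perms = 999, seed = 1) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  grouping <- as.character(grouping)
  if (length(grouping) != n) stop("grouping length must match samples")
  sizes <- table(grouping)
  if (length(sizes) < 2) stop("need at least two groups")
  if (any(sizes < 2)) {
    stop("singleton group(s): ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  }
  if (n_perms < 99) stop("n_perms must be >= 99")
  low <- lower.tri(dm)
  ranks <- rank(dm[low])  # mid-ranks for ties
  pair_i <- row(dm)[low]
  pair_j <- col(dm)[low]
  same <- function(g) g[pair_i] == g[pair_j]
  r_obs <- .anosim_r(ranks, same(grouping))
  n_total <- exp(lfactorial(n) - sum(lfactorial(sizes)))
  exact <- n_total <= n_perms + 0.5
  if (exact) {
    perms <- .label_permutations(grouping)
    r_null <- vapply(perms, function(g) .anosim_r(ranks, same(g)), 0)
    p <- mean(r_null >= r_obs - 1e-12)
    n_used <- length(perms)
  } else {
    r_null <- withr::with_seed(seed, vapply(seq_len(n_perms), function(k) {
      .anosim_r(ranks, same(sample(grouping)))
    }, 0))
    p <- (1 + sum(r_null >= r_obs - 1e-12)) / (1 + n_perms)
    n_used <- n_perms
  }
  band <- if (r_obs > 0.75) "distinct" else if (r_obs < 0.25) {
    "indistinct"
  } else "overlapping"
  structure(list(R = r_obs, p = p, n_perms = n_used, exact = exact,
                 band = band, null_R = r_null),
            class = "anosim_result")
}

#' @export
print.anosim_result <- function(x, ...) {
  cat(sprintf("ANOSIM R = %.3f, p = %.4g (%s, %d permutations) [%s]\n",
              x$R, x$p, if (x$exact) "exact" else "sampled", x$n_perms,
              x$band))
  invisible(x)
}

#' SIMPER: per-OTU contributions to between-group dissimilarity
#'
#' For every cross-group sample pair (i, j) the Bray-Curtis dissimilarity
#' decomposes exactly as d(i,j) = sum_k |x_ik - x_jk| / sum_m (x_im +
#' x_jm); the per-OTU terms are averaged over all cross pairs and ranked.
#' Samples are first converted to relative abundance (clone libraries
#' differ in size).
#'
#' @param table an `otu_table` or samples x OTUs matrix.
#' @param group_a,group_b character vectors of sample ids.
#' @param relative convert to relative abundance first (default TRUE).
#' @return data.frame ordered by decreasing contribution: `otu_id`,
#'   `contribution` (average dissimilarity share), `percent`,
#'   `cumulative_percent`, `mean_abund_a`, `mean_abund_b`, `rank`.
#'   Attribute `"average_dissimilarity"` holds the mean cross-pair
#'   Bray-Curtis; degenerate (zero-dissimilarity) comparisons are flagged
#'   by attribute `"degenerate"`.
#' @export
simper <- function(table, group_a, group_b, relative = TRUE) {
  m <- if (inherits(table, "otu_table")) table$counts else as.matrix(table)
  if (length(group_a) == 0 || length(group_b) == 0) {
    stop("both groups must be non-empty")
  }
  if (!all(c(group_a, group_b) %in% rownames(m))) {
    stop("unknown sample id(s)")
  }
  if (relative) m <- m / rowSums(m)
  contrib <- matrix(0, length(group_a) * length(group_b), ncol(m))
  pair <- 0
  for (i in group_a) {
    for (j in group_b) {
      pair <- pair + 1
      contrib[pair, ] <- abs(m[i, ] - m[j, ]) / sum(m[i, ] + m[j, ])
    }
  }
  avg <- colMeans(contrib)
  total <- sum(avg)
  degenerate <- total <= 0
  pct <- if (degenerate) rep(NA_real_, length(avg)) else 100 * avg / total
  ord <- order(avg, decreasing = TRUE)
  out <- data.frame(
    otu_id = colnames(m)[ord],
    contribution = avg[ord],
    percent = pct[ord],
    cumulative_percent = if (degenerate) NA_real_ else cumsum(pct[ord]),
    mean_abund_a = colMeans(m[group_a, , drop = FALSE])[ord],
    mean_abund_b = colMeans(m[group_b, , drop = FALSE])[ord],
    rank = seq_along(ord),
    stringsAsFactors = FALSE)
  attr(out, "average_dissimilarity") <- total
  attr(out, "degenerate") <- degenerate
  out
}

#' Non-metric multidimensional scaling with Kruskal stress
#'
#' Embeds a dissimilarity matrix in `dims` dimensions by iterative
#' majorization (Guttman transform) alternated with monotone (isotonic)
#' regression of the configuration distances on the dissimilarity order
#' (primary treatment of ties).  Stress-1 =
#' sqrt(sum (e_ij - dhat_ij)^2 / sum e_ij^2) is tracked and an update
#' that would increase it terminates the run, so the reported stress
#' sequence is monotone non-increasing.  The best of `n_restarts` seeded
#' starts (one classical-scaling start plus random starts) is returned.
#'
#' @param d a `dist` (>= 4 samples).
#' @param dims embedding dimension, default 2.
#' @param n_restarts number of starts, default 20.
#' @param max_iter iteration cap per start.
#' @param tol relative stress-improvement convergence tolerance.
#' @param seed RNG seed.
#' @return an `nmds_result`: `points` (samples x dims), `stress`
#'   (Kruskal stress-1), `stress_trace` of the winning start, `converged`,
#'   `seed`, `n_restarts`.
#' @export
nmds <- function(d, dims = 2, n_restarts = 20, max_iter = 200, tol = 1e-7,
                 seed = 1) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  if (n < 4) stop("need at least four samples")
  low <- lower.tri(dm)
  diss <- dm[low]
  ord <- order(diss)
  run_one <- function(x0) {
    x <- x0
    e <- as.vector(stats::dist(x))
    stress <- Inf
    x_best <- x
    trace <- numeric(0)
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      # isotonic regression of configuration distances on dissimilarity order
      iso <- stats::isoreg(e[ord])
      dhat <- numeric(length(e))
      dhat[ord] <- iso$yf
      denom <- sum(e^2)
      s <- sqrt(sum((e - dhat)^2) / denom)
      if (s > stress + 1e-12) break  # never accept an increase
      x_best <- x
      trace <- c(trace, s)
      if (is.finite(stress) && stress - s < tol * max(stress, 1e-12)) {
        stress <- s
        converged <- TRUE
        break
      }
      stress <- s
      # Guttman transform with disparities dhat
      b <- matrix(0, n, n)
      ratio <- ifelse(e > 1e-12, dhat / e, 0)
      b[low] <- ratio
      b <- b + t(b)
      diag(b) <- -rowSums(b)
      x_new <- -(b %*% x) / n
      x_new <- scale(x_new, center = TRUE, scale = FALSE)
      x <- x_new
      e <- as.vector(stats::dist(x))
    }
    list(points = x_best, stress = stress, trace = trace,
         converged = converged)
  }
  starts <- withr::with_seed(seed, {
    s <- list()
    cmd <- tryCatch(stats::cmdscale(dm, k = dims), error = function(e) NULL)
    if (!is.null(cmd) && ncol(cmd) == dims) s[[1]] <- cmd
    while (length(s) < n_restarts) {
      s[[length(s) + 1]] <- matrix(stats::rnorm(n * dims), n, dims)
    }
    s
  })
  fits <- lapply(starts, run_one)
  best <- fits[[which.min(vapply(fits, `[[`, 0, "stress"))]]
  rownames(best$points) <- rownames(dm)
  structure(list(points = best$points, stress = best$stress,
                 stress_trace = best$trace, converged = best$converged,
                 seed = seed, n_restarts = length(starts)),
            class = "nmds_result")
}

#' @export
print.nmds_result <- function(x, ...) {
  cat(sprintf("NMDS in %d dimensions: stress-1 = %.4f (%s, best of %d starts)\n",
              ncol(x$points), x$stress,
              if (x$converged) "converged" else "iteration cap", x$n_restarts))
  invisible(x)
}
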