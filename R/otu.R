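#' Read clone-library sequences from FASTA
#'
#' The sample a clone belongs to is parsed from the record header with a
#' configurable regular expression; by default headers look like
#' `well|fraction|clone` (e.g. `Chm94B|ATT|c0001`) and the sample id is
#' `well_fraction`.
#'
#' @param path FASTA file.
#' @param id_pattern regex with capture groups applied to the header.
#' @param sample_groups indices of the capture groups pasted (with `_`)
#'   into the sample id.
#' @return data.frame with `id`, `sample_id`, `seq` (uppercase residues).
#' @export
read_fasta <- function(path,
                       id_pattern = "^([^|]+)\\|([^|]+)\\|(.+)$",
                       sample_groups = c(1, 2)) {
  set <- Biostrings::readBStringSet(path)
  ids <- names(set)
  seqs <- toupper(as.character(set))
  if (any(nchar(seqs) == 0)) {
    stop("empty sequence(s): ", paste(ids[nchar(seqs) == 0], collapse = ", "))
  }
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  m <- regmatches(ids, regexec(id_pattern, ids))
  sample_id <- vapply(m, function(g) {
    if (length(g) == 0) return(NA_character_)
    paste(g[sample_groups + 1], collapse = "_")
  }, "")
  if (anyNA(sample_id)) {
    stop("header(s) not matching id pattern: ",
         paste(ids[is.na(sample_id)], collapse = ", "))
  }
  data.frame(id = ids, sample_id = sample_id, seq = unname(seqs),
             stringsAsFactors = FALSE)
}

#' Write sequence records to FASTA
#'
#' Inverse of [read_fasta()] for records whose `id` already encodes the
#' sample; write-then-read is the identity.
#'
#' @param records data.frame with `id` and `seq`.
#' @param path output path.
#' @export
write_fasta <- function(records, path) {
  set <- Biostrings::BStringSet(stats::setNames(records$seq, records$id))
  Biostrings::writeXStringSet(set, path, width = 70)
  invisible(path)
}

#' Pairwise sequence dissimilarity
#'
#' `mode = "aligned"` assumes the two sequences are columns of a common
#' alignment (equal length): the dissimilarity is the fraction of columns
#' that differ, ignoring columns where both sequences have a gap and
#' counting gap-versus-base columns as differences.  `mode = "global"`
#' first aligns the raw sequences with Needleman-Wunsch (match 1,
#' mismatch -1, linear gap -2) and then scores mismatch+indel columns over
#' the alignment length.
#'
#' @param a,b sequence strings.
#' @param mode `"aligned"` or `"global"`.
#' @return dissimilarity in \[0, 1\]; 0 iff identical.
#' @export
pairwise_distance <- function(a, b, mode = c("aligned", "global")) {
  mode <- match.arg(mode)
  if (nchar(a) == 0 || nchar(b) == 0) stop("empty sequence")
  if (mode == "aligned") {
    if (nchar(a) != nchar(b)) {
      stop("aligned mode requires equal lengths (", nchar(a), " vs ",
           nchar(b), ")")
    }
    ca <- strsplit(a, "")[[1]]
    cb <- strsplit(b, "")[[1]]
    keep <- !(ca == "-" & cb == "-")
    if (!any(keep)) return(0)
    sum(ca[keep] != cb[keep]) / sum(keep)
  } else {
    al <- Biostrings::pairwiseAlignment(
      Biostrings::BString(a), Biostrings::BString(b), type = "global",
      substitutionMatrix = .nw_submat(), gapOpening = 0, gapExtension = 2)
    pa <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
    pb <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
    sum(pa != pb) / length(pa)
  }
}

.nw_submat <- function() {
  letters <- c("A", "C", "G", "T", "N")
  m <- matrix(-1, 5, 5, dimnames = list(letters, letters))
  diag(m) <- 1
  m
}

#' All-pairs distance matrix for sequence records
#'
#' @param records data.frame from [read_fasta()] or [gen_sequences()].
#' @param mode see [pairwise_distance()].
#' @return a `dist` object labelled by sequence id.
#' @export
distance_matrix <- function(records, mode = "aligned") {
  n <- nrow(records)
  d <- matrix(0, n, n, dimnames = list(records$id, records$id))
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      d[i, j] <- d[j, i] <- pairwise_distance(records$seq[i], records$seq[j],
                                              mode)
    }
  }
  stats::as.dist(d)
}

#' Average-neighbour OTU clustering
#'
#' Agglomerative clustering with average linkage (UPGMA merge criterion)
#' on a pairwise distance matrix, merging while the smallest
#' cluster-to-cluster average distance does not exceed the cutoff
#' (default 0.03, i.e. 97% similarity).  Ties in the merge order are
#' broken deterministically in favour of the pair whose lexicographically
#' smallest member id is smallest.
#'
#' @param records data.frame with `id`, `sample_id`, `seq` (or NULL when
#'   `d` is supplied with ids as labels and `samples` gives membership).
#' @param cutoff dissimilarity cutoff in \[0, 1\].
#' @param mode distance mode, see [pairwise_distance()].
#' @param d optional precomputed `dist`.
#' @return an `otu_table` (see [otu_table()]); OTU membership of each
#'   sequence in attribute `"assignments"` (named by sequence id).
#' @export
cluster_average_neighbor <- function(records, cutoff = 0.03,
                                     mode = "aligned", d = NULL) {
  if (cutoff < 0 || cutoff > 1) stop("cutoff must be in [0, 1]")
  if (nrow(records) < 1) stop("need at least one sequence")
  if (is.null(d)) d <- distance_matrix(records, mode)
  dm <- as.matrix(d)
  ids <- records$id
  n <- length(ids)
  members <- lapply(seq_len(n), function(i) i)
  active <- rep(TRUE, n)
  # cluster-average distances maintained under Lance-Williams (UPGMA)
  cd <- dm
  sizes <- rep(1L, n)
  key <- function(k) min(ids[members[[k]]])
  while (sum(active) > 1) {
    idx <- which(active)
    best <- NULL
    best_d <- Inf
    for (ii in seq_along(idx)[-length(idx)]) {
      for (jj in seq((ii + 1), length(idx))) {
        i <- idx[ii]; j <- idx[jj]
        dij <- cd[i, j]
        if (dij < best_d - 1e-12) {
          best_d <- dij; best <- c(i, j)
        } else if (abs(dij - best_d) <= 1e-12) {
          # tie: lexicographically smallest member id wins
          cand <- sort(c(key(i), key(j)))
          cur <- sort(c(key(best[1]), key(best[2])))
          if (cand[1] < cur[1] || (cand[1] == cur[1] && cand[2] < cur[2])) {
            best <- c(i, j)
          }
        }
      }
    }
    if (best_d > cutoff) break
    i <- best[1]; j <- best[2]
    for (k in which(active)) {
      if (k == i || k == j) next
      cd[i, k] <- cd[k, i] <-
        (sizes[i] * cd[i, k] + sizes[j] * cd[j, k]) / (sizes[i] + sizes[j])
    }
    members[[i]] <- c(members[[i]], members[[j]])
    sizes[i] <- sizes[i] + sizes[j]
    active[j] <- FALSE
  }
  clusters <- members[active]
  # deterministic OTU order: by representative (smallest member id)
  reps <- vapply(clusters, function(m) min(ids[m]), "")
  clusters <- clusters[order(reps)]
  reps <- sort(reps)
  assignments <- integer(n)
  for (k in seq_along(clusters)) assignments[clusters[[k]]] <- k
  names(assignments) <- ids
  tab <- otu_table_from_assignments(records, assignments, reps)
  attr(tab, "assignments") <- assignments
  tab
}

#' Construct an OTU table
#'
#' A light S3 container: a non-negative integer count matrix (samples x
#' OTUs, no all-zero OTU columns) plus per-sample metadata (well, fraction
#' ATT/SUS, sulfate class) and per-OTU metadata (representative sequence
#' id, optional externally supplied taxonomy label).
#'
#' @param counts samples x OTUs matrix with dimnames.
#' @param samples data.frame with `sample_id` and optionally `well_id`,
#'   `fraction`, `sulfate_class`; rows match `rownames(counts)`.
#' @param otus data.frame with `otu_id` and optionally `representative`,
#'   `taxonomy`; rows match `colnames(counts)`.
#' @return an `otu_table`.
#' @export
otu_table <- function(counts, samples = NULL, otus = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must carry sample and OTU dimnames")
  }
  if (any(colSums(counts) == 0)) {
    stop("all-zero OTU column(s): ",
         paste(colnames(counts)[colSums(counts) == 0], collapse = ", "))
  }
  if (is.null(samples)) {
    samples <- data.frame(sample_id = rownames(counts),
                          stringsAsFactors = FALSE)
  }
  if (is.null(otus)) {
    otus <- data.frame(otu_id = colnames(counts), stringsAsFactors = FALSE)
  }
  stopifnot(identical(samples$sample_id, rownames(counts)),
            identical(otus$otu_id, colnames(counts)))
  structure(list(counts = counts, samples = samples, otus = otus),
            class = "otu_table")
}

otu_table_from_assignments <- function(records, assignments, reps) {
  samples <- sort(unique(records$sample_id))
  k <- max(assignments)
  otu_ids <- sprintf("Otu%03d", seq_len(k))
  counts <- matrix(0L, length(samples), k,
                   dimnames = list(samples, otu_ids))
  for (r in seq_len(nrow(records))) {
    counts[records$sample_id[r], assignments[r]] <-
      counts[records$sample_id[r], assignments[r]] + 1L
  }
  otu_table(counts,
            samples = data.frame(sample_id = samples,
                                 stringsAsFactors = FALSE),
            otus = data.frame(otu_id = otu_ids, representative = reps,
                              stringsAsFactors = FALSE))
}

#' @export
print.otu_table <- function(x, ...) {
  cat("otu_table:", nrow(x$counts), "samples x", ncol(x$counts), "OTUs;",
      sum(x$counts), "sequences\n")
  invisible(x)
}

#' Collector's curve of observed richness
#'
#' Cumulative number of distinct OTUs observed as sequences from one pool
#' are accumulated one at a time, in a given or a seeded-random order.
#'
#' @param counts named OTU count vector for one pooled sample set.
#' @param order optional integer vector: the OTU index of each arriving
#'   sequence (length `sum(counts)`).  When NULL, a seeded shuffle is used.
#' @param seed RNG seed for the shuffle.
#' @return data.frame with `depth` (1..N) and `richness`, monotone
#'   non-decreasing, ending at the total richness of the pool.
#' @export
collectors_curve <- function(counts, order = NULL, seed = 1) {
  counts <- counts[counts > 0]
  if (sum(counts) < 1) stop("need at least one sequence")
  arrivals <- rep(seq_along(counts), counts)
  if (is.null(order)) {
    order <- withr::with_seed(seed, sample(length(arrivals)))
  }
  seen <- !duplicated(arrivals[order])
  data.frame(depth = seq_along(arrivals), richness = cumsum(seen))
}

#' Expected rarefied richness (hypergeometric closed form)
#'
#' E\[OTUs at depth d\] = sum_j (1 - C(N - n_j, d) / C(N, d)) for OTU
#' counts n_j summing to N, computed on the log scale for stability.
#'
#' @param counts OTU count vector.
#' @param depth subsample depth d <= sum(counts).
#' @return expected number of OTUs observed in a without-replacement
#'   subsample of size `depth`.
#' @export
expected_richness <- function(counts, depth) {
  counts <- counts[counts > 0]
  N <- sum(counts)
  if (depth > N) stop("depth exceeds total count")
  miss <- ifelse(N - counts >= depth,
                 exp(lchoose(N - counts, depth) - lchoose(N, depth)), 0)
  sum(1 - miss)
}

#' Subsample an OTU table pool without replacement
#'
#' Pools the counts of a set of samples and draws `depth` sequences
#' without replacement, reproducibly under `seed`; used to normalize
#' richness comparisons across unequal library sizes.
#'
#' @param table an `otu_table`.
#' @param pool character vector of sample ids to pool (default: all).
#' @param depth number of sequences to draw.
#' @param seed RNG seed.
#' @return named OTU count vector of the subsample (zero OTUs dropped).
#' @export
subsample_table <- function(table, pool = NULL, depth, seed = 1) {
  pool <- pool %||% table$samples$sample_id
  counts <- colSums(table$counts[pool, , drop = FALSE])
  N <- sum(counts)
  if (depth > N) stop("depth ", depth, " exceeds pooled total ", N)
  if (depth == N) return(counts[counts > 0])
  arrivals <- rep(seq_along(counts), counts)
  take <- withr::with_seed(seed, sample(arrivals, depth))
  sub <- tabulate(take, nbins = length(counts))
  names(sub) <- names(counts)
  sub[sub > 0]
}

#' Unique and shared OTU richness between two sample groups
#'
#' Accounting used to compare attached (ATT) and suspended (SUS)
#' fractions: the richness of each group, the OTUs detected in both, what
#' share of each group's richness they represent, and what share of each
#' group's sequences falls into those shared OTUs.
#'
#' @param table an `otu_table`.
#' @param group_a,group_b disjoint character vectors of sample ids.
#' @return one-row data.frame: `otus_a`, `otus_b`, `shared_otus`,
#'   `pct_otus_shared_a`, `pct_otus_shared_b`, `pct_seqs_in_shared_a`,
#'   `pct_seqs_in_shared_b` (percentages in 0--100).
#' @export
shared_richness <- function(table, group_a, group_b) {
  if (length(intersect(group_a, group_b)) > 0) {
    stop("groups overlap: ",
         paste(intersect(group_a, group_b), collapse = ", "))
  }
  if (length(group_a) == 0 || length(group_b) == 0) {
    stop("both groups must be non-empty")
  }
  ca <- colSums(table$counts[group_a, , drop = FALSE])
  cb <- colSums(table$counts[group_b, , drop = FALSE])
  in_a <- ca > 0; in_b <- cb > 0
  shared <- in_a & in_b
  pct <- function(x, y) if (y == 0) 0 else 100 * x / y
  data.frame(
    otus_a = sum(in_a), otus_b = sum(in_b), shared_otus = sum(shared),
    pct_otus_shared_a = pct(sum(shared), sum(in_a)),
    pct_otus_shared_b = pct(sum(shared), sum(in_b)),
    pct_seqs_in_shared_a = pct(sum(ca[shared]), sum(ca)),
    pct_seqs_in_shared_b = pct(sum(cb[shared]), sum(cb)))
}
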