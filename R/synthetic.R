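#' Generate a synthetic well-chemistry table
#'
#' Emulates the structure of the aquifer chemistry data: sulfate drawn
#' inside each class interval (HS > 0.2 mM, LS 0.03--0.2 mM,
#' NS < 0.03 mM), methane inversely tied to the sulfate class (high in
#' NS, trace in HS), dihydrogen log-uniform over the observed 3--240 nM
#' span, and narrow field ranges for temperature (12--16 degC), pH
#' (7.1--7.9) and DIC (5--9 mM).  All values are generated strictly
#' inside their declared ranges so that [classify_sulfate()] recovers the
#' generating class exactly.
#'
#' @param n_per_class named integer vector, wells per class
#'   (default `c(HS = 9, LS = 8, NS = 8)`).
#' @param seed RNG seed; the generator is a pure function of its
#'   arguments and the seed.
#' @param ranges optional overrides, a list of `c(min, max)` entries named
#'   `so4_HS`, `so4_LS`, `so4_NS`, `ch4_HS`, `ch4_LS`, `ch4_NS` (uM),
#'   `h2` (nM), `temperature`, `ph`, `dic`, `spec_cond`, `doc`.
#' @return a `well_chem` data.frame with attribute `"true_class"`.
#' @export
gen_chemistry <- function(n_per_class = c(HS = 9, LS = 8, NS = 8), seed = 1,
                          ranges = list()) {
  def <- list(so4_HS = c(0.21, 11), so4_LS = c(0.031, 0.2),
              so4_NS = c(0.005, 0.03),
              ch4_HS = c(0.2, 20), ch4_LS = c(3, 50), ch4_NS = c(100, 1240),
              h2 = c(3, 240), temperature = c(12, 16), ph = c(7.1, 7.9),
              dic = c(5, 9), spec_cond = c(600, 1900), doc = c(0.4, 5))
  def[names(ranges)] <- ranges
  for (cl in c("HS", "LS", "NS")) {
    so4r <- def[[paste0("so4_", cl)]]
    if (!(so4r[1] <= so4r[2])) stop("invalid sulfate range for ", cl)
  }
  if (def$so4_NS[2] > 0.03 || def$so4_LS[1] <= 0.03 || def$so4_LS[2] > 0.2 ||
      def$so4_HS[1] <= 0.2) {
    stop("class sulfate ranges overlap the HS/LS/NS boundaries")
  }
  classes <- rep(c("HS", "LS", "NS"), n_per_class[c("HS", "LS", "NS")])
  n <- length(classes)
  runifr <- function(r, k) stats::runif(k, r[1], r[2])
  logunifr <- function(r, k) exp(stats::runif(k, log(r[1]), log(r[2])))
  out <- withr::with_seed(seed, {
    so4 <- vapply(classes, function(cl) {
      r <- def[[paste0("so4_", cl)]]
      if (cl == "HS") logunifr(r, 1) else runifr(r, 1)
    }, 0)
    ch4 <- vapply(classes, function(cl) {
      r <- def[[paste0("ch4_", cl)]]
      if (cl == "HS") logunifr(r, 1) else runifr(r, 1)
    }, 0)
    data.frame(
      well_id = sprintf("Syn%02d", seq_len(n)),
      formation = "unknown",
      temperature = round(runifr(def$temperature, n), 1),
      ph = round(runifr(def$ph, n), 1),
      spec_cond = round(runifr(def$spec_cond, n)),
      so4 = signif(so4, 3), so4_status = "measured",
      ch4 = signif(ch4, 3), ch4_status = "measured",
      h2 = signif(logunifr(def$h2, n), 3), h2_status = "measured",
      dic = round(runifr(def$dic, n), 1), dic_status = "measured",
      doc = round(runifr(def$doc, n), 1), doc_status = "measured",
      stringsAsFactors = FALSE)
  })
  class(out) <- c("well_chem", "data.frame")
  attr(out, "true_class") <- stats::setNames(classes, out$well_id)
  out
}

#' Specification for a synthetic clone-library community
#'
#' Describes the study design emulated by [gen_otu_table()]: wells per
#' sulfate class, the sampled fractions per well, per-library clone
#' counts, the number of OTUs, the Dirichlet base composition, and
#' planted multiplicative (log-fold) effects applied to disjoint OTU
#' blocks for chosen fraction/class combinations.
#'
#' @param n_wells named integer vector of wells per class.
#' @param fractions character vector of sampled fractions per well.
#' @param library_size clones per library (one library per
#'   well x fraction), the minimum per-sample sequencing depth of the
#'   emulated design.
#' @param n_otus number of OTUs in the regional species pool.
#' @param base_concentration Dirichlet concentration parameter; either a
#'   scalar (a geometric-decay base composition is built, mimicking the
#'   few-dominant/many-rare structure of clone libraries) or a full
#'   vector of length `n_otus`.
#' @param effects list of effect blocks, each a list with `otus` (integer
#'   indices), `log_fold` (natural-log fold change applied to the
#'   Dirichlet weights), and optional `fraction` and `class` restricting
#'   which samples are affected (NULL = all).  Blocks must be disjoint.
#' @param seed RNG seed.
#' @return a `community_spec` list.
#' @export
community_spec <- function(n_wells = c(HS = 9, LS = 8, NS = 8),
                           fractions = c("ATT", "SUS"),
                           library_size = 192,
                           n_otus = 300,
                           base_concentration = 150,
                           effects = default_effects(),
                           seed = 1) {
  if (length(base_concentration) == 1) {
    w <- 0.97^(seq_len(n_otus) - 1)
    base <- base_concentration * w / sum(w)
  } else {
    stopifnot(length(base_concentration) == n_otus)
    base <- base_concentration
  }
  if (any(base <= 0)) stop("Dirichlet concentrations must be > 0")
  all_block <- unlist(lapply(effects, `[[`, "otus"))
  if (anyDuplicated(all_block)) stop("effect OTU blocks must be disjoint")
  if (length(all_block) > 0 && max(all_block) > n_otus) {
    stop("effect blocks reference OTUs beyond n_otus")
  }
  structure(list(n_wells = n_wells, fractions = fractions,
                 library_size = library_size, n_otus = n_otus,
                 base = base, effects = effects, seed = seed),
            class = "community_spec")
}

#' Default planted effect blocks
#'
#' Mimics the headline contrasts of the aquifer communities: an
#' iron-reducer-like OTU block enriched in the attached (ATT) fraction, a
#' sulfate-reducer-like block enriched in attached samples of HS wells,
#' and a methanogen-like block enriched in NS wells.
#'
#' @param log_fold effect magnitude (natural log), default `log(15)` —
#'   the order of the fold-contrasts reported for the aquifer's
#'   discriminating taxa.
#' @return list of effect blocks for [community_spec()].
#' @export
default_effects <- function(log_fold = log(15)) {
  list(
    iron_reducers = list(otus = 1:15, log_fold = log_fold,
                         fraction = "ATT", class = NULL),
    sulfate_reducers = list(otus = 16:25, log_fold = log_fold,
                            fraction = "ATT", class = "HS"),
    methanogens = list(otus = 26:40, log_fold = log_fold,
                       fraction = NULL, class = "NS")
  )
}

# Dirichlet draw via gamma variates
.rdirichlet <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[which.max(alpha)] <- 1
  g / sum(g)
}

#' Generate a synthetic OTU count table
#'
#' One library per well x fraction.  Each library's composition is drawn
#' from Dirichlet(base * exp(effects)) where the planted effect blocks
#' are applied only to matching fraction/class samples; counts are then
#' multinomial at the specified library size, so row sums equal the
#' library size exactly.  With all effect log-folds zero the design
#' carries no group signal.
#'
#' @param spec a [community_spec()].
#' @return an `otu_table` with per-sample metadata (`well_id`, `fraction`,
#'   `sulfate_class`).
#' @export
gen_otu_table <- function(spec = community_spec()) {
  stopifnot(inherits(spec, "community_spec"))
  classes <- rep(names(spec$n_wells), spec$n_wells)
  wells <- sprintf("Syn%02d", seq_along(classes))
  design <- expand.grid(fraction = spec$fractions, well = wells,
                        stringsAsFactors = FALSE)
  design$class <- classes[match(design$well, wells)]
  sample_ids <- paste(design$well, design$fraction, sep = "_")
  counts <- withr::with_seed(spec$seed, {
    t(vapply(seq_len(nrow(design)), function(i) {
      alpha <- spec$base
      for (eff in spec$effects) {
        if (!is.null(eff$fraction) && design$fraction[i] != eff$fraction) next
        if (!is.null(eff$class) && design$class[i] != eff$class) next
        alpha[eff$otus] <- alpha[eff$otus] * exp(eff$log_fold)
      }
      # keep total concentration fixed: effects shift the expected
      # composition without also changing the overdispersion
      alpha <- alpha * sum(spec$base) / sum(alpha)
      p <- .rdirichlet(alpha)
      as.integer(stats::rmultinom(1, spec$library_size, p))
    }, integer(spec$n_otus)))
  })
  rownames(counts) <- sample_ids
  colnames(counts) <- sprintf("Otu%03d", seq_len(spec$n_otus))
  keep <- colSums(counts) > 0
  otu_table(counts[, keep, drop = FALSE],
            samples = data.frame(sample_id = sample_ids,
                                 well_id = design$well,
                                 fraction = design$fraction,
                                 sulfate_class = design$class,
                                 stringsAsFactors = FALSE),
            otus = data.frame(otu_id = colnames(counts)[keep],
                              stringsAsFactors = FALSE))
}

.BASES <- c("A", "C", "G", "T")

#' Generate clone-library sequences with planted clusters
#'
#' Draws one random ancestor per cluster and mutates each member at the
#' within-cluster substitution rate; independently drawn ancestors differ
#' at about 75% of sites, so between-cluster distances exceed any
#' practical clustering cutoff.  The planted cluster of each record is
#' returned in attribute `"truth"`.
#'
#' @param n_clusters number of planted clusters.
#' @param members_per_cluster sequences per cluster (scalar or vector).
#' @param within_divergence expected pairwise divergence between two
#'   members of the same cluster; each member is mutated away from the
#'   ancestor at half this per-site rate.
#' @param between_divergence required minimum expected divergence between
#'   clusters; must exceed `within_divergence` (and is attainable because
#'   random ancestors diverge at ~0.75).
#' @param length sequence length, nt.
#' @param seed RNG seed.
#' @param sample_ids optional sample label per record (default one pooled
#'   sample `"SynPool_ATT"`).
#' @return data.frame `id`, `sample_id`, `seq`, with attribute `"truth"`
#'   (integer planted-cluster label per record).
#' @export
gen_sequences <- function(n_clusters = 5, members_per_cluster = 6,
                          within_divergence = 0.01,
                          between_divergence = 0.10, length = 250, seed = 1,
                          sample_ids = NULL) {
  if (within_divergence >= between_divergence) {
    stop("within divergence must be below between divergence")
  }
  if (between_divergence > 0.7) {
    stop("between divergence above what random ancestors provide (~0.75)")
  }
  members <- rep_len(members_per_cluster, n_clusters)
  withr::with_seed(seed, {
    ancestors <- replicate(n_clusters, paste(
      sample(.BASES, length, replace = TRUE), collapse = ""))
    recs <- list()
    truth <- integer(0)
    idx <- 0
    for (k in seq_len(n_clusters)) {
      anc <- strsplit(ancestors[k], "")[[1]]
      for (m in seq_len(members[k])) {
        idx <- idx + 1
        s <- anc
        mut <- stats::runif(length) < within_divergence / 2
        if (any(mut)) {
          s[mut] <- vapply(s[mut], function(b)
            sample(setdiff(.BASES, b), 1), "")
        }
        recs[[idx]] <- paste(s, collapse = "")
        truth[idx] <- k
      }
    }
    ids <- sprintf("seq%04d", seq_len(idx))
    out <- data.frame(
      id = ids,
      sample_id = if (is.null(sample_ids)) "SynPool_ATT" else
        rep_len(sample_ids, idx),
      seq = unlist(recs), stringsAsFactors = FALSE)
    attr(out, "truth") <- truth
    out
  })
}
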