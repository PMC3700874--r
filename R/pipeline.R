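#' Build and validate a pipeline run configuration
#'
#' @param outdir output directory (created if needed).
#' @param seed master RNG seed; every stochastic stage derives its seed
#'   from it, so a rerun with the same config is reproducible.
#' @param chemistry either `"synthetic"`, a file path to a well-chemistry
#'   TSV, or a `well_chem` data.frame.  Default: the bundled aquifer
#'   table.
#' @param community either `"synthetic"`, a [community_spec()], an
#'   `otu_table`, or a FASTA path (clustered at `cutoff`).
#' @param cutoff OTU clustering cutoff for FASTA input.
#' @param censor_policy see [resolve_censored()].
#' @param class_override optional named vector of per-well class labels
#'   overriding [classify_sulfate()] (recorded exceptions).
#' @param energy_config options forwarded to [available_energy()].
#' @param n_perms ANOSIM permutations.
#' @param n_restarts NMDS restarts.
#' @param min_group minimum samples per group for an ANOSIM contrast to
#'   be testable (groups below it are reported as "not testable").
#' @return a validated `run_config` list.
#' @export
run_config <- function(outdir = tempfile("mahomet_run_"), seed = 1,
                       chemistry = "bundled", community = "synthetic",
                       cutoff = 0.03, censor_policy = "limit",
                       class_override = NULL, energy_config = list(),
                       n_perms = 999, n_restarts = 20, min_group = 2) {
  stopifnot(is.numeric(seed), length(seed) == 1,
            cutoff >= 0, cutoff <= 1, n_perms >= 99, n_restarts >= 1)
  censor_policy <- match.arg(censor_policy, c("limit", "half", "exclude"))
  structure(list(outdir = outdir, seed = as.integer(seed),
                 chemistry = chemistry, community = community,
                 cutoff = cutoff, censor_policy = censor_policy,
                 class_override = class_override,
                 energy_config = energy_config, n_perms = n_perms,
                 n_restarts = n_restarts, min_group = min_group),
            class = "run_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Stages, in dependency order: chemistry ingestion (or synthesis),
#' sulfate classification, available-energy table and AOM H2 thresholds;
#' community table ingestion (or synthesis), Bray-Curtis distances,
#' ANOSIM contrasts between fractions and between sulfate classes within
#' each fraction (with explicit "not testable" entries where a group is
#' too small), SIMPER rankings, NMDS ordination, and shared-richness
#' accounting between fractions.  All outputs plus a serialized config
#' snapshot are written under `config$outdir`.
#'
#' @param config a [run_config()].
#' @return a `run_report` list with every stage result and the paths of
#'   the files written.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  chem <- .stage("chemistry", {
    if (inherits(config$chemistry, "well_chem")) {
      config$chemistry
    } else if (identical(config$chemistry, "bundled")) {
      mahomet_wells()
    } else if (identical(config$chemistry, "synthetic")) {
      gen_chemistry(seed = config$seed)
    } else {
      read_well_table(config$chemistry)
    }
  })
  classes <- .stage("classification",
                    sulfate_classes(chem, config$class_override))
  e_cfg <- config$energy_config
  e_cfg$censor_policy <- e_cfg$censor_policy %||% config$censor_policy
  energy <- .stage("energetics", energy_table(chem, config = e_cfg))
  thresholds <- .stage("aom_threshold", {
    ok <- chem$ch4_status != "missing" & chem$dic_status != "missing"
    rows <- lapply(which(ok), function(i) {
      th <- h2_threshold_aom(chem[i, ], e_cfg)
      data.frame(well_id = chem$well_id[i], sulfate_class = classes[i],
                 h2_threshold_nM = th$h2_nM,
                 closed_form_nM = th$closed_form_nM,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  tab <- .stage("community", {
    if (inherits(config$community, "otu_table")) {
      config$community
    } else if (inherits(config$community, "community_spec")) {
      gen_otu_table(config$community)
    } else if (identical(config$community, "synthetic")) {
      gen_otu_table(community_spec(seed = config$seed))
    } else {
      recs <- read_fasta(config$community)
      cluster_average_neighbor(recs, cutoff = config$cutoff)
    }
  })
  meta <- tab$samples
  if (is.null(meta$fraction)) {
    # parse well/fraction out of sample ids of the form well_fraction
    parts <- strsplit(meta$sample_id, "_")
    meta$well_id <- vapply(parts, `[`, "", 1)
    meta$fraction <- vapply(parts, function(p) p[length(p)], "")
    tab$samples <- meta
  }
  if (is.null(meta$sulfate_class)) {
    meta$sulfate_class <- unname(classes[meta$well_id])
    tab$samples <- meta
  }
  d <- .stage("distances", bray_curtis(tab, relative = TRUE))
  contrasts <- .stage("anosim", {
    rows <- list()
    add <- function(label, ids_a, ids_b, ga, gb) {
      n_a <- length(ids_a); n_b <- length(ids_b)
      if (n_a < config$min_group || n_b < config$min_group) {
        rows[[length(rows) + 1]] <<- data.frame(
          contrast = label, R = NA_real_, p = NA_real_,
          n_a = n_a, n_b = n_b, band = "not testable: group too small",
          stringsAsFactors = FALSE)
        return(invisible())
      }
      ids <- c(ids_a, ids_b)
      sub <- stats::as.dist(as.matrix(d)[ids, ids])
      res <- anosim(sub, c(rep(ga, n_a), rep(gb, n_b)),
                    n_perms = config$n_perms, seed = config$seed)
      rows[[length(rows) + 1]] <<- data.frame(
        contrast = label, R = res$R, p = res$p, n_a = n_a, n_b = n_b,
        band = res$band, stringsAsFactors = FALSE)
    }
    s <- tab$samples
    att <- s$sample_id[s$fraction == "ATT"]
    sus <- s$sample_id[s$fraction == "SUS"]
    add("ATT-SUS", att, sus, "ATT", "SUS")
    for (fr in c("ATT", "SUS")) {
      for (pr in list(c("HS", "LS"), c("HS", "NS"), c("LS", "NS"))) {
        ids_a <- s$sample_id[s$fraction == fr & s$sulfate_class == pr[1]]
        ids_b <- s$sample_id[s$fraction == fr & s$sulfate_class == pr[2]]
        add(paste0(pr[1], "-", pr[2], " (", fr, ")"),
            ids_a, ids_b, pr[1], pr[2])
      }
    }
    do.call(rbind, rows)
  })
  simper_res <- .stage("simper", {
    s <- tab$samples
    att <- s$sample_id[s$fraction == "ATT"]
    sus <- s$sample_id[s$fraction == "SUS"]
    if (length(att) > 0 && length(sus) > 0) simper(tab, att, sus) else NULL
  })
  ord <- .stage("nmds", nmds(d, n_restarts = config$n_restarts,
                             seed = config$seed))
  richness <- .stage("shared_richness", {
    s <- tab$samples
    att <- s$sample_id[s$fraction == "ATT"]
    sus <- s$sample_id[s$fraction == "SUS"]
    if (length(att) > 0 && length(sus) > 0) {
      shared_richness(tab, att, sus)
    } else NULL
  })
  report <- structure(list(config = config, chemistry = chem,
                           classes = classes, energy = energy,
                           aom_thresholds = thresholds, otu_table = tab,
                           distances = d, anosim = contrasts,
                           simper = simper_res, nmds = ord,
                           shared_richness = richness),
                      class = "run_report")
  report$files <- write_report(report)
  report
}

#' Write pipeline outputs
#'
#' Serializes every stage result as TSV (distance matrix as a square
#' labelled TSV; NMDS coordinates with the stress in a `#` header
#' comment) plus a JSON config snapshot for provenance.
#'
#' @param report a `run_report` from [run_pipeline()].
#' @return named character vector of the files written.
#' @export
write_report <- function(report) {
  out <- report$config$outdir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  if (file.access(out, 2) != 0) stop("output directory not writable: ", out)
  files <- c()
  wtsv <- function(x, name, ...) {
    p <- file.path(out, name)
    utils::write.table(x, p, sep = "\t", quote = FALSE, row.names = FALSE,
                       ...)
    files[name] <<- p
    p
  }
  write_well_table(report$chemistry, file.path(out, "chemistry.tsv"))
  files["chemistry.tsv"] <- file.path(out, "chemistry.tsv")
  wtsv(data.frame(well_id = names(report$classes),
                  sulfate_class = unname(report$classes)), "classes.tsv")
  wtsv(report$energy, "energy.tsv")
  wtsv(report$aom_thresholds, "aom_thresholds.tsv")
  cm <- report$otu_table$counts
  wtsv(cbind(sample_id = rownames(cm), as.data.frame(cm)), "otu_counts.tsv")
  wtsv(report$otu_table$samples, "otu_sample_metadata.tsv")
  dmat <- as.matrix(report$distances)
  wtsv(cbind(sample_id = rownames(dmat), as.data.frame(dmat)),
       "bray_curtis.tsv")
  wtsv(report$anosim, "anosim.tsv")
  if (!is.null(report$simper)) wtsv(report$simper, "simper_att_sus.tsv")
  p <- file.path(out, "nmds.tsv")
  con <- file(p, "w")
  writeLines(sprintf("# stress-1 = %.6f", report$nmds$stress), con)
  utils::write.table(cbind(sample_id = rownames(report$nmds$points),
                           as.data.frame(report$nmds$points)),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  files["nmds.tsv"] <- p
  if (!is.null(report$shared_richness)) {
    wtsv(report$shared_richness, "shared_richness.tsv")
  }
  snap <- report$config
  snap$chemistry <- if (is.character(snap$chemistry)) snap$chemistry else
    "<in-memory table>"
  snap$community <- if (is.character(snap$community)) snap$community else
    class(snap$community)[1]
  pj <- file.path(out, "config.json")
  jsonlite::write_json(unclass(snap), pj, auto_unbox = TRUE, null = "null",
                       digits = NA)
  files["config.json"] <- pj
  files
}

#' @export
print.run_report <- function(x, ...) {
  cat("mahomet run report\n")
  cat("  wells:", nrow(x$chemistry), "| classes:",
      paste(names(table(x$classes)), table(x$classes), collapse = ", "),
      "\n")
  cat("  energy rows:", nrow(x$energy), "| OTU table:",
      nrow(x$otu_table$counts), "x", ncol(x$otu_table$counts), "\n")
  cat("  NMDS stress:", round(x$nmds$stress, 4), "\n")
  cat("  outputs in:", x$config$outdir, "\n")
  invisible(x)
}
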