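# End-to-end orchestration: simulate (optional) -> DE -> pairing -> TF
# identification -> promoter scan -> downstream prediction -> network ->
# enrichment, with a machine-readable run manifest.

LOG_LEVELS <- c(debug = 1L, info = 2L, warn = 3L)

pipe_log <- function(config, level, ...) {
  if (LOG_LEVELS[[level]] >= LOG_LEVELS[[config$log_level]]) {
    message("[", level, "] ", ...)
  }
}

#' Pipeline configuration
#'
#' Builds and validates the configuration for [run_pipeline()]. Either the
#' synthetic generator supplies every input (`simulate = TRUE`, the
#' default, with generator settings under `sim`), or all input `paths`
#' must point to existing files.
#'
#' @param outdir output directory (created if absent).
#' @param simulate if `TRUE`, inputs are generated by
#'   [simulate_scenario()] and written under `outdir/inputs` before the
#'   analysis stages run.
#' @param sim a [sim_config()] used when `simulate = TRUE`.
#' @param paths named list of input files when `simulate = FALSE`:
#'   `mirna_expression`, `mirna_groups`, `mrna_expression`, `mrna_groups`,
#'   `interactions`, `promoters` (FASTA), `motifs` (JASPAR-style),
#'   `genesets` (GMT), `tf_catalogue` (one gene id per line).
#' @param p_de raw p-value threshold for the DE flag (strict; default
#'   0.05).
#' @param fc_threshold absolute log2 fold-change threshold (strict;
#'   default 0.5).
#' @param keep_tiers evidence tiers admitted by the pairing confidence
#'   filter.
#' @param threshold_fraction promoter-scan score threshold as a fraction
#'   of each motif's maximum score (default 0.8).
#' @param p_select raw-p selection threshold for per-TF enrichment
#'   reporting (strict; default 0.1).
#' @param fdr FDR threshold annotated on enrichment output (default 0.05).
#' @param seed integer seed forwarded to the generator.
#' @param log_level `"debug"`, `"info"` or `"warn"`.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir,
                            simulate = TRUE,
                            sim = sim_config(),
                            paths = NULL,
                            p_de = 0.05,
                            fc_threshold = 0.5,
                            keep_tiers = c("experimentally_observed", "high"),
                            threshold_fraction = 0.8,
                            p_select = 0.1,
                            fdr = 0.05,
                            seed = NULL,
                            log_level = "info") {
  if (missing(outdir) || !is.character(outdir) || length(outdir) != 1L) {
    stop_input("'outdir' must be a single path")
  }
  if (!is.null(seed)) sim$seed <- as.integer(seed)
  if (simulate) {
    if (!inherits(sim, "sim_config")) {
      sim <- do.call(sim_config, sim)
    }
    validate_sim_config(sim)
  }
  if (!is_proportion(p_de)) stop_input("'p_de' must lie in [0, 1]")
  if (!is.numeric(fc_threshold) || fc_threshold < 0) {
    stop_input("'fc_threshold' must be non-negative")
  }
  if (!all(keep_tiers %in% INTERACTION_TIERS) || !length(keep_tiers)) {
    stop_input("'keep_tiers' must be drawn from {",
               paste(INTERACTION_TIERS, collapse = ", "), "}")
  }
  if (!is.numeric(threshold_fraction) || threshold_fraction <= 0 ||
      threshold_fraction > 1) {
    stop_input("'threshold_fraction' must lie in (0, 1]")
  }
  if (!is_proportion(p_select)) stop_input("'p_select' must lie in [0, 1]")
  if (!is_proportion(fdr)) stop_input("'fdr' must lie in [0, 1]")
  if (!log_level %in% names(LOG_LEVELS)) {
    stop_input("'log_level' must be one of ",
               paste(names(LOG_LEVELS), collapse = ", "))
  }
  required_inputs <- c("mirna_expression", "mirna_groups", "mrna_expression",
                       "mrna_groups", "interactions", "promoters", "motifs",
                       "genesets", "tf_catalogue")
  if (!simulate) {
    missing_p <- setdiff(required_inputs, names(paths %||% list()))
    if (length(missing_p)) {
      stop_input("missing input path(s): ", paste(missing_p, collapse = ", "))
    }
  }
  structure(list(outdir = outdir,
                 simulate = isTRUE(simulate),
                 sim = if (simulate) sim else NULL,
                 paths = paths,
                 p_de = p_de,
                 fc_threshold = fc_threshold,
                 keep_tiers = keep_tiers,
                 threshold_fraction = threshold_fraction,
                 p_select = p_select,
                 fdr = fdr,
                 log_level = log_level),
            class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' The YAML dialect round-trips: read(write(config)) reproduces the
#' configuration.
#'
#' @param config a [pipeline_config()].
#' @param path YAML file path.
#' @return `path` invisibly (writer); a `pipeline_config` (reader).
#' @export
write_pipeline_config <- function(config, path) {
  x <- unclass(config)
  if (!is.null(x$sim)) x$sim <- unclass(x$sim)
  x$sim$tier_distribution <- as.list(x$sim$tier_distribution)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop_input("file not found: ", path)
  x <- yaml::read_yaml(path)
  if (!is.null(x$sim)) {
    x$sim$tier_distribution <- unlist(x$sim$tier_distribution)
    x$sim <- do.call(sim_config, x$sim)
  }
  do.call(pipeline_config, x)
}

read_tf_catalogue <- function(path) {
  if (!file.exists(path)) stop_input("file not found: ", path)
  ids <- readLines(path)
  ids <- ids[nzchar(trimws(ids))]
  if (!length(ids)) stop_input("TF catalogue ", path, " is empty")
  radix_sort(unique(trimws(ids)))
}

write_tf_catalogue <- function(ids, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(ids, con, sep = "\n")
  invisible(path)
}

# Write files for one stage atomically: each writer targets
# "<name>.partial"; all are renamed to their final names only after the
# whole stage succeeded, so a failed stage leaves .partial files behind.
stage_write <- function(outdir, writes) {
  partials <- character(0)
  for (w in writes) {
    final <- file.path(outdir, w$name)
    partial <- paste0(final, ".partial")
    w$fun(partial)
    partials <- c(partials, partial)
  }
  for (p in partials) file.rename(p, sub("\\.partial$", "", p))
  basename(sub("\\.partial$", "", partials))
}

run_stage <- function(config, stage, fun) {
  pipe_log(config, "info", "stage ", stage)
  tryCatch(fun(), error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full integrative pipeline
#'
#' Orchestrates simulate (optional), per-layer differential expression,
#' inverse-expression pairing with the confidence filter, TF
#' identification, promoter scanning, downstream-gene prediction,
#' tripartite network assembly, and enrichment of both the paired targets
#' and each TF's downstream set. All stage outputs are written under
#' `config$outdir`; a JSON manifest records the seed, package version,
#' input and output hashes and per-stage row counts.
#'
#' @param config a [pipeline_config()].
#' @return the run manifest (a list), invisibly. The manifest is also
#'   written to `outdir/manifest.json`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  counts <- list()
  truth <- NULL

  if (config$simulate) {
    indir <- file.path(outdir, "inputs")
    dir.create(indir, recursive = TRUE, showWarnings = FALSE)
    scen <- run_stage(config, "simulate", function() simulate_scenario(config$sim))
    run_stage(config, "simulate", function() {
      write_expression(scen$mirna, file.path(indir, "mirna_expression.tsv"),
                       file.path(indir, "mirna_groups.tsv"))
      write_expression(scen$mrna, file.path(indir, "mrna_expression.tsv"),
                       file.path(indir, "mrna_groups.tsv"))
      write_interactions(scen$interactions,
                         file.path(indir, "interactions.tsv"))
      write_promoters(scen$promoters, file.path(indir, "promoters.fa"))
      write_motifs(scen$motifs, file.path(indir, "motifs.jaspar"))
      write_gmt(scen$genesets, file.path(indir, "genesets.gmt"))
      write_tf_catalogue(scen$tf_catalogue,
                         file.path(indir, "tf_catalogue.txt"))
      write_sites_bed(scen$manifest, file.path(indir, "plant_manifest.bed"))
      write_ground_truth(scen$truth, file.path(indir, "ground_truth.json"))
    })
    truth <- scen$truth
    paths <- list(mirna_expression = file.path(indir, "mirna_expression.tsv"),
                  mirna_groups = file.path(indir, "mirna_groups.tsv"),
                  mrna_expression = file.path(indir, "mrna_expression.tsv"),
                  mrna_groups = file.path(indir, "mrna_groups.tsv"),
                  interactions = file.path(indir, "interactions.tsv"),
                  promoters = file.path(indir, "promoters.fa"),
                  motifs = file.path(indir, "motifs.jaspar"),
                  genesets = file.path(indir, "genesets.gmt"),
                  tf_catalogue = file.path(indir, "tf_catalogue.txt"))
  } else {
    paths <- config$paths
  }

  # validation-first: every input must exist before any computation
  for (nm in names(paths)) {
    if (!file.exists(paths[[nm]])) {
      stop_input("input '", nm, "' not found: ", paths[[nm]])
    }
  }
  input_hashes_before <- vapply(paths, function(p)
    unname(tools::md5sum(p)), "")

  mirna <- run_stage(config, "read_inputs", function()
    read_expression(paths$mirna_expression, paths$mirna_groups))
  mrna <- run_stage(config, "read_inputs", function()
    read_expression(paths$mrna_expression, paths$mrna_groups))
  interactions <- run_stage(config, "read_inputs", function()
    read_interactions(paths$interactions))
  promoters <- run_stage(config, "read_inputs", function()
    read_promoters(paths$promoters))
  motifs <- run_stage(config, "read_inputs", function()
    read_motifs(paths$motifs))
  genesets <- run_stage(config, "read_inputs", function()
    read_gmt(paths$genesets, universe = rownames(mrna$values)))
  catalogue <- run_stage(config, "read_inputs", function()
    read_tf_catalogue(paths$tf_catalogue))

  outputs <- character(0)

  de_mirna <- run_stage(config, "de_mirna", function()
    test_differential(mirna, config$p_de, config$fc_threshold))
  outputs <- c(outputs, stage_write(outdir, list(list(
    name = "de_mirna.tsv", fun = function(p) write_de_table(de_mirna, p)))))
  counts$de_mirnas <- sum(de_mirna$is_de)

  de_mrna <- run_stage(config, "de_mrna", function()
    test_differential(mrna, config$p_de, config$fc_threshold))
  outputs <- c(outputs, stage_write(outdir, list(list(
    name = "de_mrna.tsv", fun = function(p) write_de_table(de_mrna, p)))))
  counts$de_genes <- sum(de_mrna$is_de)

  pairs <- run_stage(config, "pairing", function()
    pair_inverse(de_mirna, de_mrna, interactions, config$keep_tiers))
  outputs <- c(outputs, stage_write(outdir, list(list(
    name = "pairings.tsv", fun = function(p) write_pairing_table(pairs, p)))))
  psum <- pairing_summary(pairs)
  counts <- c(counts, psum)

  tfs <- run_stage(config, "identify_tfs", function()
    identify_tfs(pairs, catalogue))
  counts$n_tfs <- length(tfs)

  hits <- run_stage(config, "scan_promoters", function()
    scan_promoters(promoters, motifs, config$threshold_fraction))
  hits_bed <- data.frame(gene_id = hits$gene_id, start = hits$offset,
                         end = hits$offset +
                           vapply(hits$motif_id, function(id)
                             motifs[[id]]$length, 1L),
                         tf_id = hits$tf_id, score = hits$score,
                         strand = hits$strand, stringsAsFactors = FALSE)
  outputs <- c(outputs, stage_write(outdir, list(list(
    name = "tfbs_hits.bed", fun = function(p) write_sites_bed(hits_bed, p)))))
  counts$n_tfbs_hits <- nrow(hits)

  tf_map <- run_stage(config, "predict_downstream", function() {
    m <- predict_downstream(hits, de_mrna, tfs = tfs,
                            p_threshold = config$p_de)
    m[intersect(names(m), tfs)]
  })
  counts$n_downstream_genes <- length(unique(unlist(tf_map)))

  net <- run_stage(config, "assemble_network", function()
    assemble_network(pairs, tf_map, de_mrna))
  outputs <- c(outputs, stage_write(outdir, list(
    list(name = "network.sif", fun = function(p) export_sif(net, p)),
    list(name = "network.graphml", fun = function(p) export_graphml(net, p)))))
  counts$n_network_nodes <- nrow(net$nodes)
  counts$n_network_edges <- nrow(net$edges)

  directions <- stats::setNames(de_mrna$direction, de_mrna$feature_id)
  target_enrich <- run_stage(config, "enrich_targets", function()
    fisher_enrich(unique(pairs$gene_id), genesets, directions = directions))
  outputs <- c(outputs, stage_write(outdir, list(list(
    name = "enrichment_targets.tsv",
    fun = function(p) write_enrichment_table(target_enrich, p)))))
  counts$n_enriched_target_sets <-
    sum(target_enrich$q_value < config$fdr, na.rm = TRUE)

  tf_enrich <- run_stage(config, "enrich_tf_sets", function()
    tf_geneset_enrich(tf_map, genesets, p_select = config$p_select,
                      directions = directions))
  tf_dir <- file.path(outdir, "tf_enrichment")
  dir.create(tf_dir, recursive = TRUE, showWarnings = FALSE)
  for (tf in names(tf_enrich)) {
    outputs <- c(outputs, file.path("tf_enrichment", stage_write(tf_dir, list(
      list(name = paste0(tf, ".tsv"),
           fun = function(p) write_enrichment_table(tf_enrich[[tf]], p))))))
  }
  counts$n_tf_reports <- sum(vapply(tf_enrich, nrow, 1L) > 0)

  input_hashes_after <- vapply(paths, function(p)
    unname(tools::md5sum(p)), "")
  if (!identical(input_hashes_before, input_hashes_after)) {
    stop("pipeline invariant violated: an input file was mutated",
         call. = FALSE)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("mirtfnet")),
    seed = if (config$simulate) config$sim$seed else NA_integer_,
    thresholds = list(p_de = config$p_de,
                      fc_threshold = config$fc_threshold,
                      keep_tiers = config$keep_tiers,
                      threshold_fraction = config$threshold_fraction,
                      p_select = config$p_select,
                      fdr = config$fdr),
    input_hashes = as.list(input_hashes_before),
    output_hashes = as.list(stats::setNames(
      vapply(outputs, function(o)
        unname(tools::md5sum(file.path(outdir, o))), ""), outputs)),
    stage_counts = counts,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  pipe_log(config, "info", "pipeline complete: ", counts$n_network_edges,
           " network edges")
  invisible(manifest)
}

#' Hash of a run manifest with volatile fields removed
#'
#' Two runs of the same configuration and seed are equivalent iff their
#' manifest hashes match: the hash covers seed, thresholds, input and
#' output hashes and stage counts, but not the timestamp.
#'
#' @param manifest a manifest list from [run_pipeline()] or a path to a
#'   `manifest.json`.
#' @return md5 hex string.
#' @export
manifest_hash <- function(manifest) {
  if (is.character(manifest)) {
    manifest <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  }
  manifest$timestamp <- NULL
  tmp <- tempfile()
  on.exit(unlink(tmp))
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}
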