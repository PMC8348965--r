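#' Simulation configuration for the synthetic benchmark
#'
#' Builds and validates the configuration that drives every synthetic-data
#' generator in the package. The generators plant a known tripartite
#' regulatory network -- differentially expressed (DE) miRNAs, inversely
#' expressed target genes, transcription factors (TFs) among those targets,
#' TF binding sites in promoters of DE genes, and gene sets enriched for the
#' TFs' downstream genes -- so every downstream analysis stage can be
#' benchmarked against a ground truth.
#'
#' Expression is simulated on the log2 scale: each feature gets a baseline
#' intensity (uniform on 6..12, the usual post-normalisation microarray
#' range) and i.i.d. Gaussian within-group noise of `noise_sd_log2`. Planted
#' DE features have their treated-group mean shifted by exactly
#' plus/minus `effect_size_log2` before noise, so with noise disabled the
#' group-mean difference is exact.
#'
#' @param n_mirnas,n_genes number of miRNA / mRNA features.
#' @param n_replicates_per_group samples per group (control and treated).
#' @param de_fraction_mirna,de_fraction_gene fraction of features planted as
#'   differentially expressed.
#' @param effect_size_log2 planted absolute log2 fold change.
#' @param noise_sd_log2 within-group Gaussian SD on the log2 scale.
#' @param interactions_per_de_mirna planted target genes per DE miRNA; each
#'   planted pairing links a DE miRNA to a DE gene of *opposite* direction.
#' @param decoy_interaction_fraction decoy records added to the interaction
#'   table, as a fraction of the planted record count. Decoys are typed
#'   (same-sign partner / non-DE partner / moderate evidence tier) so each
#'   pairing filter is separately falsifiable.
#' @param tier_distribution named probabilities over the evidence tiers
#'   `experimentally_observed`, `high`, `moderate`; planted records draw
#'   from the first two (renormalised), moderate is reserved for decoys.
#' @param n_tfs number of planted transcription factors (chosen among
#'   planted pairing target genes).
#' @param downstream_genes_per_tf planted binding sites (downstream genes)
#'   per TF; downstream genes are drawn from the planted DE genes.
#' @param promoter_length,motif_length promoter and motif size in bp.
#' @param background_gc background G+C proportion of promoter sequence.
#' @param n_genesets,geneset_size gene-set collection geometry.
#' @param enriched_member_fraction fraction of each planted-enriched set
#'   filled with its TF's planted downstream genes (>= 0.6 by construction).
#' @param seed integer seed; the same configuration (including seed)
#'   reproduces byte-identical artifacts.
#'
#' @return an object of class `sim_config` (a validated named list).
#' @export
sim_config <- function(n_mirnas = 120L,
                       n_genes = 500L,
                       n_replicates_per_group = 3L,
                       de_fraction_mirna = 0.2,
                       de_fraction_gene = 0.2,
                       effect_size_log2 = 1.0,
                       noise_sd_log2 = 0.25,
                       interactions_per_de_mirna = 4L,
                       decoy_interaction_fraction = 0.5,
                       tier_distribution = c(experimentally_observed = 0.3,
                                             high = 0.5,
                                             moderate = 0.2),
                       n_tfs = 3L,
                       downstream_genes_per_tf = 8L,
                       promoter_length = 1000L,
                       motif_length = 8L,
                       background_gc = 0.5,
                       n_genesets = 20L,
                       geneset_size = 10L,
                       enriched_member_fraction = 0.8,
                       seed = 1L) {
  cfg <- list(n_mirnas = as.integer(n_mirnas),
              n_genes = as.integer(n_genes),
              n_replicates_per_group = as.integer(n_replicates_per_group),
              de_fraction_mirna = de_fraction_mirna,
              de_fraction_gene = de_fraction_gene,
              effect_size_log2 = effect_size_log2,
              noise_sd_log2 = noise_sd_log2,
              interactions_per_de_mirna = as.integer(interactions_per_de_mirna),
              decoy_interaction_fraction = decoy_interaction_fraction,
              tier_distribution = tier_distribution,
              n_tfs = as.integer(n_tfs),
              downstream_genes_per_tf = as.integer(downstream_genes_per_tf),
              promoter_length = as.integer(promoter_length),
              motif_length = as.integer(motif_length),
              background_gc = background_gc,
              n_genesets = as.integer(n_genesets),
              geneset_size = as.integer(geneset_size),
              enriched_member_fraction = enriched_member_fraction,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  counts <- c("n_mirnas", "n_genes", "n_replicates_per_group",
              "interactions_per_de_mirna", "promoter_length", "motif_length",
              "n_genesets", "geneset_size")
  for (f in counts) {
    if (!is_count(cfg[[f]])) {
      stop_input("invalid configuration: '", f, "' must be a positive count")
    }
  }
  # n_tfs and downstream_genes_per_tf may be zero (no TF layer planted)
  for (f in c("n_tfs", "downstream_genes_per_tf")) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1L ||
        !is.finite(cfg[[f]]) || cfg[[f]] < 0 || cfg[[f]] != round(cfg[[f]])) {
      stop_input("invalid configuration: '", f,
                 "' must be a non-negative count")
    }
  }
  props <- c("de_fraction_mirna", "de_fraction_gene",
             "decoy_interaction_fraction", "background_gc",
             "enriched_member_fraction")
  for (f in props) {
    if (!is_proportion(cfg[[f]])) {
      stop_input("invalid configuration: '", f, "' must lie in [0, 1]")
    }
  }
  for (f in c("effect_size_log2", "noise_sd_log2")) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1L ||
        !is.finite(cfg[[f]]) || cfg[[f]] < 0) {
      stop_input("invalid configuration: '", f, "' must be non-negative")
    }
  }
  td <- cfg$tier_distribution
  if (!is.numeric(td) || length(td) != 3L ||
      !setequal(names(td), INTERACTION_TIERS)) {
    stop_input("invalid configuration: 'tier_distribution' must be named ",
               "probabilities over {", paste(INTERACTION_TIERS, collapse = ", "),
               "}")
  }
  if (any(td < 0) || abs(sum(td) - 1) > 1e-8) {
    stop_input("invalid configuration: 'tier_distribution' must be ",
               "non-negative and sum to 1")
  }
  if (cfg$motif_length > cfg$promoter_length) {
    stop_input("invalid configuration: 'motif_length' exceeds ",
               "'promoter_length'")
  }
  if (cfg$geneset_size > cfg$n_genes) {
    stop_input("invalid configuration: 'geneset_size' exceeds the gene ",
               "universe ('n_genes')")
  }
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1L || is.na(cfg$seed)) {
    stop_input("invalid configuration: 'seed' must be a single integer")
  }
  invisible(cfg)
}

#' Simulate a two-group log2 expression matrix with planted DE features
#'
#' @param config a [sim_config()].
#' @param layer `"mirna"` or `"mrna"`; controls feature count, identifiers
#'   and the planted DE fraction.
#' @return a list with `matrix` (an [expression_matrix()]) and `planted`, a
#'   data.frame of planted feature ids and directions (`up`/`down`).
#' @export
simulate_expression <- function(config, layer = c("mirna", "mrna")) {
  validate_sim_config(config)
  layer <- match.arg(layer)
  n <- if (layer == "mirna") config$n_mirnas else config$n_genes
  de_frac <- if (layer == "mirna") config$de_fraction_mirna else config$de_fraction_gene
  ids <- if (layer == "mirna") {
    sprintf("miR-s%04d", seq_len(n))
  } else {
    sprintf("GENE%04d", seq_len(n))
  }
  nrep <- config$n_replicates_per_group
  samples <- c(sprintf("ctrl_%d", seq_len(nrep)), sprintf("trt_%d", seq_len(nrep)))
  group <- stats::setNames(rep(c("control", "treated"), each = nrep), samples)

  seed_offset <- if (layer == "mirna") 101L else 202L
  res <- with_seed(config$seed + seed_offset, {
    n_de <- round(de_frac * n)
    planted_idx <- if (n_de > 0) sort(sample.int(n, n_de)) else integer(0)
    direction <- if (n_de > 0) {
      sample(c("up", "down"), n_de, replace = TRUE)
    } else {
      character(0)
    }
    baseline <- stats::runif(n, 6, 12)
    shift <- numeric(n)
    shift[planted_idx] <- ifelse(direction == "up", 1, -1) * config$effect_size_log2
    mu <- cbind(matrix(baseline, n, nrep),
                matrix(baseline + shift, n, nrep))
    noise <- matrix(stats::rnorm(n * 2L * nrep, sd = config$noise_sd_log2),
                    n, 2L * nrep)
    values <- mu + noise
    dimnames(values) <- list(ids, samples)
    list(values = values,
         planted = data.frame(feature_id = ids[planted_idx],
                              direction = direction,
                              stringsAsFactors = FALSE))
  })
  list(matrix = expression_matrix(res$values, group), planted = res$planted)
}

#' Simulate a miRNA-target interaction table with typed decoys
#'
#' Planted pairings link each planted DE miRNA to
#' `interactions_per_de_mirna` planted DE genes of the opposite direction,
#' with evidence tier drawn from {experimentally_observed, high}. Decoy
#' records are added per `decoy_interaction_fraction`, cycling through three
#' explicit types: `same_sign` (DE partner of the same direction, high
#' tier), `non_de_partner` (partner gene not planted DE, high tier), and
#' `moderate_tier` (opposite-direction DE pair carried only at the moderate
#' tier). Each decoy type falsifies exactly one pairing filter.
#'
#' @param config a [sim_config()].
#' @param truth a partial ground truth holding `planted_de_mirnas` and
#'   `planted_de_genes` data.frames (from [simulate_expression()]).
#' @return list with `interactions` (data.frame: mirna_id, gene_id, tier,
#'   source) and `truth` updated with `planted_pairings` and `decoys`.
#' @export
simulate_interactions <- function(config, truth) {
  validate_sim_config(config)
  de_mir <- truth$planted_de_mirnas
  de_gene <- truth$planted_de_genes
  sources <- c("sim_pred_db_A", "sim_pred_db_B", "sim_curated_db")

  with_seed(config$seed + 303L, {
    if (nrow(de_mir) == 0L) {
      warning("no planted DE miRNAs: interaction table contains decoys only",
              call. = FALSE)
      n_decoys <- round(config$decoy_interaction_fraction *
                          config$interactions_per_de_mirna)
      all_mir <- sprintf("miR-s%04d", seq_len(config$n_mirnas))
      all_gene <- sprintf("GENE%04d", seq_len(config$n_genes))
      decoys <- data.frame(mirna_id = sample(all_mir, n_decoys, replace = TRUE),
                           gene_id = sample(all_gene, n_decoys, replace = TRUE),
                           decoy_type = rep("moderate_tier", n_decoys),
                           stringsAsFactors = FALSE)
      decoys <- unique(decoys)
      inter <- data.frame(mirna_id = decoys$mirna_id,
                          gene_id = decoys$gene_id,
                          tier = rep("moderate", nrow(decoys)),
                          source = if (nrow(decoys)) sample(sources, nrow(decoys), replace = TRUE) else character(0),
                          stringsAsFactors = FALSE)
      truth$planted_pairings <- data.frame(mirna_id = character(0),
                                           gene_id = character(0),
                                           stringsAsFactors = FALSE)
      truth$decoys <- decoys
      return(list(interactions = inter, truth = truth))
    }

    opp <- c(up = "down", down = "up")
    planted <- do.call(rbind, lapply(seq_len(nrow(de_mir)), function(i) {
      want <- opp[[de_mir$direction[i]]]
      pool <- de_gene$gene_id[de_gene$direction == want]
      k <- min(config$interactions_per_de_mirna, length(pool))
      if (k == 0L) return(NULL)
      data.frame(mirna_id = de_mir$feature_id[i],
                 gene_id = sample(pool, k),
                 stringsAsFactors = FALSE)
    }))
    if (is.null(planted)) {
      planted <- data.frame(mirna_id = character(0), gene_id = character(0),
                            stringsAsFactors = FALSE)
    }
    td <- config$tier_distribution[c("experimentally_observed", "high")]
    td <- td / sum(td)
    planted_tier <- sample(names(td), nrow(planted), replace = TRUE, prob = td)

    n_decoys <- round(config$decoy_interaction_fraction * nrow(planted))
    decoy_types <- rep(c("same_sign", "non_de_partner", "moderate_tier"),
                       length.out = n_decoys)
    non_de_genes <- setdiff(sprintf("GENE%04d", seq_len(config$n_genes)),
                            de_gene$gene_id)
    pair_key <- paste(planted$mirna_id, planted$gene_id)
    decoys <- data.frame(mirna_id = character(0), gene_id = character(0),
                         decoy_type = character(0), stringsAsFactors = FALSE)
    for (ty in decoy_types) {
      for (attempt in 1:100) {
        i <- sample.int(nrow(de_mir), 1L)
        m <- de_mir$feature_id[i]
        dir_m <- de_mir$direction[i]
        g <- switch(ty,
          same_sign = {
            pool <- de_gene$gene_id[de_gene$direction == dir_m]
            if (!length(pool)) NA_character_ else sample(pool, 1L)
          },
          non_de_partner = {
            if (!length(non_de_genes)) NA_character_ else sample(non_de_genes, 1L)
          },
          moderate_tier = {
            pool <- setdiff(de_gene$gene_id[de_gene$direction == opp[[dir_m]]],
                            planted$gene_id[planted$mirna_id == m])
            if (!length(pool)) NA_character_ else sample(pool, 1L)
          })
        if (is.na(g)) next
        key <- paste(m, g)
        if (key %in% pair_key || key %in% paste(decoys$mirna_id, decoys$gene_id)) next
        decoys <- rbind(decoys, data.frame(mirna_id = m, gene_id = g,
                                           decoy_type = ty,
                                           stringsAsFactors = FALSE))
        break
      }
    }
    decoy_tier <- ifelse(decoys$decoy_type == "moderate_tier", "moderate", "high")
    inter <- rbind(
      data.frame(mirna_id = planted$mirna_id, gene_id = planted$gene_id,
                 tier = planted_tier,
                 source = sample(sources, nrow(planted), replace = TRUE),
                 stringsAsFactors = FALSE),
      data.frame(mirna_id = decoys$mirna_id, gene_id = decoys$gene_id,
                 tier = decoy_tier,
                 source = if (nrow(decoys)) sample(sources, nrow(decoys), replace = TRUE) else character(0),
                 stringsAsFactors = FALSE))
    rownames(inter) <- NULL
    truth$planted_pairings <- planted
    truth$decoys <- decoys
    list(interactions = inter, truth = truth)
  })
}

random_dna <- function(n, gc) {
  prob <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(DNA_BASES, n, replace = TRUE, prob = prob), collapse = "")
}

#' Simulate promoter sequences with planted TF binding sites and motifs
#'
#' Picks `n_tfs` transcription factors among the planted pairing targets,
#' assigns each a unique information-rich consensus (per-position
#' probability 0.94 for the consensus base), and writes that consensus (or
#' its reverse complement for minus-strand plants) into the promoters of
#' `downstream_genes_per_tf` planted DE genes at recorded offsets. All other
#' promoter sequence is i.i.d. background at `background_gc`.
#'
#' @param config a [sim_config()].
#' @param truth ground truth carrying `planted_pairings` and
#'   `planted_de_genes`.
#' @return list with `promoters` (named character vector, one entry per
#'   gene), `motifs` (list of [motif_matrix()]), `manifest` (BED-like
#'   data.frame: gene_id, start, end, tf_id, strand; 0-based half-open) and
#'   the updated `truth` (`planted_tfs`, `planted_tfbs`, `tf_downstream`).
#' @export
simulate_promoters <- function(config, truth) {
  validate_sim_config(config)
  genes <- sprintf("GENE%04d", seq_len(config$n_genes))
  L <- config$motif_length
  P <- config$promoter_length

  with_seed(config$seed + 404L, {
    promoters <- stats::setNames(
      vapply(genes, function(g) random_dna(P, config$background_gc), ""),
      genes)

    target_pool <- unique(truth$planted_pairings$gene_id)
    n_tfs <- min(config$n_tfs, length(target_pool))
    if (n_tfs < config$n_tfs) {
      warning("fewer pairing targets than requested TFs; planting ", n_tfs,
              " TFs", call. = FALSE)
    }
    # a TF is a gene: its node id in the network is its gene id; the
    # "TF0001"-style id is the motif accession only
    tfs <- if (n_tfs > 0) radix_sort(sample(target_pool, n_tfs)) else character(0)
    motif_ids <- sprintf("TF%04d", seq_along(tfs))

    # unique consensus per TF, not equal (or revcomp-equal) to another's
    consensi <- character(0)
    for (i in seq_along(tfs)) {
      repeat {
        cons <- paste(sample(DNA_BASES, L, replace = TRUE), collapse = "")
        if (!(cons %in% consensi) && !(revcomp_chr(cons) %in% consensi)) break
      }
      consensi <- c(consensi, cons)
    }

    motifs <- lapply(seq_along(tfs), function(i) {
      cons <- strsplit(consensi[i], "", fixed = TRUE)[[1L]]
      m <- matrix(2, nrow = 4, ncol = L, dimnames = list(DNA_BASES, NULL))
      m[cbind(match(cons, DNA_BASES), seq_len(L))] <- 94
      motif_matrix(m, motif_id = motif_ids[i], tf_id = tfs[i])
    })
    names(motifs) <- motif_ids

    de_genes <- truth$planted_de_genes$gene_id
    tfbs <- data.frame(tf_id = character(0), gene_id = character(0),
                       offset = integer(0), strand = character(0),
                       stringsAsFactors = FALSE)
    occupied <- list()  # per-gene planted intervals, to avoid overlaps
    for (i in seq_along(tfs)) {
      pool <- setdiff(de_genes, tfs[i])  # no TF regulating its own gene
      k <- min(config$downstream_genes_per_tf, length(pool))
      if (k == 0L) next
      targets <- sample(pool, k)
      for (g in targets) {
        for (attempt in 1:200) {
          off <- sample.int(P - L + 1L, 1L) - 1L
          ivs <- occupied[[g]]
          clash <- !is.null(ivs) &&
            any(off < ivs[, 2L] & off + L > ivs[, 1L])
          if (!clash) break
        }
        occupied[[g]] <- rbind(occupied[[g]], c(off, off + L))
        strand <- sample(c("+", "-"), 1L)
        site <- if (strand == "+") consensi[i] else revcomp_chr(consensi[i])
        substr(promoters[[g]], off + 1L, off + L) <- site
        tfbs <- rbind(tfbs, data.frame(tf_id = tfs[i], gene_id = g,
                                       offset = off, strand = strand,
                                       stringsAsFactors = FALSE))
      }
    }
    manifest <- data.frame(gene_id = tfbs$gene_id, start = tfbs$offset,
                           end = tfbs$offset + L, tf_id = tfbs$tf_id,
                           strand = tfbs$strand, stringsAsFactors = FALSE)
    truth$planted_tfs <- tfs
    truth$tf_motif_of <- stats::setNames(motif_ids, tfs)
    truth$planted_tfbs <- tfbs
    truth$tf_downstream <- lapply(split(tfbs$gene_id, tfbs$tf_id), unique)
    list(promoters = promoters, motifs = motifs, manifest = manifest,
         truth = truth)
  })
}

#' Simulate a gene-set collection with sets enriched for TF downstream genes
#'
#' One set per planted TF is constructed to contain
#' `enriched_member_fraction` of its members from that TF's planted
#' downstream genes; all remaining sets are uniform draws from the gene
#' universe.
#'
#' @param config a [sim_config()].
#' @param truth ground truth carrying `tf_downstream`.
#' @return list with `genesets` (a [geneset_collection()]) and `truth`
#'   updated with `planted_enriched_sets` (data.frame set_id, tf_id).
#' @export
simulate_genesets <- function(config, truth) {
  validate_sim_config(config)
  universe <- sprintf("GENE%04d", seq_len(config$n_genes))
  if (config$geneset_size > length(universe)) {
    stop_input("invalid configuration: 'geneset_size' exceeds the gene universe")
  }
  with_seed(config$seed + 505L, {
    tf_down <- truth$tf_downstream %||% list()
    tf_down <- tf_down[lengths(tf_down) > 0]
    n_enriched <- min(length(tf_down), config$n_genesets)
    set_ids <- sprintf("SET%04d", seq_len(config$n_genesets))
    sets <- vector("list", config$n_genesets)
    names(sets) <- set_ids
    planted_sets <- data.frame(set_id = character(0), tf_id = character(0),
                               stringsAsFactors = FALSE)
    for (i in seq_len(config$n_genesets)) {
      if (i <= n_enriched) {
        tf <- names(tf_down)[i]
        down <- tf_down[[tf]]
        k <- min(ceiling(config$enriched_member_fraction * config$geneset_size),
                 length(down))
        core <- sample(down, k)
        filler <- sample(setdiff(universe, core), config$geneset_size - k)
        sets[[i]] <- radix_sort(c(core, filler))
        planted_sets <- rbind(planted_sets,
                              data.frame(set_id = set_ids[i], tf_id = tf,
                                         stringsAsFactors = FALSE))
      } else {
        sets[[i]] <- radix_sort(sample(universe, config$geneset_size))
      }
    }
    desc <- stats::setNames(
      ifelse(set_ids %in% planted_sets$set_id,
             "synthetic set enriched for planted TF downstream genes",
             "synthetic background set"),
      set_ids)
    truth$planted_enriched_sets <- planted_sets
    list(genesets = geneset_collection(sets, descriptions = desc,
                                       universe = universe),
         truth = truth)
  })
}

#' Simulate a complete pipeline scenario with planted ground truth
#'
#' Runs every generator in sequence and returns all pipeline inputs plus the
#' ground truth: expression matrices for both layers, the interaction
#' database, promoters, motifs, the TFBS plant manifest, the gene-set
#' collection and a TF catalogue (planted TF gene ids plus decoy catalogue
#' entries that are not pairing targets).
#'
#' @param config a [sim_config()].
#' @return a list of class `sim_scenario`.
#' @export
simulate_scenario <- function(config = sim_config()) {
  validate_sim_config(config)
  mirna <- simulate_expression(config, "mirna")
  mrna <- simulate_expression(config, "mrna")
  planted_genes <- mrna$planted
  names(planted_genes)[names(planted_genes) == "feature_id"] <- "gene_id"
  truth <- list(planted_de_mirnas = mirna$planted,
                planted_de_genes = planted_genes,
                seed = config$seed)
  inter <- simulate_interactions(config, truth)
  truth <- inter$truth
  prom <- simulate_promoters(config, truth)
  truth <- prom$truth
  gs <- simulate_genesets(config, truth)
  truth <- gs$truth

  catalogue <- with_seed(config$seed + 606L, {
    non_targets <- setdiff(sprintf("GENE%04d", seq_len(config$n_genes)),
                           unique(inter$interactions$gene_id))
    decoy_tf_genes <- sample(non_targets, min(10L, length(non_targets)))
    radix_sort(unique(c(truth$planted_tfs, decoy_tf_genes)))
  })

  truth <- structure(truth, class = "ground_truth")
  validate_ground_truth(truth, config)
  structure(list(config = config,
                 mirna = mirna$matrix,
                 mrna = mrna$matrix,
                 interactions = inter$interactions,
                 promoters = prom$promoters,
                 motifs = prom$motifs,
                 manifest = prom$manifest,
                 genesets = gs$genesets,
                 tf_catalogue = catalogue,
                 truth = truth),
            class = "sim_scenario")
}

#' Validate ground-truth invariants
#'
#' Checks that every planted pairing links features of opposite planted
#' directions and that every planted binding site lies within its promoter.
#'
#' @param truth a `ground_truth` object.
#' @param config the [sim_config()] that produced it.
#' @return `truth`, invisibly; errors if an invariant is violated.
#' @export
validate_ground_truth <- function(truth, config) {
  pp <- truth$planted_pairings
  if (nrow(pp)) {
    dm <- stats::setNames(truth$planted_de_mirnas$direction,
                          truth$planted_de_mirnas$feature_id)
    dg <- stats::setNames(truth$planted_de_genes$direction,
                          truth$planted_de_genes$gene_id %||%
                            truth$planted_de_genes$feature_id)
    if (any(dm[pp$mirna_id] == dg[pp$gene_id])) {
      stop("ground-truth invariant violated: a planted pairing has ",
           "same-direction partners", call. = FALSE)
    }
  }
  tfbs <- truth$planted_tfbs
  if (!is.null(tfbs) && nrow(tfbs)) {
    if (any(tfbs$offset < 0 |
            tfbs$offset + config$motif_length > config$promoter_length)) {
      stop("ground-truth invariant violated: a planted TFBS lies outside ",
           "its promoter", call. = FALSE)
    }
  }
  invisible(truth)
}

#' Planted network edges implied by a ground truth
#'
#' The reference edge set for benchmarking: one `targets` edge per planted
#' miRNA-gene pairing and one `regulates` edge per planted TF binding site
#' (TF gene id -> downstream gene id).
#'
#' @param truth a `ground_truth` object.
#' @return data.frame with columns `from`, `to`, `type`.
#' @export
truth_edges <- function(truth) {
  pp <- truth$planted_pairings
  e1 <- data.frame(from = pp$mirna_id, to = pp$gene_id,
                   type = rep("targets", nrow(pp)), stringsAsFactors = FALSE)
  tfbs <- truth$planted_tfbs
  if (is.null(tfbs) || !nrow(tfbs)) return(e1)
  e2 <- data.frame(from = tfbs$tf_id, to = tfbs$gene_id,
                   type = rep("regulates", nrow(tfbs)),
                   stringsAsFactors = FALSE)
  unique(rbind(e1, e2))
}
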