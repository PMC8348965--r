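test_that("config validation names the offending field", {
  expect_error(sim_config(n_genes = 0), "n_genes")
  expect_error(sim_config(de_fraction_mirna = 1.2), "de_fraction_mirna")
  expect_error(sim_config(background_gc = -0.1), "background_gc")
  expect_error(sim_config(tier_distribution = c(a = 1)), "tier_distribution")
  expect_error(sim_config(tier_distribution = c(experimentally_observed = 0.5,
                                                high = 0.4, moderate = 0.3)),
               "tier_distribution")
  expect_error(sim_config(motif_length = 50, promoter_length = 20),
               "motif_length")
})

test_that("noiseless planted features have exact group-mean differences", {
  cfg <- sim_config(n_mirnas = 40, noise_sd_log2 = 0, effect_size_log2 = 1,
                    de_fraction_mirna = 0.25, seed = 3)
  res <- simulate_expression(cfg, "mirna")
  x <- res$matrix
  diff <- rowMeans(x$values[, x$group == "treated"]) -
    rowMeans(x$values[, x$group == "control"])
  planted <- res$planted
  expect_equal(nrow(planted), 10)
  signs <- ifelse(planted$direction == "up", 1, -1)
  expect_equal(unname(diff[planted$feature_id]), signs * 1.0)
  expect_equal(unname(diff[setdiff(names(diff), planted$feature_id)]),
               rep(0, 30))
})

test_that("zero DE fraction plants nothing", {
  cfg <- sim_config(de_fraction_gene = 0, seed = 5)
  res <- simulate_expression(cfg, "mrna")
  expect_equal(nrow(res$planted), 0)
})

test_that("the same seed reproduces identical artifacts", {
  cfg <- sim_config(seed = 7)
  a <- simulate_scenario(cfg)
  b <- simulate_scenario(cfg)
  expect_identical(a$mirna$values, b$mirna$values)
  expect_identical(a$interactions, b$interactions)
  expect_identical(a$promoters, b$promoters)
  expect_identical(lapply(a$motifs, `[[`, "probs"),
                   lapply(b$motifs, `[[`, "probs"))
  expect_identical(a$genesets$sets, b$genesets$sets)
  expect_identical(a$truth$planted_pairings, b$truth$planted_pairings)
})

test_that("interaction generator arithmetic: planted plus decoy fraction", {
  # 5 DE miRNAs x 2 interactions = 10 planted; 50% decoys -> 15 records
  cfg <- sim_config(n_mirnas = 25, n_genes = 80, de_fraction_mirna = 0.2,
                    de_fraction_gene = 0.5, interactions_per_de_mirna = 2,
                    decoy_interaction_fraction = 0.5, seed = 11)
  scen <- simulate_scenario(cfg)
  expect_equal(nrow(scen$truth$planted_de_mirnas), 5)
  expect_equal(nrow(scen$truth$planted_pairings), 10)
  expect_equal(nrow(scen$interactions), 15)
  # planted records never carry the moderate tier
  planted_keys <- paste(scen$truth$planted_pairings$mirna_id,
                        scen$truth$planted_pairings$gene_id)
  rec_keys <- paste(scen$interactions$mirna_id, scen$interactions$gene_id)
  expect_true(all(scen$interactions$tier[rec_keys %in% planted_keys] %in%
                    c("experimentally_observed", "high")))
  # no duplicate (mirna, gene, source) triples
  expect_false(anyDuplicated(scen$interactions[, c("mirna_id", "gene_id",
                                                   "source")]) > 0)
})

test_that("zero decoy fraction yields planted records only", {
  cfg <- sim_config(n_mirnas = 25, n_genes = 80, de_fraction_mirna = 0.2,
                    de_fraction_gene = 0.5, interactions_per_de_mirna = 2,
                    decoy_interaction_fraction = 0, seed = 11)
  scen <- simulate_scenario(cfg)
  keys <- paste(scen$interactions$mirna_id, scen$interactions$gene_id)
  planted <- paste(scen$truth$planted_pairings$mirna_id,
                   scen$truth$planted_pairings$gene_id)
  expect_setequal(keys, planted)
})

test_that("every planted pairing has opposite planted directions", {
  for (s in 1:5) {
    scen <- simulate_scenario(sim_config(seed = s))
    dm <- setNames(scen$truth$planted_de_mirnas$direction,
                   scen$truth$planted_de_mirnas$feature_id)
    dg <- setNames(scen$truth$planted_de_genes$direction,
                   scen$truth$planted_de_genes$gene_id)
    pp <- scen$truth$planted_pairings
    expect_true(all(dm[pp$mirna_id] != dg[pp$gene_id]))
  }
})

test_that("planted binding sites appear verbatim in promoters", {
  scen <- simulate_scenario(sim_config(seed = 13))
  tfbs <- scen$truth$planted_tfbs
  expect_gt(nrow(tfbs), 0)
  L <- scen$config$motif_length
  consensus_of <- setNames(
    vapply(scen$motifs, `[[`, "", "consensus"),
    vapply(scen$motifs, `[[`, "", "tf_id"))
  for (i in seq_len(nrow(tfbs))) {
    window <- substr(scen$promoters[[tfbs$gene_id[i]]],
                     tfbs$offset[i] + 1L, tfbs$offset[i] + L)
    expected <- consensus_of[[tfbs$tf_id[i]]]
    if (tfbs$strand[i] == "-") {
      expected <- mirtfnet:::revcomp_chr(expected)
    }
    expect_identical(window, expected)
  }
  # offsets lie within promoter bounds
  expect_true(all(tfbs$offset >= 0 &
                    tfbs$offset + L <= scen$config$promoter_length))
})

test_that("planted enriched sets are dominated by TF downstream genes", {
  scen <- simulate_scenario(sim_config(seed = 17))
  ps <- scen$truth$planted_enriched_sets
  expect_gt(nrow(ps), 0)
  for (i in seq_len(nrow(ps))) {
    members <- scen$genesets$sets[[ps$set_id[i]]]
    down <- scen$truth$tf_downstream[[ps$tf_id[i]]]
    expect_gte(length(intersect(members, down)) / length(members), 0.6)
  }
})

test_that("background-only promoters yield no consensus-threshold hits", {
  cfg <- sim_config(n_mirnas = 10, n_genes = 20, de_fraction_mirna = 0,
                    de_fraction_gene = 0, seed = 19)
  scen <- suppressWarnings(simulate_scenario(cfg))
  expect_equal(length(scen$truth$planted_tfs), 0)
  motif <- random_motif(10, seed = 19)
  hits <- scan_promoters(scen$promoters, list(motif),
                         threshold_fraction = 1.0)
  expect_equal(nrow(hits), 0)
})
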