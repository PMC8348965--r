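# Evidence tiers in decreasing strength; the pairing filter keeps pairs
# whose best tier is experimentally_observed or high and discards
# moderate-only pairs.
INTERACTION_TIERS <- c("experimentally_observed", "high", "moderate")
TIER_RANK <- c(experimentally_observed = 3L, high = 2L, moderate = 1L)

#' Join DE miRNAs to inversely expressed DE targets
#'
#' Implements the integrative pairing step: a miRNA-gene pair is retained
#' iff (a) the miRNA is differentially expressed, (b) the gene is
#' differentially expressed, (c) an interaction record links them, (d)
#' their directions are opposite (the inverse-expression constraint: an
#' upregulated miRNA must pair with a downregulated target and vice versa),
#' and (e) the pair's best evidence tier is `experimentally_observed` or
#' `high` -- pairs supported only at the `moderate` tier are discarded.
#' Records for the same pair from multiple source databases are merged,
#' keeping the best tier and the union of sources.
#'
#' Directions always come from the DE tables; interaction databases carry
#' no sign.
#'
#' @param de_mirna,de_mrna `de_table`s from [test_differential()].
#' @param db data.frame of interaction records with columns `mirna_id`,
#'   `gene_id`, `tier`, `source`.
#' @param keep_tiers tiers admitted by the confidence filter.
#' @return a `pairing_table` data.frame with columns `mirna_id`,
#'   `mirna_log2fc`, `mirna_direction`, `gene_id`, `gene_log2fc`,
#'   `gene_direction`, `tier` (best), `sources` (semicolon-joined).
#' @export
pair_inverse <- function(de_mirna, de_mrna, db,
                         keep_tiers = c("experimentally_observed", "high")) {
  for (col in c("mirna_id", "gene_id", "tier", "source")) {
    if (!col %in% names(db)) {
      stop_input("interaction table lacks column '", col, "'")
    }
  }
  if (!all(keep_tiers %in% INTERACTION_TIERS)) {
    stop_input("unknown tier in 'keep_tiers'")
  }
  bad <- which(!db$tier %in% INTERACTION_TIERS)
  if (length(bad)) {
    stop_input("unknown evidence tier '", db$tier[bad[1L]],
               "' in interaction record ", bad[1L])
  }
  if (nrow(db) == 0L) stop_input("interaction table is empty")

  # dedup to one row per (mirna, gene): best tier, merged sources
  key <- paste(db$mirna_id, db$gene_id, sep = "\r")
  best <- tapply(TIER_RANK[db$tier], key, max)
  srcs <- tapply(db$source, key, function(s)
    paste(radix_sort(unique(s)), collapse = ";"))
  keys <- radix_sort(names(best))
  parts <- strsplit(keys, "\r", fixed = TRUE)
  pairs <- data.frame(mirna_id = vapply(parts, `[`, "", 1L),
                      gene_id = vapply(parts, `[`, "", 2L),
                      tier = names(TIER_RANK)[match(best[keys], TIER_RANK)],
                      sources = unname(srcs[keys]),
                      stringsAsFactors = FALSE)

  mi <- match(pairs$mirna_id, de_mirna$feature_id)
  gi <- match(pairs$gene_id, de_mrna$feature_id)
  keep <- !is.na(mi) & !is.na(gi) &
    de_mirna$is_de[mi] & de_mrna$is_de[gi] &
    de_mirna$direction[mi] != de_mrna$direction[gi] &
    pairs$tier %in% keep_tiers
  keep[is.na(keep)] <- FALSE

  out <- data.frame(mirna_id = pairs$mirna_id[keep],
                    mirna_log2fc = de_mirna$log2fc[mi[keep]],
                    mirna_direction = de_mirna$direction[mi[keep]],
                    gene_id = pairs$gene_id[keep],
                    gene_log2fc = de_mrna$log2fc[gi[keep]],
                    gene_direction = de_mrna$direction[gi[keep]],
                    tier = pairs$tier[keep],
                    sources = pairs$sources[keep],
                    stringsAsFactors = FALSE)
  out <- out[radix_order(out$mirna_id, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("pairing_table", "data.frame"))
}

#' Summarise a pairing table
#'
#' Counts pairs, distinct miRNAs and targets, and the up/down strata:
#' upregulated miRNAs with their (downregulated) targets and vice versa.
#' When every target gene is hit by miRNAs of a single direction the two
#' target strata sum to the distinct target count; targets hit from both
#' strata are surfaced explicitly in `n_targets_overlap`.
#'
#' @param table a `pairing_table`.
#' @return named list of counts: `n_pairs`, `n_mirnas`, `n_targets`,
#'   `n_up_mirnas`, `n_down_mirnas`, `n_targets_of_up`,
#'   `n_targets_of_down`, `n_targets_overlap`.
#' @export
pairing_summary <- function(table) {
  up_m <- unique(table$mirna_id[table$mirna_direction == "up"])
  down_m <- unique(table$mirna_id[table$mirna_direction == "down"])
  tgt_up <- unique(table$gene_id[table$mirna_direction == "up"])
  tgt_down <- unique(table$gene_id[table$mirna_direction == "down"])
  list(n_pairs = nrow(table),
       n_mirnas = length(unique(table$mirna_id)),
       n_targets = length(unique(table$gene_id)),
       n_up_mirnas = length(up_m),
       n_down_mirnas = length(down_m),
       n_targets_of_up = length(tgt_up),
       n_targets_of_down = length(tgt_down),
       n_targets_overlap = length(intersect(tgt_up, tgt_down)))
}

#' Top targets per miRNA by absolute fold change
#'
#' For each miRNA, the `k` targets with the largest absolute gene log2 fold
#' change (ties broken by gene id), for top-N reporting.
#'
#' @param table a `pairing_table`.
#' @param k targets per miRNA.
#' @return data.frame subset of `table` with an added `rank` column.
#' @export
top_targets_per_mirna <- function(table, k = 5L) {
  if (!is_count(k)) stop_input("'k' must be a positive count")
  ord <- radix_order(table$mirna_id, -abs(table$gene_log2fc), table$gene_id)
  tab <- table[ord, , drop = FALSE]
  rank <- stats::ave(seq_len(nrow(tab)), tab$mirna_id, FUN = seq_along)
  out <- tab[rank <= k, , drop = FALSE]
  out$rank <- rank[rank <= k]
  rownames(out) <- NULL
  out
}
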