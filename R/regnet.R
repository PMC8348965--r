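#' Identify transcription factors among paired targets
#'
#' Intersects the target genes of a pairing table with a transcription
#' factor catalogue (a set of gene identifiers). The returned TFs keep
#' their DE direction and upstream miRNAs through the pairing table.
#'
#' @param pairs a `pairing_table` from [pair_inverse()].
#' @param tf_catalogue character vector of TF gene ids.
#' @return sorted character vector of TF gene ids found among the targets.
#' @export
identify_tfs <- function(pairs, tf_catalogue) {
  if (!length(tf_catalogue)) stop_input("'tf_catalogue' is empty")
  radix_sort(intersect(unique(pairs$gene_id), tf_catalogue))
}

#' Downstream gene sets per transcription factor
#'
#' Maps each TF to the distinct genes whose promoter carries at least one
#' binding-site hit for that TF and that are differentially expressed at
#' raw p < `p_threshold` (no fold-change cut at this stage). A gene may be
#' shared across TFs, and a TF may regulate another TF's gene. TFs without
#' any qualifying downstream gene map to an empty set and are retained.
#'
#' @param hits data.frame of scan hits ([scan_promoters()]), keyed by
#'   `tf_id` and `gene_id`.
#' @param de_genes a `de_table` for the mRNA layer.
#' @param tfs character vector of TF gene ids to report (orphans included);
#'   defaults to the TFs present in `hits`.
#' @param p_threshold raw p-value cut for a downstream gene (strict).
#' @return named list: TF gene id -> sorted character vector of gene ids.
#' @export
predict_downstream <- function(hits, de_genes, tfs = NULL,
                               p_threshold = 0.05) {
  if (is.null(tfs)) tfs <- radix_sort(unique(hits$tf_id))
  p_of <- stats::setNames(de_genes$p_value, de_genes$feature_id)
  out <- lapply(tfs, function(tf) {
    g <- unique(hits$gene_id[hits$tf_id == tf])
    g <- g[g != tf]  # no self-regulation loops in the network
    pg <- p_of[g]
    radix_sort(g[!is.na(pg) & pg < p_threshold])
  })
  stats::setNames(out, tfs)
}

#' Assemble the tripartite miRNA - TF - downstream gene network
#'
#' Builds the typed regulatory network: `targets` edges from every retained
#' miRNA-target pairing (target nodes typed `tf` when in the TF map, else
#' `gene`), and `regulates` edges from each TF to its predicted downstream
#' genes. Node attributes carry the DE direction and log2 fold change;
#' TF-to-gene edges carry no activation/repression sign (TFs can act as
#' either). Self-loops across layers are excluded by construction.
#'
#' @param pairs a `pairing_table`.
#' @param tf_map named list TF gene id -> downstream gene ids, from
#'   [predict_downstream()]; every TF must appear among the pairing
#'   targets.
#' @param de_genes a `de_table` for the mRNA layer (node attributes for
#'   genes and TFs).
#' @return an object of class `tripartite_network`: list with `nodes`
#'   (data.frame id, type, direction, log2fc) and `edges` (data.frame
#'   from, to, type).
#' @export
assemble_network <- function(pairs, tf_map, de_genes) {
  tfs <- names(tf_map) %||% character(0)
  missing <- setdiff(tfs, pairs$gene_id)
  if (length(missing)) {
    stop_input("TF(s) absent from pairing targets: ",
               paste(missing, collapse = ", "))
  }
  down <- if (length(tf_map)) {
    data.frame(from = rep(tfs, lengths(tf_map)),
               to = unlist(tf_map, use.names = FALSE),
               type = "regulates", stringsAsFactors = FALSE)
  } else {
    data.frame(from = character(0), to = character(0), type = character(0),
               stringsAsFactors = FALSE)
  }
  down <- down[down$from != down$to, , drop = FALSE]
  edges <- rbind(data.frame(from = pairs$mirna_id, to = pairs$gene_id,
                            type = rep("targets", nrow(pairs)),
                            stringsAsFactors = FALSE),
                 down)
  edges <- unique(edges)
  edges <- edges[radix_order(edges$type, edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL

  mirna_ids <- unique(pairs$mirna_id)
  gene_ids <- radix_sort(unique(c(pairs$gene_id, down$to)))
  gdir <- stats::setNames(de_genes$direction, de_genes$feature_id)
  gfc <- stats::setNames(de_genes$log2fc, de_genes$feature_id)
  mdir <- stats::setNames(pairs$mirna_direction, pairs$mirna_id)
  mfc <- stats::setNames(pairs$mirna_log2fc, pairs$mirna_id)

  nodes <- rbind(
    data.frame(id = radix_sort(mirna_ids),
               type = "mirna",
               direction = unname(mdir[radix_sort(mirna_ids)]),
               log2fc = unname(mfc[radix_sort(mirna_ids)]),
               stringsAsFactors = FALSE),
    data.frame(id = gene_ids,
               type = ifelse(gene_ids %in% tfs, "tf", "gene"),
               direction = unname(gdir[gene_ids]),
               log2fc = unname(gfc[gene_ids]),
               stringsAsFactors = FALSE))
  rownames(nodes) <- NULL
  if (anyNA(nodes$direction)) {
    stop_input("network node(s) lack DE annotation: ",
               paste(nodes$id[is.na(nodes$direction)], collapse = ", "))
  }
  structure(list(nodes = nodes, edges = edges), class = "tripartite_network")
}

#' @export
print.tripartite_network <- function(x, ...) {
  tab <- table(factor(x$nodes$type, levels = c("mirna", "tf", "gene")))
  cat("tripartite_network:", nrow(x$nodes), "nodes (",
      tab[["mirna"]], "miRNA,", tab[["tf"]], "TF,", tab[["gene"]],
      "gene ),", nrow(x$edges), "edges (",
      sum(x$edges$type == "targets"), "targets,",
      sum(x$edges$type == "regulates"), "regulates )\n")
  invisible(x)
}

as_igraph <- function(net) {
  igraph::graph_from_data_frame(net$edges, directed = TRUE,
                                vertices = net$nodes)
}

#' Export a network as SIF
#'
#' One line per edge: source, relation token (`targets` for miRNA edges,
#' `regulates` for TF edges), target; tab-separated.
#'
#' @param net a `tripartite_network`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
export_sif <- function(net, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(net$edges$from, net$edges$type, net$edges$to, sep = "\t"),
             con, sep = "\n")
  invisible(path)
}

#' Export a network as GraphML
#'
#' Node attributes `type`, `direction` and `log2fc` are carried into the
#' GraphML; edge attribute `type` holds the relation token.
#'
#' @param net a `tripartite_network`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
export_graphml <- function(net, path) {
  igraph::write_graph(as_igraph(net), path, format = "graphml")
  invisible(path)
}
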