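#' Gene-set collection with a universe
#'
#' Container for named gene sets plus the background universe used by the
#' over-representation test. Members outside the universe are clipped with
#' a warning. The recommended universe is all genes measured on the array
#' (all rows of the mRNA DE table), not the genome.
#'
#' @param sets named list of character vectors (set id -> member gene ids).
#' @param descriptions optional named character vector of set descriptions.
#' @param universe character vector of gene ids forming the background.
#' @return an object of class `geneset_collection`.
#' @export
geneset_collection <- function(sets, descriptions = NULL, universe) {
  if (!is.list(sets) || is.null(names(sets)) || anyDuplicated(names(sets))) {
    stop_input("'sets' must be a named list with unique set ids")
  }
  universe <- unique(as.character(universe))
  if (!length(universe)) stop_input("'universe' is empty")
  sets <- lapply(sets, function(s) {
    s <- unique(as.character(s))
    out <- intersect(s, universe)
    if (length(out) < length(s)) {
      warning(length(s) - length(out),
              " gene-set member(s) outside the universe were clipped",
              call. = FALSE)
    }
    out
  })
  if (any(lengths(sets) < 1L)) {
    stop_input("gene set(s) with no members inside the universe: ",
               paste(names(sets)[lengths(sets) < 1L], collapse = ", "))
  }
  if (is.null(descriptions)) {
    descriptions <- stats::setNames(rep("", length(sets)), names(sets))
  }
  structure(list(sets = sets,
                 descriptions = descriptions[names(sets)],
                 universe = universe),
            class = "geneset_collection")
}

#' @export
print.geneset_collection <- function(x, ...) {
  cat("geneset_collection:", length(x$sets), "sets over a universe of",
      length(x$universe), "genes\n")
  invisible(x)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p_values numeric vector of p-values in [0, 1].
#' @return BH-adjusted q-values (monotone over the ranked list, capped at 1).
#' @export
bh_adjust <- function(p_values) {
  if (!is.numeric(p_values)) stop_input("'p_values' must be numeric")
  if (length(p_values) == 0L) return(numeric(0))
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1)) {
    stop_input("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Directional activation z-score
#'
#' Simple directionality statistic for the DE hits of a gene set:
#' z = (n_up - n_down) / sqrt(n_up + n_down). Positive values indicate
#' predominantly upregulated hits. With zero hits the score is undefined
#' (`NA`). This is a documented stand-in for proprietary pathway-activity
#' scores and is not claimed to match them.
#'
#' @param n_up,n_down counts of up- and downregulated hit genes
#'   (vectorised).
#' @return numeric z-scores.
#' @export
activation_z <- function(n_up, n_down) {
  n <- n_up + n_down
  ifelse(n > 0, (n_up - n_down) / sqrt(n), NA_real_)
}

#' Over-representation analysis by the one-sided Fisher exact test
#'
#' For each set, tests whether the query list overlaps the set more than
#' expected by chance: p = P(X >= hits) with X hypergeometric over
#' population = universe size, successes = set size, draws = query size
#' (the one-sided Fisher exact test). The reported `ratio` is hits divided
#' by set size. Benjamini-Hochberg q-values are computed across all sets of
#' the collection; collections from different repositories should be
#' adjusted separately.
#'
#' @param query character vector of gene ids; members outside the universe
#'   are dropped with a warning.
#' @param collection a [geneset_collection()].
#' @param directions optional named vector (`up`/`down`) giving DE
#'   directions of the query genes, used for per-set direction counts and
#'   the [activation_z()] score.
#' @return data.frame of class `enrichment_table`, one row per set:
#'   `set_id`, `description`, `set_size`, `hits`, `ratio`, `p_value`,
#'   `q_value`, `n_up`, `n_down`, `z_score`, `hit_genes`
#'   (semicolon-joined), sorted by p then set id.
#' @export
fisher_enrich <- function(query, collection, directions = NULL) {
  if (!inherits(collection, "geneset_collection")) {
    stop_input("'collection' must be a geneset_collection")
  }
  query <- unique(as.character(query))
  outside <- setdiff(query, collection$universe)
  if (length(outside)) {
    warning(length(outside), " query gene(s) outside the universe dropped",
            call. = FALSE)
    query <- setdiff(query, outside)
  }
  N <- length(collection$universe)
  n <- length(query)
  if (!length(collection$sets)) {
    return(structure(data.frame(set_id = character(0)),
                     class = c("enrichment_table", "data.frame")))
  }
  rows <- lapply(names(collection$sets), function(sid) {
    members <- collection$sets[[sid]]
    K <- length(members)
    hit_genes <- radix_sort(intersect(query, members))
    k <- length(hit_genes)
    p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    n_up <- n_down <- NA_integer_
    if (!is.null(directions)) {
      d <- directions[hit_genes]
      n_up <- sum(d == "up", na.rm = TRUE)
      n_down <- sum(d == "down", na.rm = TRUE)
    }
    data.frame(set_id = sid,
               description = unname(collection$descriptions[sid]),
               set_size = K,
               hits = k,
               ratio = k / K,
               p_value = p,
               n_up = n_up,
               n_down = n_down,
               hit_genes = paste(hit_genes, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- bh_adjust(out$p_value)
  out$z_score <- ifelse(is.na(out$n_up), NA_real_,
                        activation_z(out$n_up, out$n_down))
  out <- out[radix_order(out$p_value, out$set_id),
             c("set_id", "description", "set_size", "hits", "ratio",
               "p_value", "q_value", "n_up", "n_down", "z_score",
               "hit_genes")]
  rownames(out) <- NULL
  structure(out, class = c("enrichment_table", "data.frame"))
}

#' Per-TF enrichment of downstream gene sets
#'
#' Runs [fisher_enrich()] on each TF's predicted downstream gene set and
#' retains, per TF, the categories with raw p strictly below `p_select`
#' (default 0.1) for reporting. TFs with too few downstream genes to
#' overlap any set yield empty reports.
#'
#' @param tf_map named list TF gene id -> downstream gene ids, from
#'   [predict_downstream()].
#' @param collection a [geneset_collection()].
#' @param p_select raw-p selection threshold (strict).
#' @param directions optional named direction vector, as in
#'   [fisher_enrich()].
#' @return named list of `enrichment_table`s, one per TF.
#' @export
tf_geneset_enrich <- function(tf_map, collection, p_select = 0.1,
                              directions = NULL) {
  if (!is_proportion(p_select)) stop_input("'p_select' must lie in [0, 1]")
  out <- lapply(tf_map, function(genes) {
    tab <- fisher_enrich(genes, collection, directions = directions)
    tab[tab$p_value < p_select & tab$hits > 0, , drop = FALSE]
  })
  stats::setNames(out, names(tf_map))
}
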