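# Shared fixtures and independent oracles used across test files.

# Small expression matrix with explicit values.
make_expr <- function(values, n_ctrl = 3L, n_trt = 3L) {
  colnames(values) <- c(sprintf("c%d", seq_len(n_ctrl)),
                        sprintf("t%d", seq_len(n_trt)))
  group <- setNames(rep(c("control", "treated"), c(n_ctrl, n_trt)),
                    colnames(values))
  expression_matrix(values, group)
}

# Minimal DE table rows for pairing tests (direction derives from lfc).
toy_de <- function(ids, lfc, is_de = rep(TRUE, length(ids))) {
  structure(data.frame(feature_id = ids,
                       log2fc = lfc,
                       p_value = ifelse(is_de, 0.01, 0.5),
                       q_value = ifelse(is_de, 0.02, 0.6),
                       direction = ifelse(is_de, ifelse(lfc > 0, "up", "down"),
                                          "none"),
                       is_de = is_de,
                       zero_variance = rep(FALSE, length(ids)),
                       stringsAsFactors = FALSE),
            class = c("de_table", "data.frame"))
}

# Brute-force promoter scan: enumerates every window on both strands with
# score_window; independent of the vectorised scanner's indexing.
brute_scan <- function(promoters, motifs, threshold_fraction) {
  rows <- list()
  for (motif in motifs) {
    L <- motif$length
    thr <- threshold_fraction * motif$max_score
    for (g in names(promoters)) {
      seqc <- promoters[[g]]
      if (nchar(seqc) < L) next
      for (off in 0:(nchar(seqc) - L)) {
        win <- substr(seqc, off + 1L, off + L)
        for (strand in c("+", "-")) {
          s <- score_window(win, motif, strand)
          if (s >= thr) {
            rows[[length(rows) + 1L]] <-
              data.frame(tf_id = motif$tf_id, motif_id = motif$motif_id,
                         gene_id = g, offset = off, strand = strand,
                         score = s, stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(tf_id = character(0), motif_id = character(0),
                      gene_id = character(0), offset = integer(0),
                      strand = character(0), score = numeric(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$motif_id, out$gene_id, out$offset, out$strand,
                   method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Exact hypergeometric upper tail by direct enumeration of the choose()
# terms; independent of stats::phyper.
hyper_tail_oracle <- function(hits, set_size, universe_size, query_size) {
  ks <- hits:min(set_size, query_size)
  sum(choose(set_size, ks) *
        choose(universe_size - set_size, query_size - ks)) /
    choose(universe_size, query_size)
}

# Literal BH step-up: q_i = min_{j >= i}(p_(j) * m / j), capped at 1,
# mapped back to input order.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- rev(cummin(rev(p[o] * m / seq_len(m))))
  pmin(q_sorted, 1)[order(o)]
}

# Random information-rich motif for scan fixtures.
random_motif <- function(len, id = "M1", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cons <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  m <- matrix(2, 4, len, dimnames = list(c("A", "C", "G", "T"), NULL))
  m[cbind(match(cons, c("A", "C", "G", "T")), seq_len(len))] <- 94
  motif_matrix(m, motif_id = id, tf_id = id)
}

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
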