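#' Position probability matrix with pseudocount and background
#'
#' Builds the binding-site model used for promoter scanning: a per-position
#' base-probability matrix derived from counts (or probabilities), with a
#' pseudocount of `pseudocount * background` added to each position before
#' renormalisation, plus the log2-odds matrix against the background and
#' the maximum attainable window score.
#'
#' @param m numeric 4 x L matrix with rownames A, C, G, T; columns are
#'   positions. Counts or probabilities (each column is normalised).
#' @param motif_id motif accession.
#' @param tf_id identifier of the transcription factor (gene id) the motif
#'   belongs to; defaults to `motif_id`.
#' @param pseudocount weight of the background added to each position's
#'   probabilities before renormalisation (default 0.01).
#' @param background strictly positive base probabilities summing to 1.
#' @return an object of class `motif_matrix` with elements `motif_id`,
#'   `tf_id`, `probs`, `lodds` (log2(p/background)), `length`,
#'   `max_score`, `consensus`, `background`, `pseudocount`.
#' @export
motif_matrix <- function(m, motif_id, tf_id = motif_id, pseudocount = 0.01,
                         background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  if (!is.matrix(m) || nrow(m) != 4L || ncol(m) < 1L) {
    stop_input("motif matrix must be 4 x L with L >= 1")
  }
  if (is.null(rownames(m)) || !setequal(rownames(m), DNA_BASES)) {
    stop_input("motif matrix needs rownames A, C, G, T")
  }
  m <- m[DNA_BASES, , drop = FALSE]
  if (any(m < 0) || any(colSums(m) <= 0)) {
    stop_input("motif matrix entries must be non-negative with positive ",
               "column sums")
  }
  background <- background[DNA_BASES]
  if (any(is.na(background)) || any(background <= 0) ||
      abs(sum(background) - 1) > 1e-8) {
    stop_input("background must be strictly positive probabilities ",
               "summing to 1 over A, C, G, T")
  }
  probs <- sweep(m, 2L, colSums(m), "/")
  probs <- probs + pseudocount * background
  probs <- sweep(probs, 2L, colSums(probs), "/")
  lodds <- log2(probs / background)
  structure(list(motif_id = motif_id,
                 tf_id = tf_id,
                 counts = m,
                 probs = probs,
                 lodds = lodds,
                 length = ncol(probs),
                 max_score = sum(apply(lodds, 2L, max)),
                 consensus = paste(DNA_BASES[apply(probs, 2L, which.max)],
                                   collapse = ""),
                 background = background,
                 pseudocount = pseudocount),
            class = "motif_matrix")
}

#' @export
print.motif_matrix <- function(x, ...) {
  cat("motif_matrix", x$motif_id, "(TF ", x$tf_id, "): ", x$length,
      " bp, consensus ", x$consensus, ", max score ",
      format(x$max_score, digits = 4), " bits\n", sep = "")
  invisible(x)
}

# Encode a sequence as integers: A=1 C=2 G=3 T=4 N=5.
encode_dna <- function(seq) {
  codes <- match(strsplit(toupper(seq), "", fixed = TRUE)[[1L]],
                 c(DNA_BASES, "N"))
  if (anyNA(codes)) stop_input("sequence contains characters outside A/C/G/T/N")
  codes
}

# log2-odds with a fifth, all-zero row so that N contributes 0 bits.
lodds5 <- function(motif) rbind(motif$lodds, N = 0)

# Minus-strand scanning matrix: scoring the reverse complement of a
# forward-text window equals scoring the window against the motif with
# columns reversed and complementary rows swapped.
lodds5_rc <- function(motif) {
  l <- motif$lodds[c("T", "G", "C", "A"), rev(seq_len(motif$length)),
                   drop = FALSE]
  rownames(l) <- DNA_BASES
  rbind(l, N = 0)
}

#' Log2-odds score of one window against a motif
#'
#' Scores a window of the same length as the motif:
#' sum over positions of log2(p(base) / background(base)). `N` bases
#' contribute 0 bits. On the minus strand, the reverse complement of the
#' window is scored.
#'
#' @param window nucleotide string over A/C/G/T/N, nchar = motif length.
#' @param motif a [motif_matrix()].
#' @param strand `"+"` or `"-"`.
#' @return score in bits.
#' @export
score_window <- function(window, motif, strand = c("+", "-")) {
  strand <- match.arg(strand)
  if (nchar(window) != motif$length) {
    stop_input("window length ", nchar(window), " does not match motif ",
               "length ", motif$length)
  }
  if (strand == "-") window <- revcomp_chr(window)
  codes <- encode_dna(window)
  l <- lodds5(motif)
  sum(l[cbind(codes, seq_len(motif$length))])
}

#' Scan promoter sequences for motif hits on both strands
#'
#' Slides each motif along every promoter on both strands and reports every
#' window whose log2-odds score reaches `threshold_fraction` of that
#' motif's maximum attainable score. Offsets are 0-based window starts on
#' the forward promoter text; a minus-strand hit at offset o means the
#' reverse complement of the site occupies the forward text at o. No
#' per-gene collapsing happens here: all hits are reported.
#'
#' @param promoters named character vector of promoter sequences (names are
#'   gene ids), or a `Biostrings::DNAStringSet`.
#' @param motifs list of [motif_matrix()] objects.
#' @param threshold_fraction fraction of the motif's maximum score required
#'   for a hit, in (0, 1].
#' @return data.frame of hits: `tf_id`, `motif_id`, `gene_id`, `offset`,
#'   `strand`, `score`, sorted by motif, gene, offset, strand.
#' @export
scan_promoters <- function(promoters, motifs, threshold_fraction = 0.8) {
  if (methods::is(promoters, "DNAStringSet")) {
    promoters <- stats::setNames(as.character(promoters), names(promoters))
  }
  if (!is.character(promoters) || is.null(names(promoters)) ||
      anyDuplicated(names(promoters))) {
    stop_input("'promoters' must be named sequences with unique gene ids")
  }
  if (length(promoters) == 0L) stop_input("'promoters' is empty")
  if (!is.numeric(threshold_fraction) || threshold_fraction <= 0 ||
      threshold_fraction > 1) {
    stop_input("'threshold_fraction' must lie in (0, 1]")
  }
  if (inherits(motifs, "motif_matrix")) motifs <- list(motifs)

  codes_list <- lapply(promoters, encode_dna)
  out <- vector("list", length(motifs) * 2L * length(promoters))
  k <- 0L
  for (motif in motifs) {
    L <- motif$length
    thr <- threshold_fraction * motif$max_score
    mats <- list(`+` = lodds5(motif), `-` = lodds5_rc(motif))
    for (g in names(promoters)) {
      codes <- codes_list[[g]]
      W <- length(codes) - L + 1L
      if (W < 1L) next  # promoter shorter than motif: zero hits
      pos <- matrix(rep(seq_len(W), L) + rep(0:(L - 1L), each = W), W, L)
      win_codes <- matrix(codes[pos], W, L)
      col_idx <- rep(seq_len(L), each = W)
      for (strand in c("+", "-")) {
        scores <- rowSums(matrix(mats[[strand]][cbind(as.vector(win_codes),
                                                      col_idx)], W, L))
        hit <- which(scores >= thr)
        if (length(hit)) {
          k <- k + 1L
          out[[k]] <- data.frame(tf_id = motif$tf_id,
                                 motif_id = motif$motif_id,
                                 gene_id = g,
                                 offset = hit - 1L,
                                 strand = strand,
                                 score = scores[hit],
                                 stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (k == 0L) {
    return(data.frame(tf_id = character(0), motif_id = character(0),
                      gene_id = character(0), offset = integer(0),
                      strand = character(0), score = numeric(0),
                      stringsAsFactors = FALSE))
  }
  hits <- do.call(rbind, out[seq_len(k)])
  hits <- hits[radix_order(hits$motif_id, hits$gene_id, hits$offset,
                           hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}
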