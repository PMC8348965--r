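# Shared internal helpers.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) {
  stop(paste0(...), call. = FALSE)
}

# Locale-independent sort, used everywhere identifiers are ordered so that
# outputs are byte-identical across machines.
radix_sort <- function(x) x[order(x, method = "radix")]

radix_order <- function(...) order(..., method = "radix")

# Run code under a temporary RNG state; restores the caller's stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

DNA_BASES <- c("A", "C", "G", "T")

# Reverse complement of a plain character string over {A,C,G,T,N}.
revcomp_chr <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  comp <- chartr("ACGTN", "TGCAN", toupper(x))
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1L]]), collapse = "")
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == round(x)
}

is_proportion <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x <= 1
}

# Write a data.frame as TSV with header, UTF-8, LF endings (the package's
# one tabular dialect).
write_tsv_file <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n",
                     fileEncoding = "UTF-8")
  invisible(path)
}

read_tsv_file <- function(path, required_cols = NULL) {
  if (!file.exists(path)) stop_input("file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          quote = "", comment.char = "")
  if (!is.null(required_cols)) {
    missing <- setdiff(required_cols, names(df))
    if (length(missing)) {
      stop_input("file ", path, " is missing required column(s): ",
                 paste(missing, collapse = ", "))
    }
  }
  df
}
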