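# Readers and writers for the pipeline's on-disk formats. All tabular
# files are TSV with a header row, UTF-8, LF endings; every writer's
# output re-reads to an identical in-memory value.

#' Write / read a log2 expression matrix as TSV
#'
#' The expression file has a `feature_id` column plus one column per
#' sample; the sample-to-group map is a separate two-column TSV
#' (`sample_id`, `group`).
#'
#' @param x an [expression_matrix()].
#' @param path expression TSV path.
#' @param group_path group-map TSV path.
#' @return `path` invisibly (writer); an `expression_matrix` (reader).
#' @export
write_expression <- function(x, path, group_path) {
  stopifnot(inherits(x, "expr_matrix"))
  df <- data.frame(feature_id = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_file(df, path)
  write_tsv_file(data.frame(sample_id = names(x$group),
                            group = unname(x$group),
                            stringsAsFactors = FALSE), group_path)
  invisible(path)
}

#' @rdname write_expression
#' @export
read_expression <- function(path, group_path) {
  df <- read_tsv_file(path, required_cols = "feature_id")
  if (anyDuplicated(df$feature_id)) {
    stop_input("duplicate feature ids in ", path)
  }
  values <- as.matrix(df[, setdiff(names(df), "feature_id"), drop = FALSE])
  if (!is.numeric(values)) stop_input("non-numeric expression values in ", path)
  rownames(values) <- df$feature_id
  gm <- read_tsv_file(group_path, required_cols = c("sample_id", "group"))
  expression_matrix(values, stats::setNames(gm$group, gm$sample_id))
}

#' Write / read a miRNA-target interaction table
#'
#' Columns: `mirna_id`, `gene_id`, `tier`
#' (experimentally_observed / high / moderate), `source`.
#'
#' @param db interaction data.frame.
#' @param path TSV path.
#' @return `path` invisibly (writer); a data.frame (reader).
#' @export
write_interactions <- function(db, path) {
  write_tsv_file(db[, c("mirna_id", "gene_id", "tier", "source")], path)
}

#' @rdname write_interactions
#' @export
read_interactions <- function(path) {
  db <- read_tsv_file(path, required_cols = c("mirna_id", "gene_id",
                                              "tier", "source"))
  bad <- which(!db$tier %in% INTERACTION_TIERS)
  if (length(bad)) {
    stop_input("unknown evidence tier '", db$tier[bad[1L]], "' at ", path,
               " line ", bad[1L] + 1L)
  }
  db
}

#' Write / read a differential-expression table
#'
#' @param table a `de_table` from [test_differential()].
#' @param path TSV path.
#' @return `path` invisibly (writer); a `de_table` (reader).
#' @export
write_de_table <- function(table, path) {
  write_tsv_file(table[, c("feature_id", "log2fc", "p_value", "q_value",
                           "direction", "is_de")], path)
}

#' @rdname write_de_table
#' @export
read_de_table <- function(path) {
  df <- read_tsv_file(path, required_cols = c("feature_id", "log2fc",
                                              "p_value", "q_value",
                                              "direction", "is_de"))
  structure(df, class = c("de_table", "data.frame"))
}

#' Write / read promoter sequences as FASTA
#'
#' Record ids are gene ids; duplicates are rejected.
#'
#' @param promoters named character vector of sequences.
#' @param path FASTA path.
#' @return `path` invisibly (writer); named character vector (reader).
#' @export
write_promoters <- function(promoters, path) {
  if (anyDuplicated(names(promoters))) {
    stop_input("duplicate promoter ids")
  }
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(promoters), path, width = 80L)
  invisible(path)
}

#' @rdname write_promoters
#' @export
read_promoters <- function(path) {
  if (!file.exists(path)) stop_input("file not found: ", path)
  x <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(ids)) {
    stop_input("duplicate record ids in FASTA ", path, ": ",
               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  stats::setNames(as.character(x), ids)
}

#' Write / read motifs in JASPAR-style count format
#'
#' Each motif is a `>ID NAME` header followed by four rows `A`, `C`, `G`,
#' `T` of per-position counts, optionally bracketed
#' (`A [ 94 2 ... ]`). The NAME field stores the TF gene id.
#'
#' @param motifs list of [motif_matrix()] objects.
#' @param path motif file path.
#' @param pseudocount,background passed to [motif_matrix()] on read.
#' @return `path` invisibly (writer); named list of `motif_matrix`
#'   (reader).
#' @export
write_motifs <- function(motifs, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (m in motifs) {
    counts <- m$counts
    writeLines(paste0(">", m$motif_id, " ", m$tf_id), con, sep = "\n")
    for (b in DNA_BASES) {
      writeLines(paste0(b, " [ ", paste(counts[b, ], collapse = " "), " ]"),
                 con, sep = "\n")
    }
  }
  invisible(path)
}

#' @rdname write_motifs
#' @export
read_motifs <- function(path, pseudocount = 0.01,
                        background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  if (!file.exists(path)) stop_input("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  starts <- grep("^>", lines)
  if (!length(starts)) {
    if (!length(lines)) return(list())  # empty motif file: no motifs
    stop_input("no motif headers ('>') in ", path)
  }
  ends <- c(starts[-1L] - 1L, length(lines))
  motifs <- list()
  for (i in seq_along(starts)) {
    header <- sub("^>", "", lines[starts[i]])
    fields <- strsplit(trimws(header), "\\s+")[[1L]]
    motif_id <- fields[1L]
    tf_id <- if (length(fields) >= 2L) fields[2L] else motif_id
    block <- lines[(starts[i] + 1L):ends[i]]
    if (length(block) != 4L) {
      stop_input("motif ", motif_id, " in ", path,
                 " must have exactly 4 base rows (line ", starts[i], ")")
    }
    rows <- lapply(seq_along(block), function(j) {
      ln <- block[j]
      base <- sub("^\\s*([ACGT]).*", "\\1", ln)
      if (!base %in% DNA_BASES) {
        stop_input("malformed motif row at ", path, " line ",
                   starts[i] + j, ": ", ln)
      }
      nums <- gsub("[^0-9.eE+-]", " ", sub("^\\s*[ACGT]", "", ln))
      vals <- suppressWarnings(as.numeric(strsplit(trimws(nums), "\\s+")[[1L]]))
      if (!length(vals) || anyNA(vals)) {
        stop_input("malformed counts at ", path, " line ", starts[i] + j,
                   ": ", ln)
      }
      stats::setNames(list(vals), base)
    })
    rows <- unlist(rows, recursive = FALSE)
    lens <- lengths(rows)
    if (length(unique(lens)) != 1L || !setequal(names(rows), DNA_BASES)) {
      stop_input("inconsistent motif block for ", motif_id, " in ", path)
    }
    m <- do.call(rbind, rows[DNA_BASES])
    motifs[[motif_id]] <- motif_matrix(m, motif_id = motif_id, tf_id = tf_id,
                                       pseudocount = pseudocount,
                                       background = background)
  }
  motifs
}

#' Write / read gene sets in GMT format
#'
#' One set per line: set id, description, then member gene ids, all
#' tab-separated. Lines with fewer than three fields are rejected with the
#' offending line number.
#'
#' @param collection a [geneset_collection()] (writer) or GMT path
#'   (reader).
#' @param path GMT path.
#' @param universe universe to attach on read; defaults to the union of all
#'   members.
#' @return `path` invisibly (writer); a `geneset_collection` (reader).
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "geneset_collection"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (sid in names(collection$sets)) {
    writeLines(paste(c(sid, collection$descriptions[[sid]],
                       collection$sets[[sid]]), collapse = "\t"),
               con, sep = "\n")
  }
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path, universe = NULL) {
  if (!file.exists(path)) stop_input("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 3L)
  if (length(short)) {
    stop_input("GMT line ", short[1L], " in ", path,
               " has fewer than 3 fields (set id, description, members)")
  }
  ids <- vapply(parts, `[`, "", 1L)
  if (anyDuplicated(ids)) {
    stop_input("duplicate set ids in ", path)
  }
  sets <- stats::setNames(lapply(parts, function(p) p[-(1:2)]), ids)
  desc <- stats::setNames(vapply(parts, `[`, "", 2L), ids)
  if (is.null(universe)) universe <- radix_sort(unique(unlist(sets)))
  geneset_collection(sets, descriptions = desc, universe = universe)
}

#' Write / read BED-like binding-site tables
#'
#' 0-based, half-open intervals: columns `gene_id`, `start`, `end`,
#' `tf_id`, `strand` (plant manifests) plus `score` for scan hits.
#'
#' @param df data.frame of sites.
#' @param path TSV path.
#' @return `path` invisibly (writer); data.frame (reader).
#' @export
write_sites_bed <- function(df, path) {
  cols <- c("gene_id", "start", "end", "tf_id",
            intersect("score", names(df)), "strand")
  write_tsv_file(df[, cols], path)
}

#' @rdname write_sites_bed
#' @export
read_sites_bed <- function(path) {
  read_tsv_file(path, required_cols = c("gene_id", "start", "end", "tf_id",
                                        "strand"))
}

#' Write / read the ground truth as JSON
#'
#' @param truth a `ground_truth` object.
#' @param path JSON path.
#' @return `path` invisibly (writer); a `ground_truth` (reader).
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  if (!file.exists(path)) stop_input("file not found: ", path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("planted_de_mirnas", "planted_de_genes", "planted_pairings",
              "decoys", "planted_tfbs")) {
    if (!is.null(x[[f]])) x[[f]] <- as.data.frame(x[[f]],
                                                  stringsAsFactors = FALSE)
  }
  if (!is.null(x$tf_downstream)) {
    x$tf_downstream <- lapply(x$tf_downstream, as.character)
  }
  if (!is.null(x$planted_enriched_sets)) {
    x$planted_enriched_sets <- as.data.frame(x$planted_enriched_sets,
                                             stringsAsFactors = FALSE)
  }
  structure(x, class = "ground_truth")
}

#' Write a pairing table / enrichment table as TSV
#'
#' @param table the table to write.
#' @param path TSV path.
#' @return `path`, invisibly.
#' @export
write_pairing_table <- function(table, path) {
  write_tsv_file(table, path)
}

#' @rdname write_pairing_table
#' @export
read_pairing_table <- function(path) {
  df <- read_tsv_file(path, required_cols = c("mirna_id", "mirna_log2fc",
                                              "mirna_direction", "gene_id",
                                              "gene_log2fc", "gene_direction",
                                              "tier", "sources"))
  structure(df, class = c("pairing_table", "data.frame"))
}

#' @rdname write_pairing_table
#' @export
write_enrichment_table <- function(table, path) {
  write_tsv_file(as.data.frame(table), path)
}
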