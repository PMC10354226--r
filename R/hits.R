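#' Parse a 12-column tabular alignment hit file
#'
#' Reads the standard tab-separated hit table (query, subject, percent
#' identity, alignment length, mismatches, gap opens, qstart, qend, sstart,
#' send, evalue, bitscore). Extra trailing columns are tolerated and ignored.
#'
#' @param path Path to the tab-separated hit file.
#' @return A tibble with one row per hit, in file order, with columns
#'   `query_id`, `subject_id`, `percent_identity`, `alignment_length`,
#'   `mismatches`, `gap_opens`, `qstart`, `qend`, `sstart`, `send`,
#'   `evalue`, `bitscore`.
#' @export
parse_hit_table <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  cols <- c("query_id", "subject_id", "percent_identity", "alignment_length",
            "mismatches", "gap_opens", "qstart", "qend", "sstart", "send",
            "evalue", "bitscore")
  if (length(keep) == 0) {
    out <- tibble::as_tibble(setNames(
      c(list(character(), character()), replicate(10, numeric())), cols))
    return(out)
  }
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 12)) {
    stop("hit table parse error at line ", keep[which(nf < 12)[1]],
         ": fewer than 12 tab-separated fields")
  }
  mat <- t(vapply(fields, function(f) f[1:12], character(12)))
  num <- suppressWarnings(apply(mat[, 3:12, drop = FALSE], 2, as.numeric))
  num <- matrix(num, ncol = 10)
  bad <- which(apply(is.na(num[, c(1, 9, 10), drop = FALSE]), 1, any))
  if (length(bad) > 0) {
    stop("hit table parse error at line ", keep[bad[1]],
         ": non-numeric identity/evalue/bitscore")
  }
  out <- tibble::tibble(
    query_id = mat[, 1], subject_id = mat[, 2],
    percent_identity = num[, 1], alignment_length = num[, 2],
    mismatches = num[, 3], gap_opens = num[, 4],
    qstart = num[, 5], qend = num[, 6], sstart = num[, 7], send = num[, 8],
    evalue = num[, 9], bitscore = num[, 10]
  )
  if (any(out$evalue < 0, na.rm = TRUE)) stop("negative e-value in hit table")
  out
}

#' Keep the single best hit per query
#'
#' "Best" is the highest bitscore; ties are broken by lowest e-value, then by
#' first occurrence in file order, so the result is deterministic.
#'
#' @param hits Hit tibble as produced by [parse_hit_table()] (or any tibble
#'   with `query_id`, `bitscore`, `evalue`).
#' @return A tibble with exactly one row per query present in `hits`.
#' @export
best_hit_per_query <- function(hits) {
  if (nrow(hits) == 0) return(hits)
  hits %>%
    dplyr::mutate(.file_order = dplyr::row_number()) %>%
    dplyr::arrange(.data$query_id, dplyr::desc(.data$bitscore),
                   .data$evalue, .data$.file_order) %>%
    dplyr::distinct(.data$query_id, .keep_all = TRUE) %>%
    dplyr::arrange(.data$.file_order) %>%
    dplyr::select(-".file_order")
}

#' Extract on-target reads
#'
#' Returns exactly the reads whose id appears among the best hits, in their
#' original order.
#'
#' @param reads Sequence tibble (see [read_fasta()]).
#' @param best_hits Tibble with a `query_id` column, normally the output of
#'   [best_hit_per_query()].
#' @return The on-target subset of `reads` (order preserved).
#' @export
extract_on_target <- function(reads, best_hits) {
  reads[reads$id %in% best_hits$query_id, , drop = FALSE]
}

#' Match sequences to locus references by shared k-mers
#'
#' A desk-scale similarity search: for every query sequence the fraction of
#' its k-mers present in each reference is computed, and references above
#' `min_frac` are reported as rows of a standard 12-column hit table (the
#' shared k-mer count plays the role of the bitscore and the shared fraction,
#' in percent, the role of the identity). Use [best_hit_per_query()] on the
#' result exactly as for an external search tool's output.
#'
#' @param queries Sequence tibble of reads, centroids or consensuses.
#' @param references Sequence tibble of locus references.
#' @param k Word length (default 8).
#' @param min_frac Minimum shared-k-mer fraction to report a hit.
#' @return Hit tibble in the same shape as [parse_hit_table()] output.
#' @export
kmer_hit_table <- function(queries, references, k = 8, min_frac = 0.05) {
  validate_seq_tbl(queries)
  validate_seq_tbl(references)
  raw <- cpp_kmer_hits(queries$sequence, references$sequence, k, min_frac)
  tibble::tibble(
    query_id = queries$id[raw$query],
    subject_id = references$id[raw$subject],
    percent_identity = 100 * raw$frac,
    alignment_length = nchar(queries$sequence[raw$query]),
    mismatches = 0, gap_opens = 0,
    qstart = 1, qend = nchar(queries$sequence[raw$query]),
    sstart = 1, send = nchar(references$sequence[raw$subject]),
    evalue = 0, bitscore = as.numeric(raw$shared)
  )
}
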