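#' Read a FASTA file into a sequence tibble
#'
#' Sequence collections are plain tibbles with one row per record, so they
#' compose with the usual dplyr verbs. Sequences are upper-cased on input and
#' validated against the IUPAC nucleotide alphabet.
#'
#' @param path Path to a FASTA file.
#' @param individual Label of the individual the file belongs to (one FASTA
#'   per individual; read ids are treated as opaque). Defaults to the file
#'   name without extension.
#' @param role Provenance label for all records: one of `"read"`,
#'   `"centroid"`, `"consensus"`, `"reference"`.
#'
#' @return A tibble with columns `id`, `sequence`, `individual`, `role`.
#' @export
read_fasta <- function(path, individual = NULL, role = "read") {
  stopifnot(file.exists(path))
  role <- match.arg(role, c("read", "centroid", "consensus", "reference"))
  x <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(x))
  seqs <- toupper(as.character(x))
  tb <- tibble::tibble(
    id = ids,
    sequence = unname(seqs),
    individual = individual %||% sub("\\.[^.]*$", "", basename(path)),
    role = role
  )
  validate_seq_tbl(tb)
  tb
}

#' Write a sequence tibble to FASTA
#'
#' Output is line-wrapped at 80 columns.
#'
#' @param seqs Tibble with at least `id` and `sequence` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  validate_seq_tbl(seqs)
  x <- Biostrings::DNAStringSet(setNames(seqs$sequence, seqs$id))
  Biostrings::writeXStringSet(x, path, width = 80)
  invisible(path)
}

# IUPAC nucleotide alphabet; '-' tolerated only when aligned = TRUE
validate_seq_tbl <- function(tb, aligned = FALSE) {
  stopifnot(is.data.frame(tb), all(c("id", "sequence") %in% names(tb)))
  if (anyDuplicated(tb$id)) {
    stop("duplicated sequence ids: ",
         paste(unique(tb$id[duplicated(tb$id)]), collapse = ", "))
  }
  if (any(!nzchar(tb$sequence))) stop("empty sequence in collection")
  alph <- "ACGTRYSWKMBDHVN"
  if (aligned) alph <- paste0(alph, "-")
  bad <- grepl(sprintf("[^%s]", alph), tb$sequence)
  if (any(bad)) {
    stop("non-IUPAC characters in sequence(s): ",
         paste(head(tb$id[bad], 3), collapse = ", "))
  }
  invisible(tb)
}

# construct a sequence tibble from bare vectors (internal convenience)
seq_tbl <- function(id, sequence, individual = NA_character_, role = "read") {
  tb <- tibble::tibble(id = id, sequence = toupper(sequence),
                       individual = individual, role = role)
  validate_seq_tbl(tb)
  tb
}
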