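#' k-mer distance between two sequences
#'
#' The fraction of shared k-words, counted with multiplicity, normalised by
#' the number of k-mer windows of the shorter sequence:
#' `F = sum_w min(count_a(w), count_b(w)) / (min(|a|,|b|) - k + 1)`, and
#' `d = 1 - F`. The distance is symmetric, lies in [0, 1] and is zero for
#' identical sequences. It is used instead of alignment-based distances
#' because cluster consensuses can be too divergent for reliable multiple
#' alignment.
#'
#' @param a,b DNA strings of length at least `k`.
#' @param k Word length (default 8).
#' @return Distance in [0, 1].
#' @export
kmer_distance <- function(a, b, k = 8) {
  stopifnot(k >= 1)
  if (nchar(a) < k || nchar(b) < k) {
    stop("kmer_distance: sequence shorter than k")
  }
  m <- kmer_counts(c(a, b), k)
  shared <- sum(pmin(m[1, ], m[2, ]))
  1 - shared / (min(nchar(a), nchar(b)) - k + 1)
}

# k-mer count matrix (rows = sequences) via Biostrings
kmer_counts <- function(seqs, k) {
  x <- Biostrings::DNAStringSet(toupper(seqs))
  Biostrings::oligonucleotideFrequency(x, width = k)
}

#' Pairwise k-mer distance matrix for a set of sequences
#'
#' @param seqs Sequence tibble (`id`, `sequence`); all sequences must be at
#'   least `k` long.
#' @param k Word length.
#' @return A symmetric matrix with zero diagonal, dimnames = sequence ids.
#' @export
kmer_distance_matrix <- function(seqs, k = 8) {
  validate_seq_tbl(seqs)
  if (any(nchar(seqs$sequence) < k)) {
    stop("kmer_distance_matrix: sequence shorter than k")
  }
  n <- nrow(seqs)
  m <- kmer_counts(seqs$sequence, k)
  wins <- nchar(seqs$sequence) - k + 1
  d <- matrix(0, n, n, dimnames = list(seqs$id, seqs$id))
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        shared <- sum(pmin(m[i, ], m[j, ]))
        d[i, j] <- d[j, i] <- 1 - shared / min(wins[i], wins[j])
      }
    }
  }
  d
}
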