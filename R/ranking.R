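#' Percentile-based joint ranking and locus proposal
#'
#' Loci are ranked per criterion (index 1 descending = better; KBS mean,
#' KBS sd and entropy ascending = better) and each locus' percentile is
#' `100 * rank / N` with 1-based minimum-rank ties. A locus is proposed at
#' threshold q when all four percentiles are at most q, so proposed sets
#' are nested and non-decreasing in q. The proposal threshold of a locus is
#' the smallest integer q (1..99) at which it is proposed, i.e. the maximum
#' of its four percentiles rounded up; loci whose maximum exceeds 99 are
#' never proposed.
#'
#' @param rows Index tibble from [compute_all_indices()] (needs `locus_id`,
#'   `index1`, `kbs_mean`, `kbs_sd`, `entropy`, and `best_k` if present is
#'   carried through). At least two complete rows required.
#' @return A tibble with per-criterion percentiles (`pct_index1`,
#'   `pct_kbs_mean`, `pct_kbs_sd`, `pct_entropy`), the continuous
#'   `proposal_percentile`, the integer `proposal_threshold` (NA when the
#'   locus is never proposed) and `best_k` when available.
#' @export
rank_and_propose <- function(rows) {
  need <- c("locus_id", "index1", "kbs_mean", "kbs_sd", "entropy")
  stopifnot(all(need %in% names(rows)))
  if (nrow(rows) < 2) stop("rank_and_propose: need at least 2 loci")
  if (anyNA(rows[need])) stop("rank_and_propose: incomplete index rows")
  n <- nrow(rows)
  pct <- function(x) 100 * rank(x, ties.method = "min") / n
  out <- rows %>%
    dplyr::mutate(
      pct_index1 = pct(-.data$index1),
      pct_kbs_mean = pct(.data$kbs_mean),
      pct_kbs_sd = pct(.data$kbs_sd),
      pct_entropy = pct(.data$entropy)
    ) %>%
    dplyr::mutate(
      proposal_percentile = pmax(.data$pct_index1, .data$pct_kbs_mean,
                                 .data$pct_kbs_sd, .data$pct_entropy),
      proposal_threshold = {
        q <- as.integer(ceiling(.data$proposal_percentile))
        ifelse(q <= 99L, q, NA_integer_)
      }
    )
  keep <- c("locus_id", "pct_index1", "pct_kbs_mean", "pct_kbs_sd",
            "pct_entropy", "proposal_percentile", "proposal_threshold")
  if ("best_k" %in% names(rows)) keep <- c(keep, "best_k")
  dplyr::select(out, dplyr::all_of(keep))
}

#' Loci proposed at a given percentile threshold
#'
#' @param results Output of [rank_and_propose()].
#' @param q Percentile threshold in 1..99.
#' @return Character vector of proposed locus ids.
#' @export
proposed_at <- function(results, q) {
  stopifnot(q >= 1, q <= 99)
  results$locus_id[!is.na(results$proposal_threshold) &
                     results$proposal_threshold <= q]
}

#' Exclude proposed loci with too many dendrogram clades
#'
#' Proposed loci whose silhouette-optimal clade number exceeds `max_best_k`
#' are excluded as likely multi-paralog loci (with four species, up to four
#' main clades can still be explained by phylogenetic structure alone).
#'
#' @param results Output of [rank_and_propose()].
#' @param rows Index tibble providing `best_k` per locus (may be `results`
#'   itself when it carries `best_k`).
#' @param q Percentile threshold defining the proposed set.
#' @param max_best_k Largest admissible best K (default 4).
#' @return Character vector of candidate locus ids.
#' @export
candidate_filter <- function(results, rows = results, q = 50, max_best_k = 4) {
  stopifnot("best_k" %in% names(rows))
  prop <- proposed_at(results, q)
  bk <- setNames(rows$best_k, rows$locus_id)
  prop[bk[prop] <= max_best_k]
}
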