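#' Pre-choice filtering rules
#'
#' Thresholds for the first, coarse exclusion of unsuitable loci: loci with
#' too few reads cannot support consensus calling from error-prone reads,
#' and loci with very many reads are unlikely to be single-copy.
#'
#' @param min_reads Minimum total reads per locus (summed over individuals).
#' @param max_reads Exclusive upper bound: loci with more than
#'   `max_reads - 1` reads are excluded (the kept range is
#'   `[min_reads, max_reads - 1]`).
#' @param min_individuals_with_reads Reads must be present in at least this
#'   many individuals.
#' @param min_individuals_with_big_cluster At least this many individuals
#'   must each have a cluster of `big_cluster_size` or more reads.
#' @param big_cluster_size Read count from which a cluster counts towards
#'   the previous rule.
#' @return A list of class `prechoice_rules`.
#' @export
prechoice_rules <- function(min_reads = 100, max_reads = 1000,
                            min_individuals_with_reads = 3,
                            min_individuals_with_big_cluster = 3,
                            big_cluster_size = 5) {
  stopifnot(min_reads > 0, max_reads > min_reads,
            min_individuals_with_reads > 0,
            min_individuals_with_big_cluster > 0, big_cluster_size > 0)
  structure(list(min_reads = min_reads, max_reads = max_reads,
                 min_individuals_with_reads = min_individuals_with_reads,
                 min_individuals_with_big_cluster =
                   min_individuals_with_big_cluster,
                 big_cluster_size = big_cluster_size),
            class = "prechoice_rules")
}

#' Per-locus, per-individual cluster summary statistics
#'
#' One row per (locus, individual) combination present in the assigned
#' clusters: read count, cluster count, singleton count (size 1),
#' low-coverage count (size 1-4) and maximum cluster size. Locus totals are
#' obtained by summing rows.
#'
#' @param clusters Assigned cluster tibble (see [assign_cluster_locus()]);
#'   all rows must carry a `locus_id`.
#' @return A tibble `locus_id`, `individual`, `n_reads`, `n_clusters`,
#'   `n_singletons`, `n_lowcov`, `max_cluster_size`.
#' @export
summarize_loci <- function(clusters) {
  if (any(is.na(clusters$locus_id))) {
    stop("summarize_loci: unassigned clusters present; filter on status first")
  }
  clusters %>%
    dplyr::group_by(.data$locus_id, .data$individual) %>%
    dplyr::summarise(
      n_reads = sum(.data$size),
      n_clusters = dplyr::n(),
      n_singletons = sum(.data$size == 1),
      n_lowcov = sum(.data$size <= 4),
      max_cluster_size = max(.data$size),
      .groups = "drop"
    )
}

#' Apply the pre-choice locus filters
#'
#' Keeps loci whose total read count lies within the configured bounds, that
#' have reads in enough individuals, and in which enough individuals possess
#' at least one sufficiently large cluster. The rules are evaluated on the
#' complete cluster set (before any small-cluster removal).
#'
#' @param stats Per-(locus, individual) statistics from [summarize_loci()].
#' @param rules A [prechoice_rules()] object.
#' @return Character vector of kept locus ids (sorted).
#' @export
prechoice_filter <- function(stats, rules = prechoice_rules()) {
  stopifnot(inherits(rules, "prechoice_rules"))
  kept <- stats %>%
    dplyr::group_by(.data$locus_id) %>%
    dplyr::summarise(
      total_reads = sum(.data$n_reads),
      n_ind = dplyr::n_distinct(.data$individual[.data$n_reads > 0]),
      n_ind_big = sum(.data$max_cluster_size >= rules$big_cluster_size),
      .groups = "drop"
    ) %>%
    dplyr::filter(
      .data$total_reads >= rules$min_reads,
      .data$total_reads <= rules$max_reads - 1,
      .data$n_ind >= rules$min_individuals_with_reads,
      .data$n_ind_big >= rules$min_individuals_with_big_cluster
    )
  sort(kept$locus_id)
}

#' Drop singleton and low-coverage clusters
#'
#' Clusters below `min_size` reads are dismissed before consensus sequences
#' enter the index computations (they are likely artifactual); the complete
#' collection is still used for the reads-per-cluster index.
#'
#' @param clusters Cluster tibble.
#' @param min_size Minimum cluster size to retain (default 5).
#' @return The retained subset of `clusters`.
#' @export
drop_small_clusters <- function(clusters, min_size = 5) {
  clusters[clusters$size >= min_size, , drop = FALSE]
}
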