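#' Clustering parameters
#'
#' @param ct Identity threshold in (0, 1] a read must reach against a cluster
#'   centroid to join that cluster. The published default of 0.88 suits reads
#'   with a few percent error; for noisier reads the threshold should sit
#'   just below the expected read-vs-read identity (see the package
#'   vignette).
#' @param band Band half-width passed to the aligner during clustering
#'   (widened internally by the length difference of each pair).
#' @param kmer_prescreen Shared 8-mer fraction below which a centroid
#'   comparison is skipped without aligning. Skipping never reorders
#'   comparisons, so on data where the prescreen is sound it does not change
#'   results; set to 0 to disable.
#' @return A list of class `clustering_params`.
#' @export
clustering_params <- function(ct = 0.88, band = 64, kmer_prescreen = 0.05) {
  stopifnot(ct > 0, ct <= 1, band >= 1, kmer_prescreen >= 0,
            kmer_prescreen < 1)
  structure(list(ct = ct, band = band, kmer_prescreen = kmer_prescreen,
                 sort_mode = "length_desc", match_mode = "first_accept"),
            class = "clustering_params")
}

#' Greedy identity-threshold clustering of reads
#'
#' Reads of each individual are processed in order of decreasing length
#' (ties by id); each read joins the first existing centroid it reaches with
#' global-alignment identity at least `ct`, otherwise it founds a new
#' cluster with itself as centroid. The procedure is deterministic: the same
#' input and parameters give byte-identical output.
#'
#' @param reads Sequence tibble (one or more individuals; clustering is
#'   performed independently per individual).
#' @param params A [clustering_params()] object.
#' @return A tibble with one row per cluster: `cluster_id`, `individual`,
#'   `centroid_id`, `centroid_seq`, `member_ids` (list column, centroid
#'   included), `size`.
#' @export
greedy_cluster <- function(reads, params = clustering_params()) {
  cluster_with_consensus(reads, params)$clusters
}

# clustering plus streamed majority consensus in one pass (each member's
# alignment to its centroid is consumed for the consensus vote at accept
# time); equivalent to greedy_cluster + majority_consensus
cluster_with_consensus <- function(reads, params = clustering_params()) {
  validate_seq_tbl(reads)
  if (nrow(reads) == 0) stop("greedy_cluster: no reads")
  stopifnot(inherits(params, "clustering_params"))
  parts <- reads %>%
    dplyr::group_by(.data$individual) %>%
    dplyr::group_split() %>%
    purrr::map(cluster_one_individual, params = params)
  list(clusters = purrr::list_rbind(purrr::map(parts, "clusters")),
       consensus = purrr::list_rbind(purrr::map(parts, "consensus")))
}

cluster_one_individual <- function(reads, params) {
  ord <- order(-nchar(reads$sequence), reads$id)
  reads <- reads[ord, , drop = FALSE]
  res <- cpp_cluster_and_consensus(reads$sequence, params$ct,
                                   band = as.integer(params$band),
                                   k = 8L,
                                   prescreen_min = params$kmer_prescreen)
  ind <- reads$individual[1]
  cl <- res$cluster
  clusters <- tibble::tibble(
    cluster_id = sprintf("%s_c%04d", ind, seq_along(res$centroid)),
    individual = ind,
    centroid_id = reads$id[res$centroid],
    centroid_seq = reads$sequence[res$centroid],
    member_ids = unname(split(reads$id, factor(cl, levels = seq_along(res$centroid)))),
    size = as.integer(tabulate(cl, nbins = length(res$centroid)))
  )
  consensus <- tibble::tibble(
    cluster_id = clusters$cluster_id,
    individual = ind,
    sequence = res$consensus,
    support = clusters$size
  )
  list(clusters = clusters, consensus = consensus)
}

#' Majority consensus of each cluster
#'
#' Every member is globally aligned to its cluster centroid (star alignment,
#' same scoring as [pairwise_identity()]) and projected onto centroid
#' coordinates. Per column the plurality base is taken, ties resolving to
#' the centroid's base; columns in which gaps hold a strict majority are
#' removed. This deliberately simple consensus is sufficient downstream
#' because the indices consume consensus divergence, not fine error
#' structure.
#'
#' @param clusters Cluster tibble from [greedy_cluster()].
#' @param reads The sequence tibble the clusters were built from.
#' @param band Aligner band half-width.
#' @return A tibble `cluster_id`, `individual`, `sequence`, `support`
#'   (number of reads backing the consensus).
#' @export
majority_consensus <- function(clusters, reads, band = 64) {
  stopifnot(nrow(clusters) >= 1)
  seq_of <- setNames(reads$sequence, reads$id)
  cons <- purrr::map_chr(seq_len(nrow(clusters)), function(i) {
    mem <- seq_of[clusters$member_ids[[i]]]
    cpp_consensus(clusters$centroid_seq[i], unname(mem),
                  band = as.integer(band))
  })
  tibble::tibble(
    cluster_id = clusters$cluster_id,
    individual = clusters$individual,
    sequence = cons,
    support = clusters$size
  )
}

#' Assign clusters to loci from centroid and consensus hits
#'
#' A cluster whose centroid and consensus best hits agree is assigned to
#' that locus; if both are present but disagree the cluster is removed
#' (contradictory assignment); with only a centroid hit it is assigned by
#' the centroid; with neither it stays unassigned. Assigned clusters receive
#' sequential ordinals per locus and individual.
#'
#' @param clusters Cluster tibble from [greedy_cluster()].
#' @param centroid_hits Best-hit tibble for centroids, keyed by read id
#'   (`query_id` matches `centroid_id`).
#' @param consensus_hits Optional best-hit tibble for cluster consensuses,
#'   keyed by cluster id (`query_id` matches `cluster_id`).
#' @return `clusters` with added columns `locus_id`, `status` (one of
#'   `"assigned"`, `"removed"`, `"unassigned"`) and `ordinal`.
#' @export
assign_cluster_locus <- function(clusters, centroid_hits,
                                 consensus_hits = NULL) {
  cen <- setNames(centroid_hits$subject_id, centroid_hits$query_id)
  con <- if (is.null(consensus_hits)) character() else
    setNames(consensus_hits$subject_id, consensus_hits$query_id)
  cen_locus <- unname(cen[clusters$centroid_id])
  con_locus <- unname(con[clusters$cluster_id])

  status <- dplyr::case_when(
    !is.na(cen_locus) & !is.na(con_locus) & cen_locus == con_locus ~ "assigned",
    !is.na(cen_locus) & !is.na(con_locus) ~ "removed",
    !is.na(cen_locus) ~ "assigned",
    !is.na(con_locus) ~ "assigned",
    TRUE ~ "unassigned"
  )
  locus <- dplyr::if_else(status == "assigned",
                          dplyr::coalesce(cen_locus, con_locus),
                          NA_character_)
  out <- clusters %>%
    dplyr::mutate(locus_id = locus, status = status) %>%
    dplyr::group_by(.data$locus_id, .data$individual) %>%
    dplyr::mutate(ordinal = dplyr::if_else(.data$status == "assigned",
                                           dplyr::row_number(), NA_integer_)) %>%
    dplyr::ungroup()
  out$ordinal[is.na(out$locus_id)] <- NA_integer_
  out
}

#' Sweep the clustering threshold and summarise cluster structure
#'
#' Re-clusters a fixed read set at each threshold and reports the statistics
#' used to choose a sensible threshold: cluster count, maximum and mean
#' cluster size, singleton fraction, large-cluster fraction and the average
#' identity of members to their centroid. Cluster counts rise and maximum
#' sizes fall as the threshold increases.
#'
#' @param reads Sequence tibble (typically one individual).
#' @param cts Numeric vector of thresholds to test.
#' @param params Base [clustering_params()]; `ct` is overridden per sweep
#'   point.
#' @param large_size Read count from which a cluster counts as "large".
#' @return A tibble with one row per threshold, class `ct_sweep`.
#' @export
ct_sweep <- function(reads, cts = c(0.80, 0.85, 0.88, 0.90, 0.95),
                     params = clustering_params(), large_size = 100) {
  rows <- purrr::map(sort(cts), function(ct) {
    p <- params
    p$ct <- ct
    cl <- greedy_cluster(reads, p)
    seq_of <- setNames(reads$sequence, reads$id)
    ids <- purrr::map2(cl$member_ids, cl$centroid_seq, function(mem, cen) {
      mem_seq <- unname(seq_of[mem])
      purrr::map_dbl(mem_seq, function(s) {
        if (identical(s, cen)) 1.0
        else cpp_align(s, cen, band = as.integer(params$band))$identity
      })
    })
    tibble::tibble(
      ct = ct,
      n_clusters = nrow(cl),
      max_size = max(cl$size),
      mean_size = mean(cl$size),
      pct_singletons = 100 * mean(cl$size == 1),
      pct_large = 100 * mean(cl$size >= large_size),
      mean_within_identity = 100 * mean(unlist(ids))
    )
  })
  structure(purrr::list_rbind(rows), class = c("ct_sweep", "tbl_df", "tbl",
                                               "data.frame"))
}
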