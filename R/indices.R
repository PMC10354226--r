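#' Index 1: mean standardized reads per cluster
#'
#' For each individual i and locus L the read count is divided by the
#' cluster count (complete cluster collection, singletons included). Per
#' individual, the resulting ratios are z-standardized across that
#' individual's loci (population sd); the locus value is the mean z-score
#' over individuals with data. Higher values indicate low within-locus
#' divergence and hence argue for a single-copy locus. Individuals with
#' fewer than two loci, or with zero spread in their ratios, cannot be
#' standardized and are excluded with a warning.
#'
#' @param stats Per-(locus, individual) statistics from [summarize_loci()],
#'   covering all pre-choice loci.
#' @return A tibble `locus_id`, `index1`.
#' @export
index1_reads_per_cluster <- function(stats) {
  z <- stats %>%
    dplyr::mutate(ratio = .data$n_reads / .data$n_clusters) %>%
    dplyr::group_by(.data$individual) %>%
    dplyr::mutate(.n = dplyr::n(), .sd = pop_sd(.data$ratio)) %>%
    dplyr::ungroup()
  bad <- z %>%
    dplyr::filter(.data$.n < 2 | .data$.sd == 0) %>%
    dplyr::distinct(.data$individual)
  if (nrow(bad) > 0) {
    warning("index1: individual(s) excluded (fewer than 2 loci or zero sd): ",
            paste(bad$individual, collapse = ", "))
  }
  z %>%
    dplyr::filter(.data$.n >= 2, .data$.sd > 0) %>%
    dplyr::group_by(.data$individual) %>%
    dplyr::mutate(z = (.data$ratio - mean(.data$ratio)) / pop_sd(.data$ratio)) %>%
    dplyr::group_by(.data$locus_id) %>%
    dplyr::summarise(index1 = mean(.data$z), .groups = "drop")
}

#' Index 2: k-mer-based similarity (KBS) per species
#'
#' Per species s, the mean pairwise distance between that species' own
#' consensuses (W_s; 0 when the species has at most one consensus) is set
#' relative to the mean pairwise distance over all consensus pairs (A):
#' `KBS_s = 100 * (W_s - A) / A`, a percent deviation. Negative values mean
#' the species' sequences cluster together (ortholog-like); the floor of
#' -100 is attained exactly when W_s = 0. The locus score is the mean over
#' species, the spread their population sd. If A = 0 (all consensuses
#' identical) every KBS_s is defined as 0.
#'
#' @param d Symmetric distance matrix over the locus' consensuses.
#' @param species_of Named character vector mapping consensus id (rownames
#'   of `d`) to species.
#' @return A list with `per_species` (named numeric), `mean`, `sd`.
#' @export
kbs_index <- function(d, species_of) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 2) stop("kbs_index: need at least two consensuses")
  sp <- unname(species_of[rownames(d)])
  if (anyNA(sp)) stop("kbs_index: species missing for some consensuses")
  A <- mean(d[upper.tri(d)])
  per <- vapply(unique(sp), function(s) {
    i <- which(sp == s)
    if (length(i) < 2) {
      W <- 0
    } else {
      ds <- d[i, i, drop = FALSE]
      W <- mean(ds[upper.tri(ds)])
    }
    if (A == 0) 0 else 100 * (W - A) / A
  }, numeric(1))
  names(per) <- unique(sp)
  list(per_species = per, mean = mean(per), sd = pop_sd(per))
}

#' Index 3: leaf-count-weighted mean Shannon entropy
#'
#' With n_ik leaves of individual i in clade k and p_ik = n_ik / N_i, the
#' individual's entropy is `H_i = -sum_k p_ik * ln(p_ik)` (with
#' 0 * ln 0 := 0), and the locus value is the weighted mean
#' `H-bar = sum_i H_i * N_i / sum_i N_i`. A value of 0 means every
#' individual's consensuses are confined to a single clade; larger values
#' flag individuals scattered over the dendrogram, a paralogy signal.
#'
#' @param assignment Tibble with columns `individual` and `clade`, one row
#'   per dendrogram leaf (see [cut_dendrogram()]).
#' @return The weighted mean entropy (natural logarithm), >= 0.
#' @export
mean_entropy <- function(assignment) {
  stopifnot(nrow(assignment) > 0,
            all(c("individual", "clade") %in% names(assignment)))
  per <- assignment %>%
    dplyr::count(.data$individual, .data$clade, name = "n_ik") %>%
    dplyr::group_by(.data$individual) %>%
    dplyr::summarise(
      N = sum(.data$n_ik),
      H = {
        p <- .data$n_ik / sum(.data$n_ik)
        -sum(ifelse(p > 0, p * log(p), 0))
      },
      .groups = "drop"
    )
  sum(per$H * per$N) / sum(per$N)
}

#' Compute all four paralogy-diagnostic indices per locus
#'
#' Per locus the pipeline is: k-mer distance matrix over the locus'
#' consensus sequences, single-linkage dendrogram, silhouette-optimal clade
#' number (index 4), entropy of the cut at best K (index 3) and the KBS
#' score with its spread (index 2); index 1 comes from the cluster
#' statistics. Consensuses entering here should already have small clusters
#' removed ([drop_small_clusters()]), while `stats` covers the complete
#' collection. Loci with fewer than two consensuses are skipped with a
#' warning.
#'
#' @param consensus Tibble of consensus sequences with columns `locus_id`,
#'   `cluster_id`, `individual`, `sequence` and optionally `species`
#'   (defaults to `individual`).
#' @param stats Per-(locus, individual) statistics from [summarize_loci()]
#'   for the same loci (complete cluster collection).
#' @param k k-mer length (default 8).
#' @param Kmax Cap on the number of clades evaluated for index 4; default
#'   is one less than the leaf count of each locus.
#' @return A tibble with one row per locus: `locus_id`, `index1`,
#'   `kbs_mean`, `kbs_sd`, `entropy`, `best_k`, `n_consensus`, plus list
#'   columns `kbs_species` and `sil_scores`.
#' @export
compute_all_indices <- function(consensus, stats, k = 8, Kmax = NULL) {
  stopifnot(all(c("locus_id", "cluster_id", "individual", "sequence") %in%
                  names(consensus)))
  if (!"species" %in% names(consensus)) consensus$species <- consensus$individual
  idx1 <- index1_reads_per_cluster(stats)

  per_locus <- consensus %>%
    dplyr::group_by(.data$locus_id) %>%
    dplyr::group_split() %>%
    purrr::map(function(cc) {
      locus <- cc$locus_id[1]
      if (nrow(cc) < 2) {
        warning("locus ", locus, " skipped: fewer than 2 consensuses")
        return(NULL)
      }
      d <- kmer_distance_matrix(
        tibble::tibble(id = cc$cluster_id, sequence = cc$sequence), k = k)
      dend <- single_linkage_dendrogram(d)
      sil <- suppressWarnings(silhouette_best_k(dend, d, Kmax = Kmax))
      cut <- cut_dendrogram(dend, sil$best_k)
      cut$individual <- cc$individual[match(cut$leaf, cc$cluster_id)]
      kbs <- kbs_index(d, setNames(cc$species, cc$cluster_id))
      tibble::tibble(
        locus_id = locus,
        kbs_mean = kbs$mean, kbs_sd = kbs$sd,
        entropy = mean_entropy(cut),
        best_k = sil$best_k,
        n_consensus = nrow(cc),
        kbs_species = list(kbs$per_species),
        sil_scores = list(sil$scores)
      )
    }) %>%
    purrr::compact() %>%
    purrr::list_rbind()

  per_locus %>%
    dplyr::left_join(idx1, by = "locus_id") %>%
    dplyr::select("locus_id", "index1", "kbs_mean", "kbs_sd", "entropy",
                  "best_k", "n_consensus", "kbs_species", "sil_scores")
}

#' Single-linkage dendrogram of one locus' consensus sequences
#'
#' Convenience wrapper for visual inspection: distance matrix plus
#' dendrogram for one locus.
#'
#' @inheritParams compute_all_indices
#' @param locus_id Locus to extract.
#' @return A list with `dendrogram` (`hclust`) and `distances` (matrix).
#' @export
locus_dendrogram <- function(consensus, locus_id, k = 8) {
  cc <- consensus[consensus$locus_id == locus_id, , drop = FALSE]
  if (nrow(cc) < 2) stop("locus_dendrogram: fewer than 2 consensuses")
  d <- kmer_distance_matrix(
    tibble::tibble(id = cc$cluster_id, sequence = cc$sequence), k = k)
  list(dendrogram = single_linkage_dendrogram(d), distances = d)
}
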