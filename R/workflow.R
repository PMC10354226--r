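#' Run the full marker-selection workflow
#'
#' End-to-end orchestration from reads plus locus references to the
#' candidate-locus report: on-target extraction by best hit, greedy
#' clustering per individual, consensus calling, cluster-to-locus
#' assignment (with contradiction handling), per-locus statistics,
#' pre-choice filtering, removal of low-coverage clusters, the four
#' paralogy indices, percentile ranking and the best-K candidate filter.
#' Every stage's counts are recorded in a manifest so that reads and
#' clusters can be audited to sum exactly across stages.
#'
#' @param reads Sequence tibble of demultiplexed reads (column `individual`
#'   set; one value per sequenced sample).
#' @param references Sequence tibble of locus reference sequences (ids are
#'   the locus ids).
#' @param hits Optional hit tibble (12-column standard format, see
#'   [parse_hit_table()]); when `NULL`, a shared-k-mer search against
#'   `references` is used ([kmer_hit_table()]).
#' @param params [clustering_params()].
#' @param rules [prechoice_rules()].
#' @param k k-mer length for distances and the hit search.
#' @param q Proposal percentile threshold (1..99).
#' @param max_best_k Best-K cutoff for the candidate filter.
#' @param species Optional named vector mapping individual to species;
#'   defaults to one species per individual.
#' @param min_cluster_size Clusters below this size are dismissed before
#'   index computation (default 5).
#' @param out_dir Optional output directory for TSV/FASTA/newick
#'   intermediates and the manifest.
#' @return An object of class `marker_run`: a list with `on_target`,
#'   `clusters`, `stats`, `prechoice_loci`, `consensus`, `indices`,
#'   `proposals`, `candidates` and `manifest`. When too few loci survive
#'   pre-choice the run stops early (with a warning) and the later elements
#'   are `NULL`.
#' @export
run_select <- function(reads, references, hits = NULL,
                       params = clustering_params(),
                       rules = prechoice_rules(), k = 8, q = 50,
                       max_best_k = 4, species = NULL,
                       min_cluster_size = 5, out_dir = NULL) {
  validate_seq_tbl(reads)
  validate_seq_tbl(references)
  stopifnot(q >= 1, q <= 99)

  if (is.null(hits)) hits <- kmer_hit_table(reads, references, k = k)
  best <- best_hit_per_query(hits)
  on_target <- extract_on_target(reads, best)

  manifest <- list(
    n_reads = nrow(reads),
    n_on_target = nrow(on_target),
    n_off_target = nrow(reads) - nrow(on_target),
    params = unclass(params), rules = unclass(rules), k = k, q = q,
    max_best_k = max_best_k, min_cluster_size = min_cluster_size
  )
  if (nrow(on_target) == 0) {
    warning("run_select: no on-target reads; stopping before clustering")
    return(finish_run(list(manifest = manifest), out_dir))
  }

  cc <- cluster_with_consensus(on_target, params)
  clusters <- cc$clusters
  consensus_all <- cc$consensus

  centroid_best <- best[best$query_id %in% clusters$centroid_id, , drop = FALSE]
  cons_tbl <- seq_tbl(consensus_all$cluster_id, consensus_all$sequence,
                      consensus_all$individual, role = "consensus")
  consensus_best <- best_hit_per_query(kmer_hit_table(cons_tbl, references,
                                                      k = k))
  assigned <- assign_cluster_locus(clusters, centroid_best, consensus_best)

  manifest$n_clusters <- nrow(assigned)
  manifest$n_assigned <- sum(assigned$status == "assigned")
  manifest$n_removed <- sum(assigned$status == "removed")
  manifest$n_unassigned <- sum(assigned$status == "unassigned")

  ok <- assigned[assigned$status == "assigned", , drop = FALSE]
  stats <- summarize_loci(ok)
  manifest$n_enriched_loci <- dplyr::n_distinct(stats$locus_id)

  pre <- prechoice_filter(stats, rules)
  manifest$n_prechoice_loci <- length(pre)

  res <- list(on_target = on_target, clusters = assigned, stats = stats,
              prechoice_loci = pre, manifest = manifest)
  if (length(pre) < 2) {
    warning("run_select: fewer than 2 pre-choice loci; stopping before indices")
    return(finish_run(res, out_dir))
  }

  big <- drop_small_clusters(ok[ok$locus_id %in% pre, , drop = FALSE],
                             min_size = min_cluster_size)
  consensus <- consensus_all %>%
    dplyr::inner_join(
      dplyr::select(big, "cluster_id", "locus_id"), by = "cluster_id") %>%
    dplyr::mutate(species = if (is.null(species)) .data$individual
                  else unname(species[.data$individual])) %>%
    dplyr::select("locus_id", "cluster_id", "individual", "species",
                  "sequence", "support")

  stats_pre <- stats[stats$locus_id %in% pre, , drop = FALSE]
  indices <- compute_all_indices(consensus, stats_pre, k = k)
  manifest$n_indexed_loci <- nrow(indices)

  if (nrow(indices) < 2) {
    warning("run_select: fewer than 2 loci with indices; stopping before ranking")
    res$consensus <- consensus
    res$manifest <- manifest
    return(finish_run(res, out_dir))
  }

  proposals <- rank_and_propose(indices)
  candidates <- candidate_filter(proposals, indices, q = q,
                                 max_best_k = max_best_k)
  manifest$n_proposed <- length(proposed_at(proposals, q))
  manifest$n_candidates <- length(candidates)

  res$consensus <- consensus
  res$indices <- indices
  res$proposals <- proposals
  res$candidates <- candidates
  res$manifest <- manifest
  finish_run(res, out_dir)
}

finish_run <- function(res, out_dir) {
  res <- structure(res, class = "marker_run")
  if (!is.null(out_dir)) write_run(res, out_dir)
  res
}

write_run <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(res$clusters)) {
    flat <- res$clusters %>%
      dplyr::mutate(member_ids = purrr::map_chr(.data$member_ids, paste,
                                                collapse = ",")) %>%
      dplyr::select(-"centroid_seq")
    readr::write_tsv(flat, file.path(out_dir, "clusters.tsv"))
  }
  if (!is.null(res$stats)) {
    readr::write_tsv(res$stats, file.path(out_dir, "locus_stats.tsv"))
  }
  # one FASTA of member reads per assigned cluster, named by locus,
  # per-locus ordinal and individual
  if (!is.null(res$clusters) && !is.null(res$on_target)) {
    cdir <- file.path(out_dir, "clusters")
    dir.create(cdir, showWarnings = FALSE)
    ok <- res$clusters[res$clusters$status == "assigned", , drop = FALSE]
    seq_of <- setNames(res$on_target$sequence, res$on_target$id)
    for (i in seq_len(nrow(ok))) {
      mem <- ok$member_ids[[i]]
      write_fasta(
        tibble::tibble(id = mem, sequence = unname(seq_of[mem])),
        file.path(cdir, sprintf("%s_%d_%s.fasta", ok$locus_id[i],
                                ok$ordinal[i], ok$individual[i])))
    }
  }
  if (!is.null(res$consensus)) {
    readr::write_tsv(res$consensus, file.path(out_dir, "consensus.tsv"))
    for (locus in unique(res$consensus$locus_id)) {
      cc <- res$consensus[res$consensus$locus_id == locus, , drop = FALSE]
      write_fasta(seq_tbl(cc$cluster_id, cc$sequence, cc$individual,
                          role = "consensus"),
                  file.path(out_dir, paste0(locus, "_consensus.fasta")))
      if (nrow(cc) >= 2) {
        dd <- locus_dendrogram(res$consensus, locus)
        ape::write.tree(ape::as.phylo(dd$dendrogram),
                        file.path(out_dir, paste0(locus, "_dendrogram.nwk")))
      }
    }
  }
  if (!is.null(res$indices)) {
    readr::write_tsv(
      dplyr::select(res$indices, -"kbs_species", -"sil_scores"),
      file.path(out_dir, "indices.tsv"))
  }
  if (!is.null(res$proposals)) {
    readr::write_tsv(res$proposals, file.path(out_dir, "proposals.tsv"))
    writeLines(res$candidates, file.path(out_dir, "candidates.txt"))
  }
  yaml::write_yaml(res$manifest, file.path(out_dir, "manifest.yaml"))
  invisible(out_dir)
}

#' @export
print.marker_run <- function(x, ...) {
  m <- x$manifest
  cat("<marker_run>\n")
  cat("  reads:          ", m$n_reads, " (", m$n_on_target, " on-target)\n",
      sep = "")
  if (!is.null(m$n_clusters)) {
    cat("  clusters:       ", m$n_clusters, " (", m$n_assigned, " assigned, ",
        m$n_removed, " removed, ", m$n_unassigned, " unassigned)\n", sep = "")
  }
  if (!is.null(m$n_prechoice_loci)) {
    cat("  loci:           ", m$n_enriched_loci, " enriched, ",
        m$n_prechoice_loci, " pre-choice\n", sep = "")
  }
  if (!is.null(m$n_candidates)) {
    cat("  proposed at q=", m$q, ": ", m$n_proposed, "; candidates: ",
        m$n_candidates, "\n", sep = "")
  }
  invisible(x)
}

#' Tidy the per-locus results of a marker run
#'
#' One row per ranked locus: the four index values, their percentiles, the
#' proposal threshold and the candidate flag.
#'
#' @param x A `marker_run` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.marker_run <- function(x, ...) {
  if (is.null(x$proposals)) {
    return(tibble::tibble(locus_id = character()))
  }
  x$indices %>%
    dplyr::select("locus_id", "index1", "kbs_mean", "kbs_sd", "entropy",
                  "best_k") %>%
    dplyr::left_join(dplyr::select(x$proposals, -dplyr::any_of("best_k")),
                     by = "locus_id") %>%
    dplyr::mutate(candidate = .data$locus_id %in% x$candidates)
}

#' One-row summary of a marker run
#'
#' @inheritParams tidy.marker_run
#' @return A one-row tibble of stage counts.
#' @export
glance.marker_run <- function(x, ...) {
  m <- x$manifest
  tibble::tibble(
    n_reads = m$n_reads, n_on_target = m$n_on_target,
    n_clusters = m$n_clusters %||% NA_integer_,
    n_assigned = m$n_assigned %||% NA_integer_,
    n_removed = m$n_removed %||% NA_integer_,
    n_unassigned = m$n_unassigned %||% NA_integer_,
    n_enriched_loci = m$n_enriched_loci %||% NA_integer_,
    n_prechoice_loci = m$n_prechoice_loci %||% NA_integer_,
    n_proposed = m$n_proposed %||% NA_integer_,
    n_candidates = m$n_candidates %||% NA_integer_
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
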