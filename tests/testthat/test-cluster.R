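test_that("identical reads form one cluster, lone reads are their own centroid", {
  set.seed(21)
  s <- random_dna(200)
  reads <- seq_tbl_for_test(sprintf("r%d", 1:10), rep(s, 10))
  cl <- greedy_cluster(reads, clustering_params(ct = 0.88))
  expect_equal(nrow(cl), 1)
  expect_equal(cl$size, 10L)
  expect_setequal(cl$member_ids[[1]], reads$id)

  one <- greedy_cluster(reads[1, ], clustering_params())
  expect_equal(nrow(one), 1)
  expect_equal(one$centroid_id, "r1")
  expect_equal(one$size, 1L)

  expect_error(greedy_cluster(reads[0, ], clustering_params()), "no reads")
})

test_that("two divergent read groups separate at CT 0.88 and members satisfy the threshold", {
  set.seed(22)
  reads <- two_group_reads(n_per = 6, len = 400)
  cl <- greedy_cluster(reads[, c("id", "sequence", "individual", "role")],
                       clustering_params(ct = 0.88))
  expect_equal(nrow(cl), 2)
  grp <- setNames(reads$group, reads$id)
  for (i in 1:2) {
    expect_equal(length(unique(grp[cl$member_ids[[i]]])), 1)
  }
  # post-hoc invariant: every member reaches the threshold against its centroid
  seq_of <- setNames(reads$sequence, reads$id)
  for (i in 1:2) {
    for (m in cl$member_ids[[i]]) {
      expect_gte(pairwise_identity(seq_of[[m]], cl$centroid_seq[i], band = 64),
                 0.88)
    }
  }
})

test_that("clustering partitions the reads and is deterministic", {
  set.seed(23)
  reads <- dplyr::bind_rows(
    two_group_reads(n_per = 4, len = 300, individual = "i1"),
    two_group_reads(n_per = 3, len = 300, individual = "i2")
  )
  reads$id <- sprintf("r%02d", seq_len(nrow(reads)))
  p <- clustering_params(ct = 0.88)
  cl1 <- greedy_cluster(reads, p)
  cl2 <- greedy_cluster(reads, p)
  expect_identical(cl1, cl2)
  members <- unlist(cl1$member_ids)
  expect_equal(sort(members), sort(reads$id))       # exhaustive
  expect_equal(anyDuplicated(members), 0L)          # disjoint
  expect_equal(sum(cl1$size), nrow(reads))
  # per-individual clustering: no cluster mixes individuals
  ind_of <- setNames(reads$individual, reads$id)
  purrr::walk(seq_len(nrow(cl1)), function(i) {
    expect_equal(unique(unname(ind_of[cl1$member_ids[[i]]])),
                 cl1$individual[i])
  })
})

test_that("the k-mer prescreen changes nothing on clusterable data", {
  set.seed(24)
  reads <- two_group_reads(n_per = 5, len = 350)
  on <- greedy_cluster(reads, clustering_params(ct = 0.88, kmer_prescreen = 0.05))
  off <- greedy_cluster(reads, clustering_params(ct = 0.88, kmer_prescreen = 0))
  expect_identical(on, off)
})

test_that("raising the threshold never reduces the cluster count", {
  set.seed(25)
  base <- random_dna(300)
  reads <- seq_tbl_for_test(
    sprintf("r%02d", 1:20),
    vapply(1:20, function(i) paralogsieve:::mutate_subs(base, runif(1, 0, 0.2)),
           character(1)))
  counts <- vapply(c(0.7, 0.8, 0.9, 0.95, 1.0), function(ct) {
    nrow(greedy_cluster(reads, clustering_params(ct = ct)))
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("majority consensus votes by column with centroid tie-break", {
  # three identical members reproduce the member sequence
  reads <- seq_tbl_for_test(c("a", "b", "c"), rep("ACGTACGTAC", 3))
  cl <- greedy_cluster(reads, clustering_params())
  cons <- majority_consensus(cl, reads)
  expect_equal(cons$sequence, "ACGTACGTAC")
  expect_equal(cons$support, 3L)

  # {A,A,G} column -> A; centroid wins 2-2 ties
  reads2 <- seq_tbl_for_test(
    c("a", "b", "c"),
    c("AAAAAAAAAA", "AAAAAAAAAA", "AAAAGAAAAA"))
  cl2 <- greedy_cluster(reads2, clustering_params(ct = 0.5))
  expect_equal(nrow(cl2), 1)
  expect_equal(majority_consensus(cl2, reads2)$sequence, "AAAAAAAAAA")

  # gap-majority columns are dropped: two members lack the centroid's tail
  reads3 <- seq_tbl_for_test(
    c("long", "s1", "s2"),
    c("ACGTACGTACGTTTTT", "ACGTACGTACGT", "ACGTACGTACGT"))
  cl3 <- greedy_cluster(reads3, clustering_params(ct = 0.5))
  expect_equal(nrow(cl3), 1)
  expect_equal(majority_consensus(cl3, reads3)$sequence, "ACGTACGTACGT")
})

test_that("fused cluster+consensus equals the two-step composition", {
  set.seed(26)
  reads <- two_group_reads(n_per = 6, len = 300)
  p <- clustering_params(ct = 0.88)
  fused <- paralogsieve:::cluster_with_consensus(reads, p)
  cl <- greedy_cluster(reads, p)
  expect_identical(fused$clusters, cl)
  expect_identical(fused$consensus$sequence,
                   majority_consensus(cl, reads)$sequence)
})

test_that("cluster-to-locus assignment handles agreement, contradiction and centroid-only cases", {
  cl <- dplyr::bind_rows(
    make_clusters("X", "i1", c(5, 5)),
    make_clusters("Y", "i1", 5)
  )
  cl$locus_id <- NULL; cl$status <- NULL; cl$ordinal <- NULL
  centroid_hits <- tibble::tibble(
    query_id = cl$centroid_id,
    subject_id = c("At3g05230", "At3g05230", "At1g01050"))
  consensus_hits <- tibble::tibble(
    query_id = cl$cluster_id[1:2],
    subject_id = c("At3g05230", "At9g99999"))  # agree / contradict
  out <- assign_cluster_locus(cl, centroid_hits, consensus_hits)
  expect_equal(out$status, c("assigned", "removed", "assigned"))
  expect_equal(out$locus_id, c("At3g05230", NA, "At1g01050"))
  expect_equal(out$ordinal[1], 1L)
  expect_true(is.na(out$ordinal[2]))

  # sequential ordinals per locus and individual
  cl2 <- make_clusters("Z", "i1", c(5, 5, 5))
  cl2$locus_id <- NULL; cl2$status <- NULL; cl2$ordinal <- NULL
  ch <- tibble::tibble(query_id = cl2$centroid_id, subject_id = "At2g28315")
  out2 <- assign_cluster_locus(cl2, ch)
  expect_equal(out2$ordinal, 1:3)

  # no hits at all -> unassigned
  out3 <- assign_cluster_locus(cl2, ch[0, ])
  expect_true(all(out3$status == "unassigned"))
})
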