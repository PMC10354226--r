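test_that("k-mer distance matches brute-force enumeration and its bounds", {
  expect_equal(kmer_distance("ACGTACGTAC", "ACGTACGTAC"), 0)
  expect_equal(kmer_distance("ACGTACGTAC", "ACGTACGTAA"), 1 / 3)
  # no shared 8-mer
  expect_equal(kmer_distance(strrep("A", 20), strrep("C", 20)), 1)
  expect_error(kmer_distance("ACGT", "ACGTACGT"), "shorter than k")

  set.seed(51)
  for (i in 1:10) {
    a <- random_dna(60)
    b <- mutate_read(a, 0.1, 0.02, 0.02)
    expect_equal(kmer_distance(a, b), oracle_kmer_distance(a, b))
    expect_equal(kmer_distance(a, b), kmer_distance(b, a))
    expect_gte(kmer_distance(a, b), 0)
    expect_lte(kmer_distance(a, b), 1)
  }
})

test_that("single-linkage dendrograms agglomerate by minimum distance", {
  d2 <- matrix(c(0, 0.3, 0.3, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  h2 <- single_linkage_dendrogram(d2)
  expect_equal(h2$height, 0.3)

  d3 <- matrix(c(0, 0.1, 0.5,
                 0.1, 0, 0.5,
                 0.5, 0.5, 0), 3, 3,
               dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  h3 <- single_linkage_dendrogram(d3)
  expect_equal(h3$height, c(0.1, 0.5))
  expect_equal(sort(h3$labels[-h3$merge[1, ]]), c("x", "y"))

  # duplicate rows merge first at height zero
  d0 <- matrix(0.4, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  diag(d0) <- 0
  d0["a", "b"] <- d0["b", "a"] <- 0
  expect_equal(single_linkage_dendrogram(d0)$height[1], 0)

  expect_error(single_linkage_dendrogram(d3[1, 1, drop = FALSE]), ">= 2")
  dneg <- d3; dneg[1, 2] <- dneg[2, 1] <- -0.1
  expect_error(single_linkage_dendrogram(dneg), "negative")
  dasym <- d3; dasym[1, 2] <- 0.2
  expect_error(single_linkage_dendrogram(dasym), "asymmetric")
})

test_that("dendrogram cuts produce exactly K clades following merge order", {
  d3 <- matrix(c(0, 0.1, 0.5,
                 0.1, 0, 0.5,
                 0.5, 0.5, 0), 3, 3,
               dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  h3 <- single_linkage_dendrogram(d3)
  expect_equal(length(unique(cut_dendrogram(h3, 1)$clade)), 1)
  expect_equal(length(unique(cut_dendrogram(h3, 3)$clade)), 3)
  cut2 <- cut_dendrogram(h3, 2)
  byclade <- split(cut2$leaf, cut2$clade)
  expect_true(any(vapply(byclade, function(s) setequal(s, c("x", "y")), logical(1))))
  expect_error(cut_dendrogram(h3, 4), "out of range")
  expect_error(cut_dendrogram(h3, 0), "out of range")

  # exactly K components for all valid K on a random matrix
  set.seed(52)
  n <- 9
  dm <- matrix(runif(n * n), n, n); dm <- (dm + t(dm)) / 2; diag(dm) <- 0
  dimnames(dm) <- list(letters[1:n], letters[1:n])
  hh <- single_linkage_dendrogram(dm)
  for (K in 1:n) {
    expect_equal(length(unique(cut_dendrogram(hh, K)$clade)), K)
  }
})

test_that("silhouette picks the planted number of groups", {
  set.seed(53)
  centers <- c(0, 10, 20)
  pts <- rep(centers, each = 4) + runif(12, -0.5, 0.5)
  d <- as.matrix(stats::dist(pts)) / 25
  dimnames(d) <- list(sprintf("l%02d", 1:12), sprintf("l%02d", 1:12))
  h <- single_linkage_dendrogram(d)
  res <- silhouette_best_k(h, d)
  expect_equal(res$best_k, 3L)

  pts2 <- c(0, 0.2, 30, 30.2)
  d2 <- as.matrix(stats::dist(pts2)) / 40
  dimnames(d2) <- list(letters[1:4], letters[1:4])
  expect_equal(silhouette_best_k(single_linkage_dendrogram(d2), d2)$best_k, 2L)

  # all distances equal: no structure, tie-break to the smallest K
  deq <- matrix(0.5, 5, 5, dimnames = list(letters[1:5], letters[1:5]))
  diag(deq) <- 0
  resq <- silhouette_best_k(single_linkage_dendrogram(deq), deq)
  expect_equal(resq$best_k, 2L)
  expect_true(all(resq$scores <= 0))

  expect_warning(
    silhouette_best_k(single_linkage_dendrogram(d2[1:2, 1:2]), d2[1:2, 1:2]),
    "fewer than 3")
})

test_that("mean entropy reproduces the analytic cases", {
  one_clade <- tibble::tibble(individual = rep(c("a", "b"), each = 3),
                              clade = rep(1:2, each = 3))
  expect_equal(mean_entropy(one_clade), 0)

  split2 <- tibble::tibble(individual = "a", clade = c(1, 2))
  expect_equal(mean_entropy(split2), log(2))

  weighted <- tibble::tibble(individual = c(rep("A", 4), "B", "B"),
                             clade = c(1, 1, 1, 1, 1, 2))
  expect_equal(mean_entropy(weighted), (0 * 4 + log(2) * 2) / 6)

  # bound: 0 <= H <= ln(K) for random assignments
  set.seed(54)
  for (i in 1:20) {
    K <- sample(2:6, 1)
    asg <- tibble::tibble(
      individual = sample(letters[1:4], 30, replace = TRUE),
      clade = sample(seq_len(K), 30, replace = TRUE))
    h <- mean_entropy(asg)
    expect_gte(h, 0)
    expect_lte(h, log(K) + 1e-12)
  }
})

test_that("KBS index hits its analytic floor and degenerate cases", {
  # 2 species x 2 consensuses, within 0, across 0.5
  d <- matrix(0.5, 4, 4)
  diag(d) <- 0
  d[1, 2] <- d[2, 1] <- 0
  d[3, 4] <- d[4, 3] <- 0
  dimnames(d) <- list(c("a1", "a2", "b1", "b2"), c("a1", "a2", "b1", "b2"))
  sp <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B")
  res <- kbs_index(d, sp)
  expect_equal(unname(res$per_species), c(-100, -100))
  expect_equal(res$mean, -100)
  expect_equal(res$sd, 0)

  # all consensuses identical: A = 0 -> all scores 0
  dz <- matrix(0, 3, 3, dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  resz <- kbs_index(dz, c(x = "A", y = "B", z = "C"))
  expect_equal(unname(resz$per_species), c(0, 0, 0))

  expect_error(kbs_index(dz[1, 1, drop = FALSE], c(x = "A")), "two consensuses")

  # floor property: KBS >= -100, equality iff within-species mean is 0
  set.seed(55)
  for (i in 1:10) {
    n <- 6
    dm <- matrix(runif(n * n, 0.1, 0.9), n, n); dm <- (dm + t(dm)) / 2
    diag(dm) <- 0
    ids <- sprintf("c%d", 1:n)
    dimnames(dm) <- list(ids, ids)
    spp <- setNames(rep(c("A", "B", "C"), each = 2), ids)
    r <- kbs_index(dm, spp)
    expect_true(all(r$per_species >= -100))
  }
})

test_that("index-1 z-scores are centred with unit population sd per individual", {
  stats <- dplyr::bind_rows(
    summarize_loci(make_clusters("L1", "i1", 10)),
    summarize_loci(make_clusters("L2", "i1", c(10, 10))))
  # ratios 10 and 20/2=10 would be degenerate; use distinct ratios
  stats$n_reads <- c(10L, 20L)
  stats$n_clusters <- c(1L, 1L)
  idx <- index1_reads_per_cluster(stats)
  expect_equal(idx$index1[idx$locus_id == "L1"], -1)  # population sd of {10,20}
  expect_equal(idx$index1[idx$locus_id == "L2"], 1)

  set.seed(56)
  big <- purrr::list_rbind(purrr::map(1:8, function(l) {
    purrr::list_rbind(purrr::map(1:3, function(i) {
      s <- summarize_loci(make_clusters(sprintf("L%d", l), sprintf("i%d", i),
                                        sample(5:30, sample(2:5, 1), TRUE)))
      s
    }))
  }))
  z <- big %>%
    dplyr::mutate(ratio = n_reads / n_clusters) %>%
    dplyr::group_by(individual) %>%
    dplyr::mutate(z = (ratio - mean(ratio)) / paralogsieve:::pop_sd(ratio))
  per_ind <- z %>%
    dplyr::summarise(m = mean(z), s = paralogsieve:::pop_sd(z))
  expect_true(all(abs(per_ind$m) < 1e-9))
  expect_true(all(abs(per_ind$s - 1) < 1e-9))
  # and the locus index is the mean of those z-scores
  idx_big <- index1_reads_per_cluster(big)
  manual <- z %>%
    dplyr::group_by(locus_id) %>%
    dplyr::summarise(index1 = mean(z))
  expect_equal(idx_big, manual)
})

test_that("individuals without spread are excluded from index 1 with a warning", {
  stats <- dplyr::bind_rows(
    summarize_loci(make_clusters("L1", "flat", 10)),
    summarize_loci(make_clusters("L2", "flat", 10)),
    summarize_loci(make_clusters("L1", "ok", 5)),
    summarize_loci(make_clusters("L2", "ok", c(6, 6))))
  stats$n_reads[stats$individual == "ok"] <- c(10L, 30L)
  stats$n_clusters[stats$individual == "ok"] <- c(1L, 1L)
  expect_warning(idx <- index1_reads_per_cluster(stats), "flat")
  expect_equal(sort(idx$index1), c(-1, 1))
})

test_that("per-locus index computation composes the analytic floor cases", {
  set.seed(57)
  # every individual contributes one distinct consensus
  cons <- tibble::tibble(
    locus_id = "L1",
    cluster_id = sprintf("i%d_c1", 1:4),
    individual = sprintf("i%d", 1:4),
    sequence = vapply(1:4, function(i) random_dna(150), character(1)))
  stats <- purrr::list_rbind(purrr::map(1:4, function(i) {
    s <- summarize_loci(make_clusters("L1", sprintf("i%d", i), c(20, 10)))
    dplyr::bind_rows(s, summarize_loci(make_clusters("L2", sprintf("i%d", i), 12)))
  }))
  rows <- compute_all_indices(
    dplyr::bind_rows(cons,
                     tibble::tibble(locus_id = "L2",
                                    cluster_id = sprintf("i%d_cx", 1:4),
                                    individual = sprintf("i%d", 1:4),
                                    sequence = cons$sequence)),
    stats)
  r1 <- rows[rows$locus_id == "L1", ]
  expect_equal(r1$kbs_mean, -100)
  expect_equal(r1$kbs_sd, 0)
  expect_equal(r1$entropy, 0)
  expect_gte(r1$best_k, 2)

  # deterministic
  rows2 <- compute_all_indices(
    dplyr::bind_rows(cons,
                     tibble::tibble(locus_id = "L2",
                                    cluster_id = sprintf("i%d_cx", 1:4),
                                    individual = sprintf("i%d", 1:4),
                                    sequence = cons$sequence)),
    stats)
  expect_identical(rows, rows2)

  # a locus with a single consensus is skipped with a warning
  lone <- tibble::tibble(locus_id = "L3", cluster_id = "i1_c9",
                         individual = "i1", sequence = random_dna(150))
  expect_warning(
    out <- compute_all_indices(dplyr::bind_rows(cons, lone), stats),
    "fewer than 2")
  expect_false("L3" %in% out$locus_id)
})

test_that("a synthetic duplicated locus scores worse than a single-copy locus", {
  set.seed(58)
  anc <- random_dna(400)
  copies <- c(paralogsieve:::mutate_subs(anc, 0.05),
              paralogsieve:::mutate_subs(anc, 0.05))
  dup <- tibble::tibble(
    locus_id = "dup",
    cluster_id = sprintf("i%d_c%d", rep(1:4, each = 2), rep(1:2, 4)),
    individual = sprintf("i%d", rep(1:4, each = 2)),
    sequence = vapply(rep(1:2, 4), function(ci)
      paralogsieve:::mutate_subs(copies[ci], 0.01), character(1)))
  single <- tibble::tibble(
    locus_id = "single",
    cluster_id = sprintf("i%d_s1", 1:4),
    individual = sprintf("i%d", 1:4),
    sequence = vapply(1:4, function(i) paralogsieve:::mutate_subs(anc, 0.01),
                      character(1)))
  stats <- purrr::list_rbind(purrr::map(1:4, function(i) {
    dplyr::bind_rows(
      summarize_loci(make_clusters("dup", sprintf("i%d", i), c(10, 10))),
      summarize_loci(make_clusters("single", sprintf("i%d", i), 15)))
  }))
  rows <- compute_all_indices(dplyr::bind_rows(dup, single), stats)
  expect_gt(rows$entropy[rows$locus_id == "dup"],
            rows$entropy[rows$locus_id == "single"])
  expect_gt(rows$kbs_mean[rows$locus_id == "dup"],
            rows$kbs_mean[rows$locus_id == "single"])
})
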