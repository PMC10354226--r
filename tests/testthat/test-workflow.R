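workflow_dataset <- function(seed = 5) {
  simulate_dataset(synth_config(
    n_loci = 6, reads_per_copy = 10, locus_length = 400,
    error_sub = 0.02, error_ins = 0.01, error_del = 0.01, seed = seed))
}

test_that("stage counts are conserved through the pipeline", {
  d <- workflow_dataset()
  run <- run_select(d$reads, d$references,
                    params = clustering_params(ct = 0.88),
                    rules = prechoice_rules(min_reads = 20))
  g <- glance(run)
  expect_equal(g$n_reads, g$n_on_target + run$manifest$n_off_target)
  expect_equal(g$n_clusters, g$n_assigned + g$n_removed + g$n_unassigned)
  expect_equal(sum(run$stats$n_reads), sum(run$clusters$size[
    run$clusters$status == "assigned"]))
  expect_equal(g$n_candidates, length(run$candidates))
  expect_lte(g$n_candidates, g$n_proposed)
})

test_that("identical configuration and seed reproduce the report", {
  d <- workflow_dataset()
  run1 <- run_select(d$reads, d$references,
                     params = clustering_params(ct = 0.88),
                     rules = prechoice_rules(min_reads = 20))
  run2 <- run_select(d$reads, d$references,
                     params = clustering_params(ct = 0.88),
                     rules = prechoice_rules(min_reads = 20))
  expect_identical(tidy(run1), tidy(run2))
  expect_identical(run1$candidates, run2$candidates)
})

test_that("a purely single-copy noiseless dataset passes with zero entropy everywhere", {
  d <- simulate_dataset(synth_config(
    n_loci = 5, duplicated_fraction = 0, reads_per_copy = 10,
    locus_length = 400, error_sub = 0, error_ins = 0, error_del = 0,
    seed = 13))
  run <- run_select(d$reads, d$references,
                    params = clustering_params(ct = 0.88),
                    rules = prechoice_rules(min_reads = 20))
  td <- tidy(run)
  expect_equal(nrow(td), 5)
  expect_true(all(td$entropy == 0))
  expect_true(all(td$kbs_mean == -100))
  # at q = 50 all loci tie on three criteria; candidates are the proposed set
  expect_setequal(run$candidates, proposed_at(run$proposals, 50))
  expect_gte(length(run$candidates), 1)
})

test_that("degenerate inputs abort gracefully with counts preserved", {
  d <- workflow_dataset()
  # references that match nothing: no on-target reads
  refs <- seq_tbl_for_test(c("R1", "R2"),
                           c(random_dna(300), random_dna(300)))
  expect_warning(
    run <- run_select(d$reads, refs, params = clustering_params(ct = 0.88)),
    "no on-target")
  expect_equal(run$manifest$n_on_target, 0)
  expect_null(run$candidates)
  expect_equal(glance(run)$n_reads, nrow(d$reads))

  # pre-choice starves: read bounds impossible to satisfy
  expect_warning(
    run2 <- run_select(d$reads, d$references,
                       params = clustering_params(ct = 0.88),
                       rules = prechoice_rules(min_reads = 10000,
                                               max_reads = 10001)),
    "fewer than 2 pre-choice")
  expect_equal(run2$manifest$n_prechoice_loci, 0)
})

test_that("run artefacts are written as plain text", {
  d <- workflow_dataset()
  dir <- withr::local_tempdir()
  run <- run_select(d$reads, d$references,
                    params = clustering_params(ct = 0.88),
                    rules = prechoice_rules(min_reads = 20),
                    out_dir = dir)
  expect_true(file.exists(file.path(dir, "clusters.tsv")))
  expect_true(file.exists(file.path(dir, "locus_stats.tsv")))
  expect_true(file.exists(file.path(dir, "indices.tsv")))
  expect_true(file.exists(file.path(dir, "proposals.tsv")))
  expect_true(file.exists(file.path(dir, "manifest.yaml")))
  percluster <- list.files(file.path(dir, "clusters"),
                           pattern = "^L[0-9]+_[0-9]+_sp[0-9]+\\.fasta$")
  expect_gte(length(percluster), 1)
  nwk <- list.files(dir, pattern = "_dendrogram\\.nwk$")
  expect_gte(length(nwk), 1)
  tr <- ape::read.tree(file.path(dir, nwk[1]))
  expect_s3_class(tr, "phylo")
})

test_that("plots build from a finished run", {
  d <- workflow_dataset()
  run <- run_select(d$reads, d$references,
                    params = clustering_params(ct = 0.88),
                    rules = prechoice_rules(min_reads = 20))
  expect_s3_class(autoplot(run), "ggplot")
  expect_s3_class(plot_proposal_curve(run$proposals), "ggplot")
  dd <- locus_dendrogram(run$consensus, run$indices$locus_id[1])
  expect_s3_class(plot_dendrogram(dd$dendrogram), "ggplot")
})
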