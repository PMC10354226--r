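#' Configuration for the synthetic target-capture generator
#'
#' The generator emulates a small target-capture experiment: several
#' diploid species (one sequenced individual each) diverging on a fixed
#' balanced species tree, loci that are either single-copy or carry one
#' duplication predating speciation, and full-length long reads carrying
#' substitution/indel errors (the defaults total ~12%, the raw error rate
#' of the emulated chemistry).
#'
#' @param n_species Number of species / individuals (default 4, mirroring a
#'   four-individual capture design).
#' @param n_loci Number of loci (default 40).
#' @param locus_length Locus length in bp (default 1500).
#' @param species_divergence Expected substitutions per site from root to
#'   tip of the balanced species tree (default 0.02).
#' @param duplicated_fraction Fraction of loci carrying one duplication
#'   (default 0.5: 20 single-copy plus 20 duplicated loci).
#' @param duplication_divergence Expected substitutions per site between
#'   the two copies of a duplicated locus (default 0.10).
#' @param reads_per_copy Mean of the Poisson read count drawn per species
#'   and copy (default 40).
#' @param error_sub,error_ins,error_del Per-base read error rates
#'   (defaults 0.06, 0.03, 0.03).
#' @param seed Integer seed; the whole dataset is reproducible from it.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_species = 4, n_loci = 40, locus_length = 1500,
                         species_divergence = 0.02,
                         duplicated_fraction = 0.5,
                         duplication_divergence = 0.10,
                         reads_per_copy = 40,
                         error_sub = 0.06, error_ins = 0.03,
                         error_del = 0.03, seed = 1) {
  stopifnot(n_species >= 1, n_loci >= 1, locus_length > 80,
            species_divergence >= 0, species_divergence < 1,
            duplicated_fraction >= 0, duplicated_fraction <= 1,
            duplication_divergence >= 0, duplication_divergence < 1,
            reads_per_copy > 0,
            error_sub >= 0, error_ins >= 0, error_del >= 0,
            error_sub + error_ins + error_del < 1)
  structure(as.list(environment()), class = "synth_config")
}

#' Simulate a target-capture dataset with known copy-number ground truth
#'
#' Per locus an ancestral sequence is drawn i.i.d. uniform over ACGT and
#' evolved along a balanced species tree by per-site substitution.
#' Duplicated loci are duplicated before speciation, the two copies
#' diverging by `duplication_divergence` between them; each copy then
#' evolves down the species tree independently. Per species and copy a
#' Poisson number of full-length, error-mutated reads is emitted, and the
#' clean ancestral sequence of each locus stands in for the probe/EST
#' reference. Fully reproducible from `config$seed`.
#'
#' @param config A [synth_config()] object.
#' @param out_dir Optional directory; when given, one FASTA per individual,
#'   a reference FASTA, a truth TSV and a YAML echo of the configuration
#'   are written there.
#' @return A list of class `synth_dataset` with elements `reads`,
#'   `references` (sequence tibbles), `truth` (tibble `read_id`,
#'   `locus_id`, `individual`, `copy`, `copy_number`) and `config`.
#' @export
simulate_dataset <- function(config = synth_config(), out_dir = NULL) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  sp <- sprintf("sp%d", seq_len(config$n_species))
  loci <- sprintf("L%03d", seq_len(config$n_loci))
  n_dup <- round(config$duplicated_fraction * config$n_loci)
  is_dup <- seq_len(config$n_loci) <= n_dup  # first loci duplicated, by design

  refs <- character(config$n_loci)
  read_rows <- vector("list", config$n_loci)
  truth_rows <- vector("list", config$n_loci)

  for (li in seq_len(config$n_loci)) {
    anc <- random_dna(config$locus_length)
    refs[li] <- anc
    copies <- if (is_dup[li]) {
      list(`1` = mutate_subs(anc, config$duplication_divergence / 2),
           `2` = mutate_subs(anc, config$duplication_divergence / 2))
    } else {
      list(`1` = anc)
    }
    # evolve each copy down the balanced species tree
    tip_seqs <- lapply(copies, function(s) {
      evolve_balanced(s, config$n_species, config$species_divergence)
    })
    rr <- list()
    tr <- list()
    for (ci in seq_along(tip_seqs)) {
      for (si in seq_len(config$n_species)) {
        nread <- stats::rpois(1, config$reads_per_copy)
        if (nread == 0) next
        seqs <- vapply(seq_len(nread), function(j) {
          mutate_read(tip_seqs[[ci]][si], config$error_sub,
                      config$error_ins, config$error_del)
        }, character(1))
        keep <- nzchar(seqs)
        if (!any(keep)) next
        ids <- sprintf("%s_%s_c%d_r%03d", sp[si], loci[li], ci,
                       seq_len(nread))[keep]
        rr[[length(rr) + 1]] <- tibble::tibble(
          id = ids, sequence = seqs[keep], individual = sp[si], role = "read")
        tr[[length(tr) + 1]] <- tibble::tibble(
          read_id = ids, locus_id = loci[li], individual = sp[si],
          copy = ci, copy_number = length(tip_seqs))
      }
    }
    read_rows[[li]] <- purrr::list_rbind(rr)
    truth_rows[[li]] <- purrr::list_rbind(tr)
  }

  out <- structure(list(
    reads = purrr::list_rbind(read_rows),
    references = tibble::tibble(id = loci, sequence = refs,
                                individual = NA_character_,
                                role = "reference"),
    truth = purrr::list_rbind(truth_rows),
    config = config
  ), class = "synth_dataset")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (s in unique(out$reads$individual)) {
      write_fasta(out$reads[out$reads$individual == s, ],
                  file.path(out_dir, paste0(s, ".fasta")))
    }
    write_fasta(out$references, file.path(out_dir, "references.fasta"))
    readr::write_tsv(out$truth, file.path(out_dir, "truth.tsv"))
    yaml::write_yaml(unclass(config), file.path(out_dir, "config.yaml"))
  }
  out
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# substitution-only divergence: each site mutates to one of the three other
# bases with probability p (expected substitutions/site ~ p for small p)
mutate_subs <- function(seq, p) {
  if (p <= 0) return(seq)
  b <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- stats::runif(length(b)) < p
  if (any(hit)) {
    code <- match(b[hit], c("A", "C", "G", "T"))
    shift <- sample(1:3, sum(hit), replace = TRUE)
    b[hit] <- c("A", "C", "G", "T")[(code - 1 + shift) %% 4 + 1]
  }
  paste(b, collapse = "")
}

# evolve a sequence to n tips along a balanced tree with total root-to-tip
# substitution expectation `div`; returns a character vector of tip sequences
evolve_balanced <- function(seq, n, div) {
  if (n == 1) return(mutate_subs(seq, div))
  depth <- ceiling(log2(n))
  step <- div / depth
  rec <- function(s, idx, d) {
    if (length(idx) == 1 || d == 0) {
      res <- mutate_subs(s, step * d)  # spend remaining depth on the tip
      return(setNames(rep(res, length(idx)), idx))
    }
    half <- ceiling(length(idx) / 2)
    left <- rec(mutate_subs(s, step), idx[seq_len(half)], d - 1)
    right <- rec(mutate_subs(s, step), idx[-seq_len(half)], d - 1)
    c(left, right)
  }
  unname(rec(seq, as.character(seq_len(n)), depth)[as.character(seq_len(n))])
}

#' Apply a long-read error model to a sequence
#'
#' Per position the base is substituted (uniformly to another base) with
#' probability `sub`, deleted with probability `del`, and followed by a
#' uniformly drawn inserted base with probability `ins`; the expected edit
#' fraction is approximately `sub + ins + del`.
#'
#' @param seq DNA string.
#' @param sub,ins,del Error rates in [0, 1).
#' @return The mutated read (possibly empty when `del` is extreme).
#' @export
mutate_read <- function(seq, sub = 0.06, ins = 0.03, del = 0.03) {
  n <- nchar(seq)
  if (n == 0) return(seq)
  b <- strsplit(seq, "", fixed = TRUE)[[1]]
  acgt <- c("A", "C", "G", "T")
  do_sub <- stats::runif(n) < sub
  if (any(do_sub)) {
    code <- match(b[do_sub], acgt)
    shift <- sample(1:3, sum(do_sub), replace = TRUE)
    b[do_sub] <- acgt[(code - 1 + shift) %% 4 + 1]
  }
  do_del <- stats::runif(n) < del
  do_ins <- stats::runif(n) < ins
  inserts <- character(n)
  if (any(do_ins)) {
    inserts[do_ins] <- sample(acgt, sum(do_ins), replace = TRUE)
  }
  kept <- ifelse(do_del, "", b)
  paste(paste0(kept, inserts), collapse = "")
}
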