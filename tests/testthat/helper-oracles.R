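# Independent oracles and small fixture builders used across the suite.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Quadratic affine-gap (Gotoh) global alignment oracle in plain R.
# Same scoring contract as the package aligner (match +1, mismatch -1, a gap
# of length L costs open + L * ext) and the same deterministic preferences
# (final state M > X > Y; M predecessors M > X > Y; X predecessors M > X > Y;
# Y predecessors M > Y > X), so score AND identity must agree exactly.
oracle_align <- function(a, b, match = 1, mismatch = -1, open = 2, ext = 1) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A)
  m <- length(B)
  NEG <- -1e9
  go <- open + ext
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)
  Y <- matrix(NEG, n + 1, m + 1)
  tM <- matrix(NA_integer_, n + 1, m + 1)
  tX <- matrix(NA_integer_, n + 1, m + 1)
  tY <- matrix(NA_integer_, n + 1, m + 1)
  M[1, 1] <- 0
  for (j in 2:(m + 1)) {
    v <- c(M[1, j - 1] - go, NEG, Y[1, j - 1] - ext)
    tY[1, j] <- which.max(v)  # ties: earlier index = M-first
    Y[1, j] <- max(v)
  }
  for (i in 2:(n + 1)) {
    v <- c(M[i - 1, 1] - go, X[i - 1, 1] - ext, NEG)
    tX[i, 1] <- which.max(v)
    X[i, 1] <- max(v)
    for (j in 2:(m + 1)) {
      s <- if (A[i - 1] == B[j - 1]) match else mismatch
      vd <- c(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1])
      tM[i, j] <- which.max(vd)
      M[i, j] <- max(vd) + s
      vx <- c(M[i - 1, j] - go, X[i - 1, j] - ext, Y[i - 1, j] - go)
      tX[i, j] <- which.max(vx)
      X[i, j] <- max(vx)
      # preference M, then Y, then X (matches the package aligner)
      vy <- c(M[i, j - 1] - go, Y[i, j - 1] - ext, X[i, j - 1] - go)
      ty <- which.max(vy)
      tY[i, j] <- c(1L, 3L, 2L)[ty]  # report in M/X/Y coding
      Y[i, j] <- max(vy)
    }
  }
  fin <- c(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
  state <- which.max(fin)
  score <- max(fin)
  i <- n; j <- m
  matches <- 0L; columns <- 0L
  while (i > 0 || j > 0) {
    columns <- columns + 1L
    if (state == 1) {
      if (A[i] == B[j]) matches <- matches + 1L
      state <- tM[i + 1, j + 1]
      i <- i - 1; j <- j - 1
    } else if (state == 2) {
      state <- tX[i + 1, j + 1]
      i <- i - 1
    } else {
      state <- tY[i + 1, j + 1]
      j <- j - 1
    }
  }
  list(score = score, identity = matches / columns)
}

# Brute-force k-mer distance by substring enumeration (no Biostrings).
oracle_kmer_distance <- function(a, b, k = 8) {
  kmers <- function(s) {
    n <- nchar(s)
    vapply(seq_len(n - k + 1), function(i) substr(s, i, i + k - 1),
           character(1))
  }
  ka <- table(kmers(a))
  kb <- table(kmers(b))
  common <- intersect(names(ka), names(kb))
  shared <- sum(pmin(ka[common], kb[common]))
  1 - shared / (min(nchar(a), nchar(b)) - k + 1)
}

# Silhouette-based best-K oracle built on the cluster package (independent
# of the package's hand-coded silhouette).
oracle_best_k <- function(dend, d, Kmax = NULL) {
  n <- nrow(d)
  Kmax <- min(Kmax %||% (n - 1), n - 1)
  scores <- vapply(2:Kmax, function(K) {
    cl <- stats::cutree(dend, k = K)[rownames(d)]
    sil <- cluster::silhouette(cl, dmatrix = d)
    mean(sil[, "sil_width"])
  }, numeric(1))
  as.integer((2:Kmax)[which.max(scores)])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Two well-separated read groups: high identity within, ~65-70% across.
two_group_reads <- function(n_per = 5, len = 400, individual = "ind1") {
  base_a <- random_dna(len)
  base_b <- paralogsieve:::mutate_subs(base_a, 0.35)
  seqs <- c(
    vapply(seq_len(n_per), function(i) paralogsieve:::mutate_subs(base_a, 0.02),
           character(1)),
    vapply(seq_len(n_per), function(i) paralogsieve:::mutate_subs(base_b, 0.02),
           character(1))
  )
  tibble::tibble(
    id = sprintf("r%02d", seq_along(seqs)),
    sequence = seqs,
    individual = individual,
    role = "read",
    group = rep(c("A", "B"), each = n_per)
  )
}

# Minimal cluster tibble for stats tests.
make_clusters <- function(locus, individual, sizes) {
  n <- length(sizes)
  tibble::tibble(
    cluster_id = sprintf("%s_%s_c%d", individual, locus, seq_len(n)),
    individual = individual,
    centroid_id = sprintf("%s_%s_cent%d", individual, locus, seq_len(n)),
    centroid_seq = "ACGT",
    member_ids = lapply(sizes, function(s) sprintf("m%d", seq_len(s))),
    size = as.integer(sizes),
    locus_id = locus,
    status = "assigned",
    ordinal = seq_len(n)
  )
}

seq_tbl_for_test <- function(id, sequence, individual = "ind1") {
  tibble::tibble(id = id, sequence = sequence, individual = individual,
                 role = "read")
}
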