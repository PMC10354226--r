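#' Single-linkage dendrogram from a distance matrix
#'
#' Standard single-linkage agglomeration; merge heights equal the minimum
#' inter-cluster distance and are non-decreasing. Single linkage is chosen
#' deliberately: it lets shorter consensuses (covering only part of a locus)
#' chain together with full-length ones, damping artificial splitting.
#'
#' @param d Symmetric distance matrix with zero diagonal and at least two
#'   leaves (dimnames used as leaf labels).
#' @return An object of class `hclust`.
#' @export
single_linkage_dendrogram <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 2) stop("single_linkage_dendrogram: need >= 2 leaves")
  if (any(d < 0)) stop("single_linkage_dendrogram: negative distances")
  if (max(abs(d - t(d))) > 1e-12) {
    stop("single_linkage_dendrogram: asymmetric distance matrix")
  }
  if (any(diag(d) != 0)) {
    stop("single_linkage_dendrogram: nonzero diagonal")
  }
  stats::hclust(stats::as.dist(d), method = "single")
}

#' Cut a dendrogram into K clades
#'
#' Removes the K-1 highest merges (ties resolved by removing later merges
#' first, i.e. cutting follows the merge order), leaving exactly K connected
#' components.
#'
#' @param dend An `hclust` object.
#' @param K Number of clades, between 1 and the number of leaves.
#' @return A tibble `leaf`, `clade` (clade ids 1..K).
#' @export
cut_dendrogram <- function(dend, K) {
  stopifnot(inherits(dend, "hclust"))
  n <- length(dend$labels %||% dend$order)
  if (K < 1 || K > n) stop("cut_dendrogram: K out of range")
  cl <- stats::cutree(dend, k = K)
  tibble::tibble(leaf = names(cl) %||% as.character(seq_along(cl)),
                 clade = unname(as.integer(cl)))
}

#' Mean silhouette width of a clade assignment
#'
#' For leaf i with within-clade mean distance a_i and smallest other-clade
#' mean distance b_i, `s(i) = (b_i - a_i) / max(a_i, b_i)`; leaves in
#' singleton clades score 0, as do leaves for which both means are 0.
#'
#' @param d Symmetric distance matrix.
#' @param clades Integer clade label per leaf (in matrix order).
#' @return Mean silhouette width over all leaves.
#' @export
mean_silhouette <- function(d, clades) {
  d <- as.matrix(d)
  n <- nrow(d)
  stopifnot(length(clades) == n)
  if (length(unique(clades)) < 2) stop("mean_silhouette: need >= 2 clades")
  s <- vapply(seq_len(n), function(i) {
    own <- clades == clades[i]
    if (sum(own) == 1) return(0)
    a <- mean(d[i, own & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(clades), clades[i]),
                    function(k) mean(d[i, clades == k]), numeric(1)))
    if (max(a, b) == 0) return(0)
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}

#' Silhouette-optimal number of clades
#'
#' Evaluates the mean silhouette width for every cut K = 2..Kmax of the
#' dendrogram and returns the K with the highest coefficient (ties resolved
#' towards smaller K, favouring the non-paralogous interpretation). A high
#' best K suggests multiple paralog groups in the locus.
#'
#' @param dend An `hclust` object over the same leaves as `d`.
#' @param d The distance matrix the dendrogram was built from.
#' @param Kmax Largest K to evaluate; defaults to `n_leaves - 1`.
#' @return A list with `best_k` (integer) and `scores` (named numeric,
#'   one mean silhouette per evaluated K).
#' @export
silhouette_best_k <- function(dend, d, Kmax = NULL) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 3) {
    warning("silhouette_best_k: fewer than 3 leaves; best K fixed at 2")
    return(list(best_k = 2L, scores = c(`2` = 0)))
  }
  Kmax <- min(Kmax %||% (n - 1), n - 1)
  Kmax <- max(Kmax, 2)
  ks <- 2:Kmax
  scores <- vapply(ks, function(K) {
    cl <- stats::cutree(dend, k = K)
    if (!is.null(names(cl)) && !is.null(rownames(d))) cl <- cl[rownames(d)]
    mean_silhouette(d, as.integer(cl))
  }, numeric(1))
  names(scores) <- ks
  list(best_k = as.integer(ks[which.max(scores)]), scores = scores)
}
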