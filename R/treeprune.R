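#' Detect exceptionally long internal branches
#'
#' Flags internal edges whose length exceeds `factor` times the median of
#' all branch lengths and that separate at least `min_tips_per_side` tips on
#' each side. Such branches, subtending two dense subgroups, are a clear
#' sign of paralogy in a gene tree built from multi-copy markers.
#'
#' @param tree An `ape::phylo` with branch lengths, at least 4 tips.
#' @param factor Multiple of the median branch length above which an edge
#'   counts as long (default 10; the threshold is a package choice and
#'   should be reported alongside results).
#' @param min_tips_per_side Minimum tips required on both sides.
#' @return A tibble `edge` (row index into `tree$edge`), `length`,
#'   `tips_below`, `tips_above`, sorted by length descending.
#' @export
detect_long_branches <- function(tree, factor = 10, min_tips_per_side = 3) {
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length))
  ntip <- length(tree$tip.label)
  if (ntip < 4) stop("detect_long_branches: need >= 4 tips")
  med <- median(tree$edge.length)
  empty <- tibble::tibble(edge = integer(), length = numeric(),
                          tips_below = integer(), tips_above = integer())
  if (med <= 0) {
    warning("detect_long_branches: all branch lengths zero")
    return(empty)
  }
  internal <- which(tree$edge[, 2] > ntip)
  rows <- purrr::map(internal, function(e) {
    len <- tree$edge.length[e]
    if (len <= factor * med) return(NULL)
    below <- length(descendant_tips(tree, tree$edge[e, 2]))
    above <- ntip - below
    if (below < min_tips_per_side || above < min_tips_per_side) return(NULL)
    tibble::tibble(edge = e, length = len, tips_below = below,
                   tips_above = above)
  })
  out <- purrr::list_rbind(purrr::compact(rows))
  if (nrow(out) == 0) return(empty)
  dplyr::arrange(out, dplyr::desc(.data$length))
}

#' Detect tips subtended by exceptionally long terminal branches
#'
#' Terminal counterpart of [detect_long_branches()]: individual tips hanging
#' from a branch longer than `factor` times the median, candidates for
#' removal rather than tree splitting.
#'
#' @inheritParams detect_long_branches
#' @return A tibble `tip`, `length`, sorted by length descending.
#' @export
detect_long_tips <- function(tree, factor = 10) {
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length))
  med <- median(tree$edge.length)
  ntip <- length(tree$tip.label)
  term <- which(tree$edge[, 2] <= ntip)
  keep <- term[tree$edge.length[term] > factor * med & med > 0]
  tibble::tibble(tip = tree$tip.label[tree$edge[keep, 2]],
                 length = tree$edge.length[keep]) %>%
    dplyr::arrange(dplyr::desc(.data$length))
}

#' Split a gene tree at an internal edge
#'
#' Divides the tree into the clade below the edge and the remainder; branch
#' lengths are preserved within each part. The two parts are meant to be
#' treated as independent marker partitions downstream.
#'
#' @param tree An `ape::phylo`.
#' @param edge Row index into `tree$edge`; must be an internal edge.
#' @return A list of two `phylo` objects (`below`, `above`) whose tip sets
#'   partition the input's tips.
#' @export
split_at_edge <- function(tree, edge) {
  stopifnot(inherits(tree, "phylo"))
  if (!(edge %in% seq_len(nrow(tree$edge)))) {
    stop("split_at_edge: edge not in tree")
  }
  child <- tree$edge[edge, 2]
  if (child <= length(tree$tip.label)) {
    stop("split_at_edge: edge is terminal, not internal")
  }
  below <- ape::extract.clade(tree, child)
  above <- ape::drop.tip(tree, below$tip.label)
  list(below = below, above = above)
}

# tip indices descending from a node (node may be a tip)
descendant_tips <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(node)
  out <- integer()
  stack <- node
  while (length(stack) > 0) {
    nd <- stack[[1]]
    stack <- stack[-1]
    kids <- tree$edge[tree$edge[, 1] == nd, 2]
    out <- c(out, kids[kids <= ntip])
    stack <- c(stack, kids[kids > ntip])
  }
  sort(out)
}

# default mapping from tip label to accession: strip a trailing numeric
# contig suffix ("acc_2" -> "acc")
accession_of <- function(labels) sub("_[0-9]+$", "", labels)

#' Prune a rooted gene tree to one tip per accession
#'
#' Rooted-ingroup cleanup of residual paralogy: the tree is rooted on the
#' outgroup (on its largest pure clade, with a warning, if the outgroup is
#' not monophyletic); then, while any accession contributes more than one
#' tip, the smallest clade spanning a duplicated accession's tips is
#' located and, of its two children, the side with more distinct accessions
#' is kept (ties: more tips, then smaller node id). From the losing side
#' only tips of accessions duplicated across the two sides are discarded,
#' so an accession that is already unique in the tree is never pruned. A
#' losing side that would be discarded wholesale but itself contains at
#' least `min_taxa` distinct accessions is split off and cleaned
#' recursively -- a duplication spanning the root therefore yields two
#' cleaned subtrees, one per paralog.
#'
#' @param tree An `ape::phylo` with branch lengths.
#' @param outgroup Character vector of outgroup accession names; at least
#'   one must be present in the tree.
#' @param accession Optional named character vector mapping tip label to
#'   accession; by default a trailing `_<number>` contig suffix is stripped.
#' @param min_taxa Minimum distinct accessions for a split-off subtree to be
#'   emitted rather than discarded.
#' @return A list of cleaned `phylo` trees, each with at most one tip per
#'   accession; no tip occurs in more than one output tree.
#' @export
rt_prune <- function(tree, outgroup, accession = NULL, min_taxa = 2) {
  stopifnot(inherits(tree, "phylo"))
  acc <- accession %||% setNames(accession_of(tree$tip.label), tree$tip.label)
  og_tips <- tree$tip.label[acc[tree$tip.label] %in% outgroup]
  if (length(og_tips) == 0) stop("rt_prune: no outgroup tip in tree")

  root_on <- og_tips
  if (length(og_tips) > 1 &&
      !ape::is.monophyletic(tree, og_tips)) {
    warning("rt_prune: outgroup not monophyletic; rooting on its largest clade")
    root_on <- largest_pure_clade(tree, og_tips)
  }
  rooted <- ape::root(tree, outgroup = root_on, resolve.root = TRUE)
  clean_tree(rooted, acc, min_taxa)
}

largest_pure_clade <- function(tree, tips) {
  ntip <- length(tree$tip.label)
  best <- tips[1]
  for (node in (ntip + 1):(ntip + tree$Nnode)) {
    dt <- tree$tip.label[descendant_tips(tree, node)]
    if (all(dt %in% tips) && length(dt) > length(best)) best <- dt
  }
  best
}

clean_tree <- function(tree, acc, min_taxa) {
  if (is.null(tree) || length(tree$tip.label) < 2) {
    # a lone tip is not a usable gene tree
    return(list())
  }
  tip_acc <- unname(acc[tree$tip.label])
  dup <- unique(tip_acc[duplicated(tip_acc)])
  if (length(dup) == 0) return(list(tree))

  ntip <- length(tree$tip.label)
  # smallest clade spanning some duplicated accession's tips
  mrcas <- vapply(dup, function(a) {
    tips <- which(tip_acc == a)
    ape::getMRCA(tree, tips)
  }, integer(1))
  sizes <- vapply(mrcas, function(nd) length(descendant_tips(tree, nd)),
                  integer(1))
  node <- mrcas[order(sizes, mrcas)[1]]

  kids <- tree$edge[tree$edge[, 1] == node, 2]
  kid_tips <- lapply(kids, function(k) descendant_tips(tree, k))
  n_acc <- vapply(kid_tips, function(t) length(unique(tip_acc[t])), integer(1))
  n_tip <- lengths(kid_tips)
  winner <- order(-n_acc, -n_tip, kids)[1]

  # accessions represented in more than one child of this node
  acc_by_kid <- lapply(kid_tips, function(t) unique(tip_acc[t]))
  all_acc <- unlist(acc_by_kid)
  shared <- unique(all_acc[duplicated(all_acc)])

  out <- list()
  drop_labels <- character()
  for (i in seq_along(kids)) {
    if (i == winner) next
    loser_tips <- kid_tips[[i]]
    remove <- loser_tips[tip_acc[loser_tips] %in% shared]
    if (length(remove) == length(loser_tips)) {
      # whole side would vanish: split it off instead, keep it if substantial
      side_labels <- tree$tip.label[loser_tips]
      if (length(unique(tip_acc[loser_tips])) >= min_taxa) {
        side <- if (kids[i] > ntip) ape::extract.clade(tree, kids[i]) else NULL
        out <- c(out, clean_tree(side, acc, min_taxa))
      }
      drop_labels <- c(drop_labels, side_labels)
    } else {
      drop_labels <- c(drop_labels, tree$tip.label[remove])
    }
  }
  main <- ape::drop.tip(tree, drop_labels)
  c(clean_tree(main, acc, min_taxa), out)
}
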