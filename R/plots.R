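#' Plot a single-linkage dendrogram
#'
#' Rectangular dendrogram with leaves labelled by consensus id, intended
#' for the visual inspection of candidate loci.
#'
#' @param dend An `hclust` object (see [single_linkage_dendrogram()]).
#' @param title Optional plot title.
#' @return A ggplot object.
#' @export
plot_dendrogram <- function(dend, title = NULL) {
  stopifnot(inherits(dend, "hclust"))
  n <- length(dend$order)
  leaf_x <- setNames(seq_len(n), dend$order)  # position of leaf index
  node_x <- numeric(n - 1)
  node_y <- dend$height
  seg <- vector("list", n - 1)
  pos <- function(m) {
    if (m < 0) c(x = unname(leaf_x[as.character(-m)]), y = 0)
    else c(x = node_x[m], y = node_y[m])
  }
  for (i in seq_len(n - 1)) {
    a <- pos(dend$merge[i, 1])
    b <- pos(dend$merge[i, 2])
    node_x[i] <- mean(c(a["x"], b["x"]))
    seg[[i]] <- tibble::tibble(
      x = c(a["x"], b["x"], a["x"]),
      xend = c(a["x"], b["x"], b["x"]),
      y = c(a["y"], b["y"], node_y[i]),
      yend = c(node_y[i], node_y[i], node_y[i])
    )
  }
  labs <- tibble::tibble(x = seq_len(n), y = 0,
                         label = dend$labels[dend$order])
  ggplot2::ggplot(purrr::list_rbind(seg)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$x, xend = .data$xend,
                                       y = .data$y, yend = .data$yend)) +
    ggplot2::geom_text(data = labs,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    label = .data$label),
                       angle = 90, hjust = 1.1, size = 3) +
    ggplot2::scale_y_continuous(expand = ggplot2::expansion(mult = c(0.3, 0.05))) +
    ggplot2::labs(x = NULL, y = "k-mer distance", title = title) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.grid.major.x = ggplot2::element_blank())
}

#' Plot cluster structure across a threshold sweep
#'
#' Cluster count and maximum cluster size against the clustering threshold;
#' the turning point where counts explode while maximum sizes collapse
#' guides the threshold choice.
#'
#' @param sweep A `ct_sweep` tibble (see [ct_sweep()]).
#' @return A ggplot object.
#' @export
plot_ct_sweep <- function(sweep) {
  long <- sweep %>%
    dplyr::select("ct", "n_clusters", "max_size") %>%
    tidyr::pivot_longer(-"ct", names_to = "statistic")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$ct, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~statistic, scales = "free_y") +
    ggplot2::labs(x = "clustering threshold", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the number of proposed loci against the percentile threshold
#'
#' @param results Output of [rank_and_propose()].
#' @return A ggplot object.
#' @export
plot_proposal_curve <- function(results) {
  qs <- 1:99
  counts <- vapply(qs, function(q) length(proposed_at(results, q)), integer(1))
  ggplot2::ggplot(tibble::tibble(q = qs, n = counts),
                  ggplot2::aes(x = .data$q, y = .data$n)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "proposal threshold [%]", y = "proposed loci") +
    ggplot2::theme_minimal()
}

#' Index overview for a marker run
#'
#' Entropy against mean KBS per locus, sized by best K and coloured by
#' candidate status: good loci sit in the lower-left corner (entropy 0,
#' KBS -100).
#'
#' @param object A `marker_run` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.marker_run <- function(object, ...) {
  dat <- tidy(object)
  if (nrow(dat) == 0) stop("autoplot: run carries no ranked loci")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$kbs_mean, y = .data$entropy,
                                    size = .data$best_k,
                                    colour = .data$candidate)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "mean KBS [%]", y = "mean entropy",
                  size = "best K", colour = "candidate") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
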