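# ggplot2 views of the result objects.

#' Tidiers for phytoaccum result objects
#'
#' [generics::tidy()] on a `"linkage_tree"` returns the merge history (one
#' row per agglomeration step: the two clusters merged, the merge height
#' and the resulting size); [generics::glance()] returns a one-row model
#' summary including the cophenetic correlation between the input
#' dissimilarity and the tree.
#'
#' @param x A `"linkage_tree"` object.
#' @param ... Unused.
#' @return A tibble.
#' @name tidiers
NULL

.dendro_segments <- function(tree) {
  n <- length(tree$labels)
  xpos <- numeric(n)
  xpos[tree$order] <- seq_len(n)
  node_x <- numeric(n - 1)
  node_y <- tree$height
  coord <- function(i) {
    if (i < 0) c(xpos[-i], 0) else c(node_x[i], node_y[i])
  }
  segs <- vector("list", n - 1)
  for (s in seq_len(n - 1)) {
    a <- coord(tree$merge[s, 1])
    b <- coord(tree$merge[s, 2])
    node_x[s] <- (a[1] + b[1]) / 2
    segs[[s]] <- tibble::tibble(
      x = c(a[1], b[1], a[1]),
      xend = c(a[1], b[1], b[1]),
      y = c(a[2], b[2], tree$height[s]),
      yend = c(tree$height[s], tree$height[s], tree$height[s])
    )
  }
  dplyr::bind_rows(segs)
}

#' Dendrogram of a linkage tree
#'
#' Draws the merge history as a classical dendrogram: leaves in tree
#' order along the x axis, merge heights (the Ward criterion on the
#' 1 - Pearson r scale) on the y axis.
#'
#' @param object A `"linkage_tree"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.linkage_tree <- function(object, ...) {
  segs <- .dendro_segments(object)
  leaves <- tibble::tibble(
    x = seq_along(object$labels),
    label = object$labels[object$order]
  )
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = segs,
      ggplot2::aes(x = .data$x, xend = .data$xend, y = .data$y,
        yend = .data$yend)
    ) +
    ggplot2::scale_x_continuous(
      breaks = leaves$x, labels = leaves$label, expand = c(0.01, 0.01)
    ) +
    ggplot2::labs(
      x = NULL,
      y = paste0("Linkage height (", object$method, ", ",
        object$dist.method, ")")
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(
      axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5,
        hjust = 1),
      panel.grid.major.x = ggplot2::element_blank()
    )
}

#' Plot median accumulation indices per element
#'
#' Point plot of the median BcF or EF per element and horizon on a log10
#' axis, with the relevant decision threshold drawn (BcF 0.1 excluder
#' cut-off; EF 10 accumulation cut-off).
#'
#' @param med Output of [median_index()].
#' @param kind `"BcF"` or `"EF"`.
#' @return A ggplot object.
#' @export
plot_median_indices <- function(med, kind = c("BcF", "EF")) {
  kind <- match.arg(kind)
  dat <- dplyr::filter(med, .data$index_kind == kind, !is.na(.data$value))
  thr <- if (kind == "BcF") 0.1 else 10
  ggplot2::ggplot(
    dat,
    ggplot2::aes(
      x = stats::reorder(.data$element, .data$value, max),
      y = .data$value, colour = .data$horizon
    )
  ) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = thr, linetype = "dashed") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = paste("Median", kind), colour = "Horizon") +
    ggplot2::theme_minimal() +
    ggplot2::theme(
      axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5, hjust = 1)
    )
}

#' Plot shale-normalized REE patterns
#'
#' One line per site across the normalized REE sequence (La, Ce, Pr, Nd,
#' Y as available), log10 y axis — the standard spider view in which a Ce
#' anomaly appears as a dip or spike at Ce.
#'
#' @param ree Output of [ce_anomaly_table()].
#' @return A ggplot object.
#' @export
plot_ree_pattern <- function(ree) {
  order <- c("la_n", "ce_n", "pr_n", "nd_n", "y_n")
  cols <- intersect(order, names(ree))
  long <- tidyr::pivot_longer(ree,
    dplyr::all_of(cols),
    names_to = "element", values_to = "normalized"
  )
  pretty <- c(la_n = "La", ce_n = "Ce", pr_n = "Pr", nd_n = "Nd", y_n = "Y")
  long <- dplyr::mutate(long,
    element = factor(pretty[.data$element], levels = pretty[cols])
  )
  ggplot2::ggplot(
    long,
    ggplot2::aes(
      x = .data$element, y = .data$normalized,
      group = .data$site_id, colour = .data$anomaly
    )
  ) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = NULL, y = "Shale-normalized concentration", colour = "Ce anomaly"
    ) +
    ggplot2::theme_minimal()
}
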