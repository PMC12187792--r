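# Agglomerative Ward clustering on arbitrary dissimilarities.
#
# Ward linkage on a non-Euclidean dissimilarity such as 1 - Pearson r is
# mathematically loose but is the procedure legacy statistics packages
# apply; the implementation below applies the Lance-Williams Ward update
# directly to the supplied distances ("Ward.D" style), with deterministic
# lexicographic tie-breaking, so that runs are reproducible and invariant
# to input order.

#' Ward clustering of a dissimilarity matrix
#'
#' Agglomerates items by the Lance-Williams update for Ward's method
#' applied directly to the supplied dissimilarities (the "Ward.D"
#' convention, matching classic packages that accept any distance):
#' after merging clusters *i* and *j*,
#' \deqn{d(k, ij) = \frac{(n_i + n_k) d_{ki} + (n_j + n_k) d_{kj}
#'   - n_k d_{ij}}{n_i + n_j + n_k}.}
#' At each step the closest active pair is merged; exact ties are broken
#' by the lexicographically smallest pair of cluster labels (a cluster is
#' labelled by its alphabetically first leaf), making the merge history a
#' deterministic function of the dissimilarities alone.
#'
#' @param d A [stats::dist] object or symmetric matrix with zero diagonal.
#' @param labels Item labels; defaults to the labels of `d`.
#' @return A `"linkage_tree"`: list with `merge` (hclust convention),
#'   `height`, `order`, `labels`, `method`, `dist.method`, and the input
#'   `dist`. Coercible via [as.hclust()]; see [as_newick()], [tidy()],
#'   [glance()], [ggplot2::autoplot()].
#' @export
#' @examples
#' m <- matrix(rnorm(40), nrow = 4, dimnames = list(letters[1:4], NULL))
#' ward_cluster(pearson_distance(m))
ward_cluster <- function(d, labels = NULL) {
  dm <- as.matrix(d)
  if (nrow(dm) < 2) abort("ward_cluster(): need at least 2 items")
  if (any(abs(dm - t(dm)) > 1e-8) || any(diag(dm) != 0)) {
    abort("ward_cluster(): d must be symmetric with zero diagonal")
  }
  n <- nrow(dm)
  labels <- labels %||% rownames(dm) %||% as.character(seq_len(n))
  stopifnot(length(labels) == n)

  cur <- dm
  active <- seq_len(n)
  id <- -seq_len(n) # hclust convention: negative = leaf
  size <- rep(1L, n)
  rep_label <- labels # lexicographically smallest member label
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)

  for (step in seq_len(n - 1)) {
    idx <- active
    sub <- cur[idx, idx, drop = FALSE]
    sub[!upper.tri(sub)] <- Inf
    dmin <- min(sub)
    cand <- which(sub <= dmin + 1e-12 * max(1, abs(dmin)), arr.ind = TRUE)
    # deterministic tie-break: smallest (label_i, label_j) pair
    keys <- apply(cand, 1, function(rc) {
      pair <- sort(c(rep_label[idx[rc[1]]], rep_label[idx[rc[2]]]))
      paste(pair, collapse = "\r")
    })
    pick <- cand[order(keys)[1], ]
    i <- idx[min(pick)]
    j <- idx[max(pick)]

    a <- id[i]
    b <- id[j]
    # hclust ordering: leaves before clusters, ascending within
    pair <- if ((a < 0 && b < 0 && -a > -b) || (a > 0 && b < 0) ||
      (a > 0 && b > 0 && a > b)) {
      c(b, a)
    } else {
      c(a, b)
    }
    merge[step, ] <- pair
    height[step] <- cur[i, j]

    ni <- size[i]
    nj <- size[j]
    for (k in setdiff(active, c(i, j))) {
      nk <- size[k]
      newd <- ((ni + nk) * cur[k, i] + (nj + nk) * cur[k, j] -
        nk * cur[i, j]) / (ni + nj + nk)
      cur[k, i] <- newd
      cur[i, k] <- newd
    }
    size[i] <- ni + nj
    id[i] <- step
    rep_label[i] <- min(rep_label[i], rep_label[j])
    active <- setdiff(active, j)
  }

  structure(
    list(
      merge = merge,
      height = height,
      order = .leaf_order(merge),
      labels = labels,
      method = "ward.D",
      dist.method = attr(d, "method") %||% "unknown",
      dist = stats::as.dist(dm)
    ),
    class = "linkage_tree"
  )
}

.leaf_order <- function(merge) {
  rec <- function(i) {
    if (i < 0) -i else c(rec(merge[i, 1]), rec(merge[i, 2]))
  }
  rec(nrow(merge))
}

#' @export
print.linkage_tree <- function(x, ...) {
  cat(
    "<linkage_tree> ", length(x$labels), " leaves, method ", x$method,
    " on ", x$dist.method, " distance\n",
    sep = ""
  )
  invisible(x)
}

#' @export
as.hclust.linkage_tree <- function(x, ...) {
  structure(
    list(
      merge = x$merge, height = x$height, order = x$order,
      labels = x$labels, method = x$method, dist.method = x$dist.method,
      call = match.call()
    ),
    class = "hclust"
  )
}

#' Cut a linkage tree into k groups
#'
#' @param tree A `"linkage_tree"`.
#' @param k Number of groups.
#' @return Named integer vector of group memberships.
#' @export
cut_linkage <- function(tree, k) {
  cutree(as.hclust(tree), k = k)
}

#' Newick serialization of a linkage tree
#'
#' Converts the merge history to a Newick string (merge heights as node
#' heights, hence branch lengths), via [ape::as.phylo()].
#'
#' @param tree A `"linkage_tree"`.
#' @param path For `write_newick()`, the output file.
#' @return `as_newick()` returns the Newick string; `write_newick()`
#'   returns `path` invisibly.
#' @export
as_newick <- function(tree) {
  ape::write.tree(ape::as.phylo(as.hclust(tree)))
}

#' @rdname as_newick
#' @export
write_newick <- function(tree, path) {
  writeLines(as_newick(tree), path)
  invisible(path)
}

#' @rdname tidiers
#' @exportS3Method generics::tidy
tidy.linkage_tree <- function(x, ...) {
  name_of <- function(i) {
    if (i < 0) x$labels[-i] else paste0("node_", i)
  }
  sizes <- integer(nrow(x$merge))
  size_of <- function(i) if (i < 0) 1L else sizes[i]
  for (s in seq_len(nrow(x$merge))) {
    sizes[s] <- size_of(x$merge[s, 1]) + size_of(x$merge[s, 2])
  }
  tibble::tibble(
    step = seq_len(nrow(x$merge)),
    cluster_a = vapply(x$merge[, 1], name_of, character(1)),
    cluster_b = vapply(x$merge[, 2], name_of, character(1)),
    height = x$height,
    size = sizes
  )
}

#' @rdname tidiers
#' @exportS3Method generics::glance
glance.linkage_tree <- function(x, ...) {
  h <- as.hclust(x)
  coph_cor <- suppressWarnings(cor(x$dist, cophenetic(h)))
  tibble::tibble(
    n_leaves = length(x$labels),
    n_merges = nrow(x$merge),
    method = x$method,
    dist_method = x$dist.method,
    max_height = max(x$height),
    cophenetic_cor = coph_cor
  )
}

#' Cluster elements or sites of a concentration table
#'
#' The two standard dendrogram modes of a survey: per-site medians are
#' log10-transformed ([log10_medians()]), turned into a 1 - Pearson r
#' dissimilarity ([pearson_distance()]) between elements
#' (`cluster_elements()`, items = elements correlated across sites) or
#' between sites (`cluster_sites()`, items = sites correlated across
#' elements), then agglomerated by [ward_cluster()].
#'
#' @param x Long concentration tibble (one compartment).
#' @param median_of_logs Passed to [log10_medians()].
#' @return A `"linkage_tree"`.
#' @export
cluster_elements <- function(x, median_of_logs = FALSE) {
  m <- log10_medians(x, mode = "by_element", median_of_logs = median_of_logs)
  ward_cluster(pearson_distance(m))
}

#' @rdname cluster_elements
#' @export
cluster_sites <- function(x, median_of_logs = FALSE) {
  m <- log10_medians(x, mode = "by_site", median_of_logs = median_of_logs)
  ward_cluster(pearson_distance(m))
}
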