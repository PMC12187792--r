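# Independent oracles and small fixtures shared across test files.

# Brute-force agglomeration oracle: explicit cluster member lists, triple
# loops, Ward (Lance-Williams) update applied to the supplied distances.
# Returns merge heights and the partition after every merge.
naive_ward <- function(dm) {
  dm <- as.matrix(dm)
  n <- nrow(dm)
  clusters <- as.list(seq_len(n))
  D <- dm
  active <- seq_len(n)
  sizes <- rep(1, n)
  heights <- numeric(0)
  partitions <- list()
  while (length(active) > 1) {
    best <- NULL
    bestd <- Inf
    for (ai in seq_along(active)) {
      for (aj in seq_along(active)) {
        if (ai < aj) {
          i <- active[ai]
          j <- active[aj]
          if (D[i, j] < bestd) {
            bestd <- D[i, j]
            best <- c(i, j)
          }
        }
      }
    }
    i <- best[1]
    j <- best[2]
    heights <- c(heights, D[i, j])
    for (k in setdiff(active, c(i, j))) {
      upd <- ((sizes[i] + sizes[k]) * D[k, i] +
        (sizes[j] + sizes[k]) * D[k, j] -
        sizes[k] * D[i, j]) / (sizes[i] + sizes[j] + sizes[k])
      D[i, k] <- upd
      D[k, i] <- upd
    }
    clusters[[i]] <- sort(c(clusters[[i]], clusters[[j]]))
    sizes[i] <- sizes[i] + sizes[j]
    active <- setdiff(active, j)
    partitions[[length(partitions) + 1]] <-
      lapply(active, function(a) clusters[[a]])
  }
  list(heights = heights, partitions = partitions)
}

# Canonical string form of a partition, for comparing clusterings.
canon_groups <- function(membership) {
  unname(sort(vapply(
    split(seq_along(membership), membership),
    function(ix) paste(sort(ix), collapse = ","),
    character(1)
  )))
}

canon_sets <- function(sets) {
  unname(sort(
    vapply(sets, function(s) paste(sort(s), collapse = ","), character(1))
  ))
}

# Partition of a linkage_tree at k groups, in canonical form (leaves are
# compared by position, so trees must share label order).
tree_partition <- function(tree, k) {
  canon_groups(unname(cut_linkage(tree, k)))
}

# A small complete synthetic study for structural tests.
small_study <- function(n_sites = 8, seed = 11, ...) {
  generate_study(synth_config(n_sites = n_sites, seed = seed, ...))
}

# A noise-free configuration: every stochastic multiplier degenerate, so
# downstream indices are analytically predictable.
noise_free_config <- function(bcf = 0.1, n_sites = 5, seed = 2) {
  cfg <- synth_config(n_sites = n_sites, seed = seed)
  cfg$element_params$gsd_subsoil <- 1
  cfg$element_params$bcf_true <- bcf
  cfg$horizon_gsd <- 1
  cfg$frond_gsd <- 1
  cfg$replicate_gsd <- 1
  cfg$ree_rho <- 0
  cfg
}

# Write a tibble to a temp csv and return the path.
tmp_csv <- function(df) {
  path <- tempfile(fileext = ".csv")
  readr::write_csv(df, path, progress = FALSE)
  path
}
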