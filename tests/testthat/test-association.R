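# Spearman screening, correlation distances and Ward clustering.

test_that("spearman_screen recovers perfect monotone relations", {
  frame <- data.frame(x = 1:10, up = (1:10)^3, down = -(1:10))
  out <- spearman_screen(frame, "x", c("up", "down"), adjust = "none")
  expect_equal(out$rho[out$predictor == "up"], 1)
  expect_lt(out$p_value[out$predictor == "up"], 0.01)
  expect_equal(out$rho[out$predictor == "down"], -1)
  expect_equal(out$stars[out$predictor == "up"], "***")
})

test_that("spearman rho is invariant to strictly monotone transforms", {
  set.seed(12)
  x <- rnorm(30)
  y <- x + rnorm(30)
  frame <- data.frame(x = x, y = y, ylog = exp(y), xr = rank(x))
  out <- spearman_screen(frame, c("x", "xr"), c("y", "ylog"), adjust = "none")
  expect_equal(length(unique(round(out$rho, 12))), 1)
})

test_that("degenerate screen inputs are reported NA or dropped", {
  frame <- data.frame(x = 1:10, const = rep(1, 10))
  expect_warning(
    out <- spearman_screen(frame, "x", "const"), "constant"
  )
  expect_true(is.na(out$rho))
  short <- data.frame(x = c(1, 2, NA, NA, NA), y = c(NA, NA, 3, 4, 5))
  expect_equal(nrow(spearman_screen(short, "x", "y")), 0)
  # BH adjustment never decreases a p-value
  set.seed(3)
  many <- as.data.frame(matrix(rnorm(35 * 6), 35))
  scr <- spearman_screen(many, "V1", paste0("V", 2:6))
  expect_true(all(scr$adjusted_p >= scr$p_value))
})

test_that("pearson_distance maps correlation onto [0, 2]", {
  m <- rbind(
    a = c(1, 2, 3, 4),
    b = c(2, 4, 6, 8), # perfectly correlated with a
    c = c(4, 3, 2, 1), # perfectly anticorrelated
    d = c(1, -1, -1, 1) # orthogonal to a
  )
  d <- as.matrix(pearson_distance(m))
  expect_equal(d["a", "b"], 0)
  expect_equal(d["a", "c"], 2)
  expect_equal(d["a", "d"], 1)
  expect_equal(d, t(d))
  expect_equal(unname(diag(d)), rep(0, 4))
  expect_error(
    pearson_distance(rbind(a = c(1, 2), flat = c(3, 3))), "flat"
  )
})

test_that("ward_cluster merges the closest pair first", {
  dm <- matrix(c(0, 0.1, 1, 0.1, 0, 1, 1, 1, 0), 3, 3,
    dimnames = list(c("A", "B", "C"), c("A", "B", "C"))
  )
  tree <- ward_cluster(stats::as.dist(dm))
  expect_equal(sort(tree$labels[-tree$merge[1, ]]), c("A", "B"))
  expect_equal(tree$height[1], 0.1)
  expect_error(ward_cluster(matrix(0, 1, 1)), "at least 2")
})

test_that("ward_cluster agrees with brute-force oracle and hclust up to n = 6", {
  set.seed(99)
  for (rep in 1:20) {
    n <- sample(3:6, 1)
    m <- matrix(rnorm(n * 12), n, 12,
      dimnames = list(paste0("it", seq_len(n)), NULL)
    )
    d <- pearson_distance(m)
    mine <- ward_cluster(d)
    oracle <- naive_ward(d)
    expect_equal(mine$height, oracle$heights, tolerance = 1e-10)
    for (step in seq_len(n - 2)) {
      k <- n - step
      expect_equal(
        tree_partition(mine, k),
        canon_sets(oracle$partitions[[step]])
      )
    }
    # independent library implementation of the same linkage
    h <- stats::hclust(d, method = "ward.D")
    expect_equal(sort(mine$height), sort(h$height), tolerance = 1e-10)
    for (k in 2:(n - 1)) {
      expect_equal(tree_partition(mine, k), canon_groups(cutree(h, k)))
    }
  }
})

test_that("clustering is invariant to input order and duplicates merge first", {
  set.seed(17)
  m <- matrix(rnorm(8 * 20), 8, 20, dimnames = list(LETTERS[1:8], NULL))
  t1 <- ward_cluster(pearson_distance(m))
  perm <- sample(8)
  t2 <- ward_cluster(pearson_distance(m[perm, ]))
  for (k in 2:7) {
    p1 <- unname(sort(vapply(
      split(t1$labels, cut_linkage(t1, k)),
      function(s) paste(sort(s), collapse = ","), character(1)
    )))
    p2 <- unname(sort(vapply(
      split(t2$labels, cut_linkage(t2, k)),
      function(s) paste(sort(s), collapse = ","), character(1)
    )))
    expect_equal(p1, p2)
  }
  # duplicated profiles sit at distance 0 and merge first
  m2 <- rbind(m, Adup = m["A", ])
  t3 <- ward_cluster(pearson_distance(m2))
  expect_equal(t3$height[1], 0, tolerance = 1e-12)
  expect_equal(
    sort(t3$labels[-t3$merge[1, ]]), c("A", "Adup")
  )
})

test_that("two correlated blocks separate at the top split", {
  set.seed(23)
  n_sites <- 30
  latent1 <- rnorm(n_sites)
  latent2 <- rnorm(n_sites)
  block <- rep(c(1, 2), each = 5)
  m <- t(vapply(
    seq_len(10),
    function(i) {
      lat <- if (block[i] == 1) latent1 else latent2
      lat + rnorm(n_sites, sd = 0.3)
    },
    numeric(n_sites)
  ))
  rownames(m) <- paste0("e", 1:10)
  tree <- ward_cluster(pearson_distance(m))
  expect_equal(canon_groups(block), tree_partition(tree, 2))
})

test_that("cluster_elements and cluster_sites wire the full pipeline", {
  study <- small_study(n_sites = 10, seed = 13)
  etree <- cluster_elements(study$frond)
  expect_s3_class(etree, "linkage_tree")
  expect_setequal(etree$labels, unique(study$frond$element))
  stree <- cluster_sites(study$frond)
  expect_equal(length(stree$labels), 10)
  # REEs co-cluster: strong latent coherence puts all five in one branch
  # at some shallow cut
  ree <- c("La", "Ce", "Pr", "Nd", "Y")
  groups <- cut_linkage(etree, 6)
  expect_equal(length(unique(groups[ree])), 1)
  # serialization: Newick round-trips the leaf set
  nwk <- as_newick(etree)
  phy <- ape::read.tree(text = nwk)
  expect_setequal(phy$tip.label, etree$labels)
  # tidy merge list has n - 1 rows and ends with the full set
  td <- tidy(etree)
  expect_equal(nrow(td), length(etree$labels) - 1)
  expect_equal(td$size[nrow(td)], length(etree$labels))
  expect_equal(glance(etree)$n_leaves, length(etree$labels))
})

test_that("granite-affine chemistry pulls granitic sites into one branch", {
  study <- generate_study(synth_config(n_sites = 35, seed = 6))
  stree <- cluster_sites(study$frond)
  groups <- cut_linkage(stree, 2)
  granite <- as.character(
    study$sites$site_id[study$sites$bedrock_class == "GRA"]
  )
  expect_gte(length(granite), 4)
  tab <- table(groups[granite])
  # most granitic sites fall into the same branch
  expect_gte(max(tab) / sum(tab), 0.75)
})
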