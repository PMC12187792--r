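# Bioconcentration and enrichment factors, the class scale, medians and
# stoichiometry.

test_that("bcf is the plain concentration ratio with a zero guard", {
  expect_equal(bcf(7.3, 7.3), 1)
  expect_equal(bcf(10, 100), 0.1)
  expect_warning(out <- bcf(5, 0), "zero substrate")
  expect_true(is.na(out))
  expect_error(bcf(-1, 10), "nonnegative")
})

test_that("ef is the Al-normalized double ratio", {
  expect_equal(ef(2, 1, 1, 1), 2)
  # self-normalization: EF of Al itself is exactly 1
  expect_equal(ef(56.1, 56.1, 48200, 48200), 1)
  # invariant under a common unit change
  expect_equal(
    ef(2, 4, 8, 16), ef(2000, 4000, 8000, 16000)
  )
  expect_warning(out <- ef(1, 0, 1, 1), "zero Al")
  expect_true(is.na(out))
})

test_that("the six enrichment classes partition [0, Inf)", {
  cls <- ef_classes()
  expect_equal(cls$lower, c(0, 1.5, 2, 5, 20, 40))
  expect_equal(cls$upper[-6], cls$lower[-1]) # contiguous, no overlap
  expect_equal(as.character(classify_ef(1.0)), "not_enriched")
  expect_equal(as.character(classify_ef(3.0)), "moderate")
  expect_equal(as.character(classify_ef(40.0)), "extreme")
  # shared printed endpoints belong to the upper class
  expect_equal(
    as.character(classify_ef(c(1.5, 2, 5, 20, 40))),
    c("slight", "moderate", "severe", "highly_severe", "extreme")
  )
  expect_error(classify_ef(-0.1), "negative")
  # dense grid: every value classified exactly once, monotonically
  grid <- seq(0, 60, by = 0.01)
  lab <- classify_ef(grid)
  expect_false(anyNA(lab))
  expect_true(all(diff(as.integer(lab)) >= 0))
})

test_that("median_index aggregates across sites with NA accounting", {
  idx <- tibble::tibble(
    site_id = 1:4, element = "Zn", horizon = "topsoil", index_kind = "BcF",
    value = c(0.5, 1.0, 2.0, NA), ef_class = NA
  )
  med <- median_index(idx)
  expect_equal(med$value, 1.0)
  expect_equal(med$n_sites, 3)
  expect_equal(med$n_na, 1)
  one <- median_index(dplyr::slice(dplyr::mutate(idx, value = 7), 1))
  expect_equal(one$value, 7)
  # median EF carries its class, median BcF does not
  efidx <- dplyr::mutate(idx, index_kind = "EF", value = 3)
  expect_equal(as.character(median_index(efidx)$ef_class), "moderate")
  expect_true(is.na(median_index(idx)$ef_class))
})

test_that("stoichiometry flags N and P limitation from the N:P ratio", {
  s <- stoichiometry(449229, 25889, 1913) # survey medians
  expect_equal(s$cn_ratio, 17.35, tolerance = 0.001)
  expect_true(s$cn_ratio > 11.9 && s$cn_ratio < 22.6)
  mid <- stoichiometry(4e5, 15 * 2000, 2000) # N:P = 15, between thresholds
  expect_false(mid$n_limited)
  expect_false(mid$p_limited)
  low <- stoichiometry(4e5, 2000, 1000)
  expect_equal(low$np_ratio, 2)
  expect_true(low$n_limited)
  expect_error(stoichiometry(0, 1, 1), "positive")
  # flags are mutually exclusive under the defaults
  set.seed(7)
  many <- stoichiometry(5e5, runif(50, 1e4, 4e4), runif(50, 1e3, 4e3))
  expect_false(any(many$n_limited & many$p_limited))
})

test_that("indices are exact on a noise-free synthetic study", {
  cfg <- noise_free_config(bcf = 0.1)
  study <- generate_study(cfg)
  frond <- aggregate_replicates(study$frond)
  idx <- compute_indices(frond, study[c("humus", "topsoil", "subsoil")])
  topsoil_bcf <- dplyr::filter(
    idx, index_kind == "BcF", horizon == "topsoil"
  )
  expect_equal(topsoil_bcf$value, rep(0.1, nrow(topsoil_bcf)))
  # EF against the coupling horizon is bcf_e / bcf_Al = 1 for equal couplings
  topsoil_ef <- dplyr::filter(idx, index_kind == "EF", horizon == "topsoil")
  expect_equal(topsoil_ef$value, rep(1, nrow(topsoil_ef)))
  expect_true(all(topsoil_ef$ef_class == "not_enriched"))
})

test_that("humus-enriched deposition metals show humus BcF < topsoil BcF", {
  # with Cd/Pb enriched in humus, the reciprocal ordering of the BcF holds
  study <- generate_study(synth_config(n_sites = 30, seed = 21))
  frond <- aggregate_replicates(study$frond)
  idx <- compute_indices(
    frond, study[c("humus", "topsoil")],
    kind = "BcF"
  )
  med <- median_index(idx)
  for (el in c("Cd", "Pb")) {
    humus <- dplyr::filter(med, element == el, horizon == "humus")$value
    topsoil <- dplyr::filter(med, element == el, horizon == "topsoil")$value
    expect_lt(humus, topsoil)
  }
})

test_that("verdicts apply the excluder and accumulation cut-offs", {
  med <- tibble::tibble(
    element = c("Na", "Na", "Rb", "Rb", "Fe", "Fe"),
    horizon = "humus",
    index_kind = rep(c("BcF", "EF"), 3),
    value = c(0.05, 2, 1.2, 150, 0.5, 3),
    n_sites = 35, n_na = 0, ef_class = NA
  )
  v <- accumulation_verdict(med)
  expect_equal(v$verdict[v$element == "Na"], "excluder")
  expect_equal(v$verdict[v$element == "Rb"], "accumulated")
  expect_equal(v$verdict[v$element == "Fe"], "intermediate")
})
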