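# The synthetic survey generator: determinism, configured structure,
# closed loops.

test_that("the seed fully determines every generated table", {
  a <- generate_study(synth_config(n_sites = 12, seed = 42))
  b <- generate_study(synth_config(n_sites = 12, seed = 42))
  for (part in c("sites", "humus", "topsoil", "subsoil", "frond")) {
    expect_identical(a[[part]], b[[part]])
  }
  c <- generate_study(synth_config(n_sites = 12, seed = 43))
  expect_false(identical(a$frond, c$frond))
})

test_that("configuration is validated", {
  expect_error(synth_config(n_sites = 1), "n_sites")
  expect_error(
    synth_config(bedrock_probs = c(SAND = 0.5, PHYL = 0.2, GRA = 0.2,
      PAR = 0.2, BAS = 0.2)),
    "sum to 1"
  )
  expect_error(synth_config(elevation_range = c(500, 500)), "degenerate")
  expect_error(synth_config(ce_multiplier = 0), "positive")
  expect_error(synth_config(frond_gsd = 0.5), "geometric SD")
  expect_error(
    synth_config(elements = "Xq"), "lacking parameters"
  )
})

test_that("site factors follow the configured mixture and gradients", {
  all_granite <- generate_sites(synth_config(
    n_sites = 20, seed = 5,
    bedrock_probs = c(SAND = 0, PHYL = 0, GRA = 1, PAR = 0, BAS = 0)
  ))
  expect_equal(unique(all_granite$bedrock_class), "GRA")

  big <- generate_sites(synth_config(n_sites = 200, seed = 9))
  expect_true(all(big$elevation_m >= 275 & big$elevation_m <= 925))
  # negative configured slope shows up as a negative rank correlation
  expect_lt(
    cor(big$elevation_m, big$evaporation_mid, method = "spearman"), 0
  )
  # classes are proper 50 mm/y bins
  expect_true(all(
    evaporation_midpoint(big$evaporation_class) %% 25 == 0
  ))
})

test_that("noise-free generation collapses to deterministic closed forms", {
  cfg <- noise_free_config(bcf = 0.1)
  cfg$topsoil_mult <- 1
  cfg$humus_mult <- 1
  cfg$humus_al_mult <- 1
  cfg$deposition_mult <- 1
  cfg$granite_mult <- 1
  study <- generate_study(cfg)
  # all multipliers 1, GSD 1: the three substrate tables are identical
  expect_equal(
    study$humus$value_mg_kg, study$topsoil$value_mg_kg
  )
  expect_equal(
    study$topsoil$value_mg_kg, study$subsoil$value_mg_kg
  )
  # frond = 0.1 x topsoil exactly, so the computed BcF is exactly 0.1
  frond <- aggregate_replicates(study$frond)
  idx <- compute_indices(frond, study["topsoil"], kind = "BcF")
  expect_equal(idx$value, rep(0.1, nrow(idx)))
})

test_that("bedrock and horizon multipliers express in the medians", {
  cfg <- synth_config(n_sites = 300, seed = 14, granite_mult = 5)
  sites <- generate_sites(cfg)
  sub <- generate_substrate(sites, cfg)
  rb <- dplyr::filter(sub$subsoil, element == "Rb")
  rb <- dplyr::left_join(rb, sites, by = "site_id")
  ratio <- median(rb$value_mg_kg[rb$bedrock_class == "GRA"]) /
    median(rb$value_mg_kg[rb$bedrock_class != "GRA"])
  expect_gt(ratio, 3.5)
  expect_lt(ratio, 7)
  # deposition-affected Cd is enriched in humus over subsoil
  cd_h <- dplyr::filter(sub$humus, element == "Cd")$value_mg_kg
  cd_s <- dplyr::filter(sub$subsoil, element == "Cd")$value_mg_kg
  expect_gt(median(cd_h), median(cd_s))
})

test_that("REE coherence induces strong mutual frond correlations", {
  cfg <- synth_config(n_sites = 100, seed = 15, ree_rho = 0.95)
  study <- generate_study(cfg)
  wide <- tidyr::pivot_wider(
    aggregate_replicates(study$frond),
    id_cols = "site_id", names_from = "element", values_from = "value_mg_kg"
  )
  ree <- c("La", "Ce", "Pr", "Nd", "Y")
  rho <- cor(log(as.matrix(wide[ree])), method = "spearman")
  expect_true(all(rho[upper.tri(rho)] > 0.8))
})

test_that("generated concentrations look log-normal", {
  cfg <- synth_config(n_sites = 200, seed = 16)
  sub <- generate_substrate(generate_sites(cfg), cfg)
  for (el in c("Zn", "Ce")) {
    x <- dplyr::filter(sub$subsoil, element == el)
    # non-granite-affine elements: a single log-normal population
    p <- stats::shapiro.test(log(x$value_mg_kg))$p.value
    expect_gt(p, 0.01)
  }
})

test_that("generated tables round-trip through the readers", {
  study <- small_study(n_sites = 6, seed = 20)
  for (part in c("frond", "topsoil")) {
    path <- tempfile(fileext = ".csv")
    write_concentration_table(study[[part]], path, layout = "long")
    comp <- study[[part]]$compartment[1]
    back <- read_concentration_table(path, comp, layout = "long")
    expect_equal(
      dplyr::arrange(back, site_id, element, replicate)$value_mg_kg,
      dplyr::arrange(study[[part]], site_id, element, replicate)$value_mg_kg
    )
  }
  # site factors survive a csv round-trip too
  path <- tempfile(fileext = ".csv")
  readr::write_csv(study$sites, path, progress = FALSE)
  back <- read_site_factors(path)
  expect_equal(back$evaporation_mid, study$sites$evaporation_mid)
})
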