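# End-to-end report and artifact writing.

test_that("accumulation_report classifies a noise-free study by hand rules", {
  cfg <- noise_free_config(n_sites = 5, seed = 3)
  # heterogeneous couplings so the verdicts differ by construction
  cfg$element_params$bcf_true <- 0.3
  cfg$element_params$bcf_true[cfg$element_params$element == "Na"] <- 0.01
  cfg$element_params$bcf_true[cfg$element_params$element == "Rb"] <- 2
  cfg$element_params$bcf_true[cfg$element_params$element == "Al"] <- 0.05
  study <- generate_study(cfg)
  rep <- accumulation_report(study)
  # noise-free EF against the coupling horizon is bcf_e / bcf_Al exactly
  expect_equal(rep$ef_topsoil[rep$element == "Rb"], 2 / 0.05)
  expect_equal(rep$ef_topsoil[rep$element == "Na"], 0.01 / 0.05)
  expect_equal(rep$bcf_topsoil[rep$element == "Na"], 0.01)
  # hand classification of those exact ratios
  expect_equal(rep$verdict[rep$element == "Na"], "excluder")
  expect_equal(rep$verdict[rep$element == "Rb"], "accumulated") # EF = 40
  expect_equal(
    as.character(
      classify_ef(rep$ef_topsoil[rep$element == "Rb"])
    ),
    "extreme"
  )
})

test_that("default synthetic survey recovers the designed verdict classes", {
  study <- generate_study(synth_config(seed = 31))
  rep <- accumulation_report(study)
  excluded_by_design <- c("Na", "As", "Th", "W")
  expect_true(all(
    rep$verdict[rep$element %in% excluded_by_design] == "excluder"
  ))
  # mobile nutrients couple strongly and Al weakly: large EFs
  expect_true(all(
    rep$verdict[rep$element %in% c("K", "Rb", "Zn")] == "accumulated"
  ))
})

test_that("run_pipeline writes a complete, reproducible artifact set", {
  out1 <- file.path(tempdir(), "run1")
  out2 <- file.path(tempdir(), "run2")
  cfg <- analysis_config(seed = 7L)
  study <- generate_study(synth_config(n_sites = 10, seed = 7))
  res <- run_pipeline(out1, study = study, config = cfg)
  expected <- c(
    "sites.csv", "frond.csv", "humus.csv", "topsoil.csv", "subsoil.csv",
    "summary.csv", "indices.csv", "median_indices.csv", "ree_patterns.csv",
    "stoichiometry.csv", "correlations.csv", "report.csv", "elements.nwk",
    "sites.nwk", "elements_tree.json", "sites_tree.json", "report.json",
    "manifest.json"
  )
  expect_setequal(list.files(out1), expected)
  manifest <- jsonlite::read_json(file.path(out1, "manifest.json"),
    simplifyVector = TRUE
  )
  expect_equal(manifest$seed, 7)
  expect_equal(manifest$config$ree_reference, "PAAS-P2012")
  expect_true(nzchar(manifest$config_hash))

  # same study + config => byte-identical artifacts
  run_pipeline(out2, study = study, config = cfg)
  for (f in expected) {
    expect_identical(
      readLines(file.path(out1, f)), readLines(file.path(out2, f)),
      label = f
    )
  }
  # summary CSV carries the conventional column order
  hdr <- readLines(file.path(out1, "summary.csv"), n = 1)
  expect_match(hdr, "Min,Max,Mean,SD,RSD \\(%\\),I.Q,Median,III.Q,MAD")
  expect_s3_class(res$report, "tbl_df")
})

test_that("plot constructors return ggplot objects", {
  study <- small_study(n_sites = 8, seed = 19)
  frond <- aggregate_replicates(study$frond)
  med <- median_index(
    compute_indices(frond, study[c("humus", "topsoil")])
  )
  expect_s3_class(plot_median_indices(med, "BcF"), "ggplot")
  expect_s3_class(plot_median_indices(med, "EF"), "ggplot")
  expect_s3_class(plot_ree_pattern(ce_anomaly_table(frond)), "ggplot")
  tree <- cluster_elements(study$frond)
  expect_s3_class(ggplot2::autoplot(tree), "ggplot")
})
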