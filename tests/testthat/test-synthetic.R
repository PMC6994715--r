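test_that("configuration validation names the offending field", {
  expect_error(fusil_sim_config(disease_baseline_prevalence = 1.2),
               "disease_baseline_prevalence",
               class = "fusil_config_error")
  expect_error(fusil_sim_config(hom_rate_viable = 0.4),
               class = "fusil_config_error")
  bad_props <- default_props <- fusil_sim_config()$class_proportions
  bad_props["CL"] <- bad_props["CL"] + 0.05
  expect_error(fusil_sim_config(class_proportions = bad_props),
               "sum to 1", class = "fusil_config_error")
  expect_error(fusil_sim_config(true_bin_or = c(DL = -1)),
               class = "fusil_config_error")
})

test_that("the same configuration and seed reproduce the bundle exactly", {
  cfg <- small_sim_config(n_genes = 300, seed = 9)
  b1 <- generate_dataset(cfg)
  b2 <- generate_dataset(cfg)
  for (nm in setdiff(names(b1), "config")) {
    expect_identical(b1[[nm]], b2[[nm]], label = nm)
  }
  b3 <- generate_dataset(small_sim_config(n_genes = 300, seed = 10))
  expect_false(identical(b1$crosses, b3$crosses))
})

test_that("intercross counts conserve the litter and follow the binomial", {
  set.seed(2)
  z <- generate_cross(rep(0, 50), 28)
  expect_true(all(z$n_hom == 0))
  expect_true(all(z$n_hom + z$n_het + z$n_wt == z$n_total))
  x <- generate_cross(rep(0.25, 10000), 28)
  expect_true(all(x$n_hom + x$n_het + x$n_wt == 28))
  # analytic expectation of the homozygote fraction
  expect_lt(abs(mean(x$n_hom / 28) - 0.25), 0.01)
  # het:wt split of the residual mass is 2:1
  expect_lt(abs(mean(x$n_het / (28 - x$n_hom)) - 2 / 3), 0.01)
  expect_error(generate_cross(0.3, 28), class = "fusil_config_error")
  expect_error(generate_cross(0.1, 0), class = "fusil_config_error")
})

test_that("disease flags solve the odds equation per bin", {
  # DL at OR 2.6 over baseline 0.20 implies p_DL = 0.394
  odds <- 2.6 * 0.2 / 0.8
  expect_equal(round(odds / (1 + odds), 3), 0.394)
  set.seed(6)
  bins <- rep(c("DL", "VN"), each = 20000)
  flags <- generate_disease_flags(bins, 0.2, c(DL = 2.6))
  expect_lt(abs(mean(flags[bins == "DL"]) - 0.394), 0.02)
  expect_lt(abs(mean(flags[bins == "VN"]) - 0.2), 0.02)
  # all ORs 1: prevalence at baseline in every bin
  null_flags <- generate_disease_flags(bins, 0.2, c(DL = 1))
  expect_lt(abs(mean(null_flags[bins == "DL"]) - 0.2), 0.02)
  expect_error(generate_disease_flags("DL", 0, c(DL = 2)),
               class = "fusil_config_error")
})

test_that("lethal-class genes produce zero homozygotes and embryo truth", {
  b <- generate_dataset(small_sim_config(n_genes = 600, seed = 4))
  lethal_genes <- b$truth$gene_id[b$truth$latent_class %in% c("CL", "DL")]
  first_lines <- b$crosses[!duplicated(b$crosses$gene_id), ]
  expect_true(all(
    first_lines$n_hom[first_lines$gene_id %in% lethal_genes] == 0))
  # windows only exist for lethal classes
  expect_true(all(
    b$truth$latent_window[!(b$truth$latent_class %in% c("CL", "DL"))] ==
      "none"))
  expect_false(anyDuplicated(b$truth$gene_id) > 0)
})

test_that("empirical class fractions track the configured proportions", {
  cfg <- fusil_sim_config(n_genes = 5000, seed = 12)
  b <- generate_dataset(cfg)
  frac <- table(b$truth$latent_class)[names(cfg$class_proportions)] / 5000
  expect_true(all(abs(frac - cfg$class_proportions) < 0.02))
  # chi-square goodness of fit aggregated over several seeds
  counts <- Reduce(`+`, lapply(1:5, function(s) {
    tt <- generate_dataset(fusil_sim_config(n_genes = 5000,
                                            seed = 100 + s))$truth
    table(factor(tt$latent_class, levels = names(cfg$class_proportions)))
  }))
  gof <- suppressWarnings(
    chisq.test(counts, p = cfg$class_proportions))
  expect_gt(gof$p.value, 0.001)
})

test_that("written bundles round-trip through TSV with a manifest", {
  dir <- withr::local_tempdir()
  b <- generate_dataset(small_sim_config(n_genes = 120, seed = 3))
  manifest <- write_dataset_bundle(b, dir)
  expect_true(file.exists(manifest))
  mf <- jsonlite::read_json(manifest)
  expect_equal(mf$seed, 3)
  crosses <- read_fusil_tsv(file.path(dir, "crosses.tsv"),
                            required = c("gene_id", "n_total", "n_hom"))
  expect_equal(nrow(crosses), nrow(b$crosses))
  # identical regeneration gives identical files (checksum determinism)
  dir2 <- withr::local_tempdir()
  write_dataset_bundle(generate_dataset(small_sim_config(n_genes = 120,
                                                         seed = 3)), dir2)
  f1 <- sort(list.files(dir, full.names = TRUE))
  f2 <- sort(list.files(dir2, full.names = TRUE))
  expect_identical(unname(tools::md5sum(f1[basename(f1) != "manifest.json"])),
                   unname(tools::md5sum(f2[basename(f2) != "manifest.json"])))
})

test_that("borderline flags capture exactly the confusable latent genes", {
  b <- generate_dataset(fusil_sim_config(n_genes = 2000, seed = 19))
  tr <- b$truth
  # planted outliers and orthology-ambiguous genes are always borderline
  expect_true(all(tr$is_borderline[tr$latent_class %in%
                                     c("SV.outlier", "V.outlier")]))
  expect_true(all(tr$is_borderline[tr$is_ambiguous_orthology]))
  # a lethal gene with a full litter and a far-from-threshold score is not
  litter <- b$crosses$n_total[match(tr$gene_id, b$crosses$gene_id)]
  clean <- tr$latent_class == "CL" & !tr$is_ambiguous_orthology &
    !tr$is_hemizygous & !tr$is_conflicting & litter >= 28 &
    tr$latent_mean_score < -0.7
  expect_true(any(clean))
  expect_true(all(!tr$is_borderline[clean]))
  expect_true(all(tr$misclass_prob[clean] <= 0.01))
})
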