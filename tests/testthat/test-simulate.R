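test_that("simulator is deterministic under a fixed seed", {
  cfg <- small_sim_config(seed = 101)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$matrix, b$matrix)
  expect_identical(a$truth$latent_d, b$truth$latent_d)
  c_ <- simulate_dataset(small_sim_config(seed = 102))
  expect_false(identical(a$matrix, c_$matrix))
})

test_that("noiseless limit returns the program means exactly", {
  cfg <- small_sim_config(seed = 55)
  cfg$noise_sd <- 1e-12             # config validation requires > 0
  sim <- simulate_dataset(cfg)
  act <- sim$truth$program_activities
  pro_rows <- grep("^PRO_", rownames(sim$matrix))
  for (r in pro_rows)
    expect_equal(unname(sim$matrix[r, ]),
                 unname(cfg$baseline + act[, "proliferative"]),
                 tolerance = 1e-9)
  bkg <- sim$matrix[grep("^BKG_", rownames(sim$matrix)), ]
  expect_equal(unname(bkg), matrix(cfg$baseline, nrow(bkg), ncol(bkg)),
               tolerance = 1e-9)
})

test_that("latent coordinate, labels and couplings follow the design", {
  sim <- simulate_dataset(simulation_config(seed = 77))
  d <- sim$truth$latent_d
  expect_true(all(d >= 0 & d <= 1))
  lab <- sim$truth$phenotype_label
  expect_setequal(unique(lab), c("melanocytic", "transitory", "ncsc",
                                 "undifferentiated"))
  # labels are ordered along d
  expect_true(max(d[lab == "melanocytic"]) <= min(d[lab == "ncsc"]))
  act <- sim$truth$program_activities
  expect_equal(cor(act[, "proliferative"], 1 - d), 1, tolerance = 1e-12)
  expect_equal(cor(act[, "invasive"], d), 1, tolerance = 1e-12)
  # mesenchymal bump peaks near the configured NCSC position
  expect_equal(unname(d[which.max(act[, "mesenchymal"])]),
               0.7, tolerance = 0.05)
  expect_equal(max(abs(act[, "glycolysis"] / 3 -
                         act[, "mesenchymal"] / 3)), 0, tolerance = 1e-12)
})

test_that("simulate_batch derives reproducible, jittered datasets", {
  cfg <- small_sim_config()
  b1 <- simulate_batch(3, cfg, seed = 11, effect_jitter = 0.2)
  b2 <- simulate_batch(3, cfg, seed = 11, effect_jitter = 0.2)
  expect_length(b1, 3)
  expect_identical(b1$dataset_01$matrix, b2$dataset_01$matrix)
  expect_false(identical(b1$dataset_01$matrix, b1$dataset_02$matrix))

  # zero jitter: all datasets share effect sizes, differ only in draws
  z <- simulate_batch(2, cfg, seed = 4, effect_jitter = 0)
  expect_false(identical(z$dataset_01$matrix, z$dataset_02$matrix))
  expect_equal(dim(z$dataset_01$matrix), dim(z$dataset_02$matrix))
})

test_that("pipeline recovers the generator's coupling structure", {
  sim <- simulate_dataset(simulation_config(n_samples = 300, seed = 19))
  sc <- score_panel(sim$matrix, sim$gene_sets)
  mi <- spearman_pair(sc$mesenchymal, sc$invasive)
  ei <- spearman_pair(sc$epithelial, sc$invasive)
  expect_gt(mi$rho, 0.36)
  expect_true(mi$significant)
  expect_lt(abs(ei$rho), 0.36)
  # OXPHOS decreases along the axis
  expect_lt(spearman_pair(sc$oxphos, sc$invasive)$rho, -0.36)
})

test_that("top-10% calls recover the true quartile labels with high precision", {
  sim <- simulate_dataset(simulation_config(seed = 23))
  sc <- score_panel(sim$matrix, sim$gene_sets)
  calls <- suppressMessages(assign_phenotypes(
    sc[, c("melanocytic", "transitory", "ncsc", "undifferentiated")]))
  prec <- vapply(colnames(calls$flags), function(p) {
    flagged <- rownames(calls$flags)[calls$flags[, p]]
    mean(sim$truth$phenotype_label[flagged] == p)
  }, numeric(1))
  expect_true(all(prec >= 0.8))
})

test_that("raising the noise degrades the mesenchymal-invasive coupling", {
  median_rho <- function(noise_sd, seed) {
    cfg <- small_sim_config(noise_sd = noise_sd)
    batch <- simulate_batch(8, cfg, seed = seed, effect_jitter = 0)
    stats::median(vapply(batch, function(ds) {
      m <- ssgsea_score(ds$matrix, ds$gene_sets$mesenchymal_tumor)
      i <- ssgsea_score(ds$matrix, ds$gene_sets$verfaillie_invasive)
      abs(spearman_pair(m, i)$rho)
    }, numeric(1)))
  }
  rhos <- vapply(c(0.5, 2, 8), median_rho, numeric(1), seed = 13)
  expect_true(all(diff(rhos) < 0))
})

test_that("config validation rejects invalid settings before sampling", {
  expect_error(simulation_config(noise_sd = 0), "noise_sd")
  expect_error(simulation_config(mesenchymal_peak = 1), "strictly inside")
  expect_error(simulation_config(genes_per_program = c(bogus = 5)),
               "unknown program")
  expect_error(simulation_config(genes_per_program = c(fao = 0)), ">= 1")
  expect_error(simulate_dataset(list(n_samples = 5)), "simulation_config")
})
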