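test_that("run_full_pipeline writes the seven result files plus a manifest", {
  out <- withr::local_tempdir()
  cfg <- list(simulate = list(n_samples = 60,
                              genes_per_program = c(background = 60)),
              seed = 5, out_dir = out)
  res <- suppressMessages(suppressWarnings(run_full_pipeline(cfg)))
  files <- c("scores.tsv", "correlations.tsv", "volcano.json",
             "window_profiles.tsv", "phenotype_calls.tsv",
             "conditional_tests.tsv", "trends.json", "manifest.json")
  expect_true(all(file.exists(file.path(out, files))))

  manifest <- jsonlite::read_json(file.path(out, "manifest.json"))
  expect_equal(manifest$n_samples, 60)
  expect_length(manifest$files, 7)
  # checksums validate
  sums <- tools::md5sum(file.path(out, names(manifest$files)))
  expect_equal(unname(sums), unlist(manifest$files, use.names = FALSE))

  scores <- read.delim(file.path(out, "scores.tsv"))
  expect_equal(nrow(scores), 60)
  expect_equal(ncol(scores), 15)  # sample_id + 14 scores
})

test_that("reruns with the same seed and config are byte-identical", {
  cfg <- list(simulate = list(n_samples = 50,
                              genes_per_program = c(background = 50)),
              seed = 9)
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  suppressMessages(suppressWarnings(run_full_pipeline(cfg, out_dir = out1)))
  suppressMessages(suppressWarnings(run_full_pipeline(cfg, out_dir = out2)))
  for (f in list.files(out1)) {
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)), label = f)
  }
})

test_that("a 20-sample run flags two samples per phenotype", {
  out <- withr::local_tempdir()
  cfg <- list(simulate = list(n_samples = 20,
                              genes_per_program = c(background = 40)),
              quantile = 0.9, seed = 3, out_dir = out)
  res <- suppressMessages(suppressWarnings(run_full_pipeline(cfg)))
  expect_equal(unname(colSums(res$calls$flags)), rep(2L, 4))
})

test_that("stage failures name the failing stage", {
  bad <- matrix(1:4, 2, 2, dimnames = list(c("g1", "g2"), c("s1", "s2")))
  storage.mode(bad) <- "double"
  coll <- gene_set_collection(list(gene_set("x", "g1")))
  expect_error(
    run_full_pipeline(list(matrix = bad, collection = coll,
                           out_dir = withr::local_tempdir())),
    "stage 'score_panel'")
})

test_that("YAML run configs are read and validated", {
  p <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("simulate:", "  n_samples: 30", "seed: 2",
               paste0("out_dir: ", tempdir())), p)
  cfg <- read_run_config(p)
  expect_equal(cfg$simulate$n_samples, 30)

  writeLines(c("matrix: /definitely/not/here.tsv", "seed: 1"), p)
  expect_error(read_run_config(p), "does not exist")
  writeLines("seed: 1", p)
  expect_error(read_run_config(p), "either 'matrix'")
})
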