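#!/usr/bin/env Rscript
# Generate the synthetic study material: one reference dataset (200 samples)
# and a 20-dataset batch emulating a multi-cohort survey, all with ground
# truth. Later scripts regenerate the same objects from the same seeds; the
# TSV exports here are for inspection.

suppressPackageStartupMessages(library(melaxis))
dir.create("results", showWarnings = FALSE)

cfg <- simulation_config(seed = 1)
ref <- simulate_dataset(cfg)
write_tsv_matrix(ref$matrix, "results/reference_matrix.tsv",
                 id_column = "gene")
truth <- data.frame(sample_id = names(ref$truth$latent_d),
                    latent_d = ref$truth$latent_d,
                    phenotype = ref$truth$phenotype_label)
write.table(truth, "results/reference_truth.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

batch <- simulate_batch(20, cfg, seed = 1)
manifest <- data.frame(
  dataset = names(batch),
  n_samples = vapply(batch, function(d) ncol(d$matrix), integer(1)),
  n_genes = vapply(batch, function(d) nrow(d$matrix), integer(1)),
  mean_invasive_activity = vapply(batch, function(d)
    mean(d$truth$program_activities[, "invasive"]), numeric(1)))
write.table(manifest, "results/batch_manifest.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("Reference dataset:", nrow(ref$matrix), "genes x", ncol(ref$matrix),
    "samples; latent de-differentiation coordinate spans",
    sprintf("[%.3f, %.3f].\n", min(ref$truth$latent_d),
            max(ref$truth$latent_d)))
cat("Batch:", length(batch), "datasets with jittered effect sizes",
    "(manifest in results/batch_manifest.tsv).\n")
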