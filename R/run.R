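#' Read a pipeline run configuration from YAML
#'
#' Fields: `matrix` (TSV/CSV path) or `simulate` (a block of
#' [simulation_config()] arguments), `gmt` (vector of GMT paths; omitted
#' when simulating — the simulated program sets are used), `context`
#' (`tumor`/`cell_line`), analysis parameters (`rho_threshold`, `alpha`,
#' `window_frac`, `step_frac`, `quantile`, `band_method`, `p0`), `seed`,
#' `out_dir`. Unset parameters take the pipeline defaults.
#'
#' @param path YAML file path.
#' @return named list suitable for [run_full_pipeline()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$matrix) && is.null(cfg$simulate))
    stop("config must provide either 'matrix' or a 'simulate' block")
  if (!is.null(cfg$matrix) && !file.exists(cfg$matrix))
    stop("matrix path does not exist: ", cfg$matrix)
  for (g in cfg$gmt) if (!file.exists(g)) stop("GMT path does not exist: ", g)
  cfg
}

pipeline_defaults <- list(context = "tumor", rho_threshold = 0.36,
                          alpha = 0.05, window_frac = 0.60, step_frac = 0.01,
                          quantile = 0.90, band_method = "tercile",
                          p0 = NULL, ssgsea_alpha = 0.25, seed = 1L)

#' Run the full scoring-and-inference pipeline on one dataset
#'
#' Executes, in order: input preparation (read or simulate the expression
#' matrix), the 14-score panel, the correlation records and volcano
#' summary, the EMT-plane gradients (invasive overlay, moving windows
#' along the E and M axes), the top-10% phenotype assignment, the
#' intermediate-M-band conditional Z tests for all four phenotypes, and
#' the phenotype trend verdicts for the M and OXPHOS scores. All outputs
#' are written as TSV/JSON under `out_dir` together with a machine-readable
#' manifest (parameters, seed, matched-gene counts, file checksums).
#'
#' @param config named list as produced by [read_run_config()], or
#'   assembled in code; `matrix` may be a path or an in-memory matrix and
#'   `collection` may carry a ready [gene_set_collection()].
#' @param out_dir output directory (created); overrides `config$out_dir`.
#' @return (invisibly) list with all in-memory stage results and
#'   `out_dir`.
#' @export
run_full_pipeline <- function(config, out_dir = config$out_dir) {
  cfg <- utils::modifyList(pipeline_defaults, config[!vapply(config, is.null,
                                                             logical(1))])
  if (is.null(out_dir)) stop("config must name an output directory")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  # --- stage: input -------------------------------------------------------
  stage <- "input"
  res <- tryCatch({
    if (!is.null(cfg$simulate)) {
      sim_cfg <- do.call(simulation_config,
                         utils::modifyList(as.list(cfg$simulate),
                                           list(seed = cfg$seed)))
      sim <- simulate_dataset(sim_cfg)
      mat <- sim$matrix
      collection <- sim$gene_sets
    } else {
      mat <- if (is.matrix(cfg$matrix)) cfg$matrix
        else read_expression_matrix(cfg$matrix)
      collection <- if (!is.null(cfg$collection)) cfg$collection
        else {
          colls <- lapply(cfg$gmt, read_gmt)
          gene_set_collection(do.call(c, lapply(colls, unclass)))
        }
    }
    validate_expression_matrix(mat)

    stage <- "score_panel"
    scores <- score_panel(mat, collection, context = cfg$context,
                          alpha = cfg$ssgsea_alpha)

    stage <- "correlate"
    records <- correlate_panel(scores, dataset_id = "run",
                               rho_threshold = cfg$rho_threshold,
                               alpha = cfg$alpha)
    volcano <- volcano_summary(records, cfg$rho_threshold, cfg$alpha)

    stage <- "emt_plane"
    plane <- emt_plane(scores, overlay = "invasive")
    grads <- plane_gradients(plane, cfg$window_frac, cfg$step_frac)

    stage <- "classify"
    calls <- assign_phenotypes(scores[, c("melanocytic", "transitory",
                                          "ncsc", "undifferentiated")],
                               quantile = cfg$quantile)

    stage <- "conditional_test"
    m_scores <- stats::setNames(scores$mesenchymal, rownames(scores))
    band <- intermediate_band(m_scores, method = cfg$band_method)
    cond <- do.call(rbind, lapply(colnames(calls$flags), function(p)
      conditional_test(calls, band, p, p0 = cfg$p0)))

    stage <- "trend"
    trend_m <- phenotype_trend(calls, m_scores)
    trend_ox <- phenotype_trend(calls,
                                stats::setNames(scores$oxphos,
                                                rownames(scores)))
    list(matrix = mat, scores = scores, records = records, volcano = volcano,
         plane = plane, gradients = grads, calls = calls, band = band,
         conditional = cond, trend_m = trend_m, trend_oxphos = trend_ox)
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })

  # --- write outputs ------------------------------------------------------
  f <- function(name) file.path(out_dir, name)
  write_tsv_matrix(res$scores, f("scores.tsv"), id_column = "sample_id")
  utils::write.table(res$records, f("correlations.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(res$volcano, f("volcano.json"), auto_unbox = TRUE,
                       digits = NA)
  profiles <- do.call(rbind, lapply(names(res$gradients), function(axn) {
    pr <- res$gradients[[axn]]
    data.frame(axis = axn, center = pr$centers, mean = pr$means,
               count = pr$counts, slope = pr$slope)
  }))
  utils::write.table(profiles, f("window_profiles.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_tsv_matrix(res$calls$flags, f("phenotype_calls.tsv"),
                   id_column = "sample_id")
  utils::write.table(res$conditional, f("conditional_tests.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(mesenchymal = unclass(res$trend_m), oxphos = unclass(res$trend_oxphos)),
    f("trends.json"), auto_unbox = TRUE, digits = NA)

  result_files <- c("scores.tsv", "correlations.tsv", "volcano.json",
                    "window_profiles.tsv", "phenotype_calls.tsv",
                    "conditional_tests.tsv", "trends.json")
  manifest <- list(
    package_version = as.character(utils::packageVersion("melaxis")),
    parameters = cfg[setdiff(names(cfg), c("collection", "matrix"))],
    n_samples = ncol(res$matrix), n_genes = nrow(res$matrix),
    matched_genes = lapply(attr(res$scores, "score_metadata"),
                           `[[`, "n_matched"),
    band_size = length(res$band),
    files = as.list(tools::md5sum(file.path(out_dir, result_files)))
  )
  names(manifest$files) <- result_files
  jsonlite::write_json(manifest, f("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(c(res, list(out_dir = out_dir, manifest = manifest)))
}
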