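#' Configuration for the synthetic expression-program simulator
#'
#' The simulator draws, per sample, a latent de-differentiation coordinate
#' `d ~ Uniform(0, 1)` (melanocytic at 0, undifferentiated at 1) and builds
#' gene programs coupled to it the way the melanoma pipeline expects to
#' find them: the proliferative, OXPHOS and FAO programs decrease linearly
#' in `d`; the invasive program increases linearly; the mesenchymal program
#' (and the glycolysis and HIF-1 programs that track it) follows a smooth
#' unimodal bump peaking at the NCSC position (`mesenchymal_peak`, 0.7);
#' the epithelial program is statistically independent of `d`; four
#' phenotype marker programs are Gaussian kernels centred on the quartile
#' midpoints of `d`. Each program gene is its program activity plus
#' i.i.d. Gaussian noise on the log2 scale; background genes are pure
#' noise around the baseline.
#'
#' @param n_samples samples per dataset.
#' @param genes_per_program named integer vector of program sizes; defaults
#'   cover proliferative, invasive, epithelial, mesenchymal, oxphos,
#'   glycolysis, hif1, fao (14 genes, matching the FAO score's gene count),
#'   the four phenotype marker programs and background.
#' @param effect_size program activity amplitude in log2 units (single
#'   number or named per-program vector).
#' @param noise_sd per-gene Gaussian noise sd (log2 units), > 0.
#' @param mesenchymal_peak position of the mesenchymal bump's mode in
#'   (0, 1); default 0.7, the NCSC position.
#' @param bump_concentration sharpness of the mesenchymal bump (the bump is
#'   `d^a (1-d)^b` rescaled to peak at 1, with `a = c * peak`,
#'   `b = c * (1 - peak)`).
#' @param phenotype_kernel_sd sd of the phenotype marker kernels along `d`.
#' @param baseline additive log2 baseline expression.
#' @param seed RNG seed for [simulate_dataset()]; `NULL` = use current RNG
#'   state.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(n_samples = 200,
                              genes_per_program = NULL,
                              effect_size = 3,
                              noise_sd = 1,
                              mesenchymal_peak = 0.7,
                              bump_concentration = 4,
                              phenotype_kernel_sd = 0.12,
                              baseline = 6,
                              seed = NULL) {
  defaults <- c(proliferative = 30L, invasive = 30L, epithelial = 30L,
                mesenchymal = 30L, oxphos = 30L, glycolysis = 30L,
                hif1 = 30L, fao = 14L, melanocytic = 30L, transitory = 30L,
                ncsc = 30L, undifferentiated = 30L, background = 150L)
  gp <- defaults
  if (!is.null(genes_per_program)) {
    unknown <- setdiff(names(genes_per_program), names(defaults))
    if (length(unknown))
      stop("unknown program(s): ", paste(unknown, collapse = ", "))
    gp[names(genes_per_program)] <- as.integer(genes_per_program)
  }
  if (any(gp < 1)) stop("all program gene counts must be >= 1")
  programs <- setdiff(names(gp), "background")
  eff <- if (length(effect_size) == 1 && is.null(names(effect_size))) {
    stats::setNames(rep(as.numeric(effect_size), length(programs)), programs)
  } else {
    miss <- setdiff(programs, names(effect_size))
    if (length(miss))
      stop("effect_size missing program(s): ", paste(miss, collapse = ", "))
    as.numeric(effect_size[programs])
  }
  names(eff) <- programs
  if (n_samples < 2) stop("need at least 2 samples")
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  if (mesenchymal_peak <= 0 || mesenchymal_peak >= 1)
    stop("mesenchymal_peak must lie strictly inside (0, 1)")
  if (any(eff < 0)) stop("effect sizes must be >= 0")
  structure(list(n_samples = as.integer(n_samples), genes_per_program = gp,
                 effect_size = eff, noise_sd = noise_sd,
                 mesenchymal_peak = mesenchymal_peak,
                 bump_concentration = bump_concentration,
                 phenotype_kernel_sd = phenotype_kernel_sd,
                 baseline = baseline, seed = seed),
            class = "simulation_config")
}

# Unimodal bump on [0,1]: zero at 0 and 1, maximum 1 at `peak`.
mesenchymal_bump <- function(d, peak, concentration) {
  a <- concentration * peak
  b <- concentration * (1 - peak)
  (d / peak)^a * ((1 - d) / (1 - peak))^b
}

phenotype_kernel_centers <- c(melanocytic = 0.125, transitory = 0.375,
                              ncsc = 0.625, undifferentiated = 0.875)

# Expected program activities (samples x programs) given latent d; the
# epithelial program is drawn, not deterministic, so it is passed in.
program_activities <- function(d, config, epithelial_z) {
  eff <- config$effect_size
  bump <- mesenchymal_bump(d, config$mesenchymal_peak,
                           config$bump_concentration)
  act <- cbind(
    proliferative = eff["proliferative"] * (1 - d),
    invasive = eff["invasive"] * d,
    epithelial = eff["epithelial"] * 0.3 * epithelial_z,
    mesenchymal = eff["mesenchymal"] * bump,
    oxphos = eff["oxphos"] * (1 - d),
    glycolysis = eff["glycolysis"] * bump,
    hif1 = eff["hif1"] * bump,
    fao = eff["fao"] * (1 - d)
  )
  for (p in names(phenotype_kernel_centers)) {
    act <- cbind(act, eff[p] * exp(-(d - phenotype_kernel_centers[p])^2 /
                                     (2 * config$phenotype_kernel_sd^2)))
    colnames(act)[ncol(act)] <- p
  }
  rownames(act) <- NULL
  act
}

simulated_gene_names <- function(config) {
  gp <- config$genes_per_program
  prefix <- c(proliferative = "PRO", invasive = "INV", epithelial = "EPI",
              mesenchymal = "MES", oxphos = "OXP", glycolysis = "GLY",
              hif1 = "HIF", fao = "FAO", melanocytic = "TMEL",
              transitory = "TTRA", ncsc = "TNCS",
              undifferentiated = "TUND", background = "BKG")
  out <- lapply(names(gp), function(p)
    sprintf("%s_%04d", prefix[[p]], seq_len(gp[[p]])))
  names(out) <- names(gp)
  # the first epithelial gene doubles as the 76GS anchor
  out$epithelial[1] <- "CDH1"
  out
}

#' Gene sets matching a simulated dataset
#'
#' Builds the [gene_set_collection()] that [score_panel()] needs, from the
#' program gene names of a simulated dataset: the epithelial program genes
#' serve as the epithelial list (both contexts) and as the 76GS signature
#' (its first gene is named CDH1 so the anchor weighting engages), the
#' mesenchymal program genes as the mesenchymal list, and so on.
#'
#' @param config the [simulation_config()] the dataset was generated with.
#' @return a [gene_set_collection()].
#' @export
simulation_gene_sets <- function(config) {
  gn <- simulated_gene_names(config)
  mk <- function(name, genes, context = "generic")
    gene_set(name, genes, context = context, provenance = "simulated program")
  gene_set_collection(list(
    mk("verfaillie_proliferative", gn$proliferative),
    mk("verfaillie_invasive", gn$invasive),
    mk("hoek_proliferative", gn$proliferative),
    mk("hoek_invasive", gn$invasive),
    mk("epithelial_tumor", gn$epithelial, "tumor"),
    mk("mesenchymal_tumor", gn$mesenchymal, "tumor"),
    mk("epithelial_cell_line", gn$epithelial, "cell_line"),
    mk("mesenchymal_cell_line", gn$mesenchymal, "cell_line"),
    mk("GS76", gn$epithelial),
    mk("hallmark_oxphos", gn$oxphos),
    mk("hallmark_glycolysis", gn$glycolysis),
    mk("HIF1_targets", gn$hif1),
    mk("FAO_enzymes", gn$fao),
    mk("tsoi_melanocytic", gn$melanocytic),
    mk("tsoi_transitory", gn$transitory),
    mk("tsoi_ncsc", gn$ncsc),
    mk("tsoi_undifferentiated", gn$undifferentiated)
  ))
}

with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Simulate one expression dataset with ground truth
#'
#' @param config a [simulation_config()].
#' @return list with `matrix` (log2 expression, genes x samples), `truth`
#'   (list: `latent_d`, `phenotype_label` — the quartile-of-d label —,
#'   `program_activities` samples x programs), and `gene_sets`
#'   ([simulation_gene_sets()] for the config). Bit-identical under a
#'   fixed `config$seed`.
#' @export
simulate_dataset <- function(config) {
  if (!inherits(config, "simulation_config"))
    stop("config must come from simulation_config()")
  with_local_seed(config$seed, {
    n <- config$n_samples
    d <- stats::runif(n)
    epi_z <- stats::rnorm(n)
    act <- program_activities(d, config, epi_z)
    gn <- simulated_gene_names(config)
    gp <- config$genes_per_program

    blocks <- lapply(names(gp), function(p) {
      k <- gp[[p]]
      mean_mat <- if (p == "background") matrix(0, k, n)
        else matrix(act[, p], nrow = k, ncol = n, byrow = TRUE)
      noise <- if (config$noise_sd > 0)
        matrix(stats::rnorm(k * n, sd = config$noise_sd), k, n)
        else 0
      config$baseline + mean_mat + noise
    })
    mat <- do.call(rbind, blocks)
    rownames(mat) <- unlist(gn, use.names = FALSE)
    colnames(mat) <- sprintf("S%04d", seq_len(n))

    labels <- cut(d, breaks = c(-Inf, 0.25, 0.5, 0.75, Inf),
                  labels = c("melanocytic", "transitory", "ncsc",
                             "undifferentiated"))
    truth <- list(latent_d = stats::setNames(d, colnames(mat)),
                  phenotype_label = stats::setNames(as.character(labels),
                                                    colnames(mat)),
                  program_activities = act)
    list(matrix = mat, truth = truth,
         gene_sets = simulation_gene_sets(config))
  })
}

#' Simulate a batch of independent datasets
#'
#' Emulates a multi-dataset survey: each dataset is generated from the
#' template config with its own reproducibly derived seed and (optionally)
#' a per-dataset multiplicative jitter of all effect sizes, so datasets
#' differ in coupling strength as real cohorts do.
#'
#' @param n_datasets number of datasets, >= 1.
#' @param config template [simulation_config()].
#' @param seed master seed; per-dataset seeds are derived from it.
#' @param effect_jitter half-width of the uniform multiplicative jitter on
#'   effect sizes (0.2 = +/-20%); 0 disables jitter.
#' @return list of [simulate_dataset()] results, named `dataset_01`, ...
#' @export
simulate_batch <- function(n_datasets, config, seed = 1, effect_jitter = 0.2) {
  if (n_datasets < 1) stop("n_datasets must be >= 1")
  if (effect_jitter < 0 || effect_jitter >= 1)
    stop("effect_jitter must lie in [0, 1)")
  seeds <- (as.integer(seed) + 1013L * seq_len(n_datasets)) %% .Machine$integer.max
  jitters <- with_local_seed(as.integer(seed),
    stats::runif(n_datasets, 1 - effect_jitter, 1 + effect_jitter))
  out <- lapply(seq_len(n_datasets), function(i) {
    cfg_i <- config
    cfg_i$effect_size <- config$effect_size * jitters[i]
    cfg_i$seed <- seeds[i]
    simulate_dataset(cfg_i)
  })
  names(out) <- sprintf("dataset_%02d", seq_len(n_datasets))
  out
}
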