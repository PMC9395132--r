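#' Single-sample GSEA enrichment score
#'
#' For each sample, genes are ranked by expression (average ranks for ties;
#' the most highly expressed gene carries rank N) and the ranked list is
#' walked from the top down, accumulating a rank-weighted empirical CDF over
#' the set genes (weights `rank^alpha`, normalized to sum to one over the
#' set) minus a uniform ECDF over the out-of-set genes. The score is the sum
#' of the running difference over all N positions. Rank-based, so invariant
#' to any strictly increasing per-sample transform of expression.
#'
#' @param matrix log2 expression matrix (genes x samples).
#' @param gene_set a [gene_set()] or character vector of gene identifiers.
#' @param alpha rank-weight exponent, >= 0 (0.25 by default, the originating
#'   method's published default).
#' @param normalize divide the final scores by `max - min` across samples
#'   (off by default; the downstream correlation stages are rank-based, so
#'   the choice does not affect them).
#' @return named numeric vector, one score per sample.
#' @export
ssgsea_score <- function(matrix, gene_set, alpha = 0.25, normalize = FALSE) {
  validate_expression_matrix(matrix)
  if (alpha < 0) stop("alpha must be >= 0")
  m <- match_set_genes(matrix, gene_set)
  if (m$n_matched == 0) stop("no gene of the set is present in the matrix")
  n_genes <- nrow(matrix)
  if (m$n_matched >= n_genes)
    stop("gene set covers all matrix genes; out-of-set ECDF undefined")
  in_set <- rownames(matrix) %in% m$genes
  n_out <- n_genes - m$n_matched
  ids <- rownames(matrix)

  scores <- vapply(seq_len(ncol(matrix)), function(j) {
    x <- matrix[, j]
    r <- rank(x, ties.method = "average")
    ord <- order(-x, ids)               # descending; ties broken by gene id
    w <- ifelse(in_set, r^alpha, 0)[ord]
    p_in <- cumsum(w) / sum(w)
    p_out <- cumsum(!in_set[ord]) / n_out
    sum(p_in - p_out)
  }, numeric(1))
  names(scores) <- colnames(matrix)
  if (normalize) {
    rng <- max(scores) - min(scores)
    if (rng == 0) stop("cannot range-normalize: identical scores across samples")
    scores <- scores / rng
  }
  scores
}

#' Signed Kolmogorov-Smirnov EMT score
#'
#' Per sample, the empirical CDFs of the epithelial-gene and
#' mesenchymal-gene expression values are compared:
#' `D+ = sup(F_E - F_M)`, `D- = sup(F_M - F_E)`, score `= D+ - D-`.
#' The score is bounded in \[-1, +1\] and antisymmetric in the two lists;
#' positive values mean the mesenchymal genes sit higher in the sample's
#' expression distribution (more mesenchymal).
#'
#' @param matrix log2 expression matrix.
#' @param e_set epithelial [gene_set()] (or character vector).
#' @param m_set mesenchymal [gene_set()] (or character vector).
#' @return named numeric vector of per-sample scores in \[-1, 1\].
#' @export
ks_emt_score <- function(matrix, e_set, m_set) {
  validate_expression_matrix(matrix)
  e <- match_set_genes(matrix, e_set)
  m <- match_set_genes(matrix, m_set)
  if (length(intersect(e$genes, m$genes)))
    stop("epithelial and mesenchymal sets overlap after matching")
  if (e$n_matched == 0) stop("no epithelial gene present in the matrix")
  if (m$n_matched == 0) stop("no mesenchymal gene present in the matrix")
  e_idx <- base::match(e$genes, rownames(matrix))
  m_idx <- base::match(m$genes, rownames(matrix))

  scores <- vapply(seq_len(ncol(matrix)), function(j) {
    ev <- matrix[e_idx, j]
    mv <- matrix[m_idx, j]
    br <- sort(unique(c(ev, mv)))
    fe <- vapply(br, function(b) mean(ev <= b), numeric(1))
    fm <- vapply(br, function(b) mean(mv <= b), numeric(1))
    max(fe - fm) - max(fm - fe)
  }, numeric(1))
  names(scores) <- colnames(matrix)
  scores
}

#' 76-gene epithelial signature score
#'
#' Weighted sum of signature-gene expression per sample, the weight of each
#' gene being its Pearson correlation with the anchor gene (CDH1 by
#' default) across samples; the anchor itself carries weight 1. Scores are
#' mean-centered across samples. Higher = more epithelial. If the anchor is
#' absent from the matrix the engine falls back to unit weights with a
#' warning; genes with zero cross-sample variance get weight 0.
#'
#' @param matrix log2 expression matrix with >= 3 samples.
#' @param signature [gene_set()] of signature genes.
#' @param anchor_gene gene identifier used for correlation weighting.
#' @return named numeric vector of mean-centered scores (sum 0).
#' @export
gs76_score <- function(matrix, signature, anchor_gene = "CDH1") {
  validate_expression_matrix(matrix)
  if (ncol(matrix) < 3)
    stop("76GS weighting needs >= 3 samples (weights are cross-sample correlations)")
  m <- match_set_genes(matrix, signature)
  if (m$n_matched < 2) stop("fewer than 2 signature genes present in the matrix")
  sub <- matrix[m$genes, , drop = FALSE]

  if (!anchor_gene %in% rownames(matrix)) {
    warning("anchor gene '", anchor_gene,
            "' absent from matrix; falling back to unit weights")
    w <- rep(1, nrow(sub))
  } else {
    anchor <- matrix[anchor_gene, ]
    w <- apply(sub, 1L, function(g) {
      if (stats::sd(g) == 0 || stats::sd(anchor) == 0) 0
      else stats::cor(g, anchor)
    })
    w[rownames(sub) == anchor_gene] <- 1
  }
  raw <- as.vector(crossprod(sub, w))
  scores <- raw - mean(raw)
  names(scores) <- colnames(matrix)
  scores
}

#' Rank-based singscore
#'
#' Per sample, all N genes are ranked ascending (average ranks for ties)
#' and the mean rank of the set genes is rescaled so that the theoretical
#' minimum (set genes occupy the bottom |S| ranks) maps to -0.5 and the
#' theoretical maximum (top |S| ranks) maps to +0.5:
#' `score = (Rbar - Rbar_min) / (Rbar_max - Rbar_min) - 0.5`, with
#' `Rbar_min = (|S|+1)/2` and `Rbar_max = N - (|S|-1)/2`.
#'
#' @param matrix log2 expression matrix.
#' @param gene_set [gene_set()] or character vector.
#' @return named numeric vector of per-sample scores in \[-0.5, 0.5\].
#' @export
singscore <- function(matrix, gene_set) {
  validate_expression_matrix(matrix)
  m <- match_set_genes(matrix, gene_set)
  if (m$n_matched == 0) stop("no gene of the set is present in the matrix")
  n <- nrow(matrix)
  s <- m$n_matched
  if (s >= n) stop("set covers the whole gene universe; score undefined")
  in_set <- rownames(matrix) %in% m$genes
  rbar_min <- (s + 1) / 2
  rbar_max <- n - (s - 1) / 2

  scores <- vapply(seq_len(ncol(matrix)), function(j) {
    r <- rank(matrix[, j], ties.method = "average")
    rbar <- mean(r[in_set])
    (rbar - rbar_min) / (rbar_max - rbar_min) - 0.5
  }, numeric(1))
  names(scores) <- colnames(matrix)
  scores
}

#' Fatty-acid-oxidation z-mean score
#'
#' Each matched gene is z-scored across samples (mean 0, sd 1); a sample's
#' score is the mean of its z-scores over the matched genes. Genes with
#' zero cross-sample variance are dropped with a warning.
#'
#' @param matrix log2 expression matrix with >= 2 samples.
#' @param fao_genes [gene_set()] of FAO enzyme genes (or character vector).
#' @return named numeric vector; scores average to 0 across samples.
#' @export
fao_score <- function(matrix, fao_genes) {
  validate_expression_matrix(matrix)
  if (ncol(matrix) < 2) stop("z-scoring needs >= 2 samples")
  m <- match_set_genes(matrix, fao_genes)
  if (m$n_matched == 0) stop("no FAO gene present in the matrix")
  sub <- matrix[m$genes, , drop = FALSE]
  sds <- apply(sub, 1L, stats::sd)
  if (all(sds == 0)) stop("all matched FAO genes have zero cross-sample variance")
  if (any(sds == 0)) {
    warning(sum(sds == 0), " zero-variance FAO gene(s) dropped")
    sub <- sub[sds > 0, , drop = FALSE]
    sds <- sds[sds > 0]
  }
  z <- (sub - rowMeans(sub)) / sds
  scores <- colMeans(z)
  names(scores) <- colnames(matrix)
  scores
}

# Gene set names score_panel expects in the collection, by panel column.
panel_set_requirements <- function(context) {
  list(
    proliferative    = list(engine = "ssgsea", set = "verfaillie_proliferative"),
    invasive         = list(engine = "ssgsea", set = "verfaillie_invasive"),
    epithelial       = list(engine = "ssgsea",
                            set = paste0("epithelial_", context)),
    mesenchymal      = list(engine = "ssgsea",
                            set = paste0("mesenchymal_", context)),
    ks               = list(engine = "ks",
                            set = c(paste0("epithelial_", context),
                                    paste0("mesenchymal_", context))),
    gs76             = list(engine = "gs76", set = "GS76"),
    oxphos           = list(engine = "ssgsea", set = "hallmark_oxphos"),
    glycolysis       = list(engine = "ssgsea", set = "hallmark_glycolysis"),
    hif1             = list(engine = "singscore", set = "HIF1_targets"),
    fao              = list(engine = "fao", set = "FAO_enzymes"),
    melanocytic      = list(engine = "ssgsea", set = "tsoi_melanocytic"),
    transitory       = list(engine = "ssgsea", set = "tsoi_transitory"),
    ncsc             = list(engine = "ssgsea", set = "tsoi_ncsc"),
    undifferentiated = list(engine = "ssgsea", set = "tsoi_undifferentiated")
  )
}

#' Compute the full score panel for one dataset
#'
#' Assembles the 14 per-sample scores used throughout the pipeline:
#' Verfaillie proliferative/invasive, E and M (ssGSEA on the
#' context-appropriate epithelial/mesenchymal lists of the KS metric), the
#' signed KS score, 76GS, hallmark OXPHOS and glycolysis (ssGSEA), HIF-1
#' (singscore on its target genes), FAO (z-mean) and the four
#' melanocytic/transitory/NCSC/undifferentiated phenotype scores (ssGSEA).
#' Scores are always computed within one dataset, never across concatenated
#' datasets.
#'
#' @param matrix log2 expression matrix for a single dataset.
#' @param collection [gene_set_collection()] providing the sets named in
#'   the panel (see Details of [load_fixture_sets()] for the names).
#' @param context `"tumor"` or `"cell_line"`; selects the E/M lists used
#'   for the KS, E and M scores.
#' @param alpha ssGSEA rank-weight exponent.
#' @param normalize ssGSEA cross-sample range normalization.
#' @return data.frame, samples in rows, one column per score, rownames =
#'   sample ids; attribute `"score_metadata"` records per score the engine,
#'   gene set(s) and matched-gene counts.
#' @export
score_panel <- function(matrix, collection, context = c("tumor", "cell_line"),
                        alpha = 0.25, normalize = FALSE) {
  context <- match.arg(context)
  validate_expression_matrix(matrix)
  req <- panel_set_requirements(context)
  needed <- unique(unlist(lapply(req, `[[`, "set")))
  missing <- setdiff(needed, names(collection))
  if (length(missing))
    stop("collection lacks required gene set(s): ",
         paste(missing, collapse = ", "))

  meta <- list()
  cols <- lapply(names(req), function(score_name) {
    spec <- req[[score_name]]
    sets <- lapply(spec$set, get_gene_set, collection = collection)
    v <- switch(spec$engine,
      ssgsea = ssgsea_score(matrix, sets[[1]], alpha = alpha,
                            normalize = normalize),
      ks = ks_emt_score(matrix, sets[[1]], sets[[2]]),
      gs76 = gs76_score(matrix, sets[[1]]),
      singscore = singscore(matrix, sets[[1]]),
      fao = fao_score(matrix, sets[[1]])
    )
    meta[[score_name]] <<- list(
      engine = spec$engine,
      gene_sets = spec$set,
      context = context,
      alpha = if (spec$engine == "ssgsea") alpha else NA_real_,
      n_matched = vapply(sets, function(s)
        match_set_genes(matrix, s)$n_matched, integer(1))
    )
    v
  })
  names(cols) <- names(req)
  out <- as.data.frame(cols, row.names = colnames(matrix))
  stopifnot(all(vapply(out, function(v) all(is.finite(v)), logical(1))))
  attr(out, "score_metadata") <- meta
  out
}
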