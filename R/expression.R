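#' Validate a gene x sample expression matrix
#'
#' An expression matrix is a numeric matrix with unique, non-empty gene
#' identifiers as rownames and unique sample identifiers as colnames, all
#' values finite and on log2 scale (the preprocessing entry points
#' [tpm_log2()] and [collapse_probes()] are responsible for getting it there).
#'
#' @param x numeric matrix, genes in rows, samples in columns.
#' @return `x`, invisibly, after validation.
#' @export
validate_expression_matrix <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("expression matrix must be a numeric matrix (genes x samples)")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("expression matrix must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(x)))
    stop("gene identifiers are not unique; collapse probes first")
  if (anyDuplicated(colnames(x)))
    stop("sample identifiers are not unique")
  if (any(!is.finite(x)))
    stop("expression matrix contains missing or non-finite values")
  invisible(x)
}

#' Read a delimited expression matrix
#'
#' Reads a dense genes x samples text matrix: first column gene (or probe)
#' identifiers, header row of sample identifiers. The delimiter (tab or
#' comma) is sniffed from the header line, matching GEO series-matrix style
#' exports.
#'
#' @param path file path.
#' @return numeric matrix with gene rownames and sample colnames.
#' @export
read_expression_matrix <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1L,
                          check.names = FALSE, quote = "\"",
                          stringsAsFactors = FALSE)
  m <- as.matrix(df)
  storage.mode(m) <- "double"
  if (any(!is.finite(m)))
    stop("matrix at ", path, " contains missing or non-finite values")
  m
}

#' Write an expression matrix or score table as TSV
#'
#' @param x matrix or data.frame with rownames.
#' @param path output path.
#' @param id_column name for the leading identifier column.
#' @return `path`, invisibly.
#' @export
write_tsv_matrix <- function(x, path, id_column = "id") {
  df <- data.frame(rownames(x), as.data.frame(x), check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Collapse probe-level rows to gene symbols
#'
#' Multiple probes mapping to one gene are averaged (arithmetic mean per
#' sample). Probes absent from the map, and probes whose map entry is
#' ambiguous (one probe listed under several genes), are dropped; both
#' counts are reported via `message()` so gene coverage stays auditable.
#' Applying the collapse to an already gene-level matrix (identity map) is
#' a no-op.
#'
#' @param matrix probe-level expression matrix (probes x samples).
#' @param probe_map mapping from probe to gene symbol: either a named
#'   character vector (`names` = probe, value = gene) or a two-column
#'   data.frame `(probe, gene)`.
#' @return gene-level expression matrix with unique gene rownames.
#' @export
collapse_probes <- function(matrix, probe_map) {
  validate_probe_input(matrix)
  map <- normalize_probe_map(probe_map)
  probes <- rownames(matrix)

  ambiguous <- unique(map$probe[duplicated(map$probe)])
  if (length(ambiguous)) {
    message(length(ambiguous),
            " probe(s) mapping to multiple genes dropped")
    map <- map[!map$probe %in% ambiguous, , drop = FALSE]
  }

  keep <- probes %in% map$probe
  n_unmapped <- sum(!keep)
  if (n_unmapped > 0)
    message(n_unmapped, " unmapped probe(s) dropped")
  if (!any(keep))
    stop("no overlap between matrix rows and probe map")

  sub <- matrix[keep, , drop = FALSE]
  genes <- map$gene[base::match(rownames(sub), map$probe)]
  grp <- factor(genes, levels = unique(genes))
  out <- rowsum(sub, grp) / as.vector(table(grp))
  rownames(out) <- levels(grp)
  validate_expression_matrix(out)
  out
}

validate_probe_input <- function(matrix) {
  if (!is.matrix(matrix) || !is.numeric(matrix))
    stop("expression matrix must be a numeric matrix")
  if (is.null(rownames(matrix)))
    stop("probe-level matrix must have probe rownames")
  if (anyDuplicated(rownames(matrix)))
    stop("probe identifiers are not unique")
  invisible(matrix)
}

normalize_probe_map <- function(probe_map) {
  if (is.data.frame(probe_map)) {
    if (ncol(probe_map) < 2)
      stop("probe_map data.frame needs columns (probe, gene)")
    map <- data.frame(probe = as.character(probe_map[[1]]),
                      gene = as.character(probe_map[[2]]),
                      stringsAsFactors = FALSE)
  } else if (is.character(probe_map) && !is.null(names(probe_map))) {
    map <- data.frame(probe = names(probe_map), gene = unname(probe_map),
                      stringsAsFactors = FALSE)
  } else {
    stop("probe_map must be a named character vector or a two-column data.frame")
  }
  unique(map)
}

#' TPM normalization and log2(x + 1) transform
#'
#' Columns of a non-negative count (or TPM) matrix are rescaled so each
#' sample sums to 1e6 (a no-op, up to numerical error, for input already in
#' TPM), then transformed as log2(x + 1). Set `scale_tpm = FALSE` to apply
#' only the log transform.
#'
#' @param matrix non-negative expression matrix (genes x samples).
#' @param scale_tpm rescale each column to sum to 1e6 before the log.
#' @return log2-scale expression matrix.
#' @export
tpm_log2 <- function(matrix, scale_tpm = TRUE) {
  if (!is.matrix(matrix) || !is.numeric(matrix))
    stop("expression matrix must be a numeric matrix")
  if (any(!is.finite(matrix)))
    stop("matrix contains missing or non-finite values")
  if (any(matrix < 0))
    stop("negative values: TPM/log2 preprocessing expects counts or TPM")
  m <- matrix
  if (scale_tpm) {
    cs <- colSums(m)
    if (any(cs == 0)) stop("sample(s) with zero total signal cannot be TPM-scaled")
    m <- sweep(m, 2L, cs / 1e6, "/")
  }
  log2(m + 1)
}
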