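#' Construct a gene set
#'
#' @param name non-empty set label.
#' @param genes character vector of gene identifiers; duplicates are removed
#'   with a warning.
#' @param context one of `"tumor"`, `"cell_line"`, `"generic"`: the sample
#'   provenance the set was derived for (the epithelial/mesenchymal lists of
#'   the KS metric come in tumor and cell-line flavours).
#' @param provenance free-text source note.
#' @return object of class `gene_set`.
#' @export
gene_set <- function(name, genes, context = "generic", provenance = "") {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("gene set name must be a non-empty string")
  genes <- as.character(genes)
  genes <- genes[nzchar(genes)]
  if (!length(genes)) stop("gene set '", name, "' is empty")
  if (anyDuplicated(genes)) {
    warning("duplicate genes in set '", name, "' removed")
    genes <- unique(genes)
  }
  context <- match.arg(context, c("generic", "tumor", "cell_line"))
  structure(list(name = name, genes = genes, context = context,
                 provenance = provenance),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat("<gene_set> ", x$name, " (", length(x$genes), " genes, ",
      x$context, ")\n", sep = "")
  invisible(x)
}

#' Construct a gene-set collection
#'
#' A named list of [gene_set()] objects with unambiguous lookup by name.
#'
#' @param sets list of `gene_set` objects.
#' @return object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets) {
  if (!length(sets)) stop("empty gene set collection")
  if (!all(vapply(sets, inherits, logical(1), "gene_set")))
    stop("all elements must be gene_set objects")
  nms <- vapply(sets, `[[`, character(1), "name")
  if (anyDuplicated(nms))
    stop("duplicate gene set name(s): ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  names(sets) <- nms
  structure(sets, class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("<gene_set_collection> ", length(x), " sets\n", sep = "")
  for (s in x) cat("  ", s$name, ": ", length(s$genes), " genes (",
                   s$context, ")\n", sep = "")
  invisible(x)
}

#' Look up a gene set by name
#'
#' @param collection a [gene_set_collection()].
#' @param name set name.
#' @return the `gene_set`.
#' @export
get_gene_set <- function(collection, name) {
  if (!name %in% names(collection))
    stop("gene set '", name, "' not found in collection")
  collection[[name]]
}

#' Read gene sets from a GMT file
#'
#' One set per line: `name<TAB>description<TAB>gene1<TAB>gene2...`.
#' Duplicate genes within a line are deduplicated with a warning; a line
#' with fewer than three fields is a format error naming the line number;
#' duplicate set names are an error.
#'
#' @param path GMT file path.
#' @param context context assigned to every set read
#'   (`"generic"`, `"tumor"` or `"cell_line"`).
#' @return a [gene_set_collection()].
#' @export
read_gmt <- function(path, context = "generic") {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("GMT file is empty: ", path)
  sets <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L)
      stop("malformed GMT line ", i, " in ", path,
           ": fewer than 3 tab-separated fields")
    sets[[i]] <- gene_set(fields[1], fields[-(1:2)], context = context,
                          provenance = fields[2])
  }
  gene_set_collection(sets)
}

#' Write a gene-set collection to a GMT file
#'
#' @param collection a [gene_set_collection()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(collection, function(s) {
    desc <- if (nzchar(s$provenance)) s$provenance else "na"
    paste(c(s$name, desc, s$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Bundled fixture gene sets
#'
#' Loads the gene-set fixtures shipped with the package. The 76-gene
#' epithelial signature (anchored on CDH1), the 59 HIF-1 downstream targets
#' and the 14 fatty-acid-oxidation enzyme genes carry the cardinalities the
#' corresponding published scores are defined on. The
#' Verfaillie/Hoek/Tsoi/epithelial/mesenchymal entries are synthetic
#' stand-ins (the published lists live in their source papers' supplements
#' and are loaded from user-supplied GMT files via [read_gmt()]); the
#' fixtures exist so every pipeline stage runs without downloads.
#'
#' @return a [gene_set_collection()].
#' @export
load_fixture_sets <- function() {
  path <- system.file("extdata", "fixture_sets_synthetic.gmt",
                      package = "melaxis")
  if (!nzchar(path) || !file.exists(path))
    stop("bundled fixture GMT not found; reinstall the package")
  read_gmt(path)
}

#' Intersect a gene set with the genes of a matrix
#'
#' Genes in the set but absent from the matrix are silently intersected out
#' but counted, so coverage is auditable downstream.
#'
#' @param matrix expression matrix.
#' @param set a `gene_set` (or character vector of genes).
#' @return list with `genes` (matched), `n_set`, `n_matched`, `n_missing`.
#' @export
match_set_genes <- function(matrix, set) {
  genes <- if (inherits(set, "gene_set")) set$genes else as.character(set)
  matched <- intersect(genes, rownames(matrix))
  list(genes = matched, n_set = length(genes),
       n_matched = length(matched),
       n_missing = length(genes) - length(matched))
}
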