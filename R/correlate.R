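#' Spearman correlation between two score vectors
#'
#' rho is the Pearson correlation of average-ranked values. The p-value is
#' two-sided: exact (full permutation enumeration of the rank vector) for
#' n <= 7, and the usual t-approximation on n - 2 degrees of freedom
#' otherwise. A record is flagged significant when `|rho| > rho_threshold`
#' and `p < alpha` (defaults 0.36 and 0.05, the thresholds used throughout
#' the correlation survey).
#'
#' @param x,y numeric vectors of equal length >= 3, finite.
#' @param dataset_id,score_x,score_y labels carried into the record.
#' @param rho_threshold,alpha significance rule.
#' @return one-row data.frame with columns `dataset_id`, `score_x`,
#'   `score_y`, `rho`, `p_value`, `n`, `significant`.
#' @export
spearman_pair <- function(x, y, dataset_id = "dataset", score_x = "x",
                          score_y = "y", rho_threshold = 0.36, alpha = 0.05) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3) stop("need at least 3 paired observations")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("non-finite values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant vector: Spearman correlation undefined")
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  rho <- stats::cor(rx, ry)
  p <- if (n <= 7) {
    perms <- all_permutations(n)
    obs <- abs(rho)
    rhos <- apply(perms, 1L, function(p_) stats::cor(rx, ry[p_]))
    mean(abs(rhos) >= obs - 1e-12)
  } else {
    spearman_t_pvalue(rho, n)
  }
  data.frame(dataset_id = dataset_id, score_x = score_x, score_y = score_y,
             rho = rho, p_value = p, n = n,
             significant = abs(rho) > rho_threshold && p < alpha,
             stringsAsFactors = FALSE)
}

spearman_t_pvalue <- function(rho, n) {
  if (abs(rho) >= 1) return(0)
  t <- rho * sqrt((n - 2) / (1 - rho^2))
  2 * stats::pt(-abs(t), df = n - 2)
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 1L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    for (i in seq_len(nrow(sub))) {
      out[row, ] <- c(k, rest[sub[i, ]])
      row <- row + 1L
    }
  }
  out
}

#' Correlate EMT and metabolic scores with the de-differentiation axes
#'
#' Convenience wrapper producing the correlation records a single dataset
#' contributes to the survey: each EMT/metabolic score against each axis
#' score.
#'
#' @param scores score table from [score_panel()].
#' @param dataset_id label.
#' @param axes axis score columns (default proliferative and invasive).
#' @param responses score columns correlated against the axes.
#' @inheritParams spearman_pair
#' @return data.frame of correlation records (one row per pair).
#' @export
correlate_panel <- function(scores, dataset_id = "dataset",
                            axes = c("proliferative", "invasive"),
                            responses = c("ks", "gs76", "epithelial",
                                          "mesenchymal", "oxphos",
                                          "glycolysis", "hif1", "fao"),
                            rho_threshold = 0.36, alpha = 0.05) {
  missing <- setdiff(c(axes, responses), colnames(scores))
  if (length(missing))
    stop("score table lacks column(s): ", paste(missing, collapse = ", "))
  recs <- list()
  for (resp in responses) for (ax in axes) {
    recs[[paste(resp, ax, sep = ".")]] <-
      spearman_pair(scores[[resp]], scores[[ax]], dataset_id = dataset_id,
                    score_x = resp, score_y = ax,
                    rho_threshold = rho_threshold, alpha = alpha)
  }
  do.call(rbind, c(recs, list(make.row.names = FALSE)))
}

#' Summarise a batch of correlation records volcano-style
#'
#' Counts records passing the significance rule (`|rho| > rho_threshold`
#' and `p < alpha`) and splits the significant records by the identity of
#' the axis score (`score_y`) and the sign of rho, mirroring how the
#' dataset survey reports the fraction of datasets supporting each
#' direction of coupling.
#'
#' @param records data.frame of correlation records (rbind of
#'   [spearman_pair()] rows).
#' @param rho_threshold,alpha significance rule applied to the records.
#' @return list with `n_total`, `n_significant`, `fraction_significant`
#'   and `split` (data.frame: `score_y`, `direction`, `count`).
#' @export
volcano_summary <- function(records, rho_threshold = 0.36, alpha = 0.05) {
  if (is.null(records) || !nrow(records)) stop("no correlation records")
  sig <- abs(records$rho) > rho_threshold & records$p_value < alpha
  sig_recs <- records[sig, , drop = FALSE]
  if (nrow(sig_recs)) {
    direction <- ifelse(sig_recs$rho > 0, "positive", "negative")
    split <- as.data.frame(table(score_y = sig_recs$score_y,
                                 direction = direction),
                           stringsAsFactors = FALSE)
    names(split)[3] <- "count"
    split <- split[split$count > 0, , drop = FALSE]
    rownames(split) <- NULL
  } else {
    split <- data.frame(score_y = character(0), direction = character(0),
                        count = integer(0), stringsAsFactors = FALSE)
  }
  out <- list(n_total = nrow(records), n_significant = sum(sig),
              fraction_significant = sum(sig) / nrow(records),
              rho_threshold = rho_threshold, alpha = alpha, split = split)
  stopifnot(sum(split$count) == out$n_significant)
  out
}
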