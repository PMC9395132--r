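#' Assign melanoma phenotypes by the top-10% rule
#'
#' For each phenotype score column independently, the `ceil((1 - quantile)
#' * n)` highest-scoring samples are flagged with that phenotype (default
#' quantile 0.90, i.e. the top 10%). Ties at the cutoff are all included
#' and reported via `message()`. A sample may carry several flags, or none.
#'
#' @param tsoi_scores data.frame or matrix of phenotype scores, samples in
#'   rows (rownames = sample ids); typically the four
#'   melanocytic/transitory/NCSC/undifferentiated ssGSEA columns of
#'   [score_panel()].
#' @param quantile score quantile above which a sample is flagged (0.90).
#' @return object of class `phenotype_calls`: list with `flags` (logical
#'   samples x phenotypes matrix), `thresholds` (per-phenotype cutoff),
#'   `k` (flag count targeted per phenotype), `quantile`.
#' @export
assign_phenotypes <- function(tsoi_scores, quantile = 0.90) {
  m <- as.matrix(tsoi_scores)
  if (!is.numeric(m)) stop("phenotype scores must be numeric")
  n <- nrow(m)
  if (n == 0) stop("no samples to classify")
  if (quantile <= 0 || quantile >= 1) stop("quantile must be in (0, 1)")
  if (n < 10)
    warning("only ", n, " samples: top-", round(100 * (1 - quantile)),
            "% rule flags a single sample per phenotype")
  if (is.null(rownames(m))) rownames(m) <- paste0("sample_", seq_len(n))
  k <- as.integer(ceiling((1 - quantile) * n))
  flags <- matrix(FALSE, n, ncol(m), dimnames = dimnames(m))
  thresholds <- numeric(ncol(m))
  names(thresholds) <- colnames(m)
  for (j in seq_len(ncol(m))) {
    cutoff <- sort(m[, j], decreasing = TRUE)[k]
    flags[, j] <- m[, j] >= cutoff
    thresholds[j] <- cutoff
    extra <- sum(flags[, j]) - k
    if (extra > 0)
      message("phenotype '", colnames(m)[j], "': ", extra,
              " tied sample(s) at the cutoff included")
  }
  structure(list(flags = flags, thresholds = thresholds, k = k,
                 quantile = quantile),
            class = "phenotype_calls")
}

#' @export
print.phenotype_calls <- function(x, ...) {
  cat("<phenotype_calls> ", nrow(x$flags), " samples, top ",
      round(100 * (1 - x$quantile)), "% rule (k = ", x$k, ")\n", sep = "")
  print(colSums(x$flags))
  invisible(x)
}

#' Samples in the intermediate M-score band
#'
#' Returns the samples whose M score lies in the middle third of the
#' observed score range, `[min + r/3, min + 2r/3]` with `r = max - min`
#' (closed interval) — the default reading of an "intermediate score
#' range". A quantile-based alternative is exposed for sensitivity
#' analysis: `method = "quantile"` takes the samples between the `lo` and
#' `hi` empirical quantiles.
#'
#' @param m_scores named numeric vector of M scores (names = sample ids).
#' @param method `"tercile"` (middle third of the range) or `"quantile"`.
#' @param lo,hi quantile bounds used when `method = "quantile"`.
#' @return character vector of sample ids in the band.
#' @export
intermediate_band <- function(m_scores, method = c("tercile", "quantile"),
                              lo = 1 / 3, hi = 2 / 3) {
  method <- match.arg(method)
  if (length(m_scores) < 3) stop("need at least 3 samples")
  if (any(!is.finite(m_scores))) stop("non-finite M scores")
  if (is.null(names(m_scores)))
    names(m_scores) <- paste0("sample_", seq_along(m_scores))
  rng <- range(m_scores)
  if (diff(rng) == 0) stop("degenerate M-score range: all scores equal")
  if (method == "tercile") {
    lower <- rng[1] + diff(rng) / 3
    upper <- rng[1] + 2 * diff(rng) / 3
  } else {
    if (!(lo < hi)) stop("need lo < hi")
    qs <- stats::quantile(m_scores, c(lo, hi), names = FALSE)
    lower <- qs[1]
    upper <- qs[2]
  }
  names(m_scores)[m_scores >= lower & m_scores <= upper]
}

#' One-proportion Z test for conditional phenotype enrichment
#'
#' Tests whether samples in a band (e.g. the intermediate M-score band) are
#' enriched for a phenotype: `p_hat` is the fraction of band samples
#' flagged with the phenotype, and
#' `z = (p_hat - p0) / sqrt(p0 (1 - p0) / n)` with `n` the band size. The
#' p-value is the upper-tail standard-normal probability (one-sided:
#' enrichment), flagged significant at 0.05. By default the null
#' proportion `p0` is the marginal fraction of all samples flagged with
#' the phenotype (about 0.10 under the top-10% rule).
#'
#' @param calls [assign_phenotypes()] output.
#' @param band character vector of sample ids in the band.
#' @param phenotype phenotype (column) name in `calls$flags`.
#' @param p0 null proportion in (0, 1); `NULL` = marginal flag fraction.
#' @return one-row data.frame: `phenotype`, `p_hat`, `p0`, `n`, `z`,
#'   `p_value`, `significant`.
#' @export
conditional_test <- function(calls, band, phenotype, p0 = NULL) {
  if (!inherits(calls, "phenotype_calls")) stop("calls must be phenotype_calls")
  if (!phenotype %in% colnames(calls$flags))
    stop("unknown phenotype '", phenotype, "'")
  band <- as.character(band)
  if (!length(band)) stop("empty band")
  unknown <- setdiff(band, rownames(calls$flags))
  if (length(unknown))
    stop("band sample(s) not in calls: ", paste(unknown, collapse = ", "))
  if (is.null(p0)) p0 <- mean(calls$flags[, phenotype])
  if (!is.finite(p0) || p0 <= 0 || p0 >= 1)
    stop("p0 must lie strictly in (0, 1)")
  n <- length(band)
  p_hat <- mean(calls$flags[band, phenotype])
  z <- (p_hat - p0) / sqrt(p0 * (1 - p0) / n)
  p_value <- stats::pnorm(z, lower.tail = FALSE)
  data.frame(phenotype = phenotype, p_hat = p_hat, p0 = p0, n = n, z = z,
             p_value = p_value, significant = p_value < 0.05,
             stringsAsFactors = FALSE)
}

#' Median score per phenotype and monotonicity verdict
#'
#' Computes the median of a score over the samples flagged with each
#' phenotype, in de-differentiation order, and classifies the shape of the
#' sequence: `monotone_increasing`, `monotone_decreasing`, `flat`,
#' `peaked` (an interior phenotype's median strictly exceeds the first and
#' last values, rising to the peak and not rising after it — a plateau
#' from the peak onward still counts as peaked), or `irregular` when none
#' of these fits. Comparisons use tolerance `eps`.
#'
#' @param calls [assign_phenotypes()] output.
#' @param scores named numeric vector of per-sample scores (names =
#'   sample ids).
#' @param order phenotype names in increasing de-differentiation order.
#' @param eps tolerance for "remained the same".
#' @return list of class `phenotype_trend`: `medians` (named, in order),
#'   `verdict`, `peak` (index, or NA).
#' @export
phenotype_trend <- function(calls, scores,
                            order = c("melanocytic", "transitory", "ncsc",
                                      "undifferentiated"),
                            eps = 1e-9) {
  if (!inherits(calls, "phenotype_calls")) stop("calls must be phenotype_calls")
  missing <- setdiff(order, colnames(calls$flags))
  if (length(missing))
    stop("calls lack phenotype(s): ", paste(missing, collapse = ", "))
  if (is.null(names(scores))) stop("scores must be named by sample id")
  medians <- vapply(order, function(p) {
    flagged <- rownames(calls$flags)[calls$flags[, p]]
    if (!length(flagged)) stop("no sample flagged for phenotype '", p, "'")
    stats::median(scores[flagged])
  }, numeric(1))

  d <- diff(medians)
  verdict <- if (all(abs(medians - medians[1]) <= eps)) {
    "flat"
  } else if (all(d > eps)) {
    "monotone_increasing"
  } else if (all(d < -eps)) {
    "monotone_decreasing"
  } else {
    "irregular"
  }
  peak <- NA_integer_
  if (verdict == "irregular") {
    k <- which.max(medians)
    interior <- k > 1 && k < length(medians)
    if (interior &&
        medians[k] > medians[1] + eps &&
        medians[k] >= medians[length(medians)] - eps &&
        all(diff(medians[1:k]) >= -eps) &&
        all(diff(medians[k:length(medians)]) <= eps)) {
      verdict <- "peaked"
      peak <- as.integer(k)
    }
  }
  structure(list(medians = medians, verdict = verdict, peak = peak,
                 order = order),
            class = "phenotype_trend")
}

#' @export
print.phenotype_trend <- function(x, ...) {
  cat("<phenotype_trend> ", x$verdict,
      if (!is.na(x$peak)) paste0(" at '", x$order[x$peak], "'"), "\n",
      sep = "")
  print(round(x$medians, 4))
  invisible(x)
}
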