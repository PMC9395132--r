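# Independent brute-force oracles, deliberately written as naive
# position-by-position / definition-level computations so they share no
# code path with the package implementations they check.

# ssGSEA: walk the descending-expression list one position at a time.
oracle_ssgsea <- function(x, genes, set_genes, alpha = 0.25) {
  n <- length(x)
  rk <- rank(x, ties.method = "average")
  ord <- order(-x, genes)
  in_set <- genes %in% set_genes
  w_sum <- sum(rk[in_set]^alpha)
  n_out <- n - sum(in_set)
  p_in <- 0; p_out <- 0; total <- 0
  for (pos in ord) {
    if (in_set[pos]) p_in <- p_in + rk[pos]^alpha / w_sum
    else p_out <- p_out + 1 / n_out
    total <- total + (p_in - p_out)
  }
  unname(total)
}

# Signed KS: evaluate both ECDFs at every observed value.
oracle_ks <- function(e_values, m_values) {
  pts <- sort(unique(c(e_values, m_values)))
  d_plus <- -Inf; d_minus <- -Inf
  for (b in pts) {
    fe <- sum(e_values <= b) / length(e_values)
    fm <- sum(m_values <= b) / length(m_values)
    d_plus <- max(d_plus, fe - fm)
    d_minus <- max(d_minus, fm - fe)
  }
  d_plus - d_minus
}

# Singscore: closed form from the mean rank of the set genes.
oracle_singscore <- function(x, genes, set_genes) {
  n <- length(x)
  s <- sum(genes %in% set_genes)
  rbar <- mean(rank(x, ties.method = "average")[genes %in% set_genes])
  (rbar - (s + 1) / 2) / ((n - (s - 1) / 2) - (s + 1) / 2) - 0.5
}

# Spearman rho by counting-based ranks and the definition of Pearson.
oracle_spearman_rho <- function(x, y) {
  count_rank <- function(v) vapply(v, function(vi)
    sum(v < vi) + (sum(v == vi) + 1) / 2, numeric(1))
  rx <- count_rank(x); ry <- count_rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Moving window by direct membership enumeration.
oracle_moving_window <- function(axis, response, window_frac, step_frac) {
  span <- max(axis) - min(axis)
  width <- window_frac * span; step <- step_frac * span
  lefts <- seq(min(axis), max(axis) - width + 1e-9, by = step)
  centers <- means <- numeric(0)
  for (L in lefts) {
    idx <- which(axis >= L & axis <= L + width)
    if (!length(idx)) next
    centers <- c(centers, L + width / 2)
    means <- c(means, mean(response[idx]))
  }
  list(centers = centers, means = means,
       slope = unname(coef(lm(means ~ centers))[2]))
}

# Small random expression matrix with gene/sample names.
random_matrix <- function(n_genes, n_samples, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(rnorm(n_genes * n_samples, mean = 6, sd = 2),
              n_genes, n_samples,
              dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n_samples))))
  m
}

small_sim_config <- function(n_samples = 80, ...) {
  simulation_config(
    n_samples = n_samples,
    genes_per_program = c(proliferative = 10, invasive = 10, epithelial = 10,
                          mesenchymal = 10, oxphos = 10, glycolysis = 10,
                          hif1 = 10, fao = 10, melanocytic = 10,
                          transitory = 10, ncsc = 10, undifferentiated = 10,
                          background = 40),
    ...)
}
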