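test_that("ssGSEA matches the hand-enumerated running sum on the 5-gene toy", {
  m <- matrix(c(5, 4, 3, 2, 1), 5, 1,
              dimnames = list(paste0("g", 1:5), "s1"))
  sc <- ssgsea_score(m, c("g1", "g2"), alpha = 0.25)
  expect_equal(unname(sc), 2.51394285622144, tolerance = 1e-12)
})

test_that("ssGSEA agrees with the brute-force oracle on exhaustive small instances", {
  for (n_genes in 3:8) {
    set.seed(100 + n_genes)
    m <- random_matrix(n_genes, 3)
    genes <- rownames(m)
    # all proper non-empty subsets for small universes, sampled ones above
    subsets <- if (n_genes <= 6) {
      Filter(function(s) length(s) >= 1 && length(s) < n_genes,
             unlist(lapply(seq_len(n_genes - 1), function(k)
               combn(genes, k, simplify = FALSE)), recursive = FALSE))
    } else {
      lapply(1:10, function(i) sample(genes, sample(n_genes - 1, 1)))
    }
    for (s in subsets) {
      got <- ssgsea_score(m, s)
      for (j in seq_len(ncol(m)))
        expect_equal(unname(got[j]),
                     oracle_ssgsea(m[, j], genes, s), tolerance = 1e-9)
    }
  }
})

test_that("ssGSEA is rank-invariant and monotone in set position", {
  m <- random_matrix(20, 4, seed = 7)
  s <- rownames(m)[c(2, 9, 15)]
  base <- ssgsea_score(m, s)
  # strictly increasing transform per sample leaves scores untouched
  warped <- apply(m, 2, function(x) exp(x / 3) + 0.1 * x)
  dimnames(warped) <- dimnames(m)
  expect_equal(ssgsea_score(warped, s), base, tolerance = 1e-9)
  # identical rankings across samples give identical scores
  m2 <- cbind(m[, 1, drop = FALSE], s2 = 2 * m[, 1] + 5)
  sc2 <- ssgsea_score(m2, s)
  expect_equal(unname(sc2[1]), unname(sc2[2]), tolerance = 1e-9)
  # set at the top of the ranking scores strictly above set at the bottom
  x <- sort(rnorm(20), decreasing = TRUE)
  mm <- matrix(x, 20, 1, dimnames = list(sprintf("g%02d", 1:20), "s"))
  expect_gt(ssgsea_score(mm, sprintf("g%02d", 1:3)),
            ssgsea_score(mm, sprintf("g%02d", 18:20)))
})

test_that("ssGSEA errors on degenerate sets", {
  m <- random_matrix(5, 2, seed = 1)
  expect_error(ssgsea_score(m, c("nope1", "nope2")), "no gene")
  expect_error(ssgsea_score(m, rownames(m)), "all matrix genes")
})

test_that("signed KS score matches ECDF enumeration and its stated examples", {
  m <- matrix(c(1, 3, 2, 4), 4, 1,
              dimnames = list(c("e1", "e2", "m1", "m2"), "s1"))
  expect_equal(unname(ks_emt_score(m, c("e1", "e2"), c("m1", "m2"))), 0.5)

  # complete separation: all M above all E -> +1; identical multisets -> 0
  m2 <- matrix(c(1, 2, 10, 11), 4, 1,
               dimnames = list(c("e1", "e2", "m1", "m2"), "s1"))
  expect_equal(unname(ks_emt_score(m2, c("e1", "e2"), c("m1", "m2"))), 1)
  m3 <- matrix(c(1, 2, 1, 2), 4, 1,
               dimnames = list(c("e1", "e2", "m1", "m2"), "s1"))
  expect_equal(unname(ks_emt_score(m3, c("e1", "e2"), c("m1", "m2"))), 0)

  # random instances against the oracle
  for (seed in 1:25) {
    m4 <- random_matrix(12, 2, seed = 2000 + seed)
    e <- rownames(m4)[1:5]; mm <- rownames(m4)[6:12]
    got <- ks_emt_score(m4, e, mm)
    for (j in 1:2)
      expect_equal(unname(got[j]), oracle_ks(m4[e, j], m4[mm, j]),
                   tolerance = 1e-12)
  }
})

test_that("KS score is antisymmetric, bounded, and rejects overlapping sets", {
  for (seed in 1:100) {
    m <- random_matrix(10, 1, seed = 3000 + seed)
    e <- rownames(m)[1:4]; mm <- rownames(m)[5:10]
    s <- ks_emt_score(m, e, mm)
    expect_identical(unname(s), -unname(ks_emt_score(m, mm, e)))
    expect_lte(abs(s), 1)
  }
  m <- random_matrix(6, 1, seed = 4)
  expect_error(ks_emt_score(m, rownames(m)[1:3], rownames(m)[3:5]), "overlap")
})

test_that("76GS score reproduces the spreadsheet toy and is mean-centered", {
  m <- rbind(CDH1 = c(2, 4, 6, 8), G2 = c(1, 3, 2, 5), G3 = c(9, 7, 5, 1))
  colnames(m) <- paste0("s", 1:4)
  sc <- gs76_score(m, rownames(m))
  expect_equal(unname(sc),
               c(-7.89463992546949, -2.26618098458091, 0.867712434446771,
                 9.29310847560363), tolerance = 1e-9)
  expect_equal(sum(sc), 0, tolerance = 1e-9)

  # identical expression columns -> identical centered scores (both 0)
  m2 <- cbind(s1 = c(2, 1, 9), s2 = c(2, 1, 9), s3 = c(3, 5, 4))
  rownames(m2) <- c("CDH1", "G2", "G3")
  sc2 <- gs76_score(m2, rownames(m2))
  expect_equal(unname(sc2[1]), unname(sc2[2]), tolerance = 1e-12)

  expect_warning(gs76_score(m[c("G2", "G3"), ], c("G2", "G3")),
                 "unit weights")
  expect_error(gs76_score(m[, 1:2], rownames(m)), ">= 3 samples")
})

test_that("singscore matches its closed form and attains the stated bounds", {
  # N = 6, set genes at ranks {2, 5}
  x <- c(10, 2, 30, 40, 5, 60)  # ranks 4,1,5? no: values 10,2,30,40,5,60
  names(x) <- paste0("g", 1:6)
  m <- matrix(x, 6, 1, dimnames = list(names(x), "s1"))
  r <- rank(x)  # g2 has rank 1 ... pick set genes with ranks 2 and 5
  set_genes <- names(x)[r %in% c(2, 5)]
  expect_equal(unname(singscore(m, set_genes)),
               oracle_singscore(x, names(x), set_genes), tolerance = 1e-12)
  expect_equal(unname(singscore(m, set_genes)), 0)  # mean rank 3.5 -> centre

  # top-|S| ranks -> +0.5; bottom-|S| ranks -> -0.5
  top <- names(x)[r >= 5]
  bottom <- names(x)[r <= 2]
  expect_equal(unname(singscore(m, top)), 0.5)
  expect_equal(unname(singscore(m, bottom)), -0.5)
  expect_error(singscore(m, names(x)), "whole gene universe")
})

test_that("singscore stays within [-0.5, 0.5] and matches the oracle randomly", {
  for (seed in 1:100) {
    m <- random_matrix(15, 1, seed = 5000 + seed)
    s <- sample(rownames(m), sample(1:14, 1))
    got <- unname(singscore(m, s))
    expect_lte(abs(got), 0.5)
    expect_equal(got, oracle_singscore(m[, 1], rownames(m), s),
                 tolerance = 1e-9)
  }
})

test_that("FAO z-mean score matches hand arithmetic and its identities", {
  m <- rbind(g1 = c(1, 2, 3), g2 = c(10, 10, 13))
  colnames(m) <- paste0("s", 1:3)
  sc <- fao_score(m, c("g1", "g2"))
  expect_equal(unname(sc),
               c(-0.788675134594813, -0.288675134594813, 1.07735026918963),
               tolerance = 1e-12)
  expect_equal(mean(sc), 0, tolerance = 1e-9)

  # a sample equal to the per-gene mean profile scores 0
  m2 <- random_matrix(6, 4, seed = 9)
  m2 <- cbind(m2, mean_sample = rowMeans(m2))
  expect_equal(unname(fao_score(m2, rownames(m2))[5]), 0, tolerance = 1e-9)

  flat <- matrix(5, 2, 3, dimnames = list(c("a", "b"), paste0("s", 1:3)))
  expect_error(fao_score(flat, c("a", "b")), "zero cross-sample variance")
  mixed <- rbind(flat, g1 = c(1, 2, 3))
  expect_warning(fao_score(mixed, rownames(mixed)), "dropped")
})

test_that("each engine responds monotonically to an upward set-gene shift", {
  deltas <- c(0, 0.5, 1, 2)
  base <- random_matrix(30, 6, seed = 42)
  rownames(base)[1] <- "CDH1"
  set_genes <- rownames(base)[1:8]
  e_genes <- rownames(base)[9:14]
  shifted <- lapply(deltas, function(d) {
    m <- base
    m[set_genes, 1] <- m[set_genes, 1] + d
    m
  })
  first <- function(f) vapply(shifted, function(m) unname(f(m)[1]), numeric(1))

  expect_true(all(diff(first(function(m) ssgsea_score(m, set_genes))) >= 0))
  expect_true(all(diff(first(function(m)
    ks_emt_score(m, e_genes, set_genes))) >= 0))
  expect_true(all(diff(first(function(m) singscore(m, set_genes))) >= 0))
  expect_true(all(diff(first(function(m) fao_score(m, set_genes))) >= 0))
  expect_true(all(diff(first(function(m) gs76_score(m, set_genes))) >= 0))
})

test_that("score_panel assembles the 14-score table with metadata", {
  sim <- simulate_dataset(small_sim_config(seed = 21))
  sc <- score_panel(sim$matrix, sim$gene_sets, context = "tumor")
  expect_equal(ncol(sc), 14)
  expect_equal(rownames(sc), colnames(sim$matrix))
  expect_true(all(vapply(sc, function(v) all(is.finite(v)), logical(1))))
  meta <- attr(sc, "score_metadata")
  expect_equal(meta$epithelial$gene_sets, "epithelial_tumor")
  expect_true(all(unlist(lapply(meta, `[[`, "n_matched")) >= 1))

  cl <- score_panel(sim$matrix, sim$gene_sets, context = "cell_line")
  expect_equal(attr(cl, "score_metadata")$ks$gene_sets,
               c("epithelial_cell_line", "mesenchymal_cell_line"))

  broken <- sim$gene_sets[names(sim$gene_sets) != "mesenchymal_tumor"]
  class(broken) <- "gene_set_collection"
  expect_error(score_panel(sim$matrix, broken, context = "tumor"),
               "mesenchymal_tumor")
})
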