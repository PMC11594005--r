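mk_geno <- function(states, types) {
  cnvrs <- data.frame(id = sprintf("cnvr_%05d", seq_along(types)),
                      chrom = "chr1",
                      start = seq_along(types) * 1000,
                      end = seq_along(types) * 1000 + 500,
                      type = types, carrier_count = 4L,
                      stringsAsFactors = FALSE)
  g <- list(states = states, cnvrs = cnvrs,
            breed_labels = stats::setNames(rep("b1", nrow(states)),
                                           rownames(states)))
  class(g) <- "cnvr_genotypes"
  g
}

test_that("biallelic recoding maps states to allele dosages", {
  states <- matrix(c(0L, 1L, 2L,   # loss CNVR
                     3L, 2L, 4L,   # gain CNVR
                     2L, 0L, 4L),  # mixed CNVR
                   nrow = 3,
                   dimnames = list(c("i1", "i2", "i3"), NULL))
  mat <- recode_biallelic(mk_geno(states, c("loss", "gain", "mixed")))
  expect_equal(ncol(mat$G), 4L)   # mixed contributes two pseudo-loci
  expect_equal(unname(mat$G[, 1]), c(2L, 1L, 0L))        # loss: 2 - copy
  expect_equal(unname(mat$G[, 2]), c(1L, 0L, 2L))        # gain: copy - 2
  expect_equal(unname(mat$G[, 3]), c(0L, 2L, 0L))        # mixed loss-coded
  expect_equal(unname(mat$G[, 4]), c(0L, 0L, 2L))        # mixed gain-coded
  expect_equal(unname(mat$freq), colSums(mat$G) / 6, ignore_attr = TRUE)
})

test_that("IBS distances satisfy the metric axioms and the bounds", {
  G <- rbind(a = c(0, 1, 2, 0), b = c(0, 1, 2, 0), c = c(2, 1, 0, 2),
             d = c(2, 2, 2, 2))
  D <- distance_matrix(as_biallelic(G), "ibs_individual")
  expect_equal(D["a", "b"], 0)
  expect_equal(D["a", "c"], 3 / 4)   # differs by 2 at three of four loci
  expect_true(isSymmetric(D))
  expect_true(all(diag(D) == 0))
  expect_true(all(D >= 0 & D <= 1))
  G2 <- rbind(a = rep(0, 5), b = rep(2, 5))
  expect_equal(distance_matrix(as_biallelic(G2), "ibs_individual")["a", "b"],
               1)
})

test_that("population F_ST distances track the planted drift", {
  cfg <- sim_config(seed = 41, n_pops = 2, pop_sizes = c(30L, 30L),
                    n_loci = 2000, chrom_lengths = c(chr1 = 8e8),
                    F_bg = 0.2, frac_loss_loci = 1)
  tr <- simulate_genotypes(simulate_freqs(cfg), cfg)
  mat <- as_biallelic(2L - tr$genotypes, tr$breed_labels)
  D <- distance_matrix(mat, "fst_population")
  expect_gte(D["pop1", "pop2"], 0.16)
  expect_lte(D["pop1", "pop2"], 0.24)
})

test_that("three taxa solve the closed-form branch lengths", {
  D <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tree <- nj_tree(D)
  cm <- ape::cophenetic.phylo(tree)[rownames(D), colnames(D)]
  expect_equal(unname(cm), unname(D), tolerance = 1e-9)
})

test_that("the additive 4-taxon matrix reconstructs the generating tree", {
  D <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, 4,
              dimnames = list(c("A", "B", "C", "D"), c("A", "B", "C", "D")))
  tree <- nj_tree(D)
  cm <- ape::cophenetic.phylo(tree)[rownames(D), colnames(D)]
  expect_equal(unname(cm), unname(D), tolerance = 1e-9)
  # topology AB|CD: the path A-B avoids the path C-D's internal edge
  expect_equal(cm["A", "B"], 3)
  expect_equal(cm["C", "D"], 7)
  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric|taxa")
})

test_that("random additive matrices are reproduced exactly", {
  set.seed(11)
  for (trial in 1:40) {
    n <- sample(4:8, 1)
    D <- random_additive_matrix(n)
    tree <- nj_tree(D)
    cm <- ape::cophenetic.phylo(tree)[rownames(D), colnames(D)]
    expect_lt(max(abs(cm - D)), 1e-9)
    # dual route: ape's own NJ agrees on the metric
    cm2 <- ape::cophenetic.phylo(ape::nj(as.dist(D)))[rownames(D),
                                                      colnames(D)]
    expect_lt(max(abs(cm - cm2)), 1e-8)
  }
})

test_that("PCA separates duplicated blocks and normalizes variance shares", {
  G <- rbind(matrix(rep(c(0, 0, 2, 2, 0), 4), 4, 5, byrow = TRUE),
             matrix(rep(c(2, 2, 0, 0, 2), 4), 4, 5, byrow = TRUE))
  p <- cnv_pca(as_biallelic(G))
  expect_equal(p$pct_variance[1], 100, tolerance = 1e-9)
  expect_equal(sum(p$pct_variance), 100, tolerance = 1e-9)
  expect_true(all(p$eigenvalues >= 0))
  blocks <- rep(c(1, 2), each = 4)
  expect_true(max(p$coords[blocks == 1, 1]) < min(p$coords[blocks == 2, 1]) ||
                max(p$coords[blocks == 2, 1]) < min(p$coords[blocks == 1, 1]))
  expect_error(cnv_pca(as_biallelic(matrix(2, 4, 3))), "monomorphic")
})

test_that("PCA separates simulated populations on PC1", {
  cfg <- sim_config(seed = 42, n_pops = 2, pop_sizes = c(30L, 30L),
                    n_loci = 1000, chrom_lengths = c(chr1 = 4e8),
                    F_bg = 0.2, frac_loss_loci = 1)
  tr <- simulate_genotypes(simulate_freqs(cfg), cfg)
  p <- cnv_pca(as_biallelic(2L - tr$genotypes, tr$breed_labels))
  br <- tr$breed_labels
  c1 <- p$coords[, 1]
  expect_true(max(c1[br == "pop1"]) < min(c1[br == "pop2"]) ||
                max(c1[br == "pop2"]) < min(c1[br == "pop1"]))
  expect_gt(p$pct_variance[1], p$pct_variance[2])
})

test_that("K = 1 admixture collapses to the sample allele frequencies", {
  set.seed(3)
  G <- matrix(rbinom(20 * 50, 2, 0.4), 20, 50)
  mat <- as_biallelic(G)
  fit <- admixture_em(mat, K = 1, seed = 2, restarts = 1)
  expect_equal(unname(fit$Q[, 1]), rep(1, 20))
  keep <- !mat$info$monomorphic
  expect_equal(unname(fit$Fq[1, ]), unname(mat$freq[keep]),
               tolerance = 1e-6)
})

test_that("the EM log-likelihood never decreases", {
  set.seed(4)
  G <- matrix(rbinom(30 * 80, 2, runif(80, 0.1, 0.9)), 30, 80, byrow = TRUE)
  for (K in c(2, 3)) {
    fit <- admixture_em(as_biallelic(G), K = K, seed = 5, restarts = 2)
    expect_true(all(diff(fit$loglik) > -1e-8))
    expect_equal(unname(rowSums(fit$Q)), rep(1, 30), tolerance = 1e-9)
  }
})

test_that("two unadmixed populations are recovered at K = 2", {
  cfg <- sim_config(seed = 43, n_pops = 2, pop_sizes = c(20L, 20L),
                    n_loci = 1000, chrom_lengths = c(chr1 = 4e8),
                    F_bg = 0.3, frac_loss_loci = 1)
  tr <- simulate_genotypes(simulate_freqs(cfg), cfg)
  mat <- as_biallelic(2L - tr$genotypes, tr$breed_labels)
  fit <- admixture_em(mat, K = 2, seed = 9, restarts = 3)
  al <- align_q(fit$Q, tr$Q_true)
  expect_lt(al$rmse, 0.05)
})
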