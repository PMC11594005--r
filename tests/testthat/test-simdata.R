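test_that("configuration is validated", {
  expect_error(sim_config(n_pops = 2, pop_sizes = 5L), "pop_sizes")
  expect_error(sim_config(F_bg = 0), "F_bg")
  expect_error(sim_config(F_bg = 1), "F_bg")
  expect_error(sim_config(F_sel = 1.2), "F_sel")
  expect_error(
    simulate_freqs(sim_config(n_loci = 1000,
                              chrom_lengths = c(chr1 = 1e5))),
    "too small")
})

test_that("planted loci are non-overlapping, on-grid and inside chromosomes", {
  cfg <- sim_config(seed = 4, n_loci = 80,
                    chrom_lengths = c(chr1 = 3e6, chr2 = 2e6))
  lt <- simulate_freqs(cfg)$locus_table
  expect_equal(nrow(lt), 80)
  for (ch in unique(lt$chrom)) {
    d <- lt[lt$chrom == ch, ]
    d <- d[order(d$start), ]
    expect_true(all(d$end <= cfg$chrom_lengths[ch]))
    expect_true(all(d$start >= 0))
    if (nrow(d) > 1) expect_true(all(d$start[-1] >= d$end[-nrow(d)]))
  }
  expect_true(all(lt$start %% cfg$bin_width == 0))
})

test_that("near-zero drift makes population frequencies coincide", {
  cfg <- sim_config(seed = 2, n_pops = 2, pop_sizes = c(5L, 5L),
                    n_loci = 500, chrom_lengths = c(chr1 = 1e8),
                    F_bg = 1e-6)
  lt <- simulate_freqs(cfg)$locus_table
  expect_gte(mean(abs(lt$p_pop1 - lt$p_pop2) < 0.05), 0.99)
})

test_that("the selected-locus count is the ceiling of the requested fraction", {
  cfg <- sim_config(seed = 3, n_loci = 1000, frac_selected = 0.01,
                    chrom_lengths = c(chr1 = 2e8))
  expect_identical(sum(simulate_freqs(cfg)$locus_table$selected), 10L)
  expect_true(all(simulate_freqs(cfg)$locus_table$p_pop1 >= 0))
  expect_true(all(simulate_freqs(cfg)$locus_table$p_pop1 <= 1))
})

test_that("genotypes honour fixed frequencies and the loss/gain state coding", {
  cfg <- sim_config(seed = 5, n_pops = 2, pop_sizes = c(6L, 6L), n_loci = 10,
                    chrom_lengths = c(chr1 = 1e6))
  truth <- simulate_freqs(cfg)
  truth$locus_table$allele_type <- rep(c("loss", "gain"), 5)
  # fixed variant allele everywhere
  truth$locus_table$p_pop1 <- 1
  truth$locus_table$p_pop2 <- 1
  g <- simulate_genotypes(truth, cfg)$genotypes
  expect_true(all(g[, seq(1, 9, 2)] == 0L))   # loss loci: state 0
  expect_true(all(g[, seq(2, 10, 2)] == 4L))  # gain loci: state 4
  # absent variant allele everywhere
  truth$locus_table$p_pop1 <- 0
  truth$locus_table$p_pop2 <- 0
  g <- simulate_genotypes(truth, cfg)$genotypes
  expect_true(all(g == 2L))
})

test_that("unadmixed ancestry is one-hot and Dirichlet rows sum to one", {
  cfg <- sim_config(seed = 6, n_pops = 2, pop_sizes = c(4L, 4L), n_loci = 5,
                    chrom_lengths = c(chr1 = 1e6))
  tr <- simulate_genotypes(simulate_freqs(cfg), cfg)
  expect_true(all(tr$Q_true %in% c(0, 1)))
  expect_equal(unname(rowSums(tr$Q_true)), rep(1, 8))
  loss <- tr$locus_table$allele_type == "loss"
  expect_true(all(tr$genotypes[, loss] %in% 0:2))
  expect_true(all(tr$genotypes[, !loss] %in% 2:4))

  cfg2 <- sim_config(seed = 6, n_pops = 3, pop_sizes = c(4L, 4L, 4L),
                     n_loci = 5, chrom_lengths = c(chr1 = 1e6),
                     admix_alpha = 0.5)
  tr2 <- simulate_genotypes(simulate_freqs(cfg2), cfg2)
  expect_equal(unname(rowSums(tr2$Q_true)), rep(1, 12), tolerance = 1e-12)
  expect_false(all(tr2$Q_true %in% c(0, 1)))
})

test_that("depth tracks reflect copy number and are deterministic", {
  cfg <- sim_config(seed = 7, n_pops = 1, pop_sizes = 2L, n_loci = 6,
                    chrom_lengths = c(chr1 = 1e6), gc_amp = 0,
                    frac_repeat_bins = 0)
  truth <- simulate_genotypes(simulate_freqs(cfg), cfg)
  truth$genotypes[1, ] <- rep(c(0L, 4L), 3)
  tracks <- simulate_depth(truth, cfg)
  tr <- tracks[[1]]
  lt <- truth$locus_table
  for (l in seq_len(6)) {
    inl <- tr$start >= lt$start[l] & tr$end <= lt$end[l]
    counts <- tr$count[inl]
    if (truth$genotypes[1, l] == 0L) {
      expect_true(all(counts == 0))
    } else {
      m <- mean(counts)
      expect_lt(abs(m - 20), 3 * sqrt(20 / length(counts)) + 1e-9)
    }
  }
  tracks2 <- simulate_depth(truth, cfg)
  expect_identical(tracks[[2]]$count, tracks2[[2]]$count)
  expect_identical(tracks[[2]]$q0, tracks2[[2]]$q0)
})

test_that("identical configurations reproduce identical cohorts", {
  a <- small_cohort(seed = 9)
  b <- small_cohort(seed = 9)
  expect_identical(a$truth$locus_table, b$truth$locus_table)
  expect_identical(a$truth$genotypes, b$truth$genotypes)
  expect_identical(lapply(a$tracks, `[[`, "count"),
                   lapply(b$tracks, `[[`, "count"))
})

test_that("sample allele frequencies recover the planted ones", {
  cfg <- sim_config(seed = 10, n_pops = 1, pop_sizes = 500L, n_loci = 300,
                    chrom_lengths = c(chr1 = 1e8), frac_loss_loci = 1)
  tr <- simulate_genotypes(simulate_freqs(cfg), cfg)
  p_hat <- colMeans(2L - tr$genotypes) / 2
  rmse <- sqrt(mean((p_hat - tr$locus_table$p_pop1)^2))
  expect_lt(rmse, 0.03)
})

test_that("gene models have in-frame CDS totals and sorted output", {
  cfg <- sim_config(seed = 11, n_genes = 30,
                    chrom_lengths = c(chr1 = 3e6, chr2 = 3e6))
  gm <- simulate_gene_models(cfg)
  expect_equal(nrow(gm$genes), 30)
  cds_tot <- tapply(gm$cds$end - gm$cds$start, gm$cds$gene_id, sum)
  expect_true(all(cds_tot %% 3 == 0))
  ord <- order(gm$genes$chrom, gm$genes$start)
  expect_identical(ord, seq_len(nrow(gm$genes)))
  # genes do not overlap
  for (ch in unique(gm$genes$chrom)) {
    d <- gm$genes[gm$genes$chrom == ch, ]
    if (nrow(d) > 1) expect_true(all(d$start[-1] >= d$end[-nrow(d)]))
  }
  # empty case still writes a valid GFF3
  gm0 <- simulate_gene_models(sim_config(seed = 1, n_genes = 0))
  path <- tempfile(fileext = ".gff3")
  write_gff3(gm0, path)
  expect_identical(readLines(path), "##gff-version 3")
})

test_that("gene sets cover at least ten terms and plant the selected set", {
  co <- small_cohort(seed = 12, frac_selected = 0.1, n_genes = 60)
  expect_gte(length(co$gene_sets), 10)
  expect_true(all(unlist(co$gene_sets) %in% co$genes$genes$gene_id))
  if ("SELECTED_SET" %in% names(co$gene_sets)) {
    sel <- co$truth$locus_table[co$truth$locus_table$selected, ]
    g <- co$genes$genes
    hit <- vapply(seq_len(nrow(g)), function(i) {
      any(sel$chrom == g$chrom[i] & sel$start < g$end[i] &
            sel$end > g$start[i])
    }, logical(1))
    expect_setequal(co$gene_sets$SELECTED_SET, g$gene_id[hit])
  }
})
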