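# Independent oracles used across the suite. Each is written directly from
# first principles (enumeration, closed form, or the literal textbook
# formula) and never calls the implementation it checks.

# Formula-literal Weir-Cockerham (1984) components for one locus and two
# populations, computed scalar-by-scalar from sample sizes, allele
# frequencies and heterozygote proportions.
wc_oracle <- function(n1, p1, h1, n2, p2, h2) {
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r -
                              hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - s2 * (r - 1) / r -
                                hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  list(a = a, b = b, c = cc,
       fst = if (a + b + cc == 0) NA_real_ else a / (a + b + cc))
}

# Exhaustive minimum of the penalized least-squares partition cost over all
# 2^(B-1) partitions of a signal (feasible for B <= 12).
brute_partition_cost <- function(x, beta) {
  B <- length(x)
  best <- Inf
  for (m in 0:(2^(B - 1) - 1)) {
    cuts <- if (B > 1) which(bitwAnd(m, 2^(0:(B - 2))) > 0) else integer(0)
    bounds <- c(0, cuts, B)
    cost <- beta * (length(bounds) - 1)
    for (i in seq_len(length(bounds) - 1)) {
      v <- x[(bounds[i] + 1):bounds[i + 1]]
      cost <- cost + sum((v - mean(v))^2)
    }
    best <- min(best, cost)
  }
  best
}

partition_cost <- function(x, segs, beta) {
  cost <- beta * nrow(segs)
  for (i in seq_len(nrow(segs))) {
    v <- x[(segs$bin_start[i] + 1):segs$bin_end[i]]
    cost <- cost + sum((v - mean(v))^2)
  }
  cost
}

# Brute-force transitive closure of >= 1 bp overlap among intervals
# (0-based half-open): pairwise overlap graph, connected components by
# repeated expansion. Returns the component spans sorted by start.
brute_overlap_closure <- function(start, end) {
  n <- length(start)
  adj <- outer(seq_len(n), seq_len(n), function(i, j)
    start[i] < end[j] & end[i] > start[j])
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (adj[i, j] && comp[j] != comp[i]) {
        comp[comp == comp[j]] <- comp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  spans <- do.call(rbind, lapply(unique(comp), function(cm) {
    data.frame(start = min(start[comp == cm]), end = max(end[comp == cm]))
  }))
  spans[order(spans$start), , drop = FALSE]
}

# Random additive (tree-metric) distance matrix: build a random binary tree
# with positive branch lengths and return its leaf-to-leaf path metric.
random_additive_matrix <- function(n_taxa) {
  labels <- paste0("t", seq_len(n_taxa))
  tree <- ape::rtree(n_taxa, tip.label = labels,
                     br = function(k) stats::runif(k, 0.1, 2))
  ape::cophenetic.phylo(tree)
}

# Small two-population cohort with planted truth, for recovery-style tests.
small_cohort <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(seed = seed, n_pops = 2, pop_sizes = c(10L, 10L), n_loci = 30,
         chrom_lengths = c(chr1 = 2e6, chr2 = 2e6)),
    list(...))
  simulate_cohort(do.call(sim_config, args))
}

# Hand-built two-gene model on one chromosome (0-based half-open):
#   geneA (+): span [1000, 2000); exons [1000,1300) and [1700,2000);
#     CDS [1060,1300) and [1700,1940)  (total 480, divisible by 3)
#   geneB (-): span [5000, 5600); exon [5000,5600); CDS [5100,5502)
tiny_gene_model <- function() {
  gm <- list(
    genes = data.frame(
      gene_id = c("geneA", "geneB"), chrom = "chr1",
      start = c(1000, 5000), end = c(2000, 5600),
      strand = c("+", "-"), stringsAsFactors = FALSE),
    exons = data.frame(
      gene_id = c("geneA", "geneA", "geneB"), chrom = "chr1",
      start = c(1000, 1700, 5000), end = c(1300, 2000, 5600),
      stringsAsFactors = FALSE),
    cds = data.frame(
      gene_id = c("geneA", "geneA", "geneB"), chrom = "chr1",
      start = c(1060, 1700, 5100), end = c(1300, 1940, 5502),
      stringsAsFactors = FALSE))
  class(gm) <- "gene_model"
  gm
}

# Dosage matrix from genotype counts: n0 individuals of dosage 0, etc.
dosage_groups <- function(n0_1, n1_1, n2_1, n0_2, n1_2, n2_2) {
  g <- c(rep(0L, n0_1), rep(1L, n1_1), rep(2L, n2_1),
         rep(0L, n0_2), rep(1L, n1_2), rep(2L, n2_2))
  grp <- c(rep("g1", n0_1 + n1_1 + n2_1), rep("g2", n0_2 + n1_2 + n2_2))
  list(G = matrix(g, ncol = 1), groups = grp)
}
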