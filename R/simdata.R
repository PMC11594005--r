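#' Configuration for a synthetic CNV cohort
#'
#' Builds and validates the configuration object consumed by the simulation
#' functions. The simulated cohort consists of `n_pops` populations whose CNV
#' allele frequencies are differentiated under the Balding-Nichols model: for
#' each locus an ancestral frequency `p0` is drawn uniformly and each
#' population's frequency is Beta-distributed around `p0` with dispersion
#' controlled by a drift parameter `F`, so that the expected Weir-Cockerham
#' F_ST between populations is approximately `F`. A small fraction of loci can
#' be flagged as targets of differential selection and drawn with a larger
#' drift `F_sel`, which plants detectable selection signatures.
#'
#' @param seed Integer seed; all randomness in the generator flows from it in
#'   a documented order (frequencies, genotypes, repeat-bin placement, gene
#'   models, then one stream per sample's depth track).
#' @param n_pops Number of populations (breeds).
#' @param pop_sizes Integer vector of diploid individuals per population.
#' @param n_loci Number of CNV loci to plant.
#' @param chrom_lengths Named numeric vector of chromosome lengths in bp.
#' @param bin_width Read-depth bin width in bp (default 200, the resolution
#'   at which depth is summarised for calling).
#' @param mean_depth_per_bin Expected read count per diploid bin.
#' @param F_bg Background Balding-Nichols drift parameter, in (0, 1).
#' @param F_sel Drift parameter for selected loci, in (0, 1].
#' @param frac_selected Fraction of loci flagged as selected (ceiling applied).
#' @param frac_loss_loci Probability that a locus is a deletion (loss) locus
#'   rather than a duplication (gain) locus.
#' @param admix_alpha Dirichlet concentration for individual ancestry; 0 means
#'   unadmixed individuals with one-hot ancestry by breed.
#' @param n_genes Number of gene models to plant.
#' @param gc_amp Amplitude of the multiplicative GC bias on expected depth,
#'   in [0, 1).
#' @param locus_len_bins Integer range (min, max) of planted locus lengths in
#'   bins; lengths are drawn uniformly on this range.
#' @param overdispersion Non-negative; 0 gives Poisson bin counts, values > 0
#'   give negative-binomial counts with variance mu + overdispersion * mu^2.
#' @param frac_repeat_bins Fraction of bins designated repeat-like, with high
#'   mapping-quality-zero fractions.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_pops = 2L,
                       pop_sizes = c(15L, 15L),
                       n_loci = 50L,
                       chrom_lengths = c(chr1 = 1e6, chr2 = 1e6),
                       bin_width = 200L,
                       mean_depth_per_bin = 10,
                       F_bg = 0.1,
                       F_sel = 0.8,
                       frac_selected = 0,
                       frac_loss_loci = 0.6,
                       admix_alpha = 0,
                       n_genes = 40L,
                       gc_amp = 0,
                       locus_len_bins = c(15L, 40L),
                       overdispersion = 0,
                       frac_repeat_bins = 0.02) {
  cfg <- list(seed = as.integer(seed), n_pops = as.integer(n_pops),
              pop_sizes = as.integer(pop_sizes), n_loci = as.integer(n_loci),
              chrom_lengths = chrom_lengths, bin_width = as.integer(bin_width),
              mean_depth_per_bin = mean_depth_per_bin, F_bg = F_bg,
              F_sel = F_sel, frac_selected = frac_selected,
              frac_loss_loci = frac_loss_loci, admix_alpha = admix_alpha,
              n_genes = as.integer(n_genes), gc_amp = gc_amp,
              locus_len_bins = as.integer(locus_len_bins),
              overdispersion = overdispersion,
              frac_repeat_bins = frac_repeat_bins)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(length(cfg$pop_sizes) == cfg$n_pops, all(cfg$pop_sizes >= 1L))
  if (!(cfg$F_bg > 0 && cfg$F_bg < 1))
    stop("F_bg must lie in (0, 1)", call. = FALSE)
  if (!(cfg$F_sel > 0 && cfg$F_sel <= 1))
    stop("F_sel must lie in (0, 1]", call. = FALSE)
  stopifnot(cfg$frac_selected >= 0, cfg$frac_selected <= 1,
            cfg$frac_loss_loci >= 0, cfg$frac_loss_loci <= 1,
            cfg$gc_amp >= 0, cfg$gc_amp < 1,
            cfg$bin_width >= 1L, cfg$mean_depth_per_bin > 0,
            all(cfg$chrom_lengths > 0), !is.null(names(cfg$chrom_lengths)),
            cfg$locus_len_bins[1] >= 1L,
            cfg$locus_len_bins[2] >= cfg$locus_len_bins[1])
  invisible(cfg)
}

#' Genome layout of a configuration
#'
#' @param cfg A `sim_config`.
#' @param unplaced Optional named lengths of unplaced scaffolds to append
#'   (flagged `placed = FALSE`).
#' @return A data.frame with columns `chrom`, `length`, `placed`.
#' @export
sim_layout <- function(cfg, unplaced = NULL) {
  layout <- data.frame(chrom = names(cfg$chrom_lengths),
                       length = as.numeric(cfg$chrom_lengths),
                       placed = TRUE, stringsAsFactors = FALSE)
  if (length(unplaced)) {
    layout <- rbind(layout, data.frame(chrom = names(unplaced),
                                       length = as.numeric(unplaced),
                                       placed = FALSE))
  }
  layout
}

# Place n non-overlapping intervals on the bin grid. Each chromosome is cut
# into equal slots, one interval per slot at a random in-slot offset, which
# guarantees non-overlap by construction.
place_loci <- function(cfg, n, len_bins_min, len_bins_max, margin_bins = 2L) {
  w <- cfg$bin_width
  chroms <- names(cfg$chrom_lengths)
  n_per <- diff(round(n * cumsum(c(0, cfg$chrom_lengths)) /
                        sum(cfg$chrom_lengths)))
  out <- vector("list", length(chroms))
  for (ci in seq_along(chroms)) {
    nc <- n_per[ci]
    if (nc == 0) next
    n_bins <- floor(cfg$chrom_lengths[ci] / w)
    slot <- floor(n_bins / nc)
    if (slot < len_bins_max + 2L * margin_bins)
      stop("genome too small to place ", n, " non-overlapping intervals",
           call. = FALSE)
    lens <- if (len_bins_min == len_bins_max) rep(len_bins_min, nc) else
      sample(seq(len_bins_min, len_bins_max), nc, replace = TRUE)
    offs <- vapply(lens, function(l) {
      s <- seq(margin_bins, slot - l - margin_bins)
      s[sample.int(length(s), 1L)]
    }, integer(1))
    start_bin <- (seq_len(nc) - 1L) * slot + offs
    out[[ci]] <- data.frame(chrom = chroms[ci],
                            start = start_bin * w,
                            end = (start_bin + lens) * w,
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Simulate Balding-Nichols differentiated CNV allele frequencies
#'
#' Draws the per-locus ancestral frequency p0 ~ Uniform(0.05, 0.95) and the
#' per-population frequencies p_k ~ Beta(p0 (1-F)/F, (1-p0)(1-F)/F) with
#' F = `F_bg` (the neutral Balding-Nichols model, E[F_ST] ~ F_bg). The
#' ceiling(frac_selected * L) loci flagged as selected instead follow a
#' divergent-selection model: odd-numbered populations are pulled toward a
#' variant-allele equilibrium 0.5 + F_sel/2 and even-numbered ones toward
#' 0.5 - F_sel/2 (Beta draws of moderate concentration around those
#' targets), so selected loci are reliably strongly differentiated rather
#' than bimodally drifting to the same fixed allele in every population.
#' Loci are placed non-overlapping on the bin grid and are loss (deletion)
#' alleles with probability `frac_loss_loci`.
#'
#' @param cfg A `sim_config`.
#' @return A `truth_set` list with the `locus_table` filled: columns
#'   `locus_id`, `chrom`, `start`, `end` (bp, 0-based half-open),
#'   `allele_type` (loss/gain), `selected`, `p0`, and one `p_<pop>` column per
#'   population.
#' @export
simulate_freqs <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(cfg$seed)
  L <- cfg$n_loci
  loci <- place_loci(cfg, L, cfg$locus_len_bins[1], cfg$locus_len_bins[2])
  n_sel <- ceiling(cfg$frac_selected * L)
  selected <- rep(FALSE, L)
  if (n_sel > 0) selected[sample.int(L, n_sel)] <- TRUE
  p0 <- runif(L, 0.05, 0.95)
  Fvec <- ifelse(selected, cfg$F_sel, cfg$F_bg)
  P <- matrix(NA_real_, cfg$n_pops, L)
  for (k in seq_len(cfg$n_pops)) {
    if (any(!selected)) {
      Fv <- Fvec[!selected]
      P[k, !selected] <- rbeta(sum(!selected), p0[!selected] * (1 - Fv) / Fv,
                               (1 - p0[!selected]) * (1 - Fv) / Fv)
    }
    if (any(selected)) {
      # divergent selection: alternate populations favour opposite alleles,
      # with F_sel setting how far apart the equilibria sit; a moderate
      # Beta concentration keeps per-population frequencies near their
      # equilibrium instead of drifting bimodally (which would let both
      # populations fix the same allele and erase the signature)
      t_k <- 0.5 + (if (k %% 2 == 1) 1 else -1) * cfg$F_sel / 2
      t_k <- min(max(t_k, 0.02), 0.98)
      conc <- 20
      P[k, selected] <- rbeta(sum(selected), t_k * conc, (1 - t_k) * conc)
    }
  }
  allele_type <- ifelse(runif(L) < cfg$frac_loss_loci, "loss", "gain")
  lt <- data.frame(locus_id = sprintf("locus_%04d", seq_len(L)),
                   loci, allele_type = allele_type, selected = selected,
                   p0 = p0, stringsAsFactors = FALSE)
  for (k in seq_len(cfg$n_pops)) lt[[paste0("p_pop", k)]] <- P[k, ]
  truth <- list(locus_table = lt, genotypes = NULL, Q_true = NULL,
                breed_labels = NULL, cfg = cfg)
  class(truth) <- "truth_set"
  truth
}

pop_freq_matrix <- function(truth) {
  cols <- grep("^p_pop", names(truth$locus_table), value = TRUE)
  t(as.matrix(truth$locus_table[, cols, drop = FALSE]))  # n_pops x L
}

#' Simulate diploid copy-number genotypes and ancestry
#'
#' Each individual i has ancestry proportions Q_i: one-hot by breed when
#' `admix_alpha = 0`, otherwise Dirichlet(admix_alpha). At locus l the
#' individual's allele frequency is pi_il = sum_k Q_ik p_kl; the variant
#' allele count is Binomial(2, pi_il) and the copy state is 2 - x for loss
#' loci and 2 + x for gain loci, giving states in {0,1,2} and {2,3,4}.
#'
#' @param truth A `truth_set` with `locus_table` filled.
#' @param cfg The `sim_config` used to build `truth`.
#' @return The `truth_set` with `genotypes` (individuals x loci copy states),
#'   `Q_true` and `breed_labels` filled.
#' @export
simulate_genotypes <- function(truth, cfg) {
  stopifnot(inherits(truth, "truth_set"), !is.null(truth$locus_table))
  set.seed(cfg$seed + 1L)
  n <- sum(cfg$pop_sizes)
  L <- nrow(truth$locus_table)
  breed <- rep(paste0("pop", seq_len(cfg$n_pops)), cfg$pop_sizes)
  ids <- sprintf("%s_ind%02d", breed, unlist(lapply(cfg$pop_sizes, seq_len)))
  if (cfg$admix_alpha == 0) {
    Q <- matrix(0, n, cfg$n_pops)
    Q[cbind(seq_len(n), rep(seq_len(cfg$n_pops), cfg$pop_sizes))] <- 1
  } else {
    g <- matrix(rgamma(n * cfg$n_pops, shape = cfg$admix_alpha), n)
    Q <- g / rowSums(g)
  }
  P <- pop_freq_matrix(truth)
  pii <- Q %*% P                        # n x L mixed allele frequencies
  x <- matrix(rbinom(n * L, 2L, as.vector(pii)), n, L)
  loss <- truth$locus_table$allele_type == "loss"
  geno <- x
  geno[, loss] <- 2L - x[, loss]
  geno[, !loss] <- 2L + x[, !loss]
  rownames(geno) <- ids
  colnames(geno) <- truth$locus_table$locus_id
  rownames(Q) <- ids
  colnames(Q) <- paste0("pop", seq_len(cfg$n_pops))
  truth$genotypes <- geno
  truth$Q_true <- Q
  truth$breed_labels <- stats::setNames(breed, ids)
  truth
}

# Deterministic genome-wide GC track: smooth sinusoid in [0.3, 0.7].
gc_track <- function(n_bins, period_bins = 400) {
  0.5 + 0.2 * sin(2 * pi * seq_len(n_bins) / period_bins)
}

#' Simulate binned read-depth tracks consistent with planted genotypes
#'
#' For every individual, every chromosome is cut into `bin_width` bins. A bin
#' inside a planted locus carries the individual's copy state there; all other
#' bins are diploid. The expected count is
#' `mean_depth_per_bin * (copy/2) * (1 + gc_amp * sin(2*pi*gc_b))` with a
#' smooth deterministic GC track, and counts are Poisson (or negative
#' binomial when `overdispersion > 0`). Per-bin mapping-quality-zero (q0)
#' fractions are Beta(1, 19) (mean 0.05), except a designated set of
#' repeat-like bins drawn Beta(8, 2) (mean 0.8); repeat bins are shared
#' across individuals, as a genome property would be.
#'
#' @param truth A `truth_set` with genotypes filled.
#' @param cfg The corresponding `sim_config`.
#' @return Named list of `depth_track` objects (one per individual): each a
#'   data.frame with columns `chrom`, `start`, `end`, `count`, `gc`, `q0`
#'   (0-based half-open bp coordinates) and attributes `sample` and
#'   `bin_width`.
#' @export
simulate_depth <- function(truth, cfg) {
  stopifnot(!is.null(truth$genotypes))
  w <- cfg$bin_width
  chroms <- names(cfg$chrom_lengths)
  n_bins <- vapply(cfg$chrom_lengths, function(l) as.integer(ceiling(l / w)),
                   integer(1))
  grid <- do.call(rbind, lapply(seq_along(chroms), function(ci) {
    b <- seq_len(n_bins[ci]) - 1L
    data.frame(chrom = chroms[ci], start = b * w,
               end = pmin((b + 1) * w, cfg$chrom_lengths[ci]),
               gc = gc_track(n_bins[ci]), stringsAsFactors = FALSE)
  }))
  B <- nrow(grid)
  set.seed(cfg$seed + 2L)
  repeat_bins <- rep(FALSE, B)
  n_rep <- round(cfg$frac_repeat_bins * B)
  if (n_rep > 0) repeat_bins[sample.int(B, n_rep)] <- TRUE

  # per-bin copy template: locus index covering each bin (0 = none)
  lt <- truth$locus_table
  locus_of_bin <- integer(B)
  for (l in seq_len(nrow(lt))) {
    hit <- grid$chrom == lt$chrom[l] & grid$start < lt$end[l] &
      grid$end > lt$start[l]
    locus_of_bin[hit] <- l
  }
  gc_mult <- 1 + cfg$gc_amp * sin(2 * pi * grid$gc)
  ids <- rownames(truth$genotypes)
  tracks <- vector("list", length(ids))
  names(tracks) <- ids
  for (i in seq_along(ids)) {
    set.seed(cfg$seed + 1000L + i)
    copy <- rep(2, B)
    inl <- locus_of_bin > 0L
    copy[inl] <- truth$genotypes[i, locus_of_bin[inl]]
    mu <- cfg$mean_depth_per_bin * (copy / 2) * gc_mult
    count <- if (cfg$overdispersion > 0) {
      stats::rnbinom(B, size = 1 / cfg$overdispersion, mu = mu)
    } else {
      stats::rpois(B, mu)
    }
    q0 <- stats::rbeta(B, 1, 19)
    if (any(repeat_bins)) q0[repeat_bins] <- stats::rbeta(sum(repeat_bins), 8, 2)
    tr <- data.frame(grid[c("chrom", "start", "end")], count = count,
                     gc = grid$gc, q0 = q0, stringsAsFactors = FALSE)
    attr(tr, "sample") <- ids[i]
    attr(tr, "bin_width") <- w
    class(tr) <- c("depth_track", "data.frame")
    tracks[[i]] <- tr
  }
  tracks
}

#' Simulate gene models
#'
#' Places non-overlapping genes with 2-8 exons each. The first 60 bp of the
#' first exon are 5' UTR; the remaining exonic sequence is CDS, trimmed at
#' the last exon so that the total CDS length is divisible by 3. Strand is
#' random; output is sorted by (chrom, start).
#'
#' @param cfg A `sim_config`.
#' @return A `gene_model` list with data.frames `genes` (gene_id, chrom,
#'   start, end, strand), `exons` and `cds` (gene_id, chrom, start, end); all
#'   coordinates 0-based half-open.
#' @export
simulate_gene_models <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(cfg$seed + 3L)
  if (cfg$n_genes == 0) {
    empty <- data.frame(gene_id = character(), chrom = character(),
                        start = numeric(), end = numeric(),
                        strand = character(), stringsAsFactors = FALSE)
    gm <- list(genes = empty,
               exons = empty[c("gene_id", "chrom", "start", "end")],
               cds = empty[c("gene_id", "chrom", "start", "end")])
    class(gm) <- "gene_model"
    return(gm)
  }
  # gene span up to ~8 exons x 300bp + 7 introns x 1200bp ~ 10.8 kb
  span <- place_loci(cfg, cfg$n_genes, 20L, 60L, margin_bins = 1L)
  genes <- exons <- cds <- list()
  for (g in seq_len(nrow(span))) {
    gid <- sprintf("gene_%04d", g)
    gene_len <- span$end[g] - span$start[g]
    n_ex <- sample(2:8, 1L)
    ex_len <- sample(seq(120, 300, by = 3), n_ex, replace = TRUE)
    while (sum(ex_len) + (n_ex - 1) * 100 > gene_len) {
      if (n_ex > 2) { n_ex <- n_ex - 1L; ex_len <- ex_len[seq_len(n_ex)] }
      else ex_len <- pmax(120, ex_len - 60)
    }
    gap_total <- gene_len - sum(ex_len)
    gaps <- if (n_ex > 1) {
      u <- runif(n_ex - 1)
      floor(gap_total * u / sum(u))
    } else numeric(0)
    ex_start <- span$start[g] + cumsum(c(0, ex_len[-n_ex] + gaps))
    ex_end <- ex_start + ex_len
    strand <- sample(c("+", "-"), 1L)
    utr5 <- 60
    cds_start <- ex_start
    cds_end <- ex_end
    if (strand == "+") cds_start[1] <- cds_start[1] + utr5
    else cds_end[n_ex] <- cds_end[n_ex] - utr5
    total_cds <- sum(cds_end - cds_start)
    trim <- total_cds %% 3
    if (trim > 0) {
      if (strand == "+") cds_end[n_ex] <- cds_end[n_ex] - trim
      else cds_start[1] <- cds_start[1] + trim
    }
    genes[[g]] <- data.frame(gene_id = gid, chrom = span$chrom[g],
                             start = span$start[g], end = max(ex_end),
                             strand = strand, stringsAsFactors = FALSE)
    exons[[g]] <- data.frame(gene_id = gid, chrom = span$chrom[g],
                             start = ex_start, end = ex_end,
                             stringsAsFactors = FALSE)
    cds[[g]] <- data.frame(gene_id = gid, chrom = span$chrom[g],
                           start = cds_start, end = cds_end,
                           stringsAsFactors = FALSE)
  }
  gm <- list(genes = do.call(rbind, genes), exons = do.call(rbind, exons),
             cds = do.call(rbind, cds))
  ord <- order(gm$genes$chrom, gm$genes$start)
  gm$genes <- gm$genes[ord, , drop = FALSE]
  rownames(gm$genes) <- NULL
  class(gm) <- "gene_model"
  gm
}

#' Simulate a gene-set (term to gene) table
#'
#' Builds `n_terms` random gene sets over the simulated genes, plus one
#' planted term containing exactly the genes overlapped by selected loci
#' (when any exist), which gives enrichment tests a known positive.
#'
#' @param genes A `gene_model`.
#' @param truth Optional `truth_set`; when supplied, a `SELECTED_SET` term
#'   holding all genes hit by selected loci is appended.
#' @param n_terms Number of random terms (>= 10 by default).
#' @param cfg The `sim_config` (seeds the draw).
#' @return Named list of character vectors (term -> gene ids), with a
#'   `namespace` attribute.
#' @export
simulate_gene_sets <- function(genes, truth = NULL, n_terms = 12L,
                               cfg = NULL) {
  seed <- if (is.null(cfg)) 1L else cfg$seed + 4L
  set.seed(seed)
  ids <- genes$genes$gene_id
  sets <- lapply(seq_len(n_terms), function(i) {
    sort(sample(ids, max(3L, rbinom(1, length(ids), 0.15))))
  })
  names(sets) <- sprintf("TERM_%03d", seq_len(n_terms))
  if (!is.null(truth) && any(truth$locus_table$selected)) {
    sel <- truth$locus_table[truth$locus_table$selected, , drop = FALSE]
    hit <- vapply(seq_len(nrow(genes$genes)), function(g) {
      any(sel$chrom == genes$genes$chrom[g] &
            sel$start < genes$genes$end[g] & sel$end > genes$genes$start[g])
    }, logical(1))
    if (any(hit)) sets$SELECTED_SET <- sort(ids[hit])
  }
  attr(sets, "namespace") <- rep("pathway", length(sets))
  sets
}

#' Simulate a full cohort (frequencies, genotypes, depth, genes, gene sets)
#'
#' Convenience wrapper running all generator stages in their documented seed
#' order.
#'
#' @param cfg A `sim_config`.
#' @param depth Generate the per-sample depth tracks (the slow part).
#' @return List with elements `truth`, `tracks` (or NULL), `genes`,
#'   `gene_sets`, `layout`, and `cfg`.
#' @export
simulate_cohort <- function(cfg, depth = TRUE) {
  truth <- simulate_freqs(cfg)
  truth <- simulate_genotypes(truth, cfg)
  tracks <- if (depth) simulate_depth(truth, cfg) else NULL
  genes <- simulate_gene_models(cfg)
  gene_sets <- simulate_gene_sets(genes, truth, cfg = cfg)
  list(truth = truth, tracks = tracks, genes = genes, gene_sets = gene_sets,
       layout = sim_layout(cfg), cfg = cfg)
}
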