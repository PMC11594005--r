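#' Weir-Cockerham F_ST variance components, per locus
#'
#' For two groups of diploid individuals with per-group sample sizes n_i,
#' variant-allele frequencies p_i and observed heterozygote proportions h_i,
#' computes the among-population (a), among-individual-within-population (b)
#' and within-individual (c) variance components of the Weir-Cockerham
#' moment estimator, and F_ST = a / (a + b + c). Loci monomorphic in both
#' groups have a = b = c = 0 and an undefined F_ST; groups with fewer than
#' two individuals also render the locus undefined.
#'
#' @param G Individuals x loci dosage matrix with entries in {0,1,2}
#'   (heterozygotes are dosage 1).
#' @param groups Character/factor vector assigning each row to one of
#'   exactly two groups.
#' @return data.frame with columns `locus`, `a`, `b`, `c`, `fst`, `defined`.
#' @export
wc_fst <- function(G, groups) {
  groups <- as.character(groups)
  gl <- sort(unique(groups))
  if (length(gl) != 2) stop("exactly two groups are required", call. = FALSE)
  G1 <- G[groups == gl[1], , drop = FALSE]
  G2 <- G[groups == gl[2], , drop = FALSE]
  n1 <- nrow(G1); n2 <- nrow(G2)
  r <- 2
  p1 <- colMeans(G1) / 2; p2 <- colMeans(G2) / 2
  h1 <- colMeans(G1 == 1); h2 <- colMeans(G2 == 1)
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  denom <- a + b + cc
  defined <- denom != 0 & n1 >= 2 & n2 >= 2
  mono <- (p1 == 0 & p2 == 0) | (p1 == 1 & p2 == 1)
  a[mono] <- 0; b[mono] <- 0; cc[mono] <- 0
  defined[mono] <- FALSE
  fst <- ifelse(defined, a / (a + b + cc), NA_real_)
  locus <- colnames(G)
  if (is.null(locus)) locus <- paste0("locus_", seq_len(ncol(G)))
  data.frame(locus = locus, a = a, b = b, c = cc, fst = fst,
             defined = defined, stringsAsFactors = FALSE, row.names = NULL)
}

#' Multi-locus weighted F_ST (ratio of sums)
#'
#' sum(a) / sum(a + b + c) over defined loci — the genome-wide "weighted"
#' estimator.
#'
#' @param fst_table Output of [wc_fst()].
#' @return Scalar weighted F_ST (NA when no locus is defined or the
#'   denominator is zero).
#' @export
weighted_fst <- function(fst_table) {
  d <- fst_table[fst_table$defined, , drop = FALSE]
  if (nrow(d) == 0) return(NA_real_)
  den <- sum(d$a + d$b + d$c)
  if (den == 0) return(NA_real_)
  sum(d$a) / den
}

#' Top-percentile selection thresholding
#'
#' Ranks defined per-locus F_ST values and flags as selected every locus with
#' F_ST at or above the empirical `quantile` (type-7 linear interpolation),
#' ties included. Negative estimates stay in the ranking unclamped.
#'
#' @param fst_table Output of [wc_fst()].
#' @param quantile Selection quantile (default 0.99, the top 1%).
#' @return A `selection_result` list: `table` (per-locus fst, rank, selected),
#'   `threshold`, `weighted_fst`, `n_defined`.
#' @export
select_top <- function(fst_table, quantile = 0.99) {
  def <- fst_table$defined
  if (sum(def) < 100)
    warning("fewer than 100 defined loci; the empirical quantile is coarse")
  tau <- stats::quantile(fst_table$fst[def], probs = quantile, type = 7,
                         names = FALSE)
  tab <- fst_table
  tab$rank <- NA_integer_
  tab$rank[def] <- rank(-tab$fst[def], ties.method = "min")
  tab$selected <- def & tab$fst >= tau
  res <- list(table = tab, threshold = tau,
              weighted_fst = weighted_fst(fst_table),
              n_defined = sum(def))
  class(res) <- "selection_result"
  res
}

#' Candidate genes under selection
#'
#' The unique, sorted gene ids overlapped by at least 1 bp by any selected
#' CNVR.
#'
#' @param selection A `selection_result` from [select_top()].
#' @param annotated Annotated CNVR data.frame ([annotate_cnvrs()]); matched
#'   to selection loci through the `source_cnvr` of the biallelic recoding.
#' @param mat The `biallelic_matrix` whose loci were scanned (provides the
#'   locus -> CNVR map).
#' @return Character vector of candidate gene ids.
#' @export
candidate_genes <- function(selection, annotated, mat) {
  sel_loci <- selection$table$locus[selection$table$selected]
  sel_cnvr <- unique(mat$info$source_cnvr[mat$info$locus_id %in% sel_loci])
  hits <- annotated$genes[annotated$id %in% sel_cnvr]
  out <- unlist(strsplit(hits[nzchar(hits)], ","))
  if (is.null(out)) character(0) else sort(unique(out))
}

#' F_ST selection scan between two breed groups
#'
#' Convenience wrapper: recodes CNVR genotypes, maps breeds to two groups,
#' computes per-locus Weir-Cockerham components and applies the top-quantile
#' rule.
#'
#' @param geno A `cnvr_genotypes` object.
#' @param group_map Named vector breed -> group (exactly two distinct
#'   groups), e.g. pooling several breeds against one.
#' @param quantile Selection quantile (default 0.99).
#' @return A `selection_result`, with the `biallelic_matrix` attached as
#'   `$mat`.
#' @export
fst_scan <- function(geno, group_map, quantile = 0.99) {
  mat <- recode_biallelic(geno)
  grp <- group_map[mat$breed_labels[rownames(mat$G)]]
  if (any(is.na(grp))) stop("group_map does not cover all breeds",
                            call. = FALSE)
  res <- select_top(wc_fst(mat$G, grp), quantile = quantile)
  res$mat <- mat
  res
}
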