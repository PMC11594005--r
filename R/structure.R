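#' Recode CNVR copy states to biallelic dosages
#'
#' Loss CNVRs become deletion-allele dosages 2 - copy (clipped to [0, 2]);
#' gain CNVRs become duplication-allele dosages copy - 2 (clipped). Mixed
#' CNVRs are split into two pseudo-loci, one loss-coded and one gain-coded,
#' so both allele classes stay visible to the population-genetic machinery.
#'
#' @param geno A `cnvr_genotypes` object.
#' @return A `biallelic_matrix` list: `G` (individuals x loci dosage matrix
#'   in {0,1,2}), `freq` (per-locus variant-allele frequency), `info`
#'   (locus_id, source cnvr id, allele, monomorphic flag), `breed_labels`.
#' @export
recode_biallelic <- function(geno) {
  st <- geno$states
  type <- geno$cnvrs$type
  cols <- list(); info <- list()
  for (j in seq_len(ncol(st))) {
    cid <- geno$cnvrs$id[j]
    if (type[j] %in% c("loss", "mixed")) {
      cols[[length(cols) + 1L]] <- pmin(pmax(2L - st[, j], 0L), 2L)
      info[[length(info) + 1L]] <- c(cid, "loss")
    }
    if (type[j] %in% c("gain", "mixed")) {
      cols[[length(cols) + 1L]] <- pmin(pmax(st[, j] - 2L, 0L), 2L)
      info[[length(info) + 1L]] <- c(cid, "gain")
    }
  }
  G <- do.call(cbind, cols)
  inf <- do.call(rbind, info)
  info_df <- data.frame(source_cnvr = inf[, 1], allele = inf[, 2],
                        stringsAsFactors = FALSE)
  info_df$locus_id <- paste0(info_df$source_cnvr, "_", info_df$allele)
  colnames(G) <- info_df$locus_id
  rownames(G) <- rownames(st)
  freq <- colSums(G) / (2 * nrow(G))
  info_df$monomorphic <- freq == 0 | freq == 1
  res <- list(G = G, freq = freq, info = info_df,
              breed_labels = geno$breed_labels)
  class(res) <- "biallelic_matrix"
  res
}

#' Construct a biallelic matrix directly from a dosage matrix
#'
#' Convenience for simulated or externally supplied dosages.
#'
#' @param G Individuals x loci matrix with entries in {0,1,2}.
#' @param breed_labels Optional named vector sample -> breed.
#' @return A `biallelic_matrix`.
#' @export
as_biallelic <- function(G, breed_labels = NULL) {
  if (is.null(colnames(G))) colnames(G) <- paste0("locus_", seq_len(ncol(G)))
  if (is.null(rownames(G))) rownames(G) <- paste0("ind_", seq_len(nrow(G)))
  freq <- colSums(G) / (2 * nrow(G))
  res <- list(G = G, freq = freq,
              info = data.frame(source_cnvr = colnames(G), allele = NA,
                                locus_id = colnames(G),
                                monomorphic = freq %in% c(0, 1),
                                stringsAsFactors = FALSE),
              breed_labels = breed_labels)
  class(res) <- "biallelic_matrix"
  res
}

#' Genetic distance matrix from biallelic dosages
#'
#' `ibs_individual`: identity-by-state dissimilarity between individuals,
#' d_ij = mean_l |g_il - g_jl| / 2, in [0, 1]. `fst_population`: pairwise
#' multi-locus Weir-Cockerham F_ST between breeds (ratio of sums), clipped
#' below at 0.
#'
#' @param mat A `biallelic_matrix`.
#' @param mode "ibs_individual" or "fst_population".
#' @return A symmetric distance matrix with zero diagonal.
#' @export
distance_matrix <- function(mat, mode = c("ibs_individual",
                                          "fst_population")) {
  mode <- match.arg(mode)
  G <- mat$G
  if (ncol(G) == 0) stop("no loci", call. = FALSE)
  if (mode == "ibs_individual") {
    n <- nrow(G)
    D <- matrix(0, n, n, dimnames = list(rownames(G), rownames(G)))
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      D[i, j] <- D[j, i] <- mean(abs(G[i, ] - G[j, ])) / 2
    }
    return(D)
  }
  br <- mat$breed_labels[rownames(G)]
  if (is.null(br)) stop("fst_population mode needs breed labels",
                        call. = FALSE)
  breeds <- sort(unique(br))
  m <- length(breeds)
  if (m < 2) stop("need at least two breeds", call. = FALSE)
  D <- matrix(0, m, m, dimnames = list(breeds, breeds))
  for (i in seq_len(m - 1)) for (j in (i + 1):m) {
    sub <- G[br %in% breeds[c(i, j)], , drop = FALSE]
    grp <- br[br %in% breeds[c(i, j)]]
    fst <- wc_fst(sub, grp)
    D[i, j] <- D[j, i] <- max(0, weighted_fst(fst))
  }
  D
}

#' Neighbor-joining tree
#'
#' Saitou-Nei agglomeration on a symmetric distance matrix with the
#' rate-corrected join criterion Q_ij = (r-2) d_ij - R_i - R_j; the minimal
#' pair is joined, with ties broken by the smallest (i, j) index pair.
#' Negative branch lengths are clamped to zero. On an additive (tree-like)
#' matrix the path metric of the result reproduces the input exactly.
#'
#' @param D Symmetric distance matrix with labels as dimnames.
#' @return An [ape::read.tree()]-compatible `phylo` object (unrooted).
#' @export
nj_tree <- function(D) {
  if (!isSymmetric(unname(as.matrix(D))))
    stop("distance matrix must be symmetric", call. = FALSE)
  D <- as.matrix(D)
  n <- nrow(D)
  if (n < 3) stop("need at least 3 taxa", call. = FALSE)
  labels <- rownames(D)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  # nodes referenced by newick fragments; distances shrink as we join
  frag <- labels
  active <- seq_len(n)
  M <- D
  while (length(active) > 2) {
    r <- length(active)
    Rsum <- rowSums(M)
    Qc <- (r - 2) * M - outer(Rsum, Rsum, `+`)
    diag(Qc) <- Inf
    best <- which(Qc == min(Qc), arr.ind = TRUE)
    best <- best[order(pmin(best[, 1], best[, 2]),
                       pmax(best[, 1], best[, 2])), , drop = FALSE]
    ij <- sort(best[1, ])
    i <- ij[1]; j <- ij[2]
    vi <- 0.5 * M[i, j] + (Rsum[i] - Rsum[j]) / (2 * (r - 2))
    vj <- M[i, j] - vi
    vi <- max(vi, 0); vj <- max(vj, 0)
    newfrag <- sprintf("(%s:%.10f,%s:%.10f)", frag[i], vi, frag[j], vj)
    dnew <- 0.5 * (M[i, ] + M[j, ] - M[i, j])
    dnew <- dnew[-c(i, j)]
    M <- M[-c(i, j), -c(i, j), drop = FALSE]
    M <- rbind(cbind(M, dnew), c(dnew, 0))
    frag <- c(frag[-c(i, j)], newfrag)
    active <- seq_len(nrow(M))
  }
  v <- max(M[1, 2], 0)
  newick <- if (length(frag) == 2) {
    sprintf("(%s:%.10f,%s:0);", frag[1], v, frag[2])
  } else sprintf("(%s);", frag[1])
  ape::read.tree(text = newick)
}

#' Principal component analysis of biallelic dosages
#'
#' Monomorphic loci are dropped; each locus is centered by 2 p and scaled by
#' sqrt(2 p (1 - p)) (the variance-standardized convention of genotype PCA),
#' then the sample covariance is eigendecomposed. Per component, the sign is
#' fixed so the largest-magnitude sample coordinate is positive.
#'
#' @param mat A `biallelic_matrix`.
#' @return A `cnv_pca` list: `coords` (samples x PCs), `eigenvalues`,
#'   `pct_variance`, `n_loci_used`, `n_monomorphic_dropped`.
#' @export
cnv_pca <- function(mat) {
  keep <- !mat$info$monomorphic
  if (!any(keep)) stop("all loci are monomorphic", call. = FALSE)
  G <- mat$G[, keep, drop = FALSE]
  p <- mat$freq[keep]
  X <- sweep(G, 2, 2 * p)
  X <- sweep(X, 2, sqrt(2 * p * (1 - p)), "/")
  n <- nrow(X)
  C <- tcrossprod(X) / ncol(X)
  eig <- eigen(C, symmetric = TRUE)
  nc <- min(n - 1, ncol(X))
  lam <- pmax(eig$values[seq_len(nc)], 0)
  vec <- eig$vectors[, seq_len(nc), drop = FALSE]
  coords <- vec %*% diag(sqrt(lam), nc)
  for (k in seq_len(nc)) {
    if (abs(min(coords[, k])) > abs(max(coords[, k])))
      coords[, k] <- -coords[, k]
  }
  rownames(coords) <- rownames(G)
  colnames(coords) <- paste0("PC", seq_len(nc))
  res <- list(coords = coords, eigenvalues = lam,
              pct_variance = 100 * lam / sum(lam),
              n_loci_used = ncol(G),
              n_monomorphic_dropped = sum(!keep))
  class(res) <- "cnv_pca"
  res
}

admix_loglik <- function(G, Q, Fq) {
  P <- Q %*% Fq
  sum(G * log(P) + (2 - G) * log1p(-P))
}

#' Maximum-likelihood admixture model by EM
#'
#' Fits the K-ancestral-population admixture model: individual i carries
#' ancestry proportions Q_i (rows sum to 1) and population k has allele
#' frequency Fq_kl at locus l; the dosage g_il is Binomial(2, pi_il) with
#' pi_il = sum_k Q_ik Fq_kl. The EM scheme alternates allele-origin
#' responsibilities with closed-form updates of Q and Fq; the log-likelihood
#' is non-decreasing at every iteration. The best of `restarts` random
#' initializations is returned.
#'
#' @param mat A `biallelic_matrix` (monomorphic loci are dropped).
#' @param K Number of ancestral populations.
#' @param seed Integer seed for the restarts.
#' @param restarts Number of random initializations (default 5).
#' @param max_iter,tol EM stopping rule: at most `max_iter` iterations or
#'   log-likelihood improvement below `tol`.
#' @return An `admixture_fit` list: `K`, `Q`, `Fq`, `loglik` (trace of the
#'   best run), `seed`, `restarts`.
#' @export
admixture_em <- function(mat, K, seed = 1L, restarts = 5L,
                         max_iter = 2000L, tol = 1e-6) {
  keep <- !mat$info$monomorphic
  G <- mat$G[, keep, drop = FALSE]
  n <- nrow(G); L <- ncol(G)
  if (K > n) stop("K exceeds the number of individuals", call. = FALSE)
  if (K < 1) stop("K must be >= 1", call. = FALSE)
  p_hat <- colSums(G) / (2 * n)
  best <- NULL
  for (rs in seq_len(restarts)) {
    set.seed(seed + rs - 1L)
    Q <- matrix(stats::rgamma(n * K, 1), n, K)
    Q <- Q / rowSums(Q)
    Fq <- matrix(pmin(pmax(rep(p_hat, each = K) *
                             stats::runif(K * L, 0.5, 1.5), 1e-6),
                      1 - 1e-6), K, L)
    trace <- numeric(0)
    ll_old <- -Inf
    for (it in seq_len(max_iter)) {
      P <- Q %*% Fq
      P <- pmin(pmax(P, 1e-12), 1 - 1e-12)
      Qnum <- matrix(0, n, K)
      Fnum <- matrix(0, K, L)
      Fden <- matrix(0, K, L)
      for (k in seq_len(K)) {
        Rk <- (Q[, k] %o% Fq[k, ]) / P          # variant-allele resp.
        Sk <- (Q[, k] %o% (1 - Fq[k, ])) / (1 - P)
        num_var <- G * Rk
        num_ref <- (2 - G) * Sk
        Qnum[, k] <- rowSums(num_var + num_ref)
        Fnum[k, ] <- colSums(num_var)
        Fden[k, ] <- colSums(num_var + num_ref)
      }
      Q <- Qnum / (2 * L)
      Q <- Q / rowSums(Q)                       # guard rounding drift
      Fq <- Fnum / Fden
      Fq <- pmin(pmax(Fq, 1e-6), 1 - 1e-6)
      ll <- admix_loglik(G, Q, Fq)
      trace <- c(trace, ll)
      if (is.finite(ll_old) && ll - ll_old < tol) break
      ll_old <- ll
    }
    if (is.null(best) || trace[length(trace)] > best$loglik[length(best$loglik)]) {
      rownames(Q) <- rownames(G)
      best <- list(K = K, Q = Q, Fq = Fq, loglik = trace, seed = seed,
                   restarts = restarts)
    }
  }
  class(best) <- "admixture_fit"
  best
}

#' Align an estimated Q matrix to a reference by label permutation
#'
#' Ancestry components are identifiable only up to permutation; this finds
#' the column permutation of `Q` minimizing the root-mean-square error to
#' `Q_ref` and returns the permuted matrix plus the attained RMSE.
#'
#' @param Q,Q_ref n x K ancestry matrices.
#' @return List with `Q` (permuted) and `rmse`.
#' @export
align_q <- function(Q, Q_ref) {
  K <- ncol(Q)
  perms <- perms_of(K)
  best <- NULL
  for (p in perms) {
    r <- sqrt(mean((Q[, p, drop = FALSE] - Q_ref)^2))
    if (is.null(best) || r < best$rmse)
      best <- list(Q = Q[, p, drop = FALSE], rmse = r)
  }
  best
}

perms_of <- function(k) {
  if (k == 1) return(list(1L))
  out <- list()
  for (i in seq_len(k)) {
    for (p in perms_of(k - 1L)) {
      rest <- setdiff(seq_len(k), i)
      out[[length(out) + 1L]] <- c(i, rest[p])
    }
  }
  out
}
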