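#' Upper-tail hypergeometric over-representation p-value
#'
#' P(X >= k) where X counts the overlap between a query of size n and a term
#' of size K drawn without replacement from a universe of size N. With
#' `ease = TRUE` the more conservative EASE variant is used (one overlap
#' gene discounted, i.e. the tail is evaluated at k - 1).
#'
#' @param query Character vector of query genes (deduplicated; genes outside
#'   the universe are dropped with a warning).
#' @param term Character vector of the term's genes.
#' @param universe Character vector of background genes.
#' @param ease Use the EASE-score variant (default FALSE).
#' @return List with `p`, `k` (overlap), `K` (term size), `n` (query size),
#'   `N` (universe size).
#' @export
hypergeom_test <- function(query, term, universe, ease = FALSE) {
  if (length(universe) == 0) stop("empty universe", call. = FALSE)
  universe <- unique(universe)
  query <- unique(query)
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warning(length(outside), " query gene(s) outside the universe dropped")
    query <- intersect(query, universe)
  }
  term <- intersect(unique(term), universe)
  k <- length(intersect(query, term))
  K <- length(term)
  n <- length(query)
  N <- length(universe)
  kk <- if (ease) max(k - 1L, 0L) else k
  p <- stats::phyper(kk - 1L, K, N - K, n, lower.tail = FALSE)
  list(p = p, k = k, K = K, n = n, N = N)
}

#' Multiple-testing corrections
#'
#' Bonferroni (min(1, m p)) and Benjamini-Hochberg step-up q-values with
#' enforced monotonicity, over `m` tests.
#'
#' @param p Numeric vector of p-values.
#' @param m Number of tests (defaults to `length(p)`).
#' @return List with `bonferroni` and `bh`.
#' @export
correct_pvalues <- function(p, m = length(p)) {
  list(bonferroni = pmin(1, m * p),
       bh = stats::p.adjust(p, method = "BH", n = m))
}

#' Gene-set over-representation analysis
#'
#' Tests every term of a gene-set database against a query gene list with
#' the upper-tail hypergeometric test; corrections are computed within each
#' term namespace (e.g. GO aspects and pathways separately). The universe
#' defaults to all genes appearing in the database, the background
#' convention of annotation-driven tools.
#'
#' @param query Character vector of query genes.
#' @param gmt Named list term -> character vector of genes, optionally with
#'   a `namespace` attribute (parallel character vector).
#' @param universe Background genes; default union of all term genes.
#' @param ease Use the EASE variant of the test.
#' @return data.frame sorted by p: Term, Namespace, k, K, n, N, Gene.ratio,
#'   p, Bonferroni, BH, Genes (comma-separated overlap).
#' @export
enrich_test <- function(query, gmt, universe = NULL, ease = FALSE) {
  if (is.null(universe)) universe <- sort(unique(unlist(gmt)))
  ns <- attr(gmt, "namespace")
  if (is.null(ns)) ns <- rep("all", length(gmt))
  rows <- lapply(seq_along(gmt), function(i) {
    ht <- suppressWarnings(hypergeom_test(query, gmt[[i]], universe,
                                          ease = ease))
    ov <- intersect(intersect(unique(query), universe), gmt[[i]])
    data.frame(Term = names(gmt)[i], Namespace = ns[i], k = ht$k, K = ht$K,
               n = ht$n, N = ht$N,
               Gene.ratio = if (ht$n > 0) ht$k / ht$n else 0,
               p = ht$p, Genes = paste(sort(ov), collapse = ","),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$Bonferroni <- NA_real_
  res$BH <- NA_real_
  for (space in unique(res$Namespace)) {
    ix <- res$Namespace == space
    cr <- correct_pvalues(res$p[ix], m = sum(ix))
    res$Bonferroni[ix] <- cr$bonferroni
    res$BH[ix] <- cr$bh
  }
  res <- res[order(res$p, res$Term), , drop = FALSE]
  rownames(res) <- NULL
  res[c("Term", "Namespace", "k", "K", "n", "N", "Gene.ratio", "p",
        "Bonferroni", "BH", "Genes")]
}
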