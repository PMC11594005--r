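region_class_levels <- c("exonic", "UTR", "intronic", "upstream",
                         "downstream", "intergenic")

# interval overlap in bp between one region and a table of 0-based
# half-open intervals on the same chromosome scale
overlap_bp <- function(start, end, tab) {
  if (nrow(tab) == 0) return(0)
  sum(pmax(0, pmin(end, tab$end) - pmax(start, tab$start)))
}

#' Classify CNVRs by genomic context
#'
#' Against a gene model, each CNVR is assigned the highest-precedence class
#' among the features it overlaps by at least 1 bp, with precedence
#' exonic > UTR > intronic > upstream > downstream > intergenic (the
#' gene-based convention of standard variant annotators). "Exonic" means
#' overlap with coding sequence; exonic-but-non-coding overlap is "UTR";
#' within a gene body outside exons is "intronic". Upstream and downstream
#' are strand-aware windows (default 1 kb) flanking the gene. Gene hits are
#' all genes whose body is overlapped by at least 1 bp. Loss CNVRs that are
#' exonic additionally get the frameshift subtype of
#' [frameshift_subtype()].
#'
#' @param cnvrs CNVR data.frame (id, chrom, start, end, type).
#' @param genes A `gene_model` (as from [simulate_gene_models()] or
#'   [read_gff3()]).
#' @param flank Upstream/downstream window in bp (default 1000).
#' @return The CNVR data.frame with columns `region_class`, `genes`
#'   (comma-separated gene ids, "" if none), `exonic_subtype` and
#'   `whole_gene` added.
#' @export
annotate_cnvrs <- function(cnvrs, genes, flank = 1000) {
  n <- nrow(cnvrs)
  cls <- character(n); hits <- character(n)
  sub <- character(n); whole <- logical(n)
  for (i in seq_len(n)) {
    a <- classify_region(cnvrs$chrom[i], cnvrs$start[i], cnvrs$end[i],
                         genes, flank = flank)
    cls[i] <- a$region_class
    hits[i] <- paste(a$genes, collapse = ",")
    sub[i] <- if (a$region_class == "exonic" && cnvrs$type[i] == "loss") {
      frameshift_subtype(cnvrs$chrom[i], cnvrs$start[i], cnvrs$end[i], genes)
    } else "not_applicable"
    whole[i] <- a$whole_gene
  }
  cnvrs$region_class <- cls
  cnvrs$genes <- hits
  cnvrs$exonic_subtype <- sub
  cnvrs$whole_gene <- whole
  cnvrs
}

#' Classify a single region
#'
#' @param chrom,start,end Region coordinates (0-based half-open).
#' @param genes A `gene_model`.
#' @param flank Upstream/downstream window in bp.
#' @return List with `region_class`, `genes` (sorted ids of genes whose body
#'   overlaps the region) and `whole_gene` (TRUE when some hit gene is
#'   entirely contained in the region).
#' @export
classify_region <- function(chrom, start, end, genes, flank = 1000) {
  g <- genes$genes[genes$genes$chrom == chrom, , drop = FALSE]
  if (nrow(g) == 0)
    return(list(region_class = "intergenic", genes = character(0),
                whole_gene = FALSE))
  ex <- genes$exons[genes$exons$chrom == chrom, , drop = FALSE]
  cd <- genes$cds[genes$cds$chrom == chrom, , drop = FALSE]
  body_hit <- g$start < end & g$end > start
  hit_ids <- sort(g$gene_id[body_hit])
  up_s <- ifelse(g$strand == "+", g$start - flank, g$end)
  up_e <- ifelse(g$strand == "+", g$start, g$end + flank)
  dn_s <- ifelse(g$strand == "+", g$end, g$start - flank)
  dn_e <- ifelse(g$strand == "+", g$end + flank, g$start)
  cds_bp <- overlap_bp(start, end, cd)
  exon_bp <- overlap_bp(start, end, ex)
  cls <- if (cds_bp > 0) "exonic"
  else if (exon_bp > 0) "UTR"
  else if (any(body_hit)) "intronic"
  else if (any(up_s < end & up_e > start)) "upstream"
  else if (any(dn_s < end & dn_e > start)) "downstream"
  else "intergenic"
  whole <- any(body_hit & g$start >= start & g$end <= end)
  list(region_class = cls, genes = hit_ids, whole_gene = whole)
}

#' Frameshift subtype of an exonic deletion
#'
#' The deleted coding length is the summed overlap of the region with all
#' CDS intervals. A deletion is `frameshift_deletion` when that length is
#' not a multiple of 3, `nonframeshift_deletion` when it is a positive
#' multiple of 3 (the reading frame is preserved), and `unknown` when the
#' exonic overlap touches no coding sequence (e.g. a non-coding exon).
#'
#' @param chrom,start,end Region coordinates (0-based half-open).
#' @param genes A `gene_model`.
#' @return One of "frameshift_deletion", "nonframeshift_deletion",
#'   "unknown".
#' @export
frameshift_subtype <- function(chrom, start, end, genes) {
  cd <- genes$cds[genes$cds$chrom == chrom, , drop = FALSE]
  del <- overlap_bp(start, end, cd)
  if (del == 0) "unknown"
  else if (del %% 3 != 0) "frameshift_deletion"
  else "nonframeshift_deletion"
}

#' Exonic gene sets per population, with set algebra
#'
#' From per-population annotated CNVR tables, collects the genes hit by
#' exonic CNVRs of each population and computes all pairwise differences and
#' the global intersection, deterministically sorted — the inputs of a Venn
#' comparison across populations.
#'
#' @param annotated Named list of annotated CNVR data.frames (one per
#'   population), as returned by [annotate_cnvrs()].
#' @return List with `sets` (named list of sorted gene vectors),
#'   `intersection`, and `difference` (named list, `A_minus_B`).
#' @export
gene_sets <- function(annotated) {
  sets <- lapply(annotated, function(d) {
    ex <- d[d$region_class == "exonic" & nzchar(d$genes), , drop = FALSE]
    sort(unique(unlist(strsplit(ex$genes, ","))))
  })
  inter <- if (length(sets)) Reduce(intersect, sets) else character(0)
  diffs <- list()
  nm <- names(sets)
  for (a in nm) for (b in nm) if (a != b)
    diffs[[paste0(a, "_minus_", b)]] <- sort(setdiff(sets[[a]], sets[[b]]))
  list(sets = sets, intersection = sort(inter), difference = diffs)
}
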