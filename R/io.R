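# All internal coordinates are 0-based half-open. Conversions live here:
# VCF and GFF3 are written 1-based (inclusive end), BED stays 0-based
# half-open.

#' Write / read a binned depth track as bedGraph-like TSV
#'
#' Columns: chrom, start, end, count, gc, q0 (0-based half-open).
#'
#' @param track A `depth_track` data.frame.
#' @param path Output file.
#' @export
write_depth <- function(track, path) {
  con <- file(path, "w")
  writeLines(sprintf("#sample=%s bin_width=%d", attr(track, "sample"),
                     attr(track, "bin_width")), con)
  utils::write.table(track, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  close(con)
  invisible(path)
}

#' @rdname write_depth
#' @return `read_depth` returns the `depth_track`.
#' @export
read_depth <- function(path) {
  hdr <- readLines(path, n = 1)
  meta <- regmatches(hdr, regexec("#sample=(\\S+) bin_width=(\\d+)", hdr))[[1]]
  tr <- utils::read.table(path, header = TRUE, sep = "\t", skip = 1,
                          stringsAsFactors = FALSE)
  attr(tr, "sample") <- meta[2]
  attr(tr, "bin_width") <- as.integer(meta[3])
  class(tr) <- c("depth_track", "data.frame")
  tr
}

vcf_header <- function(sample_cols, contigs = NULL) {
  c("##fileformat=VCFv4.2",
    "##source=cnvpop",
    if (!is.null(contigs))
      sprintf("##contig=<ID=%s,length=%d>", contigs$chrom,
              as.integer(contigs$length)),
    "##ALT=<ID=DEL,Description=\"Deletion\">",
    "##ALT=<ID=DUP,Description=\"Duplication\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"Length\">",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
    "##INFO=<ID=CN,Number=1,Type=Integer,Description=\"Copy number\">",
    "##INFO=<ID=Q0,Number=1,Type=Float,Description=\"Zero-MQ fraction\">",
    "##INFO=<ID=PVAL,Number=1,Type=Float,Description=\"Call p-value\">",
    "##FORMAT=<ID=CN,Number=1,Type=Integer,Description=\"Copy number\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            if (length(sample_cols)) c("FORMAT", sample_cols)),
          collapse = "\t"))
}

#' Write per-sample CNV calls as a VCF 4.2 CNV dialect
#'
#' One record per call: POS is 1-based start, INFO carries END (1-based
#' inclusive), SVLEN, SVTYPE (DEL/DUP), CN, Q0 and PVAL; ALT is <DEL> or
#' <DUP>.
#'
#' @param calls Call data.frame.
#' @param path Output file.
#' @param layout Optional genome layout for contig header lines.
#' @export
write_calls_vcf <- function(calls, path, layout = NULL) {
  lines <- vcf_header(character(0), layout)
  if (nrow(calls)) {
    svtype <- ifelse(calls$copy_state < 2, "DEL", "DUP")
    recs <- sprintf(
      "%s\t%d\t%s\t.\t<%s>\t.\tPASS\tEND=%d;SVLEN=%d;SVTYPE=%s;CN=%d;Q0=%.6g;PVAL=%.6g",
      calls$chrom, calls$start + 1L,
      sprintf("%s_call%04d", calls$sample, seq_len(nrow(calls))),
      svtype, as.integer(calls$end), as.integer(calls$end - calls$start),
      svtype, calls$copy_state, calls$q0_frac, calls$p_value)
    lines <- c(lines, recs)
  }
  writeLines(lines, path)
  invisible(path)
}

info_field <- function(info, key) {
  m <- regmatches(info, regexec(paste0("(?:^|;)", key, "=([^;]+)"), info))
  vapply(m, function(x) if (length(x) == 2) x[2] else NA_character_,
         character(1))
}

#' Read a CNV VCF dialect back into a call data.frame
#'
#' @param path VCF file written by [write_calls_vcf()] or any SVTYPE/END/CN
#'   dialect.
#' @param sample Sample id to assign (default: from filename).
#' @export
read_calls_vcf <- function(path, sample = NULL) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  if (is.null(sample))
    sample <- sub("\\.vcf$", "", basename(path))
  if (length(body) == 0) return(empty_calls())
  f <- strsplit(body, "\t")
  bad <- which(lengths(f) < 8)
  if (length(bad))
    stop("malformed VCF record at line ", bad[1], call. = FALSE)
  chrom <- vapply(f, `[`, "", 1)
  pos <- as.numeric(vapply(f, `[`, "", 2))
  info <- vapply(f, `[`, "", 8)
  end <- as.numeric(info_field(info, "END"))
  cn <- as.integer(info_field(info, "CN"))
  q0 <- as.numeric(info_field(info, "Q0"))
  pv <- as.numeric(info_field(info, "PVAL"))
  data.frame(sample = sample, chrom = chrom, start = pos - 1, end = end,
             copy_state = cn, d = cn / 2,
             p_value = ifelse(is.na(pv), 0, pv),
             q0_frac = ifelse(is.na(q0), 0, q0), stringsAsFactors = FALSE)
}

#' Write CNVRs as BED6
#'
#' name = type, score = carrier count, 0-based half-open.
#' @param cnvrs CNVR data.frame.
#' @param path Output file.
#' @export
write_cnvr_bed <- function(cnvrs, path) {
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t.", cnvrs$chrom,
                   as.integer(cnvrs$start), as.integer(cnvrs$end),
                   cnvrs$type, cnvrs$carrier_count)
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED file of regions
#'
#' Records with end <= start are rejected with their line number.
#' @param path BED file (>= 3 columns).
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "track")]
  f <- strsplit(lines, "\t")
  start <- as.numeric(vapply(f, `[`, "", 2))
  end <- as.numeric(vapply(f, `[`, "", 3))
  bad <- which(!(end > start))
  if (length(bad))
    stop("BED record with end <= start at line ", bad[1], call. = FALSE)
  data.frame(chrom = vapply(f, `[`, "", 1), start = start, end = end,
             name = vapply(f, function(x) if (length(x) >= 4) x[4] else ".",
                           ""),
             score = vapply(f, function(x)
               if (length(x) >= 5) as.numeric(x[5]) else NA_real_, 0),
             stringsAsFactors = FALSE)
}

#' Write a merged multi-sample CNVR VCF with per-sample CN genotypes
#'
#' @param geno A `cnvr_genotypes` object.
#' @param path Output file.
#' @param layout Optional layout for contig lines.
#' @export
write_cnvr_vcf <- function(geno, path, layout = NULL) {
  samples <- rownames(geno$states)
  lines <- vcf_header(samples, layout)
  cn <- geno$cnvrs
  for (j in seq_len(nrow(cn))) {
    svtype <- c(loss = "DEL", gain = "DUP", mixed = "CNV")[cn$type[j]]
    rec <- sprintf("%s\t%d\t%s\t.\t<%s>\t.\tPASS\tEND=%d;SVTYPE=%s\tCN\t%s",
                   cn$chrom[j], as.integer(cn$start[j]) + 1L, cn$id[j],
                   svtype, as.integer(cn$end[j]), svtype,
                   paste(geno$states[, j], collapse = "\t"))
    lines <- c(lines, rec)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a merged CNVR VCF back into a `cnvr_genotypes` object
#' @param path File written by [write_cnvr_vcf()].
#' @export
read_cnvr_vcf <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#CHROM")]
  cols <- strsplit(hdr, "\t")[[1]]
  samples <- cols[-(1:9)]
  body <- lines[!startsWith(lines, "#")]
  f <- strsplit(body, "\t")
  chrom <- vapply(f, `[`, "", 1)
  start <- as.numeric(vapply(f, `[`, "", 2)) - 1
  id <- vapply(f, `[`, "", 3)
  info <- vapply(f, `[`, "", 8)
  end <- as.numeric(info_field(info, "END"))
  alt <- vapply(f, `[`, "", 5)
  type <- c("<DEL>" = "loss", "<DUP>" = "gain", "<CNV>" = "mixed")[alt]
  states <- t(vapply(f, function(x) as.integer(x[-(1:9)]),
                     integer(length(samples))))
  rownames(states) <- id
  states <- t(states)
  rownames(states) <- samples
  colnames(states) <- id
  cnvrs <- data.frame(id = id, chrom = chrom, start = start, end = end,
                      type = unname(type),
                      carrier_count = colSums(states != 2L),
                      stringsAsFactors = FALSE)
  res <- list(states = states, cnvrs = cnvrs, breed_labels = NULL)
  class(res) <- "cnvr_genotypes"
  res
}

#' Write gene models as GFF3 (1-based inclusive)
#'
#' @param genes A `gene_model`.
#' @param path Output file.
#' @export
write_gff3 <- function(genes, path) {
  lines <- "##gff-version 3"
  g <- genes$genes
  ord <- order(g$chrom, g$start)
  for (i in ord) {
    gid <- g$gene_id[i]
    lines <- c(lines, sprintf(
      "%s\tcnvpop\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
      g$chrom[i], as.integer(g$start[i]) + 1L, as.integer(g$end[i]),
      g$strand[i], gid))
    ex <- genes$exons[genes$exons$gene_id == gid, , drop = FALSE]
    cd <- genes$cds[genes$cds$gene_id == gid, , drop = FALSE]
    if (nrow(ex)) lines <- c(lines, sprintf(
      "%s\tcnvpop\texon\t%d\t%d\t.\t%s\t.\tID=%s.exon%d;Parent=%s",
      ex$chrom, as.integer(ex$start) + 1L, as.integer(ex$end),
      g$strand[i], gid, seq_len(nrow(ex)), gid))
    if (nrow(cd)) lines <- c(lines, sprintf(
      "%s\tcnvpop\tCDS\t%d\t%d\t.\t%s\t0\tID=%s.cds%d;Parent=%s",
      cd$chrom, as.integer(cd$start) + 1L, as.integer(cd$end),
      g$strand[i], gid, seq_len(nrow(cd)), gid))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Uses rtracklayer's GFF3 importer; gene/exon/CDS records are collected
#' into the internal 0-based half-open representation. Exons and CDS are
#' attached to genes through their Parent (or ID prefix) attribute.
#'
#' @param path GFF3 file.
#' @return A `gene_model`.
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1,
                   end = GenomicRanges::end(gr),
                   strand = as.character(GenomicRanges::strand(gr)),
                   type = as.character(gr$type),
                   id = if (!is.null(gr$ID)) as.character(gr$ID) else
                     NA_character_,
                   stringsAsFactors = FALSE)
  parent <- if (!is.null(gr$Parent)) {
    vapply(gr$Parent, function(p) if (length(p)) as.character(p[1]) else
      NA_character_, character(1))
  } else rep(NA_character_, nrow(df))
  df$gene_id <- ifelse(df$type == "gene", df$id, parent)
  gm <- list(
    genes = df[df$type == "gene",
               c("gene_id", "chrom", "start", "end", "strand")],
    exons = df[df$type == "exon", c("gene_id", "chrom", "start", "end")],
    cds = df[df$type == "CDS", c("gene_id", "chrom", "start", "end")])
  rownames(gm$genes) <- rownames(gm$exons) <- rownames(gm$cds) <- NULL
  class(gm) <- "gene_model"
  gm
}

#' Write / read gene sets in GMT format
#'
#' Tab-separated: term, description (namespace), genes...
#' @param sets Named list term -> genes, optional `namespace` attribute.
#' @param path Output file.
#' @export
write_gmt <- function(sets, path) {
  ns <- attr(sets, "namespace")
  if (is.null(ns)) ns <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], ns[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  f <- strsplit(readLines(path), "\t")
  sets <- lapply(f, function(x) x[-(1:2)])
  names(sets) <- vapply(f, `[`, "", 1)
  attr(sets, "namespace") <- vapply(f, `[`, "", 2)
  sets
}

#' Write / read breed labels as two-column TSV (sample, breed)
#' @param labels Named character vector sample -> breed.
#' @param path Output file.
#' @export
write_labels <- function(labels, path) {
  utils::write.table(data.frame(sample = names(labels),
                                breed = unname(labels)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  stats::setNames(d[[2]], d[[1]])
}

#' Write a phylogenetic tree in Newick format (6-decimal branch lengths)
#' @param tree A `phylo` object.
#' @param path Output file.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 6)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) ape::read.tree(path)
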