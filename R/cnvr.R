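calls_granges <- function(calls) {
  GenomicRanges::GRanges(calls$chrom,
                         IRanges::IRanges(calls$start + 1L, calls$end))
}

cnvr_type <- function(states) {
  has_del <- any(states %in% c(0L, 1L))
  has_dup <- any(states %in% c(3L, 4L))
  if (has_del && has_dup) "mixed" else if (has_del) "loss" else "gain"
}

#' Merge per-sample CNV calls into CNV regions (CNVRs)
#'
#' Within each breed, calls overlapping by at least 1 bp are chained
#' transitively; each chain defines a CNVR spanning the union of its calls.
#' The carrier count is the number of distinct individuals contributing at
#' least one call; regions with fewer than `min_carriers` carriers are
#' dropped. Type is `loss` if all member states are deletions (0/1), `gain`
#' if all are duplications (3/4), `mixed` otherwise.
#'
#' @param calls Filtered call data.frame (columns sample, chrom, start, end,
#'   copy_state).
#' @param breed_labels Named character vector sample -> breed. If NULL all
#'   samples form one breed ("all").
#' @param min_carriers Minimum distinct carriers (default 4). Use
#'   `carrier_frequency` instead to express it as a fraction of the breed's
#'   cohort size.
#' @param carrier_frequency Optional fraction f; overrides `min_carriers`
#'   with ceiling(f * n_breed) per breed.
#' @return CNVR data.frame: id, chrom, start, end (0-based half-open), type,
#'   carrier_count, plus list-columns `carriers` (sample ids) and `breeds`.
#' @export
merge_cnvrs <- function(calls, breed_labels = NULL, min_carriers = 4L,
                        carrier_frequency = NULL) {
  if (nrow(calls) == 0) return(empty_cnvrs())
  if (is.null(breed_labels)) {
    breed_labels <- stats::setNames(rep("all", length(unique(calls$sample))),
                                    unique(calls$sample))
  }
  calls$breed <- unname(breed_labels[calls$sample])
  out <- list()
  for (br in unique(calls$breed)) {
    cc <- calls[calls$breed == br, , drop = FALSE]
    gr <- calls_granges(cc)
    red <- GenomicRanges::reduce(gr, min.gapwidth = 0L)
    hit <- GenomicRanges::findOverlaps(gr, red)
    grp <- S4Vectors::subjectHits(hit)[order(S4Vectors::queryHits(hit))]
    k_br <- if (!is.null(carrier_frequency))
      ceiling(carrier_frequency * sum(breed_labels == br)) else min_carriers
    for (g in seq_along(red)) {
      members <- cc[grp == g, , drop = FALSE]
      carriers <- unique(members$sample)
      if (length(carriers) < k_br) next
      out[[length(out) + 1L]] <- data.frame(
        chrom = as.character(GenomicRanges::seqnames(red)[g]),
        start = GenomicRanges::start(red)[g] - 1L,
        end = GenomicRanges::end(red)[g],
        type = cnvr_type(members$copy_state),
        carrier_count = length(carriers), breed = br,
        stringsAsFactors = FALSE)
      out[[length(out)]]$carriers <- list(sort(carriers))
    }
  }
  if (length(out) == 0) return(empty_cnvrs())
  res <- do.call(rbind, out)
  res$breeds <- lapply(res$breed, identity)
  res$breed <- NULL
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  res$id <- sprintf("cnvr_%05d", seq_len(nrow(res)))
  rownames(res) <- NULL
  res[c("id", "chrom", "start", "end", "type", "carrier_count",
        "carriers", "breeds")]
}

empty_cnvrs <- function() {
  data.frame(id = character(), chrom = character(), start = numeric(),
             end = numeric(), type = character(), carrier_count = integer(),
             stringsAsFactors = FALSE)
}

#' Merge per-breed CNVR lists into one cross-breed locus set
#'
#' Pools the per-breed CNVRs and chains >= 1 bp overlaps across breeds; each
#' chain becomes one CNVR spanning the union, with carriers aggregated and
#' the per-breed provenance kept. Ids are assigned deterministically by
#' (chrom, start).
#'
#' @param ... CNVR data.frames (or one list of them) from [merge_cnvrs()].
#' @return A merged CNVR data.frame of the same shape.
#' @export
merge_across_breeds <- function(...) {
  lists <- list(...)
  if (length(lists) == 1 && is.data.frame(lists[[1]])) lists <- lists[1]
  if (length(lists) == 1 && !is.data.frame(lists[[1]])) lists <- lists[[1]]
  all <- do.call(rbind, lapply(lists, function(d)
    d[c("id", "chrom", "start", "end", "type", "carrier_count",
        "carriers", "breeds")]))
  if (is.null(all) || nrow(all) == 0) return(empty_cnvrs())
  gr <- GenomicRanges::GRanges(all$chrom,
                               IRanges::IRanges(all$start + 1L, all$end))
  red <- GenomicRanges::reduce(gr, min.gapwidth = 0L)
  hit <- GenomicRanges::findOverlaps(gr, red)
  grp <- S4Vectors::subjectHits(hit)[order(S4Vectors::queryHits(hit))]
  rows <- lapply(seq_along(red), function(g) {
    members <- all[grp == g, , drop = FALSE]
    carriers <- sort(unique(unlist(members$carriers)))
    types <- unique(members$type)
    type <- if (length(types) == 1) types else "mixed"
    r <- data.frame(chrom = as.character(GenomicRanges::seqnames(red)[g]),
                    start = GenomicRanges::start(red)[g] - 1L,
                    end = GenomicRanges::end(red)[g], type = type,
                    carrier_count = length(carriers),
                    stringsAsFactors = FALSE)
    r$carriers <- list(carriers)
    r$breeds <- list(sort(unique(unlist(members$breeds))))
    r
  })
  res <- do.call(rbind, rows)
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  res$id <- sprintf("cnvr_%05d", seq_len(nrow(res)))
  rownames(res) <- NULL
  res[c("id", "chrom", "start", "end", "type", "carrier_count",
        "carriers", "breeds")]
}

#' Genotype all individuals at the CNVR loci
#'
#' An individual's state at a CNVR is the copy state of its largest-overlap
#' call there (ties broken by the earlier call start); individuals without
#' any overlapping call are diploid (state 2) by convention. A call
#' overlapping several CNVRs is credited only to the CNVR it overlaps most.
#'
#' @param cnvrs CNVR data.frame.
#' @param calls Filtered calls for every individual.
#' @param samples Character vector of all individual ids (so call-free
#'   individuals still get a genotype row).
#' @param breed_labels Optional named vector sample -> breed.
#' @return A `cnvr_genotypes` list: `states` (individuals x CNVR integer
#'   matrix), `cnvrs` (the metadata), `breed_labels`.
#' @export
genotype_cnvrs <- function(cnvrs, calls, samples = NULL,
                           breed_labels = NULL) {
  if (is.null(samples)) samples <- sort(unique(calls$sample))
  states <- matrix(2L, nrow = length(samples), ncol = nrow(cnvrs),
                   dimnames = list(samples, cnvrs$id))
  if (nrow(cnvrs) > 0 && nrow(calls) > 0) {
    gr_calls <- calls_granges(calls)
    gr_cnvr <- GenomicRanges::GRanges(cnvrs$chrom,
                                      IRanges::IRanges(cnvrs$start + 1L,
                                                       cnvrs$end))
    hit <- GenomicRanges::findOverlaps(gr_calls, gr_cnvr)
    if (length(hit)) {
      qh <- S4Vectors::queryHits(hit)
      sh <- S4Vectors::subjectHits(hit)
      ov <- IRanges::width(IRanges::pintersect(gr_calls[qh], gr_cnvr[sh]))
      # each call goes to its largest-overlap CNVR
      keep <- unlist(lapply(split(seq_along(qh), qh), function(ix) {
        ix[which.max(ov[ix])]
      }))
      qh <- qh[keep]; sh <- sh[keep]; ov <- ov[keep]
      # per (sample, cnvr): largest overlap wins, ties to earlier call start
      key <- paste(calls$sample[qh], sh)
      for (grp_ix in split(seq_along(key), key)) {
        o <- ov[grp_ix]
        st <- calls$start[qh[grp_ix]]
        best <- grp_ix[order(-o, st)][1]
        states[calls$sample[qh[best]], sh[best]] <-
          as.integer(calls$copy_state[qh[best]])
      }
    }
  }
  res <- list(states = states, cnvrs = cnvrs, breed_labels = breed_labels)
  class(res) <- "cnvr_genotypes"
  res
}

#' Summary statistics of CNV calls and CNVRs
#'
#' Computes the per-type call counts and mean lengths for copy states
#' {0,1,3,4}, the call-length histogram over configurable bins, the
#' deletion/duplication sequence proportions (deleted bp over deleted plus
#' duplicated bp), the CNVR type and chromosome tallies, and the fraction of
#' the genome covered by the CNVR union.
#'
#' @param calls Filtered call data.frame.
#' @param cnvrs CNVR data.frame.
#' @param layout Genome layout (placed chromosomes define the genome size).
#' @param length_breaks Breakpoints (bp) of the call-length bins; defaults to
#'   20 kb and 500 kb, giving bins <=20 kb, 20-500 kb, >500 kb.
#' @return A `cnvr_summary` list.
#' @export
summarize_cnvrs <- function(calls, cnvrs, layout,
                            length_breaks = c(2e4, 5e5)) {
  len <- calls$end - calls$start
  by_state <- lapply(split(len, calls$copy_state), function(v)
    c(n = length(v), mean_bp = mean(v)))
  brk <- c(0, length_breaks, Inf)
  lab <- paste0(c("<=", rep("", length(length_breaks))),
                c(format(length_breaks, scientific = FALSE, trim = TRUE),
                  paste0(">", format(length_breaks[length(length_breaks)],
                                     scientific = FALSE, trim = TRUE))))
  length_bins <- table(cut(len, breaks = brk, labels = lab))
  del_bp <- sum(len[calls$copy_state %in% c(0L, 1L)])
  dup_bp <- sum(len[calls$copy_state %in% c(3L, 4L)])
  del_prop <- if (del_bp + dup_bp > 0) del_bp / (del_bp + dup_bp) else NA_real_
  genome_bp <- sum(layout$length[layout$placed])
  cov_bp <- if (nrow(cnvrs) > 0) {
    gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
      cnvrs$chrom, IRanges::IRanges(cnvrs$start + 1L, cnvrs$end)))
    sum(GenomicRanges::width(gr))
  } else 0
  res <- list(
    n_calls = nrow(calls), n_cnvrs = nrow(cnvrs),
    calls_by_state = by_state,
    length_bins = length_bins,
    mean_call_length_bp = if (length(len)) mean(len) else NA_real_,
    deletion_seq_proportion = del_prop,
    duplication_seq_proportion = if (is.na(del_prop)) NA_real_ else 1 - del_prop,
    cnvr_by_type = table(cnvrs$type),
    cnvr_by_chrom = table(cnvrs$chrom),
    genome_coverage = cov_bp / genome_bp)
  class(res) <- "cnvr_summary"
  res
}

#' @export
print.cnvr_summary <- function(x, ...) {
  cat(sprintf("CNV summary: %d calls, %d CNVRs\n", x$n_calls, x$n_cnvrs))
  cat(sprintf("  mean call length: %.2f kb\n", x$mean_call_length_bp / 1e3))
  cat(sprintf("  deleted sequence: %.2f%%, duplicated: %.2f%%\n",
              100 * x$deletion_seq_proportion,
              100 * x$duplication_seq_proportion))
  cat(sprintf("  genome covered by CNVRs: %.2f%%\n",
              100 * x$genome_coverage))
  invisible(x)
}
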