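#' GC-bias correction of a binned depth track
#'
#' Bins are stratified by GC fraction into 1%-wide strata; counts in each
#' stratum are rescaled by the ratio of the global to the stratum typical
#' depth. Typical depth is a 20%-trimmed mean: robust to the minority of
#' bins sitting inside real CNVs, yet smooth where an integer-count median
#' would jump by whole units. Strata holding fewer than `min_bins` bins
#' borrow the correction factor of the nearest populated stratum; strata
#' with zero typical depth are left uncorrected.
#'
#' @param track A `depth_track` data.frame (columns chrom, start, end, count,
#'   gc, q0).
#' @param min_bins Minimum bins for a stratum to stand on its own.
#' @return The track with `count` replaced by real-valued corrected counts.
#' @export
gc_correct <- function(track, min_bins = 100L) {
  if (nrow(track) == 0 || all(track$count == 0))
    stop("no coverage: all bin counts are zero", call. = FALSE)
  stratum <- pmin(pmax(floor(track$gc * 100), 0), 99)
  typical <- function(v) mean(v, trim = 0.1)
  global_med <- typical(track$count)
  tab <- tapply(track$count, stratum, typical)
  sizes <- table(stratum)
  levels_present <- as.integer(names(tab))
  populated <- levels_present[sizes >= min_bins]
  factor_of <- rep(1, 100)
  for (s in levels_present) {
    src <- if (s %in% populated || length(populated) == 0) s else
      populated[which.min(abs(populated - s))]
    med <- tab[as.character(src)]
    if (!is.na(med) && med > 0) factor_of[s + 1] <- global_med / med
  }
  track$count <- track$count * factor_of[stratum + 1]
  track
}

#' Normalize a corrected depth track to diploid expectation 1
#'
#' Divides every bin by the genome-wide (autosomal) mean corrected count, so
#' a diploid bin has expectation 1 and copy state c has expectation c/2.
#'
#' @param track A GC-corrected `depth_track`.
#' @return Numeric vector `x` of normalized depth, one value per bin, with
#'   the track's chrom column as an attribute-free companion (use
#'   `split(x, track$chrom)` for per-chromosome work).
#' @export
normalize_depth <- function(track) {
  m <- mean(track$count)
  if (m == 0) stop("autosomal mean coverage is zero", call. = FALSE)
  track$count / m
}

# Exact penalized least-squares changepoint detection (PELT pruning; the
# pruning provably never discards an optimal last-changepoint candidate for
# this penalty, so the result equals the full O(B^2) dynamic programme).
pelt_partition <- function(x, beta) {
  B <- length(x)
  if (B == 1L) return(c(0L, 1L))
  cs <- c(0, cumsum(x))
  cs2 <- c(0, cumsum(x^2))
  segcost <- function(i, j) {
    # cost of segment (i, j], i may be a vector; prefix sums are 1-shifted
    n <- j - i
    s <- cs[j + 1L] - cs[i + 1L]
    s2 <- cs2[j + 1L] - cs2[i + 1L]
    s2 - s^2 / n
  }
  FF <- rep(NA_real_, B + 1L)
  FF[1] <- -beta
  cp <- integer(B + 1L)
  cand <- 0L
  for (t in seq_len(B)) {
    costs <- FF[cand + 1L] + segcost(cand, t) + beta
    best <- which.min(costs)
    FF[t + 1L] <- costs[best]
    cp[t + 1L] <- cand[best]
    keep <- FF[cand + 1L] + segcost(cand, t) <= FF[t + 1L]
    cand <- c(cand[keep], t)
  }
  # backtrack changepoints
  bounds <- integer(0)
  t <- B
  while (t > 0L) {
    bounds <- c(t, bounds)
    t <- cp[t + 1L]
  }
  c(0L, bounds)
}

#' Segment a normalized depth signal into constant-mean pieces
#'
#' Finds the exact minimizer of
#' sum_seg sum_b (x_b - mean_seg)^2 + beta * n_segments with
#' beta = lambda * sigma2 * log(B), where sigma2 is a median-absolute
#' -deviation estimate of the per-bin noise variance. Solved by pruned exact
#' linear-time dynamic programming, which returns the same partition as the
#' full quadratic-time programme.
#'
#' @param x Normalized depth values for one chromosome.
#' @param lambda Penalty multiplier (default 2).
#' @param beta Optional explicit penalty overriding the lambda rule.
#' @return data.frame with columns `bin_start`, `bin_end` (0-based half-open
#'   bin indices) and `d` (segment mean).
#' @export
segment_depth <- function(x, lambda = 2, beta = NULL) {
  stopifnot(length(x) >= 1)
  if (is.null(beta)) {
    sigma2 <- stats::mad(x)^2
    if (sigma2 == 0) sigma2 <- stats::mad(diff(x))^2 / 2
    beta <- lambda * sigma2 * log(length(x))
  }
  beta <- max(beta, 1e-12)   # ties resolve toward fewer segments
  bounds <- pelt_partition(x, beta)
  k <- length(bounds) - 1L
  data.frame(bin_start = bounds[-(k + 1L)], bin_end = bounds[-1L],
             d = vapply(seq_len(k), function(i) {
               mean(x[(bounds[i] + 1L):bounds[i + 1L]])
             }, numeric(1)))
}

round_half_away <- function(v) sign(v) * floor(abs(v) + 0.5)

# two-sided one-sample t-test of bins against mean 1; conservative p = 1 for
# single-bin segments, p = 0 for zero-variance segments off the null mean
segment_pvalue <- function(vals) {
  n <- length(vals)
  if (n < 2L) return(1)
  s <- stats::sd(vals)
  if (s == 0) return(if (abs(mean(vals) - 1) < .Machine$double.eps^0.5) 1 else 0)
  tstat <- (mean(vals) - 1) / (s / sqrt(n))
  2 * stats::pt(-abs(tstat), df = n - 1)
}

# Refine one boundary by Poisson likelihood. Bins in [a, c) are assigned
# "outside" left of the cut and "inside" right of it (or mirrored); the cut
# maximizing the Poisson log-likelihood kernel k*log(lam) - lam is returned.
# The factorial term cancels because each bin's count is fixed either way.
refine_edge <- function(counts, a, c_, lam_out, lam_in, left = TRUE) {
  if (c_ <= a) return(if (left) a else c_)
  idx <- (a + 1L):c_            # bins a..c_-1 in 0-based terms
  k <- counts[idx]
  ll_out <- k * log(lam_out) - lam_out
  ll_in <- k * log(max(lam_in, 1e-9)) - lam_in
  if (left) {
    # cut s in a..c_: bins < s outside, >= s inside
    score <- c(0, cumsum(ll_out)) + rev(c(0, cumsum(rev(ll_in))))
    a + which.max(score) - 1L
  } else {
    # cut s in a..c_: bins < s inside, >= s outside
    score <- c(0, cumsum(ll_in)) + rev(c(0, cumsum(rev(ll_out))))
    a + which.max(score) - 1L
  }
}

# Refine all call boundaries of one chromosome against the corrected raw
# counts; the search window never crosses a neighbouring call.
refine_call_bins <- function(calls_bins, counts, mean_count, window = 10L) {
  n <- nrow(calls_bins)
  B <- length(counts)
  for (i in seq_len(n)) {
    lam_in <- mean_count * max(calls_bins$copy[i] / 2, 0.02)
    lo <- if (i == 1) 0L else calls_bins$bin_end[i - 1L]
    hi <- if (i == n) B else calls_bins$bin_start[i + 1L]
    mid <- calls_bins$bin_start[i] +
      (calls_bins$bin_end[i] - calls_bins$bin_start[i]) %/% 2L
    a <- max(lo, calls_bins$bin_start[i] - window)
    c_ <- min(mid, calls_bins$bin_start[i] + window)
    calls_bins$bin_start[i] <- refine_edge(counts, a, c_, mean_count,
                                           lam_in, left = TRUE)
    a <- max(mid, calls_bins$bin_end[i] - window)
    c_ <- min(hi, calls_bins$bin_end[i] + window)
    calls_bins$bin_end[i] <- refine_edge(counts, a, c_, mean_count,
                                         lam_in, left = FALSE)
  }
  calls_bins
}

#' Call copy states from segments
#'
#' A segment with mean normalized depth d is assigned copy state
#' min(round(2 d), 4) with half rounded away from zero; diploid (state 2)
#' segments are dropped, adjacent same-state segments are merged, and per
#' call a two-sided one-sample t-test of the member bins against 1.0 and a
#' count-weighted mean q0 are attached. Coordinates are converted from bins
#' to bp (0-based half-open), clipped to the chromosome end.
#'
#' @param segments Per-chromosome segment data.frame from [segment_depth()].
#' @param x The normalized signal the segments partition.
#' @param track The (uncorrected or corrected) `depth_track` rows for the
#'   same chromosome, used for q0 weighting and coordinates.
#' @param chrom Chromosome name.
#' @param chrom_length Chromosome length in bp.
#' @param bin_width Bin width in bp.
#' @param sample_id Sample identifier carried into the calls.
#' @return data.frame of calls: sample, chrom, start, end, copy_state, d,
#'   p_value, q0_frac, plus the bin-unit bounds (bin_start, bin_end) used
#'   by the breakpoint refinement step.
#' @export
call_states <- function(segments, x, track, chrom, chrom_length, bin_width,
                        sample_id = "sample") {
  copy <- pmin(round_half_away(2 * segments$d), 4)
  copy <- pmax(copy, 0)
  keep <- which(copy != 2)
  if (length(keep) == 0) return(empty_calls())
  seg <- segments[keep, , drop = FALSE]
  seg$copy <- copy[keep]
  # merge adjacent same-state segments (contiguous in bins)
  merged <- list()
  cur <- seg[1, ]
  if (nrow(seg) > 1) for (i in 2:nrow(seg)) {
    if (seg$bin_start[i] == cur$bin_end && seg$copy[i] == cur$copy) {
      cur$bin_end <- seg$bin_end[i]
    } else {
      merged[[length(merged) + 1L]] <- cur
      cur <- seg[i, ]
    }
  }
  merged[[length(merged) + 1L]] <- cur
  bins <- do.call(rbind, merged)[c("bin_start", "bin_end", "copy")]
  call_stats(bins, x, track, chrom, chrom_length, bin_width, sample_id)
}

call_stats <- function(bins, x, track, chrom, chrom_length, bin_width,
                       sample_id) {
  rows <- lapply(seq_len(nrow(bins)), function(i) {
    idx <- (bins$bin_start[i] + 1L):bins$bin_end[i]
    vals <- x[idx]
    wts <- track$count[idx]
    q0 <- if (sum(wts) > 0) sum(track$q0[idx] * wts) / sum(wts) else
      mean(track$q0[idx])
    data.frame(sample = sample_id, chrom = chrom,
               start = bins$bin_start[i] * bin_width,
               end = min(bins$bin_end[i] * bin_width, chrom_length),
               copy_state = as.integer(bins$copy[i]), d = mean(vals),
               p_value = segment_pvalue(vals), q0_frac = q0,
               bin_start = bins$bin_start[i], bin_end = bins$bin_end[i],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

empty_calls <- function() {
  data.frame(sample = character(), chrom = character(), start = numeric(),
             end = numeric(), copy_state = integer(), d = numeric(),
             p_value = numeric(), q0_frac = numeric(),
             bin_start = integer(), bin_end = integer(),
             stringsAsFactors = FALSE)
}

#' Filter CNV calls on significance, length, q0 and placement
#'
#' Keeps a call iff p_value < `max_p` AND length > `min_len` bp AND
#' q0_frac < `max_q0` AND its chromosome is a placed one. All four
#' inequalities are strict, so boundary values (length exactly `min_len`,
#' q0 exactly `max_q0`) are removed; input order is preserved.
#'
#' @param calls Call data.frame as from [call_states()].
#' @param layout Genome layout data.frame (chrom, length, placed).
#' @param max_p,min_len,max_q0 Filter thresholds (defaults 0.001, 1000 bp,
#'   0.5).
#' @return The filtered call data.frame.
#' @export
filter_calls <- function(calls, layout, max_p = 0.001, min_len = 1000,
                         max_q0 = 0.5) {
  if (nrow(calls) == 0) return(calls)
  placed <- layout$chrom[layout$placed]
  keep <- calls$p_value < max_p &
    (calls$end - calls$start) > min_len &
    calls$q0_frac < max_q0 &
    calls$chrom %in% placed
  calls[keep, , drop = FALSE]
}

#' Call CNVs for one sample end-to-end
#'
#' GC-corrects, normalizes, segments each chromosome, calls copy states and
#' (optionally) applies the standard filters.
#'
#' @param track A `depth_track`.
#' @param layout Genome layout data.frame.
#' @param lambda Segmentation penalty multiplier.
#' @param filter Apply [filter_calls()] before returning.
#' @param ... Passed to [filter_calls()].
#' @return Call data.frame.
#' @export
call_sample <- function(track, layout, lambda = 2, filter = TRUE, ...) {
  w <- attr(track, "bin_width")
  sample_id <- attr(track, "sample")
  if (is.null(sample_id)) sample_id <- "sample"
  corr <- gc_correct(track)
  x_all <- normalize_depth(corr)
  mean_count <- mean(corr$count)
  calls <- list()
  for (chrom in unique(track$chrom)) {
    idx <- which(track$chrom == chrom)
    x <- x_all[idx]
    segs <- segment_depth(x, lambda = lambda)
    cl <- layout$length[match(chrom, layout$chrom)]
    if (is.na(cl)) cl <- max(track$end[idx])
    cc <- call_states(segs, x, corr[idx, , drop = FALSE],
                      chrom, cl, w, sample_id)
    if (nrow(cc) > 0) {
      # refine boundaries against the Poisson likelihood of raw counts
      bins <- data.frame(bin_start = cc$bin_start, bin_end = cc$bin_end,
                         copy = cc$copy_state)
      bins <- refine_call_bins(bins, corr$count[idx], mean_count)
      keep <- bins$bin_end > bins$bin_start
      cc <- call_stats(bins[keep, , drop = FALSE], x,
                       corr[idx, , drop = FALSE], chrom, cl, w, sample_id)
    }
    calls[[chrom]] <- cc
  }
  calls <- do.call(rbind, c(calls, list(empty_calls())))
  rownames(calls) <- NULL
  if (filter) calls <- filter_calls(calls, layout, ...)
  calls$bin_start <- calls$bin_end <- NULL
  rownames(calls) <- NULL
  calls
}
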