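mk_call <- function(sample, chrom, start, end, state) {
  data.frame(sample = sample, chrom = chrom, start = start, end = end,
             copy_state = as.integer(state), d = state / 2, p_value = 1e-6,
             q0_frac = 0.05, stringsAsFactors = FALSE)
}

test_that("overlapping calls chain into a union-span CNVR", {
  calls <- rbind(mk_call("A", "chr1", 100, 300, 1),
                 mk_call("B", "chr1", 250, 400, 1))
  r <- merge_cnvrs(calls, min_carriers = 2)
  expect_equal(nrow(r), 1L)
  expect_equal(r$start, 100)
  expect_equal(r$end, 400)
  expect_equal(r$type, "loss")
  expect_equal(r$carrier_count, 2L)
  # the same calls fail a carrier minimum of four
  expect_equal(nrow(merge_cnvrs(calls, min_carriers = 4)), 0L)
})

test_that("a single-bp overlap merges and mixes deletion with duplication", {
  calls <- rbind(
    do.call(rbind, lapply(c("A", "B", "C", "D"), mk_call,
                          chrom = "chr1", start = 100, end = 300, state = 1)),
    do.call(rbind, lapply(c("A", "B", "C", "D"), mk_call,
                          chrom = "chr1", start = 299, end = 500, state = 3)))
  r <- merge_cnvrs(calls, min_carriers = 4)
  expect_equal(nrow(r), 1L)
  expect_equal(c(r$start, r$end), c(100, 500))
  expect_equal(r$type, "mixed")
  # bookended calls (end == start) must NOT merge
  calls2 <- rbind(
    do.call(rbind, lapply(c("A", "B"), mk_call,
                          chrom = "chr1", start = 100, end = 300, state = 1)),
    do.call(rbind, lapply(c("A", "B"), mk_call,
                          chrom = "chr1", start = 300, end = 500, state = 3)))
  r2 <- merge_cnvrs(calls2, min_carriers = 2)
  expect_equal(nrow(r2), 2L)
  expect_setequal(r2$type, c("loss", "gain"))
})

test_that("merging matches the brute-force overlap-closure oracle", {
  set.seed(7)
  for (trial in 1:60) {
    n <- sample(2:20, 1)
    start <- sample(0:400, n, replace = TRUE)
    end <- start + sample(5:120, n, replace = TRUE)
    calls <- do.call(rbind, lapply(seq_len(n), function(i)
      mk_call(paste0("s", i), "chr1", start[i], end[i], 1)))
    r <- merge_cnvrs(calls, min_carriers = 1)
    oracle <- brute_overlap_closure(start, end)
    expect_equal(r$start, oracle$start)
    expect_equal(r$end, oracle$end)
  }
})

test_that("merging is idempotent and produces non-overlapping regions", {
  co <- small_cohort(seed = 31)
  calls <- do.call(rbind, lapply(co$tracks, call_sample,
                                 layout = sim_layout(co$cfg)))
  labels <- co$truth$breed_labels
  r <- merge_cnvrs(calls, labels, min_carriers = 2)
  # within one breed the merged regions are disjoint
  for (br in unique(unlist(r$breeds))) {
    d <- r[vapply(r$breeds, function(b) br %in% b, logical(1)), ]
    for (ch in unique(d$chrom)) {
      dc <- d[d$chrom == ch, ]
      dc <- dc[order(dc$start), ]
      if (nrow(dc) > 1) expect_true(all(dc$start[-1] >= dc$end[-nrow(dc)]))
    }
  }
  expect_true(all(r$carrier_count <= max(table(labels))))
  m1 <- merge_across_breeds(r)
  # after the cross-breed union the full locus set is disjoint
  for (ch in unique(m1$chrom)) {
    dc <- m1[m1$chrom == ch, ]
    dc <- dc[order(dc$start), ]
    if (nrow(dc) > 1) expect_true(all(dc$start[-1] >= dc$end[-nrow(dc)]))
  }
  m2 <- merge_across_breeds(m1)
  expect_equal(m1[c("chrom", "start", "end", "carrier_count")],
               m2[c("chrom", "start", "end", "carrier_count")])
})

test_that("cross-breed merge unions carriers and keeps disjoint sets apart", {
  a <- merge_cnvrs(rbind(mk_call("a1", "chr1", 100, 300, 1),
                         mk_call("a2", "chr1", 150, 280, 1)),
                   min_carriers = 2)
  b_same <- merge_cnvrs(rbind(mk_call("b1", "chr1", 100, 300, 1),
                              mk_call("b2", "chr1", 120, 260, 1)),
                        min_carriers = 2)
  b_far <- merge_cnvrs(rbind(mk_call("b1", "chr2", 700, 900, 3),
                             mk_call("b2", "chr2", 750, 950, 3)),
                       min_carriers = 2)
  m <- merge_across_breeds(a, b_same)
  expect_equal(nrow(m), 1L)
  expect_equal(m$carrier_count, 4L)
  m2 <- merge_across_breeds(a, b_far)
  expect_equal(nrow(m2), 2L)
  expect_identical(m2$chrom, c("chr1", "chr2"))
})

test_that("CNVR genotyping takes the largest-overlap call and defaults to 2", {
  cnvrs <- merge_cnvrs(rbind(mk_call("A", "chr1", 1000, 3000, 1),
                             mk_call("B", "chr1", 1500, 3500, 1)),
                       min_carriers = 2)
  # C has two calls over the CNVR: state 1 overlap 500, state 0 overlap 800
  calls <- rbind(mk_call("A", "chr1", 1000, 3000, 1),
                 mk_call("B", "chr1", 1500, 3500, 1),
                 mk_call("C", "chr1", 1000, 1500, 1),
                 mk_call("C", "chr1", 2000, 2800, 0))
  g <- genotype_cnvrs(cnvrs, calls, samples = c("A", "B", "C", "D"))
  expect_identical(unname(g$states[, 1]), c(1L, 1L, 0L, 2L))
  expect_true(all(g$states["D", ] == 2L))
})

test_that("summary statistics follow the printed arithmetic conventions", {
  layout <- data.frame(chrom = "chr1", length = 1e7, placed = TRUE)
  calls <- rbind(mk_call("A", "chr1", 0, 16016, 0),
                 mk_call("B", "chr1", 20000, 28000, 1),
                 mk_call("C", "chr1", 40000, 42000, 3))
  cnvrs <- data.frame(id = "cnvr_00001", chrom = "chr1", start = 0,
                      end = 3.635e6, type = "loss", carrier_count = 4L,
                      stringsAsFactors = FALSE)
  s <- summarize_cnvrs(calls, cnvrs, layout)
  expect_equal(s$calls_by_state[["0"]][["mean_bp"]], 16016)
  expect_equal(s$deletion_seq_proportion, (16016 + 8000) / (16016 + 10000))
  expect_equal(s$genome_coverage, 0.3635)
  expect_equal(s$deletion_seq_proportion + s$duplication_seq_proportion, 1)
  # deletion proportion example: one 8 kb DEL and one 2 kb DUP -> 0.8
  s2 <- summarize_cnvrs(rbind(mk_call("A", "chr1", 0, 8000, 1),
                              mk_call("B", "chr1", 10000, 12000, 3)),
                        cnvrs, layout)
  expect_equal(s2$deletion_seq_proportion, 0.8)
})

test_that("every filtered call overlaps a CNVR when the carrier filter allows", {
  co <- small_cohort(seed = 32)
  calls <- do.call(rbind, lapply(co$tracks, call_sample,
                                 layout = sim_layout(co$cfg)))
  r <- merge_cnvrs(calls, co$truth$breed_labels, min_carriers = 1)
  m <- merge_across_breeds(r)
  ov <- vapply(seq_len(nrow(calls)), function(i) {
    any(m$chrom == calls$chrom[i] & m$start < calls$end[i] &
          m$end > calls$start[i])
  }, logical(1))
  expect_true(all(ov))
})
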