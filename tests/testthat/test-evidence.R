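test_that("SL detection matches leader suffixes against read prefixes", {
  # exact 5-nt suffix match
  r <- c(r1 = paste0("TTTAA", strrep("ACGT", 7)))
  out <- detect_and_trim_sl(r, "GGTTTAA", min_match = 5L, max_mismatch = 0L)
  expect_equal(out$evidence_kind, "SL")
  expect_equal(out$trimmed_prefix_len, 5L)
  expect_equal(out$sequence, strrep("ACGT", 7))

  # no leader-derived prefix
  out <- detect_and_trim_sl(c(r1 = strrep("CCCC", 10)), "GGTTTAA",
                            min_match = 5L)
  expect_equal(out$evidence_kind, "NONE")
  expect_equal(out$trimmed_prefix_len, 0L)

  # suffix match shorter than min_match does not qualify
  r <- c(r1 = paste0("TTAA", strrep("ACGT", 8)))
  out <- detect_and_trim_sl(r, "GGTTTAA", min_match = 5L, max_mismatch = 0L)
  expect_equal(out$evidence_kind, "NONE")
})

test_that("SL detection tolerates mismatches and enforces remaining length", {
  leader <- "CGTTACCGATTGGTCAAGTC"
  body <- strrep("GA", 30)
  read <- c(r = paste0(sub("C$", "T", leader), body))  # 1 mismatch in prefix
  out <- detect_and_trim_sl(read, leader, min_match = 10L, max_mismatch = 1L)
  expect_equal(out$evidence_kind, "SL")
  expect_equal(out$trimmed_prefix_len, nchar(leader))

  short <- c(r = paste0(leader, "ACGTACGTAC"))  # only 10 nt remain
  out <- detect_and_trim_sl(short, leader, min_match = 10L, max_mismatch = 0L)
  expect_equal(out$evidence_kind, "NONE")

  expect_error(detect_and_trim_sl(read, ""), "empty SL leader")
})

test_that("poly(A) tail detection trims qualifying A-runs", {
  out <- detect_polya_tail(c(r = paste0(strrep("CGT", 10), "AAAAAAA")),
                           min_a_run = 5L)
  expect_equal(out$evidence_kind, "POLYA")
  expect_equal(out$trimmed_prefix_len, 7L)
  expect_equal(out$sequence, strrep("CGT", 10))

  out <- detect_polya_tail(c(r = paste0(strrep("CGT", 10), "AAAA")),
                           min_a_run = 5L)
  expect_equal(out$evidence_kind, "NONE")

  # pre-tagged T-fill read without an A-run is still 3' evidence
  out <- detect_polya_tail(c(r = strrep("CGT", 10)), min_a_run = 5L,
                           pretagged = TRUE)
  expect_equal(out$evidence_kind, "POLYA")
  expect_equal(out$trimmed_prefix_len, 0L)

  # interrupted tail: one non-A tolerated
  out <- detect_polya_tail(c(r = paste0("CGTCGT", "AAAATAAA")),
                           min_a_run = 5L, max_non_a = 1L)
  expect_equal(out$evidence_kind, "POLYA")
  expect_equal(out$trimmed_prefix_len, 8L)
})

test_that("pileup accumulates counts per (scaffold, strand, position)", {
  pl <- data.frame(scaffold = "s1", pos = c(100L, 100L, 100L),
                   strand = "+")
  tr <- pileup_end_positions(pl, "SL")
  expect_equal(nrow(tr), 1L)
  expect_equal(tr$count, 3L)
  expect_equal(tr$pos, 100L)

  pl2 <- data.frame(scaffold = "s1", pos = 100L, strand = c("+", "-"))
  tr2 <- pileup_end_positions(pl2, "SL")
  expect_equal(nrow(tr2), 2L)
  expect_setequal(tr2$strand, c("+", "-"))

  tr3 <- pileup_end_positions(
    data.frame(scaffold = character(), pos = integer(), strand = character()),
    "POLYA")
  expect_equal(nrow(tr3), 0L)
  expect_equal(attr(tr3, "kind"), "POLYA")

  expect_error(
    pileup_end_positions(data.frame(scaffold = "s1", pos = 50L, strand = "+"),
                         "SL", genome = c(s1 = "ACGT")),
    "outside scaffold bounds")
  expect_equal(sum(tr$count), nrow(pl))  # track total equals placements
})

test_that("peak calling groups positions by gap and filters by total count", {
  tr <- data.frame(scaffold = "s1", strand = "+", pos = c(100L, 101L),
                   count = c(7L, 2L))
  attr(tr, "kind") <- "SL"
  pk <- call_peaks(tr, min_site_count = 5L, merge_distance = 10L)
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$summit, 100L)
  expect_equal(pk$total_count, 9L)

  tr2 <- data.frame(scaffold = "s1", strand = "+", pos = c(100L, 200L),
                    count = c(2L, 2L))
  attr(tr2, "kind") <- "SL"
  expect_equal(nrow(call_peaks(tr2, 5L, 10L)), 0L)

  tr3 <- data.frame(scaffold = "s1", strand = "+", pos = c(100L, 104L),
                    count = c(4L, 4L))
  attr(tr3, "kind") <- "SL"
  pk3 <- call_peaks(tr3, 5L, 10L)
  expect_equal(nrow(pk3), 1L)
  expect_equal(pk3$total_count, 8L)
  # exhaustive grouping oracle agrees on the toy track
  oracle <- oracle_group_positions(tr3$pos, 10L)
  expect_equal(length(oracle), 1L)
  expect_equal(sort(oracle[[1]]), c(100, 104))
})

test_that("peak grouping equals the exhaustive-partition oracle on random tracks", {
  set.seed(11)
  for (rep in 1:20) {
    pos <- sort(sample(0:300, sample(3:9, 1)))
    cnt <- sample(1:8, length(pos), replace = TRUE)
    md <- sample(c(0L, 5L, 10L, 25L), 1)
    tr <- data.frame(scaffold = "s1", strand = "+", pos = pos, count = cnt)
    attr(tr, "kind") <- "SL"
    pk <- call_peaks(tr, min_site_count = 1L, merge_distance = md)
    oracle <- oracle_group_positions(pos, md)
    expect_equal(nrow(pk), length(oracle))
    expect_equal(pk$start, unname(vapply(oracle, min, 1)))
    expect_equal(pk$end, unname(vapply(oracle, max, 1) + 1))
  }
})

test_that("summit ties break toward the transcript 5' direction", {
  tr <- data.frame(scaffold = "s1", strand = "+", pos = c(50L, 55L),
                   count = c(6L, 6L))
  attr(tr, "kind") <- "SL"
  expect_equal(call_peaks(tr, 1L, 10L)$summit, 50L)
  tr$strand <- "-"
  expect_equal(call_peaks(tr, 1L, 10L)$summit, 55L)
})

test_that("count conservation and min_site_count monotonicity hold", {
  set.seed(21)
  pos <- sort(sample(0:2000, 60))
  cnt <- sample(1:10, 60, replace = TRUE)
  tr <- data.frame(scaffold = "s1", strand = "+", pos = pos, count = cnt)
  attr(tr, "kind") <- "SL"
  all_groups <- call_peaks(tr, min_site_count = 1L, merge_distance = 10L)
  expect_equal(sum(all_groups$total_count), sum(cnt))  # conservation
  n_prev <- Inf
  for (ms in c(1L, 3L, 5L, 10L, 20L)) {
    n <- nrow(call_peaks(tr, ms, 10L))
    expect_lte(n, n_prev)
    n_prev <- n
  }
})

test_that("RPKM follows its standard closed form", {
  expect_equal(compute_rpkm(10, 1000, 1e6), 10)
  expect_equal(compute_rpkm(0, 500, 1e6), 0)
  expect_equal(compute_rpkm(5, 2000, 1e7), 0.25)
  expect_error(compute_rpkm(1, 0, 1e6), "transcript_length")
  expect_error(compute_rpkm(1, 100, 0), "total_mapped")
})

test_that("SAM placements use aligned bases only, strand-aware", {
  sam <- withr::local_tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:unknown",
    "@SQ\tSN:s1\tLN:1000",
    # + strand, 5 nt soft clip at 5' end: SL position = POS - 1 = 100
    paste("r1", 0, "s1", 101, 60, "5S20M", "*", 0, 0,
          strrep("A", 25), "*", sep = "\t"),
    # - strand: SL position = rightmost aligned base = 101 + 20 - 1 - 1 = 119
    paste("r2", 16, "s1", 101, 60, "20M5S", "*", 0, 0,
          strrep("A", 25), "*", sep = "\t")), sam)
  sl <- read_placements(sam, "SL")
  expect_equal(sl$pos, c(100L, 119L))
  expect_equal(sl$strand, c("+", "-"))
  pa <- read_placements(sam, "POLYA")
  expect_equal(pa$pos, c(119L, 100L))
})

test_that("BED placements map 5' and 3' ends by strand", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("s1\t10\t60\tr1\t0\t+", "s1\t10\t60\tr2\t0\t-"), bed)
  sl <- read_placements(bed, "SL")
  expect_equal(sl$pos, c(10L, 59L))
  pa <- read_placements(bed, "POLYA")
  expect_equal(pa$pos, c(59L, 10L))
})
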