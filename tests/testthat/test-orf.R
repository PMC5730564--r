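test_that("longest-ORF calling handles the canonical small cases", {
  orf <- find_longest_orf("ATGAAATAA", min_aa = 2L)
  expect_equal(orf$protein, "MK")
  expect_true(orf$complete)
  expect_equal(orf$start, 0L)
  expect_equal(orf$end, 9L)
  expect_equal((orf$end - orf$start) / 3 - 1, nchar(orf$protein))

  expect_null(find_longest_orf("CCCATGTAA", min_aa = 2L))  # protein "M" too short
  expect_null(find_longest_orf("AT", min_aa = 1L))

  # open-ended ORF without a stop is incomplete
  orf2 <- find_longest_orf("ATGAAAAAA", min_aa = 2L)
  expect_false(orf2$complete)
  expect_equal(orf2$protein, "MKK")
})

test_that("ties between equally long ORFs break to the 5'-most start", {
  # two complete 3-aa ORFs in different frames
  s <- paste0("ATGAAAAAATAA", "G", "ATGCCCCCCTAA")
  orf <- find_longest_orf(s, min_aa = 2L)
  expect_equal(orf$start, 0L)
})

test_that("longest-ORF agrees with the brute-force oracle on random sequences", {
  set.seed(31)
  for (i in 1:200) {
    s <- rand_seq(sample(60:400, 1))
    for (min_aa in c(5L, 15L)) {
      got <- find_longest_orf(s, min_aa = min_aa)
      want <- oracle_longest_orf(s, min_aa = min_aa)
      if (is.null(want)) {
        expect_null(got)
      } else {
        expect_equal(got$start, want$start)
        expect_equal(got$end, want$end)
        expect_equal(nchar(got$protein) + as.integer(got$complete) * 0L,
                     want$prot_len)
      }
    }
  }
})


test_that("only the single stated flag combination merges", {
  for (orf_a in c(TRUE, FALSE)) for (polya_a in c(TRUE, FALSE))
    for (orf_b in c(TRUE, FALSE)) for (polya_b in c(TRUE, FALSE)) {
      fx <- merge_fixture(orf_a, polya_a, orf_b, polya_b)
      res <- merge_split_transcripts(fx$genes, fx$genome, fx$repeats,
                                     min_aa = 5L)
      should <- orf_a && !polya_a && !orf_b && polya_b
      expect_equal(nrow(res$report), as.integer(should),
                   info = sprintf("ORF_A=%s pA_A=%s ORF_B=%s pA_B=%s",
                                  orf_a, polya_a, orf_b, polya_b))
      expect_equal(nrow(res$genes$genes), 2L - as.integer(should))
    }
})

test_that("gap length and repeat coverage gate the merge", {
  # mergeable flags, 2.2 kb fully repeat-covered gap -> merged
  fx <- merge_fixture(TRUE, FALSE, FALSE, TRUE, gap_repeat = TRUE)
  expect_equal(nrow(merge_split_transcripts(fx$genes, fx$genome, fx$repeats,
                                            min_aa = 5L)$report), 1L)

  # same flags, non-repetitive gap -> kept apart
  fx <- merge_fixture(TRUE, FALSE, FALSE, TRUE, gap_repeat = FALSE)
  expect_equal(nrow(merge_split_transcripts(fx$genes, fx$genome, fx$repeats,
                                            min_aa = 5L)$report), 0L)

  # gap above 10 kb -> kept apart even when repetitive
  fx <- merge_fixture(TRUE, FALSE, FALSE, TRUE, gap_repeat = TRUE,
                      b_start = 11000L, b_end = 11600L)
  expect_equal(nrow(merge_split_transcripts(fx$genes, fx$genome, fx$repeats,
                                            min_aa = 5L)$report), 0L)
})

test_that("merged models keep both exon sets and the downstream poly(A)", {
  fx <- merge_fixture(TRUE, FALSE, FALSE, TRUE)
  before_len <- sum(fx$genes$exons$end - fx$genes$exons$start)
  res <- merge_split_transcripts(fx$genes, fx$genome, fx$repeats, min_aa = 5L)
  m <- res$genes
  expect_equal(nrow(m$genes), 1L)
  expect_equal(m$genes$start, 100L)
  expect_equal(m$genes$end, 3500L)
  expect_true(m$genes$has_polya_3p)
  expect_equal(nrow(m$exons), 2L)  # the gap is an intron, not exon
  expect_equal(sum(m$exons$end - m$exons$start), before_len)
})

test_that("overlapping input genes on one strand are rejected", {
  fx <- merge_fixture(TRUE, FALSE, FALSE, TRUE)
  g <- fx$genes$genes
  g$start[2] <- 600L  # overlaps gene A
  ex <- fx$genes$exons
  ex$start[2] <- 600L
  expect_error(
    merge_split_transcripts(gene_set(g, ex), fx$genome, fx$repeats),
    "overlapping gene models")
})
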