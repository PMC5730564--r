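test_that("masking replaces repeat positions with N, preserving length", {
  g <- c(s1 = "ACGTACGTAC")
  m <- mask_genome(g, data.frame(scaffold = "s1", start = 0, end = 5,
                                 strand = "."))
  expect_equal(m[["s1"]], "NNNNNCGTAC")
  expect_equal(mask_genome(g, data.frame(scaffold = character(),
                                         start = integer(), end = integer(),
                                         strand = character())), g)
  full <- mask_genome(g, data.frame(scaffold = "s1", start = 0, end = 10,
                                    strand = "."))
  expect_equal(full[["s1"]], strrep("N", 10))
})

# Hand-built two-scaffold genome with a planted copy; flanks around the copy
# are homopolymer runs that cannot extend an alignment.
planted_genome <- function(len, n_subs = 0, inverted = FALSE, seed = 83) {
  set.seed(seed)
  seg <- rand_seq(len)
  copy <- seg
  if (n_subs > 0) {
    ch <- strsplit(copy, "")[[1]]
    idx <- sample(len, n_subs)
    for (i in idx) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
    copy <- paste(ch, collapse = "")
  }
  if (inverted) {
    copy <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(copy)))
  }
  c(s1 = paste0(rand_seq(700), strrep("A", 30), seg, strrep("A", 30), rand_seq(700)),
    s2 = paste0(rand_seq(600), strrep("C", 30), copy, strrep("C", 30), rand_seq(600)))
}

test_that("an exact 600 nt cross-scaffold copy is reported at identity 1", {
  g <- planted_genome(600)
  bl <- find_dup_blocks(g)
  expect_equal(nrow(bl), 1L)
  expect_equal(bl$identity, 1)
  expect_equal(bl$aligned_length, 600L)
  expect_equal(bl$start_a, 730L)
  expect_equal(bl$orientation, "same")
})

test_that("short and diverged copies are rejected by the stated rule", {
  expect_equal(nrow(find_dup_blocks(planted_genome(400))), 0L)
  # 600 nt with 40 substitutions: identity about 0.933
  g <- planted_genome(600, n_subs = 40)
  expect_equal(nrow(find_dup_blocks(g)), 0L)
})

test_that("inverted duplications are found with the inverted orientation", {
  g <- planted_genome(640, inverted = TRUE)
  bl <- find_dup_blocks(g)
  expect_equal(nrow(bl), 1L)
  expect_equal(bl$orientation, "inverted")
  expect_equal(bl$aligned_length, 640L)
})

test_that("the length rule is strict at exactly 500 nt", {
  # non-extendable flanks make the planted length the aligned length
  expect_equal(nrow(find_dup_blocks(planted_genome(500))), 0L)
  bl <- find_dup_blocks(planted_genome(501))
  expect_equal(nrow(bl), 1L)
  expect_equal(bl$aligned_length, 501L)
})

test_that("reported identity matches a global-alignment oracle of the loci", {
  g <- planted_genome(700, n_subs = 21)  # identity 0.97
  bl <- find_dup_blocks(g)
  expect_equal(nrow(bl), 1L)
  a <- substr(g[[bl$scaffold_a]], bl$start_a + 1, bl$end_a)
  b <- substr(g[[bl$scaffold_b]], bl$start_b + 1, bl$end_b)
  pa <- Biostrings::pairwiseAlignment(a, b, type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(1, -1, baseOnly = FALSE),
    gapOpening = 4, gapExtension = 2)
  oracle <- Biostrings::nmatch(pa) / Biostrings::nchar(pa)
  expect_lt(abs(bl$identity - oracle), 0.005)
})

test_that("block discovery is invariant under scaffold reordering", {
  g <- planted_genome(600)
  bl1 <- find_dup_blocks(g)
  bl2 <- find_dup_blocks(g[c("s2", "s1")])
  expect_equal(bl1, bl2)
})

test_that("tandem self-overlapping hits are discarded as self", {
  set.seed(89)
  seg <- rand_seq(600)
  # direct tandem: the two copies abut, anchors give overlapping intervals
  g <- c(s1 = paste0(rand_seq(500), seg, seg, rand_seq(500)))
  bl <- find_dup_blocks(g)
  if (nrow(bl) > 0) {
    ok <- !(bl$scaffold_a == bl$scaffold_b &
              bl$start_a < bl$end_b & bl$start_b < bl$end_a)
    expect_true(all(ok))
  } else {
    succeed()
  }
})

test_that("duplicated fraction is a union without double counting", {
  blocks <- data.frame(
    scaffold_a = "s1", start_a = 0L, end_a = 600L,
    scaffold_b = "s1", start_b = 5000L, end_b = 5600L,
    orientation = "same", identity = 1, aligned_length = 600L)
  genome <- c(s1 = strrep("A", 10000))
  df <- duplicated_fraction(blocks, genome)
  expect_equal(df$nt, 1200L)
  expect_equal(df$fraction, 0.12)

  two <- rbind(blocks, blocks)  # fully overlapping blocks counted once
  expect_equal(duplicated_fraction(two, genome)$nt, 1200L)

  none <- blocks[0, ]
  expect_equal(duplicated_fraction(none, genome)$nt, 0L)

  # exclude repeat-masked positions on request
  mask <- data.frame(scaffold = "s1", start = 0L, end = 300L, strand = ".")
  expect_equal(duplicated_fraction(blocks, genome, mask,
                                   include_repeats = FALSE)$nt, 900L)
})
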