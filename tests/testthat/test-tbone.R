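test_that("peak assignment respects containment, strand and end slack", {
  tus <- make_tu_set(make_tu("t1", "s1", list(c(1000, 2000)), "+"))
  inside <- make_peaks("SL", "s1", 1500, "+")
  expect_equal(nrow(assign_peaks_to_tu(tus, inside)), 1L)

  opposite <- make_peaks("SL", "s1", 1500, "-")
  expect_equal(nrow(assign_peaks_to_tu(tus, opposite)), 0L)

  upstream <- make_peaks("SL", "s1", 980, "+")  # 20 nt upstream
  expect_equal(nrow(assign_peaks_to_tu(tus, upstream, end_slack = 50L)), 1L)
  expect_equal(nrow(assign_peaks_to_tu(tus, upstream, end_slack = 10L)), 0L)

  # a peak overlapping two TUs is assigned to both
  tus2 <- make_tu_set(make_tu("a", "s1", list(c(0, 100)), "+"),
                      make_tu("b", "s1", list(c(80, 200)), "+"))
  both <- make_peaks("SL", "s1", 90, "+")
  expect_equal(sort(assign_peaks_to_tu(tus2, both)$tu_id), c("a", "b"))
})

test_that("a TU with two SL sites is cut into two poly(A)-defined genes", {
  tus <- make_tu_set(make_tu("t1", "s1", list(c(1000, 9001)), "+"))
  peaks <- rbind(make_peaks("SL", "s1", c(1000, 5000), "+", counts = 20),
                 make_peaks("POLYA", "s1", c(4800, 9000), "+", counts = 20))
  genes <- cut_transcriptional_units(tus, peaks)
  g <- genes$genes
  expect_equal(nrow(g), 2L)
  expect_equal(g$start, c(1000L, 5000L))
  expect_equal(g$end, c(4801L, 9001L))
  expect_true(all(g$has_sl_5p))
  expect_true(all(g$has_polya_3p))
  expect_equal(g$classification, rep("SL_MULTIPLE_PARENT", 2))
})

test_that("a gene without poly(A) evidence falls back to the TU 3' end", {
  tus <- make_tu_set(make_tu("t1", "s1", list(c(1000, 9000)), "+"))
  peaks <- make_peaks("SL", "s1", 1000, "+")
  g <- cut_transcriptional_units(tus, peaks)$genes
  expect_equal(nrow(g), 1L)
  expect_equal(g$end, 9000L)
  expect_false(g$has_polya_3p)
  expect_equal(g$classification, "SL_SINGLE")
})

test_that("cutting commutes with coordinate reflection (strand symmetry)", {
  L <- 20000L
  tus <- make_tu_set(make_tu("t1", "s1", list(c(1000, 9001)), "+"))
  peaks <- rbind(make_peaks("SL", "s1", c(1000, 5000), "+", counts = c(9, 7)),
                 make_peaks("POLYA", "s1", c(4800, 9000), "+", counts = c(8, 6)))
  fwd <- cut_transcriptional_units(tus, peaks)$genes

  r_ex <- reflect_intervals(tus$exons, L)
  r_tr <- reflect_intervals(tus$transcripts, L)
  r_tus <- tu_set(r_tr, r_ex)
  r_peaks <- peaks
  r_peaks$summit <- reflect_pos(peaks$summit, L)
  r_peaks$start <- r_peaks$summit
  r_peaks$end <- r_peaks$summit + 1L
  r_peaks$strand <- "-"
  rev <- cut_transcriptional_units(r_tus, r_peaks)$genes

  expect_equal(nrow(rev), nrow(fwd))
  # gene i on + corresponds to gene i on - after reflection
  expect_equal(sort(rev$start), sort(L - fwd$end))
  expect_equal(sort(rev$end), sort(L - fwd$start))
  expect_equal(sum(rev$has_polya_3p), sum(fwd$has_polya_3p))
  expect_equal(sort(reflect_pos(rev$sl_summit, L)), sort(fwd$sl_summit))
})

test_that("a long unspliced 5' leader segment is emitted without SL evidence", {
  tus <- make_tu_set(make_tu("t1", "s1", list(c(0, 5000)), "+"))
  peaks <- make_peaks("SL", "s1", 2000, "+")
  g <- cut_transcriptional_units(tus, peaks, min_gene_len = 100L)$genes
  expect_equal(nrow(g), 2L)
  expect_false(g$has_sl_5p[1])
  expect_equal(g$end[1], 2000L)  # ends immediately 5' of the SL summit
  expect_true(g$has_sl_5p[2])

  # a short leader is dropped
  tus2 <- make_tu_set(make_tu("t1", "s1", list(c(1950, 5000)), "+"))
  g2 <- cut_transcriptional_units(tus2, peaks, min_gene_len = 100L)$genes
  expect_equal(nrow(g2), 1L)
  expect_true(g2$has_sl_5p[1])
})

test_that("TUs without SL evidence pass through as single NO_SL genes", {
  tus <- make_tu_set(make_tu("t1", "s1", list(c(100, 900), c(1200, 2000)), "-"))
  g <- cut_transcriptional_units(tus, data.frame(
    kind = character(), scaffold = character(), start = integer(),
    end = integer(), strand = character(), summit = integer(),
    total_count = integer()))
  expect_equal(nrow(g$genes), 1L)
  expect_equal(g$genes$classification, "NO_SL")
  expect_equal(g$genes$start, 100L)
  expect_equal(g$genes$end, 2000L)
  expect_equal(nrow(g$exons), 2L)  # exon structure inherited
})

test_that("intronic evidence summits snap onto exonic bases", {
  # exons [0,500) and [1000,2000); intron [500,1000)
  tus <- make_tu_set(make_tu("t1", "s1", list(c(0, 500), c(1000, 2000)), "+"))
  # SL summit inside the intron snaps 3'-wards to base 1000
  peaks <- make_peaks("SL", "s1", 700, "+")
  g <- cut_transcriptional_units(tus, peaks, min_gene_len = 50L)$genes
  g_sl <- g[g$has_sl_5p, ]
  expect_equal(g_sl$sl_summit, 1000L)
  expect_equal(g_sl$start, 1000L)

  # poly(A) summit inside the intron snaps 5'-wards to base 499
  peaks2 <- rbind(make_peaks("SL", "s1", 0, "+"),
                  make_peaks("POLYA", "s1", 600, "+"))
  g2 <- cut_transcriptional_units(tus, peaks2, min_gene_len = 50L)$genes
  expect_equal(g2$polya_summit, 499L)
  expect_equal(g2$end, 500L)
})

test_that("evidence outside the assembled span extends terminal exons", {
  tus <- make_tu_set(make_tu("t1", "s1", list(c(1000, 2000)), "+"))
  peaks <- rbind(make_peaks("SL", "s1", 980, "+"),
                 make_peaks("POLYA", "s1", 2030, "+"))
  g <- cut_transcriptional_units(tus, peaks, end_slack = 50L)
  expect_equal(g$genes$start, 980L)
  expect_equal(g$genes$end, 2031L)
  expect_equal(g$exons$start, 980L)
  expect_equal(g$exons$end, 2031L)
})

test_that("genes below min_gene_len are dropped after clipping", {
  tus <- make_tu_set(make_tu("t1", "s1", list(c(0, 5000)), "+"))
  peaks <- rbind(make_peaks("SL", "s1", c(0, 4950), "+"))
  g <- cut_transcriptional_units(tus, peaks, min_gene_len = 100L)$genes
  expect_equal(nrow(g), 1L)  # the 50-nt second gene is dropped
  expect_equal(g$start, 0L)
})

test_that("classification counts follow parent SL-site multiplicity", {
  # 10 TUs: 4 single-SL, 2 multi-SL, 4 no evidence -> 40% / 20% / 40%
  parts <- list(); peak_list <- list()
  for (i in 1:10) {
    start <- (i - 1) * 10000
    parts[[i]] <- make_tu(sprintf("t%02d", i), "s1",
                          list(c(start, start + 4000)), "+")
    if (i <= 4) {
      peak_list[[length(peak_list) + 1]] <- make_peaks("SL", "s1", start, "+")
    } else if (i <= 6) {
      peak_list[[length(peak_list) + 1]] <-
        make_peaks("SL", "s1", c(start, start + 2000), "+")
    }
  }
  tus <- do.call(make_tu_set, parts)
  peaks <- do.call(rbind, peak_list)
  cl <- classify_genes(cut_transcriptional_units(tus, peaks))
  s <- cl$summary
  expect_equal(s$n[s$category == "tus_single_sl"], 4)
  expect_equal(s$n[s$category == "tus_multiple_sl"], 2)
  expect_equal(s$n[s$category == "tus_no_sl"], 4)
  expect_equal(s$percent[s$category == "tus_single_sl"], 40)
  expect_equal(s$percent[s$category == "tus_multiple_sl"], 20)
  expect_equal(s$percent[s$category == "tus_no_sl"], 40)
})

test_that("children partition their parent and SL summits appear exactly once", {
  sim <- simulate_dataset(simulation_config(seed = 303, n_tus = 30))
  peaks <- rbind(
    call_peaks(pileup_end_positions(sim$sl_placements, "SL")),
    call_peaks(pileup_end_positions(sim$polya_placements, "POLYA")))
  genes <- cut_transcriptional_units(sim$tus, peaks)
  g <- genes$genes
  tr <- sim$tus$transcripts
  for (tu in unique(g$parent_tu_id)) {
    kids <- g[g$parent_tu_id == tu, ]
    kids <- kids[order(kids$start), ]
    parent <- tr[tr$tu_id == tu, ]
    slack <- 50L
    expect_gte(min(kids$start), parent$start - slack)
    expect_lte(max(kids$end), parent$end + slack)
    if (nrow(kids) > 1) {
      expect_true(all(kids$start[-1] >= kids$end[-nrow(kids)]))  # disjoint
    }
  }
  # every assigned SL summit appears as exactly one child 5' boundary
  asg <- assign_peaks_to_tu(sim$tus, peaks)
  sl_assigned <- unique(peaks$summit[asg$peak[asg$kind == "SL"]])
  expect_equal(sort(g$sl_summit[g$has_sl_5p]), sort(sl_assigned))
})
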