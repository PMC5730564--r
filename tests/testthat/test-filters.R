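# Antisense pair on one scaffold: sense TU [0,1000)+, antisense [0,1000)-.
antisense_fixture <- function(count_sense, count_anti) {
  tus <- make_tu_set(make_tu("sense", "s1", list(c(0, 1000)), "+"),
                     make_tu("anti", "s1", list(c(0, 1000)), "-"))
  counts <- c(sense = count_sense, anti = count_anti)
  list(tus = tus, counts = counts)
}

test_that("the fivefold antisense threshold is inclusive", {
  fx <- antisense_fixture(100, 20)  # ratio exactly 5.0
  res <- filter_antisense(fx$tus, fx$counts)
  expect_equal(res$discarded$transcripts$tu_id, "anti")

  fx <- antisense_fixture(100, 21)  # ratio 4.76
  res <- filter_antisense(fx$tus, fx$counts)
  expect_equal(nrow(res$discarded$transcripts), 0L)

  fx <- antisense_fixture(50, 0)  # infinite ratio
  res <- filter_antisense(fx$tus, fx$counts)
  expect_equal(res$discarded$transcripts$tu_id, "anti")

  # both zero: no fold difference demonstrable, keep both
  fx <- antisense_fixture(0, 0)
  res <- filter_antisense(fx$tus, fx$counts)
  expect_equal(nrow(res$discarded$transcripts), 0L)
})

test_that("pairs below the overlap fraction are not evaluated", {
  # antisense overlaps only 300/1000 of its own exonic length
  tus <- make_tu_set(make_tu("sense", "s1", list(c(0, 300)), "+"),
                     make_tu("anti", "s1", list(c(0, 1000)), "-"))
  counts <- c(sense = 100, anti = 10)
  res <- filter_antisense(tus, counts, min_overlap_frac = 0.5)
  expect_equal(nrow(res$discarded$transcripts), 0L)
  res2 <- filter_antisense(tus, counts, min_overlap_frac = 0.25)
  expect_equal(res2$discarded$transcripts$tu_id, "anti")
})

test_that("antisense filtering is idempotent and monotone in the threshold", {
  set.seed(5)
  parts <- list(); counts <- numeric()
  for (i in 1:10) {
    base <- (i - 1) * 3000
    s_id <- sprintf("s%02d", i); a_id <- sprintf("a%02d", i)
    parts[[length(parts) + 1]] <- make_tu(s_id, "s1",
                                          list(c(base, base + 1000)), "+")
    parts[[length(parts) + 1]] <- make_tu(a_id, "s1",
                                          list(c(base, base + 1000)), "-")
    counts[s_id] <- sample(10:200, 1)
    counts[a_id] <- sample(0:100, 1)
  }
  tus <- do.call(make_tu_set, parts)
  once <- filter_antisense(tus, counts)
  twice <- filter_antisense(once$kept, counts)
  expect_equal(twice$kept$transcripts$tu_id, once$kept$transcripts$tu_id)
  expect_equal(nrow(twice$discarded$transcripts), 0L)

  n_prev <- -1
  for (thr in c(100, 20, 5, 2, 1.01)) {
    n <- nrow(filter_antisense(tus, counts, ratio_threshold = thr)$discarded$transcripts)
    expect_gte(n, n_prev)
    n_prev <- n
  }
})

test_that("antisense filter matches exhaustive pairwise evaluation", {
  set.seed(17)
  for (rep in 1:3) {
    parts <- list(); counts <- numeric()
    for (i in 1:10) {
      base <- (i - 1) * 2000
      span <- sort(sample(base:(base + 1500), 2))
      if (diff(span) < 50) span[2] <- span[1] + 50
      id1 <- sprintf("p%02d", i); id2 <- sprintf("m%02d", i)
      parts[[length(parts) + 1]] <- make_tu(id1, "s1", list(span), "+")
      # antisense partner shifted so overlap varies
      sh <- sample(0:400, 1)
      parts[[length(parts) + 1]] <- make_tu(id2, "s1",
                                            list(span + sh), "-")
      counts[id1] <- sample(0:150, 1)
      counts[id2] <- sample(0:150, 1)
    }
    tus <- do.call(make_tu_set, parts)
    res <- filter_antisense(tus, counts)

    # oracle: direct O(n^2) over transcripts
    tr <- tus$transcripts
    discard <- character()
    for (i in seq_len(nrow(tr))) for (j in seq_len(nrow(tr))) {
      if (i >= j) next
      a <- tr[i, ]; b <- tr[j, ]
      if (a$strand == b$strand || a$scaffold != b$scaffold) next
      ov <- max(0, min(a$end, b$end) - max(a$start, b$start))
      if (ov == 0) next
      ca <- counts[[a$tu_id]]; cb <- counts[[b$tu_id]]
      lower <- if (ca <= cb) a$tu_id else b$tu_id
      len_lower <- (tr$end - tr$start)[tr$tu_id == lower]
      if (ov / len_lower < 0.5) next
      lo <- min(ca, cb); hi <- max(ca, cb)
      if (hi == 0) next
      if (lo == 0 || hi / lo >= 5) discard <- union(discard, lower)
    }
    expect_setequal(res$discarded$transcripts$tu_id, discard)
  }
})

test_that("low-expression novel transcripts are discarded by strict conjunction", {
  tus <- make_tu_set(make_tu("a", "s1", list(c(0, 1000)), "+", rpkm = 0.4),
                     make_tu("b", "s1", list(c(2000, 3000)), "+", rpkm = 0.4),
                     make_tu("c", "s1", list(c(4000, 5000)), "+", rpkm = 0.5))
  res <- filter_low_expression_novel(tus, reference_overlaps = "b")
  expect_equal(res$discarded$transcripts$tu_id, "a")   # low and novel
  expect_true("b" %in% res$kept$transcripts$tu_id)     # low but referenced
  expect_true("c" %in% res$kept$transcripts$tu_id)     # exactly at threshold
})

test_that("missing read counts are reported by TU id", {
  fx <- antisense_fixture(10, 10)
  expect_error(filter_antisense(fx$tus, c(sense = 10)), "anti")
})
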