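# Fixture builders shared across tests. Everything is generated in code;
# no data files.

rand_seq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# One TU with explicit exon blocks given as a list of c(start, end).
make_tu <- function(tu_id, scaffold, exon_blocks, strand = "+", rpkm = 10) {
  ex <- do.call(rbind, lapply(exon_blocks, function(b) {
    data.frame(tu_id = tu_id, scaffold = scaffold, start = b[1], end = b[2],
               strand = strand, stringsAsFactors = FALSE)
  }))
  tr <- data.frame(tu_id = tu_id, scaffold = scaffold,
                   start = min(ex$start), end = max(ex$end), strand = strand,
                   rpkm = rpkm, stringsAsFactors = FALSE)
  list(transcripts = tr, exons = ex)
}

make_tu_set <- function(...) {
  parts <- list(...)
  tu_set(do.call(rbind, lapply(parts, `[[`, "transcripts")),
         do.call(rbind, lapply(parts, `[[`, "exons")))
}

make_peaks <- function(kind, scaffold, summits, strand = "+", counts = 10) {
  counts <- rep_len(counts, length(summits))
  data.frame(kind = kind, scaffold = scaffold, start = summits,
             end = summits + 1L, strand = strand, summit = summits,
             total_count = counts, stringsAsFactors = FALSE)
}

# Reflect a half-open interval table through a scaffold of length L
# (reverse complement of coordinates: strand flips, order mirrors).
reflect_intervals <- function(df, L) {
  out <- df
  out$start <- L - df$end
  out$end <- L - df$start
  out$strand <- chartr("+-", "-+", df$strand)
  out
}

reflect_pos <- function(pos, L) L - 1L - pos

# Independent peak-grouping oracle: enumerate every partition of the sorted
# positions into consecutive runs and keep the unique one that satisfies the
# gap rule both within and between runs.
oracle_group_positions <- function(pos, merge_distance) {
  pos <- sort(pos)
  n <- length(pos)
  if (n == 0) return(list())
  valid <- NULL
  enumerate <- function(breaks_left, idx) {
    if (idx > n - 1) {
      groups <- split(pos, cumsum(c(0, breaks_left)))
      ok <- all(vapply(groups, function(g)
        all(diff(g) <= merge_distance), TRUE)) &&
        all(vapply(seq_len(length(groups) - 1), function(i)
          min(groups[[i + 1]]) - max(groups[[i]]) > merge_distance,
          TRUE))
      if (ok) valid <<- groups
      return(invisible())
    }
    enumerate(c(breaks_left, 0), idx + 1)
    enumerate(c(breaks_left, 1), idx + 1)
  }
  if (n == 1) return(list(pos))
  enumerate(c(), 1)
  valid
}

# Brute-force longest-ORF oracle: walk every ATG in every forward frame.
oracle_longest_orf <- function(seq, min_aa = 100L) {
  seq <- toupper(seq)
  n <- nchar(seq)
  stops <- c("TAA", "TAG", "TGA")
  best <- NULL
  for (s in seq_len(max(n - 2, 0))) {
    if (substr(seq, s, s + 2) != "ATG") next
    p <- s
    prot_len <- 0L
    complete <- FALSE
    end <- NA_integer_
    while (p + 2 <= n) {
      cod <- substr(seq, p, p + 2)
      if (p > s && cod %in% stops) {
        complete <- TRUE
        end <- p + 2
        break
      }
      prot_len <- prot_len + 1L
      end <- p + 2
      p <- p + 3
    }
    if (complete) prot_len <- prot_len - 0L else prot_len <- prot_len
    aa <- if (complete) (end - (s - 1) - 3) / 3 else prot_len
    if (aa < min_aa) next
    cand <- list(start = s - 1L, end = end, prot_len = aa)
    if (is.null(best) || cand$prot_len > best$prot_len ||
        (cand$prot_len == best$prot_len && cand$start < best$start)) {
      best <- cand
    }
  }
  best
}

# Full-pairwise-matrix clustering oracle: same identity rule and greedy
# order, but driven off a precomputed identity matrix.
oracle_cluster_matrix <- function(seqs, threshold) {
  ord <- order(-nchar(seqs), names(seqs))
  seqs <- seqs[ord]
  ids <- names(seqs)
  n <- length(seqs)
  idm <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j) idm[i, j] <- alignment_identity(seqs[[i]], seqs[[j]])
  }
  reps <- character()
  assign <- character()
  for (i in seq_len(n)) {
    hit <- NA_character_
    for (r in reps) {
      if (idm[ids[i], r] >= threshold) { hit <- r; break }
    }
    if (is.na(hit)) { reps <- c(reps, ids[i]); hit <- ids[i] }
    assign[ids[i]] <- hit
  }
  assign
}

# Random CDS of n_codons sense codons (ATG ... stop), for codon tests.
rand_cds <- function(n_codons) {
  sense <- setdiff(names(Biostrings::GENETIC_CODE), c("TAA", "TAG", "TGA"))
  sense <- chartr("U", "T", sense)
  paste0("ATG", paste(sample(sense, n_codons, replace = TRUE), collapse = ""),
         "TAA")
}

AA20 <- unique(Biostrings::GENETIC_CODE[Biostrings::GENETIC_CODE != "*"])

rand_protein <- function(n) paste(sample(AA20, n, replace = TRUE), collapse = "")

# Build a two-gene merge fixture on a designed genome. Flags are imposed on
# the records; the gap between A [100,700) and B [2900,3500) is 2200 nt.
merge_fixture <- function(orf_a, polya_a, orf_b, polya_b,
                          gap_repeat = TRUE, b_start = 2900L, b_end = 3500L) {
  set.seed(73)
  genome <- c(s1 = rand_seq(max(4000, b_end + 500)))
  g <- data.frame(
    gene_id = c("A", "B"), parent_tu_id = c("tA", "tB"), scaffold = "s1",
    start = c(100L, b_start), end = c(700L, b_end), strand = "+",
    has_sl_5p = TRUE, has_polya_3p = c(polya_a, polya_b),
    sl_summit = c(100L, b_start), polya_summit = NA_integer_,
    classification = "SL_SINGLE",
    orf_start = c(if (orf_a) 0L else NA_integer_,
                  if (orf_b) 0L else NA_integer_),
    orf_end = NA_integer_, orf_frame = 0L, orf_complete = NA,
    orf_protein = NA_character_, stringsAsFactors = FALSE)
  ex <- data.frame(gene_id = c("A", "B"), scaffold = "s1",
                   start = c(100L, b_start), end = c(700L, b_end),
                   strand = "+", stringsAsFactors = FALSE)
  repeats <- if (gap_repeat) {
    data.frame(scaffold = "s1", start = 700L, end = b_start, strand = ".")
  } else {
    data.frame(scaffold = character(), start = integer(), end = integer(),
               strand = character())
  }
  list(genes = gene_set(g, ex), genome = genome, repeats = repeats)
}
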