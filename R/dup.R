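# Duplicated-block detection: a repeat-masked genome is compared against
# itself with exact k-mer anchors; collinear anchors are chained (both
# orientations) and chained candidate loci are locally aligned. Non-self
# blocks longer than 500 nt (strict) and at least 95% identical (inclusive)
# are reported, with identity = matches / alignment columns.

#' Replace repeat-masked positions with N
#'
#' @param genome Named character vector of scaffold sequences.
#' @param repeat_mask data.frame of intervals (`scaffold,start,end`).
#' @return The masked genome; lengths preserved.
#' @export
mask_genome <- function(genome, repeat_mask) {
  if (nrow(repeat_mask) == 0L) return(genome)
  validate_intervals(repeat_mask, genome = genome)
  mask <- merge_intervals(repeat_mask)
  for (i in seq_len(nrow(mask))) {
    sc <- mask$scaffold[i]
    substr(genome[[sc]], mask$start[i] + 1L, mask$end[i]) <-
      strrep("N", mask$end[i] - mask$start[i])
  }
  genome
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# k-mer occurrence table of a genome: data.frame(kmer, scaffold, pos, flag)
# where flag records whether the canonical form equals the forward k-mer.
kmer_occurrences <- function(genome, k) {
  out <- list()
  for (sc in sort(names(genome))) {
    s <- genome[[sc]]
    n <- nchar(s)
    if (n < k) next
    starts <- seq_len(n - k + 1L)
    kms <- substring(s, starts, starts + k - 1L)
    ok <- !grepl("N", kms, fixed = TRUE)
    if (!any(ok)) next
    fwd <- kms[ok]
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(fwd)))
    canon <- pmin(fwd, rc)
    out[[sc]] <- data.frame(kmer = canon, scaffold = sc,
                            pos = starts[ok] - 1L, fwd = canon == fwd,
                            stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(kmer = character(), scaffold = character(),
                      pos = integer(), fwd = logical()))
  }
  do.call(rbind, out)
}

# Local alignment of two candidate loci; returns refined intervals, identity
# and aligned length. b_seq is already orientation-adjusted.
align_candidate <- function(a_seq, b_seq) {
  # mismatch penalty of 3x match: extending the alignment requires a local
  # match density above 75%, so random flanking sequence (~25% matches)
  # cannot stretch a block and dilute the identity of blocks sitting at the
  # reporting threshold; dense terminal mismatches are trimmed instead.
  # Gaps cost more than a mismatch so substitutions are never re-coded as
  # indel pairs, keeping the column denominator honest.
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -3,
                                                  baseOnly = FALSE)
  pa <- Biostrings::pairwiseAlignment(a_seq, b_seq, type = "local",
                                      substitutionMatrix = mat,
                                      gapOpening = 4, gapExtension = 2)
  list(
    a_start = Biostrings::start(Biostrings::pattern(pa)) - 1L,
    a_end = Biostrings::end(Biostrings::pattern(pa)),
    b_start = Biostrings::start(Biostrings::subject(pa)) - 1L,
    b_end = Biostrings::end(Biostrings::subject(pa)),
    columns = Biostrings::nchar(pa),
    matches = Biostrings::nmatch(pa)
  )
}

#' Find duplicated non-repetitive genomic blocks
#'
#' @param genome Masked genome (named character vector; see
#'   [mask_genome()]).
#' @param k Anchor k-mer size (>= 12), default 16.
#' @param min_len Minimum aligned length, strict (`> min_len`), default 500.
#' @param min_identity Minimum identity, inclusive, default 0.95.
#' @param max_gap Maximum anchor gap within a chain, default 300. At 95%
#'   identity the expected spacing of exact 16-mers is ~20 nt but the tail
#'   of the spacing distribution reaches past 100 nt on blocks of a few
#'   hundred nt, so the limit is set well above the typical spacing while
#'   staying far below `min_len`.
#' @param flank Flank in nt added around chained candidates before the
#'   refining local alignment.
#' @param max_occ k-mers occurring more often than this are skipped as
#'   unmasked repeats.
#' @return data.frame `scaffold_a,start_a,end_a,scaffold_b,start_b,end_b,
#'   orientation,identity,aligned_length` with canonical ordering
#'   (`a <= b`); self-overlapping pairs removed.
#' @export
find_dup_blocks <- function(genome, k = 16L, min_len = 500L,
                            min_identity = 0.95, max_gap = 300L,
                            flank = 60L, max_occ = 8L) {
  stopifnot(k >= 12L, min_len > k)
  occ <- kmer_occurrences(genome, k)
  empty <- data.frame(scaffold_a = character(), start_a = integer(),
                      end_a = integer(), scaffold_b = character(),
                      start_b = integer(), end_b = integer(),
                      orientation = character(), identity = numeric(),
                      aligned_length = integer(), stringsAsFactors = FALSE)
  if (nrow(occ) == 0L) return(empty)
  occ <- occ[order(occ$kmer, occ$scaffold, occ$pos), , drop = FALSE]
  dup_kmer <- occ$kmer %in% occ$kmer[duplicated(occ$kmer)]
  occ <- occ[dup_kmer, , drop = FALSE]
  if (nrow(occ) == 0L) return(empty)
  # anchor pairs
  anchors <- list()
  for (grp in split(occ, occ$kmer)) {
    if (nrow(grp) > max_occ) next
    for (i in seq_len(nrow(grp) - 1L)) for (j in (i + 1L):nrow(grp)) {
      a <- grp[i, ]; b <- grp[j, ]
      # canonical locus order: (scaffold, pos)
      if (a$scaffold > b$scaffold ||
          (a$scaffold == b$scaffold && a$pos > b$pos)) { tmp <- a; a <- b; b <- tmp }
      orientation <- if (a$fwd == b$fwd) "same" else "inverted"
      diag <- if (orientation == "same") b$pos - a$pos else a$pos + b$pos
      anchors[[length(anchors) + 1L]] <- data.frame(
        scaffold_a = a$scaffold, pos_a = a$pos,
        scaffold_b = b$scaffold, pos_b = b$pos,
        orientation = orientation, diag = diag, stringsAsFactors = FALSE)
    }
  }
  if (!length(anchors)) return(empty)
  an <- do.call(rbind, anchors)
  an <- an[!(an$scaffold_a == an$scaffold_b & an$pos_a == an$pos_b), , drop = FALSE]
  if (nrow(an) == 0L) return(empty)
  res <- list()
  for (grp in split(an, paste(an$scaffold_a, an$scaffold_b, an$orientation, an$diag))) {
    grp <- grp[order(grp$pos_a), , drop = FALSE]
    brk <- cumsum(c(0L, diff(grp$pos_a) > max_gap + k))
    for (run in split(grp, brk)) {
      a_start <- min(run$pos_a); a_end <- max(run$pos_a) + k
      b_start <- min(run$pos_b); b_end <- max(run$pos_b) + k
      if (a_end - a_start <= k) next  # single isolated anchor
      res[[length(res) + 1L]] <- data.frame(
        scaffold_a = run$scaffold_a[1L], start_a = a_start, end_a = a_end,
        scaffold_b = run$scaffold_b[1L], start_b = b_start, end_b = b_end,
        orientation = run$orientation[1L], stringsAsFactors = FALSE)
    }
  }
  if (!length(res)) return(empty)
  cand <- do.call(rbind, res)
  # merge candidates whose A and B intervals both overlap (nearby diagonals)
  cand <- cand[order(cand$scaffold_a, cand$start_a), , drop = FALSE]
  merged <- list()
  for (i in seq_len(nrow(cand))) {
    placed <- FALSE
    for (j in seq_along(merged)) {
      m <- merged[[j]]
      if (m$scaffold_a == cand$scaffold_a[i] && m$scaffold_b == cand$scaffold_b[i] &&
          m$orientation == cand$orientation[i] &&
          cand$start_a[i] < m$end_a && cand$end_a[i] > m$start_a &&
          cand$start_b[i] < m$end_b && cand$end_b[i] > m$start_b) {
        m$start_a <- min(m$start_a, cand$start_a[i])
        m$end_a <- max(m$end_a, cand$end_a[i])
        m$start_b <- min(m$start_b, cand$start_b[i])
        m$end_b <- max(m$end_b, cand$end_b[i])
        merged[[j]] <- m
        placed <- TRUE
        break
      }
    }
    if (!placed) merged[[length(merged) + 1L]] <- as.list(cand[i, ])
  }
  blocks <- list()
  for (m in merged) {
    la <- nchar(genome[[m$scaffold_a]]); lb <- nchar(genome[[m$scaffold_b]])
    fa <- c(max(m$start_a - flank, 0L), min(m$end_a + flank, la))
    fb <- c(max(m$start_b - flank, 0L), min(m$end_b + flank, lb))
    a_seq <- substr(genome[[m$scaffold_a]], fa[1L] + 1L, fa[2L])
    b_seq <- substr(genome[[m$scaffold_b]], fb[1L] + 1L, fb[2L])
    if (m$orientation == "inverted") b_seq <- revcomp(b_seq)
    al <- align_candidate(a_seq, b_seq)
    ident <- al$matches / al$columns
    if (!(al$columns > min_len) || ident < min_identity) next
    a_iv <- c(fa[1L] + al$a_start, fa[1L] + al$a_end)
    b_iv <- if (m$orientation == "same") {
      c(fb[1L] + al$b_start, fb[1L] + al$b_end)
    } else {
      c(fb[2L] - al$b_end, fb[2L] - al$b_start)
    }
    # non-self: drop blocks whose two intervals overlap
    if (m$scaffold_a == m$scaffold_b &&
        a_iv[1L] < b_iv[2L] && b_iv[1L] < a_iv[2L]) next
    blocks[[length(blocks) + 1L]] <- data.frame(
      scaffold_a = m$scaffold_a, start_a = a_iv[1L], end_a = a_iv[2L],
      scaffold_b = m$scaffold_b, start_b = b_iv[1L], end_b = b_iv[2L],
      orientation = m$orientation, identity = ident,
      aligned_length = al$columns, stringsAsFactors = FALSE)
  }
  if (!length(blocks)) return(empty)
  out <- do.call(rbind, blocks)
  out <- out[!duplicated(out[, c("scaffold_a", "start_a", "end_a",
                                 "scaffold_b", "start_b", "end_b")]), , drop = FALSE]
  out <- out[order(out$scaffold_a, out$start_a, out$scaffold_b, out$start_b), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Duplicated fraction of the genome
#'
#' Counts genomic positions covered by at least one block side (union, no
#' double counting).
#'
#' @param blocks Output of [find_dup_blocks()].
#' @param genome Named character vector.
#' @param repeat_mask data.frame of repeat intervals.
#' @param include_repeats If `FALSE`, masked positions covered by blocks are
#'   excluded from the count.
#' @return List: `nt` (covered positions) and `fraction` (of total genome
#'   length).
#' @export
duplicated_fraction <- function(blocks, genome, repeat_mask = NULL,
                                include_repeats = TRUE) {
  total <- sum(nchar(genome))
  if (nrow(blocks) == 0L) return(list(nt = 0L, fraction = 0))
  iv <- rbind(
    data.frame(scaffold = blocks$scaffold_a, start = blocks$start_a,
               end = blocks$end_a, strand = "."),
    data.frame(scaffold = blocks$scaffold_b, start = blocks$start_b,
               end = blocks$end_b, strand = "."))
  cov <- merge_intervals(iv)
  nt <- sum(cov$end - cov$start)
  if (!include_repeats && !is.null(repeat_mask) && nrow(repeat_mask) > 0L) {
    nt <- nt - sum(masked_overlap_nt(cov, merge_intervals(repeat_mask)))
  }
  list(nt = as.integer(nt), fraction = nt / total)
}

#' Write duplication blocks as a paired-interval TSV
#' @param blocks Output of [find_dup_blocks()].
#' @param path Output path.
#' @param header Optional header lines.
#' @export
write_dup_blocks_tsv <- function(blocks, path, header = character()) {
  writeLines(c(header,
               "scaffold_a\tstart_a\tend_a\tscaffold_b\tstart_b\tend_b\torientation\tidentity\taligned_length",
               sprintf("%s\t%d\t%d\t%s\t%d\t%d\t%s\t%.4f\t%d",
                       blocks$scaffold_a, blocks$start_a, blocks$end_a,
                       blocks$scaffold_b, blocks$start_b, blocks$end_b,
                       blocks$orientation, blocks$identity,
                       blocks$aligned_length)),
             path)
  invisible(path)
}
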