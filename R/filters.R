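# Expression-based transcript filters: antisense discarding (lower-expressed
# strand of an exon-overlapping opposite-strand pair is dropped when the read
# count differs at least `ratio_threshold`-fold) and removal of lowly
# expressed novel transcripts that lack support from a trusted reference.

# Exonic overlap (nt) between opposite-strand TU pairs on the same scaffold.
antisense_overlap_pairs <- function(tus) {
  ex <- tus$exons
  empty <- data.frame(sense_id = character(), antisense_id = character(),
                      exonic_overlap_nt = integer(), stringsAsFactors = FALSE)
  if (nrow(ex) == 0L) return(empty)
  gr <- intervals_to_granges(ex)
  hits <- GenomicRanges::findOverlaps(gr, gr, ignore.strand = TRUE)
  q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
  keep <- ex$tu_id[q] < ex$tu_id[s] & ex$strand[q] != ex$strand[s]
  q <- q[keep]; s <- s[keep]
  if (!length(q)) return(empty)
  w <- pmin(ex$end[q], ex$end[s]) - pmax(ex$start[q], ex$start[s])
  key <- paste(ex$tu_id[q], ex$tu_id[s], sep = "\r")
  agg <- tapply(w, key, sum)
  parts <- strsplit(names(agg), "\r", fixed = TRUE)
  out <- data.frame(sense_id = vapply(parts, `[`, "", 1L),
                    antisense_id = vapply(parts, `[`, "", 2L),
                    exonic_overlap_nt = as.integer(agg),
                    stringsAsFactors = FALSE)
  out[order(out$sense_id, out$antisense_id), , drop = FALSE]
}

#' Filter antisense transcripts by strand-specific read count ratio
#'
#' For each pair of exon-overlapping transcripts on opposite strands of the
#' same genomic coordinates, where the overlap covers at least
#' `min_overlap_frac` of the lower-expressed transcript's exonic length: if
#' the read count ratio (higher/lower) is at least `ratio_threshold`
#' ("at least fivefold" by default, inclusive), the lower-count transcript
#' is discarded. A zero count against a positive count is treated as an
#' infinite ratio; a transcript discarded through one pair cannot rescue
#' another (decisions use the original counts).
#'
#' @param tus A [tu_set].
#' @param read_counts Named numeric vector: strand-specific exonic read
#'   count per `tu_id` (e.g. read 5' ends within exons, strand-matched).
#' @param ratio_threshold Fold-difference threshold (> 1), default 5.
#' @param min_overlap_frac Minimum overlap fraction of the lower-expressed
#'   transcript's exonic length, default 0.5.
#' @return List: `kept` and `discarded` [tu_set]s plus a `report`
#'   data.frame of evaluated pairs.
#' @export
filter_antisense <- function(tus, read_counts, ratio_threshold = 5,
                             min_overlap_frac = 0.5) {
  stopifnot(ratio_threshold > 1)
  ids <- tus$transcripts$tu_id
  missing <- setdiff(ids, names(read_counts))
  if (length(missing)) {
    stop("missing read count for TU(s): ", paste(missing, collapse = ", "))
  }
  exonic_len <- tapply(tus$exons$end - tus$exons$start, tus$exons$tu_id, sum)
  pairs <- antisense_overlap_pairs(tus)
  report <- data.frame(sense_id = character(), antisense_id = character(),
                       exonic_overlap_nt = integer(), count_a = numeric(),
                       count_b = numeric(), ratio = numeric(),
                       discarded = character(), stringsAsFactors = FALSE)
  discard <- character()
  for (i in seq_len(nrow(pairs))) {
    a <- pairs$sense_id[i]; b <- pairs$antisense_id[i]
    ca <- read_counts[[a]]; cb <- read_counts[[b]]
    lower_id <- if (ca <= cb) a else b
    lo <- min(ca, cb); hi <- max(ca, cb)
    frac <- pairs$exonic_overlap_nt[i] / exonic_len[[lower_id]]
    if (frac < min_overlap_frac) next
    ratio <- if (lo == 0) { if (hi == 0) NA_real_ else Inf } else hi / lo
    kill <- !is.na(ratio) && ratio >= ratio_threshold
    if (kill) discard <- union(discard, lower_id)
    report <- rbind(report, data.frame(
      sense_id = a, antisense_id = b,
      exonic_overlap_nt = pairs$exonic_overlap_nt[i],
      count_a = ca, count_b = cb, ratio = ratio,
      discarded = if (kill) lower_id else "", stringsAsFactors = FALSE))
  }
  keep <- !(ids %in% discard)
  list(kept = subset_tu_set(tus, ids[keep]),
       discarded = subset_tu_set(tus, ids[!keep]),
       report = report)
}

#' Filter lowly expressed novel transcripts
#'
#' A TU is discarded iff its expression is below `rpkm_min` AND it does not
#' overlap the trusted reference (strict `<`, conjunction of both
#' conditions).
#'
#' @param tus A [tu_set] with `rpkm` populated.
#' @param reference_overlaps Character vector of `tu_id`s overlapping a
#'   trusted reference mapping.
#' @param rpkm_min Expression threshold, default 0.5.
#' @return List: `kept` and `discarded` [tu_set]s.
#' @export
filter_low_expression_novel <- function(tus, reference_overlaps,
                                        rpkm_min = 0.5) {
  tr <- tus$transcripts
  if (anyNA(tr$rpkm)) {
    stop("TU(s) without expression_rpkm: ",
         paste(tr$tu_id[is.na(tr$rpkm)], collapse = ", "))
  }
  drop <- tr$rpkm < rpkm_min & !(tr$tu_id %in% reference_overlaps)
  list(kept = subset_tu_set(tus, tr$tu_id[!drop]),
       discarded = subset_tu_set(tus, tr$tu_id[drop]))
}

#' Subset a tu_set by transcript identifiers
#' @param tus A [tu_set].
#' @param ids `tu_id`s to keep.
#' @return A [tu_set].
#' @export
subset_tu_set <- function(tus, ids) {
  tr <- tus$transcripts[tus$transcripts$tu_id %in% ids, , drop = FALSE]
  ex <- tus$exons[tus$exons$tu_id %in% ids, , drop = FALSE]
  if (nrow(tr) == 0L) {
    return(structure(list(transcripts = tr, exons = ex), class = "tu_set"))
  }
  tu_set(tr, ex)
}

#' Count strand-matched read 5' ends within TU exons
#'
#' @param tus A [tu_set].
#' @param placements data.frame `scaffold, pos, strand` of read 5' ends.
#' @return Named numeric vector of counts per `tu_id` (zero-filled).
#' @export
count_reads_in_exons <- function(tus, placements) {
  counts <- stats::setNames(numeric(nrow(tus$transcripts)),
                            tus$transcripts$tu_id)
  if (nrow(placements) == 0L || nrow(tus$exons) == 0L) return(counts)
  ex_gr <- intervals_to_granges(tus$exons)
  pl_gr <- GenomicRanges::GRanges(placements$scaffold,
    IRanges::IRanges(placements$pos + 1L, placements$pos + 1L),
    strand = placements$strand)
  hits <- GenomicRanges::findOverlaps(pl_gr, ex_gr, ignore.strand = FALSE)
  tu_of_hit <- tus$exons$tu_id[S4Vectors::subjectHits(hits)]
  # a read counted once per TU even if exon bookkeeping overlapped
  dedup <- !duplicated(paste(S4Vectors::queryHits(hits), tu_of_hit))
  tab <- table(tu_of_hit[dedup])
  counts[names(tab)] <- as.numeric(tab)
  counts
}
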