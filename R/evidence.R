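# Evidence extraction: spliced-leader (SL) tagged 5' read ends and poly(A)
# 3' read ends, their strand-specific pileup tracks, and peak calling.
#
# SL trans-splicing attaches a short leader RNA to the 5' end of mature
# mRNAs; a read whose prefix matches a 3' suffix of the leader therefore
# pinpoints a trans-splice acceptor site once the leader-derived prefix is
# trimmed. T-fill 3'-end reads stop immediately upstream of the poly(A)
# tail and pinpoint cleavage/polyadenylation sites.

#' Detect and trim spliced-leader prefixes from reads
#'
#' A read is tagged `SL` iff some 3' suffix of the leader, of length at
#' least `min_match`, matches the read prefix with at most `max_mismatch`
#' mismatches. The longest qualifying suffix is trimmed. Reads shorter than
#' `min_remaining` after trimming are demoted to `NONE` (too short to place
#' on the genome reliably).
#'
#' @param reads Named character vector of read sequences (or a FASTQ path).
#' @param sl_leader The spliced-leader sequence, 5'->3'.
#' @param min_match Minimum matched suffix length (>= 8).
#' @param max_mismatch Maximum mismatches tolerated in the match.
#' @param min_remaining Minimum remaining read length after trimming.
#' @return data.frame `read_id, sequence, trimmed_prefix_len, evidence_kind`
#'   where `sequence` is the trimmed sequence for `SL` reads.
#' @export
detect_and_trim_sl <- function(reads, sl_leader, min_match = 10L,
                               max_mismatch = 1L, min_remaining = 20L) {
  if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
    reads <- read_fastq(reads)
  }
  sl_leader <- toupper(sl_leader)
  if (nchar(sl_leader) == 0L) stop("empty SL leader")
  if (min_match < 1L) stop("min_match must be >= 1")
  if (nchar(sl_leader) < min_match) stop("sl_leader shorter than min_match")
  llen <- nchar(sl_leader)
  out <- data.frame(read_id = names(reads), sequence = unname(reads),
                    trimmed_prefix_len = 0L, evidence_kind = "NONE",
                    stringsAsFactors = FALSE)
  for (i in seq_along(reads)) {
    r <- reads[[i]]
    best <- 0L
    maxm <- min(llen, nchar(r) - 1L)
    if (maxm >= min_match) {
      for (m in maxm:min_match) {  # longest qualifying suffix wins
        suf <- substr(sl_leader, llen - m + 1L, llen)
        pre <- substr(r, 1L, m)
        mm <- sum(utf8ToInt(suf) != utf8ToInt(pre))
        if (mm <= max_mismatch) { best <- m; break }
      }
    }
    if (best >= min_match && nchar(r) - best >= min_remaining) {
      out$trimmed_prefix_len[i] <- best
      out$sequence[i] <- substr(r, best + 1L, nchar(r))
      out$evidence_kind[i] <- "SL"
    }
  }
  out
}

#' Detect and trim poly(A) tails from reads
#'
#' Removes the longest read suffix that starts and ends with `A` and
#' contains at most `max_non_a` non-A interruptions. The read is tagged
#' `POLYA` if the removed run contains at least `min_a_run` A's, or if it
#' arrives pre-tagged as a T-fill 3'-end read (such reads end exactly at
#' the base upstream of the tail and need not carry any A's).
#'
#' @param reads Named character vector (or FASTQ path).
#' @param min_a_run Minimum number of A's in the trimmed tail (>= 5).
#' @param max_non_a Maximum non-A interruptions tolerated inside the tail.
#' @param pretagged Logical vector (or character vector of read ids) marking
#'   T-fill reads that are 3' evidence regardless of an A-run.
#' @return data.frame `read_id, sequence, trimmed_prefix_len, evidence_kind`
#'   (`trimmed_prefix_len` holds the trimmed tail length for `POLYA` reads).
#' @export
detect_polya_tail <- function(reads, min_a_run = 5L, max_non_a = 1L,
                              pretagged = FALSE) {
  if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
    reads <- read_fastq(reads)
  }
  if (min_a_run < 5L) stop("min_a_run must be >= 5")
  if (is.character(pretagged)) pretagged <- names(reads) %in% pretagged
  pretagged <- rep_len(pretagged, length(reads))
  out <- data.frame(read_id = names(reads), sequence = unname(reads),
                    trimmed_prefix_len = 0L, evidence_kind = "NONE",
                    stringsAsFactors = FALSE)
  for (i in seq_along(reads)) {
    ch <- rev(strsplit(reads[[i]], "")[[1L]])
    non_a <- cumsum(ch != "A")
    ok <- which(non_a <= max_non_a & ch == "A")  # suffix ends (5'-most char) at an A
    trim <- if (length(ok)) max(ok) else 0L
    n_a <- if (trim > 0L) trim - non_a[trim] else 0L
    if (n_a >= min_a_run) {
      out$trimmed_prefix_len[i] <- trim
      out$sequence[i] <- substr(reads[[i]], 1L, nchar(reads[[i]]) - trim)
      out$evidence_kind[i] <- "POLYA"
    } else if (pretagged[i]) {
      out$evidence_kind[i] <- "POLYA"
    }
  }
  out
}

#' Pile up biological end positions into a strand-specific signal track
#'
#' For SL evidence the recorded position is the first transcribed base (the
#' read 5' end after leader trimming, strand-aware); for poly(A) evidence it
#' is the last transcribed base before the tail.
#'
#' @param placements data.frame `scaffold, pos, strand` (0-based base
#'   positions), one row per read end.
#' @param kind `"SL"` or `"POLYA"`.
#' @param genome Optional genome (named character vector) for bounds checks.
#' @return A track: data.frame `scaffold, strand, pos, count` with attribute
#'   `kind`; all counts >= 1.
#' @export
pileup_end_positions <- function(placements, kind = c("SL", "POLYA"),
                                 genome = NULL) {
  kind <- match.arg(kind)
  if (nrow(placements) == 0L) {
    tr <- data.frame(scaffold = character(), strand = character(),
                     pos = integer(), count = integer())
    attr(tr, "kind") <- kind
    return(tr)
  }
  if (!all(placements$strand %in% c("+", "-"))) {
    stop("placements must be stranded (+/-)")
  }
  if (!is.null(genome)) {
    len <- nchar(genome)[placements$scaffold]
    if (anyNA(len)) stop("placement on unknown scaffold")
    if (any(placements$pos < 0L | placements$pos >= len)) {
      stop("placement position outside scaffold bounds")
    }
  }
  key <- paste(placements$scaffold, placements$strand, placements$pos, sep = "\r")
  tab <- table(key)
  parts <- strsplit(names(tab), "\r", fixed = TRUE)
  tr <- data.frame(
    scaffold = vapply(parts, `[`, "", 1L),
    strand = vapply(parts, `[`, "", 2L),
    pos = as.integer(vapply(parts, `[`, "", 3L)),
    count = as.integer(tab),
    stringsAsFactors = FALSE
  )
  tr <- tr[order(tr$scaffold, tr$strand, tr$pos), , drop = FALSE]
  rownames(tr) <- NULL
  attr(tr, "kind") <- kind
  tr
}

#' Read end placements from a SAM/BAM or BED file
#'
#' SAM alignments: strand comes from the flag; the SL position is the
#' leftmost aligned base on `+` and the rightmost aligned base on `-`
#' (soft-clipped bases are ignored; positions are taken from aligned bases
#' only). For `POLYA` the convention is mirrored (rightmost aligned base on
#' `+`). BED input (6 columns) uses `start` on `+` and `end - 1` on `-` for
#' SL, and the mirror for POLYA.
#'
#' @param path SAM, BAM or BED file.
#' @param kind `"SL"` or `"POLYA"`.
#' @return data.frame `scaffold, pos, strand`.
#' @export
read_placements <- function(path, kind = c("SL", "POLYA")) {
  kind <- match.arg(kind)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("sam", "bam")) {
    bam <- if (ext == "sam") {
      Rsamtools::asBam(path, tempfile(), overwrite = TRUE, indexDestination = FALSE)
    } else path
    aln <- GenomicAlignments::readGAlignments(bam)
    scaffold <- as.character(GenomicAlignments::seqnames(aln))
    strand <- as.character(GenomicAlignments::strand(aln))
    left <- GenomicAlignments::start(aln) - 1L
    right <- GenomicAlignments::end(aln) - 1L
    five_prime <- ifelse(strand == "+", left, right)
    three_prime <- ifelse(strand == "+", right, left)
    pos <- if (kind == "SL") five_prime else three_prime
    return(data.frame(scaffold = scaffold, pos = as.integer(pos),
                      strand = strand, stringsAsFactors = FALSE))
  }
  bed <- read_bed(path)
  if (any(bed$strand == ".")) stop("BED placements must be stranded")
  five_prime <- ifelse(bed$strand == "+", bed$start, bed$end - 1L)
  three_prime <- ifelse(bed$strand == "+", bed$end - 1L, bed$start)
  data.frame(scaffold = bed$scaffold,
             pos = as.integer(if (kind == "SL") five_prime else three_prime),
             strand = bed$strand, stringsAsFactors = FALSE)
}

#' Call evidence peaks on a signal track
#'
#' Per (scaffold, strand), positions with signal are grouped into runs where
#' consecutive positions are at most `merge_distance` apart; a group becomes
#' a peak iff its total count is at least `min_site_count`. The summit is the
#' highest-count position; ties break toward the transcript 5' direction
#' (genomic left on `+`, right on `-`), which yields the longest mature mRNA.
#'
#' @param track A track from [pileup_end_positions()].
#' @param min_site_count Minimum total read count per peak (>= 1).
#' @param merge_distance Maximum gap between member positions (>= 0).
#' @return data.frame `kind, scaffold, start, end, strand, summit,
#'   total_count` (0-based half-open span over member positions).
#' @export
call_peaks <- function(track, min_site_count = 5L, merge_distance = 10L) {
  stopifnot(min_site_count >= 1L, merge_distance >= 0L)
  kind <- attr(track, "kind")
  if (is.null(kind)) kind <- "SL"
  empty <- data.frame(kind = character(), scaffold = character(),
                      start = integer(), end = integer(), strand = character(),
                      summit = integer(), total_count = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(track) == 0L) return(empty)
  res <- list()
  for (grp in split(track, paste(track$scaffold, track$strand))) {
    grp <- grp[order(grp$pos), , drop = FALSE]
    brk <- cumsum(c(0L, diff(grp$pos) > merge_distance))
    for (run in split(grp, brk)) {
      total <- sum(run$count)
      if (total < min_site_count) next
      mx <- run$pos[run$count == max(run$count)]
      summit <- if (run$strand[1L] == "+") min(mx) else max(mx)
      res[[length(res) + 1L]] <- data.frame(
        kind = kind, scaffold = run$scaffold[1L], start = min(run$pos),
        end = max(run$pos) + 1L, strand = run$strand[1L],
        summit = summit, total_count = total, stringsAsFactors = FALSE)
    }
  }
  if (!length(res)) return(empty)
  out <- do.call(rbind, res)
  out <- out[order(out$scaffold, out$strand, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Reads per kilobase of transcript per million mapped reads
#'
#' @param read_count Number of reads assigned to the transcript.
#' @param transcript_length_nt Transcript (exonic) length in nt (>= 1).
#' @param total_mapped_reads Library size (>= 1).
#' @return `read_count * 1e9 / (transcript_length_nt * total_mapped_reads)`.
#' @export
compute_rpkm <- function(read_count, transcript_length_nt, total_mapped_reads) {
  if (any(transcript_length_nt < 1L)) stop("transcript_length_nt must be >= 1")
  if (any(total_mapped_reads < 1L)) stop("total_mapped_reads must be >= 1")
  read_count * 1e9 / (transcript_length_nt * total_mapped_reads)
}

#' Write a signal track as a per-strand pair of bedGraph files
#' @param track A track from [pileup_end_positions()].
#' @param prefix Output prefix; files `<prefix>.plus.bedgraph` and
#'   `<prefix>.minus.bedgraph` are written.
#' @param header Optional header lines.
#' @return Character vector of the two paths.
#' @export
write_track_bedgraph <- function(track, prefix, header = character()) {
  paths <- c(paste0(prefix, ".plus.bedgraph"), paste0(prefix, ".minus.bedgraph"))
  for (i in 1:2) {
    s <- c("+", "-")[i]
    sub <- track[track$strand == s, , drop = FALSE]
    write_bedgraph(data.frame(scaffold = sub$scaffold, start = sub$pos,
                              end = sub$pos + 1L, count = sub$count),
                   paths[i], header = header)
  }
  paths
}

#' Read a per-strand bedGraph pair back into a signal track
#' @param prefix Prefix used by [write_track_bedgraph()].
#' @param kind Track kind.
#' @return A track data.frame.
#' @export
read_track_bedgraph <- function(prefix, kind = c("SL", "POLYA")) {
  kind <- match.arg(kind)
  out <- list()
  for (i in 1:2) {
    s <- c("+", "-")[i]
    path <- paste0(prefix, c(".plus.bedgraph", ".minus.bedgraph")[i])
    if (!file.exists(path)) next
    bg <- read_bedgraph(path)
    if (nrow(bg) == 0L) next
    # expand multi-base intervals to unit positions
    reps <- bg$end - bg$start
    out[[i]] <- data.frame(
      scaffold = rep(bg$scaffold, reps), strand = s,
      pos = unlist(mapply(seq, bg$start, bg$end - 1L, SIMPLIFY = FALSE)),
      count = rep(as.integer(bg$count), reps), stringsAsFactors = FALSE)
  }
  tr <- do.call(rbind, out)
  if (is.null(tr)) tr <- data.frame(scaffold = character(), strand = character(),
                                    pos = integer(), count = integer())
  tr <- tr[order(tr$scaffold, tr$strand, tr$pos), , drop = FALSE]
  rownames(tr) <- NULL
  attr(tr, "kind") <- kind
  tr
}

#' Write evidence peaks as BED6 (score = total_count, name = kind)
#' @param peaks Peaks from [call_peaks()].
#' @param path Output path.
#' @param header Optional header lines.
#' @export
write_peaks_bed <- function(peaks, path, header = character()) {
  write_bed(data.frame(scaffold = peaks$scaffold, start = peaks$start,
                       end = peaks$end,
                       name = sprintf("%s:%d", peaks$kind, peaks$summit),
                       score = peaks$total_count, strand = peaks$strand),
            path, header = header)
}

#' Read peaks written by [write_peaks_bed()]
#' @param path BED6 path.
#' @return Peaks data.frame.
#' @export
read_peaks_bed <- function(path) {
  bed <- read_bed(path)
  parts <- strsplit(bed$name, ":", fixed = TRUE)
  data.frame(kind = vapply(parts, `[`, "", 1L), scaffold = bed$scaffold,
             start = bed$start, end = bed$end, strand = bed$strand,
             summit = as.integer(vapply(parts, `[`, "", 2L)),
             total_count = as.integer(bed$score), stringsAsFactors = FALSE)
}
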