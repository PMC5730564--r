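# Internal coordinate convention: 0-based half-open [start, end) on the
# genomic forward axis. GTF I/O converts to/from 1-based inclusive; BED and
# bedGraph are natively 0-based half-open. This file is the only place where
# "oriented" (transcript 5'->3') coordinates are defined.

#' Construct a table of genomic intervals
#'
#' Builds the plain-data.frame interval representation used throughout the
#' package: 0-based half-open coordinates with strand in `+`, `-` or `.`
#' (`.` is permitted only for strand-agnostic features such as repeats and
#' duplication blocks).
#'
#' @param scaffold character vector of scaffold identifiers.
#' @param start,end integer vectors, 0-based half-open.
#' @param strand character vector in `c("+", "-", ".")`.
#' @return A `data.frame` with columns `scaffold`, `start`, `end`, `strand`.
#' @export
genomic_intervals <- function(scaffold, start, end, strand = ".") {
  df <- data.frame(
    scaffold = as.character(scaffold),
    start = as.integer(start),
    end = as.integer(end),
    strand = as.character(strand),
    stringsAsFactors = FALSE
  )
  validate_intervals(df)
  df
}

validate_intervals <- function(df, genome = NULL, allow_unstranded = TRUE) {
  stopifnot(all(c("scaffold", "start", "end", "strand") %in% names(df)))
  bad <- df$start < 0L | df$end <= df$start
  if (any(bad)) {
    stop("invalid interval(s): start must satisfy 0 <= start < end (rows ",
         paste(utils::head(which(bad), 5), collapse = ", "), ")")
  }
  ok_strand <- df$strand %in% (if (allow_unstranded) c("+", "-", ".") else c("+", "-"))
  if (!all(ok_strand)) {
    stop("invalid strand value(s): ",
         paste(unique(df$strand[!ok_strand]), collapse = ", "))
  }
  if (!is.null(genome)) {
    len <- nchar(genome)[df$scaffold]
    if (anyNA(len)) {
      stop("interval(s) on scaffold(s) absent from genome: ",
           paste(unique(df$scaffold[is.na(len)]), collapse = ", "))
    }
    if (any(df$end > len)) {
      stop("interval(s) exceed scaffold length on: ",
           paste(unique(df$scaffold[df$end > len]), collapse = ", "))
    }
  }
  invisible(df)
}

# Oriented (transcript 5'->3') base coordinates: a genomic base p maps to p on
# '+' and to -p on '-', so oriented order always increases 5'->3'.
to_oriented <- function(pos, strand) {
  ifelse(rep_len(strand == "-", length(pos)), -pos, pos)
}
from_oriented <- function(opos, strand) {
  ifelse(rep_len(strand == "-", length(opos)), -opos, opos)
}

# Inclusive oriented base range of a half-open genomic interval.
interval_to_oriented <- function(start, end, strand) {
  if (strand == "-") cbind(lo = -(end - 1L), hi = -start)
  else cbind(lo = start, hi = end - 1L)
}

# Half-open genomic interval from inclusive oriented base range.
oriented_to_interval <- function(lo, hi, strand) {
  if (strand == "-") cbind(start = -hi, end = -lo + 1L)
  else cbind(start = lo, end = hi + 1L)
}

intervals_to_granges <- function(df, ignore_strand = FALSE) {
  GenomicRanges::GRanges(
    seqnames = df$scaffold,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = if (ignore_strand) "*" else ifelse(df$strand == ".", "*", df$strand)
  )
}

# Merge (union) a strand-agnostic interval set; returns normalized data.frame.
merge_intervals <- function(df) {
  if (nrow(df) == 0L) {
    return(data.frame(scaffold = character(), start = integer(),
                      end = integer(), strand = character(),
                      stringsAsFactors = FALSE))
  }
  gr <- GenomicRanges::reduce(intervals_to_granges(df, ignore_strand = TRUE))
  out <- data.frame(
    scaffold = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = ".",
    stringsAsFactors = FALSE
  )
  out[order(out$scaffold, out$start, out$end), , drop = FALSE]
}

# Total number of genomic positions of `df` covered by the merged set `mask`.
masked_overlap_nt <- function(df, mask) {
  if (nrow(df) == 0L || nrow(mask) == 0L) return(integer(nrow(df)))
  a <- intervals_to_granges(df, ignore_strand = TRUE)
  b <- intervals_to_granges(mask, ignore_strand = TRUE)
  hits <- GenomicRanges::findOverlaps(a, b)
  w <- IRanges::width(IRanges::pintersect(
    IRanges::ranges(a)[S4Vectors::queryHits(hits)],
    IRanges::ranges(b)[S4Vectors::subjectHits(hits)]
  ))
  out <- integer(nrow(df))
  if (length(hits)) {
    agg <- tapply(w, S4Vectors::queryHits(hits), sum)
    out[as.integer(names(agg))] <- as.integer(agg)
  }
  out
}

sort_interval_df <- function(df, id_col = NULL) {
  keys <- list(df$scaffold, df$start, df$end)
  if (!is.null(id_col)) keys <- c(keys, list(df[[id_col]]))
  df[do.call(order, keys), , drop = FALSE]
}
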