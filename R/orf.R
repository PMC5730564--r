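# Longest-ORF calling on mature transcript sequences (forward frames only:
# gene models are stranded), and ORF/poly(A)-aware merging of transcripts
# split across repetitive genomic gaps: an upstream gene with an ORF but no
# poly(A) evidence followed by a gene with poly(A) evidence but no ORF is a
# candidate broken gene if the gap is small and repeat-covered.

STOP_CODONS <- c("TAA", "TAG", "TGA")

codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc) <- chartr("U", "T", names(gc))
  gc
}

translate_cds <- function(seq) {
  n <- (nchar(seq) %/% 3L) * 3L
  if (n == 0L) return("")
  codons <- substring(seq, seq(1L, n, 3L), seq(3L, n, 3L))
  aa <- codon_table()[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Find the longest open reading frame in a transcript sequence
#'
#' Scans the three forward frames. A candidate runs from an `ATG` to the
#' first in-frame stop (complete) or to the end of the last full codon if no
#' stop follows (incomplete). The longest candidate with protein length at
#' least `min_aa` is returned; ties break to the 5'-most start.
#'
#' @param seq Transcript sequence, 5'->3'.
#' @param min_aa Minimum protein length in amino acids (default 100, the
#'   conventional minimum for coding-potential calling).
#' @return `NULL`, or a list `start, end` (0-based half-open transcript
#'   offsets; `end` includes the stop codon when complete), `frame`,
#'   `protein` (no stop symbol), `complete`.
#' @export
find_longest_orf <- function(seq, min_aa = 100L) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n < 3L) return(NULL)
  best <- NULL
  for (frame in 0:2) {
    m <- ((n - frame) %/% 3L) * 3L
    if (m < 3L) next
    starts1 <- seq(frame + 1L, frame + m - 2L, 3L)
    codons <- substring(seq, starts1, starts1 + 2L)
    atg <- which(codons == "ATG")
    stp <- which(codons %in% STOP_CODONS)
    if (!length(atg)) next
    # earliest ATG ending at each stop gives the longest ORF for that stop;
    # plus one open-ended candidate after the last stop
    ns <- vapply(atg, function(a) {
      j <- stp[stp > a]
      if (length(j)) j[1L] else NA_integer_
    }, integer(1))
    for (i in seq_along(atg)) {
      a <- atg[i]
      if (i > 1L && identical(ns[i], ns[i - 1L])) next  # not 5'-most for this stop
      if (!is.na(ns[i])) {
        prot_len <- ns[i] - a
        complete <- TRUE
        end0 <- starts1[ns[i]] + 2L  # includes stop codon, 0-based half-open
      } else {
        prot_len <- length(codons) - a + 1L
        complete <- FALSE
        end0 <- starts1[length(codons)] + 2L
      }
      if (prot_len < min_aa) next
      start0 <- starts1[a] - 1L
      cand <- list(start = start0, end = end0, frame = frame,
                   prot_len = prot_len, complete = complete)
      if (is.null(best) || cand$prot_len > best$prot_len ||
          (cand$prot_len == best$prot_len && cand$start < best$start)) {
        best <- cand
      }
    }
  }
  if (is.null(best)) return(NULL)
  cds <- substr(seq, best$start + 1L, best$end)
  prot <- translate_cds(cds)
  if (best$complete) prot <- substr(prot, 1L, nchar(prot) - 1L)
  list(start = best$start, end = best$end, frame = best$frame,
       protein = prot, complete = best$complete)
}

#' Spliced transcript sequence of a gene model
#'
#' @param exons Exon rows (`scaffold,start,end,strand`) of one model.
#' @param genome Named character vector of scaffold sequences.
#' @return The mature transcript sequence, 5'->3'.
#' @export
transcript_sequence <- function(exons, genome) {
  exons <- exons[order(exons$start), , drop = FALSE]
  scaf <- genome[[exons$scaffold[1L]]]
  parts <- substring(scaf, exons$start + 1L, exons$end)
  s <- paste(parts, collapse = "")
  if (exons$strand[1L] == "-") {
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }
  s
}

#' Call ORFs for every gene in a gene_set
#'
#' @param genes A [gene_set].
#' @param genome Named character vector.
#' @param min_aa See [find_longest_orf()].
#' @return The [gene_set] with `orf_*` columns populated.
#' @export
call_orfs <- function(genes, genome, min_aa = 100L) {
  g <- genes$genes
  for (i in seq_len(nrow(g))) {
    ex <- genes$exons[genes$exons$gene_id == g$gene_id[i], , drop = FALSE]
    orf <- find_longest_orf(transcript_sequence(ex, genome), min_aa = min_aa)
    if (!is.null(orf)) {
      g$orf_start[i] <- orf$start; g$orf_end[i] <- orf$end
      g$orf_frame[i] <- orf$frame; g$orf_complete[i] <- orf$complete
      g$orf_protein[i] <- orf$protein
    } else {
      g$orf_start[i] <- NA_integer_; g$orf_end[i] <- NA_integer_
      g$orf_frame[i] <- NA_integer_; g$orf_complete[i] <- NA
      g$orf_protein[i] <- NA_character_
    }
  }
  gene_set(g, genes$exons)
}

#' Merge transcripts split across repetitive gaps
#'
#' For each adjacent same-strand pair (A 5' of B in transcript orientation):
#' merge iff A has an ORF, A lacks poly(A) evidence, B lacks an ORF, B has
#' poly(A) evidence, the genomic gap between A's 3' end and B's 5' start is
#' at most `max_gap`, and repeat coverage of the gap is at least
#' `min_repeat_frac`. The merged model takes the union span, the exons of
#' both (the gap becomes an intron), poly(A) from B, and its ORF is
#' re-called on the merged sequence. Merging is single-pass 5'->3'.
#'
#' @param genes A [gene_set] with ORFs called ([call_orfs()]).
#' @param genome Named character vector (for ORF re-calling).
#' @param repeat_mask data.frame of repeat intervals (merged or not).
#' @param max_gap Maximum gap in nt, default 10000.
#' @param min_repeat_frac Minimum repeat coverage of the gap, default 0.5.
#' @param min_aa Passed to [find_longest_orf()] when re-calling.
#' @return List: merged [gene_set] (`genes`), and `report` of merges.
#' @export
merge_split_transcripts <- function(genes, genome, repeat_mask,
                                    max_gap = 10000L, min_repeat_frac = 0.5,
                                    min_aa = 100L) {
  mask <- merge_intervals(repeat_mask)
  g <- genes$genes
  ex <- genes$exons
  report <- data.frame(upstream_id = character(), downstream_id = character(),
                       gap_nt = integer(), repeat_frac = numeric(),
                       stringsAsFactors = FALSE)
  out_rows <- list(); out_ex <- list()
  for (key in unique(paste(g$scaffold, g$strand))) {
    sub <- g[paste(g$scaffold, g$strand) == key, , drop = FALSE]
    strand <- sub$strand[1L]
    # transcript orientation: ascending oriented 5' coordinate
    o5 <- to_oriented(if (strand == "+") sub$start else sub$end - 1L, strand)
    sub <- sub[order(o5), , drop = FALSE]
    if (nrow(sub) > 1L) {
      ss <- sub[order(sub$start), , drop = FALSE]
      ov <- ss$start[-1L] < ss$end[-nrow(ss)]
      if (any(ov)) stop("overlapping gene models on one strand: ",
                        paste(ss$gene_id[which(ov) + 1L], collapse = ", "))
    }
    cur <- sub[1L, ]
    cur_ex <- ex[ex$gene_id == cur$gene_id, , drop = FALSE]
    i <- 2L
    while (i <= nrow(sub) + 1L) {
      if (i > nrow(sub)) break
      nxt <- sub[i, ]
      nxt_ex <- ex[ex$gene_id == nxt$gene_id, , drop = FALSE]
      gap_iv <- if (strand == "+") c(cur$end, nxt$start) else c(nxt$end, cur$start)
      gap_nt <- gap_iv[2L] - gap_iv[1L]
      rep_frac <- if (gap_nt <= 0L) 1 else {
        gap_df <- data.frame(scaffold = cur$scaffold, start = gap_iv[1L],
                             end = gap_iv[2L], strand = ".")
        masked_overlap_nt(gap_df, mask) / gap_nt
      }
      do_merge <- !is.na(cur$orf_start) && !cur$has_polya_3p &&
        is.na(nxt$orf_start) && nxt$has_polya_3p &&
        gap_nt <= max_gap && rep_frac >= min_repeat_frac
      if (do_merge) {
        report <- rbind(report, data.frame(
          upstream_id = cur$gene_id, downstream_id = nxt$gene_id,
          gap_nt = gap_nt, repeat_frac = rep_frac, stringsAsFactors = FALSE))
        cur$start <- min(cur$start, nxt$start)
        cur$end <- max(cur$end, nxt$end)
        cur$has_polya_3p <- TRUE
        cur$polya_summit <- nxt$polya_summit
        cur_ex <- rbind(cur_ex, transform(nxt_ex, gene_id = cur$gene_id))
        cur_ex <- cur_ex[order(cur_ex$start), , drop = FALSE]
        orf <- find_longest_orf(transcript_sequence(cur_ex, genome), min_aa = min_aa)
        if (!is.null(orf)) {
          cur$orf_start <- orf$start; cur$orf_end <- orf$end
          cur$orf_frame <- orf$frame; cur$orf_complete <- orf$complete
          cur$orf_protein <- orf$protein
        } else {
          cur$orf_start <- NA_integer_; cur$orf_end <- NA_integer_
          cur$orf_frame <- NA_integer_; cur$orf_complete <- NA
          cur$orf_protein <- NA_character_
        }
      } else {
        out_rows[[length(out_rows) + 1L]] <- cur
        out_ex[[length(out_ex) + 1L]] <- cur_ex
        cur <- nxt; cur_ex <- nxt_ex
      }
      i <- i + 1L
    }
    out_rows[[length(out_rows) + 1L]] <- cur
    out_ex[[length(out_ex) + 1L]] <- cur_ex
  }
  g2 <- do.call(rbind, out_rows)
  e2 <- do.call(rbind, out_ex)
  g2 <- g2[order(g2$scaffold, g2$start, g2$gene_id), , drop = FALSE]
  e2 <- e2[order(match(e2$gene_id, g2$gene_id), e2$start), , drop = FALSE]
  list(genes = gene_set(g2, e2), report = report)
}
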