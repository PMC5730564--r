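# The cutter: overlap SL / poly(A) evidence peaks with transcriptional units
# and establish mature-mRNA gene boundaries. A TU with k SL summits is
# partitioned into k genes (plus, possibly, an unspliced 5' leader segment);
# each gene's 3' end is the strongest poly(A) summit strictly inside its
# segment, falling back to the position immediately 5' of the next SL site
# (or the TU 3' end) when no poly(A) evidence is present.

#' Construct a gene-model set
#'
#' Mature-mRNA-level records produced by cutting. `genes` has one row per
#' gene (`gene_id`, `parent_tu_id`, `scaffold`, `start`, `end`, `strand`,
#' `has_sl_5p`, `has_polya_3p`, `sl_summit`, `polya_summit`,
#' `classification`, plus optional ORF columns); `exons` mirrors the
#' [tu_set] layout with `gene_id` keys.
#'
#' @param genes,exons data.frames as described.
#' @return An object of class `gene_set`.
#' @export
gene_set <- function(genes, exons) {
  genes$start <- as.integer(genes$start)
  genes$end <- as.integer(genes$end)
  exons$start <- as.integer(exons$start)
  exons$end <- as.integer(exons$end)
  validate_intervals(genes, allow_unstranded = FALSE)
  validate_intervals(exons, allow_unstranded = FALSE)
  orf_cols <- c("orf_start", "orf_end", "orf_frame", "orf_complete", "orf_protein")
  for (cc in orf_cols) if (!cc %in% names(genes)) {
    genes[[cc]] <- if (cc == "orf_complete") NA else
      if (cc == "orf_protein") NA_character_ else NA_integer_
  }
  rownames(genes) <- NULL
  rownames(exons) <- NULL
  structure(list(genes = genes, exons = exons), class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat("gene_set:", nrow(x$genes), "gene models on",
      length(unique(x$genes$parent_tu_id)), "parent TUs\n")
  invisible(x)
}

#' Assign evidence peaks to transcriptional units
#'
#' A peak is assigned to a TU iff its summit lies within the TU interval
#' extended by `end_slack` on both sides and the strands match. A peak whose
#' summit overlaps several TUs is assigned to each.
#'
#' @param tus A [tu_set].
#' @param peaks Peaks from [call_peaks()] (any mix of kinds).
#' @param end_slack Slack in nt around each TU span (default 50; SL evidence
#'   slightly upstream of an under-assembled 5' end extends rather than cuts).
#' @return data.frame `tu_id, peak` (row index into `peaks`), `kind`.
#' @export
assign_peaks_to_tu <- function(tus, peaks, end_slack = 50L) {
  empty <- data.frame(tu_id = character(), peak = integer(),
                      kind = character(), stringsAsFactors = FALSE)
  if (nrow(peaks) == 0L || nrow(tus$transcripts) == 0L) return(empty)
  tr <- tus$transcripts
  tu_gr <- GenomicRanges::GRanges(tr$scaffold,
    IRanges::IRanges(pmax(tr$start - end_slack, 0L) + 1L, tr$end + end_slack),
    strand = tr$strand)
  pk_gr <- GenomicRanges::GRanges(peaks$scaffold,
    IRanges::IRanges(peaks$summit + 1L, peaks$summit + 1L),
    strand = peaks$strand)
  hits <- GenomicRanges::findOverlaps(pk_gr, tu_gr, ignore.strand = FALSE)
  out <- data.frame(tu_id = tr$tu_id[S4Vectors::subjectHits(hits)],
                    peak = S4Vectors::queryHits(hits),
                    kind = peaks$kind[S4Vectors::queryHits(hits)],
                    stringsAsFactors = FALSE)
  out <- out[order(out$tu_id, out$peak), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Snap an oriented base position to the nearest exonic base in the given
# direction. ex_or: matrix of inclusive oriented exon ranges (ascending).
snap_to_exon <- function(opos, ex_or, direction = c("3p", "5p")) {
  direction <- match.arg(direction)
  inside <- any(opos >= ex_or[, "lo"] & opos <= ex_or[, "hi"])
  if (inside) return(opos)
  if (direction == "3p") {
    cand <- ex_or[ex_or[, "lo"] > opos, "lo"]
    if (length(cand)) min(cand) else NA_integer_
  } else {
    cand <- ex_or[ex_or[, "hi"] < opos, "hi"]
    if (length(cand)) max(cand) else NA_integer_
  }
}

#' Cut one transcriptional unit into gene models
#'
#' @param tu One-row data.frame from `tu_set$transcripts`.
#' @param exons Exon rows of this TU.
#' @param sl_peaks,polya_peaks Peak rows assigned to this TU (possibly empty).
#' @param min_gene_len Genes with clipped exonic length below this are
#'   dropped; an unspliced 5' leader segment must exceed it to be emitted.
#' @param end_slack Slack used during assignment (bounds 5'/3' extensions).
#' @return A [gene_set] for this TU (possibly zero rows).
#' @export
cut_tu <- function(tu, exons, sl_peaks, polya_peaks,
                   min_gene_len = 100L, end_slack = 50L) {
  strand <- tu$strand
  sl_peaks$summit <- as.integer(sl_peaks$summit)
  polya_peaks$summit <- as.integer(polya_peaks$summit)
  if ((nrow(sl_peaks) && any(sl_peaks$strand != strand)) ||
      (nrow(polya_peaks) && any(polya_peaks$strand != strand))) {
    stop("internal error: peak strand inconsistent with TU ", tu$tu_id)
  }
  exons <- exons[order(exons$start), , drop = FALSE]
  ex_or <- interval_to_oriented(exons$start, exons$end, strand)
  ex_or <- ex_or[order(ex_or[, "lo"]), , drop = FALSE]
  t5 <- ex_or[1L, "lo"]; t3 <- ex_or[nrow(ex_or), "hi"]

  # oriented summits; snap intronic evidence onto exons
  sl <- sort(unique(to_oriented(sl_peaks$summit, strand)))
  sl <- sl[sl >= t5 - end_slack & sl <= t3]
  sl <- vapply(sl, function(p) {
    if (p < t5) p else snap_to_exon(p, ex_or, "3p")
  }, integer(1))
  sl <- sort(unique(sl[!is.na(sl)]))

  pa_pos <- to_oriented(polya_peaks$summit, strand)
  pa_cnt <- polya_peaks$total_count
  keep <- pa_pos >= t5 & pa_pos <= t3 + end_slack
  pa_pos <- pa_pos[keep]; pa_cnt <- pa_cnt[keep]
  snapped <- vapply(pa_pos, function(p) {
    if (p > t3) p else snap_to_exon(p, ex_or, "5p")
  }, integer(1))
  pa_pos <- snapped[!is.na(snapped)]; pa_cnt <- pa_cnt[!is.na(snapped)]

  classification <- if (length(sl) == 0L) "NO_SL" else
    if (length(sl) == 1L) "SL_SINGLE" else "SL_MULTIPLE_PARENT"

  # segment table in oriented coords: (b5, next_bound, has_sl)
  segs <- list()
  if (length(sl) == 0L) {
    segs[[1L]] <- list(b5 = t5, nxt = NA_integer_, has_sl = FALSE, sl = NA_integer_,
                       pick_polya = FALSE)
  } else {
    if (sl[1L] > t5) {
      segs[[1L]] <- list(b5 = t5, nxt = sl[1L], has_sl = FALSE, sl = NA_integer_,
                         pick_polya = TRUE)
    }
    for (i in seq_along(sl)) {
      segs[[length(segs) + 1L]] <- list(
        b5 = sl[i], nxt = if (i < length(sl)) sl[i + 1L] else NA_integer_,
        has_sl = TRUE, sl = sl[i], pick_polya = TRUE)
    }
  }

  g_rows <- list(); e_rows <- list(); n <- 0L
  for (sg in segs) {
    if (sg$pick_polya) {
      hi <- if (is.na(sg$nxt)) t3 + end_slack else sg$nxt - 1L
      lo <- if (sg$has_sl) sg$b5 + 1L else sg$b5  # strictly after an SL summit
      in_seg <- pa_pos >= lo & pa_pos <= hi
      if (any(in_seg)) {
        cands <- pa_pos[in_seg]; cnts <- pa_cnt[in_seg]
        best <- cands[cnts == max(cnts)]
        b3 <- max(best)  # tie -> 3'-most (longest gene)
        has_pa <- TRUE
      } else {
        b3 <- if (is.na(sg$nxt)) t3 else sg$nxt - 1L
        has_pa <- FALSE
      }
    } else {
      b3 <- t3; has_pa <- FALSE
    }
    if (b3 < sg$b5) next
    # clip exons to [b5, b3]; SL/polyA evidence beyond the TU span extends
    # the terminal exons
    exx <- ex_or
    exx[1L, "lo"] <- min(exx[1L, "lo"], sg$b5)
    exx[nrow(exx), "hi"] <- max(exx[nrow(exx), "hi"], b3)
    lo_c <- pmax(exx[, "lo"], sg$b5); hi_c <- pmin(exx[, "hi"], b3)
    keep_ex <- lo_c <= hi_c
    lo_c <- lo_c[keep_ex]; hi_c <- hi_c[keep_ex]
    exonic_len <- sum(hi_c - lo_c + 1L)
    if (sg$has_sl || length(segs) > 1L) {
      if (sg$has_sl && exonic_len < min_gene_len) next
      if (!sg$has_sl && !(exonic_len > min_gene_len)) next  # leader segment
    }
    n <- n + 1L
    gid <- sprintf("%s.g%d", tu$tu_id, n)
    giv <- oriented_to_interval(sg$b5, b3, strand)
    eiv <- oriented_to_interval(lo_c, hi_c, strand)
    g_rows[[n]] <- data.frame(
      gene_id = gid, parent_tu_id = tu$tu_id, scaffold = tu$scaffold,
      start = giv[1L, "start"], end = giv[1L, "end"], strand = strand,
      has_sl_5p = sg$has_sl, has_polya_3p = has_pa,
      sl_summit = if (sg$has_sl) from_oriented(sg$sl, strand) else NA_integer_,
      polya_summit = if (has_pa) from_oriented(b3, strand) else NA_integer_,
      classification = if (sg$has_sl) classification else "NO_SL",
      stringsAsFactors = FALSE)
    e_rows[[n]] <- data.frame(
      gene_id = gid, scaffold = tu$scaffold,
      start = eiv[, "start"], end = eiv[, "end"], strand = strand,
      stringsAsFactors = FALSE)
  }
  if (n == 0L) {
    return(gene_set(
      data.frame(gene_id = character(), parent_tu_id = character(),
                 scaffold = character(), start = integer(), end = integer(),
                 strand = character(), has_sl_5p = logical(),
                 has_polya_3p = logical(), sl_summit = integer(),
                 polya_summit = integer(), classification = character(),
                 stringsAsFactors = FALSE),
      data.frame(gene_id = character(), scaffold = character(),
                 start = integer(), end = integer(), strand = character(),
                 stringsAsFactors = FALSE)))
  }
  genes <- do.call(rbind, g_rows)
  exdf <- do.call(rbind, e_rows)
  exdf <- exdf[order(match(exdf$gene_id, genes$gene_id), exdf$start), , drop = FALSE]
  gene_set(genes, exdf)
}

#' Cut all transcriptional units against assigned evidence peaks
#'
#' @param tus A [tu_set].
#' @param peaks Combined SL and POLYA peaks ([call_peaks()] output, rbind-ed).
#' @param min_gene_len,end_slack See [cut_tu()].
#' @return A [gene_set] covering all TUs, sibling genes ordered 5'->3'.
#' @export
cut_transcriptional_units <- function(tus, peaks, min_gene_len = 100L,
                                      end_slack = 50L) {
  asg <- assign_peaks_to_tu(tus, peaks, end_slack = end_slack)
  g_all <- list(); e_all <- list()
  for (i in seq_len(nrow(tus$transcripts))) {
    tu <- tus$transcripts[i, ]
    exons <- tus$exons[tus$exons$tu_id == tu$tu_id, , drop = FALSE]
    pk_idx <- asg$peak[asg$tu_id == tu$tu_id]
    pk <- peaks[pk_idx, , drop = FALSE]
    gs <- cut_tu(tu, exons,
                 sl_peaks = pk[pk$kind == "SL", , drop = FALSE],
                 polya_peaks = pk[pk$kind == "POLYA", , drop = FALSE],
                 min_gene_len = min_gene_len, end_slack = end_slack)
    g_all[[i]] <- gs$genes; e_all[[i]] <- gs$exons
  }
  gene_set(do.call(rbind, g_all), do.call(rbind, e_all))
}

#' Classify genes by parent-TU trans-splicing status and summarize
#'
#' Re-derives per-parent classification (a parent with one SL site yields
#' `SL_SINGLE` children; two or more, `SL_MULTIPLE_PARENT`) and tabulates
#' parent-level and gene-level counts and percentages.
#'
#' @param genes A [gene_set].
#' @return List with the reclassified `gene_set` and a `summary` data.frame
#'   (category, n, percent).
#' @export
classify_genes <- function(genes) {
  g <- genes$genes
  n_sl <- tapply(g$has_sl_5p, g$parent_tu_id, sum)
  cls <- function(parent, has_sl) {
    k <- n_sl[[parent]]
    if (!has_sl) "NO_SL" else if (k == 1L) "SL_SINGLE" else "SL_MULTIPLE_PARENT"
  }
  g$classification <- mapply(cls, g$parent_tu_id, g$has_sl_5p)
  n_parent <- length(n_sl)
  pct <- function(x, tot) if (tot == 0L) 0 else round(100 * x / tot, 2)
  n_single <- sum(n_sl == 1L); n_multi <- sum(n_sl >= 2L); n_none <- sum(n_sl == 0L)
  n_genes <- nrow(g); n_pa <- sum(g$has_polya_3p); n_sl_genes <- sum(g$has_sl_5p)
  summary <- data.frame(
    category = c("tus_total", "tus_single_sl", "tus_multiple_sl", "tus_no_sl",
                 "genes_total", "genes_trans_spliced", "genes_with_polya"),
    n = c(n_parent, n_single, n_multi, n_none, n_genes, n_sl_genes, n_pa),
    percent = c(100, pct(n_single, n_parent), pct(n_multi, n_parent),
                pct(n_none, n_parent), 100, pct(n_sl_genes, n_genes),
                pct(n_pa, n_genes)),
    stringsAsFactors = FALSE)
  list(genes = gene_set(g, genes$exons), summary = summary)
}

#' Write a gene_set as GTF with provenance attributes
#'
#' Attributes carried per record: `parent_tu`, `has_sl`, `has_polya`,
#' `class`.
#'
#' @param genes A [gene_set].
#' @param path Output path.
#' @param header Optional provenance header lines.
#' @export
write_gtf_genes <- function(genes, path, header = character()) {
  g <- sort_interval_df(genes$genes, "gene_id")
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(header, con)
  for (i in seq_len(nrow(g))) {
    g1 <- g[i, ]
    ex <- genes$exons[genes$exons$gene_id == g1$gene_id, , drop = FALSE]
    at <- sprintf(paste0("gene_id \"%s\"; transcript_id \"%s\"; parent_tu \"%s\"; ",
                         "has_sl \"%s\"; has_polya \"%s\"; class \"%s\";"),
                  g1$gene_id, g1$gene_id, g1$parent_tu_id,
                  tolower(g1$has_sl_5p), tolower(g1$has_polya_3p),
                  g1$classification)
    writeLines(gtf_line(g1$scaffold, "tbone", "transcript", g1$start, g1$end,
                        g1$strand, at), con)
    for (j in seq_len(nrow(ex))) {
      writeLines(gtf_line(ex$scaffold[j], "tbone", "exon", ex$start[j],
                          ex$end[j], ex$strand[j], at), con)
    }
  }
  invisible(path)
}

#' Read a gene_set written by [write_gtf_genes()]
#' @param path GTF path.
#' @return A [gene_set] (boundary-evidence flags restored from attributes;
#'   summit positions are not serialized).
#' @export
read_gtf_genes <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  m <- S4Vectors::mcols(gr)
  types <- as.character(m$type)
  is_tr <- types == "transcript"; is_ex <- types == "exon"
  g <- data.frame(
    gene_id = as.character(m$transcript_id[is_tr]),
    parent_tu_id = as.character(m$parent_tu[is_tr]),
    scaffold = as.character(GenomicRanges::seqnames(gr))[is_tr],
    start = GenomicRanges::start(gr)[is_tr] - 1L,
    end = GenomicRanges::end(gr)[is_tr],
    strand = as.character(GenomicRanges::strand(gr))[is_tr],
    has_sl_5p = as.character(m$has_sl[is_tr]) == "true",
    has_polya_3p = as.character(m$has_polya[is_tr]) == "true",
    sl_summit = NA_integer_, polya_summit = NA_integer_,
    classification = as.character(m$class[is_tr]),
    stringsAsFactors = FALSE)
  e <- data.frame(
    gene_id = as.character(m$transcript_id[is_ex]),
    scaffold = as.character(GenomicRanges::seqnames(gr))[is_ex],
    start = GenomicRanges::start(gr)[is_ex] - 1L,
    end = GenomicRanges::end(gr)[is_ex],
    strand = as.character(GenomicRanges::strand(gr))[is_ex],
    stringsAsFactors = FALSE)
  e <- e[order(match(e$gene_id, g$gene_id), e$start), , drop = FALSE]
  gene_set(g, e)
}
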