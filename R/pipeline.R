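# Orchestration and reporting: assembly summary statistics in the layout of
# a transcriptome-characteristics table, provenance headers, and a
# config-driven end-to-end pipeline runner.

TBONE_VERSION <- "0.1.0"

provenance_header <- function(config = NULL, seed = NULL) {
  hash <- "none"
  if (!is.null(config)) {
    tmp <- tempfile()
    on.exit(unlink(tmp))
    dput(config[order(names(config))], tmp)
    hash <- substr(unname(tools::md5sum(tmp)), 1L, 12L)
  }
  sprintf("#tbone %s %s%s", TBONE_VERSION, hash,
          if (is.null(seed)) "" else sprintf(" seed=%s", seed))
}

exonic_lengths <- function(exons, id_col) {
  tapply(exons$end - exons$start, exons[[id_col]], sum)
}

#' Summarize an annotated transcriptome assembly
#'
#' Computes the characteristics table of a finished run: transcript counts
#' and lengths, non-redundant counts, trans-splicing and poly(A) evidence
#' rates, and intron statistics. All fields derive from the records alone
#' and the output is deterministic.
#'
#' @param genes A [gene_set] (after classification).
#' @param tus The parent [tu_set].
#' @param clusters Optional [cluster_nt()] assignment of gene sequences;
#'   used for the non-redundant counts.
#' @return data.frame `field, value` of class `assembly_summary`.
#' @export
summarize_assembly <- function(genes, tus, clusters = NULL) {
  g <- genes$genes
  if (nrow(g) == 0L) {
    warning("empty gene set; all-zero summary")
  }
  glen <- exonic_lengths(genes$exons, "gene_id")
  tlen <- exonic_lengths(tus$exons, "tu_id")
  n_sl <- tapply(g$has_sl_5p, g$parent_tu_id, sum)
  introns_per_gene <- vapply(split(genes$exons, genes$exons$gene_id),
                             function(e) nrow(e) - 1L, integer(1))
  intron_lens <- unlist(lapply(split(genes$exons, genes$exons$gene_id), function(e) {
    e <- e[order(e$start), , drop = FALSE]
    if (nrow(e) < 2L) return(numeric())
    e$start[-1L] - e$end[-nrow(e)]
  }))
  pct <- function(x, tot) if (tot == 0) 0 else round(100 * x / tot, 2)
  avg <- function(x) if (length(x) == 0L) 0 else round(mean(x), 2)
  n_tus <- nrow(tus$transcripts); n_genes <- nrow(g)
  n_nr <- if (!is.null(clusters)) length(unique(clusters$representative_id)) else NA
  nr_len <- if (!is.null(clusters)) {
    reps <- unique(clusters$representative_id)
    sum(glen[intersect(reps, names(glen))])
  } else NA
  fields <- c(
    n_transcriptional_units = n_tus,
    n_genes = n_genes,
    total_tu_length_nt = sum(tlen),
    total_gene_length_nt = sum(glen),
    n_nonredundant = n_nr,
    nonredundant_length_nt = nr_len,
    shortest_transcript_nt = if (n_genes) min(glen) else 0,
    longest_transcript_nt = if (n_genes) max(glen) else 0,
    average_transcript_nt = avg(as.numeric(glen)),
    n_single_sl = sum(n_sl == 1L),
    pct_single_sl = pct(sum(n_sl == 1L), length(n_sl)),
    n_multiple_sl = sum(n_sl >= 2L),
    pct_multiple_sl = pct(sum(n_sl >= 2L), length(n_sl)),
    n_with_polya = sum(g$has_polya_3p),
    pct_with_polya = pct(sum(g$has_polya_3p), n_genes),
    average_gene_span_nt = avg(g$end - g$start),
    average_introns_per_gene = avg(introns_per_gene),
    average_intron_length_nt = avg(intron_lens)
  )
  out <- data.frame(field = names(fields), value = unname(fields),
                    stringsAsFactors = FALSE)
  class(out) <- c("assembly_summary", class(out))
  out
}

#' @export
print.assembly_summary <- function(x, ...) {
  cat("Assembly summary\n")
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-28s %s\n", x$field[i], format(x$value[i], big.mark = ",")))
  }
  invisible(x)
}

#' Write an assembly summary as TSV
#' @param summary Output of [summarize_assembly()].
#' @param path Output path.
#' @param header Optional header lines.
#' @export
write_summary_tsv <- function(summary, path, header = character()) {
  writeLines(c(header, "field\tvalue",
               sprintf("%s\t%s", summary$field,
                       format(summary$value, trim = TRUE, scientific = FALSE))),
             path)
  invisible(path)
}

#' Default pipeline parameters
#'
#' Every threshold the pipeline uses, overridable per run: peak calling
#' (`min_site_count` 5, `merge_distance` 10), assignment slack
#' (`end_slack` 50), minimum gene length (`min_gene_len` 100), antisense
#' ratio (5), novel-transcript expression floor (RPKM 0.5), ORF calling
#' (`min_aa` 100), split-gene merging (10 kb gap, half-repetitive),
#' clustering identity (0.95), duplication rule (> 500 nt, >= 0.95), codon
#' matrix size (top 100).
#'
#' @return Named list of defaults.
#' @export
pipeline_defaults <- function() {
  list(min_site_count = 5L, merge_distance = 10L, end_slack = 50L,
       min_gene_len = 100L, sl_min_match = 10L, sl_max_mismatch = 1L,
       antisense_ratio = 5, antisense_min_overlap_frac = 0.5,
       rpkm_min = 0.5, orf_min_aa = 100L, merge_max_gap = 10000L,
       merge_min_repeat_frac = 0.5, cluster_identity = 0.95,
       dup_k = 16L, dup_min_len = 500L, dup_min_identity = 0.95,
       codon_top_n = 100L)
}

#' Run the full annotation pipeline on in-memory inputs
#'
#' Stage order: antisense filter -> low-expression filter -> evidence pileup
#' and peak calling -> TU cutting -> classification -> ORF calling ->
#' split-transcript merging -> redundancy clustering -> summary. Per-stage
#' record counts are logged to standard error; artifacts (when `outdir` is
#' given) carry a provenance header with version and config hash.
#'
#' @param sim Input bundle as produced by [simulate_dataset()] (or an
#'   equivalent list built from files: `genome`, `tus`, `sl_placements`,
#'   `polya_placements`, `repeats`, `read_counts`, `expression`).
#' @param params Parameter list; see [pipeline_defaults()].
#' @param outdir Optional artifact directory.
#' @param reference_overlaps `tu_id`s exempt from the low-expression filter
#'   (default: all input TUs, i.e. the filter is a no-op unless the caller
#'   supplies real reference support).
#' @param cluster Run the redundancy-clustering stage (the most expensive
#'   stage; boundary-accuracy studies can skip it).
#' @param quiet Suppress the per-stage log.
#' @return List with `tus_kept`, `genes` ([gene_set]), `peaks`, `clusters`,
#'   `summary`, `antisense_report`, `merge_report`, `counts` (per-stage
#'   record counts).
#' @export
run_pipeline <- function(sim, params = list(), outdir = NULL,
                         reference_overlaps = NULL, cluster = TRUE,
                         quiet = FALSE) {
  p <- utils::modifyList(pipeline_defaults(), params)
  log <- function(...) if (!quiet) message(sprintf(...))
  counts <- list()
  hdr <- provenance_header(p, seed = sim$config$seed)

  tus <- sim$tus
  counts$tus_in <- nrow(tus$transcripts)

  fa <- filter_antisense(tus, sim$read_counts,
                         ratio_threshold = p$antisense_ratio,
                         min_overlap_frac = p$antisense_min_overlap_frac)
  counts$antisense_discarded <- nrow(fa$discarded$transcripts)
  log("antisense filter: %d in, %d discarded", counts$tus_in,
      counts$antisense_discarded)

  refs <- if (is.null(reference_overlaps)) fa$kept$transcripts$tu_id else
    reference_overlaps
  fl <- filter_low_expression_novel(fa$kept, refs, rpkm_min = p$rpkm_min)
  counts$low_expression_discarded <- nrow(fl$discarded$transcripts)
  tus_kept <- fl$kept
  counts$tus_kept <- nrow(tus_kept$transcripts)

  sl_track <- pileup_end_positions(sim$sl_placements, "SL", genome = sim$genome)
  pa_track <- pileup_end_positions(sim$polya_placements, "POLYA",
                                   genome = sim$genome)
  peaks <- rbind(
    call_peaks(sl_track, p$min_site_count, p$merge_distance),
    call_peaks(pa_track, p$min_site_count, p$merge_distance))
  counts$peaks <- nrow(peaks)
  log("peak calling: %d SL + POLYA peaks", counts$peaks)

  genes <- cut_transcriptional_units(tus_kept, peaks,
                                     min_gene_len = p$min_gene_len,
                                     end_slack = p$end_slack)
  cl <- classify_genes(genes)
  genes <- cl$genes
  counts$genes <- nrow(genes$genes)
  log("cutting: %d TUs -> %d genes", counts$tus_kept, counts$genes)

  genes <- call_orfs(genes, sim$genome, min_aa = p$orf_min_aa)
  mg <- merge_split_transcripts(genes, sim$genome, sim$repeats,
                                max_gap = p$merge_max_gap,
                                min_repeat_frac = p$merge_min_repeat_frac,
                                min_aa = p$orf_min_aa)
  genes <- mg$genes
  counts$merges <- nrow(mg$report)
  counts$genes_after_merge <- nrow(genes$genes)

  clusters <- NULL
  if (cluster) {
    seqs <- vapply(split(genes$exons, genes$exons$gene_id),
                   transcript_sequence, "", genome = sim$genome)
    clusters <- cluster_nt(seqs, identity_threshold = p$cluster_identity)
    counts$clusters <- length(unique(clusters$representative_id))
    log("clustering: %d genes -> %d clusters", counts$genes_after_merge,
        counts$clusters)
  }

  summary <- summarize_assembly(genes, tus_kept, clusters)

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_gtf_genes(genes, file.path(outdir, "genes.gtf"), header = hdr)
    write_gtf_tus(tus_kept, file.path(outdir, "tus_kept.gtf"), header = hdr)
    write_peaks_bed(peaks, file.path(outdir, "peaks.bed"), header = hdr)
    write_summary_tsv(summary, file.path(outdir, "summary.tsv"), header = hdr)
    write_track_bedgraph(sl_track, file.path(outdir, "sl"), header = hdr)
    write_track_bedgraph(pa_track, file.path(outdir, "polya"), header = hdr)
  }

  list(tus_kept = tus_kept, genes = genes, peaks = peaks, clusters = clusters,
       summary = summary, antisense_report = fa$report,
       merge_report = mg$report, counts = counts)
}

#' Compare recovered gene boundaries against simulation ground truth
#'
#' A planted SL (or poly(A)) boundary counts as recovered when some gene on
#' the same scaffold and strand places its evidence-supported 5' (3')
#' boundary within `tol` nt of the planted position.
#'
#' @param genes A [gene_set] from the pipeline.
#' @param truth The `truth` element of [simulate_dataset()].
#' @param tol Tolerance in nt (0 = exact base).
#' @return List: `sl_recovered`, `sl_total`, `polya_recovered`,
#'   `polya_total`, `sl_rate`, `polya_rate` (percent).
#' @export
boundary_recovery <- function(genes, truth, tol = 0L) {
  g <- genes$genes
  hit <- function(planted, summits) {
    vapply(seq_len(NROW(planted)), function(i) {
      p <- planted[i, ]
      any(summits$scaffold == p$scaffold & summits$strand == p$strand &
            abs(summits$pos - p$pos) <= tol, na.rm = TRUE)
    }, logical(1))
  }
  sl_planted <- truth$genes[!is.na(truth$genes$sl_pos), , drop = FALSE]
  pa_planted <- truth$genes[!is.na(truth$genes$polya_pos), , drop = FALSE]
  sl_planted$pos <- sl_planted$sl_pos
  pa_planted$pos <- pa_planted$polya_pos
  sl_found <- data.frame(scaffold = g$scaffold, strand = g$strand,
                         pos = g$sl_summit)[g$has_sl_5p, , drop = FALSE]
  pa_found <- data.frame(scaffold = g$scaffold, strand = g$strand,
                         pos = g$polya_summit)[g$has_polya_3p, , drop = FALSE]
  sl_ok <- hit(sl_planted, sl_found)
  pa_ok <- hit(pa_planted, pa_found)
  rate <- function(ok) if (length(ok) == 0L) 100 else 100 * mean(ok)
  list(sl_recovered = sum(sl_ok), sl_total = length(sl_ok),
       polya_recovered = sum(pa_ok), polya_total = length(pa_ok),
       sl_rate = rate(sl_ok), polya_rate = rate(pa_ok))
}
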