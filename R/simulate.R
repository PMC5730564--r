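# Synthetic-data generator: multi-scaffold genomes, strand-assigned
# multi-exon transcriptional units (single-gene, polycistronic and
# no-evidence classes), SL-leader-prefixed 5' reads and T-fill 3' reads with
# Poisson counts and positional jitter, antisense contamination at a
# controlled count ratio, repeat intervals and planted duplications -- all
# with machine-readable ground truth, so every pipeline stage is testable
# without external data.
#
# Determinism: every output stream draws from its own RNG substream derived
# from the master seed, so adding one output never perturbs the others.

DEFAULT_SL_LEADER <- "CGTTACCGATTGGTCAAGTC"  # synthetic fixed 20-mer

#' Build a simulation configuration
#'
#' Defaults describe a clean mid-sized study: 50 TUs on two 120 kb
#' scaffolds, Poisson(20) read support per evidence site, no positional
#' jitter and no sequencing error (jitter and error are dials for robustness
#' studies), antisense contamination on 20% of TUs at the filter's
#' five-fold count ratio, 5% repeat content, no planted duplications.
#'
#' @param seed Master seed (mandatory; there is no implicit entropy).
#' @param n_scaffolds,scaffold_len Genome shape.
#' @param n_tus Number of transcriptional units.
#' @param genes_per_tu Named probability vector over gene counts per TU;
#'   name `"0"` is the no-evidence class (one gene, no SL/poly(A) sites).
#' @param sl_leader Spliced-leader sequence used for read prefixes.
#' @param reads_per_sl_site,reads_per_polya_site Poisson means.
#' @param position_jitter_sd Gaussian jitter (nt, sd) applied to read end
#'   placements.
#' @param antisense_fraction Fraction of TUs receiving a planted antisense
#'   partner.
#' @param antisense_count_ratio Sense/antisense read count ratio planted for
#'   those partners.
#' @param repeat_fraction Target fraction of the genome annotated as repeat.
#' @param planted_dups List of `c(length, identity)` or
#'   `c(length, identity, orientation)` duplication specs (orientation
#'   `1` = same, `-1` = inverted).
#' @param error_rate Per-base substitution rate in simulated reads.
#' @param read_length Read length for emitted FASTQ.
#' @return A list of class `sim_config`.
#' @export
simulation_config <- function(seed,
                              n_scaffolds = 2L,
                              scaffold_len = 120000L,
                              n_tus = 50L,
                              genes_per_tu = c("0" = 0.30, "1" = 0.45,
                                               "2" = 0.15, "3" = 0.10),
                              sl_leader = DEFAULT_SL_LEADER,
                              reads_per_sl_site = 20,
                              reads_per_polya_site = 20,
                              position_jitter_sd = 0,
                              antisense_fraction = 0.2,
                              antisense_count_ratio = 5,
                              repeat_fraction = 0.05,
                              planted_dups = list(),
                              error_rate = 0,
                              read_length = 100L) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(abs(sum(genes_per_tu) - 1) < 1e-9,
            all(genes_per_tu >= 0),
            position_jitter_sd >= 0, error_rate >= 0, error_rate <= 1,
            antisense_fraction >= 0, antisense_fraction <= 1,
            repeat_fraction >= 0, repeat_fraction <= 1)
  structure(as.list(environment()), class = "sim_config")
}

with_substream <- function(seed, offset, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer((as.numeric(seed) * 131 + offset) %% 2147483647))
  expr
}

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_seq <- function(s, n_subs) {
  if (n_subs == 0L) return(s)
  ch <- strsplit(s, "")[[1L]]
  idx <- sample(length(ch), n_subs)
  for (i in idx) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1L)
  paste(ch, collapse = "")
}

oriented_subseq <- function(genome, scaffold, pos, len, strand) {
  # sequence of `len` bases starting at base `pos` and moving 3'-wards
  sc <- genome[[scaffold]]
  if (strand == "+") {
    substr(sc, pos + 1L, min(pos + len, nchar(sc)))
  } else {
    s <- substr(sc, max(pos - len + 2L, 1L), pos + 1L)
    revcomp(s)
  }
}

# Lay out one TU in oriented offsets [0, tu_len): returns gene/exon/site
# structure. Polycistronic TUs have `n_genes` gene blocks separated by
# exonic spacers; each gene block is exon(-intron-exon...) with the SL site
# at its first base and the poly(A) site at its last.
layout_tu <- function(n_genes, no_evidence) {
  segs <- list()   # (kind, len): kind in exon/intron/spacer
  genes <- list()
  off <- 0L
  push <- function(kind, len) {
    segs[[length(segs) + 1L]] <<- list(kind = kind, lo = off, hi = off + len - 1L)
    off <<- off + len
  }
  for (gi in seq_len(n_genes)) {
    g_lo <- off
    n_ex <- sample(1:3, 1L)
    for (e in seq_len(n_ex)) {
      push("exon", sample(200:600, 1L))
      if (e < n_ex) push("intron", sample(150:500, 1L))
    }
    genes[[gi]] <- list(lo = g_lo, hi = off - 1L)
    if (gi < n_genes) push("spacer", sample(40:120, 1L))
  }
  exonic <- do.call(rbind, lapply(segs, function(s)
    if (s$kind != "intron") c(s$lo, s$hi) else NULL))
  # collapse adjacent exonic segments (exon+spacer runs)
  exonic <- exonic[order(exonic[, 1L]), , drop = FALSE]
  keep <- list(exonic[1L, ])
  for (i in seq_len(nrow(exonic))[-1L]) {
    last <- keep[[length(keep)]]
    if (exonic[i, 1L] == last[2L] + 1L) keep[[length(keep)]] <- c(last[1L], exonic[i, 2L])
    else keep[[length(keep) + 1L]] <- exonic[i, ]
  }
  list(tu_len = off,
       exons = do.call(rbind, keep),
       genes = genes,
       has_sites = !no_evidence)
}

#' Simulate a full synthetic dataset
#'
#' @param config A [simulation_config()].
#' @param outdir Optional directory; when given, all artifacts are written
#'   (genome FASTA, TU GTF, SL/T-fill FASTQ, placement BEDs, repeats BED,
#'   expression and read-count TSVs, ground-truth TSVs).
#' @return List with in-memory objects: `genome`, `tus` ([tu_set] including
#'   antisense TUs), `sl_reads`, `polya_reads` (named character vectors),
#'   `sl_placements`, `polya_placements`, `repeats`, `expression`,
#'   `read_counts`, `truth` (gene boundaries, sites, antisense pairs,
#'   duplication registry), and `config`.
#' @export
simulate_dataset <- function(config, outdir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  cf <- config

  ## 1. TU layout and genome ------------------------------------------------
  layout <- with_substream(cf$seed, 1L, {
    scafs <- sprintf("scaf%d", seq_len(cf$n_scaffolds))
    tu_rows <- list(); ex_rows <- list(); truth_genes <- list()
    sl_sites <- list(); pa_sites <- list()
    cursor <- stats::setNames(rep(500L, cf$n_scaffolds), scafs)
    choices <- as.integer(names(cf$genes_per_tu))
    for (t in seq_len(cf$n_tus)) {
      tu_id <- sprintf("TU%04d", t)
      pick <- sample(choices, 1L, prob = cf$genes_per_tu)
      no_ev <- pick == 0L
      n_genes <- max(pick, 1L)
      ly <- layout_tu(n_genes, no_ev)
      sc <- scafs[which.min(cursor)]
      strand <- sample(c("+", "-"), 1L)
      tu_start <- cursor[[sc]]
      cursor[[sc]] <- cursor[[sc]] + ly$tu_len + sample(800L:2000L, 1L)
      if (max(cursor) > cf$scaffold_len - 500L) {
        stop("infeasible packing: too many/long TUs for scaffold_len")
      }
      tu_end <- tu_start + ly$tu_len
      # oriented offset -> genomic base
      o2g <- function(off) if (strand == "+") tu_start + off else tu_end - 1L - off
      ex_iv <- t(apply(ly$exons, 1L, function(r) sort(c(o2g(r[1L]), o2g(r[2L])))))
      ex_rows[[t]] <- data.frame(tu_id = tu_id, scaffold = sc,
                                 start = ex_iv[, 1L], end = ex_iv[, 2L] + 1L,
                                 strand = strand, stringsAsFactors = FALSE)
      tu_rows[[t]] <- data.frame(tu_id = tu_id, scaffold = sc,
                                 start = tu_start, end = tu_end,
                                 strand = strand, stringsAsFactors = FALSE)
      for (gi in seq_along(ly$genes)) {
        g <- ly$genes[[gi]]
        g_iv <- sort(c(o2g(g$lo), o2g(g$hi)))
        has <- ly$has_sites
        truth_genes[[length(truth_genes) + 1L]] <- data.frame(
          tu_id = tu_id, gene_index = gi, scaffold = sc,
          start = g_iv[1L], end = g_iv[2L] + 1L, strand = strand,
          sl_pos = if (has) o2g(g$lo) else NA_integer_,
          polya_pos = if (has) o2g(g$hi) else NA_integer_,
          class = if (!has) "NO_SL" else if (n_genes == 1L) "SL_SINGLE"
                  else "SL_MULTIPLE_PARENT",
          stringsAsFactors = FALSE)
        if (has) {
          sl_sites[[length(sl_sites) + 1L]] <- data.frame(
            tu_id = tu_id, gene_index = gi, scaffold = sc,
            pos = o2g(g$lo), strand = strand, stringsAsFactors = FALSE)
          pa_sites[[length(pa_sites) + 1L]] <- data.frame(
            tu_id = tu_id, gene_index = gi, scaffold = sc,
            pos = o2g(g$hi), strand = strand, stringsAsFactors = FALSE)
        }
      }
    }
    list(transcripts = do.call(rbind, tu_rows), exons = do.call(rbind, ex_rows),
         truth_genes = do.call(rbind, truth_genes),
         sl_sites = do.call(rbind, sl_sites), pa_sites = do.call(rbind, pa_sites),
         scafs = scafs)
  })

  genome <- with_substream(cf$seed, 2L, {
    g <- stats::setNames(
      vapply(layout$scafs, function(s) random_seq(cf$scaffold_len), ""),
      layout$scafs)
    g
  })

  ## 2. antisense partners ---------------------------------------------------
  anti <- with_substream(cf$seed, 3L, {
    tr <- layout$transcripts
    n_anti <- round(cf$antisense_fraction * nrow(tr))
    rows <- list(); pairs <- list(); counts <- stats::setNames(
      50L + stats::rpois(nrow(tr), 30), tr$tu_id)
    if (n_anti > 0L) {
      picked <- sort(sample(nrow(tr), n_anti))
      for (i in seq_along(picked)) {
        t1 <- tr[picked[i], ]
        ex1 <- layout$exons[layout$exons$tu_id == t1$tu_id, , drop = FALSE]
        ex1 <- ex1[which.max(ex1$end - ex1$start), ]  # widest exon
        as_id <- sprintf("AS_%s", t1$tu_id)
        as_strand <- if (t1$strand == "+") "-" else "+"
        rows[[i]] <- data.frame(tu_id = as_id, scaffold = t1$scaffold,
                                start = ex1$start, end = ex1$end,
                                strand = as_strand, stringsAsFactors = FALSE)
        sense_count <- counts[[t1$tu_id]]
        as_count <- as.integer(floor(sense_count / cf$antisense_count_ratio))
        counts[as_id] <- as_count
        pairs[[i]] <- data.frame(
          sense_id = t1$tu_id, antisense_id = as_id,
          count_sense = sense_count, count_antisense = as_count,
          ratio = if (as_count == 0L) Inf else sense_count / as_count,
          expect_discard = if (sense_count / max(as_count, 1e-9) >= cf$antisense_count_ratio ||
                               as_count == 0L) as_id else "",
          stringsAsFactors = FALSE)
      }
    }
    list(rows = if (length(rows)) do.call(rbind, rows) else NULL,
         pairs = if (length(pairs)) do.call(rbind, pairs) else
           data.frame(sense_id = character(), antisense_id = character(),
                      count_sense = integer(), count_antisense = integer(),
                      ratio = numeric(), expect_discard = character(),
                      stringsAsFactors = FALSE),
         counts = counts)
  })

  transcripts <- layout$transcripts
  exons <- layout$exons
  if (!is.null(anti$rows)) {
    transcripts <- rbind(transcripts, anti$rows)
    ae <- anti$rows; ae <- ae[, c("tu_id", "scaffold", "start", "end", "strand")]
    exons <- rbind(exons, ae)
  }

  ## 3. expression -----------------------------------------------------------
  expression <- with_substream(cf$seed, 4L, {
    v <- stats::rlnorm(nrow(transcripts), meanlog = 2, sdlog = 1)
    v[startsWith(transcripts$tu_id, "AS_")] <-
      v[startsWith(transcripts$tu_id, "AS_")] / cf$antisense_count_ratio
    stats::setNames(round(v, 4), transcripts$tu_id)
  })
  transcripts$rpkm <- unname(expression[transcripts$tu_id])
  transcripts$source <- "sim"
  tus <- tu_set(transcripts, exons)

  ## 4. reads and placements -------------------------------------------------
  jitter_pos <- function(pos, strand, sd) {
    if (sd == 0) return(pos)
    as.integer(pos + round(stats::rnorm(length(pos), 0, sd)))
  }
  apply_errors <- function(s, rate) {
    if (rate == 0) return(s)
    n <- stats::rbinom(1L, nchar(s), rate)
    mutate_seq(s, n)
  }
  sl <- with_substream(cf$seed, 5L, {
    reads <- character(); placements <- list(); planted <- list()
    sites <- layout$sl_sites
    for (i in seq_len(NROW(sites))) {
      st <- sites[i, ]
      n <- stats::rpois(1L, cf$reads_per_sl_site)
      planted[[i]] <- cbind(st, count = n)
      if (n == 0L) next
      pos <- jitter_pos(rep(st$pos, n), st$strand, cf$position_jitter_sd)
      pos <- pmin(pmax(pos, 0L), nchar(genome[[st$scaffold]]) - 1L)
      for (r in seq_len(n)) {
        body_len <- cf$read_length - nchar(cf$sl_leader)
        body <- oriented_subseq(genome, st$scaffold, pos[r], body_len, st$strand)
        rid <- sprintf("slr_%s_g%d_%d", st$tu_id, st$gene_index, r)
        reads[rid] <- apply_errors(paste0(cf$sl_leader, body), cf$error_rate)
        placements[[length(placements) + 1L]] <- data.frame(
          scaffold = st$scaffold, pos = pos[r], strand = st$strand,
          read_id = rid, stringsAsFactors = FALSE)
      }
    }
    list(reads = reads,
         placements = if (length(placements)) do.call(rbind, placements) else
           data.frame(scaffold = character(), pos = integer(),
                      strand = character(), read_id = character()),
         planted = if (length(planted)) do.call(rbind, planted) else NULL)
  })
  pa <- with_substream(cf$seed, 6L, {
    reads <- character(); placements <- list(); planted <- list()
    sites <- layout$pa_sites
    for (i in seq_len(NROW(sites))) {
      st <- sites[i, ]
      n <- stats::rpois(1L, cf$reads_per_polya_site)
      planted[[i]] <- cbind(st, count = n)
      if (n == 0L) next
      pos <- jitter_pos(rep(st$pos, n), st$strand, cf$position_jitter_sd)
      pos <- pmin(pmax(pos, 0L), nchar(genome[[st$scaffold]]) - 1L)
      for (r in seq_len(n)) {
        # read ends at the last transcribed base: take upstream sequence
        up_start <- if (st$strand == "+") pos[r] - (cf$read_length - 1L) else
          pos[r] + (cf$read_length - 1L)
        body <- oriented_subseq(genome, st$scaffold,
                                max(min(up_start, nchar(genome[[st$scaffold]]) - 1L), 0L),
                                cf$read_length, st$strand)
        rid <- sprintf("par_%s_g%d_%d", st$tu_id, st$gene_index, r)
        # half the reads carry a residual A-tail, half stop at the cleavage
        # site (pure T-fill behaviour)
        s <- if (r %% 2L == 0L) paste0(body, strrep("A", 12L)) else body
        reads[rid] <- apply_errors(s, cf$error_rate)
        placements[[length(placements) + 1L]] <- data.frame(
          scaffold = st$scaffold, pos = pos[r], strand = st$strand,
          read_id = rid, stringsAsFactors = FALSE)
      }
    }
    list(reads = reads,
         placements = if (length(placements)) do.call(rbind, placements) else
           data.frame(scaffold = character(), pos = integer(),
                      strand = character(), read_id = character()),
         planted = if (length(planted)) do.call(rbind, planted) else NULL)
  })

  ## 5. repeats --------------------------------------------------------------
  repeats <- with_substream(cf$seed, 7L, {
    rows <- list()
    target <- cf$repeat_fraction * cf$scaffold_len
    for (sc in layout$scafs) {
      placed <- 0
      guard <- 0L
      while (placed < target && guard < 1000L) {
        guard <- guard + 1L
        len <- sample(200:800, 1L)
        start <- sample(0:(cf$scaffold_len - len), 1L)
        rows[[length(rows) + 1L]] <- data.frame(
          scaffold = sc, start = start, end = start + len, strand = ".",
          stringsAsFactors = FALSE)
        placed <- placed + len
      }
    }
    if (!length(rows)) {
      data.frame(scaffold = character(), start = integer(), end = integer(),
                 strand = character(), stringsAsFactors = FALSE)
    } else {
      merge_intervals(do.call(rbind, rows))
    }
  })

  ## 6. planted duplications -------------------------------------------------
  dup <- with_substream(cf$seed, 8L, {
    registry <- list()
    if (length(cf$planted_dups)) {
      pad <- 400L
      total <- sum(vapply(cf$planted_dups, function(d) as.integer(d[1L]), 1L)) +
        pad * (length(cf$planted_dups) + 1L)
      sink <- random_seq(total)
      src_sc <- layout$scafs[1L]
      cur <- pad
      used <- matrix(numeric(0), ncol = 2L)
      for (i in seq_along(cf$planted_dups)) {
        d <- cf$planted_dups[[i]]
        len <- as.integer(d[1L]); ident <- as.numeric(d[2L])
        orient <- if (length(d) >= 3L && as.numeric(d[3L]) < 0) "inverted" else "same"
        # source loci kept >= 200 nt apart so planted blocks stay distinct
        repeat {
          src_start <- sample(0:(cf$scaffold_len - len), 1L)
          if (!nrow(used) ||
              all(src_start + len + 200L <= used[, 1L] |
                  src_start >= used[, 2L] + 200L)) break
        }
        used <- rbind(used, c(src_start, src_start + len))
        seg <- substr(genome[[src_sc]], src_start + 1L, src_start + len)
        n_subs <- as.integer(round((1 - ident) * len))
        copy <- mutate_seq(seg, n_subs)
        if (orient == "inverted") copy <- revcomp(copy)
        substr(sink, cur + 1L, cur + len) <- copy
        registry[[i]] <- data.frame(
          scaffold_a = src_sc, start_a = src_start, end_a = src_start + len,
          scaffold_b = "dup_sink", start_b = cur, end_b = cur + len,
          orientation = orient, length = len,
          identity = (len - n_subs) / len, stringsAsFactors = FALSE)
        cur <- cur + len + pad
      }
      genome["dup_sink"] <- sink
    }
    list(genome = genome,
         registry = if (length(registry)) do.call(rbind, registry) else
           data.frame(scaffold_a = character(), start_a = integer(),
                      end_a = integer(), scaffold_b = character(),
                      start_b = integer(), end_b = integer(),
                      orientation = character(), length = integer(),
                      identity = numeric(), stringsAsFactors = FALSE))
  })
  genome <- dup$genome

  truth <- list(genes = layout$truth_genes,
                sl_sites = sl$planted, polya_sites = pa$planted,
                antisense_pairs = anti$pairs,
                duplications = dup$registry)

  out <- list(genome = genome, tus = tus,
              sl_reads = sl$reads, polya_reads = pa$reads,
              sl_placements = sl$placements, polya_placements = pa$placements,
              repeats = repeats, expression = expression,
              read_counts = anti$counts, truth = truth, config = cf)

  if (!is.null(outdir)) write_sim_dataset(out, outdir)
  out
}

#' Write a simulated dataset to a directory
#' @param sim Output of [simulate_dataset()].
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_sim_dataset <- function(sim, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(outdir, f)
  write_fasta(sim$genome, p("genome.fasta"))
  write_gtf_tus(sim$tus, p("tus.gtf"))
  write_fastq(sim$sl_reads, p("sl_reads.fastq"))
  write_fastq(sim$polya_reads, p("polya_reads.fastq"))
  pl <- sim$sl_placements
  write_bed(data.frame(scaffold = pl$scaffold, start = pl$pos,
                       end = pl$pos + 1L, name = pl$read_id, score = 1,
                       strand = pl$strand), p("sl_placements.bed"))
  pl <- sim$polya_placements
  write_bed(data.frame(scaffold = pl$scaffold, start = pl$pos,
                       end = pl$pos + 1L, name = pl$read_id, score = 1,
                       strand = pl$strand), p("polya_placements.bed"))
  write_bed(sim$repeats, p("repeats.bed"))
  write_expression_tsv(sim$expression, p("expression.tsv"))
  write_expression_tsv(sim$read_counts, p("read_counts.tsv"))
  tg <- sim$truth$genes
  utils::write.table(tg[order(tg$tu_id, tg$gene_index), ],
                     p("truth_genes.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(sim$truth$antisense_pairs, p("truth_antisense.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$duplications, p("truth_duplications.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(outdir)
}
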