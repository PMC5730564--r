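# On-disk formats. Readers lean on Biostrings / rtracklayer / ShortRead;
# writers are plain sprintf so that output is byte-deterministic (records are
# always sorted by (scaffold, start, end, id) before writing).

FASTA_ALPHABET <- c("A", "C", "G", "T", "N")

#' Read a genome FASTA file
#'
#' Sequences are uppercased on read; only `A`, `C`, `G`, `T`, `N` are
#' accepted after normalization, and duplicate record identifiers are
#' rejected. Identifiers are taken as the first whitespace-delimited token of
#' each header.
#'
#' @param path Path to a FASTA file.
#' @return A named character vector, one element per record.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- tryCatch(
    Biostrings::readBStringSet(path, format = "fasta"),
    error = function(e) stop("malformed FASTA in ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  ids <- sub("\\s.*$", "", names(x))
  if (any(ids == "")) stop("malformed FASTA header (empty ID) in ", path)
  if (anyDuplicated(ids)) {
    stop("duplicate ID in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- toupper(as.character(x))
  bad <- grepl(paste0("[^", paste(FASTA_ALPHABET, collapse = ""), "]"), seqs)
  if (any(bad)) {
    chars <- unique(unlist(strsplit(gsub("[ACGTN]", "", seqs[bad]), "")))
    stop("illegal character(s) ", paste(chars, collapse = ", "),
         " in record(s): ", paste(ids[bad], collapse = ", "))
  }
  if (any(nchar(seqs) < 1L)) {
    stop("empty sequence in record(s): ", paste(ids[nchar(seqs) < 1L], collapse = ", "))
  }
  names(seqs) <- ids
  seqs
}

#' Write sequences as FASTA
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @param width Line wrap width.
#' @param sort Sort records by identifier before writing (default `TRUE`;
#'   keeps writers byte-deterministic).
#' @export
write_fasta <- function(seqs, path, width = 70L, sort = TRUE) {
  if (sort) seqs <- seqs[order(names(seqs))]
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a FASTQ file
#'
#' @param path Path to a FASTQ file.
#' @return A named character vector of read sequences (uppercased).
#' @export
read_fastq <- function(path) {
  x <- ShortRead::readFastq(path)
  seqs <- toupper(as.character(ShortRead::sread(x)))
  names(seqs) <- sub("\\s.*$", "", as.character(ShortRead::id(x)))
  seqs
}

#' Write reads as FASTQ (constant placeholder qualities)
#' @param seqs Named character vector of read sequences.
#' @param path Output path.
#' @export
write_fastq <- function(seqs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(c(paste0("@", names(seqs)[i]), seqs[[i]], "+",
                 strrep("I", nchar(seqs[[i]]))), con)
  }
  invisible(path)
}

## ---- transcriptional units (GTF) ------------------------------------------

#' Construct a transcriptional-unit set
#'
#' A transcriptional unit (TU) is an assembled, possibly polycistronic,
#' transcript. The set holds two tables: `transcripts` (one row per TU:
#' `tu_id`, `scaffold`, `start`, `end`, `strand`, `rpkm`, `source`) and
#' `exons` (`tu_id`, `scaffold`, `start`, `end`, `strand`), all in 0-based
#' half-open coordinates. Invariants checked: exons sorted, non-overlapping,
#' same scaffold/strand as their TU, and the TU span equals the exon span.
#'
#' @param transcripts,exons data.frames as described above.
#' @return An object of class `tu_set`.
#' @export
tu_set <- function(transcripts, exons) {
  transcripts$tu_id <- as.character(transcripts$tu_id)
  exons$tu_id <- as.character(exons$tu_id)
  transcripts$start <- as.integer(transcripts$start)
  transcripts$end <- as.integer(transcripts$end)
  exons$start <- as.integer(exons$start)
  exons$end <- as.integer(exons$end)
  if (!"rpkm" %in% names(transcripts)) transcripts$rpkm <- NA_real_
  if (!"source" %in% names(transcripts)) transcripts$source <- "tbone"
  validate_intervals(transcripts, allow_unstranded = FALSE)
  validate_intervals(exons, allow_unstranded = FALSE)
  if (anyDuplicated(transcripts$tu_id)) {
    stop("duplicate tu_id: ",
         paste(unique(transcripts$tu_id[duplicated(transcripts$tu_id)]), collapse = ", "))
  }
  exons <- exons[order(exons$tu_id, exons$start), , drop = FALSE]
  by_tu <- split(exons, exons$tu_id)
  for (id in transcripts$tu_id) {
    ex <- by_tu[[id]]
    if (is.null(ex) || nrow(ex) == 0L) stop("TU without exons: ", id)
    tr <- transcripts[transcripts$tu_id == id, ]
    if (any(ex$scaffold != tr$scaffold) || any(ex$strand != tr$strand)) {
      stop("exon scaffold/strand mismatch for TU ", id)
    }
    if (nrow(ex) > 1L && any(ex$start[-1L] < ex$end[-nrow(ex)])) {
      stop("overlapping exons in TU ", id)
    }
    if (ex$start[1L] != tr$start || ex$end[nrow(ex)] != tr$end) {
      stop("TU span does not match exon span for TU ", id)
    }
  }
  extra <- setdiff(unique(exons$tu_id), transcripts$tu_id)
  if (length(extra)) stop("exons for unknown TU(s): ", paste(extra, collapse = ", "))
  rownames(transcripts) <- NULL
  rownames(exons) <- NULL
  structure(list(transcripts = transcripts, exons = exons), class = "tu_set")
}

#' @export
print.tu_set <- function(x, ...) {
  cat("tu_set:", nrow(x$transcripts), "transcriptional units,",
      nrow(x$exons), "exons\n")
  invisible(x)
}

#' Read transcriptional units from a GTF file
#'
#' Consumes transcript/exon features (the interchange format with upstream
#' genome-guided assemblers). 1-based inclusive GTF coordinates are converted
#' to the internal 0-based half-open convention. Transcripts must be
#' stranded; exon-only files are accepted (the transcript span is then the
#' exon span). An `RPKM` attribute, if present, populates `rpkm`.
#'
#' @param path Path to a GTF file.
#' @return A [tu_set].
#' @export
read_gtf <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "gtf"),
                 error = function(e) stop("malformed GTF in ", path, ": ",
                                          conditionMessage(e), call. = FALSE))
  m <- S4Vectors::mcols(gr)
  if (!"transcript_id" %in% names(m) || anyNA(m$transcript_id)) {
    stop("GTF record(s) missing transcript_id in ", path)
  }
  types <- as.character(m$type)
  is_ex <- types == "exon"
  if (!any(is_ex)) stop("no exon features in ", path)
  strands <- as.character(GenomicRanges::strand(gr))
  if (any(strands[is_ex | types == "transcript"] == "*")) {
    bad <- unique(m$transcript_id[(is_ex | types == "transcript") & strands == "*"])
    stop("unstranded transcript(s) in ", path, ": ", paste(bad, collapse = ", "))
  }
  ex <- data.frame(
    tu_id = as.character(m$transcript_id[is_ex]),
    scaffold = as.character(GenomicRanges::seqnames(gr))[is_ex],
    start = GenomicRanges::start(gr)[is_ex] - 1L,
    end = GenomicRanges::end(gr)[is_ex],
    strand = strands[is_ex],
    stringsAsFactors = FALSE
  )
  ex <- ex[order(ex$tu_id, ex$start), , drop = FALSE]
  sp <- split(ex, ex$tu_id)
  tr <- do.call(rbind, lapply(sp, function(e) {
    data.frame(tu_id = e$tu_id[1L], scaffold = e$scaffold[1L],
               start = min(e$start), end = max(e$end), strand = e$strand[1L],
               stringsAsFactors = FALSE)
  }))
  # declared transcript features, if any, must contain their exons
  is_tr <- types == "transcript"
  if (any(is_tr)) {
    decl <- data.frame(tu_id = as.character(m$transcript_id[is_tr]),
                       start = GenomicRanges::start(gr)[is_tr] - 1L,
                       end = GenomicRanges::end(gr)[is_tr],
                       stringsAsFactors = FALSE)
    idx <- match(tr$tu_id, decl$tu_id)
    hit <- !is.na(idx)
    outside <- hit & (tr$start < decl$start[idx] | tr$end > decl$end[idx])
    if (any(outside)) {
      stop("exon outside declared transcript span for: ",
           paste(tr$tu_id[outside], collapse = ", "))
    }
  }
  rpkm <- rep(NA_real_, nrow(tr))
  if ("RPKM" %in% names(m)) {
    v <- suppressWarnings(as.numeric(m$RPKM))
    first <- !duplicated(m$transcript_id)
    rpkm <- v[first][match(tr$tu_id, m$transcript_id[first])]
  }
  tr$rpkm <- rpkm
  src <- "tbone"
  if ("source" %in% names(m)) src <- as.character(m$source[1L])
  tr$source <- src
  tu_set(tr, ex)
}

gtf_line <- function(scaffold, source, type, start0, end0, strand, attrs) {
  sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t.\t%s",
          scaffold, source, type, start0 + 1L, end0, strand, attrs)
}

#' Write a tu_set as GTF
#' @param tus A [tu_set].
#' @param path Output path.
#' @param header Optional provenance header lines (prefixed `#`).
#' @export
write_gtf_tus <- function(tus, path, header = character()) {
  tr <- sort_interval_df(tus$transcripts, "tu_id")
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(header, con)
  for (i in seq_len(nrow(tr))) {
    t1 <- tr[i, ]
    ex <- tus$exons[tus$exons$tu_id == t1$tu_id, , drop = FALSE]
    at <- sprintf("gene_id \"%s\"; transcript_id \"%s\"; RPKM \"%s\";",
                  t1$tu_id, t1$tu_id,
                  ifelse(is.na(t1$rpkm), "NA", format(t1$rpkm, trim = TRUE)))
    writeLines(gtf_line(t1$scaffold, t1$source, "transcript", t1$start, t1$end,
                        t1$strand, at), con)
    for (j in seq_len(nrow(ex))) {
      writeLines(gtf_line(ex$scaffold[j], t1$source, "exon", ex$start[j],
                          ex$end[j], ex$strand[j], at), con)
    }
  }
  invisible(path)
}

## ---- BED / bedGraph / wiggle ----------------------------------------------

#' Read a BED file (3 or 6 columns)
#'
#' @param path Path to a BED file.
#' @return A data.frame `scaffold,start,end,name,score,strand` (missing BED
#'   columns filled with `"."`, `0`, `"."`).
#' @export
read_bed <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "bed"),
                 error = function(e) stop("malformed BED in ", path, ": ",
                                          conditionMessage(e), call. = FALSE))
  m <- S4Vectors::mcols(gr)
  data.frame(
    scaffold = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    name = if ("name" %in% names(m)) as.character(m$name) else ".",
    score = if ("score" %in% names(m) && !all(is.na(m$score))) as.numeric(m$score) else 0,
    strand = sub("\\*", ".", as.character(GenomicRanges::strand(gr))),
    stringsAsFactors = FALSE
  )
}

#' Write a BED6 file
#' @param df data.frame with columns `scaffold,start,end` and optionally
#'   `name,score,strand`.
#' @param path Output path.
#' @param header Optional header lines.
#' @export
write_bed <- function(df, path, header = character()) {
  if (!"name" %in% names(df)) df$name <- "."
  if (!"score" %in% names(df)) df$score <- 0
  if (!"strand" %in% names(df)) df$strand <- "."
  df <- df[order(df$scaffold, df$start, df$end, df$name), , drop = FALSE]
  lines <- sprintf("%s\t%d\t%d\t%s\t%s\t%s", df$scaffold, df$start, df$end,
                   df$name, format(df$score, trim = TRUE, scientific = FALSE),
                   df$strand)
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Read a bedGraph file
#' @param path Path to a bedGraph file.
#' @return data.frame `scaffold,start,end,count`.
#' @export
read_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  data.frame(
    scaffold = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    count = as.numeric(S4Vectors::mcols(gr)$score),
    stringsAsFactors = FALSE
  )
}

#' Write a bedGraph file
#' @param df data.frame `scaffold,start,end,count` (0-based half-open).
#' @param path Output path.
#' @param header Optional header lines.
#' @export
write_bedgraph <- function(df, path, header = character()) {
  df <- df[order(df$scaffold, df$start, df$end), , drop = FALSE]
  writeLines(c(header,
               sprintf("%s\t%d\t%d\t%s", df$scaffold, df$start, df$end,
                       format(df$count, trim = TRUE, scientific = FALSE))),
             path)
  invisible(path)
}

#' Read a fixedStep wiggle file (compatibility reader)
#'
#' @param path Path to a fixedStep wiggle file.
#' @return data.frame `scaffold,start,end,count` in 0-based half-open
#'   coordinates (wiggle declarations are 1-based).
#' @export
read_wiggle <- function(path) {
  lines <- readLines(path)
  out <- list()
  scaffold <- NULL; pos <- NA_integer_; step <- 1L; span <- 1L
  for (ln in lines) {
    if (startsWith(ln, "track") || startsWith(ln, "#") || ln == "") next
    if (startsWith(ln, "fixedStep")) {
      kv <- strsplit(strsplit(ln, "\\s+")[[1]][-1], "=")
      kv <- stats::setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
      scaffold <- kv[["chrom"]]
      pos <- as.integer(kv[["start"]]) - 1L
      step <- if ("step" %in% names(kv)) as.integer(kv[["step"]]) else 1L
      span <- if ("span" %in% names(kv)) as.integer(kv[["span"]]) else 1L
      next
    }
    if (is.null(scaffold)) stop("wiggle data line before fixedStep declaration")
    out[[length(out) + 1L]] <- data.frame(
      scaffold = scaffold, start = pos, end = pos + span,
      count = as.numeric(ln), stringsAsFactors = FALSE)
    pos <- pos + step
  }
  if (!length(out)) {
    return(data.frame(scaffold = character(), start = integer(),
                      end = integer(), count = numeric()))
  }
  do.call(rbind, out)
}

#' Read a tu_id to RPKM expression table
#' @param path Path to a two-column TSV (`tu_id<TAB>rpkm`), `#` comments and
#'   an optional header line allowed.
#' @return Named numeric vector.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          comment.char = "#", stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expression table must have two columns: ", path)
  if (is.character(df[[2L]])) df <- df[-1L, , drop = FALSE]  # header line
  v <- as.numeric(df[[2L]])
  if (anyNA(v)) stop("non-numeric rpkm value(s) in ", path)
  if (any(v < 0)) stop("negative rpkm value(s) in ", path)
  stats::setNames(v, as.character(df[[1L]]))
}

#' Write an expression table
#' @param expr Named numeric vector of RPKM values.
#' @param path Output path.
#' @export
write_expression_tsv <- function(expr, path) {
  expr <- expr[order(names(expr))]
  writeLines(c("tu_id\trpkm",
               sprintf("%s\t%s", names(expr), format(expr, trim = TRUE, scientific = FALSE))),
             path)
  invisible(path)
}
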