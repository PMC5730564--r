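# Codon-usage weight matrices from highly expressed genes, and deterministic
# codon optimization of coding sequences for transgene design. Weights are
# relative adaptiveness: per amino-acid family, codon count divided by the
# maximal synonymous count, so every family's preferred codon has weight 1.

SENSE_CODONS <- {
  gc <- Biostrings::GENETIC_CODE
  names(gc) <- chartr("U", "T", names(gc))
  sort(names(gc)[gc != "*"])
}

validate_cds <- function(cds) {
  for (id in names(cds)) {
    s <- cds[[id]]
    if (nchar(s) %% 3L != 0L) stop("CDS length not divisible by 3: ", id)
    if (substr(s, 1L, 3L) != "ATG") stop("CDS does not start with ATG: ", id)
    n <- nchar(s)
    codons <- substring(s, seq(1L, n, 3L), seq(3L, n, 3L))
    if (!codons[length(codons)] %in% STOP_CODONS) {
      stop("CDS does not end with a stop codon: ", id)
    }
    if (any(codons[-length(codons)] %in% STOP_CODONS)) {
      stop("internal stop codon in CDS: ", id)
    }
  }
  invisible(cds)
}

#' Build a codon weight matrix from top-expressed genes
#'
#' Selects the `top_n` most abundantly expressed genes (ties by identifier),
#' counts codon occurrences over their CDS excluding the terminal stop, and
#' derives per-codon relative adaptiveness. Zero-count codons receive a
#' pseudo-weight of `0.5 / max_family_count` so they are never selected by
#' the optimizer; an entirely unobserved family gets uniform weight 1
#' (flagged in the table).
#'
#' @param cds Named character vector of coding sequences (each `ATG ...
#'   stop`, validated). Redundant genes should be removed beforehand (see
#'   [cluster_nt()] / [dedupe_orf_aa()]).
#' @param expression Named numeric vector of RPKM values.
#' @param top_n Number of top genes to use, default 100. If fewer genes are
#'   available a warning is emitted and all are used.
#' @return An object of class `codon_weight_matrix`: list with `weight`
#'   (61 sense codons), `counts`, `stop_counts`, `source_gene_ids`, `table`.
#' @export
build_weight_matrix <- function(cds, expression, top_n = 100L) {
  validate_cds(cds)
  missing <- setdiff(names(cds), names(expression))
  if (length(missing)) stop("no expression for gene(s): ",
                            paste(missing, collapse = ", "))
  ids <- names(cds)[order(-expression[names(cds)], names(cds))]
  if (length(ids) < top_n) {
    warning("only ", length(ids), " genes available (top_n = ", top_n, ")")
  }
  ids <- utils::head(ids, top_n)
  counts <- stats::setNames(integer(length(SENSE_CODONS)), SENSE_CODONS)
  stop_counts <- stats::setNames(integer(3L), STOP_CODONS)
  for (id in ids) {
    s <- cds[[id]]
    n <- nchar(s)
    codons <- substring(s, seq(1L, n, 3L), seq(3L, n, 3L))
    stop_counts[codons[n %/% 3L]] <- stop_counts[codons[n %/% 3L]] + 1L
    codons <- codons[-(n %/% 3L)]
    tab <- table(codons)
    counts[names(tab)] <- counts[names(tab)] + as.integer(tab)
  }
  gc <- codon_table()
  aa <- gc[SENSE_CODONS]
  weight <- stats::setNames(numeric(length(SENSE_CODONS)), SENSE_CODONS)
  flagged <- character()
  for (a in unique(aa)) {
    fam <- SENSE_CODONS[aa == a]
    mx <- max(counts[fam])
    if (mx == 0L) {
      weight[fam] <- 1
      flagged <- c(flagged, a)
    } else {
      w <- counts[fam] / mx
      w[counts[fam] == 0L] <- 0.5 / mx
      weight[fam] <- w
    }
  }
  tab <- data.frame(codon = SENSE_CODONS, aa = unname(aa),
                    count = unname(counts[SENSE_CODONS]),
                    weight = unname(weight[SENSE_CODONS]),
                    unobserved_family = unname(aa) %in% flagged,
                    stringsAsFactors = FALSE)
  structure(list(weight = weight, counts = counts, stop_counts = stop_counts,
                 source_gene_ids = ids, table = tab),
            class = "codon_weight_matrix")
}

#' @export
print.codon_weight_matrix <- function(x, ...) {
  cat("codon_weight_matrix from", length(x$source_gene_ids), "genes;",
      sum(x$counts), "codons counted\n")
  invisible(x)
}

#' Write a codon weight matrix as TSV
#' @param matrix A `codon_weight_matrix`.
#' @param path Output path.
#' @export
write_weight_matrix_tsv <- function(matrix, path) {
  t <- matrix$table
  writeLines(c("codon\taa\tcount\tweight",
               sprintf("%s\t%s\t%d\t%.6g", t$codon, t$aa, t$count, t$weight)),
             path)
  invisible(path)
}

#' Emit a codon-optimized coding sequence
#'
#' In the default deterministic mode each residue is encoded by its
#' synonymous codon of weight 1 (ties to the alphabetically first codon);
#' the most frequently observed stop codon is appended. A seeded
#' weighted-sampling mode is available but not the default. The output
#' always translates back to the input protein.
#'
#' @param x A protein string, or a translatable CDS (detected by alphabet;
#'   translated first, terminal stop dropped).
#' @param matrix A `codon_weight_matrix` from [build_weight_matrix()].
#' @param mode `"max_weight"` (default) or `"sample"`.
#' @return Nucleotide string: optimized CDS including a stop codon.
#' @export
optimize_cds <- function(x, matrix, mode = c("max_weight", "sample")) {
  mode <- match.arg(mode)
  x <- toupper(x)
  # CDS detection heuristic: pure-nucleotide alphabet, whole codons, ends in
  # a stop with no internal stop. (A protein written entirely in A/C/G/T
  # residues that happens to satisfy this is translated; pass proteins with
  # at least one non-ACGT residue, or CDS, for unambiguous behaviour.)
  if (grepl("^[ACGT]+$", x) && nchar(x) %% 3L == 0L && nchar(x) >= 6L) {
    aa <- translate_cds(x)
    if (endsWith(aa, "*") && !grepl("\\*", substr(aa, 1L, nchar(aa) - 1L))) {
      x <- substr(aa, 1L, nchar(aa) - 1L)
    }
  }
  residues <- strsplit(x, "")[[1L]]
  gc <- codon_table()
  aa_of <- gc[SENSE_CODONS]
  known <- unique(unname(aa_of))
  bad <- setdiff(unique(residues), known)
  if (length(bad)) stop("unknown residue symbol(s): ", paste(bad, collapse = ", "))
  pick <- vapply(known, function(a) {
    fam <- SENSE_CODONS[aa_of == a]
    w <- matrix$weight[fam]
    sort(fam[w == max(w)])[1L]  # tie -> alphabetical
  }, "")
  names(pick) <- known
  if (mode == "max_weight") {
    body <- paste(pick[residues], collapse = "")
  } else {
    body <- paste(vapply(residues, function(a) {
      fam <- SENSE_CODONS[aa_of == a]
      sample(fam, 1L, prob = matrix$weight[fam])
    }, ""), collapse = "")
  }
  stop_codon <- if (all(matrix$stop_counts == 0L)) "TAA" else
    sort(names(matrix$stop_counts)[matrix$stop_counts == max(matrix$stop_counts)])[1L]
  paste0(body, stop_codon)
}
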