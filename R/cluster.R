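.submat_cache <- new.env(parent = emptyenv())
nt_submat <- function() {
  if (is.null(.submat_cache$m)) {
    .submat_cache$m <- Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -2, baseOnly = FALSE)
  }
  .submat_cache$m
}

# Redundancy handling: greedy incremental clustering of transcripts at 95%
# nucleotide identity (denominator = length of the shorter sequence, the
# conventional semantics of -c in greedy clustering tools; reverse-complement
# comparison disabled, mirroring -r 0), exact amino-acid deduplication of
# ORFs, and cluster-aware naming.

#' Global-alignment nucleotide identity between two sequences
#'
#' Identity is identical aligned bases divided by the length of the shorter
#' sequence.
#'
#' @param a,b Nucleotide strings.
#' @return Identity in `[0, 1]`.
#' @export
alignment_identity <- function(a, b) {
  pa <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                      substitutionMatrix = nt_submat(),
                                      gapOpening = 5, gapExtension = 2)
  Biostrings::nmatch(pa) / min(nchar(a), nchar(b))
}

#' Greedy nucleotide-identity clustering
#'
#' Sequences are sorted by length descending (ties by identifier); each
#' sequence joins the first existing cluster whose representative it matches
#' at `identity_threshold` or better, otherwise it founds a new cluster.
#' Reverse-complement comparison is disabled: a sequence and its reverse
#' complement land in different clusters.
#'
#' @param seqs Named character vector of non-empty nucleotide sequences.
#' @param identity_threshold Identity threshold in `(0.5, 1]`, default 0.95.
#' @return data.frame `member_id, representative_id, identity_to_rep`
#'   (representatives map to themselves with identity 1).
#' @export
cluster_nt <- function(seqs, identity_threshold = 0.95) {
  stopifnot(identity_threshold > 0.5, identity_threshold <= 1)
  if (any(nchar(seqs) == 0L)) {
    stop("empty sequence(s): ",
         paste(names(seqs)[nchar(seqs) == 0L], collapse = ", "))
  }
  ord <- order(-nchar(seqs), names(seqs))
  seqs <- seqs[ord]
  reps <- character()
  member <- character(); repr <- character(); ident <- numeric()
  for (i in seq_along(seqs)) {
    id <- names(seqs)[i]
    assigned <- FALSE
    for (r in reps) {  # founding order
      idy <- alignment_identity(seqs[[i]], seqs[[r]])
      if (idy >= identity_threshold) {
        member <- c(member, id); repr <- c(repr, r); ident <- c(ident, idy)
        assigned <- TRUE
        break
      }
    }
    if (!assigned) {
      reps <- c(reps, id)
      member <- c(member, id); repr <- c(repr, id); ident <- c(ident, 1)
    }
  }
  data.frame(member_id = member, representative_id = repr,
             identity_to_rep = ident, stringsAsFactors = FALSE)
}

#' Deduplicate ORFs at 100% amino-acid identity
#'
#' @param proteins Named character vector of protein sequences.
#' @param source_len Optional named numeric: length of the source transcript
#'   per id (defaults to protein length). Among identical proteins the id
#'   with the longest source transcript is kept; ties by identifier.
#' @return List: `kept` (character vector of ids) and `mapping` data.frame
#'   `member_id, kept_id`.
#' @export
dedupe_orf_aa <- function(proteins, source_len = NULL) {
  if (length(proteins) == 0L) {
    return(list(kept = character(),
                mapping = data.frame(member_id = character(),
                                     kept_id = character(),
                                     stringsAsFactors = FALSE)))
  }
  if (is.null(source_len)) {
    source_len <- stats::setNames(nchar(proteins), names(proteins))
  }
  sp <- split(names(proteins), unname(proteins))
  mapping <- do.call(rbind, lapply(sp, function(ids) {
    ids <- ids[order(-source_len[ids], ids)]
    data.frame(member_id = ids, kept_id = ids[1L], stringsAsFactors = FALSE)
  }))
  mapping <- mapping[order(mapping$member_id), , drop = FALSE]
  rownames(mapping) <- NULL
  list(kept = sort(unique(mapping$kept_id)), mapping = mapping)
}

#' Assign cluster-aware names
#'
#' Clustered transcripts share a numeric prefix: member `j` of cluster `i`
#' is named `<prefix><i, zero-padded>.g<j>`. Clusters are numbered by sorted
#' representative id; within a cluster the representative is member 1 and
#' remaining members follow in sorted order.
#'
#' @param assignment Output of [cluster_nt()].
#' @param prefix Name prefix (default `"Mlig"`).
#' @param pad Zero-padding width of the cluster number.
#' @return Named character vector: `member_id` -> name (bijective).
#' @export
assign_cluster_names <- function(assignment, prefix = "Mlig", pad = 6L) {
  reps <- sort(unique(assignment$representative_id))
  out <- character(0)
  for (i in seq_along(reps)) {
    members <- assignment$member_id[assignment$representative_id == reps[i]]
    members <- c(reps[i], sort(setdiff(members, reps[i])))
    nm <- sprintf("%s%0*d.g%d", prefix, pad, i, seq_along(members))
    out[members] <- nm
  }
  out
}
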