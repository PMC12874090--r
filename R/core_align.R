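#' Construct a catalog of protein records
#'
#' A protein catalog is a plain `data.frame` with columns `id`, `sample_id`
#' and `sequence` — the unit that flows through search, curation and
#' quantification. Sequences are validated against the 20 amino-acid
#' letters plus `X`.
#'
#' @param id Character vector of record identifiers, unique within the
#'   catalog.
#' @param sample_id Character vector (recycled) naming the sample of origin.
#' @param sequence Character vector of uppercase amino-acid sequences.
#' @return A `data.frame` with columns `id`, `sample_id`, `sequence`.
#' @export
protein_records <- function(id, sequence, sample_id = NA_character_) {
  id <- as.character(id)
  sequence <- toupper(as.character(sequence))
  if (length(id) != length(sequence))
    input_error("id and sequence lengths differ")
  if (anyDuplicated(id))
    input_error("duplicate record ids: %s",
                paste(unique(id[duplicated(id)]), collapse = ", "))
  if (any(!nzchar(sequence)))
    input_error("empty sequence for record %s", id[!nzchar(sequence)][1])
  bad <- vapply(sequence, function(s) anyNA(encode_seq(s)), logical(1))
  if (any(bad))
    input_error("unknown residue character in record %s", id[bad][1])
  data.frame(id = id, sample_id = rep_len(as.character(sample_id), length(id)),
             sequence = sequence, stringsAsFactors = FALSE)
}

#' Alignment parameters
#'
#' Affine-gap scoring parameters for global protein alignment. A gap of
#' length k costs `gap_open + (k - 1) * gap_extend`; end gaps are penalized
#' like any other gap (true global alignment).
#'
#' @param matrix_name Substitution matrix name (see [scoring_matrix()]).
#' @param gap_open Score for opening a gap (non-positive).
#' @param gap_extend Score for each additional gapped column (non-positive,
#'   with `|gap_open| >= |gap_extend|`).
#' @return An object of class `align_params`.
#' @export
align_params <- function(matrix_name = "BLOSUM62", gap_open = -11,
                         gap_extend = -1) {
  if (gap_open > 0 || gap_extend > 0 || abs(gap_open) < abs(gap_extend))
    input_error("require gap_open <= 0, gap_extend <= 0, |gap_open| >= |gap_extend|")
  structure(list(matrix_name = matrix_name,
                 smat = scoring_matrix(matrix_name),
                 gap_open = as.numeric(gap_open),
                 gap_extend = as.numeric(gap_extend)),
            class = "align_params")
}

# accept a plain string or a one-row protein_records data.frame
.as_seq <- function(x, what = "sequence") {
  if (is.data.frame(x)) {
    if (nrow(x) != 1L)
      input_error("%s: expected a single record, got %d rows", what, nrow(x))
    return(list(seq = x$sequence[[1]], id = x$id[[1]]))
  }
  list(seq = toupper(as.character(x)[1]), id = what)
}

.check_seq <- function(s, id) {
  if (is.na(s) || !nzchar(s))
    input_error("empty sequence in record %s", id)
  if (anyNA(encode_seq(s)))
    input_error("unknown residue character in record %s", id)
  s
}

#' Optimal global alignment of two protein sequences
#'
#' Needleman-Wunsch with affine gap penalties and penalized end gaps.
#' Traceback ties are broken deterministically: diagonal, then gap-in-b
#' ("up"), then gap-in-a ("left"). Identity uses the CD-HIT convention:
#' identical columns divided by the length of the shorter unaligned
#' sequence; `X` never counts as identical.
#'
#' @param a,b Sequences (strings or single-row catalogs, see
#'   [protein_records()]).
#' @param params An [align_params()] object.
#' @return A list of class `protein_alignment` with `aligned_a`,
#'   `aligned_b`, `score`, `n_identical`, `identity`.
#' @export
global_align <- function(a, b, params = align_params()) {
  sa <- .as_seq(a, "a"); sb <- .as_seq(b, "b")
  .check_seq(sa$seq, sa$id); .check_seq(sb$seq, sb$id)
  res <- cpp_global_align(sa$seq, sb$seq, params$smat,
                          params$gap_open, params$gap_extend, TRUE)
  res$identity <- percent_identity(res, nchar(sa$seq), nchar(sb$seq))
  class(res) <- "protein_alignment"
  res
}

# score-only variant used in inner loops
.align_score <- function(a, b, params) {
  cpp_global_align(a, b, params$smat, params$gap_open, params$gap_extend,
                   FALSE)$score
}

#' Alignment identity under the short-sequence denominator
#'
#' @param aln An alignment with an `n_identical` field.
#' @param len_a,len_b Unaligned sequence lengths.
#' @return Fraction in `[0, 1]`: `n_identical / min(len_a, len_b)`.
#' @export
percent_identity <- function(aln, len_a, len_b) {
  aln$n_identical / min(len_a, len_b)
}

#' Greedy dereplication at an identity threshold
#'
#' CD-HIT-style greedy incremental clustering: records are sorted by
#' descending length (ties by ascending id) and each record joins the first
#' existing cluster whose representative it matches at `>= threshold`
#' identity, else founds a new cluster. Representatives are therefore the
#' longest member of each cluster (ties by id). Output clusters follow
#' founding order.
#'
#' @param records A protein catalog ([protein_records()]).
#' @param threshold Identity threshold in `(0, 1]` (default 0.90).
#' @param params An [align_params()] object.
#' @return A list of class `cluster_set`: `clusters` (list of
#'   `list(representative, members)`), `threshold`, and `table`
#'   (`data.frame` with `cluster_id`, `representative_id`, `member_id`,
#'   `identity_to_representative`).
#' @export
dereplicate <- function(records, threshold = 0.9, params = align_params()) {
  if (threshold <= 0 || threshold > 1)
    input_error("threshold must be in (0, 1]")
  empty <- structure(list(clusters = list(), threshold = threshold,
                          table = data.frame(cluster_id = integer(),
                                             representative_id = character(),
                                             member_id = character(),
                                             identity_to_representative = numeric())),
                     class = "cluster_set")
  if (is.null(records) || nrow(records) == 0L) return(empty)

  ord <- order(-nchar(records$sequence), records$id)
  rec <- records[ord, , drop = FALSE]
  reps_id <- character(0); reps_seq <- character(0); reps_len <- integer(0)
  member_cluster <- integer(nrow(rec)); member_ident <- numeric(nrow(rec))
  for (k in seq_len(nrow(rec))) {
    s <- rec$sequence[k]; ln <- nchar(s)
    placed <- FALSE
    if (length(reps_id)) {
      for (ci in seq_along(reps_id)) {
        aln <- cpp_global_align(reps_seq[ci], s, params$smat,
                                params$gap_open, params$gap_extend, TRUE)
        ident <- aln$n_identical / min(reps_len[ci], ln)
        if (ident >= threshold) {
          member_cluster[k] <- ci; member_ident[k] <- ident
          placed <- TRUE; break
        }
      }
    }
    if (!placed) {
      reps_id <- c(reps_id, rec$id[k]); reps_seq <- c(reps_seq, s)
      reps_len <- c(reps_len, ln)
      member_cluster[k] <- length(reps_id); member_ident[k] <- 1
    }
  }
  clusters <- lapply(seq_along(reps_id), function(ci)
    list(representative = reps_id[ci],
         members = rec$id[member_cluster == ci]))
  tab <- data.frame(cluster_id = member_cluster,
                    representative_id = reps_id[member_cluster],
                    member_id = rec$id,
                    identity_to_representative = member_ident,
                    stringsAsFactors = FALSE)
  tab <- tab[order(tab$cluster_id), , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(clusters = clusters, threshold = threshold, table = tab),
            class = "cluster_set")
}

#' Write a cluster table as TSV
#'
#' @param cs A `cluster_set` from [dereplicate()].
#' @param path Output file path.
#' @export
write_cluster_tsv <- function(cs, path) {
  write_tsv(cs$table, path)
}
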