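#' Sample contexts
#'
#' @param sample_id,station,depth_m Equal-length vectors; `(station,
#'   depth_m)` must be unique per sample.
#' @return A `data.frame` with one row per sample.
#' @export
sample_contexts <- function(sample_id, station, depth_m) {
  if (anyDuplicated(paste(station, depth_m)))
    input_error("(station, depth_m) pairs must be unique")
  if (any(depth_m <= 0)) input_error("depth_m must be positive")
  data.frame(sample_id = as.character(sample_id),
             station = as.character(station),
             depth_m = as.numeric(depth_m), stringsAsFactors = FALSE)
}

#' Count validated records per sample and family
#'
#' Counts only records that passed curation; every sample in `contexts`
#' appears for every family, with zero counts where nothing passed.
#'
#' @param results Validation `data.frame` from [validate_hits()].
#' @param contexts A [sample_contexts()] table.
#' @param families Families to tabulate.
#' @return A `data.frame`: `sample_id`, `family`, `validated_count`.
#' @export
count_validated <- function(results, contexts,
                            families = c("hgcA", "hgcB", "merA", "merB")) {
  if (nrow(results)) {
    orphan <- setdiff(results$sample_id, contexts$sample_id)
    if (length(orphan))
      input_error("validation results reference unknown sample_id: %s",
                  orphan[1])
  }
  grid <- expand.grid(sample_id = contexts$sample_id, family = families,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  passed <- results[results$passed & results$family %in% families, ,
                    drop = FALSE]
  key <- paste(passed$sample_id, passed$family)
  tab <- table(key)
  grid$validated_count <- as.integer(tab[paste(grid$sample_id, grid$family)])
  grid$validated_count[is.na(grid$validated_count)] <- 0L
  grid[order(grid$sample_id, grid$family), , drop = FALSE] -> grid
  rownames(grid) <- NULL
  grid
}

#' rpoB-normalized relative abundance
#'
#' Normalizes per-sample validated counts to the abundance of the
#' single-copy marker rpoB: `relative_pct = 100 * validated_count /
#' rpob_count`. A zero or missing rpoB count is an explicit error naming
#' the sample (never a silent NaN).
#'
#' @param counts Output of [count_validated()].
#' @param rpob_counts A `data.frame` with `sample_id`, `rpob_count`.
#' @return An abundance `data.frame`: `sample_id`, `family`,
#'   `validated_count`, `rpob_count`, `relative_pct`.
#' @export
relative_abundance <- function(counts, rpob_counts) {
  idx <- match(counts$sample_id, rpob_counts$sample_id)
  if (anyNA(idx))
    input_error("no rpoB count for sample %s",
                counts$sample_id[is.na(idx)][1])
  rc <- rpob_counts$rpob_count[idx]
  if (any(rc <= 0))
    input_error("rpoB count is zero for sample %s",
                counts$sample_id[rc <= 0][1])
  out <- counts
  out$rpob_count <- as.integer(rc)
  out$relative_pct <- 100 * out$validated_count / rc
  out
}

#' Assign a lineage by best labeled reference
#'
#' Stands in for tree placement: the candidate is globally aligned against
#' every labeled reference of its family and takes the lineage of the
#' best-scoring one (ties broken by ascending reference id). The score gap
#' to the second-best reference is reported as `margin`; assignments with
#' `margin < 5` bits are flagged `ambiguous` (the lineage is still the
#' argmax).
#'
#' @param record A single-row protein catalog.
#' @param labeled_references A `data.frame` with `id`, `lineage`,
#'   `sequence` for one family.
#' @param params An [align_params()] object.
#' @return One-row `data.frame`: `record_id`, `lineage`,
#'   `best_reference_id`, `score`, `margin`, `ambiguous`.
#' @export
assign_lineage <- function(record, labeled_references,
                           params = align_params()) {
  if (is.null(labeled_references) || nrow(labeled_references) == 0L)
    input_error("no labeled references for lineage assignment")
  refs <- labeled_references[order(labeled_references$id), , drop = FALSE]
  s <- .as_seq(record, "record")
  scores <- cpp_align_scores(s$seq, refs$sequence, params$smat,
                             params$gap_open, params$gap_extend)
  best <- which.max(scores) # first maximum = smallest id on ties
  margin <- if (nrow(refs) > 1L) scores[best] - max(scores[-best]) else Inf
  data.frame(record_id = s$id, lineage = refs$lineage[best],
             best_reference_id = refs$id[best], score = scores[best],
             margin = margin, ambiguous = margin < 5,
             stringsAsFactors = FALSE)
}

#' Assign lineages for a whole catalog of one family
#'
#' @param records Protein catalog.
#' @param labeled_references As in [assign_lineage()].
#' @param family Family label attached to the output.
#' @param params An [align_params()] object.
#' @return A `data.frame` with one row per record, including `family`.
#' @export
assign_lineages <- function(records, labeled_references, family,
                            params = align_params()) {
  rows <- lapply(seq_len(nrow(records)), function(k)
    assign_lineage(records[k, , drop = FALSE], labeled_references, params))
  out <- do.call(rbind, rows)
  out$sample_id <- records$sample_id
  out$family <- family
  out[, c("record_id", "sample_id", "family", "lineage",
          "best_reference_id", "score", "margin", "ambiguous")]
}

#' Lineage proportions per family
#'
#' Tabulates assigned lineages as percentages within each family; with
#' `stratify_by_depth = TRUE` the percentages are computed within each
#' (family, station, depth) stratum instead.
#'
#' @param assignments Output of [assign_lineages()] (families
#'   concatenated).
#' @param contexts A [sample_contexts()] table (required when
#'   stratifying).
#' @param stratify_by_depth Logical.
#' @return A `data.frame`: `family`, `lineage`, `n_records`,
#'   `pct_of_family` (plus `station`, `depth_m` when stratified). Within
#'   each group the percentages sum to 100.
#' @export
lineage_proportions <- function(assignments, contexts = NULL,
                                stratify_by_depth = FALSE) {
  a <- assignments
  if (stratify_by_depth) {
    if (is.null(contexts)) input_error("contexts required for stratification")
    idx <- match(a$sample_id, contexts$sample_id)
    if (anyNA(idx))
      input_error("assignment references unknown sample_id: %s",
                  a$sample_id[is.na(idx)][1])
    a$station <- contexts$station[idx]
    a$depth_m <- contexts$depth_m[idx]
    grp <- paste(a$family, a$station, a$depth_m, sep = "\r")
  } else {
    grp <- a$family
  }
  rows <- lapply(split(seq_len(nrow(a)), grp), function(i) {
    sub <- a[i, , drop = FALSE]
    tab <- table(sub$lineage)
    out <- data.frame(family = sub$family[1], lineage = names(tab),
                      n_records = as.integer(tab),
                      pct_of_family = 100 * as.integer(tab) / nrow(sub),
                      stringsAsFactors = FALSE)
    if (stratify_by_depth) {
      out$station <- sub$station[1]
      out$depth_m <- sub$depth_m[1]
    }
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  ord <- if (stratify_by_depth)
    order(out$family, out$station, out$depth_m, -out$pct_of_family,
          out$lineage)
  else order(out$family, -out$pct_of_family, out$lineage)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
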