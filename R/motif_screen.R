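#' Curation rules for mercury-gene families
#'
#' Encodes the conserved catalytic and metal-binding residues required of
#' each family, anchored to the ungapped 1-based coordinates of a named
#' reference sequence:
#' \itemize{
#'   \item hgcA: the strictly conserved cap-helix cysteine at position 93.
#'   \item hgcB: two ferredoxin-type `CX2CX2CX3C` cysteine clusters
#'     (a pattern count on the candidate itself, not a mapped position).
#'   \item merA: the catalytic cysteine pair 207/212, Tyr-264, Tyr-or-Phe
#'     605 (bacterial vs archaeal variants), and the C-terminal vicinal
#'     cysteine pair 628/629, in the numbering of the Bacillus sp. RC607
#'     mercuric reductase.
#'   \item merB: Cys-96, Asp-99, Cys-117 and Cys-159 of the R831b
#'     organomercury lyase.
#'   \item rpoB: no rules — it is the single-copy normalization marker,
#'     not a curated family.
#' }
#'
#' @param reference_ids Named character vector giving the anchor reference
#'   id for each family with residue rules. Real anchor sequences can be
#'   supplied as data; the defaults name the synthetic anchors produced by
#'   [make_reference_family()].
#' @return A list of class `rule_set`: per family, a list with
#'   `residue_rules` (data.frame), `pattern_rules` (data.frame) and
#'   `reference_id`.
#' @export
default_rulesets <- function(reference_ids = c(hgcA = "hgcA_anchor",
                                               merA = "merA_anchor",
                                               merB = "merB_anchor")) {
  rr <- function(family, position, allowed)
    data.frame(family = family, reference_id = reference_ids[[family]],
               position = as.integer(position), allowed = allowed,
               label = sprintf("%s:%s%d", family,
                               substr(allowed, 1, 1), position),
               stringsAsFactors = FALSE)
  pr <- function(family, pattern, min_count, label)
    data.frame(family = family, pattern = pattern,
               min_count = as.integer(min_count), label = label,
               stringsAsFactors = FALSE)
  empty_rr <- data.frame(family = character(), reference_id = character(),
                         position = integer(), allowed = character(),
                         label = character(), stringsAsFactors = FALSE)
  empty_pr <- data.frame(family = character(), pattern = character(),
                         min_count = integer(), label = character(),
                         stringsAsFactors = FALSE)
  structure(list(
    hgcA = list(residue_rules = rr("hgcA", 93, "C"),
                pattern_rules = empty_pr,
                reference_id = reference_ids[["hgcA"]]),
    hgcB = list(residue_rules = empty_rr,
                pattern_rules = pr("hgcB", "CX2CX2CX3C", 2L,
                                   "hgcB:2xCX2CX2CX3C"),
                reference_id = NA_character_),
    merA = list(residue_rules = rbind(rr("merA", 207, "C"),
                                      rr("merA", 212, "C"),
                                      rr("merA", 264, "Y"),
                                      rr("merA", 605, "YF"),
                                      rr("merA", 628, "C"),
                                      rr("merA", 629, "C")),
                pattern_rules = empty_pr,
                reference_id = reference_ids[["merA"]]),
    merB = list(residue_rules = rbind(rr("merB", 96, "C"),
                                      rr("merB", 99, "D"),
                                      rr("merB", 117, "C"),
                                      rr("merB", 159, "C")),
                pattern_rules = empty_pr,
                reference_id = reference_ids[["merB"]]),
    rpoB = list(residue_rules = empty_rr, pattern_rules = empty_pr,
                reference_id = NA_character_)
  ), class = "rule_set")
}

# "CX2CX2CX3C" -> regex "C..C..C...C"
.pattern_regex <- function(pattern) {
  out <- character(0)
  toks <- regmatches(pattern, gregexpr("[A-Z]|[0-9]+", pattern))[[1]]
  i <- 1
  while (i <= length(toks)) {
    if (toks[i] == "X") {
      if (i < length(toks) && grepl("^[0-9]+$", toks[i + 1])) {
        out <- c(out, strrep(".", as.integer(toks[i + 1]))); i <- i + 2
      } else {
        out <- c(out, "."); i <- i + 1
      }
    } else {
      out <- c(out, toks[i]); i <- i + 1
    }
  }
  paste(out, collapse = "")
}

#' Map a reference coordinate through an alignment
#'
#' Given a global alignment with the reference as sequence `a` and a
#' candidate as sequence `b`, returns the candidate character in the
#' alignment column holding the `position`-th non-gap reference character,
#' or `"GAP"` when the candidate has a gap there. The mapping is by
#' reference coordinates, so it is invariant to insertions in the
#' candidate.
#'
#' @param aln A `protein_alignment` (reference as `a`).
#' @param position 1-based index into the ungapped reference.
#' @return Single residue character, or `"GAP"`.
#' @export
map_reference_position <- function(aln, position) {
  achars <- strsplit(aln$aligned_a, "")[[1]]
  ref_idx <- cumsum(achars != "-")
  col <- match(position, ref_idx)
  if (is.na(col))
    input_error("position %d beyond reference length %d", position,
                max(ref_idx))
  b <- substr(aln$aligned_b, col, col)
  if (b == "-") "GAP" else b
}

#' Check a candidate against a family's residue rules
#'
#' Computes one global alignment of the family's anchor reference against
#' the candidate and evaluates every rule: a candidate residue outside the
#' rule's allowed set — or a gap at the rule position — fails that rule.
#'
#' @param candidate,reference Sequences (strings or single-row catalogs).
#' @param rules A `residue_rules` data.frame (see [default_rulesets()]).
#' @param params An [align_params()] object.
#' @return A list of class `validation_result`: `record_id`, `family`,
#'   `passed`, `failed_rules`, `positions_checked` (data.frame `label`,
#'   `observed`).
#' @export
check_residue_rules <- function(candidate, reference, rules,
                                params = align_params()) {
  aln <- global_align(reference, candidate, params)
  observed <- vapply(rules$position, function(p)
    map_reference_position(aln, p), character(1))
  ok <- mapply(function(obs, allowed) {
    obs != "GAP" && grepl(obs, allowed, fixed = TRUE)
  }, observed, rules$allowed)
  rec_id <- if (is.data.frame(candidate)) candidate$id[[1]] else NA_character_
  structure(list(record_id = rec_id,
                 family = if (nrow(rules)) rules$family[[1]] else NA_character_,
                 passed = all(ok),
                 failed_rules = rules$label[!ok],
                 positions_checked = data.frame(label = rules$label,
                                                observed = observed,
                                                stringsAsFactors = FALSE)),
            class = "validation_result")
}

#' Count occurrences of a cysteine-cluster pattern
#'
#' Counts non-overlapping left-to-right occurrences of an ordered residue
#' template (e.g. `CX2CX2CX3C`) in the raw candidate sequence.
#'
#' @param candidate Sequence (string or single-row catalog).
#' @param rule One row of a `pattern_rules` data.frame.
#' @return A list with `count` and `passed` (`count >= min_count`).
#' @export
check_pattern_rule <- function(candidate, rule) {
  s <- .as_seq(candidate, "candidate")$seq
  rx <- .pattern_regex(rule$pattern[[1]])
  m <- gregexpr(rx, s)[[1]]
  count <- if (m[1] == -1L) 0L else length(m)
  list(count = count, passed = count >= rule$min_count[[1]])
}

#' Validate HMM hits against the family rule sets
#'
#' Applies the conserved-residue curation to every hit: residue rules are
#' checked via one global alignment to the family anchor, pattern rules on
#' the raw candidate. Families with empty rule lists (rpoB) pass
#' automatically.
#'
#' @param hits Hit `data.frame` from [search_catalog()] (possibly several
#'   families concatenated).
#' @param catalog The searched protein catalog.
#' @param rulesets A [default_rulesets()]-style `rule_set`.
#' @param references Named list mapping each family with residue rules to
#'   its anchor record (single-row catalog whose id matches the ruleset's
#'   `reference_id`).
#' @param params An [align_params()] object.
#' @return A `data.frame` with one row per hit: `record_id`, `sample_id`,
#'   `family`, `passed`, `failed_rules` (semicolon-joined labels), plus an
#'   attribute `"positions"` holding the long table of observed residues
#'   per residue rule.
#' @export
validate_hits <- function(hits, catalog, rulesets, references,
                          params = align_params()) {
  out <- data.frame(record_id = character(), sample_id = character(),
                    family = character(), passed = logical(),
                    failed_rules = character(), stringsAsFactors = FALSE)
  pos_long <- list()
  if (is.null(hits) || nrow(hits) == 0L) {
    attr(out, "positions") <- data.frame(record_id = character(),
                                         label = character(),
                                         observed = character())
    return(out)
  }
  idx <- match(hits$record_id, catalog$id)
  if (anyNA(idx))
    input_error("hit references unknown record id: %s",
                hits$record_id[is.na(idx)][1])
  rows <- vector("list", nrow(hits))
  for (k in seq_len(nrow(hits))) {
    fam <- hits$family[k]
    fs <- rulesets[[fam]]
    if (is.null(fs))
      input_error("no ruleset entry for family '%s'", fam)
    rec <- catalog[idx[k], , drop = FALSE]
    failed <- character(0)
    if (nrow(fs$residue_rules)) {
      anchor <- references[[fam]]
      if (is.null(anchor))
        input_error("no anchor reference supplied for family '%s'", fam)
      if (!identical(anchor$id[[1]], fs$reference_id))
        input_error("anchor id '%s' does not match ruleset anchor '%s'",
                    anchor$id[[1]], fs$reference_id)
      vr <- check_residue_rules(rec, anchor, fs$residue_rules, params)
      failed <- c(failed, vr$failed_rules)
      pl <- vr$positions_checked
      pl$record_id <- rec$id[[1]]
      pos_long[[length(pos_long) + 1L]] <- pl
    }
    if (nrow(fs$pattern_rules)) {
      for (pk in seq_len(nrow(fs$pattern_rules))) {
        pr <- check_pattern_rule(rec, fs$pattern_rules[pk, , drop = FALSE])
        if (!pr$passed) failed <- c(failed, fs$pattern_rules$label[pk])
      }
    }
    rows[[k]] <- data.frame(record_id = rec$id[[1]],
                            sample_id = rec$sample_id[[1]],
                            family = fam, passed = length(failed) == 0L,
                            failed_rules = paste(failed, collapse = ";"),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "positions") <-
    if (length(pos_long)) do.call(rbind, pos_long)[, c("record_id", "label",
                                                       "observed")]
    else data.frame(record_id = character(), label = character(),
                    observed = character())
  out
}

#' Read or write a rule file
#'
#' Rules ship as an editable TSV (`family`, `rule_type`, `reference_id`,
#' `position`, `allowed`, `pattern`, `min_count`, `label`) so real anchor
#' sequences and rules can replace the defaults without code changes.
#'
#' @param rulesets A `rule_set`.
#' @param path File path.
#' @export
write_rules <- function(rulesets, path) {
  rows <- list()
  for (fam in names(rulesets)) {
    fs <- rulesets[[fam]]
    if (nrow(fs$residue_rules))
      rows[[length(rows) + 1L]] <-
        data.frame(family = fam, rule_type = "residue",
                   reference_id = fs$reference_id,
                   position = fs$residue_rules$position,
                   allowed = fs$residue_rules$allowed,
                   pattern = "", min_count = NA_integer_,
                   label = fs$residue_rules$label, stringsAsFactors = FALSE)
    if (nrow(fs$pattern_rules))
      rows[[length(rows) + 1L]] <-
        data.frame(family = fam, rule_type = "pattern",
                   reference_id = "", position = NA_integer_, allowed = "",
                   pattern = fs$pattern_rules$pattern,
                   min_count = fs$pattern_rules$min_count,
                   label = fs$pattern_rules$label, stringsAsFactors = FALSE)
    if (!nrow(fs$residue_rules) && !nrow(fs$pattern_rules))
      rows[[length(rows) + 1L]] <-
        data.frame(family = fam, rule_type = "none", reference_id = "",
                   position = NA_integer_, allowed = "", pattern = "",
                   min_count = NA_integer_, label = "",
                   stringsAsFactors = FALSE)
  }
  write_tsv(do.call(rbind, rows), path)
}

#' @rdname write_rules
#' @return `read_rules()` returns a `rule_set`.
#' @export
read_rules <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  out <- list()
  for (fam in unique(tab$family)) {
    sub <- tab[tab$family == fam, , drop = FALSE]
    res <- sub[sub$rule_type == "residue", , drop = FALSE]
    pat <- sub[sub$rule_type == "pattern", , drop = FALSE]
    out[[fam]] <- list(
      residue_rules = data.frame(family = res$family,
                                 reference_id = res$reference_id,
                                 position = as.integer(res$position),
                                 allowed = res$allowed, label = res$label,
                                 stringsAsFactors = FALSE),
      pattern_rules = data.frame(family = pat$family, pattern = pat$pattern,
                                 min_count = as.integer(pat$min_count),
                                 label = pat$label, stringsAsFactors = FALSE),
      reference_id = if (nrow(res)) res$reference_id[[1]] else NA_character_)
  }
  structure(out, class = "rule_set")
}

#' Write a validation report as TSV
#'
#' One row per hit with `record_id`, `sample_id`, `family`, `passed`,
#' `failed_rules`, plus one column per residue rule holding the observed
#' candidate residue (or GAP).
#'
#' @param results Output of [validate_hits()].
#' @param path Output path.
#' @export
write_validation_tsv <- function(results, path) {
  pos <- attr(results, "positions")
  wide <- results
  if (!is.null(pos) && nrow(pos)) {
    for (lab in unique(pos$label)) {
      sub <- pos[pos$label == lab, , drop = FALSE]
      wide[[lab]] <- sub$observed[match(wide$record_id, sub$record_id)]
    }
  }
  write_tsv(wide, path)
}
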