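# Seeded generators for reference families, sample catalogs with ground
# truth, and environment tables. The defaults encode the benchmark world:
# 3 stations x 4 depths (200-1,500 m), Hg-gene counts increasing into the
# mesopelagic, dMeHg/AOU/nutrients increasing and temperature/O2/cells
# decreasing with depth.

#' Design for one synthetic reference family
#'
#' @param family Family label.
#' @param length Ungapped template length in residues (must exceed every
#'   rule coordinate).
#' @param lineages Named integer vector: references per lineage.
#' @param ruleset Entry of a [default_rulesets()] `rule_set` for this
#'   family.
#' @param divergence Per-reference fraction of differing sites (lineage
#'   marker sites count toward the budget, so pairwise reference identity
#'   stays `>= 1 - 2 * divergence`). In `[0, 0.3]`.
#' @param n_markers Lineage-specific marker sites per lineage.
#' @param indel_len Length of the deletion planted in every third
#'   reference (0 disables); always placed outside rule and marker sites.
#' @param seed Integer seed.
#' @return A list of class `family_design`.
#' @export
family_design <- function(family, length, lineages, ruleset,
                          divergence = 0.08, n_markers = 10L,
                          indel_len = 3L, seed = 1L) {
  if (divergence < 0 || divergence > 0.3)
    input_error("divergence must be in [0, 0.3]")
  if (any(ruleset$residue_rules$position > length))
    input_error("rule position beyond template length for %s", family)
  structure(list(family = family, length = as.integer(length),
                 lineages = lineages, ruleset = ruleset,
                 divergence = divergence, n_markers = as.integer(n_markers),
                 indel_len = as.integer(indel_len), seed = as.integer(seed)),
            class = "family_design")
}

# positions of the planted pattern-rule cysteines, and window starts
.pattern_plant <- function(pattern, min_count, length) {
  rx <- .pattern_regex(pattern)
  w <- nchar(gsub("\\\\", "", rx)) # window width (pattern has no escapes)
  starts <- 20L + (seq_len(min_count) - 1L) * (w + 9L)
  if (max(starts) + w - 1L > length)
    input_error("template too short to plant %d pattern occurrences",
                min_count)
  chars <- strsplit(rx, "")[[1]]
  fixed <- which(chars != ".")
  list(starts = starts, width = w,
       positions = as.integer(outer(fixed - 1L, starts, "+")),
       letters = rep(chars[fixed], times = length(starts)))
}

.sample_residue <- function(n, exclude_c = FALSE) {
  pool <- if (exclude_c) setdiff(AA20, "C") else AA20
  sample(pool, n, replace = TRUE)
}

# mutate positions `at` of a character vector to a different residue
.mutate_sites <- function(chars, at, exclude_c = FALSE) {
  for (p in at) {
    pool <- setdiff(if (exclude_c) setdiff(AA20, "C") else AA20, chars[p])
    chars[p] <- sample(pool, 1)
  }
  chars
}

#' Generate a synthetic reference family
#'
#' Draws a template sequence with all required rule residues planted,
#' derives lineage-labeled references by lineage-specific marker
#' substitutions plus random point mutations that never touch rule sites,
#' optionally plants short deletions in some references, and returns the
#' exact MSA (anchor + references). For families with a cysteine-cluster
#' pattern rule the background is kept cysteine-free outside the planted
#' motifs, so motif counts are exact by construction.
#'
#' @param design A [family_design()].
#' @return A list of class `reference_family`: `family`, `anchor`
#'   (single-row catalog), `references` (data.frame `id`, `lineage`,
#'   `sequence`), `msa`, `rule_positions` (per reference id, the rule
#'   coordinates in that reference's own ungapped sequence), `design`.
#' @export
make_reference_family <- function(design) {
  set.seed(design$seed)
  L <- design$length
  fam <- design$family
  rs <- design$ruleset
  no_c <- nrow(rs$pattern_rules) > 0L

  # template with planted rule residues
  tmpl <- .sample_residue(L, exclude_c = no_c)
  rule_pos <- integer(0); rule_letter <- character(0)
  if (nrow(rs$residue_rules)) {
    rule_pos <- rs$residue_rules$position
    rule_letter <- substr(rs$residue_rules$allowed, 1, 1)
  }
  if (nrow(rs$pattern_rules)) {
    pp <- .pattern_plant(rs$pattern_rules$pattern[1],
                         rs$pattern_rules$min_count[1], L)
    rule_pos <- c(rule_pos, pp$positions)
    rule_letter <- c(rule_letter, pp$letters)
  }
  if (anyDuplicated(rule_pos)) input_error("rule position conflict in %s", fam)
  tmpl[rule_pos] <- rule_letter

  # lineage marker sites: disjoint, outside rule sites
  lineage_names <- names(design$lineages)
  free <- setdiff(seq_len(L), rule_pos)
  marker_sites <- list()
  for (ln in lineage_names) {
    sites <- sample(free, design$n_markers)
    free <- setdiff(free, sites)
    marker_sites[[ln]] <- sort(sites)
  }

  # one deletion window shared by the refs that carry it
  del_window <- integer(0)
  if (design$indel_len > 0L) {
    safe <- setdiff(seq_len(L), c(rule_pos, unlist(marker_sites)))
    runs <- split(safe, cumsum(c(1, diff(safe) != 1)))
    runs <- Filter(function(r) length(r) >= design$indel_len, runs)
    if (length(runs)) {
      r <- runs[[which.max(vapply(runs, length, integer(1)))]]
      del_window <- r[seq_len(design$indel_len)]
    }
  }

  n_mut <- max(0L, round(design$divergence * L) - design$n_markers)
  refs <- list(); msa_rows <- character(0); rule_positions <- list()
  anchor_id <- paste0(fam, "_anchor")
  msa_ids <- anchor_id
  msa_rows <- paste(tmpl, collapse = "")
  rule_positions[[anchor_id]] <- rule_pos
  k <- 0L
  for (ln in lineage_names) {
    for (j in seq_len(design$lineages[[ln]])) {
      k <- k + 1L
      has_del <- length(del_window) > 0L && k %% 3L == 0L
      chars <- tmpl
      chars <- .mutate_sites(chars, marker_sites[[ln]], exclude_c = no_c)
      pool <- setdiff(seq_len(L), c(rule_pos, marker_sites[[ln]], del_window))
      # deleted residues count against the divergence budget so pairwise
      # identity stays >= 1 - 2 * divergence under the min-length denominator
      n_mut_k <- max(0L, n_mut - if (has_del) design$indel_len else 0L)
      if (n_mut_k > 0L)
        chars <- .mutate_sites(chars,
                               sample(pool, min(n_mut_k, length(pool))),
                               exclude_c = no_c)
      row <- chars
      if (has_del) row[del_window] <- "-"
      id <- sprintf("%s_%s_%02d", fam, ln, j)
      refs[[id]] <- list(lineage = ln,
                         sequence = paste(row[row != "-"], collapse = ""))
      msa_ids <- c(msa_ids, id)
      msa_rows <- c(msa_rows, paste(row, collapse = ""))
      # rule coordinates in this reference's own ungapped numbering
      keep <- if (has_del) setdiff(seq_len(L), del_window) else seq_len(L)
      rule_positions[[id]] <- match(rule_pos, keep)
    }
  }
  references <- data.frame(id = names(refs),
                           lineage = vapply(refs, `[[`, "", "lineage"),
                           sequence = vapply(refs, `[[`, "", "sequence"),
                           stringsAsFactors = FALSE)
  rownames(references) <- NULL
  structure(list(family = fam,
                 anchor = protein_records(anchor_id,
                                          paste(tmpl, collapse = "")),
                 references = references,
                 msa = msa(msa_ids, msa_rows),
                 rule_positions = rule_positions,
                 no_c = no_c,
                 design = design),
            class = "reference_family")
}

#' Default family designs for the synthetic benchmark
#'
#' Template lengths host every rule coordinate (merA needs >= 629); rpoB is
#' scaled to 300 residues (the real gene is ~1,340 codons) so the desk-scale
#' benchmark stays fast. Lineage labels follow the dominant lineages
#' reported for marine Hg genes (Nitrospina-dominated hgcA/hgcB, diverse
#' proteobacterial merA/merB).
#'
#' @param seed Integer base seed (one derived seed per family).
#' @param rulesets A `rule_set` (defaults to [default_rulesets()]).
#' @return Named list of [family_design()] objects.
#' @export
default_family_designs <- function(seed = 1L, rulesets = default_rulesets()) {
  spec <- list(
    hgcA = list(length = 330L,
                lineages = c(Nitrospina = 3L, Deltaproteobacteria = 2L,
                             Alphaproteobacteria = 2L)),
    hgcB = list(length = 100L,
                lineages = c(Nitrospina = 3L, Deltaproteobacteria = 2L)),
    merA = list(length = 640L,
                lineages = c(Gammaproteobacteria = 3L,
                             Alphaproteobacteria = 2L,
                             Betaproteobacteria = 2L)),
    merB = list(length = 220L,
                lineages = c(Alphaproteobacteria = 3L,
                             Betaproteobacteria = 2L, Euryarchaeota = 2L)),
    rpoB = list(length = 300L, lineages = c(Bacteria = 4L)))
  out <- list()
  for (i in seq_along(spec)) {
    fam <- names(spec)[i]
    out[[fam]] <- family_design(fam, spec[[i]]$length, spec[[i]]$lineages,
                                rulesets[[fam]],
                                seed = seed * 100L + i)
  }
  out
}

#' Design for synthetic per-sample catalogs
#'
#' The default emulates the 12-sample field design: stations St1/St6/St9
#' with four depths each (200, 500, ~1,000, 1,500 m), planted-valid Hg-gene
#' counts increasing into the mesopelagic (flat for hgcB), 5 rule-ablated
#' sequences per Hg family per sample, 200 background decoys and 500 rpoB
#' records per sample (~10^4 records in total).
#'
#' @param seed Integer seed.
#' @param mutation_rate Per-site substitution probability for valid/ablated
#'   records (rule sites always protected); in `[0, 0.2]`.
#' @param decoys_per_sample,rpob_per_sample,ablated_per_sample Counts.
#' @param valid_counts Named list: family -> length-4 integer vector of
#'   planted-valid counts by depth rank (shallow to deep).
#' @return A list of class `catalog_design`.
#' @export
catalog_design <- function(seed = 1L, mutation_rate = 0.05,
                           decoys_per_sample = 200L,
                           rpob_per_sample = 500L,
                           ablated_per_sample = 5L,
                           valid_counts = list(
                             hgcA = c(5L, 8L, 16L, 20L),
                             hgcB = c(8L, 8L, 8L, 8L),
                             merA = c(4L, 6L, 10L, 12L),
                             merB = c(4L, 6L, 10L, 12L))) {
  if (mutation_rate < 0 || mutation_rate > 0.2)
    input_error("mutation_rate must be in [0, 0.2]")
  stations <- list(St1 = c(200, 500, 1000, 1500),
                   St6 = c(200, 500, 967, 1500),
                   St9 = c(200, 500, 1175, 1500))
  rows <- list()
  for (st in names(stations)) {
    d <- stations[[st]]
    rows[[st]] <- data.frame(sample_id = sprintf("%s_%04dm", st, d),
                             station = st, depth_m = d,
                             depth_rank = seq_along(d),
                             stringsAsFactors = FALSE)
  }
  samples <- do.call(rbind, rows)
  rownames(samples) <- NULL
  structure(list(samples = samples, valid_counts = valid_counts,
                 ablated_per_sample = as.integer(ablated_per_sample),
                 decoys_per_sample = as.integer(decoys_per_sample),
                 rpob_per_sample = as.integer(rpob_per_sample),
                 mutation_rate = mutation_rate,
                 decoy_length_range = c(100L, 650L),
                 seed = as.integer(seed)),
            class = "catalog_design")
}

# substitution that breaks a rule: chemically conservative but disallowed
.ablate_residue <- function(current) {
  switch(current, C = "S", D = "N", Y = "H", F = "H", "A")
}

#' Generate per-sample catalogs with ground truth
#'
#' Valid records are mutated copies of random references with rule sites
#' protected; ablated records additionally carry exactly one rule-breaking
#' substitution (or one destroyed cysteine cluster for hgcB); decoys are
#' i.i.d. uniform background sequences; rpoB records are mutated reference
#' copies (no curation rules apply). Every record is labeled in the truth
#' table.
#'
#' @param cat_design A [catalog_design()].
#' @param families Named list of [make_reference_family()] outputs
#'   (must include rpoB).
#' @return A list of class `synthetic_catalog`: `catalog`
#'   (protein-records data.frame over all samples), `truth` (data.frame
#'   `record_id`, `sample_id`, `class`, `family`, `lineage`,
#'   `ablated_rule`, `template_ref`), `contexts`
#'   ([sample_contexts()]), `design`.
#' @export
make_catalog <- function(cat_design, families) {
  set.seed(cat_design$seed)
  samples <- cat_design$samples
  fam_order <- c(names(cat_design$valid_counts), "rpoB")
  ids <- character(0); seqs <- character(0); sample_ids <- character(0)
  tr <- list(record_id = character(0), sample_id = character(0),
             class = character(0), family = character(0),
             lineage = character(0), ablated_rule = character(0),
             template_ref = character(0))
  note <- function(record_id, sample_id, class, family, lineage,
                   ablated_rule, template_ref) {
    tr$record_id <<- c(tr$record_id, record_id)
    tr$sample_id <<- c(tr$sample_id, sample_id)
    tr$class <<- c(tr$class, class)
    tr$family <<- c(tr$family, family)
    tr$lineage <<- c(tr$lineage, lineage)
    tr$ablated_rule <<- c(tr$ablated_rule, ablated_rule)
    tr$template_ref <<- c(tr$template_ref, template_ref)
  }

  make_derived <- function(famobj, rate, no_c) {
    ridx <- sample(nrow(famobj$references), 1)
    ref <- famobj$references[ridx, , drop = FALSE]
    chars <- strsplit(ref$sequence, "")[[1]]
    protected <- famobj$rule_positions[[ref$id]]
    pool <- setdiff(seq_along(chars), protected)
    if (rate > 0) {
      hit <- pool[runif(length(pool)) < rate]
      chars <- .mutate_sites(chars, hit, exclude_c = no_c)
    }
    list(chars = chars, ref = ref, protected = protected)
  }

  for (si in seq_len(nrow(samples))) {
    sid <- samples$sample_id[si]
    rk <- samples$depth_rank[si]
    for (fam in fam_order) {
      famobj <- families[[fam]]
      if (is.null(famobj)) input_error("missing reference family '%s'", fam)
      no_c <- isTRUE(famobj$no_c)
      rs <- famobj$design$ruleset
      n_valid <- if (fam == "rpoB") cat_design$rpob_per_sample
                 else cat_design$valid_counts[[fam]][rk]
      n_abl <- if (fam == "rpoB") 0L else cat_design$ablated_per_sample
      for (i in seq_len(n_valid)) {
        d <- make_derived(famobj, cat_design$mutation_rate, no_c)
        id <- sprintf("%s_%s_valid%04d", sid, fam, i)
        ids <- c(ids, id); seqs <- c(seqs, paste(d$chars, collapse = ""))
        sample_ids <- c(sample_ids, sid)
        note(id, sid, "valid", fam, d$ref$lineage, NA_character_, d$ref$id)
      }
      if (n_abl > 0L) {
        labels <- c(rs$residue_rules$label, rs$pattern_rules$label)
        for (i in seq_len(n_abl)) {
          d <- make_derived(famobj, cat_design$mutation_rate, no_c)
          lab <- labels[(i - 1L) %% length(labels) + 1L]
          chars <- d$chars
          if (lab %in% rs$residue_rules$label) {
            which_rule <- match(lab, rs$residue_rules$label)
            pos <- d$protected[which_rule]
            chars[pos] <- .ablate_residue(chars[pos])
          } else {
            # destroy the first planted cysteine cluster
            pos <- d$protected[nrow(rs$residue_rules) + 1L]
            chars[pos] <- "S"
          }
          id <- sprintf("%s_%s_ablated%04d", sid, fam, i)
          ids <- c(ids, id); seqs <- c(seqs, paste(chars, collapse = ""))
          sample_ids <- c(sample_ids, sid)
          note(id, sid, "ablated", fam, d$ref$lineage, lab, d$ref$id)
        }
      }
    }
    rng <- cat_design$decoy_length_range
    for (i in seq_len(cat_design$decoys_per_sample)) {
      n <- sample(seq(rng[1], rng[2]), 1)
      id <- sprintf("%s_decoy%04d", sid, i)
      ids <- c(ids, id)
      seqs <- c(seqs, paste(.sample_residue(n), collapse = ""))
      sample_ids <- c(sample_ids, sid)
      note(id, sid, "decoy", NA_character_, NA_character_, NA_character_,
           NA_character_)
    }
  }
  catalog <- protein_records(ids, seqs, sample_ids)
  truth <- data.frame(tr, stringsAsFactors = FALSE)
  structure(list(catalog = catalog, truth = truth,
                 contexts = sample_contexts(samples$sample_id,
                                            samples$station,
                                            samples$depth_m),
                 design = cat_design),
            class = "synthetic_catalog")
}

#' Generate a synthetic environment table
#'
#' Draws depth profiles with the monotone structure of open-ocean
#' observations: dMeHg, AOU, NO3, PO4 and SiO2 increase with depth
#' (strictly, via cumulative positive random increments); temperature,
#' oxygen and cell counts decrease; dTHg is flat with noise in the
#' 0.42-0.66 pM range. Units follow the column names; dMeHg reaches
#' ~0.03-0.05 pM at the deepest level.
#'
#' @param contexts A [sample_contexts()] table (station, depth per
#'   sample).
#' @param seed Integer seed.
#' @return An environment `data.frame` (one row per sample) with columns
#'   `sample_id`, `station`, `depth_m`, `temperature_C`, `oxygen_umol_kg`,
#'   `AOU_umol_kg`, `NO3_uM`, `PO4_uM`, `SiO2_uM`, `dTHg_pM`, `dMeHg_pM`,
#'   `dMeHg_over_dTHg`, `cells_per_mL`.
#' @export
make_env_table <- function(contexts, seed = 1L) {
  set.seed(seed)
  rows <- list()
  inc <- function(start, step_lo, step_hi, n)
    start + c(0, cumsum(runif(n - 1, step_lo, step_hi)))
  for (st in unique(contexts$station)) {
    sub <- contexts[contexts$station == st, , drop = FALSE]
    sub <- sub[order(sub$depth_m), , drop = FALSE]
    n <- nrow(sub)
    if (n < 3L) input_error("need >= 3 depths per station")
    aou <- inc(runif(1, 20, 30), 40, 80, n)
    no3 <- inc(runif(1, 4, 6), 8, 14, n)
    po4 <- inc(runif(1, 0.3, 0.5), 0.6, 1.0, n)
    sio2 <- inc(runif(1, 3, 8), 30, 60, n)
    dmehg <- inc(runif(1, 0.004, 0.007), 0.007, 0.013, n)
    temp <- inc(runif(1, 17, 19), -6, -3, n)
    o2 <- inc(runif(1, 195, 215), -60, -40, n)
    cells <- inc(runif(1, 3.6e5, 4.2e5), -1.2e5, -0.9e5, n)
    dthg <- runif(n, 0.42, 0.66)
    rows[[st]] <- data.frame(sample_id = sub$sample_id, station = st,
                             depth_m = sub$depth_m, temperature_C = temp,
                             oxygen_umol_kg = o2, AOU_umol_kg = aou,
                             NO3_uM = no3, PO4_uM = po4, SiO2_uM = sio2,
                             dTHg_pM = dthg, dMeHg_pM = dmehg,
                             dMeHg_over_dTHg = dmehg / dthg,
                             cells_per_mL = cells, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
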