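test_that("default rule sets encode the family curation rules", {
  rs <- default_rulesets()
  expect_equal(nrow(rs$merA$residue_rules), 6L)
  expect_setequal(rs$merA$residue_rules$position,
                  c(207L, 212L, 264L, 605L, 628L, 629L))
  expect_equal(rs$merA$residue_rules$allowed[
    rs$merA$residue_rules$position == 605], "YF")
  expect_equal(nrow(rs$merB$residue_rules), 4L)
  expect_setequal(rs$merB$residue_rules$position, c(96L, 99L, 117L, 159L))
  expect_equal(rs$hgcA$residue_rules$position, 93L)
  expect_equal(rs$hgcB$pattern_rules$min_count, 2L)
  expect_equal(nrow(rs$rpoB$residue_rules) + nrow(rs$rpoB$pattern_rules), 0L)
})

test_that("rule files round-trip through TSV", {
  rs <- default_rulesets()
  tf <- tempfile(fileext = ".tsv")
  write_rules(rs, tf)
  rs2 <- read_rules(tf)
  for (fam in names(rs)) {
    expect_equal(rs2[[fam]]$residue_rules$position,
                 rs[[fam]]$residue_rules$position, info = fam)
    expect_equal(rs2[[fam]]$residue_rules$allowed,
                 rs[[fam]]$residue_rules$allowed, info = fam)
    expect_equal(rs2[[fam]]$pattern_rules$pattern,
                 rs[[fam]]$pattern_rules$pattern, info = fam)
  }
})

test_that("reference-position mapping is identity-, deletion- and insertion-aware", {
  set.seed(31)
  ref <- random_protein(60)
  # identical candidate
  aln <- global_align(ref, ref)
  for (p in c(1, 30, 60))
    expect_equal(map_reference_position(aln, p),
                 substr(ref, p, p))
  # deletion covering position 30
  cand_del <- paste0(substr(ref, 1, 24), substr(ref, 35, 60))
  expect_equal(map_reference_position(global_align(ref, cand_del), 30), "GAP")
  # insertion before position 30 leaves the mapping unchanged
  cand_ins <- paste0(substr(ref, 1, 20), "WWPGW", substr(ref, 21, 60))
  expect_equal(map_reference_position(global_align(ref, cand_ins), 30),
               substr(ref, 30, 30))
  expect_error(map_reference_position(aln, 61), "beyond")
})

test_that("residue rules pass/fail candidates as specified", {
  w <- tiny_world()
  f <- w$fams$merA
  rules <- default_rulesets()$merA$residue_rules
  anchor <- f$anchor
  rp <- f$rule_positions[[anchor$id]]

  # mutations only outside rule positions pass
  set.seed(32)
  ch <- strsplit(anchor$sequence, "")[[1]]
  pool <- setdiff(seq_along(ch), rp)
  hit <- sample(pool, floor(length(ch) * 0.1))
  ch2 <- ch; ch2[hit] <- sample(AA20_T, length(hit), replace = TRUE)
  vr <- check_residue_rules(protein_records("cand", paste(ch2, collapse = "")),
                            anchor, rules)
  expect_true(vr$passed)
  expect_equal(nrow(vr$positions_checked), 6L)

  # C207 -> S fails exactly merA:C207
  ch3 <- ch; ch3[rp[rules$position == 207]] <- "S"
  vr3 <- check_residue_rules(protein_records("c207s",
                                             paste(ch3, collapse = "")),
                             anchor, rules)
  expect_false(vr3$passed)
  expect_equal(vr3$failed_rules, "merA:C207")

  # phenylalanine at position 605 is allowed (Y or F)
  ch4 <- ch; ch4[rp[rules$position == 605]] <- "F"
  vr4 <- check_residue_rules(protein_records("f605",
                                             paste(ch4, collapse = "")),
                             anchor, rules)
  expect_true(vr4$passed)

  # a fragment with a gap at a rule position fails
  frag <- paste(ch[300:640], collapse = "")
  vrf <- check_residue_rules(protein_records("frag", frag), anchor, rules)
  expect_false(vrf$passed)
  expect_true("merA:C207" %in% vrf$failed_rules)
})

test_that("pattern counting matches the sliding-window oracle", {
  rs <- default_rulesets()
  rule <- rs$hgcB$pattern_rules[1, , drop = FALSE]
  r1 <- check_pattern_rule("CAACAACAAAC", rule)
  expect_equal(r1$count, 1L)
  expect_false(r1$passed)
  two <- paste0("CAACAACAAAC", "W", "CGGCGGCGGGC", "AA")
  r2 <- check_pattern_rule(two, rule)
  expect_equal(r2$count, 2L)
  expect_true(r2$passed)
  set.seed(33)
  for (k in 1:100) {
    s <- random_protein(200, alphabet = c("C", "A", "G")) # C-rich stress
    expect_equal(check_pattern_rule(s, rule)$count, bf_pattern_count(s),
                 info = s)
  }
})

test_that("validate_hits applies the right rules per family and is order-independent", {
  w <- tiny_world()
  rs <- default_rulesets()
  fams <- w$fams
  refs <- list(hgcA = fams$hgcA$anchor, merA = fams$merA$anchor,
               merB = fams$merB$anchor)

  expect_equal(nrow(validate_hits(NULL, NULL, rs, refs)), 0L)

  # construct valid + single-rule-ablated candidates per residue family
  mk <- function(fam, ablate_rule = NULL) {
    f <- fams[[fam]]
    ch <- strsplit(f$anchor$sequence, "")[[1]]
    if (!is.null(ablate_rule)) {
      rules <- rs[[fam]]$residue_rules
      pos <- f$rule_positions[[f$anchor$id]][match(ablate_rule, rules$label)]
      ch[pos] <- switch(substr(ch[pos], 1, 1), C = "S", D = "N", Y = "H", "A")
    }
    paste(ch, collapse = "")
  }
  catalog <- protein_records(
    c("v_hgcA", "a_hgcA", "v_merB", "a_merB", "r_rpoB"),
    c(mk("hgcA"), mk("hgcA", "hgcA:C93"), mk("merB"), mk("merB", "merB:D99"),
      fams$rpoB$references$sequence[1]),
    "s1")
  hits <- data.frame(record_id = catalog$id, sample_id = "s1",
                     family = c("hgcA", "hgcA", "merB", "merB", "rpoB"),
                     bit_score = 100, evalue = 1e-20,
                     stringsAsFactors = FALSE)
  res <- validate_hits(hits, catalog, rs, refs)
  expect_equal(res$passed, c(TRUE, FALSE, TRUE, FALSE, TRUE))
  expect_equal(res$failed_rules[2], "hgcA:C93")
  expect_equal(res$failed_rules[4], "merB:D99")

  # order independence
  res_rev <- validate_hits(hits[5:1, ], catalog, rs, refs)
  expect_equal(res_rev[order(res_rev$record_id), ]$passed,
               res[order(res$record_id), ]$passed)

  # unknown record id errors
  bad <- hits; bad$record_id[1] <- "nope"
  expect_error(validate_hits(bad, catalog, rs, refs), "nope")
})

test_that("validation is monotone in the rule set", {
  w <- tiny_world()
  rs <- default_rulesets()
  f <- w$fams$merA
  set.seed(34)
  ch <- strsplit(f$anchor$sequence, "")[[1]]
  cands <- vapply(1:12, function(i) {
    c2 <- ch
    k <- sample(seq_along(c2), 40)
    c2[k] <- sample(AA20_T, 40, replace = TRUE)
    paste(c2, collapse = "")
  }, character(1))
  recs <- protein_records(sprintf("m%02d", 1:12), cands, "s1")
  full <- rs$merA$residue_rules
  sub <- full[1:2, , drop = FALSE]
  pass_sub <- vapply(seq_len(nrow(recs)), function(i)
    check_residue_rules(recs[i, ], f$anchor, sub)$passed, logical(1))
  pass_full <- vapply(seq_len(nrow(recs)), function(i)
    check_residue_rules(recs[i, ], f$anchor, full)$passed, logical(1))
  expect_true(all(pass_full <= pass_sub)) # adding rules only shrinks the set
})
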