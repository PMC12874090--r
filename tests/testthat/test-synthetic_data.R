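test_that("generated references satisfy their own family rules", {
  w <- tiny_world()
  rs <- default_rulesets()
  for (fam in c("hgcA", "merA", "merB")) {
    f <- w$fams[[fam]]
    for (i in seq_len(nrow(f$references))) {
      vr <- check_residue_rules(
        protein_records(f$references$id[i], f$references$sequence[i]),
        f$anchor, rs[[fam]]$residue_rules)
      expect_true(vr$passed, info = f$references$id[i])
    }
  }
  f <- w$fams$hgcB
  for (i in seq_len(nrow(f$references)))
    expect_true(check_pattern_rule(f$references$sequence[i],
                                   rs$hgcB$pattern_rules[1, ])$passed,
                info = f$references$id[i])
})

test_that("pairwise reference identity respects the divergence budget", {
  w <- tiny_world()
  for (fam in c("hgcA", "merB")) {
    f <- w$fams[[fam]]
    div <- f$design$divergence
    n <- nrow(f$references)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      aln <- global_align(f$references$sequence[i], f$references$sequence[j])
      expect_gte(aln$identity, 1 - 2 * div - 1e-9)
    }
  }
})

test_that("generators are byte-deterministic under a fixed seed", {
  d <- default_family_designs(99L)
  f1 <- make_reference_family(d$hgcA)
  f2 <- make_reference_family(d$hgcA)
  expect_identical(f1$references, f2$references)
  expect_identical(f1$msa$aligned, f2$msa$aligned)
  cd <- catalog_design(seed = 7L, decoys_per_sample = 5L,
                       rpob_per_sample = 5L,
                       valid_counts = list(hgcA = c(1L, 1L, 2L, 2L)),
                       ablated_per_sample = 1L)
  fams <- list(hgcA = f1, rpoB = make_reference_family(d$rpoB))
  c1 <- make_catalog(cd, fams)
  c2 <- make_catalog(cd, fams)
  expect_identical(c1$catalog, c2$catalog)
  expect_identical(c1$truth, c2$truth)
  e1 <- make_env_table(c1$contexts, seed = 3L)
  e2 <- make_env_table(c1$contexts, seed = 3L)
  expect_identical(e1, e2)
})

test_that("catalog class counts equal the design and truth matches the FASTA ids", {
  w <- tiny_world()
  cd <- catalog_design(seed = 8L, decoys_per_sample = 10L,
                       rpob_per_sample = 20L)
  syn <- make_catalog(cd, w$fams)
  expect_setequal(syn$truth$record_id, syn$catalog$id)
  for (sid in syn$contexts$sample_id) {
    tt <- syn$truth[syn$truth$sample_id == sid, ]
    rk <- which(syn$contexts$sample_id == sid)
    rk <- ((rk - 1) %% 4) + 1 # depth rank within station
    for (fam in names(cd$valid_counts))
      expect_equal(sum(tt$class == "valid" & tt$family == fam),
                   cd$valid_counts[[fam]][rk], info = paste(sid, fam))
    expect_equal(sum(tt$class == "decoy"), 10L)
    expect_equal(sum(tt$family == "rpoB", na.rm = TRUE), 20L)
    expect_equal(sum(tt$class == "ablated"), 4L * 5L)
  }
  # depth trend planted for hgcA/merA/merB: deeper samples carry more
  deep <- syn$truth$sample_id %in%
    syn$contexts$sample_id[syn$contexts$depth_m >= 967]
  for (fam in c("hgcA", "merA", "merB")) {
    n_deep <- sum(syn$truth$class == "valid" & syn$truth$family == fam & deep,
                  na.rm = TRUE)
    n_shallow <- sum(syn$truth$class == "valid" & syn$truth$family == fam &
                       !deep, na.rm = TRUE)
    expect_gt(n_deep, n_shallow)
  }
})

test_that("every ablated record fails exactly its named rule", {
  w <- tiny_world()
  rs <- default_rulesets()
  cd <- catalog_design(seed = 9L, decoys_per_sample = 0L,
                       rpob_per_sample = 0L,
                       valid_counts = list(hgcA = rep(1L, 4),
                                           hgcB = rep(1L, 4),
                                           merA = rep(1L, 4),
                                           merB = rep(1L, 4)),
                       ablated_per_sample = 6L)
  syn <- make_catalog(cd, w$fams)
  abl <- syn$truth[syn$truth$class == "ablated", ]
  refs <- list(hgcA = w$fams$hgcA$anchor, merA = w$fams$merA$anchor,
               merB = w$fams$merB$anchor)
  hits <- data.frame(record_id = abl$record_id, sample_id = abl$sample_id,
                     family = abl$family, bit_score = 0, evalue = 0,
                     stringsAsFactors = FALSE)
  res <- validate_hits(hits, syn$catalog, rs, refs)
  expect_true(all(!res$passed))
  expect_equal(res$failed_rules,
               abl$ablated_rule[match(res$record_id, abl$record_id)])
})

test_that("valid records dominate decoys in HMM score (class separation)", {
  w <- tiny_world()
  f <- w$fams$hgcA
  p <- build_profile(f$msa, "hgcA")
  set.seed(61)
  valid <- vapply(1:100, function(i) {
    ch <- strsplit(f$references$sequence[sample(nrow(f$references), 1)],
                   "")[[1]]
    k <- floor(length(ch) * 0.05)
    ch[sample(length(ch), k)] <- sample(AA20_T, k, replace = TRUE)
    paste(ch, collapse = "")
  }, character(1))
  decoys <- vapply(1:100, function(i) random_protein(330), character(1))
  sv <- hgscreen:::.score_many(p, valid)
  sd_ <- hgscreen:::.score_many(p, decoys)
  wt <- wilcox.test(sv, sd_, alternative = "greater")
  expect_lt(wt$p.value, 1e-6)
})

test_that("environment tables have the planted monotone depth structure", {
  ctx <- sample_contexts(sprintf("s%d", 1:12),
                         rep(c("St1", "St6", "St9"), each = 4),
                         c(200, 500, 1000, 1500, 200.1, 500.1, 967, 1500.1,
                           200.2, 500.2, 1175, 1500.2))
  env <- make_env_table(ctx, seed = 10L)
  expect_equal(env$dMeHg_over_dTHg, env$dMeHg_pM / env$dTHg_pM)
  for (st in unique(env$station)) {
    sub <- env[env$station == st, ]
    sub <- sub[order(sub$depth_m), ]
    expect_gt(sub$dMeHg_pM[nrow(sub)], sub$dMeHg_pM[1])
    expect_true(all(diff(sub$AOU_umol_kg) > 0))
    expect_true(all(diff(sub$NO3_uM) > 0))
    expect_true(all(diff(sub$temperature_C) < 0))
    expect_true(all(diff(sub$oxygen_umol_kg) < 0))
    expect_true(all(diff(sub$cells_per_mL) < 0))
  }
  # ranges on the order of open-ocean observations
  expect_true(all(env$dTHg_pM >= 0.42 & env$dTHg_pM <= 0.66))
  expect_true(all(env$dMeHg_pM < 0.08))
})

test_that("planted dMeHg-AOU relation is recovered by the statistics module", {
  ctx <- sample_contexts(sprintf("s%d", 1:12),
                         rep(c("St1", "St6", "St9"), each = 4),
                         rep(c(200, 500, 1000, 1500), 3) + rep(0:2, each = 4) / 10)
  ok <- 0L
  for (seed in 1:40) {
    env <- make_env_table(ctx, seed = seed)
    s <- spearman(env$dMeHg_pM, env$AOU_umol_kg)
    if (s$rho > 0 && s$p_value < 0.01) ok <- ok + 1L
  }
  expect_gte(ok / 40, 0.95)
})
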