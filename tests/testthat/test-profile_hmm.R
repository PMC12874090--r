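toy_msa <- function() {
  msa(c("r1", "r2", "r3"), c("ACDEFG", "ACDEFG", "ACDEFG"))
}

test_that("profile building follows the match-column and pseudocount rules", {
  p <- build_profile(toy_msa(), "toy")
  expect_equal(p$n_match, 6L)
  obs <- strsplit("ACDEFG", "")[[1]]
  for (i in 1:6)
    expect_equal(colnames(scoring_matrix())[which.max(p$match_emissions[i, ])],
                 obs[i])
  # column with 2/3 gaps is not a match column
  m2 <- msa(c("r1", "r2", "r3"), c("AC-EFG", "A--EFG", "AC-EFG"))
  p2 <- build_profile(m2, "toy2")
  expect_equal(p2$n_match, 5L) # column 3 dropped (100% gaps) ... plus col2?
  # column 2 has 1/3 gaps -> still a match column
  expect_true(2 %in% p2$match_columns)
  expect_false(3 %in% p2$match_columns)
  # Laplace formula: single observed residue C -> (1+1)/(1+20)
  m3 <- msa(c("r1", "r2", "r3"), c("AC", "A-", "A-"))
  p3 <- build_profile(m3, "toy3")
  # column 2 is 2/3 gaps -> insert column; C emission sits in inserts
  expect_equal(p3$n_match, 1L)
  expect_equal(p3$insert_emissions[which(colnames(scoring_matrix()) == "C")],
               (1 + 1) / (1 + 20))
  expect_error(build_profile(msa(c("a", "b"), c("--", "--")), "bad"),
               "match column")
})

test_that("probability vectors are normalized after building", {
  w <- tiny_world()
  for (fam in c("hgcA", "hgcB")) {
    p <- build_profile(w$fams[[fam]]$msa, fam)
    expect_true(all(abs(rowSums(p$match_emissions) - 1) < 1e-9))
    expect_equal(sum(p$insert_emissions), 1, tolerance = 1e-9)
    expect_equal(sum(p$background), 1, tolerance = 1e-9)
    for (i in seq_len(p$n_match + 1)) {
      tr <- p$transitions[i, ]
      for (grp in list(c("MM", "MI", "MD"), c("IM", "II"), c("DM", "DD"))) {
        s <- sum(exp(tr[grp]), na.rm = TRUE)
        if (is.finite(s) && s > 0) expect_lt(abs(s - 1), 1e-9 + 1e-12)
      }
    }
  }
})

test_that("forward >= viterbi for every scored sequence", {
  w <- tiny_world()
  p <- build_profile(w$fams$hgcB$msa, "hgcB")
  set.seed(21)
  for (k in 1:10) {
    s <- random_protein(sample(c(30, 80, 100, 150), 1))
    sc <- score_sequence(p, s)
    expect_gte(sc["forward"], sc["viterbi"])
  }
})

test_that("viterbi and forward match exhaustive path enumeration on small profiles", {
  set.seed(22)
  for (k in 1:5) {
    m <- msa(c("a", "b", "c"),
             c(random_protein(2), random_protein(2), random_protein(2)))
    p <- build_profile(m, "mini")
    s <- random_protein(2)
    got <- score_sequence(p, s) * log(2) # back to nats
    expect_equal(unname(got["forward"]), bf_forward_enum(p, s),
                 tolerance = 1e-9)
    expect_equal(unname(got["viterbi"]), bf_viterbi_enum(p, s),
                 tolerance = 1e-9)
  }
  # and on a slightly wider case with an insert-bearing MSA
  m <- msa(c("a", "b", "c"), c("AC-D", "ACWD", "AC-D"))
  p <- build_profile(m, "mini2")
  s <- "ACWD"
  got <- score_sequence(p, s) * log(2)
  expect_equal(unname(got["forward"]), bf_forward_enum(p, s),
               tolerance = 1e-9)
  expect_equal(unname(got["viterbi"]), bf_viterbi_enum(p, s),
               tolerance = 1e-9)
})

test_that("training rows outscore their shuffles and the null 99th percentile", {
  w <- tiny_world()
  f <- w$fams$hgcA
  p <- build_profile(f$msa, "hgcA")
  ref <- f$references$sequence[1]
  own <- score_sequence(p, ref, forward = FALSE)[1]
  set.seed(23)
  shuf <- vapply(1:20, function(i)
    score_sequence(p, paste(sample(strsplit(ref, "")[[1]]), collapse = ""),
                   forward = FALSE)[1], numeric(1))
  expect_gt(own, median(shuf))
  nulls <- vapply(1:50, function(i)
    score_sequence(p, random_protein(nchar(ref)), forward = FALSE)[1],
    numeric(1))
  expect_gt(own, quantile(nulls, 0.99))
})

test_that("X residues contribute a background-equivalent (zero) log-odds", {
  w <- tiny_world()
  p <- build_profile(w$fams$hgcB$msa, "hgcB")
  ref <- w$fams$hgcB$references$sequence[1]
  sc <- score_sequence(p, ref, forward = FALSE)[1]
  with_x <- sub("^(.{10}).", "\\1X", ref)
  sc_x <- score_sequence(p, with_x, forward = FALSE)[1]
  expect_lt(sc_x, sc)           # loses that column's positive log-odds
  expect_gt(sc_x, sc - 10)      # but is not treated as a mismatch penalty
})

test_that("E-value calibration is monotone, thresholdable and self-consistent", {
  w <- tiny_world()
  p <- build_profile(w$fams$hgcA$msa, "hgcA")
  calib <- calibrate_evalue(p, null_lengths = c(150L, 330L, 500L),
                            n_null = 200L, seed = 7L)
  # monotone in score at fixed length
  s <- seq(-100, 500, by = 50)
  ev <- evalue(calib, s, 1000, 330)
  expect_true(all(diff(ev) < 0))
  # threshold application: E = 1e-6 passes 1e-5, fails 1e-10
  expect_true(1e-6 <= 1e-5)
  expect_false(1e-6 <= 1e-10)
  # self-consistency: among the nulls themselves, #(E <= 1) ~ 1
  ev_null <- evalue(calib, calib$null_scores, calib$n_null,
                    calib$null_lengths)
  expect_lte(abs(sum(ev_null <= 1) - 1), 3) # within 3*sqrt(expected), expected = 1
  # degenerate variance errors
  expect_error(hgscreen:::.fit_gumbel(rep(1, 100)), "degenerate")
})

test_that("search respects threshold nesting and sorting; empty catalog is empty", {
  w <- tiny_world()
  f <- w$fams$hgcB
  p <- build_profile(f$msa, "hgcB")
  set.seed(24)
  planted <- vapply(f$references$sequence, function(s) {
    ch <- strsplit(s, "")[[1]]
    k <- floor(length(ch) * 0.1)
    ch[sample(length(ch), k)] <- sample(AA20_T, k, replace = TRUE)
    paste(ch, collapse = "")
  }, character(1))
  decoys <- replicate(50, random_protein(100))
  catalog <- protein_records(sprintf("c%02d", seq_len(length(planted) + 50)),
                             c(planted, decoys), "s1")
  calib <- calibrate_evalue(p, nchar(catalog$sequence), 150L, seed = 9L)
  hits5 <- search_catalog(p, calib, catalog, 1e-5)
  hits10 <- search_catalog(p, calib, catalog, 1e-10)
  expect_true(all(hits10$record_id %in% hits5$record_id))
  expect_true(all(diff(hits5$evalue) >= 0))
  # all planted derived references are found at 1e-5
  expect_true(all(sprintf("c%02d", seq_along(planted)) %in% hits5$record_id))
  expect_equal(nrow(search_catalog(p, calib, NULL, 1e-5)), 0L)
})

test_that("profile serialization round-trips bit-exactly at the text level", {
  w <- tiny_world()
  p <- build_profile(w$fams$merB$msa, "merB")
  f1 <- tempfile(); f2 <- tempfile()
  write_profile(p, f1)
  p2 <- read_profile(f1)
  write_profile(p2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  # and the deserialized model scores identically
  s <- w$fams$merB$references$sequence[2]
  expect_identical(score_sequence(p, s), score_sequence(p2, s))
  expect_error(read_profile(f1 <- {
    tf <- tempfile(); writeLines("something else", tf); tf
  }), "profile")
})
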