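# Independent brute-force oracles used by the unit and acceptance tests.
# These deliberately re-derive results by enumeration/closed form and never
# call the code paths they check.

AA20_T <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_protein <- function(n, alphabet = AA20_T) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Exhaustive enumeration of all global alignments of a vs b under affine
# scoring (gap of length k costs open + (k-1)*extend; end gaps penalized).
# Returns the optimal score. Only feasible for short sequences.
bf_align_score <- function(a, b, smat, open, extend) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  best <- -Inf
  rec <- function(i, j, prev, acc) {
    if (i == n && j == m) {
      if (acc > best) best <<- acc
      return(invisible())
    }
    if (i < n && j < m)
      rec(i + 1, j + 1, "M", acc + smat[av[i + 1], bv[j + 1]])
    if (i < n) # gap in b, consumes a
      rec(i + 1, j, "A", acc + if (prev == "A") extend else open)
    if (j < m) # gap in a, consumes b
      rec(i, j + 1, "B", acc + if (prev == "B") extend else open)
  }
  rec(0, 0, "start", 0)
  best
}

# Greedy clustering oracle: same rule as dereplicate() but written over a
# precomputed all-pairs identity matrix.
bf_dereplicate <- function(records, threshold, params) {
  ord <- order(-nchar(records$sequence), records$id)
  rec <- records[ord, , drop = FALSE]
  n <- nrow(rec)
  ident <- function(i, j) {
    aln <- global_align(rec$sequence[i], rec$sequence[j], params)
    aln$n_identical / min(nchar(rec$sequence[i]), nchar(rec$sequence[j]))
  }
  reps <- integer(0)
  assign <- integer(n)
  for (k in seq_len(n)) {
    hit <- 0L
    for (r in reps) {
      if (ident(r, k) >= threshold) { hit <- r; break }
    }
    if (hit == 0L) { reps <- c(reps, k); assign[k] <- k }
    else assign[k] <- hit
  }
  lapply(reps, function(r) sort(rec$id[assign == r]))
}

# Sliding-window pattern-count oracle with greedy non-overlap.
bf_pattern_count <- function(seq, template = "C..C..C...C") {
  chars <- strsplit(seq, "")[[1]]
  tpl <- strsplit(template, "")[[1]]
  w <- length(tpl)
  count <- 0L; i <- 1L
  while (i + w - 1L <= length(chars)) {
    win <- chars[i:(i + w - 1L)]
    if (all(tpl == "." | tpl == win)) {
      count <- count + 1L
      i <- i + w
    } else i <- i + 1L
  }
  count
}

# Exhaustive path enumeration oracle for the profile HMM: every state
# path B -> ... -> E emitting exactly `seq`, with log-odds emission and
# log transition weights (nats). Forward = log-sum-exp, Viterbi = max.
bf_path_logs <- function(profile, seq) {
  enc <- match(strsplit(seq, "")[[1]], c(AA20_T, "X"))
  n <- length(enc)
  L <- profile$n_match
  mlo <- cbind(log(profile$match_emissions) -
                 rep(log(profile$background), each = L), 0)
  ilo <- c(log(profile$insert_emissions) - log(profile$background), 0)
  tr <- profile$transitions
  logs <- c()
  rec <- function(i, st, j, acc) {
    if (!is.finite(acc)) return(invisible())
    if (i == L) { # transition to E (recorded in the *M slot of row L+1)
      toE <- acc + tr[L + 1, paste0(st, "M")]
      if (j == n && is.finite(toE)) logs <<- c(logs, toE)
    }
    if (st != "D" && j < n) # self-position insert (D -> I disallowed)
      rec(i, "I", j + 1, acc + tr[i + 1, paste0(st, "I")] + ilo[enc[j + 1]])
    if (i < L) {
      if (j < n)
        rec(i + 1, "M", j + 1,
            acc + tr[i + 1, paste0(st, "M")] + mlo[i + 1, enc[j + 1]])
      if (st != "I") # I -> D disallowed
        rec(i + 1, "D", j, acc + tr[i + 1, paste0(st, "D")])
    }
  }
  rec(0, "M", 0, 0)
  logs
}

bf_forward_enum <- function(profile, seq) {
  logs <- bf_path_logs(profile, seq)
  m <- max(logs)
  m + log(sum(exp(logs - m)))
}

bf_viterbi_enum <- function(profile, seq) {
  max(bf_path_logs(profile, seq))
}

# Spearman closed form for untied vectors: 1 - 6*sum(d^2)/(n(n^2-1))
bf_spearman_untied <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# Exact two-sided permutation p by full enumeration (independent of the
# package's permutation generator); uses base cor() for rho.
bf_perm_p_exact <- function(x, y) {
  n <- length(x)
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  obs <- abs(cor(rank(x), rank(y)))
  stats <- vapply(perms(seq_len(n)), function(p)
    abs(cor(rank(x), rank(y[p]))), numeric(1))
  sum(stats >= obs - 1e-12) / factorial(n)
}

# A small shared benchmark world for expensive tests (built once per run).
tiny_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      designs <- default_family_designs(42L)
      fams <- lapply(designs, make_reference_family)
      cache <<- list(designs = designs, fams = fams)
    }
    cache
  }
})
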