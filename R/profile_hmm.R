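#' Build a multiple-sequence-alignment object
#'
#' @param ids Character vector of reference ids.
#' @param aligned Character vector of equal-length aligned sequences using
#'   `-` as the gap character.
#' @return A list of class `msa` with `ids`, `aligned`, `n_columns`.
#' @export
msa <- function(ids, aligned) {
  if (length(ids) != length(aligned) || length(ids) < 2L)
    input_error("an MSA needs at least 2 rows with one id each")
  nc <- unique(nchar(aligned))
  if (length(nc) != 1L)
    input_error("aligned sequences have unequal lengths")
  structure(list(ids = as.character(ids), aligned = toupper(aligned),
                 n_columns = nc),
            class = "msa")
}

# split aligned rows into a character matrix (rows x columns)
.msa_matrix <- function(m) {
  do.call(rbind, strsplit(m$aligned, ""))
}

#' Build a per-family profile hidden Markov model
#'
#' Columns with less than 50% gaps become match states. Match and insert
#' emissions are Laplace-smoothed residue frequencies
#' (`(count + 1) / (n + 20)`); transitions among match/insert/delete states
#' are estimated from the gap structure of the alignment with +1
#' pseudocounts; the background model is the overall residue frequency of
#' the MSA (smoothed). All probabilities are strictly positive.
#'
#' @param m An [msa()] object.
#' @param family Family label (e.g. `"hgcA"`).
#' @return A list of class `profile_model`.
#' @export
build_profile <- function(m, family) {
  cm <- .msa_matrix(m)
  gapfrac <- colMeans(cm == "-")
  match_cols <- which(gapfrac < 0.5)
  if (length(match_cols) == 0L)
    input_error("no match columns (alignment is mostly gaps)")
  L <- length(match_cols)

  # emissions
  count_res <- function(chars) {
    chars <- chars[chars %in% AA20]
    tab <- table(factor(chars, levels = AA20))
    as.numeric(tab)
  }
  match_em <- t(vapply(match_cols, function(j) {
    cnt <- count_res(cm[, j])
    (cnt + 1) / (sum(cnt) + 20)
  }, numeric(20)))
  ins_chars <- cm[, setdiff(seq_len(ncol(cm)), match_cols), drop = FALSE]
  ins_cnt <- count_res(as.vector(ins_chars))
  insert_em <- (ins_cnt + 1) / (sum(ins_cnt) + 20)
  bg_cnt <- count_res(as.vector(cm))
  background <- (bg_cnt + 1) / (sum(bg_cnt) + 20)

  # transitions: walk each row's state path B, {M/D/I}..., E
  # counts indexed by out-position 0..L and type MM, MI, MD, IM, II, DM, DD
  types <- c("MM", "MI", "MD", "IM", "II", "DM", "DD")
  cnt <- matrix(0, L + 1, 7, dimnames = list(NULL, types))
  is_match <- seq_len(ncol(cm)) %in% match_cols
  col_pos <- cumsum(is_match) # profile position of each match column
  # D->I and I->D are disallowed (Plan7 convention); when a row's gap
  # structure implies one, the event is dropped from the counts (the
  # pseudocounts keep every allowed transition strictly positive).
  add <- function(pos, key) {
    if (key %in% types) cnt[pos + 1L, key] <<- cnt[pos + 1L, key] + 1
  }
  for (r in seq_len(nrow(cm))) {
    prev_state <- "M"; prev_pos <- 0L
    for (j in seq_len(ncol(cm))) {
      ch <- cm[r, j]
      if (is_match[j]) {
        st <- if (ch == "-") "D" else "M"
        add(prev_pos, paste0(prev_state, st))
        prev_state <- st; prev_pos <- col_pos[j]
      } else if (ch != "-") {
        add(prev_pos, paste0(prev_state, "I"))
        prev_state <- "I"
      }
    }
    # exit to E recorded in the *M slot of the final position
    add(prev_pos, paste0(prev_state, "M"))
  }

  trans <- matrix(-Inf, L + 1, 7, dimnames = list(NULL, types))
  for (i in 0:L) {
    at_end <- (i == L)
    m_out <- if (at_end) c("MM", "MI") else c("MM", "MI", "MD")
    i_out <- c("IM", "II")
    d_out <- if (at_end) "DM" else c("DM", "DD")
    for (grp in list(m_out, i_out, d_out)) {
      k <- cnt[i + 1L, grp] + 1 # +1 pseudocount on each allowed transition
      trans[i + 1L, grp] <- log(k / sum(k))
    }
    if (i == 0L) trans[1L, c("DM", "DD")] <- -Inf # no delete state at begin
  }

  structure(list(family = family, n_match = L,
                 match_emissions = match_em,
                 insert_emissions = insert_em,
                 transitions = trans,
                 background = background,
                 match_columns = match_cols),
            class = "profile_model")
}

# log-odds pieces consumed by the C++ scorer (natural log; X column = 0)
.profile_logodds <- function(profile) {
  mlo <- cbind(log(profile$match_emissions) -
                 rep(log(profile$background), each = profile$n_match), 0)
  ilo <- c(log(profile$insert_emissions) - log(profile$background), 0)
  list(mlo = mlo, ilo = ilo, tr = profile$transitions)
}

#' Score a protein sequence against a profile
#'
#' Global-in-model Viterbi and forward log-odds scores relative to the
#' profile's background model, in bits. `X` residues contribute 0 to the
#' log-odds (background-equivalent emission). The forward score is always
#' greater than or equal to the Viterbi score.
#'
#' @param profile A [build_profile()] model.
#' @param rec A sequence (string or single-row catalog).
#' @param forward Also compute the forward score (default `TRUE`).
#' @return Named numeric vector `c(viterbi =, forward =)`, in bits.
#' @export
score_sequence <- function(profile, rec, forward = TRUE) {
  s <- .as_seq(rec, "rec")
  .check_seq(s$seq, s$id)
  lo <- .profile_logodds(profile)
  r <- cpp_profile_score(lo$mlo, lo$ilo, lo$tr, encode_seq(s$seq), forward)
  r / log(2)
}

# Viterbi bits for a character vector of sequences
.score_many <- function(profile, seqs) {
  lo <- .profile_logodds(profile)
  enc <- lapply(seqs, encode_seq)
  cpp_profile_score_many(lo$mlo, lo$ilo, lo$tr, enc) / log(2)
}

# maximum-likelihood Gumbel (max) fit
.fit_gumbel <- function(x) {
  if (sd(x) < 1e-9)
    stop("degenerate null score variance; cannot calibrate")
  mn <- min(x); xbar <- mean(x)
  g <- function(beta) {
    w <- exp(-(x - mn) / beta) # in (0, 1]; stabilized by the minimum
    beta - xbar + sum(x * w) / sum(w)
  }
  s <- sd(x)
  beta <- uniroot(g, lower = s * 1e-3, upper = s * 1e3, tol = 1e-10)$root
  mu <- mn - beta * log(mean(exp(-(x - mn) / beta)))
  c(mu = mu, lam = beta)
}

#' Calibrate an empirical E-value model for a profile
#'
#' Draws `n_null` i.i.d. background sequences (residues from the profile's
#' background distribution, lengths resampled from a supplied length
#' distribution) and scores them with Viterbi. Because the model is global
#' in the profile, null scores depend strongly on sequence length — roughly
#' piecewise around the profile length `L` (forced deletions below, forced
#' inserts above). The calibration removes this trend by least squares on
#' the hinge features `max(L - len, 0)` and `max(len - L, 0)` (linear and
#' quadratic terms), models the residual variance as a linear function of
#' length (longer null sequences fluctuate more), and fits a Gumbel law by
#' maximum likelihood to the standardized residuals. E-values are then
#' `E(s, len | N) = N * (1 - GumbelCDF((s - trend(len)) / scale(len)))`.
#'
#' @param profile A [build_profile()] model.
#' @param null_lengths Integer vector; null sequence lengths are resampled
#'   from it.
#' @param n_null Number of null sequences (>= 100; default 500).
#' @param seed Integer seed recorded in the calibration.
#' @return A list of class `evalue_calibration` with `mu`, `lam`, `n_null`,
#'   `seed`.
#' @export
calibrate_evalue <- function(profile, null_lengths, n_null = 500L,
                             seed = 1L) {
  if (n_null < 100L) input_error("n_null must be >= 100")
  if (length(null_lengths) == 0L || any(null_lengths < 1))
    input_error("null_lengths must be positive integers")
  set.seed(seed)
  pool <- as.integer(null_lengths)
  if (length(pool) == 1L) pool <- rep(pool, 2L) # avoid sample(n) semantics
  lens <- sample(pool, n_null, replace = TRUE)
  seqs <- vapply(lens, function(n)
    paste(sample(AA20, n, replace = TRUE, prob = profile$background),
          collapse = ""), character(1))
  scores <- .score_many(profile, seqs)
  trend_fit <- .fit_length_trend(scores, lens, profile$n_match)
  resid <- scores - trend_fit$trend(lens)
  var_fit <- .fit_length_scale(resid, lens)
  fit <- .fit_gumbel(resid / var_fit$scale(lens))
  structure(list(mu = unname(fit["mu"]), lam = unname(fit["lam"]),
                 trend_coef = trend_fit$coef,
                 var_coef = var_fit$coef, var_floor = var_fit$floor,
                 n_match = profile$n_match,
                 n_null = as.integer(n_null), seed = as.integer(seed),
                 null_scores = scores, null_lengths = lens),
            class = "evalue_calibration")
}

#' E-value of a bit score under a calibration
#'
#' @param calib An [calibrate_evalue()] object.
#' @param score Bit score(s).
#' @param n_database Number of sequences in the searched catalog.
#' @param length Unaligned sequence length(s) of the scored record(s),
#'   consumed by the calibration's length correction.
#' @return Non-negative E-value(s), strictly decreasing in `score` at
#'   fixed `length`.
#' @export
evalue <- function(calib, score, n_database, length) {
  resid <- score - .length_trend(calib$trend_coef, length, calib$n_match)
  z <- resid / .length_scale(calib$var_coef, calib$var_floor, length)
  t <- exp(-(z - calib$mu) / calib$lam)
  n_database * (-expm1(-t))
}

# residual standard deviation as a linear-in-length variance model,
# floored at 20% of the pooled spread to keep the scale positive
.fit_length_scale <- function(resid, lens) {
  co <- stats::coef(stats::lm.fit(cbind(1, lens), resid^2))
  co[is.na(co)] <- 0
  floor_ <- (0.2 * sd(resid))^2
  list(coef = co, floor = floor_,
       scale = function(l) .length_scale(co, floor_, l))
}

.length_scale <- function(coef, floor_, lens) {
  sqrt(pmax(coef[1] + coef[2] * lens, floor_))
}

# least-squares fit of the piecewise length trend of null Viterbi scores
.fit_length_trend <- function(scores, lens, n_match) {
  h1 <- pmax(n_match - lens, 0)
  h2 <- pmax(lens - n_match, 0)
  X <- cbind(1, h1, h1^2, h2, h2^2)
  keep <- c(TRUE, apply(X[, -1, drop = FALSE], 2, function(v) any(v != 0)))
  co <- numeric(5)
  co[keep] <- stats::coef(stats::lm.fit(X[, keep, drop = FALSE], scores))
  co[is.na(co)] <- 0
  list(coef = co,
       trend = function(l) .length_trend(co, l, n_match))
}

.length_trend <- function(coef, lens, n_match) {
  h1 <- pmax(n_match - lens, 0)
  h2 <- pmax(lens - n_match, 0)
  coef[1] + coef[2] * h1 + coef[3] * h1^2 + coef[4] * h2 + coef[5] * h2^2
}

#' Search a protein catalog with a calibrated profile
#'
#' Scores every record (Viterbi), converts scores to E-values with the
#' catalog size as the database size, and returns hits passing the E-value
#' threshold sorted by ascending E-value then record id.
#'
#' @param profile A [build_profile()] model.
#' @param calib A [calibrate_evalue()] object for the same profile.
#' @param catalog A protein catalog ([protein_records()]).
#' @param evalue_threshold Positive E-value cutoff (the pipeline defaults
#'   are 1e-5 for hgcA/hgcB/merB and 1e-10 for merA).
#' @return A `data.frame` of hits: `record_id`, `sample_id`, `family`,
#'   `bit_score`, `evalue`.
#' @export
search_catalog <- function(profile, calib, catalog, evalue_threshold) {
  if (evalue_threshold <= 0) input_error("evalue threshold must be > 0")
  empty <- data.frame(record_id = character(), sample_id = character(),
                      family = character(), bit_score = numeric(),
                      evalue = numeric(), stringsAsFactors = FALSE)
  if (is.null(catalog) || nrow(catalog) == 0L) return(empty)
  scores <- .score_many(profile, catalog$sequence)
  ev <- evalue(calib, scores, nrow(catalog), nchar(catalog$sequence))
  keep <- which(ev <= evalue_threshold)
  hits <- data.frame(record_id = catalog$id[keep],
                     sample_id = catalog$sample_id[keep],
                     family = rep(profile$family, length(keep)),
                     bit_score = scores[keep], evalue = ev[keep],
                     stringsAsFactors = FALSE)
  hits <- hits[order(hits$evalue, hits$record_id), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Serialize a profile to a plain-text file
#'
#' The format is a versioned key-value + matrix text layout that
#' round-trips bit-exactly: `write_profile(read_profile(p))` reproduces the
#' file byte for byte (numbers are printed with `%.17g`).
#'
#' @param profile A [build_profile()] model.
#' @param path Output path.
#' @export
write_profile <- function(profile, path) {
  num <- function(x) paste(sprintf("%.17g", x), collapse = " ")
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(...) writeLines(paste0(...), con, sep = "\n")
  wr("hgscreen-profile 1")
  wr("family ", profile$family)
  wr("n_match ", profile$n_match)
  wr("alphabet ", paste(AA20, collapse = ""))
  wr("background ", num(profile$background))
  wr("insert_emissions ", num(profile$insert_emissions))
  wr("match_columns ", paste(profile$match_columns, collapse = " "))
  wr("match_emissions")
  for (i in seq_len(profile$n_match)) wr(num(profile$match_emissions[i, ]))
  wr("transitions")
  for (i in seq_len(profile$n_match + 1L)) wr(num(profile$transitions[i, ]))
}

#' @rdname write_profile
#' @return `read_profile()` returns the deserialized `profile_model`.
#' @export
read_profile <- function(path) {
  lines <- readLines(path)
  if (lines[1] != "hgscreen-profile 1")
    input_error("not an hgscreen profile file (or unknown version): %s", path)
  kv <- function(key) {
    ln <- lines[startsWith(lines, paste0(key, " "))][1]
    sub(paste0("^", key, " "), "", ln)
  }
  nums <- function(s) as.numeric(strsplit(trimws(s), " +")[[1]])
  L <- as.integer(kv("n_match"))
  i_me <- which(lines == "match_emissions")
  i_tr <- which(lines == "transitions")
  match_em <- do.call(rbind, lapply(lines[(i_me + 1):(i_me + L)], nums))
  trans <- do.call(rbind, lapply(lines[(i_tr + 1):(i_tr + L + 1)], nums))
  colnames(trans) <- c("MM", "MI", "MD", "IM", "II", "DM", "DD")
  structure(list(family = kv("family"), n_match = L,
                 match_emissions = match_em,
                 insert_emissions = nums(kv("insert_emissions")),
                 transitions = trans,
                 background = nums(kv("background")),
                 match_columns = as.integer(nums(kv("match_columns")))),
            class = "profile_model")
}

#' Write a hit table as TSV
#'
#' @param hits A hit `data.frame` from [search_catalog()].
#' @param path Output path.
#' @export
write_hit_tsv <- function(hits, path) write_tsv(hits, path)
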