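.check_xy <- function(x, y) {
  if (length(x) != length(y)) input_error("x and y lengths differ")
  if (length(x) < 3L) input_error("need n >= 3")
  if (anyNA(x) || anyNA(y)) input_error("missing values not allowed here")
  if (sd(x) == 0 || sd(y) == 0)
    input_error("constant vector: Spearman's rho is undefined")
}

# rho of two rank vectors via the Pearson product-moment form (handles ties)
.rank_rho <- function(rx, ry) {
  cx <- rx - mean(rx); cy <- ry - mean(ry)
  sum(cx * cy) / sqrt(sum(cx^2) * sum(cy^2))
}

#' Spearman's rank correlation with asymptotic p-value
#'
#' Ranks use the average-rank convention for ties; rho is the Pearson
#' correlation of the rank vectors; the two-sided p-value uses the t
#' transform `t = rho * sqrt((n - 2) / (1 - rho^2))` with `n - 2` degrees
#' of freedom.
#'
#' @param x,y Equal-length numeric vectors, `n >= 3`, no missing values,
#'   neither constant.
#' @return A list with `rho`, `p_value`, `n`, `method = "asymptotic"`.
#' @export
spearman <- function(x, y) {
  .check_xy(x, y)
  n <- length(x)
  rho <- .rank_rho(rank(x), rank(y))
  if (abs(rho) >= 1) {
    p <- 2 * pt(-Inf, df = n - 2) # 0; clamp below
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p_value = max(p, .Machine$double.xmin), n = n,
       method = "asymptotic")
}

# all permutations of 1..n as a matrix (n! rows); n <= 7 in practice
.all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- .all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

#' Permutation p-value for Spearman's rho
#'
#' Two-sided permutation test of the observed `|rho|`. For `n <= 7` all
#' `n!` permutations are enumerated and the p-value is exact
#' (`count / n!`); otherwise `n_perm` random permutations are drawn and
#' the add-one estimator `(1 + count) / (n_perm + 1)` is used.
#'
#' @param x,y As in [spearman()].
#' @param n_perm Number of random permutations (>= 99) for the Monte-Carlo
#'   branch.
#' @param seed Integer seed for the Monte-Carlo branch.
#' @return A list with `rho`, `p_value`, `n`, `method = "permutation"`.
#' @export
spearman_permutation_p <- function(x, y, n_perm = 999L, seed = 1L) {
  .check_xy(x, y)
  if (n_perm < 99L) input_error("n_perm must be >= 99")
  n <- length(x)
  rx <- rank(x); ry <- rank(y)
  obs <- abs(.rank_rho(rx, ry))
  tol <- 1e-12 # |rho*| >= |rho_obs| up to float noise
  if (n <= 7L) {
    perms <- .all_perms(n)
    stat <- apply(perms, 1, function(p) abs(.rank_rho(rx, ry[p])))
    p_val <- sum(stat >= obs - tol) / nrow(perms)
  } else {
    set.seed(seed)
    stat <- replicate(n_perm, abs(.rank_rho(rx, ry[sample.int(n)])))
    p_val <- (1 + sum(stat >= obs - tol)) / (n_perm + 1)
  }
  list(rho = .rank_rho(rx, ry), p_value = p_val, n = n,
       method = "permutation")
}

#' Correlation matrix between gene abundances and environmental variables
#'
#' Joins an abundance table (per-sample rpoB-normalized percentages, one
#' column per family) with an environment table by `sample_id` and computes
#' Spearman correlations for every unordered pair of the requested
#' variables. Rows with a missing value in either member of a pair are
#' dropped pairwise; the effective `n` is reported per pair.
#'
#' @param abundance Abundance table from [relative_abundance()] (long
#'   format), or `NULL` to correlate environment variables only.
#' @param env An environment table (see [make_env_table()]).
#' @param variables Character vector of variable names drawn from the
#'   joined table (family names refer to their `relative_pct`).
#' @param method `"asymptotic"` or `"permutation"`.
#' @param n_perm,seed Passed to [spearman_permutation_p()].
#' @param adjust Add a Benjamini-Hochberg adjusted column `p_adj`
#'   (off-diagonal pairs only). Off by default, matching the unadjusted
#'   reporting convention of depth-profile studies.
#' @return A `data.frame` of `variable_x`, `variable_y`, `rho`, `p_value`,
#'   `n`, `method` (one row per unordered pair, including self-pairs).
#' @export
correlation_matrix <- function(abundance, env, variables,
                               method = c("asymptotic", "permutation"),
                               n_perm = 999L, seed = 1L, adjust = FALSE) {
  method <- match.arg(method)
  joined <- env
  if (!is.null(abundance) && nrow(abundance)) {
    for (fam in unique(abundance$family)) {
      sub <- abundance[abundance$family == fam, , drop = FALSE]
      idx <- match(joined$sample_id, sub$sample_id)
      if (anyNA(idx))
        input_error("abundance/environment join mismatch for samples: %s",
                    paste(joined$sample_id[is.na(idx)], collapse = ", "))
      joined[[fam]] <- sub$relative_pct[idx]
    }
  }
  missing_vars <- setdiff(variables, names(joined))
  if (length(missing_vars))
    input_error("unknown variables: %s", paste(missing_vars, collapse = ", "))
  pairs <- which(upper.tri(diag(length(variables)), diag = TRUE),
                 arr.ind = TRUE)
  rows <- lapply(seq_len(nrow(pairs)), function(k) {
    vx <- variables[pairs[k, "row"]]; vy <- variables[pairs[k, "col"]]
    x <- joined[[vx]]; y <- joined[[vy]]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 3L || sd(x[ok]) == 0 || sd(y[ok]) == 0) {
      # degenerate pair (e.g. a constant abundance profile): report NA
      # rather than aborting the whole matrix
      res <- list(rho = NA_real_, p_value = NA_real_, n = sum(ok),
                  method = method)
    } else {
      res <- if (method == "asymptotic") spearman(x[ok], y[ok])
             else spearman_permutation_p(x[ok], y[ok], n_perm, seed)
    }
    data.frame(variable_x = vx, variable_y = vy, rho = res$rho,
               p_value = res$p_value, n = res$n, method = res$method,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (adjust) {
    off <- out$variable_x != out$variable_y
    out$p_adj <- NA_real_
    out$p_adj[off] <- stats::p.adjust(out$p_value[off], method = "BH")
  }
  rownames(out) <- NULL
  out
}
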