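## Shared fixtures and independent oracles (kept deliberately naive and
## separate from the package implementation).

make_counts <- function(m, samples = NULL, taxa = NULL) {
  samples <- samples %||% sprintf("S%02d", seq_len(nrow(m)))
  taxa <- taxa %||% sprintf("g%02d", seq_len(ncol(m)))
  dimnames(m) <- list(samples, taxa)
  genus_count_table(m)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

## Small, fast simulation settings for unit tests (not the study-size
## defaults used in the acceptance checks).
tiny_params <- function(...) {
  defaults <- list(n_subjects = 10, n_taxa = 24, n_depleted = 12,
                   n_bloomed = 7, depth_meanlog = log(5000),
                   missingness = 0)
  do.call(simulation_params, utils::modifyList(defaults, list(...)))
}

## Balanced 2x2 cohort with exact cell means: placebo cells (10, 11), FL2
## cells (10, 14).  Subject offsets share the same multiset in both arms,
## and the within-subject jitter sums to zero in every arm x timepoint
## cell, so the design stays balanced and every fixed-effect contrast is
## exactly the difference of cell means while all variance components
## remain positive (a numerically regular mixed-model fit).
did_cohort <- function(n_per_arm = 4) {
  subjects <- sprintf("S%02d", seq_len(2 * n_per_arm))
  arm <- rep(c("placebo", "FL2"), each = n_per_arm)
  cells <- list(placebo = c(CID2 = 10, SuV1 = 11),
                FL2 = c(CID2 = 10, SuV1 = 14))
  off <- rep(seq(-0.5, 0.5, length.out = n_per_arm), 2)
  jit <- list(c(0.2, -0.2), c(-0.2, 0.2), c(0.4, -0.4), c(-0.4, 0.4))
  do.call(rbind, lapply(seq_along(subjects), function(i) {
    a <- arm[i]
    tibble::tibble(subject_id = subjects[i], arm = a,
                   timepoint = c("CID2", "SuV1"), variable = "y",
                   value = cells[[a]] + off[i] +
                     jit[[(i - 1) %% n_per_arm + 1]])
  }))
}

## Brute-force CLR of one count row: log of pseudocounted parts over their
## geometric mean, computed without the package's vectorized path.
brute_clr <- function(row, p = 1) {
  x <- row + p
  gm <- prod(x)^(1 / length(x))
  log(x / gm)
}

## Exact two-sided Wilcoxon signed-rank p by enumeration of all 2^n sign
## patterns (no ties, no zeros).
enum_signed_rank_p <- function(diffs) {
  n <- length(diffs)
  r <- rank(abs(diffs))
  v_obs <- sum(r[diffs > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  v_all <- as.matrix(signs) %*% r
  p_ge <- mean(v_all >= v_obs)
  p_le <- mean(v_all <= v_obs)
  min(1, 2 * min(p_ge, p_le))
}

## Exact two-sided Mann-Whitney p by enumeration of all choose(m+n, m)
## group labellings (no ties).
enum_mann_whitney_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(a)
  u_of <- function(idx) {
    ra <- rank(pooled)[idx]
    sum(ra) - n * (n + 1) / 2
  }
  u_obs <- u_of(seq_len(n))
  combos <- utils::combn(length(pooled), n)
  u_all <- apply(combos, 2, u_of)
  m2 <- length(pooled) - n
  mu <- n * m2 / 2
  min(1, 2 * min(mean(u_all >= u_obs), mean(u_all <= u_obs)))
}

## Step-up Benjamini-Hochberg executed literally from the definition.
step_up_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m))
    q_sorted[i] <- min(1, min(p[o][i:m] * m / (i:m)))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}
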