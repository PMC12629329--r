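test_that("interaction estimate equals the difference-in-differences on balanced noiseless data", {
  fit <- suppressWarnings(
    fit_lmm(did_cohort(), lmm_spec("y", time_levels = c("CID2", "SuV1"),
                                   log_transform = "none")))
  est <- fit$fixed_effects$estimate[fit$fixed_effects$term ==
                                      "armFL2:timepointSuV1"]
  expect_equal(unname(est), 3, tolerance = 1e-6)
  expect_lt(fit$p_interaction, 0.05)

  ph <- posthoc_contrast(fit, "SuV1")
  expect_equal(ph$estimate, 3, tolerance = 1e-6)
  ph0 <- posthoc_contrast(fit, "CID2")
  expect_equal(ph0$estimate, 0, tolerance = 1e-6)
})

test_that("constant outcome gives zero interaction and p = 1", {
  d <- did_cohort()
  d$value <- 5
  fit <- fit_lmm(d, lmm_spec("y", time_levels = c("CID2", "SuV1"),
                             log_transform = "none"))
  expect_equal(fit$p_interaction, 1)
  expect_true(all(fit$fixed_effects$estimate[-1] == 0))
  expect_error(posthoc_contrast(fit, "SuV1"), class = "contract_error")
})

test_that("degenerate designs are rejected", {
  d <- did_cohort()
  expect_error(fit_lmm(d[d$arm == "placebo", ],
                       lmm_spec("y", time_levels = c("CID2", "SuV1"))),
               class = "design_error")
  expect_error(fit_lmm(d, lmm_spec("z", time_levels = c("CID2", "SuV1"))),
               class = "design_error")
  expect_error(lmm_spec("y", time_levels = "CID2"),
               class = "parameter_error")
  expect_error(lmm_spec("y", covariates = "shoe_size"),
               class = "parameter_error")
})

test_that("vanco_delta covariate is the CID2 - CID1 change of the outcome", {
  d <- did_cohort()
  base <- tibble::tibble(subject_id = unique(d$subject_id),
                         arm = d$arm[!duplicated(d$subject_id)],
                         timepoint = "CID1", variable = "y",
                         value = 9 + seq_along(unique(d$subject_id)) * 0.1)
  vd <- compute_vanco_delta(rbind(base, d))
  expect_equal(length(vd), 8)
  s1 <- d$value[d$subject_id == "S01" & d$timepoint == "CID2"] -
    base$value[base$subject_id == "S01"]
  expect_equal(unname(vd["S01"]), unname(s1))
})

test_that("paired Wilcoxon matches exact enumeration and handles zeros", {
  res <- paired_wilcoxon(rep(0, 6), c(1, 2, 3, 4, 5, 6))
  expect_equal(res$p, 2 / 2^6)
  expect_equal(res$p, 0.03125)

  set.seed(41)
  for (i in 1:10) {
    n <- sample(5:8, 1)
    before <- rnorm(n); after <- before + rnorm(n)
    expect_equal(paired_wilcoxon(before, after)$p,
                 enum_signed_rank_p(after - before), tolerance = 1e-12)
  }

  ## scale invariance of the rank test
  b <- rnorm(7); a <- b + rnorm(7)
  expect_equal(paired_wilcoxon(b, a)$p,
               paired_wilcoxon(b * 3.7, a * 3.7)$p)

  expect_error(paired_wilcoxon(1:4, 2:5),
               class = "insufficient_data_error")
  expect_error(paired_wilcoxon(1:6, 1:6),
               class = "insufficient_data_error")
})

test_that("Mann-Whitney matches exact enumeration; identical groups give p near 1", {
  res <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$U, 0)
  expect_equal(res$p, 2 / choose(6, 3))
  expect_equal(res$p, 0.1)

  set.seed(42)
  for (i in 1:10) {
    a <- rnorm(sample(3:6, 1)); b <- rnorm(sample(3:6, 1))
    expect_equal(mann_whitney(a, b)$p, enum_mann_whitney_p(a, b),
                 tolerance = 1e-12)
    ## rank invariance under common monotone transforms
    expect_equal(mann_whitney(exp(a), exp(b))$p, mann_whitney(a, b)$p)
  }

  same <- c(1, 2, 3, 4)
  expect_gte(mann_whitney(same, same)$p, 0.88)
  expect_error(mann_whitney(numeric(0), 1:3),
               class = "insufficient_data_error")
})

test_that("BH adjustment matches the literal step-up rule in any input order", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), class = "validation_error")

  set.seed(43)
  for (i in 1:10) {
    p <- runif(sample(3:12, 1))
    expect_equal(bh_adjust(p), step_up_bh(p), tolerance = 1e-12)
    ## permuting the input permutes, but never changes, each hypothesis' q
    perm <- sample(length(p))
    expect_equal(bh_adjust(p[perm]), bh_adjust(p)[perm], tolerance = 1e-12)
  }
})

test_that("correlations distinguish linear from monotone association", {
  x <- seq(-2, 2, length.out = 12)
  expect_equal(correlate(x, 2 * x + 1, "pearson")$rho, 1)
  sp <- correlate(x, exp(x), "spearman")
  expect_equal(sp$rho, 1)
  expect_lt(correlate(x, exp(x), "pearson")$rho, 1)

  set.seed(44)
  xr <- rnorm(1000); yr <- rnorm(1000)
  expect_lt(abs(correlate(xr, yr, "pearson")$rho), 0.1)

  expect_error(correlate(1:3, 1:3), class = "insufficient_data_error")
  expect_error(correlate(rep(1, 6), 1:6),
               class = "undefined_correlation_error")
})

test_that("taxa screen wires tests, families and directions correctly", {
  set.seed(45)
  n_sub <- 12
  subjects <- sprintf("S%02d", 1:n_sub)
  meta <- tibble::tibble(
    sample_id = c(paste0(subjects, "_CID1"), paste0(subjects, "_CID2")),
    subject_id = rep(subjects, 2),
    arm = rep(rep(c("placebo", "FL2"), each = n_sub / 2), 2),
    timepoint = rep(c("CID1", "CID2"), each = n_sub))
  m <- matrix(rpois(2 * n_sub * 6, 50), 2 * n_sub, 6,
              dimnames = list(meta$sample_id, paste0("g", 1:6)))
  ## taxon g1 is strongly depleted at CID2 in every subject
  m[meta$timepoint == "CID2", 1] <- rpois(n_sub, 2)
  clr <- clr_transform(m, 1)

  scr <- taxa_screen(clr, meta, design = "paired_vanco")
  expect_equal(nrow(scr), 6)
  expect_true(all(scr$q >= scr$p - 1e-12))
  expect_equal(scr$q, bh_adjust(scr$p))
  expect_equal(scr$direction[1], -1)
  expect_lt(scr$p[1], 0.05)

  ## single-taxon family: q equals p
  scr1 <- taxa_screen(clr[, 1, drop = FALSE], meta,
                      design = "paired_vanco")
  expect_equal(scr1$q, scr1$p)

  scr2 <- taxa_screen(clr, meta, design = "per_timepoint_arms",
                      timepoint = "CID2")
  expect_equal(nrow(scr2), 6)
  expect_true(all(scr2$p >= 0 & scr2$p <= 1))
  expect_error(taxa_screen(clr, meta, design = "per_timepoint_arms"),
               class = "parameter_error")
})

test_that("mostly-null taxa screen controls false calls on synthetic data", {
  set.seed(46)
  bundle <- suppressMessages(generate_study(
    tiny_params(rng_seed = 46, n_depleted = 0, n_bloomed = 0)))
  filt <- suppressMessages(prevalence_filter(bundle$table, 0.15))
  clr <- clr_transform(filt, 1)
  scr <- taxa_screen(clr, bundle$meta, design = "paired_vanco")
  ## no taxa were perturbed: expect (almost) no q < 0.05 calls
  expect_lte(sum(scr$q < 0.05), 1)
})
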