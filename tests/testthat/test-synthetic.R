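test_that("minimization assigns deterministically toward marginal balance", {
  ## one factor (sex): level F currently 2 placebo vs 0 FL2, so the next
  ## F enrollee must go to FL2
  part <- tibble::tibble(age = rep(30, 4), sex = c("F", "F", "F", "F"),
                         bmi = rep(25, 4))
  arms <- minimization_randomize(part, factors = "sex", seed = 1)
  expect_equal(as.character(arms[2]), setdiff(arm_levels(),
                                              as.character(arms[1])))
  expect_equal(as.character(arms[4]), setdiff(arm_levels(),
                                              as.character(arms[3])))

  ## arm sizes stay near-balanced: the overall margin bounds drift to the
  ## parity-compatible minimum plus one block
  set.seed(50)
  big <- tibble::tibble(age = sample(c(30, 60), 40, TRUE),
                        sex = sample(c("F", "M"), 40, TRUE),
                        bmi = sample(c(25, 35), 40, TRUE))
  diffs <- sapply(1:5, function(s)
    abs(diff(as.integer(table(minimization_randomize(big, seed = s))))))
  expect_true(all(diffs <= 2))
  ## odd cohort: the default 37-subject study splits 19/18
  odd <- big[1:37, ]
  expect_lte(abs(diff(as.integer(table(
    minimization_randomize(odd, seed = 3))))), 1)
  expect_error(minimization_randomize(big, factors = character(0)),
               class = "parameter_error")
})

test_that("latent trajectories recover toward baseline at the configured rate", {
  p_fast <- tiny_params(rng_seed = 60, recovery_rate = 50,
                        recovery_rate_sd = 0, sample_noise_sd = 0)
  arms <- factor(rep(arm_levels(), 5), levels = arm_levels())
  fast <- simulate_latent_trajectories(p_fast, arms, seed = 60)
  s1 <- fast$latent[["S01_CID3"]] - fast$latent[["S01_CID1"]]
  expect_lt(max(abs(s1)), 1e-6) # instant recovery: CID3 = baseline

  p_frozen <- tiny_params(rng_seed = 60, recovery_rate = 0,
                          recovery_rate_sd = 0, sample_noise_sd = 0)
  froz <- simulate_latent_trajectories(p_frozen, arms, seed = 60)
  d_cid2 <- froz$latent[["S01_CID2"]] - froz$latent[["S01_CID1"]]
  d_cid3 <- froz$latent[["S01_CID3"]] - froz$latent[["S01_CID1"]]
  expect_equal(d_cid3, d_cid2, tolerance = 1e-9) # no recovery

  ## depleted taxa fall, bloomed taxa rise at the perturbation (taxa the
  ## subject does not carry stay flat, so compare class means)
  cls <- froz$truth$taxon_class
  expect_lt(mean(d_cid2[cls == "depleted"]), 0)
  expect_gt(mean(d_cid2[cls == "bloomed"]), 0)
  expect_equal(unname(d_cid2[cls == "unaffected"]),
               rep(0, sum(cls == "unaffected")))
})

test_that("sequencing counts converge to softmax proportions at high depth", {
  lat <- list(A = setNames(c(2, 0, -1, -3), paste0("g", 1:4)))
  tab <- sample_sequencing_counts(lat, depth_meanlog = log(1e6),
                                  depth_sdlog = 0, seed = 61)
  p_hat <- tab$counts[1, ] / sum(tab$counts[1, ])
  p_true <- exp(lat$A) / sum(exp(lat$A))
  expect_lt(max(abs(p_hat - p_true)), 1e-2)

  tab2 <- sample_sequencing_counts(lat, depth_meanlog = log(1e6),
                                   depth_sdlog = 0, seed = 61)
  expect_identical(tab$counts, tab2$counts)
})

test_that("study bundles have the contracted shape and are seed-reproducible", {
  b1 <- suppressMessages(generate_study(tiny_params(rng_seed = 62)))
  b2 <- suppressMessages(generate_study(tiny_params(rng_seed = 62)))
  b3 <- suppressMessages(generate_study(tiny_params(rng_seed = 63)))
  expect_identical(b1$table$counts, b2$table$counts)
  expect_identical(b1$outcomes$value, b2$outcomes$value)
  expect_false(identical(b1$table$counts, b3$table$counts))

  expect_equal(n_taxa(b1$table), 24)
  expect_lte(n_samples(b1$table), 10 * 6)
  expect_setequal(unique(as.character(b1$meta$arm)), arm_levels())
  expect_equal(nrow(b1$participants), 10)
  expect_length(b1$truth$taxon_class, 24)
  expect_length(b1$truth$subject_rate, 10)

  d <- tempfile()
  write_study(b1, d)
  expect_identical(read_count_table(file.path(d, "counts.tsv"))$counts,
                   b1$table$counts)
  expect_equal(nrow(read_sample_metadata(file.path(d, "metadata.tsv"))),
               nrow(b1$meta))
})

test_that("default perturbation collapses observed richness below 40% of baseline", {
  ratios <- sapply(1:3, function(s) {
    b <- suppressMessages(generate_study(simulation_params(rng_seed = s)))
    dv <- suppressMessages(diversity_table(b$table))
    mean(dv$richness[dv$timepoint == "CID2"]) /
      mean(dv$richness[dv$timepoint == "CID1"])
  })
  expect_lt(mean(ratios), 0.40)
})

test_that("ground-truth perturbation classes show the right CLR shifts", {
  b <- suppressMessages(generate_study(tiny_params(rng_seed = 64)))
  clr <- clr_transform(b$table, 1)
  meta <- b$meta
  shift <- colMeans(clr[meta$sample_id[meta$timepoint == "CID2"], ]) -
    colMeans(clr[meta$sample_id[meta$timepoint == "CID1"], ])
  cls <- b$truth$taxon_class
  expect_lt(mean(shift[cls == "depleted"]), 0)
  expect_gt(mean(shift[cls == "bloomed"]), 0)
})

test_that("injected metabolic arm-by-time effects are recovered by the mixed model", {
  hits <- sapply(1:10, function(s) {
    p <- tiny_params(rng_seed = s, n_subjects = 30)
    arms <- factor(rep(arm_levels(), length.out = 30),
                   levels = arm_levels())
    out <- simulate_metabolic_outcomes(p, arms, seed = s)
    fit <- suppressWarnings(
      fit_lmm(out, lmm_spec("il6", time_levels = c("CID2", "CID3"),
                            log_transform = "none")))
    est <- fit$fixed_effects$estimate[grepl(":", fit$fixed_effects$term)]
    se <- fit$fixed_effects$se[grepl(":", fit$fixed_effects$term)]
    ## interaction coefficient is the 8-week arm contrast: slope x 8
    abs(est - 8 * p$outcomes$il6$arm_time_slope) <= 2.2 * se
  })
  expect_gte(mean(hits), 0.8)
})
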