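## Synthetic two-arm perturbation-recovery cohort generator.
##
## The generator emulates the statistical structure the analysis assumes:
## a severe antibiotic perturbation at the second visit (richness
## collapsing from about 46 to about 15 observed genera), arm-specific
## exponential recovery in latent log-abundance space, multinomial
## sequencing noise, correlated metabolic outcomes with a subject random
## intercept, occasional missing samples, and the trial's minimization
## randomization.  Every dataset carries its ground truth so downstream
## estimators can be validated against known effects.

#' Parameters of the synthetic perturbation-recovery cohort
#'
#' Defaults describe the study design the pipeline targets: 37 subjects in
#' two arms, 73 genera, six visits, with 36 taxa depleted and 22 bloomed by
#' the perturbation (15 unaffected) and perturbation magnitudes calibrated
#' so mean observed richness collapses from roughly 46 genera at baseline
#' to roughly 15 directly after antibiotic use.
#'
#' @param n_subjects total cohort size.
#' @param n_taxa number of genera.
#' @param taxon_logmean_sd spread (SD, natural-log scale) of taxon mean
#'   log-abundances across the 73 genera; sets how uneven the baseline
#'   community is.
#' @param occupancy probability that a given subject carries a given genus
#'   at baseline; non-carried genera are effectively absent from that
#'   subject throughout.  Decouples observed richness (occupancy x
#'   `n_taxa`) from evenness among carried genera.
#' @param subject_sd between-subject SD of a taxon's baseline
#'   log-abundance.
#' @param sample_noise_sd per-sample latent log-abundance noise SD.
#' @param n_depleted,n_bloomed numbers of taxa depleted / bloomed at the
#'   perturbation visit; the remainder are unaffected.
#' @param depletion_logfold,bloom_logfold mean latent log-fold
#'   displacement of depleted / bloomed taxa at the perturbation.
#' @param perturbation_noise_sd subject-level SD around those log-folds.
#' @param recovery_rate baseline (placebo-arm) exponential recovery rate r
#'   in week^-1: the remaining displacement after w weeks is
#'   `exp(-r w)` of the initial displacement.
#' @param recovery_effect additive recovery-rate advantage of the
#'   supplemented arm (week^-1).
#' @param transient if `TRUE` the advantage accrues during weeks 0-2 of
#'   supplementation only, after which both arms recover at the shared
#'   base rate and their displacement difference decays away with the
#'   perturbation itself; if `FALSE` the advantage keeps accruing
#'   through week 8.
#' @param recovery_rate_sd between-subject SD of the recovery rate.
#' @param depth_meanlog,depth_sdlog log-normal sequencing depth
#'   parameters.
#' @param missingness per-visit probability that a sample is missing
#'   (completely at random; baseline visits included).
#' @param outcomes named list of metabolic outcome generators; each
#'   element is a list with `intercept`, `subject_sd`, `sigma`,
#'   `time_slope` (per week), `arm_time_slope` (additional per-week slope
#'   in the supplemented arm), `vanco_shift` (mean change from CID1 to
#'   CID2) and `lognormal` (simulate on the log scale and exponentiate).
#'   The default emulates a plasma IL-6-like marker that drifts up under
#'   placebo and down under supplementation.
#' @param rng_seed integer seed; the whole bundle is reproducible from the
#'   parameters and this seed.
#' @return list of class `simulation_params`.
#' @export
simulation_params <- function(n_subjects = 37,
                              n_taxa = 73,
                              taxon_logmean_sd = 1.5,
                              occupancy = 0.63,
                              subject_sd = 0.6,
                              sample_noise_sd = 0.3,
                              n_depleted = 36,
                              n_bloomed = 22,
                              depletion_logfold = -9,
                              bloom_logfold = 8,
                              perturbation_noise_sd = 2,
                              recovery_rate = 0.5,
                              recovery_effect = 0,
                              transient = TRUE,
                              recovery_rate_sd = 0.2,
                              depth_meanlog = log(20000),
                              depth_sdlog = 0.3,
                              missingness = 0.03,
                              outcomes = list(
                                il6 = list(intercept = 0.85,
                                           subject_sd = 0.25,
                                           sigma = 0.12,
                                           time_slope = 0.011,
                                           arm_time_slope = -0.022,
                                           vanco_shift = 0.03,
                                           lognormal = FALSE)),
                              rng_seed = 1L) {
  check_number(n_subjects, "n_subjects", min = 4)
  check_number(n_taxa, "n_taxa", min = 2)
  if (n_depleted + n_bloomed > n_taxa)
    stop_mr("n_depleted + n_bloomed exceeds n_taxa",
            class = "parameter_error")
  check_number(missingness, "missingness", min = 0, max = 1)
  check_number(occupancy, "occupancy", min = 0, max = 1)
  if (recovery_rate < 0 || recovery_rate_sd < 0)
    stop_mr("recovery rates must be >= 0", class = "parameter_error")
  structure(list(n_subjects = n_subjects, n_taxa = n_taxa,
                 taxon_logmean_sd = taxon_logmean_sd,
                 occupancy = occupancy,
                 subject_sd = subject_sd,
                 sample_noise_sd = sample_noise_sd,
                 n_depleted = n_depleted, n_bloomed = n_bloomed,
                 depletion_logfold = depletion_logfold,
                 bloom_logfold = bloom_logfold,
                 perturbation_noise_sd = perturbation_noise_sd,
                 recovery_rate = recovery_rate,
                 recovery_effect = recovery_effect,
                 transient = transient,
                 recovery_rate_sd = recovery_rate_sd,
                 depth_meanlog = depth_meanlog, depth_sdlog = depth_sdlog,
                 missingness = missingness, outcomes = outcomes,
                 rng_seed = as.integer(rng_seed)),
            class = "simulation_params")
}

#' Pocock-Simon minimization randomization
#'
#' Sequentially assigns each participant to the arm that minimizes the
#' total marginal imbalance across the levels of the prognostic factors
#' (equal factor weights); exact ties are broken by a seeded coin flip.
#' Overall arm size is included as one additional margin, which keeps the
#' final arm sizes within one of each other.  Default factors are sex, age
#' dichotomized at 45 years, and BMI dichotomized at 30 kg/m2.
#'
#' @param participants data frame with columns `age`, `sex`, `bmi` (rows in
#'   enrolment order).
#' @param factors character vector naming the factors to balance, a subset
#'   of `c("sex", "age", "bmi")`.
#' @param age_cut,bmi_cut dichotomization cut-points.
#' @param seed integer seed for tie-breaking coin flips.
#' @return factor of arm assignments (`placebo` / `FL2`) in enrolment
#'   order.
#' @export
minimization_randomize <- function(participants,
                                   factors = c("sex", "age", "bmi"),
                                   age_cut = 45, bmi_cut = 30,
                                   seed = 1L) {
  if (length(factors) == 0)
    stop_mr("at least one minimization factor required",
            class = "parameter_error")
  miss <- setdiff(factors, names(participants))
  if (length(miss))
    stop_mr("participants missing factor column(s): ",
            paste(miss, collapse = ", "), class = "parameter_error")
  n <- nrow(participants)
  levels_of <- list(
    sex = function(df) as.character(df$sex),
    age = function(df) ifelse(df$age >= age_cut, "age_high", "age_low"),
    bmi = function(df) ifelse(df$bmi >= bmi_cut, "bmi_high", "bmi_low"))
  lev <- vapply(factors, function(f) levels_of[[f]](participants),
                character(n))
  lev <- matrix(lev, nrow = n)
  arms <- character(n)
  ## marginal counts per (factor, level, arm)
  counts <- list(placebo = list(), FL2 = list())
  get_ct <- function(arm, key) counts[[arm]][[key]] %||% 0L
  set.seed(as.integer(seed)) # tie-breaking coin flips
  for (i in seq_len(n)) {
    keys <- c(paste(factors, lev[i, ], sep = ":"), "overall")
    imb <- vapply(ARM_LEVELS, function(cand) {
      sum(vapply(keys, function(k) {
        np <- get_ct("placebo", k) + (cand == "placebo")
        nf <- get_ct("FL2", k) + (cand == "FL2")
        abs(np - nf)
      }, numeric(1)))
    }, numeric(1))
    pick <- if (imb[1] < imb[2]) "placebo"
            else if (imb[2] < imb[1]) "FL2"
            else sample(ARM_LEVELS, 1)
    arms[i] <- pick
    for (k in keys) counts[[pick]][[k]] <- get_ct(pick, k) + 1L
  }
  factor(arms, levels = ARM_LEVELS)
}

## Integrated recovery exposure at week w for one subject: the remaining
## fraction of the perturbation displacement is exp(-exposure).  In the
## transient scenario the supplementation advantage accrues during weeks
## 0-2 only; afterwards both arms recover at the shared base rate, so the
## absolute between-arm displacement difference decays to zero as both
## approach baseline.  In the persistent scenario the advantage keeps
## accruing through week 8.
recovery_exposure <- function(week, r_subject, effect, transient, is_fl2) {
  base <- r_subject * week
  if (!is_fl2 || effect == 0) return(base)
  if (transient) base + effect * pmin(week, 2) else base + effect * week
}

#' Simulate latent per-subject log-abundance trajectories
#'
#' Baseline log-abundances are drawn around per-taxon means; at the
#' perturbation visit (CID2) depleted and bloomed taxa are displaced by
#' their log-folds plus subject-level noise; at later visits the
#' displacement relaxes exponentially toward the subject's own baseline at
#' a subject-specific rate centred on the arm mean.  Per-sample noise is
#' added to every visit.
#'
#' @param params a [simulation_params()].
#' @param assignments factor of arm assignments, length `n_subjects`.
#' @param seed integer seed.
#' @return list with `latent` (named list: per sample id a taxon-length
#'   latent log-abundance vector), `meta` (sample metadata tibble), and
#'   `truth` (list: `taxon_class`, `subject_rate`, per-subject arm).
#' @export
simulate_latent_trajectories <- function(params, assignments,
                                         seed = params$rng_seed) {
  stopifnot(inherits(params, "simulation_params"))
  set.seed(as.integer(seed))
  n <- params$n_subjects
  J <- params$n_taxa
  if (length(assignments) != n)
    stop_mr("assignments must have length n_subjects",
            class = "parameter_error")
  subjects <- sprintf("S%02d", seq_len(n))
  taxa <- sprintf("genus_%02d", seq_len(J))
  mu <- rnorm(J, 0, params$taxon_logmean_sd)
  cls <- rep("unaffected", J)
  idx <- sample.int(J, params$n_depleted + params$n_bloomed)
  cls[idx[seq_len(params$n_depleted)]] <- "depleted"
  cls[idx[-seq_len(params$n_depleted)]] <- "bloomed"
  logfold <- c(depleted = params$depletion_logfold,
               bloomed = params$bloom_logfold, unaffected = 0)[cls]
  rate <- pmax(rnorm(n, params$recovery_rate, params$recovery_rate_sd), 0)
  names(rate) <- subjects

  latent <- list()
  meta_rows <- list()
  for (s in seq_len(n)) {
    carried <- runif(J) < params$occupancy
    b <- mu + rnorm(J, 0, params$subject_sd)
    ## non-carried genera are effectively absent from this subject
    b[!carried] <- b[!carried] - 25
    delta <- ifelse(cls == "unaffected" | !carried, 0,
                    logfold + rnorm(J, 0, params$perturbation_noise_sd))
    is_fl2 <- assignments[s] == "FL2"
    for (tp in TIMEPOINT_LEVELS) {
      id <- paste0(subjects[s], "_", tp)
      if (tp == "CID1") {
        x <- b
      } else {
        w <- TIMEPOINT_WEEKS[[tp]]
        ex <- recovery_exposure(w, rate[s], params$recovery_effect,
                                params$transient, is_fl2)
        x <- b + delta * exp(-ex)
      }
      x <- x + rnorm(J, 0, params$sample_noise_sd)
      latent[[id]] <- setNames(x, taxa)
      meta_rows[[id]] <- tibble::tibble(
        sample_id = id, subject_id = subjects[s],
        arm = as.character(assignments[s]), timepoint = tp)
    }
  }
  list(latent = latent,
       meta = dplyr::bind_rows(meta_rows),
       truth = list(taxon_class = setNames(cls, taxa),
                    subject_rate = rate,
                    arm = setNames(as.character(assignments), subjects)))
}

#' Multinomial sequencing counts from latent abundances
#'
#' Per-sample read depth is log-normal; counts are multinomial on the
#' softmax of the latent log-abundances.
#'
#' @param latent named list of latent log-abundance vectors (one per
#'   sample), as produced by [simulate_latent_trajectories()].
#' @param depth_meanlog,depth_sdlog log-normal depth parameters.
#' @param seed integer seed.
#' @return `genus_count_table` (unannotated) over all samples.
#' @export
sample_sequencing_counts <- function(latent, depth_meanlog = log(20000),
                                     depth_sdlog = 0.3, seed = 1L) {
  set.seed(as.integer(seed))
  ids <- names(latent)
  taxa <- names(latent[[1]])
  m <- matrix(0L, length(ids), length(taxa),
              dimnames = list(ids, taxa))
  for (i in seq_along(ids)) {
    depth <- round(rlnorm(1, depth_meanlog, depth_sdlog))
    if (depth <= 0) {
      mr_log("sample %s drawn with depth 0: all-zero row", ids[i])
      next
    }
    x <- latent[[ids[i]]]
    p <- exp(x - max(x))
    m[i, ] <- rmultinom(1, depth, p / sum(p))[, 1]
  }
  genus_count_table(m)
}

#' Simulate longitudinal metabolic outcomes
#'
#' Each outcome follows a linear mixed structure: subject random intercept
#' plus a per-week time trend, an additional per-week arm-by-time effect in
#' the supplemented arm, a mean shift over the antibiotic week (CID1 to
#' CID2), and Gaussian noise; log-normal outcomes are generated on the log
#' scale and exponentiated.  Outcomes are produced at the three clinical
#' investigation days (CID1, CID2, CID3).
#'
#' @inheritParams simulate_latent_trajectories
#' @param seed integer seed.
#' @return long outcome tibble (subject_id, arm, timepoint, variable,
#'   value) with the true per-outcome arm-by-time slopes attached as
#'   attribute `true_effects`.
#' @export
simulate_metabolic_outcomes <- function(params, assignments,
                                        seed = params$rng_seed) {
  stopifnot(inherits(params, "simulation_params"))
  set.seed(as.integer(seed))
  n <- params$n_subjects
  subjects <- sprintf("S%02d", seq_len(n))
  rows <- list()
  for (nm in names(params$outcomes)) {
    o <- params$outcomes[[nm]]
    b <- rnorm(n, 0, o$subject_sd)
    for (s in seq_len(n)) {
      is_fl2 <- assignments[s] == "FL2"
      for (tp in c("CID1", "CID2", "CID3")) {
        w <- if (tp == "CID1") 0 else TIMEPOINT_WEEKS[[tp]]
        shift <- if (tp == "CID1") 0 else (o$vanco_shift %||% 0)
        y <- o$intercept + b[s] + shift + o$time_slope * w +
          (if (is_fl2) o$arm_time_slope * w else 0) +
          rnorm(1, 0, o$sigma)
        if (isTRUE(o$lognormal)) y <- exp(y)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          subject_id = subjects[s], arm = as.character(assignments[s]),
          timepoint = tp, variable = nm, value = y)
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "true_effects") <-
    vapply(params$outcomes, function(o) o$arm_time_slope, numeric(1))
  out
}

#' Generate a complete synthetic study bundle
#'
#' Composes minimization randomization (on simulated age/sex/BMI),
#' latent perturbation-recovery trajectories, multinomial sequencing
#' counts, metabolic outcomes, and completely-at-random missing samples
#' into one reproducible dataset with ground truth.
#'
#' @param params a [simulation_params()].
#' @return list with elements `table` (annotated `genus_count_table`),
#'   `outcomes` (long outcome tibble), `meta` (sample metadata),
#'   `participants` (simulated covariates with arm assignments), `truth`
#'   (taxon classes, subject recovery rates, true outcome effects), and
#'   `params`.
#' @export
generate_study <- function(params = simulation_params()) {
  stopifnot(inherits(params, "simulation_params"))
  seed <- params$rng_seed
  set.seed(seed)
  n <- params$n_subjects
  participants <- tibble::tibble(
    subject_id = sprintf("S%02d", seq_len(n)),
    age = round(rnorm(n, 44, 12)),
    sex = sample(c("F", "M"), n, replace = TRUE),
    bmi = round(rnorm(n, 30.4, 4), 1))
  arms <- minimization_randomize(participants, seed = seed + 1L)
  participants$arm <- arms
  lat <- simulate_latent_trajectories(params, arms, seed = seed + 2L)
  tab <- sample_sequencing_counts(lat$latent, params$depth_meanlog,
                                  params$depth_sdlog, seed = seed + 3L)
  outcomes <- simulate_metabolic_outcomes(params, arms, seed = seed + 4L)
  set.seed(seed + 5L)
  keep <- runif(nrow(tab$counts)) >= params$missingness
  if (any(!keep))
    mr_log("missingness: dropping %d of %d samples", sum(!keep),
           length(keep))
  meta <- lat$meta[keep, , drop = FALSE]
  tab <- genus_count_table(tab$counts[keep, , drop = FALSE],
                           meta)
  truth <- lat$truth
  truth$outcome_effects <- attr(outcomes, "true_effects")
  list(table = tab, outcomes = outcomes, meta = meta,
       participants = participants, truth = truth, params = params)
}

#' Write a study bundle to a directory
#'
#' Writes the standard file set: `counts.tsv`, `metadata.tsv`,
#' `outcomes.tsv`, `ground_truth.tsv`.
#'
#' @param bundle result of [generate_study()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_study <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_count_table(bundle$table, file.path(dir, "counts.tsv"))
  write_sample_metadata(bundle$meta, file.path(dir, "metadata.tsv"))
  write.table(bundle$outcomes, file.path(dir, "outcomes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  gt <- tibble::tibble(taxon_id = names(bundle$truth$taxon_class),
                       class = unname(bundle$truth$taxon_class))
  write.table(gt, file.path(dir, "ground_truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}
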