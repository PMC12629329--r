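## Statistical machinery: treatment x time linear mixed models (with and
## without covariates), post-hoc contrasts, paired/two-group nonparametric
## tests, Benjamini-Hochberg correction, and correlation screens.

SUPPLEMENTATION_LEVELS <- c("CID2", "SuV1", "SuV2", "SuV3", "CID3")

#' Specify a treatment x time linear mixed model
#'
#' The model is `outcome ~ arm * timepoint [+ covariates] + (1 | subject)`,
#' with time as a categorical factor over the supplementation-period visits
#' (CID2 = week 0 through CID3 = week 8).  The single interaction p-value
#' is a likelihood-ratio test of all treatment x time terms jointly
#' (maximum-likelihood refits); estimates are reported from the REML fit.
#'
#' @param outcome name of the outcome variable (matches the `variable`
#'   column of the long outcome table).
#' @param covariates character subset of `c("vanco_delta",
#'   "baseline_bmi")`.  `vanco_delta` (the within-subject change of the
#'   outcome from CID1 to CID2, i.e. over antibiotic use) is derived from
#'   the data; `baseline_bmi` must be supplied as a column.  Metabolic
#'   outcome models typically include both; taxa and resilience models
#'   include none.
#' @param time_levels timepoints entering the model, a subset of
#'   CID2, SuV1, SuV2, SuV3, CID3.  The full set spans the eight-week
#'   supplementation; `c("CID2", "SuV1")` restricts to the first two weeks.
#' @param log_transform `"auto"` natural-log-transforms the outcome when
#'   its moment skewness exceeds `skew_threshold` in absolute value (a
#'   normality aid for right-skewed biomarkers); `"log"` forces it;
#'   `"none"` disables it.
#' @param skew_threshold skewness cut-off for `"auto"` (default 1).
#' @param alpha significance level gating post-hoc contrasts.
#' @return list of class `lmm_spec`.
#' @export
lmm_spec <- function(outcome, covariates = character(),
                     time_levels = SUPPLEMENTATION_LEVELS,
                     log_transform = c("auto", "none", "log"),
                     skew_threshold = 1, alpha = 0.05) {
  log_transform <- match.arg(log_transform)
  bad <- setdiff(covariates, c("vanco_delta", "baseline_bmi"))
  if (length(bad))
    stop_mr("unknown covariate(s): ", paste(bad, collapse = ", "),
            class = "parameter_error")
  time_levels <- as.character(parse_timepoint(time_levels))
  if (!all(time_levels %in% SUPPLEMENTATION_LEVELS))
    stop_mr("time_levels must be post-baseline visits (CID2...CID3)",
            class = "parameter_error")
  if (length(time_levels) < 2)
    stop_mr("need at least two timepoints to model time",
            class = "parameter_error")
  structure(list(outcome = outcome, covariates = covariates,
                 time_levels = time_levels, log_transform = log_transform,
                 skew_threshold = skew_threshold, alpha = alpha),
            class = "lmm_spec")
}

moment_skewness <- function(x) {
  x <- x[is.finite(x)]
  s <- sd(x)
  if (length(x) < 3 || s == 0) return(0)
  mean((x - mean(x))^3) / s^3
}

#' Within-subject change of an outcome over antibiotic use
#'
#' The `vanco_delta` covariate of the metabolic mixed models: per subject,
#' the outcome's value at CID2 (post-antibiotic) minus its value at CID1
#' (baseline).
#'
#' @param data long outcome rows for one variable, containing at least the
#'   CID1 and CID2 visits.
#' @return named numeric vector of deltas, one per subject.
#' @export
compute_vanco_delta <- function(data) {
  wide <- data[data$timepoint %in% c("CID1", "CID2"), ] |>
    dplyr::select("subject_id", "timepoint", "value") |>
    tidyr::pivot_wider(names_from = "timepoint", values_from = "value")
  if (!all(c("CID1", "CID2") %in% names(wide)))
    stop_mr("vanco_delta covariate needs CID1 and CID2 values of the outcome",
            class = "design_error")
  setNames(wide$CID2 - wide$CID1, wide$subject_id)
}

#' Fit a treatment x time linear mixed model
#'
#' @param data long outcome table: columns `subject_id`, `arm`,
#'   `timepoint`, `variable`, `value` (plus `baseline_bmi` if used as a
#'   covariate).  Rows for other variables are ignored.
#' @param spec an [lmm_spec()].
#' @return object of class `lmm_result`: fixed-effect estimates and
#'   standard errors (REML), `p_interaction` from the joint
#'   likelihood-ratio test of the treatment x time terms, post-hoc
#'   per-timepoint arm contrasts (populated only when
#'   `p_interaction < alpha`), and a convergence flag.
#' @examples
#' \donttest{
#' sim <- generate_study(simulation_params(rng_seed = 7))
#' fit <- fit_lmm(sim$outcomes, lmm_spec("il6", covariates = character()))
#' fit$p_interaction
#' }
#' @export
fit_lmm <- function(data, spec) {
  stopifnot(inherits(spec, "lmm_spec"))
  d0 <- tibble::as_tibble(data)
  need <- c("subject_id", "arm", "timepoint", "variable", "value")
  miss <- setdiff(need, names(d0))
  if (length(miss))
    stop_mr("long outcome table missing column(s): ",
            paste(miss, collapse = ", "), class = "validation_error")
  d0 <- d0[d0$variable == spec$outcome, , drop = FALSE]
  if (nrow(d0) == 0L)
    stop_mr("no rows for outcome ", sQuote(spec$outcome),
            class = "design_error")
  d0$arm <- parse_arm(d0$arm)
  d0$timepoint <- parse_timepoint(d0$timepoint)
  if ("vanco_delta" %in% spec$covariates) {
    vd <- compute_vanco_delta(d0)
    d0$vanco_delta <- unname(vd[d0$subject_id])
  }
  d <- d0[as.character(d0$timepoint) %in% spec$time_levels, , drop = FALSE]
  d$timepoint <- droplevels(factor(as.character(d$timepoint),
                                   levels = spec$time_levels))
  d <- d[is.finite(d$value), , drop = FALSE]
  for (cv in spec$covariates) {
    if (!cv %in% names(d))
      stop_mr("covariate column missing: ", cv, class = "design_error")
    d <- d[is.finite(d[[cv]]), , drop = FALSE]
  }
  if (dplyr::n_distinct(d$arm) < 2)
    stop_mr("both arms required (rank-deficient design)",
            class = "design_error")
  if (dplyr::n_distinct(d$timepoint) < 2)
    stop_mr("at least two observed timepoints required",
            class = "design_error")
  per_arm <- table(unique(d[, c("subject_id", "arm")])$arm)
  if (any(per_arm < 2))
    stop_mr("need >= 2 subjects per arm", class = "design_error")

  logged <- spec$log_transform == "log" ||
    (spec$log_transform == "auto" &&
       abs(moment_skewness(d$value)) > spec$skew_threshold)
  if (logged) {
    if (any(d$value <= 0))
      stop_mr("log transform requested for outcome with non-positive values",
              class = "design_error")
    d$value <- log(d$value)
  }

  ## Constant outcome: the mixed model is degenerate (all variance
  ## components zero); report the exact null result rather than fitting.
  if (var(d$value) == 0) {
    tp_obs <- levels(d$timepoint)
    terms <- c("(Intercept)",
               paste0("arm", ARM_LEVELS[2]),
               paste0("timepoint", tp_obs[-1]),
               paste0("arm", ARM_LEVELS[2], ":timepoint", tp_obs[-1]))
    fe <- tibble::tibble(term = terms,
                         estimate = c(d$value[1], rep(0, length(terms) - 1)),
                         se = rep(0, length(terms)))
    return(structure(list(outcome = spec$outcome, spec = spec,
                          fixed_effects = fe, p_interaction = 1,
                          posthoc = NULL, converged = TRUE, logged = logged,
                          model = NULL, n_obs = nrow(d),
                          n_subjects = dplyr::n_distinct(d$subject_id)),
                     class = "lmm_result"))
  }

  cov_part <- if (length(spec$covariates))
    paste("+", paste(spec$covariates, collapse = " + ")) else ""
  f_full <- as.formula(paste("value ~ arm * timepoint", cov_part,
                             "+ (1 | subject_id)"))
  f_null <- as.formula(paste("value ~ arm + timepoint", cov_part,
                             "+ (1 | subject_id)"))
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            check.conv.grad = "ignore",
                            check.conv.hess = "ignore")
  msgs <- character()
  fit <- withCallingHandlers(
    lme4::lmer(f_full, data = d, REML = TRUE, control = ctrl),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w)); invokeRestart("muffleWarning")
    })
  m1 <- suppressWarnings(suppressMessages(
    lme4::lmer(f_full, data = d, REML = FALSE, control = ctrl)))
  m0 <- suppressWarnings(suppressMessages(
    lme4::lmer(f_null, data = d, REML = FALSE, control = ctrl)))
  lrt <- suppressMessages(anova(m0, m1))
  p_int <- lrt[["Pr(>Chisq)"]][2]
  converged <- length(msgs) == 0 ||
    all(grepl("boundary|singular|Roundoff", msgs))
  fe_mat <- summary(fit)$coefficients
  fe <- tibble::tibble(term = rownames(fe_mat),
                       estimate = unname(fe_mat[, "Estimate"]),
                       se = unname(fe_mat[, "Std. Error"]))
  posthoc <- NULL
  if (is.finite(p_int) && p_int < spec$alpha) {
    emm <- suppressMessages(
      emmeans::emmeans(fit, ~ arm | timepoint,
                       lmer.df = "satterthwaite", data = d))
    ctr <- as.data.frame(
      emmeans::contrast(emm, method = "revpairwise", adjust = "none"))
    posthoc <- tibble::tibble(timepoint = as.character(ctr$timepoint),
                              estimate = ctr$estimate, se = ctr$SE,
                              p = ctr$p.value)
  }
  structure(list(outcome = spec$outcome, spec = spec, fixed_effects = fe,
                 p_interaction = unname(p_int), posthoc = posthoc,
                 converged = converged, logged = logged, model = fit,
                 messages = msgs, n_obs = nrow(d),
                 n_subjects = dplyr::n_distinct(d$subject_id)),
            class = "lmm_result")
}

#' @export
print.lmm_result <- function(x, ...) {
  cat("Treatment x time mixed model for", sQuote(x$outcome), "\n")
  cat(sprintf("  %d observations, %d subjects%s%s\n", x$n_obs, x$n_subjects,
              if (x$logged) ", ln-transformed outcome" else "",
              if (x$converged) "" else "  [NOT CONVERGED]"))
  cat(sprintf("  treatment x time interaction: LRT p = %.4g\n",
              x$p_interaction))
  if (!is.null(x$posthoc)) {
    cat("  post-hoc arm contrasts (FL2 - placebo):\n")
    print(as.data.frame(x$posthoc), row.names = FALSE)
  }
  invisible(x)
}

#' Post-hoc between-arm contrast at one timepoint
#'
#' Available only after a significant treatment x time interaction.
#'
#' @param result an `lmm_result`.
#' @param timepoint one of the modelled timepoints.
#' @return list with `estimate` (FL2 minus placebo on the modelled scale)
#'   and `p`.
#' @export
posthoc_contrast <- function(result, timepoint) {
  stopifnot(inherits(result, "lmm_result"))
  if (is.null(result$posthoc))
    stop_mr("post-hoc contrasts are only defined after a significant ",
            "treatment x time interaction (p_interaction = ",
            signif(result$p_interaction, 3), " >= alpha)",
            class = "contract_error")
  tp <- as.character(parse_timepoint(timepoint))
  row <- result$posthoc[result$posthoc$timepoint == tp, , drop = FALSE]
  if (nrow(row) == 0L)
    stop_mr("timepoint ", tp, " not in the fitted model",
            class = "parameter_error")
  list(estimate = row$estimate, p = row$p)
}

#' Wilcoxon signed-rank test on paired values
#'
#' Two-sided; exact for 25 or fewer informative pairs without ties, normal
#' approximation with continuity correction otherwise.  Zero differences
#' are dropped before ranking.
#'
#' @param before,after numeric vectors of per-subject values, aligned;
#'   pairs with a missing value are dropped listwise.
#' @return list with `statistic` (V) and `p`.
#' @export
paired_wilcoxon <- function(before, after) {
  ok <- is.finite(before) & is.finite(after)
  if (sum(ok) < 5)
    stop_mr("need >= 5 complete pairs, got ", sum(ok),
            class = "insufficient_data_error")
  diffs <- after[ok] - before[ok]
  diffs <- diffs[diffs != 0]
  if (length(diffs) == 0)
    stop_mr("no informative (non-zero) paired differences",
            class = "insufficient_data_error")
  exact <- length(diffs) <= 25 && !any(duplicated(abs(diffs)))
  ht <- suppressWarnings(wilcox.test(diffs, mu = 0, exact = exact,
                                     correct = TRUE))
  list(statistic = unname(ht$statistic), p = ht$p.value)
}

#' Mann-Whitney U test on two groups
#'
#' Two-sided; exact for small samples without ties, normal approximation
#' with tie correction otherwise.
#'
#' @param group_a,group_b numeric vectors; missing values dropped.
#' @return list with `U` (statistic for `group_a`) and `p`.
#' @export
mann_whitney <- function(group_a, group_b) {
  a <- group_a[is.finite(group_a)]
  b <- group_b[is.finite(group_b)]
  if (length(a) == 0 || length(b) == 0)
    stop_mr("both groups must be non-empty",
            class = "insufficient_data_error")
  ties <- any(duplicated(c(a, b)))
  exact <- !ties && length(a) <= 25 && length(b) <= 25
  ht <- suppressWarnings(wilcox.test(a, b, exact = exact, correct = TRUE))
  list(U = unname(ht$statistic), p = ht$p.value)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate correction; q-values are returned in input
#' order, capped at 1.
#'
#' @param p_values numeric vector of raw p-values in \[0, 1\].
#' @return vector of q-values.
#' @export
bh_adjust <- function(p_values) {
  if (any(!is.finite(p_values) | p_values < 0 | p_values > 1))
    stop_mr("p-values must lie in [0, 1]", class = "validation_error")
  p.adjust(p_values, method = "BH")
}

#' Correlation with two-sided test
#'
#' Pearson (for approximately normal quantities such as richness and
#' Shannon diversity) or Spearman (for taxon abundances); pairs with
#' missing values are dropped listwise.
#'
#' @param x,y numeric vectors, aligned per subject.
#' @param method `"pearson"` or `"spearman"`.
#' @return list with `rho` and `p`.
#' @export
correlate <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 4)
    stop_mr("need >= 4 complete pairs, got ", sum(ok),
            class = "insufficient_data_error")
  if (var(x[ok]) == 0 || var(y[ok]) == 0)
    stop_mr("correlation undefined: zero variance",
            class = "undefined_correlation_error")
  ht <- suppressWarnings(cor.test(x[ok], y[ok], method = method))
  list(rho = unname(ht$estimate), p = ht$p.value)
}

#' Per-taxon differential abundance screen
#'
#' Applies one test per taxon to CLR-transformed, prevalence-filtered
#' abundances and adjusts the family of raw p-values with
#' Benjamini-Hochberg (one family per screen).
#'
#' Designs: `paired_vanco` - Wilcoxon signed-rank of CID2 vs CID1 within
#' subjects (the antibiotic perturbation contrast); `per_timepoint_arms` -
#' Mann-Whitney of FL2 vs placebo at `timepoint`; `lmm_8week` /
#' `lmm_2week` - per-taxon treatment x time mixed models without
#' covariates over the full supplementation period or its first two weeks,
#' with the likelihood-ratio interaction p.
#'
#' @param clr_filtered `clr_matrix` over the prevalence-filtered taxa.
#' @param meta sample metadata covering the CLR rows.
#' @param design one of `"paired_vanco"`, `"per_timepoint_arms"`,
#'   `"lmm_8week"`, `"lmm_2week"`.
#' @param timepoint visit for `per_timepoint_arms`.
#' @return tibble (taxon_id, statistic, p, q, direction) in input taxon
#'   order; `direction` is the sign of the median paired difference (paired
#'   design), of the group median difference (two-group design), or of the
#'   final interaction coefficient (mixed-model designs).
#' @export
taxa_screen <- function(clr_filtered, meta,
                        design = c("paired_vanco", "per_timepoint_arms",
                                   "lmm_8week", "lmm_2week"),
                        timepoint = NULL) {
  design <- match.arg(design)
  m <- unclass(clr_filtered)
  meta <- validate_sample_metadata(meta)
  meta <- meta[meta$sample_id %in% rownames(m), , drop = FALSE]
  taxa <- colnames(m)
  one_taxon <- function(j) {
    v <- m[meta$sample_id, j]
    if (design == "paired_vanco") {
      wide <- tidyr::pivot_wider(
        tibble::tibble(subject_id = meta$subject_id,
                       timepoint = as.character(meta$timepoint), value = v),
        names_from = "timepoint", values_from = "value")
      if (!all(c("CID1", "CID2") %in% names(wide)))
        stop_mr("paired_vanco needs CID1 and CID2 samples",
                class = "design_error")
      res <- paired_wilcoxon(wide$CID1, wide$CID2)
      c(stat = res$statistic, p = res$p,
        dir = sign(median(wide$CID2 - wide$CID1, na.rm = TRUE)))
    } else if (design == "per_timepoint_arms") {
      if (is.null(timepoint))
        stop_mr("per_timepoint_arms requires a timepoint",
                class = "parameter_error")
      tp <- as.character(parse_timepoint(timepoint))
      sel <- as.character(meta$timepoint) == tp
      a <- v[sel & meta$arm == "FL2"]
      b <- v[sel & meta$arm == "placebo"]
      res <- mann_whitney(a, b)
      c(stat = res$U, p = res$p, dir = sign(median(a) - median(b)))
    } else {
      lv <- if (design == "lmm_2week") c("CID2", "SuV1")
            else SUPPLEMENTATION_LEVELS
      long <- tibble::tibble(subject_id = meta$subject_id, arm = meta$arm,
                             timepoint = meta$timepoint,
                             variable = "taxon", value = v)
      fit <- fit_lmm(long, lmm_spec("taxon", time_levels = lv,
                                    log_transform = "none"))
      ie <- fit$fixed_effects$estimate[grepl(":", fit$fixed_effects$term)]
      c(stat = NA_real_, p = fit$p_interaction,
        dir = if (length(ie)) sign(ie[length(ie)]) else NA_real_)
    }
  }
  res <- t(vapply(taxa, one_taxon, numeric(3)))
  tibble::tibble(taxon_id = taxa, statistic = unname(res[, "stat"]),
                 p = unname(res[, "p"]), q = bh_adjust(unname(res[, "p"])),
                 direction = unname(res[, "dir"]))
}
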