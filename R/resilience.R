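## The resilience statistic and its per-subject trajectory.
##
## For each subject, every post-baseline sample is placed at its Aitchison
## distance d(t) from that subject's own CID1 (pre-antibiotic) sample; dmax
## is the largest available d(t); resilience is
## R(t) = (dmax - d(t)) / (dmax + d(t)), 0 at maximal displacement and 1 on
## full return to baseline.

#' Per-subject Aitchison distances from baseline
#'
#' Computes, for each subject with a CID1 sample, the Aitchison distance
#' between every later sample and the subject's CID1 sample, on the full
#' (unfiltered) taxon set.  Subjects lacking a CID1 sample are skipped with
#' a logged warning; missing visits simply leave gaps (no imputation).
#'
#' @param clr a `clr_matrix` over all samples.
#' @param meta sample metadata (see [read_sample_metadata()]) covering the
#'   CLR rows.
#' @return tibble (subject_id, arm, timepoint, week, d) for post-baseline
#'   timepoints, ordered by subject and study visit.
#' @export
distance_from_baseline <- function(clr, meta) {
  meta <- validate_sample_metadata(meta)
  meta <- meta[meta$sample_id %in% rownames(clr), , drop = FALSE]
  subjects <- unique(meta$subject_id)
  has_baseline <- vapply(subjects, function(s)
    any(meta$subject_id == s & meta$timepoint == "CID1"), logical(1))
  if (!any(has_baseline))
    stop_mr("no subject has a CID1 baseline sample",
            class = "empty_result_error")
  if (any(!has_baseline)) {
    mr_log("distance_from_baseline: %d of %d subjects lack CID1 and are skipped (%s)",
           sum(!has_baseline), length(subjects),
           paste(subjects[!has_baseline], collapse = ", "))
  }
  rows <- lapply(subjects[has_baseline], function(s) {
    sm <- meta[meta$subject_id == s, , drop = FALSE]
    sm <- sm[order(match(sm$timepoint, TIMEPOINT_LEVELS)), , drop = FALSE]
    base <- clr[sm$sample_id[sm$timepoint == "CID1"], ]
    post <- sm[sm$timepoint != "CID1", , drop = FALSE]
    if (nrow(post) == 0L) return(NULL)
    tibble::tibble(
      subject_id = s,
      arm = post$arm,
      timepoint = post$timepoint,
      week = post$week,
      d = vapply(post$sample_id, function(id)
        aitchison_distance(clr[id, ], base), numeric(1),
        USE.NAMES = FALSE))
  })
  dplyr::bind_rows(rows)
}

#' Resilience score
#'
#' `R = (dmax - d) / (dmax + d)`: 0 where the community is maximally
#' displaced from baseline, 1 on exact return.
#'
#' @param d non-negative distance from baseline at a timepoint.
#' @param dmax the subject's maximum distance from baseline over
#'   post-baseline visits; must be positive.
#' @return resilience value in \[0, 1\]; vectorized over `d`.
#' @export
resilience_score <- function(d, dmax) {
  check_number(dmax, "dmax")
  if (dmax == 0)
    stop_mr("dmax = 0: subject identical to baseline at every visit, ",
            "resilience undefined", class = "undefined_resilience_error")
  if (dmax < 0 || any(d < 0) || any(d > dmax + 1e-12))
    stop_mr("resilience requires 0 <= d <= dmax", class = "invariant_error")
  (dmax - d) / (dmax + d)
}

#' Per-subject resilience trajectories
#'
#' Composes [clr_transform()], [distance_from_baseline()] and
#' [resilience_score()]: for every subject with a baseline sample, each
#' post-baseline visit gets its distance from baseline `d`, the subject
#' maximum `dmax`, and the resilience value `R`.  Subjects whose dmax is
#' zero (identical to baseline at every visit) are excluded with a warning.
#'
#' @param table an annotated `genus_count_table` (unfiltered).
#' @param config an [analysis_config()]; its pseudocount feeds the CLR
#'   transform.
#' @return tibble (subject_id, arm, timepoint, week, d, dmax, R) in long
#'   format, ready for mixed modelling.
#' @export
resilience_trajectories <- function(table, config = analysis_config()) {
  stopifnot(inherits(table, "genus_count_table"))
  if (is.null(table$meta))
    stop_mr("resilience requires an annotated table (join_and_validate first)",
            class = "validation_error")
  clr <- clr_transform(table, config$pseudocount)
  dist <- distance_from_baseline(clr, table$meta)
  out <- dist |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::mutate(dmax = max(.data$d)) |>
    dplyr::ungroup()
  flat <- out$dmax == 0
  if (any(flat)) {
    drop <- unique(out$subject_id[flat])
    warning("excluding subject(s) with dmax = 0: ",
            paste(drop, collapse = ", "), call. = FALSE)
    out <- out[!flat, , drop = FALSE]
  }
  if (nrow(out) == 0L)
    stop_mr("no subjects with positive dmax", class = "empty_result_error")
  out$R <- (out$dmax - out$d) / (out$dmax + out$d)
  out
}

#' Treatment x time mixed model on resilience trajectories
#'
#' Convenience wrapper: reshapes a [resilience_trajectories()] result into
#' the long outcome format and fits the covariate-free treatment x time
#' mixed model over the requested supplementation-period visits.
#'
#' @param trajectories output of [resilience_trajectories()].
#' @param time_levels visits to model; the full supplementation period by
#'   default, `c("CID2", "SuV1")` for the two-week model.
#' @param alpha significance level gating post-hoc contrasts.
#' @return an `lmm_result` (see [fit_lmm()]).
#' @export
resilience_lmm <- function(trajectories,
                           time_levels = c("CID2", "SuV1", "SuV2",
                                           "SuV3", "CID3"),
                           alpha = 0.05) {
  long <- tibble::tibble(subject_id = trajectories$subject_id,
                         arm = as.character(trajectories$arm),
                         timepoint = as.character(trajectories$timepoint),
                         variable = "resilience",
                         value = trajectories$R)
  fit_lmm(long, lmm_spec("resilience", time_levels = time_levels,
                         log_transform = "none", alpha = alpha))
}

#' Median split of baseline values
#'
#' Labels subjects LOW or HIGH around the median of a baseline quantity
#' (e.g. observed richness or Shannon diversity at CID1), optionally within
#' groups (e.g. per arm).  Values equal to the median go to LOW - a
#' deterministic, documented tie rule.
#'
#' @param baseline_values named numeric vector, one value per subject
#'   (names are subject ids).
#' @param within optional grouping vector aligned with `baseline_values`
#'   (e.g. arm); the split is computed separately per group.
#' @return factor with levels `LOW`, `HIGH`, named by subject.
#' @export
median_split <- function(baseline_values, within = NULL) {
  if (is.null(names(baseline_values)))
    stop_mr("baseline_values must be named by subject id",
            class = "validation_error")
  groups <- if (is.null(within)) rep("all", length(baseline_values))
            else as.character(within)
  out <- rep(NA_character_, length(baseline_values))
  for (g in unique(groups)) {
    idx <- groups == g
    if (sum(idx) < 2)
      stop_mr("median split needs at least 2 subjects per group (group ",
              sQuote(g), ")", class = "parameter_error")
    v <- baseline_values[idx]
    med <- median(v)
    if (all(v == v[1]))
      warning("degenerate split in group ", sQuote(g),
              ": all values identical, all labelled LOW", call. = FALSE)
    out[idx] <- ifelse(v > med, "HIGH", "LOW")
  }
  setNames(factor(out, levels = c("LOW", "HIGH")), names(baseline_values))
}
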