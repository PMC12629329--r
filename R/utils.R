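## Internal helpers: argument checking and the audit log.

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_mr <- function(..., class) {
  stop(errorCondition(paste0(...), class = c(class, "microresilience_error")))
}

## Every filtering / dropping step reports its before/after counts through
## here so a pipeline run leaves an audit trail.
mr_log <- function(fmt, ...) {
  message(sprintf(paste0("[microresilience] ", fmt), ...))
}

check_number <- function(x, name, positive = FALSE, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_mr(name, " must be a single finite number", class = "parameter_error")
  if (positive && x <= 0)
    stop_mr(name, " must be > 0, got ", x, class = "parameter_error")
  if (x < min || x > max)
    stop_mr(name, " must be in [", min, ", ", max, "], got ", x,
            class = "parameter_error")
  invisible(x)
}

## Canonicalize free-text arm labels to the two study arms.
parse_arm <- function(x) {
  key <- gsub("[^a-z0-9]", "", tolower(as.character(x)))
  out <- rep(NA_character_, length(key))
  out[key %in% c("placebo", "control", "maltodextrin")] <- "placebo"
  out[key %in% c("fl2", "2fl", "2fucosyllactose", "fl")] <- "FL2"
  bad <- unique(x[is.na(out) | !nzchar(key)])
  if (length(bad))
    stop_mr("unknown arm label(s): ", paste(sQuote(bad), collapse = ", "),
            "; allowed: placebo, 2'-FL (FL2)", class = "validation_error")
  factor(out, levels = ARM_LEVELS)
}

## Canonicalize visit codes (case-insensitive) to the six study timepoints.
parse_timepoint <- function(x) {
  key <- toupper(as.character(x))
  map <- setNames(TIMEPOINT_LEVELS, toupper(TIMEPOINT_LEVELS))
  out <- unname(map[key])
  bad <- unique(x[is.na(out)])
  if (length(bad))
    stop_mr("unknown timepoint label(s): ", paste(sQuote(bad), collapse = ", "),
            "; allowed: ", paste(TIMEPOINT_LEVELS, collapse = ", "),
            class = "validation_error")
  factor(out, levels = TIMEPOINT_LEVELS)
}
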