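## Genus count table: the pipeline's central input.  Samples are rows,
## genera are columns; per-sample metadata (subject, arm, timepoint) rides
## along in `meta`, aligned to the count rows by sample id.

#' Construct and validate a genus count table
#'
#' A `genus_count_table` holds a samples x genera matrix of non-negative
#' integer counts, optionally joined to per-sample metadata (subject id,
#' treatment arm, study timepoint).
#'
#' @param counts numeric matrix, samples as rows and genera as columns, with
#'   unique rownames (sample ids) and colnames (taxon labels); all entries
#'   must be non-negative integers.
#' @param meta optional data frame of sample metadata as returned by
#'   [read_sample_metadata()]; may be `NULL` for an unannotated table.
#' @return an object of class `genus_count_table` with elements `counts`
#'   (integer matrix) and `meta` (tibble or `NULL`).
#' @examples
#' m <- matrix(c(1, 2, 3, 4, 0, 5), nrow = 3, byrow = TRUE,
#'             dimnames = list(paste0("S", 1:3), c("gA", "gB")))
#' tab <- genus_count_table(m)
#' n_samples(tab)
#' @export
genus_count_table <- function(counts, meta = NULL) {
  if (!is.matrix(counts))
    stop_mr("counts must be a matrix", class = "format_error")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop_mr("counts must carry sample ids as rownames and taxon labels as colnames",
            class = "format_error")
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts),
               arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop_mr("counts must be non-negative integers; offending cell: sample ",
            sQuote(rownames(counts)[bad[1, 1]]), ", taxon ",
            sQuote(colnames(counts)[bad[1, 2]]), " = ",
            counts[bad[1, 1], bad[1, 2]], class = "format_error")
  if (anyDuplicated(rownames(counts)))
    stop_mr("duplicate sample ids: ",
            paste(unique(rownames(counts)[duplicated(rownames(counts))]),
                  collapse = ", "), class = "validation_error")
  if (anyDuplicated(colnames(counts)))
    stop_mr("duplicate taxon ids: ",
            paste(unique(colnames(counts)[duplicated(colnames(counts))]),
                  collapse = ", "), class = "validation_error")
  storage.mode(counts) <- "integer"
  if (!is.null(meta)) {
    meta <- validate_sample_metadata(meta)
    missing <- setdiff(rownames(counts), meta$sample_id)
    if (length(missing))
      stop_mr("samples without metadata: ", paste(missing, collapse = ", "),
              " (use join_and_validate() to drop them)",
              class = "validation_error")
    meta <- meta[match(rownames(counts), meta$sample_id), , drop = FALSE]
  }
  structure(list(counts = counts, meta = meta), class = "genus_count_table")
}

#' @rdname genus_count_table
#' @param x a `genus_count_table`.
#' @export
n_samples <- function(x) nrow(x$counts)

#' @rdname genus_count_table
#' @export
n_taxa <- function(x) ncol(x$counts)

#' @export
print.genus_count_table <- function(x, ...) {
  cat("genus_count_table:", n_samples(x), "samples x", n_taxa(x), "taxa;",
      if (is.null(x$meta)) "no metadata" else "with metadata", "\n")
  invisible(x)
}

#' @export
dim.genus_count_table <- function(x) dim(x$counts)

validate_sample_metadata <- function(meta) {
  meta <- tibble::as_tibble(meta)
  need <- c("sample_id", "subject_id", "arm", "timepoint")
  miss <- setdiff(need, names(meta))
  if (length(miss))
    stop_mr("metadata missing column(s): ", paste(miss, collapse = ", "),
            class = "validation_error")
  meta$sample_id <- as.character(meta$sample_id)
  meta$subject_id <- as.character(meta$subject_id)
  meta$arm <- parse_arm(meta$arm)
  meta$timepoint <- parse_timepoint(meta$timepoint)
  meta$week <- unname(TIMEPOINT_WEEKS[as.character(meta$timepoint)])
  if (anyDuplicated(meta$sample_id))
    stop_mr("duplicate sample_id in metadata", class = "validation_error")
  key <- paste(meta$subject_id, meta$timepoint)
  if (anyDuplicated(key))
    stop_mr("duplicated (subject_id, timepoint): ",
            paste(unique(key[duplicated(key)]), collapse = "; "),
            class = "validation_error")
  meta
}

#' Read a genus count table from disk
#'
#' The TSV dialect is UTF-8, tab-separated, samples as rows: a header row of
#' taxon labels, first column holding sample ids.  BIOM (JSON dialect) is
#' supported through the biomformat package; BIOM matrices are stored taxa x
#' samples and are transposed on read.
#'
#' @param path file to read.
#' @param format `"tsv"` (default) or `"biom"`.
#' @return a `genus_count_table` (without metadata).
#' @seealso [write_count_table()], [read_sample_metadata()],
#'   [join_and_validate()]
#' @export
read_count_table <- function(path, format = c("tsv", "biom")) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop_mr("file not found: ", path, class = "format_error")
  if (format == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE))
      stop_mr("biomformat package required for BIOM input",
              class = "format_error")
    b <- biomformat::read_biom(path)
    m <- t(as.matrix(biomformat::biom_data(b)))
    return(genus_count_table(m))
  }
  if (file.size(path) == 0L)
    stop_mr("empty file: ", path, class = "format_error")
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (ncol(df) < 2L)
    stop_mr("count TSV must have a sample-id column plus at least one taxon",
            class = "format_error")
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(apply(df[, -1, drop = FALSE], 2,
                                              as.numeric))), arr.ind = TRUE)
    cell <- if (nrow(bad)) paste0("sample ", sQuote(ids[bad[1, 1]]),
                                  ", taxon ",
                                  sQuote(colnames(df)[-1][bad[1, 2]]))
            else "unknown cell"
    stop_mr("non-numeric counts in ", path, " at ", cell,
            class = "format_error")
  }
  rownames(m) <- ids
  genus_count_table(m)
}

#' @rdname read_count_table
#' @param table a `genus_count_table` to write.
#' @export
write_count_table <- function(table, path) {
  stopifnot(inherits(table, "genus_count_table"))
  df <- data.frame(sample_id = rownames(table$counts), table$counts,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Read per-sample metadata
#'
#' Expects a TSV with columns `sample_id`, `subject_id`, `arm`, `timepoint`
#' (a `sample_id` equal to `subject_id` + timepoint is not assumed).  Arm
#' labels are canonicalized to `placebo` / `FL2`; timepoints to
#' CID1, CID2, SuV1, SuV2, SuV3, CID3 with their week mapping (CID2 = week 0
#' of supplementation; SuV1/2/3 = weeks 2/4/6; CID3 = week 8; CID1 is the
#' pre-perturbation baseline and carries no numeric week).
#'
#' @param path metadata TSV.
#' @return tibble with parsed `arm` and `timepoint` factors and a `week`
#'   column.
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path))
    stop_mr("file not found: ", path, class = "format_error")
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  validate_sample_metadata(df)
}

#' @rdname read_sample_metadata
#' @param meta a metadata data frame to write.
#' @export
write_sample_metadata <- function(meta, path) {
  write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Join counts to metadata, dropping unannotated samples
#'
#' Samples present in the count table but absent from the metadata are
#' dropped with a logged warning; the number dropped is attached as
#' attribute `n_dropped`.  The operation is idempotent.
#'
#' @param table a `genus_count_table`.
#' @param meta sample metadata (see [read_sample_metadata()]).
#' @return annotated `genus_count_table` restricted to samples with
#'   metadata.
#' @export
join_and_validate <- function(table, meta) {
  stopifnot(inherits(table, "genus_count_table"))
  meta <- validate_sample_metadata(meta)
  keep <- rownames(table$counts) %in% meta$sample_id
  n_dropped <- sum(!keep)
  if (n_dropped > 0L) {
    warning(sprintf("dropping %d sample(s) without metadata: %s", n_dropped,
                    paste(head(rownames(table$counts)[!keep], 5),
                          collapse = ", ")), call. = FALSE)
    mr_log("join: %d samples in, %d retained, %d dropped (no metadata)",
           length(keep), sum(keep), n_dropped)
  }
  if (!any(keep))
    stop_mr("no samples remain after joining with metadata",
            class = "empty_join_error")
  out <- genus_count_table(table$counts[keep, , drop = FALSE],
                           meta[meta$sample_id %in% rownames(table$counts), ,
                                drop = FALSE])
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Analysis configuration
#'
#' Bundles the tunable constants of the pipeline: the pseudocount added to
#' raw counts before the centred log-ratio transform, the prevalence
#' threshold below which taxa are excluded from per-taxon modelling, the
#' significance levels, and the Shannon log base.
#'
#' @param pseudocount positive number added to each count before log-ratio
#'   work (default 1).
#' @param prevalence_threshold fraction of samples in which a taxon must be
#'   detected to enter per-taxon modelling (default 0.15).
#' @param alpha per-test significance level (default 0.05).
#' @param q_threshold FDR significance level for taxon screens
#'   (default 0.05).
#' @param shannon_log_base base of the logarithm in the Shannon index
#'   (default `exp(1)`, natural log).
#' @param rng_seed integer seed recorded in the configuration.
#' @return a list of class `analysis_config`.
#' @export
analysis_config <- function(pseudocount = 1, prevalence_threshold = 0.15,
                            alpha = 0.05, q_threshold = 0.05,
                            shannon_log_base = exp(1), rng_seed = 1L) {
  check_number(pseudocount, "pseudocount", positive = TRUE)
  check_number(prevalence_threshold, "prevalence_threshold", min = 0, max = 1)
  check_number(alpha, "alpha", min = 0, max = 1)
  check_number(q_threshold, "q_threshold", min = 0, max = 1)
  check_number(shannon_log_base, "shannon_log_base", positive = TRUE)
  structure(list(pseudocount = pseudocount,
                 prevalence_threshold = prevalence_threshold,
                 alpha = alpha, q_threshold = q_threshold,
                 shannon_log_base = shannon_log_base,
                 rng_seed = as.integer(rng_seed)),
            class = "analysis_config")
}

#' @rdname analysis_config
#' @param path YAML file whose top-level keys override the defaults.
#' @export
read_analysis_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(analysis_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop_mr("unknown config key(s): ", paste(unknown, collapse = ", "),
            class = "validation_error")
  do.call(analysis_config, vals)
}
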