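## Compositional transforms, alpha-diversity, Aitchison distance,
## prevalence filtering, and PCA ordination.
##
## Two distinct pipeline paths: richness, diversity, CLR, distances and
## ordination run on the UNFILTERED table; the prevalence filter applies
## only upstream of per-taxon statistical modelling.

#' Centred log-ratio transform
#'
#' Maps each sample's pseudocounted composition into Euclidean (Aitchison)
#' geometry: `clr(x)_j = ln(x_j + p) - mean_j ln(x_j + p)`.  Rows of the
#' result sum to zero.
#'
#' @param table a `genus_count_table`, or a numeric matrix
#'   (samples x taxa).
#' @param pseudocount positive offset added to every count before taking
#'   logs; the default 1 keeps integer counts integer-valued pre-log.
#' @return numeric matrix of CLR values with the input's dimnames, class
#'   `clr_matrix`.
#' @examples
#' m <- matrix(c(8, 2), 1, dimnames = list("S1", c("gA", "gB")))
#' clr_transform(genus_count_table(m), pseudocount = 1)
#' @export
clr_transform <- function(table, pseudocount = 1) {
  check_number(pseudocount, "pseudocount", positive = TRUE)
  m <- if (inherits(table, "genus_count_table")) table$counts else table
  if (!is.matrix(m)) m <- matrix(m, nrow = 1)
  lg <- log(m + pseudocount)
  out <- lg - rowMeans(lg)
  class(out) <- c("clr_matrix", class(out))
  out
}

#' Observed richness of a count vector
#'
#' Number of taxa detected (count strictly greater than zero).
#'
#' @param counts_row numeric vector of counts for one sample.
#' @return integer richness.
#' @export
observed_richness <- function(counts_row) {
  sum(counts_row > 0)
}

#' Shannon diversity of a count vector
#'
#' `H = -sum p_j log(p_j)` over detected taxa, with `p_j` the relative
#' abundances.  Defaults to the natural log.
#'
#' @param counts_row numeric vector of counts for one sample; at least one
#'   must be positive.
#' @param log_base base of the logarithm (default `exp(1)`).
#' @return non-negative Shannon index; 0 for a single-taxon sample.
#' @export
shannon_diversity <- function(counts_row, log_base = exp(1)) {
  tot <- sum(counts_row)
  if (tot <= 0)
    stop_mr("Shannon diversity undefined for an all-zero sample",
            class = "undefined_diversity_error")
  p <- counts_row[counts_row > 0] / tot
  -sum(p * log(p, base = log_base))
}

#' Per-sample diversity table
#'
#' Computes observed genus richness and Shannon diversity for every sample
#' of an (unfiltered) count table.
#'
#' @param table a `genus_count_table`.
#' @param log_base Shannon log base.
#' @return tibble with `sample_id`, `richness`, `shannon`, plus the sample
#'   metadata columns when the table is annotated.
#' @export
diversity_table <- function(table, log_base = exp(1)) {
  stopifnot(inherits(table, "genus_count_table"))
  out <- tibble::tibble(
    sample_id = rownames(table$counts),
    richness = apply(table$counts, 1, observed_richness),
    shannon = apply(table$counts, 1, function(r)
      if (sum(r) > 0) shannon_diversity(r, log_base) else NA_real_))
  if (!is.null(table$meta))
    out <- dplyr::left_join(out, table$meta, by = "sample_id")
  out
}

#' Aitchison distance between two CLR vectors
#'
#' The Euclidean distance between centred log-ratio representations of two
#' compositions; the beta-diversity measure of the pipeline.
#'
#' @param row_a,row_b CLR-transformed numeric vectors over the same taxa in
#'   the same order (named vectors are checked for alignment).
#' @return non-negative distance; zero iff the CLR vectors coincide.
#' @export
aitchison_distance <- function(row_a, row_b) {
  if (length(row_a) != length(row_b))
    stop_mr("CLR vectors differ in length (", length(row_a), " vs ",
            length(row_b), ")", class = "alignment_error")
  if (!is.null(names(row_a)) && !is.null(names(row_b)) &&
      !identical(names(row_a), names(row_b)))
    stop_mr("CLR vectors are over different or re-ordered taxon sets",
            class = "alignment_error")
  sqrt(sum((row_a - row_b)^2))
}

#' Prevalence filter
#'
#' Retains taxa detected (count > 0) in at least `threshold` of all
#' samples; the boundary is inclusive.  Counts of retained taxa are never
#' altered and the sample set is unchanged.  Applied before per-taxon
#' modelling only, never before diversity or distance computation.
#'
#' @param table a `genus_count_table`.
#' @param threshold prevalence fraction in \[0, 1\] (default 0.15).
#' @return filtered `genus_count_table`; number of removed taxa attached as
#'   attribute `n_removed`.
#' @export
prevalence_filter <- function(table, threshold = 0.15) {
  stopifnot(inherits(table, "genus_count_table"))
  check_number(threshold, "threshold", min = 0, max = 1)
  prev <- colMeans(table$counts > 0)
  keep <- prev >= threshold
  n_removed <- sum(!keep)
  mr_log("prevalence filter at %.0f%%: %d taxa in, %d retained, %d removed",
         100 * threshold, length(keep), sum(keep), n_removed)
  if (!any(keep))
    warning("prevalence filter removed every taxon", call. = FALSE)
  out <- table
  out$counts <- table$counts[, keep, drop = FALSE]
  attr(out, "n_removed") <- n_removed
  out
}

#' PCA ordination of CLR-transformed abundances
#'
#' Principal component analysis of the column-centred CLR matrix without
#' unit-variance scaling, the standard ordination for Aitchison geometry.
#'
#' @param clr a `clr_matrix` (samples x taxa).
#' @param n_components number of components to return (default
#'   `min(dim) - ` as permitted by the data).
#' @return list of class `ordination_result` with `sample_ids`, `scores`
#'   (samples x components), and `explained_variance_fraction`
#'   (non-increasing, each in \[0, 1\]).
#' @export
pca_ordination <- function(clr, n_components = 2) {
  m <- unclass(clr)
  if (nrow(m) < 2)
    stop_mr("ordination needs at least 2 samples", class = "parameter_error")
  if (n_components > nrow(m))
    stop_mr("cannot extract ", n_components, " components from ", nrow(m),
            " samples", class = "parameter_error")
  pc <- prcomp(m, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  tot <- sum(pc$sdev^2)
  expl <- if (tot > 0) pc$sdev[seq_len(k)]^2 / tot else rep(0, k)
  structure(list(sample_ids = rownames(m),
                 scores = pc$x[, seq_len(k), drop = FALSE],
                 explained_variance_fraction = expl,
                 rotation = pc$rotation[, seq_len(k), drop = FALSE],
                 center = pc$center),
            class = "ordination_result")
}

#' Log2 abundance matrix for visualization
#'
#' Elementwise `log2(count + pseudocount)`; used for display of genus
#' abundances, not for distance or model computation.
#'
#' @inheritParams clr_transform
#' @return numeric matrix.
#' @export
log2_abundance <- function(table, pseudocount = 1) {
  check_number(pseudocount, "pseudocount", positive = TRUE)
  m <- if (inherits(table, "genus_count_table")) table$counts else table
  log2(m + pseudocount)
}
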