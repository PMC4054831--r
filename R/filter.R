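#' Filter probes by detection P-value and chromosome
#'
#' Retains CpGs whose detection P-value is below `detection_threshold` in
#' every sample (the complete-case convention for array QC) and whose
#' chromosome is not in `drop_chromosomes` (e.g. `"Y"` in an all-female
#' cohort). Counts removed per criterion are attached as the
#' `"filter_counts"` attribute and reported via `message()`.
#'
#' @param x a [beta_matrix()] object.
#' @param detection_threshold keep a CpG only if detection P <
#'   `detection_threshold` in all samples; `NULL` skips the detection
#'   filter. Requires detection P-values to be present.
#' @param drop_chromosomes character vector of chromosome labels to drop
#'   (requires annotation); default none.
#' @return the filtered `BetaMatrix`, with attribute `filter_counts`
#'   (named vector: `input`, `removed_detection`, `removed_chromosome`,
#'   `kept`).
#' @export
filter_probes <- function(x, detection_threshold = NULL,
                          drop_chromosomes = character()) {
  stopifnot(inherits(x, "BetaMatrix"))
  n_in <- nrow(x$beta)
  keep_det <- rep(TRUE, n_in)
  if (!is.null(detection_threshold)) {
    stop_if(is.null(x$detp),
            "detection threshold given but matrix has no detection P-values")
    check_fraction(detection_threshold, "detection_threshold")
    keep_det <- apply(x$detp < detection_threshold, 1, all)
    keep_det[is.na(keep_det)] <- FALSE
  }
  keep_chr <- rep(TRUE, n_in)
  if (length(drop_chromosomes) > 0) {
    stop_if(is.null(x$anno), "chromosome filter requires annotation")
    keep_chr <- !(x$anno$chrom %in% drop_chromosomes)
  }
  counts <- c(input = n_in,
              removed_detection = sum(!keep_det),
              removed_chromosome = sum(keep_det & !keep_chr),
              kept = sum(keep_det & keep_chr))
  out <- subset_beta(x, cpgs = which(keep_det & keep_chr))
  message(sprintf("filter_probes: %d CpGs in, %d removed by detection P, %d by chromosome, %d kept",
                  counts["input"], counts["removed_detection"],
                  counts["removed_chromosome"], counts["kept"]))
  attr(out, "filter_counts") <- counts
  out
}

#' Restrict a BetaMatrix and a ReferencePanel to their common CpGs
#'
#' Arrays of different generations share only part of their probe
#' complement with reference panels; both objects are restricted to the
#' intersection and aligned in the same CpG order.
#'
#' @param x a [beta_matrix()] object.
#' @param panel a [reference_panel()] object.
#' @return a list with elements `matrix` and `panel`, both restricted to
#'   the common CpG set in matching order.
#' @export
intersect_with_panel <- function(x, panel) {
  stopifnot(inherits(x, "BetaMatrix"), inherits(panel, "ReferencePanel"))
  common <- intersect(rownames(x$beta), rownames(panel$means))
  stop_if(length(common) == 0, "matrix and panel share no CpGs")
  list(matrix = subset_beta(x, cpgs = common),
       panel = reference_panel(panel$means[common, , drop = FALSE]))
}

#' Pairwise array-wide Pearson correlations between samples
#'
#' Computes the symmetric matrix of pairwise Pearson correlation
#' coefficients across all CpGs for each pair of samples, the exploratory
#' statistic used to spot samples with deviating genome-wide profiles
#' (e.g. a shifted cell-type composition). Missing beta values are
#' excluded pairwise.
#'
#' @param x a [beta_matrix()] object with at least 2 samples and 2 CpGs.
#' @return symmetric numeric matrix (samples x samples) with unit
#'   diagonal; a pair involving a zero-variance sample gets `NA` with a
#'   warning.
#' @export
sample_correlation_matrix <- function(x) {
  stopifnot(inherits(x, "BetaMatrix"))
  stop_if(ncol(x$beta) < 2, "need at least 2 samples")
  stop_if(nrow(x$beta) < 2, "need at least 2 CpGs")
  r <- suppressWarnings(stats::cor(x$beta, use = "pairwise.complete.obs"))
  diag(r) <- 1
  if (anyNA(r)) {
    warning("correlation undefined for some sample pair(s) (zero variance); reported as NA")
  }
  r
}
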