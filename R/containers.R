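#' Beta-value matrix container
#'
#' A `BetaMatrix` holds DNA methylation beta values (the fraction of
#' methylated cytosines at a CpG site, in \[0, 1\]) for a set of CpGs
#' (rows) measured in a set of samples (columns), with optional per-probe
#' detection P-values of identical shape and optional CpG annotation
#' (chromosome, 1-based position, gene symbol).
#'
#' @param beta numeric matrix of beta values, CpGs in rows (unique
#'   rownames), samples in columns (unique colnames). `NA` marks a missing
#'   measurement; all non-missing values must lie in \[0, 1\].
#' @param detp optional numeric matrix of detection P-values, same
#'   dimensions and dimnames as `beta`.
#' @param anno optional `data.frame` with one row per CpG (rownames =
#'   CpG ids) and columns `chrom` (character, e.g. `"1"`, `"X"`, `"Y"`),
#'   `pos` (1-based integer) and optionally `gene`.
#'
#' @return an object of class `BetaMatrix`: a list with elements `beta`,
#'   `detp` and `anno`.
#' @export
#' @examples
#' b <- matrix(c(0.1, 0.9, 0.5, 0.4), 2, 2,
#'             dimnames = list(c("cg1", "cg2"), c("s1", "s2")))
#' bm <- beta_matrix(b)
#' dim(bm)
beta_matrix <- function(beta, detp = NULL, anno = NULL) {
  stop_if(!is.matrix(beta) || !is.numeric(beta), "'beta' must be a numeric matrix")
  cpgs <- rownames(beta)
  samples <- colnames(beta)
  stop_if(is.null(cpgs) || is.null(samples),
          "'beta' must have rownames (CpG ids) and colnames (sample ids)")
  stop_if(anyDuplicated(cpgs) > 0,
          sprintf("duplicate CpG identifier: '%s'", cpgs[anyDuplicated(cpgs)]))
  stop_if(anyDuplicated(samples) > 0,
          sprintf("duplicate sample identifier: '%s'", samples[anyDuplicated(samples)]))
  bad <- which(!is.na(beta) & (!is.finite(beta) | beta < 0 | beta > 1),
               arr.ind = TRUE)
  stop_if(nrow(bad) > 0,
          sprintf("beta value out of [0, 1] at CpG '%s', sample '%s' (value %g)",
                  cpgs[bad[1, 1]], samples[bad[1, 2]],
                  beta[bad[1, 1], bad[1, 2]]))
  if (!is.null(detp)) {
    stop_if(!is.matrix(detp) || !identical(dim(detp), dim(beta)),
            "'detp' must be a numeric matrix with the same shape as 'beta'")
    dimnames(detp) <- dimnames(beta)
    badp <- which(!is.na(detp) & (detp < 0 | detp > 1), arr.ind = TRUE)
    stop_if(nrow(badp) > 0,
            sprintf("detection P out of [0, 1] at CpG '%s', sample '%s'",
                    cpgs[badp[1, 1]], samples[badp[1, 2]]))
  }
  if (!is.null(anno)) {
    stop_if(!is.data.frame(anno), "'anno' must be a data.frame")
    stop_if(!all(c("chrom", "pos") %in% names(anno)),
            "'anno' needs columns 'chrom' and 'pos'")
    stop_if(!all(cpgs %in% rownames(anno)),
            "every CpG in 'beta' needs a row in 'anno'")
    anno <- anno[cpgs, , drop = FALSE]
    anno$chrom <- as.character(anno$chrom)
  }
  structure(list(beta = beta, detp = detp, anno = anno), class = "BetaMatrix")
}

#' @export
dim.BetaMatrix <- function(x) dim(x$beta)

#' @export
dimnames.BetaMatrix <- function(x) dimnames(x$beta)

#' @export
print.BetaMatrix <- function(x, ...) {
  cat(sprintf("BetaMatrix: %d CpGs x %d samples%s%s\n",
              nrow(x$beta), ncol(x$beta),
              if (!is.null(x$detp)) ", with detection P" else "",
              if (!is.null(x$anno)) ", annotated" else ""))
  invisible(x)
}

#' Subset a BetaMatrix by CpGs and/or samples
#'
#' @param x a [beta_matrix()] object.
#' @param cpgs,samples character vectors of identifiers (or logical/integer
#'   indices) to keep; `NULL` keeps all.
#' @return a `BetaMatrix` restricted to the requested rows/columns.
#' @export
subset_beta <- function(x, cpgs = NULL, samples = NULL) {
  stopifnot(inherits(x, "BetaMatrix"))
  if (is.null(cpgs)) cpgs <- rownames(x$beta)
  if (is.null(samples)) samples <- colnames(x$beta)
  beta_matrix(x$beta[cpgs, samples, drop = FALSE],
              detp = if (!is.null(x$detp)) x$detp[cpgs, samples, drop = FALSE],
              anno = if (!is.null(x$anno)) x$anno[cpgs, , drop = FALSE])
}

#' Cell-type reference panel
#'
#' Mean beta value per CpG per cell type, e.g. averaged whole-blood and
#' buccal epithelium profiles. Used to screen for discriminatively
#' methylated marker CpGs and to estimate mixture proportions.
#'
#' @param means numeric matrix, CpGs in rows (unique rownames), cell types
#'   in columns (unique colnames); all values in \[0, 1\], no missing values.
#' @return an object of class `ReferencePanel` wrapping `means`.
#' @export
reference_panel <- function(means) {
  stop_if(!is.matrix(means) || !is.numeric(means),
          "'means' must be a numeric matrix")
  stop_if(is.null(rownames(means)) || is.null(colnames(means)),
          "'means' must have CpG rownames and cell-type colnames")
  stop_if(anyDuplicated(rownames(means)) > 0, "duplicate CpG in panel")
  stop_if(anyDuplicated(colnames(means)) > 0, "duplicate cell type in panel")
  stop_if(anyNA(means), "reference panel must have a value for every CpG and cell type")
  check_fraction(means, "panel means")
  structure(list(means = means), class = "ReferencePanel")
}

#' @export
print.ReferencePanel <- function(x, ...) {
  cat(sprintf("ReferencePanel: %d CpGs x cell types {%s}\n",
              nrow(x$means), paste(colnames(x$means), collapse = ", ")))
  invisible(x)
}

#' Twin-pair design table
#'
#' Records which sample is the heavier-born and which the lighter-born
#' member of each monozygotic pair.
#'
#' @param pair_id character vector of unique pair identifiers.
#' @param heavy,light sample identifiers of the heavier / lighter co-twin;
#'   each sample may appear in exactly one pair and `heavy != light`.
#' @return a `data.frame` of class `TwinDesign` with columns `pair_id`,
#'   `heavy`, `light`.
#' @export
twin_design <- function(pair_id, heavy, light) {
  stop_if(length(pair_id) != length(heavy) || length(heavy) != length(light),
          "'pair_id', 'heavy' and 'light' must have equal length")
  stop_if(anyDuplicated(pair_id) > 0, "duplicate pair_id")
  stop_if(any(heavy == light), "heavy and light member must differ within a pair")
  all_samples <- c(heavy, light)
  stop_if(anyDuplicated(all_samples) > 0,
          sprintf("sample '%s' appears in more than one design slot",
                  all_samples[anyDuplicated(all_samples)]))
  structure(data.frame(pair_id = as.character(pair_id),
                       heavy = as.character(heavy),
                       light = as.character(light),
                       stringsAsFactors = FALSE),
            class = c("TwinDesign", "data.frame"))
}

design_samples <- function(design) c(design$heavy, design$light)
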