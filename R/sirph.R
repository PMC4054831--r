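# Methylation-index quantification from SNuPE primer-extension peak
# areas (SIRPH assays) and its paired association analysis for
# repetitive elements, with optional marker-based composition adjustment
# through the same code path as the array data.

#' SIRPH assay container
#'
#' Raw peak areas of the C-extended (methylated) and T-extended
#' (unmethylated) primer per element CpG and sample; methylation indices
#' are computed from the areas on demand so the MI formula is always
#' exercised.
#'
#' @param df data.frame with columns `element`, `cpg_index`,
#'   `sample_id`, `area_c`, `area_t` (areas >= 0).
#' @return the validated data.frame with class `SirphAssay`.
#' @export
sirph_assay <- function(df) {
  stop_if(!is.data.frame(df), "'df' must be a data.frame")
  need <- c("element", "cpg_index", "sample_id", "area_c", "area_t")
  stop_if(!all(need %in% names(df)),
          sprintf("missing column(s): %s",
                  paste(setdiff(need, names(df)), collapse = ", ")))
  stop_if(any(df$area_c < 0) || any(df$area_t < 0), "peak areas must be >= 0")
  structure(df, class = c("SirphAssay", "data.frame"))
}

#' Read / write SIRPH peak areas as tab-separated text
#'
#' @param x a [sirph_assay()].
#' @param path file path.
#' @return `path` invisibly, or the assay table read back.
#' @export
write_sirph_tsv <- function(x, path) {
  stopifnot(inherits(x, "SirphAssay"))
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_sirph_tsv
#' @export
read_sirph_tsv <- function(path) {
  stop_if(!file.exists(path), sprintf("file not found: '%s'", path))
  sirph_assay(utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE))
}

#' Methylation index from primer-extension peak areas
#'
#' `MI = AC / (AC + AT)`, where AC and AT are the areas under the peaks
#' of the ddCTP- and ddTTP-extended primer. The MI is the primer-
#' extension analogue of an array beta value and is scale-invariant in
#' the areas.
#'
#' @param area_c,area_t nonnegative peak areas (vectorized); their sum
#'   must be positive.
#' @return MI fraction(s) in \[0, 1\].
#' @export
#' @examples
#' methylation_index(3, 7)  # 0.3
methylation_index <- function(area_c, area_t) {
  stop_if(any(area_c < 0) || any(area_t < 0), "peak areas must be >= 0")
  stop_if(any(area_c + area_t == 0),
          "MI undefined: both peak areas are zero")
  area_c / (area_c + area_t)
}

# MI matrix (element.cpg rows x samples) from an assay table
sirph_mi_matrix <- function(assays) {
  stopifnot(inherits(assays, "SirphAssay"))
  key <- paste(assays$element, assays$cpg_index, sep = ".")
  mi <- methylation_index(assays$area_c, assays$area_t)
  rows <- unique(key)
  cols <- unique(assays$sample_id)
  m <- matrix(NA_real_, length(rows), length(cols),
              dimnames = list(rows, cols))
  m[cbind(match(key, rows), match(assays$sample_id, cols))] <- mi
  m
}

#' Paired association analysis of SIRPH methylation indices
#'
#' For every element CpG: group means among heavy and light co-twins,
#' mean heavy - light MI difference, and the two-sided exact Wilcoxon
#' signed-rank P-value. When per-sample marker values (the buccal-
#' epithelium marker CpG betas) are supplied, MIs are first residual-
#' adjusted for composition through exactly the same
#' [fit_marker_models()] / [adjust_for_composition()] path as the array
#' data.
#'
#' @param assays a [sirph_assay()] table covering every design sample.
#' @param design a [twin_design()].
#' @param marker_values optional named numeric vector of marker beta
#'   values per sample.
#' @param affected_p regression-P threshold of the adjustment rule
#'   (default 0.01, as for arrays).
#' @param mode Wilcoxon mode, see [wilcoxon_signed_rank_paired()].
#' @return data.frame with columns `element`, `cpg_index`,
#'   `mean_heavy`, `mean_light`, `mean_diff`, `p.value`, `adjusted`.
#' @export
sirph_association <- function(assays, design, marker_values = NULL,
                              affected_p = 0.01, mode = "exact") {
  stopifnot(inherits(assays, "SirphAssay"), inherits(design, "TwinDesign"))
  m <- sirph_mi_matrix(assays)
  needed <- design_samples(design)
  missing <- needed[!needed %in% colnames(m)]
  stop_if(length(missing) > 0,
          sprintf("no MI for sample '%s'", missing[1]))
  bad <- which(is.na(m[, needed, drop = FALSE]), arr.ind = TRUE)
  stop_if(nrow(bad) > 0,
          sprintf("missing MI for sample '%s' at '%s'",
                  needed[bad[1, 2]], rownames(m)[bad[1, 1]]))
  m <- m[, needed, drop = FALSE]
  adjusted_rows <- rep(FALSE, nrow(m))
  if (!is.null(marker_values)) {
    stop_if(!all(needed %in% names(marker_values)),
            "marker_values missing for some design samples")
    full <- rbind(m, .marker. = marker_values[needed])
    bm <- beta_matrix(full)
    fit <- fit_marker_models(bm, ".marker.", affected_p = affected_p)
    adj <- adjust_for_composition(bm, fit)
    m <- adj$beta$beta[rownames(m), , drop = FALSE]
    adjusted_rows <- unname(adj$adjusted[rownames(m)])
  }
  H <- m[, design$heavy, drop = FALSE]
  L <- m[, design$light, drop = FALSE]
  res <- do.call(rbind, lapply(seq_len(nrow(m)), function(i) {
    wt <- suppressWarnings(
      wilcoxon_signed_rank_paired(H[i, ], L[i, ], mode = mode))
    data.frame(mean_heavy = mean(H[i, ]), mean_light = mean(L[i, ]),
               mean_diff = mean_difference(H[i, ], L[i, ]),
               p.value = wt$p.value)
  }))
  key <- do.call(rbind, strsplit(rownames(m), "\\.(?=[^.]+$)", perl = TRUE))
  out <- data.frame(element = key[, 1], cpg_index = as.integer(key[, 2]),
                    res, adjusted = adjusted_rows,
                    row.names = NULL, stringsAsFactors = FALSE)
  out
}
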