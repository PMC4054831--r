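# Tabular IO. The beta-matrix dialect mirrors a GenomeStudio-style export:
# one header line, tab separated, CpG ids in the first column ("cpg_id"),
# optional annotation columns (chrom, pos, gene), one column per sample,
# and optional detection-P columns named "<sample>.detP".

ANNO_COLS <- c("chrom", "pos", "gene")

#' Write a BetaMatrix to tab-separated text
#'
#' @param x a [beta_matrix()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_beta_tsv <- function(x, path) {
  stopifnot(inherits(x, "BetaMatrix"))
  df <- data.frame(cpg_id = rownames(x$beta), stringsAsFactors = FALSE)
  if (!is.null(x$anno)) {
    for (col in intersect(ANNO_COLS, names(x$anno))) df[[col]] <- x$anno[[col]]
  }
  for (s in colnames(x$beta)) df[[s]] <- x$beta[, s]
  if (!is.null(x$detp)) {
    for (s in colnames(x$beta)) df[[paste0(s, ".detP")]] <- x$detp[, s]
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Read a BetaMatrix from tab-separated text
#'
#' Expects the dialect written by [write_beta_tsv()]: first column
#' `cpg_id`, optional `chrom`/`pos`/`gene` annotation columns, sample
#' columns, and optional `<sample>.detP` detection-P columns. Invariant
#' violations (values outside \[0, 1\], duplicate identifiers) are rejected
#' with an error naming the offending row/column, never clamped.
#'
#' @param path file to read.
#' @return a [beta_matrix()] object.
#' @export
read_beta_tsv <- function(path) {
  stop_if(!file.exists(path), sprintf("file not found: '%s'", path))
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE)
  stop_if(names(df)[1] != "cpg_id", "first column must be 'cpg_id'")
  cpgs <- as.character(df$cpg_id)
  anno_cols <- intersect(ANNO_COLS, names(df))
  detp_cols <- grep("\\.detP$", names(df), value = TRUE)
  sample_cols <- setdiff(names(df), c("cpg_id", anno_cols, detp_cols))
  stop_if(length(sample_cols) == 0, "no sample columns found")
  beta <- as.matrix(df[, sample_cols, drop = FALSE])
  storage.mode(beta) <- "double"
  rownames(beta) <- cpgs
  detp <- NULL
  if (length(detp_cols) > 0) {
    stop_if(!setequal(sub("\\.detP$", "", detp_cols), sample_cols),
            "detection-P columns must match sample columns one-to-one")
    detp <- as.matrix(df[, paste0(sample_cols, ".detP"), drop = FALSE])
    storage.mode(detp) <- "double"
    dimnames(detp) <- list(cpgs, sample_cols)
  }
  anno <- NULL
  if (length(anno_cols) > 0) {
    anno <- df[, anno_cols, drop = FALSE]
    if (!"pos" %in% names(anno)) anno$pos <- NA_integer_
    if (!"chrom" %in% names(anno)) anno$chrom <- NA_character_
    rownames(anno) <- cpgs
  }
  beta_matrix(beta, detp = detp, anno = anno)
}

#' Write / read a ReferencePanel as tab-separated text
#'
#' Columns: `cpg_id`, then one mean-beta column per cell type.
#'
#' @param x a [reference_panel()] object.
#' @param path file path.
#' @return `path` invisibly, or the panel read back.
#' @export
write_panel_tsv <- function(x, path) {
  stopifnot(inherits(x, "ReferencePanel"))
  df <- data.frame(cpg_id = rownames(x$means), x$means, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_panel_tsv
#' @export
read_panel_tsv <- function(path) {
  stop_if(!file.exists(path), sprintf("file not found: '%s'", path))
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE)
  stop_if(names(df)[1] != "cpg_id", "first column must be 'cpg_id'")
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df$cpg_id
  reference_panel(m)
}

#' Write / read a TwinDesign as tab-separated text
#'
#' Columns: `pair_id`, `heavy`, `light` (one row per twin pair).
#'
#' @param x a [twin_design()] object.
#' @param path file path.
#' @return `path` invisibly, or the design read back.
#' @export
write_design_tsv <- function(x, path) {
  stopifnot(inherits(x, "TwinDesign"))
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_design_tsv
#' @export
read_design_tsv <- function(path) {
  stop_if(!file.exists(path), sprintf("file not found: '%s'", path))
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  stop_if(!all(c("pair_id", "heavy", "light") %in% names(df)),
          "design file needs columns pair_id, heavy, light")
  twin_design(df$pair_id, df$heavy, df$light)
}

#' Export CpG coordinates as BED
#'
#' Writes the annotated CpG positions of a BetaMatrix as a 0-based,
#' half-open BED file (chrom, pos-1, pos, cpg_id).
#'
#' @param x an annotated [beta_matrix()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
export_bed <- function(x, path) {
  stopifnot(inherits(x, "BetaMatrix"))
  stop_if(is.null(x$anno), "BetaMatrix carries no annotation")
  bed <- data.frame(chrom = x$anno$chrom,
                    start = x$anno$pos - 1L,
                    end = x$anno$pos,
                    name = rownames(x$beta))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
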