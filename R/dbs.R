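# Read-level bisulfite amplicon analysis used to validate array MVPs:
# quality filtering, per-CpG methylation fractions, cross-platform
# concordance, and SNP allele balance as a technical-noise floor.

#' Amplicon read set container
#'
#' One row per sequenced read. Calls over the amplicon's CpGs are encoded
#' as a string of `'1'` (methylated), `'0'` (unmethylated) and `'.'`
#' (missing); all reads of an amplicon must have the same call length.
#'
#' @param df data.frame with columns `amplicon_id`, `sample_id`,
#'   `read_id`, `calls` (call string), `conversion` (per-read bisulfite
#'   conversion-rate estimate in \[0, 1\]), and optionally `allele`
#'   (allele label at an amplicon SNP, `NA` when absent).
#' @return the validated data.frame with class `AmpliconReadSet`.
#' @export
amplicon_read_set <- function(df) {
  stop_if(!is.data.frame(df), "'df' must be a data.frame")
  need <- c("amplicon_id", "sample_id", "read_id", "calls", "conversion")
  stop_if(!all(need %in% names(df)),
          sprintf("missing column(s): %s",
                  paste(setdiff(need, names(df)), collapse = ", ")))
  if (!"allele" %in% names(df)) df$allele <- NA_character_
  stop_if(anyDuplicated(df$read_id) > 0, "duplicate read_id")
  check_fraction(df$conversion, "conversion", allow_na = FALSE)
  stop_if(any(grepl("[^01.]", df$calls)),
          "call strings may only contain '1', '0' and '.'")
  len_by_amp <- tapply(nchar(df$calls), df$amplicon_id,
                       function(z) length(unique(z)))
  stop_if(any(len_by_amp > 1),
          "all reads of an amplicon must have the same number of CpG calls")
  structure(df, class = c("AmpliconReadSet", "data.frame"))
}

#' Read / write amplicon read calls as tab-separated text
#'
#' One row per read: `amplicon_id`, `sample_id`, `read_id`, `calls`,
#' `conversion`, `allele` (empty when absent).
#'
#' @param x an [amplicon_read_set()].
#' @param path file path.
#' @return `path` invisibly, or the read set read back.
#' @export
write_reads_tsv <- function(x, path) {
  stopifnot(inherits(x, "AmpliconReadSet"))
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_reads_tsv
#' @export
read_reads_tsv <- function(path) {
  stop_if(!file.exists(path), sprintf("file not found: '%s'", path))
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          colClasses = c(calls = "character"))
  df$allele[!is.na(df$allele) & df$allele == ""] <- NA_character_
  amplicon_read_set(df)
}

#' Filter low-quality amplicon reads
#'
#' Retains reads whose per-read conversion-rate estimate is at least
#' `min_conversion` and whose fraction of missing calls is at most
#' `max_missing_fraction`. Counts removed per criterion are attached as
#' the `"filter_report"` attribute.
#'
#' @param reads an [amplicon_read_set()].
#' @param min_conversion minimum conversion rate (default 0.95).
#' @param max_missing_fraction maximum fraction of `'.'` calls per read
#'   (default 0.2).
#' @return the filtered `AmpliconReadSet` with attribute `filter_report`
#'   (named vector: `input`, `low_conversion`, `high_missing`, `kept`).
#' @export
filter_reads <- function(reads, min_conversion = 0.95,
                         max_missing_fraction = 0.2) {
  stopifnot(inherits(reads, "AmpliconReadSet"))
  check_fraction(min_conversion, "min_conversion")
  check_fraction(max_missing_fraction, "max_missing_fraction")
  n_calls <- nchar(reads$calls)
  n_miss <- n_calls - nchar(gsub(".", "", reads$calls, fixed = TRUE))
  fail_conv <- reads$conversion < min_conversion
  fail_miss <- n_miss / n_calls > max_missing_fraction
  keep <- !fail_conv & !fail_miss
  out <- amplicon_read_set(as.data.frame(reads)[keep, , drop = FALSE])
  attr(out, "filter_report") <- c(input = nrow(reads),
                                  low_conversion = sum(fail_conv),
                                  high_missing = sum(fail_miss),
                                  kept = sum(keep))
  out
}

#' Per-CpG methylation fractions from read calls
#'
#' For every amplicon/sample/CpG, the methylation fraction is the number
#' of methylated calls divided by the number of non-missing calls
#' (coverage). CpGs with zero non-missing calls get `NA` and are flagged.
#'
#' @param reads an [amplicon_read_set()] (usually after
#'   [filter_reads()]).
#' @return data.frame with columns `amplicon_id`, `sample_id`,
#'   `cpg_index`, `beta`, `coverage`, `undefined`.
#' @export
amplicon_methylation <- function(reads) {
  stopifnot(inherits(reads, "AmpliconReadSet"))
  stop_if(nrow(reads) < 1, "no reads")
  groups <- split(seq_len(nrow(reads)),
                  list(reads$amplicon_id, reads$sample_id), drop = TRUE)
  out <- lapply(groups, function(idx) {
    mat <- do.call(rbind, strsplit(reads$calls[idx], ""))
    meth <- colSums(mat == "1")
    cov <- colSums(mat != ".")
    data.frame(amplicon_id = reads$amplicon_id[idx[1]],
               sample_id = reads$sample_id[idx[1]],
               cpg_index = seq_along(meth),
               beta = ifelse(cov > 0, meth / cov, NA_real_),
               coverage = cov, undefined = cov == 0,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$amplicon_id, res$sample_id, res$cpg_index), ]
}

#' Cross-platform concordance between array and bisulfite-sequencing data
#'
#' Pearson correlation between array beta values and sequencing-derived
#' methylation fractions, computed per sample (across validated CpGs) or
#' per CpG (across samples), plus the median correlation over items.
#'
#' @param array_values,dbs_values numeric matrices (CpGs x samples) with
#'   matching dimnames.
#' @param axis `"per_sample"` (correlate columns) or `"per_cpg"`
#'   (correlate rows).
#' @return list with `table` (data.frame: `item`, `r`, `n`, `undefined`)
#'   and `median_r` (median over defined items).
#' @export
cross_platform_concordance <- function(array_values, dbs_values,
                                       axis = c("per_sample", "per_cpg")) {
  axis <- match.arg(axis)
  stop_if(!is.matrix(array_values) || !is.matrix(dbs_values),
          "inputs must be matrices (CpGs x samples)")
  stop_if(!identical(dim(array_values), dim(dbs_values)),
          "matrices must have identical shape")
  if (axis == "per_cpg") {
    array_values <- t(array_values)
    dbs_values <- t(dbs_values)
  }
  items <- colnames(array_values) %||% as.character(seq_len(ncol(array_values)))
  tab <- do.call(rbind, lapply(seq_len(ncol(array_values)), function(j) {
    a <- array_values[, j]
    b <- dbs_values[, j]
    ok <- !is.na(a) & !is.na(b)
    r <- if (sum(ok) >= 3 && stats::sd(a[ok]) > 0 && stats::sd(b[ok]) > 0) {
      stats::cor(a[ok], b[ok])
    } else NA_real_
    data.frame(item = items[j], r = r, n = sum(ok), undefined = is.na(r),
               stringsAsFactors = FALSE)
  }))
  if (any(tab$undefined))
    warning("correlation undefined for some item(s) (zero variance or < 3 pairs)")
  list(table = tab, median_r = stats::median(tab$r, na.rm = TRUE))
}

#' SNP allele balance and intra-pair allele-frequency noise
#'
#' In amplicons carrying a heterozygous SNP the two alleles are expected
#' at a 0.5/0.5 ratio in every read set; the mean absolute within-pair
#' difference of observed allele fractions therefore estimates the
#' technical noise floor of the assay (PCR/sampling bias), against which
#' candidate methylation differences can be judged.
#'
#' @param reads an [amplicon_read_set()] whose reads carry allele calls.
#' @param ref_allele allele counted in the numerator; default the
#'   lexicographically first allele observed.
#' @return named numeric vector: fraction of reads carrying `ref_allele`
#'   per sample.
#' @export
snp_allele_balance <- function(reads, ref_allele = NULL) {
  stopifnot(inherits(reads, "AmpliconReadSet"))
  has <- !is.na(reads$allele)
  stop_if(!any(has), "reads carry no allele calls")
  alleles <- sort(unique(reads$allele[has]))
  if (is.null(ref_allele)) ref_allele <- alleles[1]
  stop_if(!ref_allele %in% alleles,
          sprintf("allele '%s' not observed", ref_allele))
  df <- reads[has, ]
  tapply(df$allele == ref_allele, df$sample_id, mean)[unique(df$sample_id)]
}

#' @rdname snp_allele_balance
#' @param design a [twin_design()].
#' @param fractions named per-sample allele fractions (from
#'   [snp_allele_balance()]).
#' @return `paired_allele_noise()`: the mean absolute within-pair
#'   difference of allele fractions.
#' @export
paired_allele_noise <- function(design, fractions) {
  stopifnot(inherits(design, "TwinDesign"))
  stop_if(!all(design_samples(design) %in% names(fractions)),
          "fractions missing for some design samples")
  mean(abs(fractions[design$heavy] - fractions[design$light]))
}
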