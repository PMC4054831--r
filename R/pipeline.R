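# End-to-end study orchestration over synthetic (or user-supplied) data:
# simulate -> write/load -> filter -> screen/select marker -> adjust
# (single- and multi-marker) -> paired association on both -> MVP
# intersection -> DBS validation of called MVPs -> SIRPH stage ->
# summary report. Every stage writes its intermediates and counts.

#' Build a pipeline configuration
#'
#' Returns the default configuration list for [run_study()], optionally
#' overridden field by field. All stochastic steps derive their seeds
#' from the single top-level `seed`.
#'
#' @param ... named overrides of the defaults (nested lists are replaced
#'   wholesale).
#' @return a list of class `PipelineConfig`.
#' @export
study_config <- function(...) {
  cfg <- list(
    seed = 1L,
    simulation = list(n_cpgs = 2000L, n_discriminative = 25L,
                      separation = 0.6, n_pairs = 17L,
                      proportion_sampler = list(min = 0.1, max = 0.9,
                                                pair_correlation = 0.3),
                      effects = NULL, noise_sd = 0.02),
    filter = list(detection_p = 0.001, drop_chromosomes = "Y"),
    adjust = list(k = 10L, affected_p = 0.01, n_mad = 3,
                  n_multi_markers = 3L),
    association = list(p_threshold = 0.01, d_threshold = 0.05,
                       mode = "auto"),
    dbs = list(n_validate = 8L, n_reads = 400L, conversion_rate = 0.992,
               min_conversion = 0.95, max_missing_fraction = 0.2),
    sirph = list(total_area = 1000, noise_sd = 10),
    out_dir = NULL)
  override <- list(...)
  for (nm in names(override)) {
    if (is.list(override[[nm]]) && is.list(cfg[[nm]])) {
      for (k in names(override[[nm]])) cfg[[nm]][[k]] <- override[[nm]][[k]]
    } else {
      cfg[[nm]] <- override[[nm]]
    }
  }
  stop_if(is.null(cfg$seed), "a seed is mandatory")
  structure(cfg, class = c("PipelineConfig", "list"))
}

log_stage <- function(log_path, fmt, ...) {
  line <- sprintf(fmt, ...)
  message(line)
  if (!is.null(log_path)) cat(line, "\n", file = log_path, append = TRUE, sep = "")
}

#' Run the full study pipeline on synthetic data
#'
#' Executes the complete analysis sequence on data drawn from the
#' synthetic two-cell-type mixture model: cohort simulation, TSV
#' round-trip, probe filtering, marker screening and selection, outlier
#' exclusion, single- and multi-marker composition adjustment, paired
#' Wilcoxon association on both adjusted variants, MVP intersection
#' calling, deep-bisulfite-sequencing validation of called MVPs
#' (concordance and paired re-testing), and a SIRPH repetitive-element
#' stage. All intermediates, the resolved configuration and a stage log
#' are written to the output directory.
#'
#' @param config a [study_config()] list.
#' @param out_dir output directory (created if needed); overrides
#'   `config$out_dir`; `NULL` uses a temporary directory.
#' @return the report list (also serialized as `report.json`), with
#'   stage counts, marker choice, MVP counts before/after adjustment,
#'   and validation summaries.
#' @export
run_study <- function(config = study_config(), out_dir = config$out_dir) {
  stopifnot(inherits(config, "PipelineConfig"))
  if (is.null(out_dir)) out_dir <- tempfile("salivamix_run_")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  cat(sprintf("salivamix run, seed %d\n", config$seed), file = log_path)
  jsonlite::write_json(unclass(config), file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  seed <- as.integer(config$seed)

  # --- simulate -----------------------------------------------------------
  sim_cfg <- config$simulation
  pan <- simulate_reference_panel(sim_cfg$n_cpgs, sim_cfg$n_discriminative,
                                  sim_cfg$separation, seed = seed)
  coh <- simulate_cohort(pan$panel, sim_cfg$n_pairs,
                         proportion_sampler = sim_cfg$proportion_sampler,
                         effect_spec = sim_cfg$effects,
                         noise_sd = sim_cfg$noise_sd, seed = seed + 1L)
  write_panel_tsv(pan$panel, file.path(out_dir, "panel.tsv"))
  write_beta_tsv(coh$beta, file.path(out_dir, "beta_raw.tsv"))
  write_design_tsv(coh$design, file.path(out_dir, "design.tsv"))
  jsonlite::write_json(list(discriminative = pan$truth$discriminative,
                            proportion = as.list(coh$truth$proportion),
                            seed = seed),
                       file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  log_stage(log_path, "simulate: %d CpGs (%d discriminative), %d pairs",
            sim_cfg$n_cpgs, sim_cfg$n_discriminative, sim_cfg$n_pairs)

  # --- load + filter ------------------------------------------------------
  beta <- read_beta_tsv(file.path(out_dir, "beta_raw.tsv"))
  design <- read_design_tsv(file.path(out_dir, "design.tsv"))
  panel <- read_panel_tsv(file.path(out_dir, "panel.tsv"))
  filtered <- suppressMessages(
    filter_probes(beta, detection_threshold = config$filter$detection_p,
                  drop_chromosomes = config$filter$drop_chromosomes))
  fc <- attr(filtered, "filter_counts")
  log_stage(log_path,
            "filter: %d in, %d removed by detection P, %d by chromosome, %d kept",
            fc["input"], fc["removed_detection"], fc["removed_chromosome"],
            fc["kept"])

  # --- marker screening, selection, outliers ------------------------------
  ip <- intersect_with_panel(filtered, panel)
  cand <- screen_discriminative(ip$panel, k = config$adjust$k)
  sel <- select_marker(ip$matrix, cand$cpg,
                       affected_p = config$adjust$affected_p)
  marker <- sel$marker
  excluded <- detect_outlier_samples(ip$matrix, marker, design = design,
                                     n_mad = config$adjust$n_mad)
  corr <- classify_marker_correlation(ip$matrix, marker)
  prop <- estimate_proportion(ip$matrix, marker, ip$panel)
  utils::write.table(data.frame(sample = names(prop), proportion = prop),
                     file.path(out_dir, "proportions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  log_stage(log_path,
            "marker: %s selected from %d candidates; %d samples excluded; correlation classes strong=%d moderate=%d weak=%d",
            marker, nrow(cand), length(excluded), corr$counts["strong"],
            corr$counts["moderate"], corr$counts["weak"])

  # --- adjustment (single- and multi-marker) ------------------------------
  fit1 <- fit_marker_models(ip$matrix, marker, exclude_samples = excluded,
                            affected_p = config$adjust$affected_p)
  adj1 <- adjust_for_composition(ip$matrix, fit1)
  multi <- utils::head(cand$cpg, config$adjust$n_multi_markers)
  fit2 <- fit_marker_models(ip$matrix, multi, exclude_samples = excluded,
                            affected_p = config$adjust$affected_p)
  adj2 <- adjust_for_composition(ip$matrix, fit2)
  write_beta_tsv(adj1$beta, file.path(out_dir, "beta_adjusted_single.tsv"))
  write_beta_tsv(adj2$beta, file.path(out_dir, "beta_adjusted_multi.tsv"))
  jsonlite::write_json(list(marker = marker, multi_markers = multi,
                            n_adjusted = sum(adj1$adjusted),
                            n_unchanged = sum(!adj1$adjusted),
                            excluded_samples = excluded,
                            n_truncated = adj1$n_truncated),
                       file.path(out_dir, "adjustment.json"),
                       auto_unbox = TRUE, digits = NA)
  log_stage(log_path, "adjust: %d/%d CpGs adjusted (single marker), %d (multi), %d truncation(s)",
            sum(adj1$adjusted), length(adj1$adjusted), sum(adj2$adjusted),
            adj1$n_truncated)

  # --- paired association + MVP intersection ------------------------------
  keep_pairs <- !(design$heavy %in% excluded | design$light %in% excluded)
  design_used <- design[keep_pairs, , drop = FALSE]
  class(design_used) <- class(design)
  tab0 <- paired_ewas(ip$matrix, design_used, mode = config$association$mode)
  tab1 <- paired_ewas(adj1$beta, design_used, mode = config$association$mode)
  tab2 <- paired_ewas(adj2$beta, design_used, mode = config$association$mode)
  mvp_before <- call_mvps(tab0, config$association$p_threshold,
                          config$association$d_threshold)
  mvp_after <- call_mvps(list(tab1, tab2), config$association$p_threshold,
                         config$association$d_threshold)
  utils::write.table(tab1, file.path(out_dir, "association_single.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(tab2, file.path(out_dir, "association_multi.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  volcano_export(tab0, file.path(out_dir, "volcano_unadjusted.tsv"),
                 mvp_flags = mvp_before$flags)
  volcano_export(tab1, file.path(out_dir, "volcano_adjusted.tsv"),
                 mvp_flags = call_mvps(tab1, config$association$p_threshold,
                                       config$association$d_threshold)$flags)
  log_stage(log_path,
            "associate: %d pairs tested; MVPs before adjustment = %d, after (intersection) = %d",
            nrow(design_used), mvp_before$counts["mvp"], mvp_after$counts["mvp"])

  # --- DBS validation -----------------------------------------------------
  val_cpgs <- mvp_after$mvps
  if (length(val_cpgs) == 0) {
    # no MVPs called: validate the top-ranked CpGs by adjusted P instead
    val_cpgs <- tab1$cpg[order(tab1$p.value)]
  }
  val_cpgs <- utils::head(val_cpgs, config$dbs$n_validate)
  samples_used <- design_samples(design_used)
  reads_all <- list()
  for (cg in val_cpgs) {
    for (s in samples_used) {
      reads_all[[paste(cg, s)]] <- simulate_dbs_reads(
        true_beta = adj1$beta$beta[cg, s],
        n_reads = config$dbs$n_reads,
        conversion_rate = config$dbs$conversion_rate,
        seed = seed + 1000L + length(reads_all),
        amplicon_id = cg, sample_id = s)
    }
  }
  reads <- amplicon_read_set(do.call(rbind, lapply(reads_all, as.data.frame)))
  write_reads_tsv(reads, file.path(out_dir, "dbs_reads.tsv"))
  reads_f <- filter_reads(reads, config$dbs$min_conversion,
                          config$dbs$max_missing_fraction)
  fr <- attr(reads_f, "filter_report")
  meth <- amplicon_methylation(reads_f)
  utils::write.table(meth, file.path(out_dir, "dbs_methylation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  dbs_mat <- matrix(NA_real_, length(val_cpgs), length(samples_used),
                    dimnames = list(val_cpgs, samples_used))
  dbs_mat[cbind(match(meth$amplicon_id, val_cpgs),
                match(meth$sample_id, samples_used))] <- meth$beta
  arr_mat <- adj1$beta$beta[val_cpgs, samples_used, drop = FALSE]
  conc <- cross_platform_concordance(arr_mat, dbs_mat, axis = "per_sample")
  utils::write.table(conc$table, file.path(out_dir, "dbs_concordance.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  dbs_bm <- beta_matrix(dbs_mat)
  dbs_retest <- paired_ewas(dbs_bm, design_used,
                            mode = config$association$mode)
  utils::write.table(dbs_retest, file.path(out_dir, "dbs_retest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  log_stage(log_path,
            "validate-dbs: %d loci x %d samples, %d/%d reads kept, median per-sample r = %.3f",
            length(val_cpgs), length(samples_used), fr["kept"], fr["input"],
            conc$median_r)

  # --- SIRPH repetitive elements ------------------------------------------
  marker_beta <- ip$matrix$beta[marker, samples_used]
  sirph_rows <- list()
  # field-typical repetitive-element MIs; CpG 1 of each element tracks
  # composition (global methylation lower in buccal epithelium)
  sirph_spec <- data.frame(element = c("HERVK", "HERVK", "LINE1", "LINE1"),
                           cpg_index = c(1L, 2L, 1L, 2L),
                           base = c(0.61, 0.36, 0.58, 0.37),
                           slope = c(-0.15, 0, -0.08, 0))
  prop_used <- prop[samples_used]
  for (i in seq_len(nrow(sirph_spec))) {
    true_mi <- pmin(1, pmax(0, sirph_spec$base[i] +
                              sirph_spec$slope[i] * (prop_used - mean(prop_used))))
    sirph_rows[[i]] <- simulate_sirph_assay(
      true_mi, total_area = config$sirph$total_area,
      noise_sd = config$sirph$noise_sd, seed = seed + 2000L + i,
      element = sirph_spec$element[i], cpg_index = sirph_spec$cpg_index[i],
      sample_id = samples_used)
  }
  sirph <- sirph_assay(do.call(rbind, lapply(sirph_rows, as.data.frame)))
  write_sirph_tsv(sirph, file.path(out_dir, "sirph_areas.tsv"))
  sirph_unadj <- sirph_association(sirph, design_used)
  sirph_adj <- sirph_association(sirph, design_used,
                                 marker_values = marker_beta,
                                 affected_p = config$adjust$affected_p)
  utils::write.table(sirph_adj, file.path(out_dir, "sirph_association.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  log_stage(log_path, "sirph: %d element CpGs tested, %d adjusted for composition",
            nrow(sirph_adj), sum(sirph_adj$adjusted))

  # --- report -------------------------------------------------------------
  report <- list(
    seed = seed,
    cpgs = list(input = unname(fc["input"]),
                removed_detection = unname(fc["removed_detection"]),
                removed_chromosome = unname(fc["removed_chromosome"]),
                analyzed = nrow(ip$matrix$beta)),
    marker = list(selected = marker, candidates = cand$cpg,
                  scores = as.list(sel$scores),
                  correlation_classes = as.list(corr$counts)),
    excluded_samples = excluded,
    adjustment = list(adjusted = sum(adj1$adjusted),
                      unchanged = sum(!adj1$adjusted),
                      truncated = adj1$n_truncated),
    mvp = list(before_adjustment = unname(mvp_before$counts["mvp"]),
               p_only_single = unname(call_mvps(tab1,
                 config$association$p_threshold, 1)$counts["mvp"]),
               p_intersection = unname(mvp_after$counts["p_intersection"]),
               after_adjustment = unname(mvp_after$counts["mvp"]),
               ids = mvp_after$mvps),
    dbs = list(loci = val_cpgs,
               reads_kept = unname(fr["kept"]),
               reads_total = unname(fr["input"]),
               median_concordance = conc$median_r,
               retest_min_p = min(dbs_retest$p.value, na.rm = TRUE)),
    sirph = list(n_tested = nrow(sirph_adj),
                 n_adjusted = sum(sirph_adj$adjusted),
                 min_p_unadjusted = min(sirph_unadj$p.value),
                 min_p_adjusted = min(sirph_adj$p.value)))
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(format_report(report), file.path(out_dir, "report.txt"))
  invisible(report)
}

format_report <- function(report) {
  c(sprintf("salivamix study report (seed %d)", report$seed),
    "",
    sprintf("Probes: %d input, %d removed by detection P, %d removed by chromosome, %d analyzed",
            report$cpgs$input, report$cpgs$removed_detection,
            report$cpgs$removed_chromosome, report$cpgs$analyzed),
    sprintf("Marker: %s (of %d candidates); correlation classes strong=%d moderate=%d weak=%d",
            report$marker$selected, length(report$marker$candidates),
            report$marker$correlation_classes$strong,
            report$marker$correlation_classes$moderate,
            report$marker$correlation_classes$weak),
    sprintf("Excluded samples: %s",
            if (length(report$excluded_samples) == 0) "none"
            else paste(report$excluded_samples, collapse = ", ")),
    sprintf("Adjustment: %d CpGs adjusted + %d unchanged = %d total (%d truncation(s))",
            report$adjustment$adjusted, report$adjustment$unchanged,
            report$adjustment$adjusted + report$adjustment$unchanged,
            report$adjustment$truncated),
    sprintf("MVPs: %d before adjustment; %d significant in both adjusted analyses; %d MVPs after effect-size filter",
            report$mvp$before_adjustment, report$mvp$p_intersection,
            report$mvp$after_adjustment),
    sprintf("DBS validation: %d loci, %d/%d reads kept, median per-sample concordance r = %.3f, re-test min P = %.3g",
            length(report$dbs$loci), report$dbs$reads_kept,
            report$dbs$reads_total, report$dbs$median_concordance,
            report$dbs$retest_min_p),
    sprintf("SIRPH: %d element CpGs tested (%d composition-adjusted), min P unadjusted = %.3g, adjusted = %.3g",
            report$sirph$n_tested, report$sirph$n_adjusted,
            report$sirph$min_p_unadjusted, report$sirph$min_p_adjusted))
}

#' Summarize a completed run directory
#'
#' Re-renders the human-readable stage summary from the artifacts a
#' [run_study()] call wrote. Regeneration is idempotent.
#'
#' @param run_dir directory written by [run_study()].
#' @return character vector of report lines (also printed).
#' @export
generate_report <- function(run_dir) {
  needed <- c("report.json", "config.json", "run.log")
  missing <- needed[!file.exists(file.path(run_dir, needed))]
  stop_if(length(missing) > 0,
          sprintf("incomplete run directory; missing: %s",
                  paste(missing, collapse = ", ")))
  report <- jsonlite::read_json(file.path(run_dir, "report.json"),
                                simplifyVector = TRUE)
  report$marker$correlation_classes <- as.list(report$marker$correlation_classes)
  lines <- format_report(report)
  cat(lines, sep = "\n")
  invisible(lines)
}
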