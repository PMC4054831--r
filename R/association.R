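# Paired epigenome-wide testing and the study's supporting statistics.
# The exact signed-rank null distribution is built by a generating-
# function convolution over (doubled, hence integer) midranks, which is
# equivalent to enumerating all 2^n sign assignments and therefore also
# correct under ties; ties make the exact distribution data-dependent.

# counts of the signed-rank statistic on the doubled-rank scale:
# counts[w + 1] = number of sign assignments with sum of positive doubled
# ranks equal to w. Exact as doubles for n <= ~50 (counts < 2^53).
signrank_counts <- function(d2) {
  total <- sum(d2)
  counts <- numeric(total + 1)
  counts[1] <- 1
  for (d in d2) {
    shifted <- c(rep(0, d), counts[seq_len(total + 1 - d)])
    counts <- counts + shifted
  }
  counts
}

# two-sided exact P from doubled ranks d2 and observed doubled statistic w2
signrank_exact_p <- function(d2, w2) {
  counts <- signrank_counts(d2)
  tot <- 2^length(d2)
  # guard against floating error in the doubled statistic
  w2 <- round(w2)
  p_le <- sum(counts[seq_len(w2 + 1)]) / tot
  p_ge <- sum(counts[(w2 + 1):length(counts)]) / tot
  min(1, 2 * min(p_le, p_ge))
}

#' Paired Wilcoxon signed-rank test with exact enumeration
#'
#' Tests the null hypothesis that paired differences are symmetric about
#' zero. The exact two-sided P-value is computed from the full null
#' distribution of the signed-rank statistic over all sign assignments
#' (handled by convolution over midranks, so ties are treated exactly);
#' the minimum attainable two-sided P for n untied nonzero pairs is
#' `2 * 2^-n`. Above `exact_limit` nonzero pairs (mode `"auto"`) a normal
#' approximation with tie-corrected variance and continuity correction is
#' used.
#'
#' @param heavy,light numeric vectors of paired measurements (e.g. beta
#'   values of the heavier and lighter co-twin), equal length.
#' @param mode `"auto"` (exact up to `exact_limit` nonzero pairs),
#'   `"exact"`, or `"normal"`.
#' @param zero_method `"wilcoxon"` (default: zero differences are dropped
#'   before ranking) or `"pratt"` (zeros are ranked, then their ranks
#'   discarded).
#' @param exact_limit largest number of nonzero pairs handled exactly in
#'   `"auto"` mode (default 25).
#' @return list with `statistic` (signed-rank sum W of positive
#'   differences), `p.value` (two-sided, in (0, 1\]), `n` (nonzero pairs
#'   used) and `method`.
#' @export
#' @examples
#' wilcoxon_signed_rank_paired(c(0.6, 0.7, 0.8), c(0.5, 0.55, 0.6))$p.value
wilcoxon_signed_rank_paired <- function(heavy, light,
                                        mode = c("auto", "exact", "normal"),
                                        zero_method = c("wilcoxon", "pratt"),
                                        exact_limit = 25) {
  mode <- match.arg(mode)
  zero_method <- match.arg(zero_method)
  stop_if(length(heavy) != length(light), "'heavy' and 'light' lengths differ")
  stop_if(length(heavy) < 1, "need at least one pair")
  d <- heavy - light
  ok <- !is.na(d)
  d <- d[ok]
  if (all(d == 0)) {
    warning("all paired differences are zero; P = 1")
    return(list(statistic = 0, p.value = 1, n = 0L, method = "degenerate"))
  }
  if (zero_method == "wilcoxon") {
    d <- d[d != 0]
    r <- rank(abs(d))
  } else {
    r_all <- rank(abs(d))
    r <- r_all[d != 0]
    d <- d[d != 0]
  }
  n <- length(d)
  w <- sum(r[d > 0])
  use_exact <- mode == "exact" || (mode == "auto" && n <= exact_limit)
  if (use_exact) {
    p <- signrank_exact_p(round(2 * r), 2 * w)
    method <- "exact"
  } else {
    mu <- sum(r) / 2
    ties <- table(r)
    sigma2 <- sum(r^2) / 4
    z <- w - mu
    z <- sign(z) * max(0, abs(z) - 0.5) / sqrt(sigma2)  # continuity corr.
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal approximation"
  }
  list(statistic = w, p.value = p, n = n, method = method)
}

#' Mean paired difference
#'
#' Arithmetic mean of `heavy - light` (complete pairs only).
#'
#' @param heavy,light numeric vectors of equal length.
#' @return signed mean difference.
#' @export
mean_difference <- function(heavy, light) {
  stop_if(length(heavy) != length(light), "'heavy' and 'light' lengths differ")
  stop_if(length(heavy) < 1, "need at least one pair")
  mean(heavy - light, na.rm = TRUE)
}

#' Paired epigenome-wide association scan
#'
#' Runs the paired Wilcoxon signed-rank test and mean-difference
#' computation for every CpG of a beta matrix against a twin design.
#' Rows with untied, nonzero differences share a single exact null
#' distribution, which is cached for speed; ties and zeros fall back to
#' the general path. CpGs with any missing value get `NA` results
#' (complete-case rule).
#'
#' @param x a [beta_matrix()].
#' @param design a [twin_design()]; pairs whose members are absent from
#'   `x` are dropped with a warning.
#' @param mode passed to [wilcoxon_signed_rank_paired()].
#' @return an `AssociationTable` data.frame with columns `cpg`,
#'   `statistic`, `p.value`, `mean_diff`.
#' @export
paired_ewas <- function(x, design, mode = "auto") {
  stopifnot(inherits(x, "BetaMatrix"), inherits(design, "TwinDesign"))
  present <- design$heavy %in% colnames(x$beta) &
    design$light %in% colnames(x$beta)
  if (!all(present)) {
    warning(sprintf("dropping %d pair(s) with missing samples", sum(!present)))
    design <- design[present, , drop = FALSE]
  }
  stop_if(nrow(design) < 1, "no usable pairs")
  D <- x$beta[, design$heavy, drop = FALSE] - x$beta[, design$light, drop = FALSE]
  n <- ncol(D)
  exact_ok <- mode %in% c("auto", "exact") && n <= 25
  cdf_plain <- NULL
  if (exact_ok) {
    counts <- signrank_counts(2 * seq_len(n))
    cdf_plain <- cumsum(counts) / 2^n
    sf_plain <- rev(cumsum(rev(counts))) / 2^n
  }
  res <- apply(D, 1, function(d) {
    if (anyNA(d)) return(c(NA_real_, NA_real_))
    if (all(d == 0)) return(c(0, 1))
    dz <- d[d != 0]
    r <- rank(abs(dz))
    if (exact_ok && length(dz) == n && !anyDuplicated(abs(dz))) {
      w2 <- round(2 * sum(r[dz > 0]))
      p <- min(1, 2 * min(cdf_plain[w2 + 1], sf_plain[w2 + 1]))
      c(sum(r[dz > 0]), p)
    } else {
      out <- wilcoxon_signed_rank_paired(d, rep(0, length(d)), mode = mode)
      c(out$statistic, out$p.value)
    }
  })
  tab <- data.frame(cpg = rownames(D), statistic = res[1, ],
                    p.value = res[2, ], mean_diff = rowMeans(D),
                    row.names = NULL, stringsAsFactors = FALSE)
  class(tab) <- c("AssociationTable", "data.frame")
  tab
}

#' Call methylation variable positions (MVPs)
#'
#' A CpG is an MVP when its P-value is below `p_threshold` and its
#' absolute mean beta difference exceeds `d_threshold` in every supplied
#' association table (intersection rule across adjustment variants).
#' Counts are reported at each filter stage.
#'
#' @param tables one `AssociationTable` or a list of them, all covering
#'   the same CpG set.
#' @param p_threshold uncorrected P-value threshold (default 0.01).
#' @param d_threshold absolute mean beta-difference threshold
#'   (default 0.05).
#' @return list with `mvps` (character vector of CpG ids), `counts`
#'   (named: per-table P-pass counts, `p_intersection`, `mvp`), and
#'   `flags` (named logical over CpGs).
#' @export
call_mvps <- function(tables, p_threshold = 0.01, d_threshold = 0.05) {
  if (inherits(tables, "AssociationTable")) tables <- list(tables)
  stop_if(length(tables) < 1, "need at least one association table")
  cpgs <- tables[[1]]$cpg
  for (t in tables) {
    stop_if(!identical(sort(t$cpg), sort(cpgs)),
            "association tables cover different CpG sets")
  }
  p_pass <- sapply(tables, function(t) {
    v <- t$p.value[match(cpgs, t$cpg)]
    !is.na(v) & v < p_threshold
  })
  d_pass <- sapply(tables, function(t) {
    v <- t$mean_diff[match(cpgs, t$cpg)]
    !is.na(v) & abs(v) > d_threshold
  })
  p_pass <- matrix(p_pass, nrow = length(cpgs))
  d_pass <- matrix(d_pass, nrow = length(cpgs))
  p_all <- rowSums(p_pass) == length(tables)
  flags <- p_all & rowSums(d_pass) == length(tables)
  counts <- c(stats::setNames(colSums(p_pass),
                              paste0("p_pass_table", seq_along(tables))),
              p_intersection = sum(p_all), mvp = sum(flags))
  list(mvps = cpgs[flags], counts = counts,
       flags = stats::setNames(flags, cpgs))
}

#' Freeman-Halton exact test for r x c contingency tables
#'
#' Exact generalization of Fisher's 2 x 2 test: the two-sided P-value is
#' the sum of probabilities of all tables with the observed margins whose
#' conditional (multivariate hypergeometric) probability does not exceed
#' that of the observed table. Tables are enumerated depth-first with
#' margin pruning; a relative tolerance of 1e-9 guards floating-point
#' ties in the probability comparison.
#'
#' @param table r x c matrix of nonnegative integer counts (r, c >= 2).
#' @param max_tables safety cap on the number of enumerated tables.
#' @return list with `p.value` and `n_tables` (tables enumerated);
#'   attribute `total_prob` carries the summed probability of all
#'   enumerated tables (a self-check, equal to 1).
#' @export
#' @examples
#' fisher_exact_rxc(matrix(c(12, 4, 0, 4, 9, 3), nrow = 3))$p.value
fisher_exact_rxc <- function(table, max_tables = 5e6) {
  stop_if(!is.matrix(table) || !is.numeric(table), "'table' must be a numeric matrix")
  stop_if(any(table < 0) || any(table != round(table)),
          "'table' must hold nonnegative integer counts")
  stop_if(nrow(table) < 2 || ncol(table) < 2, "need at least a 2 x 2 table")
  table <- round(table)
  n <- sum(table)
  stop_if(n < 1, "total count must be >= 1")
  rs <- rowSums(table)
  cs <- colSums(table)
  const <- sum(lgamma(rs + 1)) + sum(lgamma(cs + 1)) - lgamma(n + 1)
  logp_table <- function(m) const - sum(lgamma(m + 1))
  logp_obs <- logp_table(table)
  tol <- 1e-9
  env <- new.env()
  env$p <- 0
  env$total <- 0
  env$count <- 0L
  r <- nrow(table); cc <- ncol(table)
  cells <- as.vector(t(table))  # row-major traversal
  # depth-first fill, cell by cell in row-major order
  recurse <- function(idx, row_rem, col_rem, lg_acc) {
    i <- ((idx - 1) %/% cc) + 1
    j <- ((idx - 1) %% cc) + 1
    if (j == cc) {
      v <- row_rem[i]
      if (v > col_rem[j]) return(invisible())
      lg <- lg_acc - lgamma(v + 1)
      col_rem[j] <- col_rem[j] - v
      row_rem[i] <- 0
      if (i == r - 1) {
        # last row is determined by remaining column margins
        lg <- lg - sum(lgamma(col_rem + 1))
        env$count <- env$count + 1L
        stop_if(env$count > max_tables, "table space too large to enumerate")
        logp <- const + lg
        env$total <- env$total + exp(logp)
        if (logp <= logp_obs + tol) env$p <- env$p + exp(logp)
      } else {
        recurse(idx + 1, row_rem, col_rem, lg)
      }
    } else {
      vmax <- min(row_rem[i], col_rem[j])
      for (v in 0:vmax) {
        rr <- row_rem; cr <- col_rem
        rr[i] <- rr[i] - v
        cr[j] <- cr[j] - v
        recurse(idx + 1, rr, cr, lg_acc - lgamma(v + 1))
      }
    }
  }
  if (r == 1) {
    return(list(p.value = 1, n_tables = 1L))
  }
  recurse(1, rs, cs, 0)
  structure(list(p.value = min(1, env$p), n_tables = env$count),
            total_prob = env$total)
}

#' Paired t-test for continuous phenotypes
#'
#' Standard paired t-test on the differences (wraps [stats::t.test()]),
#' with an explicit error when the differences have zero variance.
#'
#' @param a,b numeric vectors of paired measurements, equal length >= 2.
#' @return list with `statistic`, `df`, `p.value`, `mean_diff`.
#' @export
paired_t_test <- function(a, b) {
  stop_if(length(a) != length(b), "'a' and 'b' lengths differ")
  stop_if(length(a) < 2, "need at least 2 pairs")
  d <- a - b
  stop_if(stats::sd(d) == 0, "paired differences have zero variance")
  ht <- stats::t.test(a, b, paired = TRUE)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p.value = ht$p.value, mean_diff = unname(ht$estimate))
}

#' Power of the two-sided paired t-test
#'
#' Analytic power from the noncentral t distribution with `n_pairs - 1`
#' degrees of freedom and noncentrality `delta * sqrt(n_pairs) /
#' sd_diff`. With `delta = 0` the power equals `alpha` (size of the
#' test).
#'
#' @param n_pairs number of pairs (>= 2).
#' @param delta true mean difference on the beta scale.
#' @param sd_diff standard deviation of the paired differences (> 0).
#' @param alpha two-sided significance level in (0, 1).
#' @return power as a fraction in \[0, 1\].
#' @export
#' @examples
#' power_paired_t(16, 0.05, 0.025, 0.01)
power_paired_t <- function(n_pairs, delta, sd_diff, alpha = 0.01) {
  n_pairs <- check_count(n_pairs, "n_pairs", min = 2)
  stop_if(!is.numeric(sd_diff) || sd_diff <= 0, "'sd_diff' must be > 0")
  stop_if(!is.numeric(alpha) || alpha <= 0 || alpha >= 1,
          "'alpha' must lie in (0, 1)")
  df <- n_pairs - 1
  ncp <- delta * sqrt(n_pairs) / sd_diff
  tc <- stats::qt(1 - alpha / 2, df)
  stats::pt(-tc, df, ncp = ncp) + stats::pt(tc, df, ncp = ncp, lower.tail = FALSE)
}

#' Relative birth-weight discordance
#'
#' `(heavier - lighter) / heavier`, the fraction by which the lighter
#' co-twin's birth weight falls short of the heavier co-twin's.
#'
#' @param heavier_bw,lighter_bw birth weights (grams), `heavier_bw >=
#'   lighter_bw > 0`; vectorized.
#' @return fraction(s) in \[0, 1).
#' @export
#' @examples
#' relative_discordance(2619, 1921)  # 0.267
relative_discordance <- function(heavier_bw, lighter_bw) {
  stop_if(any(lighter_bw <= 0), "birth weights must be positive")
  stop_if(any(lighter_bw > heavier_bw),
          "lighter birth weight exceeds heavier birth weight")
  (heavier_bw - lighter_bw) / heavier_bw
}

#' Export an association table for volcano plotting
#'
#' Writes a TSV of `(cpg, mean_diff, neglog10_p, mvp)` — the coordinates
#' of the familiar volcano plot of effect size against significance.
#'
#' @param table an `AssociationTable` from [paired_ewas()].
#' @param path output file path.
#' @param mvp_flags optional named logical vector (from [call_mvps()]).
#' @return `path`, invisibly.
#' @export
volcano_export <- function(table, path, mvp_flags = NULL) {
  df <- data.frame(cpg = table$cpg, mean_diff = table$mean_diff,
                   neglog10_p = -log10(table$p.value),
                   mvp = if (is.null(mvp_flags)) rep(FALSE, length(table$cpg))
                         else unname(mvp_flags[table$cpg]))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
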