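# Seeded synthetic-data generators emulating the statistical structure of
# a saliva methylome study: a two-cell-type reference panel, per-sample
# convex mixtures in a twin-pair design, in-vitro-style mixture series,
# read-level bisulfite amplicon data, and SNuPE/SIRPH peak areas. Every
# generator is a pure function of its arguments including the seed, and
# returns the ground truth alongside the data.

#' Simulate a two-cell-type reference panel
#'
#' Generates mean beta profiles for two cell types (default buccal
#' epithelium vs whole blood) in which exactly `n_discriminative` CpGs are
#' discriminatively methylated (absolute reference difference at least
#' `separation`, drawn uniformly up to `max_separation`) and all remaining
#' CpGs differ by less than the methylation-variable-position effect
#' threshold (uniform in \[0, min(0.05, 0.9 separation)\]).
#'
#' @param n_cpgs total number of CpGs on the panel.
#' @param n_discriminative number of discriminative marker-like CpGs
#'   (`<= n_cpgs`).
#' @param separation minimum absolute between-type beta difference of a
#'   discriminative CpG, in (0, 1\].
#' @param seed integer seed; identical arguments give bit-identical output.
#' @param type_a,type_b cell-type labels (columns of the panel).
#' @param max_separation upper end of the discriminative-difference draw;
#'   clipped to `[separation, 0.93]`.
#' @return list with `panel` (a [reference_panel()]) and `truth` (class
#'   `SimulationTruth`: discriminative CpG ids, per-type means, seed and
#'   call parameters).
#' @export
#' @examples
#' sim <- simulate_reference_panel(100, 10, separation = 0.7, seed = 1)
#' sim$truth$discriminative
simulate_reference_panel <- function(n_cpgs, n_discriminative, separation,
                                     seed, type_a = "buccal",
                                     type_b = "blood",
                                     max_separation = 0.93) {
  n_cpgs <- check_count(n_cpgs, "n_cpgs", min = 1)
  n_discriminative <- check_count(n_discriminative, "n_discriminative", min = 0)
  stop_if(n_discriminative > n_cpgs, "'n_discriminative' exceeds 'n_cpgs'")
  stop_if(!is.numeric(separation) || length(separation) != 1 ||
            separation <= 0 || separation > 1,
          "'separation' must lie in (0, 1]")
  max_separation <- max(separation, min(max_separation, 0.93))
  with_seed(seed, {
    cpgs <- sprintf("cg%08d", seq_len(n_cpgs))
    disc_idx <- if (n_discriminative > 0) {
      sort(sample.int(n_cpgs, n_discriminative))
    } else integer(0)
    m_b <- stats::runif(n_cpgs, 0.05, 0.95)   # baseline (type_b) means
    d_small <- stats::runif(n_cpgs, 0, min(0.05, 0.9 * separation))
    sgn <- sample(c(-1, 1), n_cpgs, replace = TRUE)
    m_a <- pmin(1, pmax(0, m_b + sgn * d_small))
    if (n_discriminative > 0) {
      d_big <- stats::runif(n_discriminative, separation, max_separation)
      lo <- stats::runif(n_discriminative, 0.02, 1 - d_big - 0.02)
      swap <- sample(c(TRUE, FALSE), n_discriminative, replace = TRUE)
      a <- ifelse(swap, lo, lo + d_big)
      b <- ifelse(swap, lo + d_big, lo)
      m_a[disc_idx] <- a
      m_b[disc_idx] <- b
    }
    means <- cbind(m_a, m_b)
    dimnames(means) <- list(cpgs, c(type_a, type_b))
    truth <- structure(list(discriminative = cpgs[disc_idx],
                            means = means, seed = seed,
                            separation = separation),
                       class = "SimulationTruth")
    list(panel = reference_panel(means), truth = truth)
  })
}

# draw per-sample buccal proportions for n_pairs twin pairs; pair members
# share a latent component controlled by pair_correlation in [0, 1), and
# heavy members can carry a systematic composition bias (heavy_shift) to
# emulate group-associated confounding
draw_proportions <- function(n_pairs, sampler) {
  lo <- sampler$min %||% 0.1
  hi <- sampler$max %||% 0.9
  rho <- sampler$pair_correlation %||% 0
  shift <- sampler$heavy_shift %||% 0
  stop_if(rho < 0 || rho >= 1, "'pair_correlation' must lie in [0, 1)")
  u_ind <- matrix(stats::runif(2 * n_pairs), nrow = 2)
  if (rho > 0) {
    # mixing weight giving approximately the requested member correlation
    s <- sqrt(rho / (1 - rho))
    lam <- s / (1 + s)
    u_pair <- stats::runif(n_pairs)
    u <- (1 - lam) * u_ind + lam * matrix(u_pair, 2, n_pairs, byrow = TRUE)
  } else {
    u <- u_ind
  }
  p <- lo + (hi - lo) * u   # heavy member = row 1, light = row 2
  p[1, ] <- pmin(pmax(p[1, ] + shift, 0), min(hi + shift, 1))
  p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a paired twin cohort of two-cell-type mixtures
#'
#' Each sample's beta value at CpG j is the convex combination
#' `p * beta_a(j) + (1 - p) * beta_b(j)` of the two reference profiles,
#' with per-sample mixing proportion `p` drawn from `proportion_sampler`,
#' optional injected mean-beta effects on one member of each pair, and
#' additive Gaussian technical noise truncated to \[0, 1\].
#'
#' @param panel a [reference_panel()] with exactly two cell types (or the
#'   `$panel` element of [simulate_reference_panel()] output).
#' @param n_pairs number of twin pairs (two samples each, one heavy and
#'   one light member).
#' @param proportion_sampler list with elements `min`, `max` (uniform
#'   range of the type-a proportion, default \[0.1, 0.9\]),
#'   `pair_correlation` (within-pair correlation of proportions in
#'   \[0, 1), default 0 — composition discordance within pairs) and
#'   `heavy_shift` (systematic proportion offset of the heavy member,
#'   default 0 — group-associated composition confounding).
#' @param effect_spec optional `data.frame(cpg, effect, member)` of
#'   injected beta-scale effects; `member` is `"heavy"` or `"light"`.
#' @param noise_sd standard deviation of the additive beta-scale noise.
#' @param seed integer seed.
#' @param type_a,type_b panel columns used as the mixing endpoints.
#' @param detp if `TRUE` (default), attach synthetic detection P-values:
#'   background-level values with a small fraction (`detp_fail_rate`) of
#'   probe/sample failures above 0.001.
#' @param detp_fail_rate fraction of CpGs given one failing sample.
#' @param chrom_labels chromosome labels sampled for the annotation;
#'   default human autosomes plus X and Y.
#' @return list with `beta` ([beta_matrix()]), `design`
#'   ([twin_design()]) and `truth` (proportions, effects, noise sd, seed).
#' @export
simulate_cohort <- function(panel, n_pairs,
                            proportion_sampler = list(min = 0.1, max = 0.9,
                                                      pair_correlation = 0),
                            effect_spec = NULL, noise_sd = 0.02, seed = 1,
                            type_a = "buccal", type_b = "blood",
                            detp = TRUE, detp_fail_rate = 0.005,
                            chrom_labels = c(as.character(1:22), "X", "Y")) {
  stopifnot(inherits(panel, "ReferencePanel"))
  n_pairs <- check_count(n_pairs, "n_pairs", min = 1)
  stop_if(!is.numeric(noise_sd) || noise_sd < 0, "'noise_sd' must be >= 0")
  stop_if(!all(c(type_a, type_b) %in% colnames(panel$means)),
          "panel lacks the requested cell types")
  if (!is.null(effect_spec)) {
    stop_if(!is.data.frame(effect_spec) ||
              !all(c("cpg", "effect") %in% names(effect_spec)),
            "'effect_spec' must be a data.frame with columns cpg, effect")
    if (is.null(effect_spec$member)) effect_spec$member <- "light"
    missing_cpg <- setdiff(effect_spec$cpg, rownames(panel$means))
    stop_if(length(missing_cpg) > 0,
            sprintf("effect CpG not in panel: '%s'", missing_cpg[1]))
    stop_if(!all(effect_spec$member %in% c("heavy", "light")),
            "'effect_spec$member' must be 'heavy' or 'light'")
  }
  with_seed(seed, {
    cpgs <- rownames(panel$means)
    a <- panel$means[, type_a]
    b <- panel$means[, type_b]
    pair_id <- sprintf("pair%02d", seq_len(n_pairs))
    heavy <- paste0(pair_id, "_H")
    light <- paste0(pair_id, "_L")
    p_mat <- draw_proportions(n_pairs, proportion_sampler)
    samples <- c(heavy, light)
    p <- stats::setNames(c(p_mat[1, ], p_mat[2, ]), samples)
    beta <- outer(a, p) + outer(b, 1 - p)
    dimnames(beta) <- list(cpgs, samples)
    if (!is.null(effect_spec)) {
      for (i in seq_len(nrow(effect_spec))) {
        cols <- if (effect_spec$member[i] == "heavy") heavy else light
        beta[effect_spec$cpg[i], cols] <-
          beta[effect_spec$cpg[i], cols] + effect_spec$effect[i]
      }
    }
    if (noise_sd > 0) {
      beta <- beta + matrix(stats::rnorm(length(beta), 0, noise_sd),
                            nrow(beta), ncol(beta))
    }
    beta <- truncate01(beta)
    n_trunc <- attr(beta, "n_truncated")
    attr(beta, "n_truncated") <- NULL
    detp_mat <- NULL
    if (isTRUE(detp)) {
      detp_mat <- matrix(stats::runif(length(beta), 0, 2e-4),
                         nrow(beta), ncol(beta), dimnames = dimnames(beta))
      n_fail <- round(detp_fail_rate * length(cpgs))
      if (n_fail > 0) {
        fail_cpg <- sample.int(length(cpgs), n_fail)
        fail_smp <- sample.int(length(samples), n_fail, replace = TRUE)
        detp_mat[cbind(fail_cpg, fail_smp)] <- stats::runif(n_fail, 0.0011, 0.05)
      }
    }
    anno <- data.frame(chrom = sample(chrom_labels, length(cpgs), replace = TRUE,
                                      prob = c(rep(1, 22), 0.7, 0.05)[seq_along(chrom_labels)]),
                       pos = sample.int(2e8, length(cpgs), replace = TRUE),
                       gene = NA_character_, row.names = cpgs,
                       stringsAsFactors = FALSE)
    truth <- structure(list(proportion = p, effects = effect_spec,
                            noise_sd = noise_sd, seed = seed,
                            n_truncated = n_trunc),
                       class = "SimulationTruth")
    list(beta = beta_matrix(beta, detp = detp_mat, anno = anno),
         design = twin_design(pair_id, heavy, light),
         truth = truth)
  })
}

#' Simulate an in-vitro-style two-cell-type mixture series
#'
#' One sample per requested mixing fraction, built with the same convex
#' mixture model as [simulate_cohort()]; used to check that marker-based
#' proportion estimation recovers known mixing fractions.
#'
#' @param panel a [reference_panel()].
#' @param fractions numeric vector of type-a mixing fractions in \[0, 1\].
#' @param noise_sd beta-scale noise standard deviation.
#' @param seed integer seed.
#' @param type_a,type_b panel columns used as mixing endpoints.
#' @return list with `beta` ([beta_matrix()], one column per fraction)
#'   and `truth` (the fractions, named by sample).
#' @export
simulate_mixture_series <- function(panel, fractions, noise_sd = 0, seed = 1,
                                    type_a = "buccal", type_b = "blood") {
  stopifnot(inherits(panel, "ReferencePanel"))
  stop_if(length(fractions) == 0, "'fractions' must not be empty")
  check_fraction(fractions, "fractions")
  with_seed(seed, {
    a <- panel$means[, type_a]
    b <- panel$means[, type_b]
    samples <- sprintf("mix_%03d", round(100 * fractions))
    samples <- make.unique(samples, sep = "_")
    beta <- outer(a, fractions) + outer(b, 1 - fractions)
    if (noise_sd > 0) {
      beta <- beta + matrix(stats::rnorm(length(beta), 0, noise_sd),
                            nrow(beta), ncol(beta))
    }
    beta <- truncate01(beta)
    attr(beta, "n_truncated") <- NULL
    dimnames(beta) <- list(rownames(panel$means), samples)
    truth <- structure(list(proportion = stats::setNames(fractions, samples),
                            noise_sd = noise_sd, seed = seed),
                       class = "SimulationTruth")
    list(beta = beta_matrix(beta), truth = truth)
  })
}

#' Simulate read-level bisulfite amplicon data
#'
#' Generates per-read binary methylation calls over an amplicon's CpGs.
#' Each read's call at CpG j is methylated with probability
#' `true_beta[j]`; an unmethylated cytosine additionally escapes bisulfite
#' conversion (and therefore appears methylated) with probability
#' `1 - conversion_rate`. A per-read conversion-rate estimate is attached,
#' simulated from `n_conversion_sites` non-CpG cytosines per read.
#'
#' @param true_beta numeric vector of true methylation fractions, one per
#'   CpG in the amplicon.
#' @param n_reads number of reads (>= 1).
#' @param conversion_rate bisulfite conversion probability in (0, 1\].
#' @param seed integer seed.
#' @param amplicon_id,sample_id identifiers stamped on every read.
#' @param missing_rate per-call probability of a missing call (default 0).
#' @param n_conversion_sites non-CpG cytosines per read used for the
#'   per-read conversion estimate.
#' @param snp_allele_freq optional true allele fraction; when non-`NULL`
#'   each read carries an allele call `"A"` (reference, with this
#'   probability) or `"B"`.
#' @return an [amplicon_read_set()] data.frame, one row per read.
#' @export
simulate_dbs_reads <- function(true_beta, n_reads, conversion_rate = 0.99,
                               seed = 1, amplicon_id = "amp1",
                               sample_id = "s1", missing_rate = 0,
                               n_conversion_sites = 25,
                               snp_allele_freq = NULL) {
  check_fraction(true_beta, "true_beta")
  n_reads <- check_count(n_reads, "n_reads", min = 1)
  stop_if(!is.numeric(conversion_rate) || conversion_rate <= 0 ||
            conversion_rate > 1, "'conversion_rate' must lie in (0, 1]")
  check_fraction(missing_rate, "missing_rate")
  with_seed(seed, {
    k <- length(true_beta)
    meth <- matrix(stats::rbinom(n_reads * k, 1,
                                 rep(true_beta, each = n_reads)),
                   n_reads, k)
    # conversion failure flips observed call of unmethylated cytosines to 1
    fail <- matrix(stats::rbinom(n_reads * k, 1, 1 - conversion_rate),
                   n_reads, k)
    obs <- ifelse(meth == 1, 1, fail)
    calls <- matrix(as.character(obs), n_reads, k)
    if (missing_rate > 0) {
      miss <- matrix(stats::runif(n_reads * k) < missing_rate, n_reads, k)
      calls[miss] <- "."
    }
    conv_est <- stats::rbinom(n_reads, n_conversion_sites, conversion_rate) /
      n_conversion_sites
    allele <- rep(NA_character_, n_reads)
    if (!is.null(snp_allele_freq)) {
      check_fraction(snp_allele_freq, "snp_allele_freq")
      allele <- ifelse(stats::runif(n_reads) < snp_allele_freq, "A", "B")
    }
    amplicon_read_set(data.frame(
      amplicon_id = amplicon_id, sample_id = sample_id,
      read_id = sprintf("%s_%s_r%05d", amplicon_id, sample_id, seq_len(n_reads)),
      calls = apply(calls, 1, paste0, collapse = ""),
      conversion = conv_est, allele = allele,
      stringsAsFactors = FALSE))
  })
}

#' Simulate a SNuPE/SIRPH peak-area measurement
#'
#' Peak areas for the C-extended (methylated) and T-extended
#' (unmethylated) primer: `AC = true_beta * total_area + noise` and
#' `AT = (1 - true_beta) * total_area + noise`, independent Gaussian
#' noise, truncated at 0.
#'
#' @param true_beta true methylation fraction(s); one assay row per value.
#' @param total_area total peak area (> 0).
#' @param noise_sd standard deviation of the additive area noise (>= 0).
#' @param seed integer seed.
#' @param element repetitive-element label.
#' @param cpg_index CpG index within the assay.
#' @param sample_id sample identifier(s), recycled against `true_beta`.
#' @return a [sirph_assay()] data.frame with columns `element`,
#'   `cpg_index`, `sample_id`, `area_c`, `area_t`.
#' @export
simulate_sirph_assay <- function(true_beta, total_area = 1000, noise_sd = 0,
                                 seed = 1, element = "ELEMENT",
                                 cpg_index = 1L, sample_id = "s1") {
  check_fraction(true_beta, "true_beta")
  stop_if(!is.numeric(total_area) || total_area <= 0, "'total_area' must be > 0")
  stop_if(!is.numeric(noise_sd) || noise_sd < 0, "'noise_sd' must be >= 0")
  n <- length(true_beta)
  with_seed(seed, {
    ac <- pmax(0, true_beta * total_area + stats::rnorm(n, 0, noise_sd))
    at <- pmax(0, (1 - true_beta) * total_area + stats::rnorm(n, 0, noise_sd))
    sirph_assay(data.frame(element = element, cpg_index = as.integer(cpg_index),
                           sample_id = rep_len(sample_id, n),
                           area_c = ac, area_t = at,
                           stringsAsFactors = FALSE))
  })
}
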