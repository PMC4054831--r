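test_that("exact signed-rank P matches brute-force sign enumeration", {
  set.seed(11)
  for (n in c(3, 5, 8, 12)) {
    for (rep in 1:4) {
      d <- round(runif(n, -1, 1), 2)
      d[d == 0] <- 0.11
      p_pkg <- wilcoxon_signed_rank_paired(d, rep(0, n), mode = "exact")$p.value
      expect_equal(p_pkg, bf_signed_rank_p(d), tolerance = 1e-12,
                   info = sprintf("n=%d rep=%d untied", n, rep))
      # tied absolute differences exercise the midrank path
      dt <- sample(c(0.2, -0.2, 0.5, 0.3), n, replace = TRUE)
      p_tie <- wilcoxon_signed_rank_paired(dt, rep(0, n), mode = "exact")$p.value
      expect_equal(p_tie, bf_signed_rank_p(dt), tolerance = 1e-12,
                   info = sprintf("n=%d rep=%d tied", n, rep))
    }
  }
})

test_that("exact signed-rank agrees with the reference implementation when untied", {
  set.seed(4)
  for (n in c(6, 10, 16)) {
    a <- runif(n); b <- runif(n)
    p_pkg <- wilcoxon_signed_rank_paired(a, b, mode = "exact")$p.value
    p_ref <- stats::wilcox.test(a, b, paired = TRUE, exact = TRUE)$p.value
    expect_equal(p_pkg, p_ref, tolerance = 1e-12)
  }
})

test_that("signed-rank floor, symmetry and degenerate cases behave", {
  # n same-sign untied pairs attain the floor 2 * 2^-n
  for (n in c(5, 10, 16)) {
    p <- wilcoxon_signed_rank_paired(seq_len(n) + 0.5, seq_len(n),
                                     mode = "exact")$p.value
    expect_equal(p, 2 * 2^-n)
  }
  # symmetric +d/-d differences sit at the null center
  p_sym <- wilcoxon_signed_rank_paired(c(1.2, 0.8, 1.4, 0.6),
                                       c(0.8, 1.2, 0.6, 1.4))$p.value
  expect_equal(p_sym, 1)
  expect_warning(res <- wilcoxon_signed_rank_paired(rep(0.5, 4), rep(0.5, 4)),
                 "zero")
  expect_equal(res$p.value, 1)
  # zeros are dropped before ranking (classical treatment)
  pz <- wilcoxon_signed_rank_paired(c(1, 2, 3, 4), c(1, 1, 1, 1), mode = "exact")
  expect_equal(pz$n, 3L)
  # Pratt option keeps zero ranks in the scale
  pp <- wilcoxon_signed_rank_paired(c(1, 2, 3, 4), c(1, 1, 1, 1),
                                    mode = "exact", zero_method = "pratt")
  expect_equal(pp$n, 3L)
  expect_true(pp$p.value >= pz$p.value * 0.1 && pp$p.value <= 1)
  # normal approximation tracks the exact P reasonably at moderate n
  set.seed(9); a <- runif(20); b <- a + rnorm(20, 0.05, 0.1)
  pe <- wilcoxon_signed_rank_paired(a, b, mode = "exact")$p.value
  pn <- wilcoxon_signed_rank_paired(a, b, mode = "normal")$p.value
  expect_lt(abs(pe - pn), 0.05)
})

test_that("mean difference is plain pairwise arithmetic", {
  expect_equal(mean_difference(c(1, 2), c(1, 2)), 0)
  expect_equal(mean_difference(rep(0.6, 5), rep(0.5, 5)), 0.1)
  expect_equal(mean_difference(c(0.27, 0.25, 0.29), c(0.20, 0.20, 0.20)), 0.07)
})

test_that("MVP calling applies both thresholds across all tables", {
  mk <- function(p, d) {
    t <- data.frame(cpg = sprintf("cg%d", seq_along(p)), statistic = 0,
                    p.value = p, mean_diff = d)
    class(t) <- c("AssociationTable", "data.frame")
    t
  }
  t1 <- mk(c(0.001, 0.5, 0.005, 0.002, 0.9, 0.001),
           c(0.10, 0.10, 0.01, -0.08, 0.2, 0.06))
  t2 <- mk(c(0.002, 0.001, 0.004, 0.003, 0.8, 0.5),
           c(0.09, 0.12, 0.02, -0.07, 0.1, 0.07))
  res <- call_mvps(list(t1, t2), p_threshold = 0.01, d_threshold = 0.05)
  expect_setequal(res$mvps, c("cg1", "cg4"))
  expect_equal(unname(res$counts["p_intersection"]), 3)
  all_in <- call_mvps(t1, p_threshold = 1.0, d_threshold = 0)
  expect_length(all_in$mvps, 6)
  none <- call_mvps(mk(rep(0.5, 3), rep(0.2, 3)), 0.01, 0.05)
  expect_length(none$mvps, 0)
  expect_error(call_mvps(list(t1, mk(0.5, 0.1))), "different CpG sets")
})

test_that("Freeman-Halton test reproduces closed-form and reference results", {
  # 2x2 tables against the closed-form hypergeometric oracle
  set.seed(21)
  for (i in 1:10) {
    tab <- matrix(rpois(4, 6), 2, 2)
    if (sum(tab) == 0) tab[1, 1] <- 1
    expect_equal(fisher_exact_rxc(tab)$p.value, fisher_2x2_oracle(tab),
                 tolerance = 1e-10, info = paste(tab, collapse = ","))
  }
  # r x c tables against the reference implementation
  for (i in 1:5) {
    tab <- matrix(rpois(6, 5), 3, 2)
    if (sum(tab) == 0) tab[1, 1] <- 1
    expect_equal(fisher_exact_rxc(tab)$p.value,
                 stats::fisher.test(tab)$p.value, tolerance = 1e-7)
  }
  # enumerated probabilities are a full distribution
  f <- fisher_exact_rxc(matrix(c(12, 4, 0, 4, 9, 3), nrow = 3))
  expect_equal(attr(f, "total_prob"), 1, tolerance = 1e-10)
  # balanced table is the most probable one
  expect_equal(fisher_exact_rxc(matrix(5, 2, 2))$p.value, 1)
  expect_error(fisher_exact_rxc(matrix(c(-1, 2, 3, 4), 2, 2)), "nonnegative")
})

test_that("paired t-test matches hand computation and rejects degenerate input", {
  a <- c(3, 1, 5, 2, 4); b <- c(1, 2, 2, 2, 3)  # differences 2,-1,3,0,1
  res <- paired_t_test(a, b)
  expect_equal(res$statistic, sqrt(2), tolerance = 1e-12)  # mean/(sd/sqrt(5))
  expect_equal(res$p.value, stats::t.test(a, b, paired = TRUE)$p.value)
  expect_error(paired_t_test(c(1, 2, 3), c(1, 2, 3)), "zero variance")
  expect_error(paired_t_test(c(2, 3, 4, 5), c(1, 2, 3, 4)), "zero variance")
})

test_that("paired-t power is analytic, calibrated and monotone", {
  expect_equal(power_paired_t(16, 0, 0.025, alpha = 0.05), 0.05, tolerance = 1e-12)
  expect_gt(power_paired_t(20, 0.05, 0.025), power_paired_t(10, 0.05, 0.025))
  expect_gt(power_paired_t(16, 0.06, 0.025), power_paired_t(16, 0.04, 0.025))
  expect_gt(power_paired_t(16, 0.05, 0.02), power_paired_t(16, 0.05, 0.04))
  expect_gt(power_paired_t(16, 0.03, 0.025, alpha = 0.05),
            power_paired_t(16, 0.03, 0.025, alpha = 0.001))
  # Monte-Carlo cross-check at a mid-power setting
  n <- 10; delta <- 0.02; sd <- 0.025; alpha <- 0.05; nrep <- 20000
  p_ana <- power_paired_t(n, delta, sd, alpha)
  rej <- withr::with_seed(99, {
    d <- matrix(rnorm(n * nrep, delta, sd), n)
    tt <- colMeans(d) / (apply(d, 2, sd) / sqrt(n))
    mean(abs(tt) > qt(1 - alpha / 2, n - 1))
  })
  expect_lt(abs(rej - p_ana), 3 * sqrt(p_ana * (1 - p_ana) / nrep))
})

test_that("relative discordance follows the birth-weight formula", {
  expect_equal(round(relative_discordance(2619, 1921), 3), 0.267)
  expect_equal(relative_discordance(3000, 3000), 0)
  expect_equal(relative_discordance(1000, 500), 0.5)
  expect_error(relative_discordance(1900, 2000), "exceeds")
  expect_error(relative_discordance(1000, 0), "positive")
})

test_that("the EWAS scan equals per-CpG testing and exports volcano tables", {
  sim <- simulate_reference_panel(60, 5, 0.6, seed = 3)
  coh <- simulate_cohort(sim$panel, 9, noise_sd = 0.03, seed = 3)
  tab <- paired_ewas(coh$beta, coh$design)
  for (cg in rownames(coh$beta$beta)[c(1, 17, 42)]) {
    ref <- wilcoxon_signed_rank_paired(coh$beta$beta[cg, coh$design$heavy],
                                       coh$beta$beta[cg, coh$design$light])
    expect_equal(tab$p.value[tab$cpg == cg], ref$p.value)
    expect_equal(tab$mean_diff[tab$cpg == cg],
                 mean_difference(coh$beta$beta[cg, coh$design$heavy],
                                 coh$beta$beta[cg, coh$design$light]))
  }
  expect_equal(nrow(tab), nrow(coh$beta$beta))
  path <- withr::local_tempfile(fileext = ".tsv")
  volcano_export(tab, path)
  v <- read.delim(path)
  expect_equal(nrow(v), nrow(tab))
  expect_equal(v$mean_diff, tab$mean_diff, tolerance = 1e-12)
  expect_equal(v$neglog10_p, -log10(tab$p.value), tolerance = 1e-12)
  empty <- tab[0, ]
  class(empty) <- class(tab)
  volcano_export(empty, path)
  expect_equal(nrow(read.delim(path)), 0)
})
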