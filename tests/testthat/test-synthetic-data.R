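test_that("reference panel plants exactly the requested discriminative CpGs", {
  sim <- simulate_reference_panel(1000, 10, separation = 0.7, seed = 11)
  d <- abs(sim$panel$means[, "buccal"] - sim$panel$means[, "blood"])
  expect_length(sim$truth$discriminative, 10)
  expect_setequal(names(d)[d >= 0.7], sim$truth$discriminative)
  expect_true(all(sim$panel$means >= 0 & sim$panel$means <= 1))

  none <- simulate_reference_panel(200, 0, separation = 0.5, seed = 2)
  expect_length(none$truth$discriminative, 0)
  d0 <- abs(none$panel$means[, 1] - none$panel$means[, 2])
  expect_true(all(d0 < 0.5))

  expect_error(simulate_reference_panel(0, 0, 0.5, 1), "n_cpgs")
  expect_error(simulate_reference_panel(10, 2, 1.5, 1), "separation")
  expect_error(simulate_reference_panel(10, 20, 0.5, 1), "exceeds")
})

test_that("generators are bit-reproducible under a fixed seed", {
  a <- simulate_reference_panel(300, 8, 0.6, seed = 42)
  b <- simulate_reference_panel(300, 8, 0.6, seed = 42)
  expect_identical(a$panel$means, b$panel$means)
  c1 <- simulate_cohort(a$panel, 6, seed = 9)
  c2 <- simulate_cohort(a$panel, 6, seed = 9)
  expect_identical(c1$beta$beta, c2$beta$beta)
  expect_identical(c1$beta$detp, c2$beta$detp)
  expect_identical(c1$truth$proportion, c2$truth$proportion)
  r1 <- simulate_dbs_reads(c(0.3, 0.7), 50, 0.98, seed = 5)
  r2 <- simulate_dbs_reads(c(0.3, 0.7), 50, 0.98, seed = 5)
  expect_identical(r1$calls, r2$calls)
})

test_that("degenerate mixtures reproduce the pure cell-type profiles", {
  pan <- simulate_reference_panel(100, 5, 0.6, seed = 3)$panel
  blood_only <- simulate_cohort(pan, 4, proportion_sampler = list(min = 0, max = 0),
                                noise_sd = 0, seed = 1)
  expect_equal(unname(blood_only$beta$beta[, 1]),
               unname(pan$means[, "blood"]), tolerance = 1e-14)
  buccal_only <- simulate_cohort(pan, 4, proportion_sampler = list(min = 1, max = 1),
                                 noise_sd = 0, seed = 1)
  expect_equal(unname(buccal_only$beta$beta[, 5]),
               unname(pan$means[, "buccal"]), tolerance = 1e-14)
})

test_that("noise-free cohort betas equal the convex combination exactly", {
  pan <- simulate_reference_panel(150, 6, 0.5, seed = 8)$panel
  coh <- simulate_cohort(pan, 5, noise_sd = 0, seed = 21)
  p <- coh$truth$proportion
  expected <- outer(pan$means[, "buccal"], p) +
    outer(pan$means[, "blood"], 1 - p)
  expect_equal(coh$beta$beta, expected, tolerance = 1e-14)
  expect_true(all(coh$beta$beta >= 0 & coh$beta$beta <= 1))
})

test_that("injected effects land on the requested pair member", {
  pan <- simulate_reference_panel(50, 2, 0.5, seed = 4)$panel
  cg <- rownames(pan$means)[10]
  eff <- data.frame(cpg = cg, effect = 0.1, member = "heavy")
  with_eff <- simulate_cohort(pan, 6, noise_sd = 0, seed = 2, effect_spec = eff)
  no_eff <- simulate_cohort(pan, 6, noise_sd = 0, seed = 2)
  dsg <- with_eff$design
  expect_equal(unname(with_eff$beta$beta[cg, dsg$heavy] -
                        no_eff$beta$beta[cg, dsg$heavy]),
               rep(0.1, 6), tolerance = 1e-12)
  expect_equal(with_eff$beta$beta[cg, dsg$light],
               no_eff$beta$beta[cg, dsg$light])
  expect_error(simulate_cohort(pan, 3, effect_spec = data.frame(cpg = "nope", effect = 0.1)),
               "not in panel")
})

test_that("mixture series is linear in the mixing fraction", {
  pan <- toy_panel(buccal = c(0.82, 0.4), blood = c(0.05, 0.38),
                   cpgs = c("marker", "flat"))
  ser <- simulate_mixture_series(pan, c(0, 0.5, 1), noise_sd = 0, seed = 1)
  expect_equal(unname(ser$beta$beta["marker", ]), c(0.05, 0.435, 0.82))
  one <- simulate_mixture_series(pan, 0.5, seed = 1)
  expect_equal(ncol(one$beta$beta), 1L)
  expect_error(simulate_mixture_series(pan, numeric(0)), "empty")
})

test_that("simulated bisulfite reads respect methylation and conversion extremes", {
  all_m <- simulate_dbs_reads(c(1, 1, 1), 200, conversion_rate = 0.9, seed = 1)
  expect_true(all(strsplit(paste(all_m$calls, collapse = ""), "")[[1]] == "1"))
  none <- simulate_dbs_reads(c(0, 0), 200, conversion_rate = 1, seed = 1)
  expect_true(all(strsplit(paste(none$calls, collapse = ""), "")[[1]] == "0"))
  # binomial sampling bound at intermediate methylation
  mid <- simulate_dbs_reads(0.55, 1000, conversion_rate = 1, seed = 7)
  frac <- mean(substr(mid$calls, 1, 1) == "1")
  expect_lt(abs(frac - 0.55), 3 * sqrt(0.55 * 0.45 / 1000))
  # incomplete conversion inflates apparent methylation of unmethylated CpGs
  low_conv <- simulate_dbs_reads(0, 2000, conversion_rate = 0.9, seed = 3)
  expect_gt(mean(substr(low_conv$calls, 1, 1) == "1"), 0.05)
  expect_error(simulate_dbs_reads(1.2, 10), "true_beta")
})

test_that("simulated SIRPH areas give back the methylation index", {
  exact <- simulate_sirph_assay(0.36, total_area = 1000, noise_sd = 0, seed = 1)
  expect_equal(methylation_index(exact$area_c, exact$area_t), 0.36)
  zero <- simulate_sirph_assay(0, total_area = 500, noise_sd = 0, seed = 1)
  expect_equal(zero$area_c, 0)
  expect_equal(methylation_index(zero$area_c, zero$area_t), 0)
  # Monte-Carlo: noisy areas stay unbiased for the MI
  noisy <- simulate_sirph_assay(rep(0.36, 400), total_area = 1000,
                                noise_sd = 50, seed = 6)
  expect_lt(abs(mean(methylation_index(noisy$area_c, noisy$area_t)) - 0.36), 0.02)
  expect_error(simulate_sirph_assay(0.5, total_area = 0), "total_area")
})

test_that("generated values stay inside [0, 1] across seeds", {
  for (s in 1:5) {
    pan <- simulate_reference_panel(80, 10, 0.8, seed = s)$panel
    coh <- simulate_cohort(pan, 4, noise_sd = 0.1, seed = s)
    expect_true(all(coh$beta$beta >= 0 & coh$beta$beta <= 1))
    expect_true(all(coh$truth$proportion >= 0 & coh$truth$proportion <= 1))
  }
})
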