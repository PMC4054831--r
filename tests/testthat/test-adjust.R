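test_that("discriminative screening ranks by absolute reference difference", {
  # planted buccal/blood marker at 0.82/0.05 among CpGs differing by <= 0.5
  set.seed(1)
  base <- runif(30, 0.2, 0.5)
  pan <- toy_panel(buccal = c(0.82, base + runif(30, 0, 0.4)),
                   blood = c(0.05, base),
                   cpgs = c("marker", sprintf("bg%02d", 1:30)))
  top <- screen_discriminative(pan, k = 10)
  expect_identical(top$cpg[1], "marker")
  expect_equal(top$abs_delta[1], 0.77)
  expect_true(all(diff(top$abs_delta) <= 0))

  pan3 <- toy_panel(c(0.95, 0.6, 0.35), c(0.05, 0.1, 0.25))
  expect_identical(screen_discriminative(pan3, k = 2)$cpg, c("cg01", "cg02"))
  expect_error(screen_discriminative(pan3, k = 5), "exceeds")
  # identical profiles: all-zero differences, both warnings raised
  flat <- toy_panel(c(0.5, 0.5), c(0.5, 0.5))
  expect_warning(expect_warning(screen_discriminative(flat, k = 1), "tie"),
                 "zero")
})

test_that("proportion estimation inverts the mixture at the marker", {
  pan <- toy_panel(0.82, 0.05, cpgs = "m")
  x <- toy_beta(matrix(c(0.82, 0.05, 0.435), 1, 3), cpgs = "m")
  p <- estimate_proportion(x, "m", pan)
  expect_equal(unname(p), c(1, 0, 0.5))
  expect_named(p, colnames(x$beta))
  weak <- toy_panel(0.5, 0.4, cpgs = "m")
  expect_error(estimate_proportion(x, "m", weak), "uninformative")
})

test_that("proportion recovery on a noisy mixture series beats RMSE 0.03", {
  sim <- simulate_reference_panel(400, 10, 0.7, seed = 13)
  marker <- screen_discriminative(sim$panel, k = 1)$cpg
  errs <- unlist(lapply(1:6, function(i) {
    ser <- simulate_mixture_series(sim$panel, seq(0, 1, by = 0.1),
                                   noise_sd = 0.02, seed = 100 + i)
    est <- estimate_proportion(ser$beta, marker, sim$panel)
    est - ser$truth$proportion
  }))
  expect_lt(sqrt(mean(errs^2)), 0.03)
})

test_that("marker model fitting recovers slopes, fit statistics and edge cases", {
  set.seed(7)
  m <- runif(10, 0.1, 0.9)
  Y <- rbind(marker = m, dup = m, const = rep(0.4, 10),
             noise = runif(10))
  x <- toy_beta(Y, cpgs = rownames(Y))
  fit <- fit_marker_models(x, "marker")
  expect_equal(unname(fit$coef["marker", "dup"]), 1, tolerance = 1e-12)
  expect_equal(unname(fit$coef["(Intercept)", "dup"]), 0, tolerance = 1e-12)
  expect_equal(unname(fit$r2["dup"]), 1)
  expect_true(fit$affected["dup"])
  expect_equal(unname(fit$coef["marker", "const"]), 0, tolerance = 1e-12)
  expect_equal(unname(fit$r2["const"]), 0)
  expect_false(fit$affected["const"])
  expect_false(fit$affected["marker"])   # a marker never adjusts itself

  zv <- toy_beta(rbind(marker = rep(0.5, 5), a = runif(5)),
                 cpgs = c("marker", "a"))
  expect_error(fit_marker_models(zv, "marker"), "zero variance")
  expect_error(fit_marker_models(x, "marker",
                                 exclude_samples = colnames(x$beta)[1:8]),
               "at least 3")
})

test_that("noise-free mixture slopes equal the reference-difference ratio", {
  sim <- simulate_reference_panel(60, 5, 0.6, seed = 9)
  coh <- simulate_cohort(sim$panel, 8, noise_sd = 0, seed = 9)
  marker <- screen_discriminative(sim$panel, k = 1)$cpg
  fit <- fit_marker_models(coh$beta, marker)
  dm <- sim$panel$means[marker, "buccal"] - sim$panel$means[marker, "blood"]
  dj <- sim$panel$means[, "buccal"] - sim$panel$means[, "blood"]
  others <- setdiff(rownames(sim$panel$means), marker)
  expect_equal(unname(fit$coef[marker, others]),
               unname(dj[others] / dm), tolerance = 1e-8)
})

test_that("marker selection prefers the cleanest composition proxy", {
  sim <- simulate_reference_panel(200, 6, 0.7, seed = 31)
  coh <- simulate_cohort(sim$panel, 10, noise_sd = 0.01, seed = 31)
  cand <- screen_discriminative(sim$panel, k = 2)
  x <- coh$beta
  # candidate B gets heavy independent noise on top of the mixture signal
  noisy <- cand$cpg[2]
  x$beta[noisy, ] <- pmin(pmax(
    x$beta[noisy, ] + withr::with_seed(5, rnorm(ncol(x$beta), 0, 0.3)), 0), 1)
  sel <- select_marker(x, cand$cpg)
  expect_identical(sel$marker, cand$cpg[1])
  expect_gt(sel$scores[1], sel$scores[2])
  expect_identical(select_marker(x, cand$cpg[1])$marker, cand$cpg[1])
  # identical candidates tie; first kept with a warning
  x2 <- x
  x2$beta[noisy, ] <- x2$beta[cand$cpg[1], ]
  expect_warning(tied <- select_marker(x2, cand$cpg), "tie")
  expect_identical(tied$marker, cand$cpg[1])
})

test_that("marker correlation classes count strong/moderate/weak correctly", {
  set.seed(2)
  m <- runif(8, 0.1, 0.9)
  Y <- rbind(marker = m, d1 = m, d2 = 1 - m,
             c1 = rep(0.2, 8), c2 = rep(0.5, 8), c3 = rep(0.8, 8))
  x <- toy_beta(Y, cpgs = rownames(Y))
  cl <- classify_marker_correlation(x, "marker")
  expect_equal(unname(cl$counts["strong"]), 2)
  expect_equal(unname(cl$counts["weak"]), 3)
  expect_equal(unname(cl$counts["undefined"]), 3)
  expect_false("marker" %in% names(cl$r))   # self-correlation excluded
  # mixture-driven CpGs are strongly correlated, independent ones are not
  sim <- simulate_reference_panel(20, 10, 0.8, seed = 17)
  coh <- simulate_cohort(sim$panel, 10, noise_sd = 0.01, seed = 17)
  x2 <- coh$beta
  ind <- setdiff(rownames(x2$beta), sim$truth$discriminative)[1:10]
  x2$beta[ind, ] <- matrix(withr::with_seed(3, runif(10 * ncol(x2$beta))),
                           10, ncol(x2$beta))
  marker <- sim$truth$discriminative[1]
  cl2 <- classify_marker_correlation(x2, marker)
  expect_gte(unname(cl2$counts["strong"]), 9)
})

test_that("outlier detection flags extreme-composition samples pairwise", {
  sim <- simulate_reference_panel(100, 5, 0.7, seed = 23)
  # pairs at moderate proportions, one pair planted at 0.99
  coh <- simulate_cohort(sim$panel, 8,
                         proportion_sampler = list(min = 0.2, max = 0.5),
                         noise_sd = 0.01, seed = 23)
  marker <- screen_discriminative(sim$panel, k = 1)$cpg
  a <- sim$panel$means[marker, "buccal"]; b <- sim$panel$means[marker, "blood"]
  x <- coh$beta
  x$beta[marker, c("pair01_H", "pair01_L")] <- 0.99 * a + 0.01 * b
  out <- detect_outlier_samples(x, marker, design = coh$design)
  expect_setequal(out, c("pair01_H", "pair01_L"))
  expect_identical(detect_outlier_samples(x, marker, n_mad = Inf), character(0))
  flat <- toy_beta(matrix(0.4, 1, 6), cpgs = "m")
  expect_identical(detect_outlier_samples(flat, "m"), character(0))
})

test_that("selective adjustment removes the composition component and nothing else", {
  sim <- simulate_reference_panel(300, 10, 0.7, seed = 41)
  coh <- simulate_cohort(sim$panel, 12, noise_sd = 0.02, seed = 41)
  marker <- screen_discriminative(sim$panel, k = 1)$cpg
  fit <- fit_marker_models(coh$beta, marker)
  adj <- adjust_for_composition(coh$beta, fit)

  # unaffected CpGs are bit-identical
  unaff <- names(fit$affected)[!fit$affected]
  expect_identical(adj$beta$beta[unaff, ], coh$beta$beta[unaff, ])
  # orthogonality: adjusted CpGs no longer correlate with the marker
  aff <- names(fit$affected)[fit$affected]
  m <- coh$beta$beta[marker, ]
  r <- apply(adj$beta$beta[aff, , drop = FALSE], 1, cor, y = m)
  expect_lt(max(abs(r)), 0.05)
  # idempotence: refitting on adjusted data finds ~zero slopes
  fit2 <- fit_marker_models(adj$beta, marker)
  expect_lt(max(abs(fit2$coef[marker, aff])), 1e-6)

  # noise-free mixture: adjusted CpGs become constant at the anchor value
  coh0 <- simulate_cohort(sim$panel, 12, noise_sd = 0, seed = 41)
  fit0 <- fit_marker_models(coh0$beta, marker)
  adj0 <- adjust_for_composition(coh0$beta, fit0)
  aff0 <- names(fit0$affected)[fit0$affected]
  spread <- apply(adj0$beta$beta[aff0, , drop = FALSE], 1,
                  function(v) diff(range(v)))
  expect_lt(max(spread), 1e-10)
  p_anchor <- estimate_proportion(
    toy_beta(matrix(adj0$anchor, 1, 1), cpgs = marker), marker, sim$panel)
  expected_at_anchor <- p_anchor * sim$panel$means[aff0, "buccal"] +
    (1 - p_anchor) * sim$panel$means[aff0, "blood"]
  expect_equal(unname(adj0$beta$beta[aff0, 1]),
               unname(expected_at_anchor), tolerance = 1e-8)

  expect_error(adjust_for_composition(coh$beta, fit, reference_point = 1.2),
               "reference_point")
})

test_that("adjustment preserves injected pair effects at composition-independent CpGs", {
  sim <- simulate_reference_panel(400, 10, 0.7, seed = 57)
  ind <- setdiff(rownames(sim$panel$means), sim$truth$discriminative)
  mid <- ind[sim$panel$means[ind, "blood"] > 0.2 &
               sim$panel$means[ind, "blood"] < 0.7][1:5]
  eff <- data.frame(cpg = mid, effect = 0.08, member = "heavy")
  coh <- simulate_cohort(sim$panel, 16, effect_spec = eff,
                         noise_sd = 0.02, seed = 57)
  marker <- screen_discriminative(sim$panel, k = 1)$cpg
  fit <- fit_marker_models(coh$beta, marker)
  adj <- adjust_for_composition(coh$beta, fit)
  d_before <- rowMeans(coh$beta$beta[mid, coh$design$heavy] -
                         coh$beta$beta[mid, coh$design$light])
  d_after <- rowMeans(adj$beta$beta[mid, coh$design$heavy] -
                        adj$beta$beta[mid, coh$design$light])
  expect_lt(max(abs(d_after - d_before)), 0.005)
})

test_that("multi-marker fits drop collinear markers and adjust jointly", {
  sim <- simulate_reference_panel(150, 8, 0.6, seed = 71)
  coh <- simulate_cohort(sim$panel, 10, noise_sd = 0.02, seed = 71)
  cand <- screen_discriminative(sim$panel, k = 3)
  fit <- fit_marker_models(coh$beta, cand$cpg)
  expect_length(fit$markers, 3)
  adj <- adjust_for_composition(coh$beta, fit)
  expect_true(all(adj$beta$beta >= 0 & adj$beta$beta <= 1))
  # a duplicated marker column makes the design rank-deficient
  x <- toy_beta(rbind(coh$beta$beta, cgdup = coh$beta$beta[cand$cpg[1], ]),
                cpgs = c(rownames(coh$beta$beta), "cgdup"))
  expect_warning(fit2 <- fit_marker_models(x, c(cand$cpg[1], "cgdup")),
                 "rank-deficient")
  expect_length(fit2$markers, 1)
})
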