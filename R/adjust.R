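# Marker-based cell-type heterogeneity adjustment: screen a reference
# panel for discriminatively methylated CpGs, pick the marker whose
# measurements behave most linearly across the cohort, estimate mixture
# proportions from it, and selectively remove the composition component
# from affected CpGs by ordinary least squares.

#' Screen a reference panel for discriminatively methylated CpGs
#'
#' Ranks CpGs by descending absolute between-cell-type reference beta
#' difference and returns the top `k` — the candidate marker CpGs whose
#' measured beta tracks the cell-type mixing proportion.
#'
#' @param panel a [reference_panel()].
#' @param type_a,type_b cell-type labels to contrast.
#' @param k number of top CpGs to return.
#' @return `data.frame(cpg, beta_a, beta_b, delta, abs_delta)` sorted by
#'   decreasing `abs_delta`; ties are broken by panel order with a warning.
#' @export
screen_discriminative <- function(panel, type_a = "buccal",
                                  type_b = "blood", k = 10) {
  stopifnot(inherits(panel, "ReferencePanel"))
  stop_if(!all(c(type_a, type_b) %in% colnames(panel$means)),
          "panel lacks the requested cell types")
  k <- check_count(k, "k", min = 1)
  stop_if(k > nrow(panel$means), "'k' exceeds the panel CpG count")
  d <- panel$means[, type_a] - panel$means[, type_b]
  ord <- order(-abs(d))   # stable: ties keep panel order
  ad <- abs(d)[ord]
  if (k < length(ad) && isTRUE(ad[k] == ad[k + 1]))
    warning("tie at rank k broken by panel order")
  if (all(ad == 0)) warning("all reference differences are zero")
  top <- ord[seq_len(k)]
  data.frame(cpg = rownames(panel$means)[top],
             beta_a = panel$means[top, type_a],
             beta_b = panel$means[top, type_b],
             delta = d[top], abs_delta = abs(d)[top],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Estimate per-sample cell-type proportions from a marker CpG
#'
#' Under the convex two-cell-type mixture model the observed beta at a
#' discriminative marker is linear in the mixing proportion, so
#' `p = (beta_obs - beta_b) / (beta_a - beta_b)`, truncated to \[0, 1\].
#'
#' @param x a [beta_matrix()].
#' @param marker marker CpG identifier (present in `x` and `panel`).
#' @param panel a [reference_panel()] providing the endpoint betas.
#' @param type_a,type_b cell-type labels; the result is the `type_a`
#'   fraction.
#' @param min_separation minimum `|beta_a - beta_b|` for the marker to be
#'   considered informative (default 0.3).
#' @return named numeric vector of estimated `type_a` proportions per
#'   sample.
#' @export
estimate_proportion <- function(x, marker, panel, type_a = "buccal",
                                type_b = "blood", min_separation = 0.3) {
  stopifnot(inherits(x, "BetaMatrix"), inherits(panel, "ReferencePanel"))
  stop_if(!marker %in% rownames(x$beta), sprintf("marker '%s' not in matrix", marker))
  stop_if(!marker %in% rownames(panel$means), sprintf("marker '%s' not in panel", marker))
  a <- panel$means[marker, type_a]
  b <- panel$means[marker, type_b]
  stop_if(abs(a - b) < min_separation,
          sprintf("marker '%s' is uninformative: |beta_a - beta_b| = %.3f < %.3f",
                  marker, abs(a - b), min_separation))
  p <- (x$beta[marker, ] - b) / (a - b)
  pmin(pmax(p, 0), 1)
}

#' Fit per-CpG linear models against one or more marker CpGs
#'
#' For every non-marker CpG, fits an ordinary least-squares regression of
#' its beta values on the marker beta values across the non-excluded
#' samples. The slope captures how strongly the CpG's measurement depends
#' on cell-type composition; a CpG is flagged "affected" when the overall
#' regression P-value falls below `affected_p`. CpGs with any missing
#' beta value are excluded from fitting (complete-case rule) and never
#' flagged.
#'
#' @param x a [beta_matrix()].
#' @param markers character vector of marker CpG identifiers (rows of
#'   `x`); with several markers a multiple regression is fitted. A
#'   rank-deficient marker design drops later markers with a warning.
#' @param exclude_samples sample identifiers excluded from fitting (e.g.
#'   outlier pairs).
#' @param affected_p per-CpG regression P-value threshold marking a CpG
#'   as composition-affected (default 0.01, unadjusted).
#' @return object of class `MarkerFit`: list with `markers`, `coef`
#'   (matrix, intercept + one slope per marker, CpGs in columns), `r2`,
#'   `p.value`, `affected` (logical, named by CpG), `excluded_samples`,
#'   `n_samples`, `affected_p`.
#' @export
fit_marker_models <- function(x, markers, exclude_samples = character(),
                              affected_p = 0.01) {
  stopifnot(inherits(x, "BetaMatrix"))
  stop_if(!all(markers %in% rownames(x$beta)),
          sprintf("marker '%s' not in matrix",
                  setdiff(markers, rownames(x$beta))[1]))
  keep <- setdiff(colnames(x$beta), exclude_samples)
  stop_if(length(keep) < 3, "need at least 3 non-excluded samples")
  M <- t(x$beta[markers, keep, drop = FALSE])      # samples x markers
  mvar <- apply(M, 2, stats::var)
  stop_if(any(mvar == 0 | is.na(mvar)),
          sprintf("marker '%s' has zero variance", markers[which(mvar == 0 | is.na(mvar))[1]]))
  X <- cbind(`(Intercept)` = 1, M)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop_idx <- qrX$pivot[(qrX$rank + 1):ncol(X)]
    warning(sprintf("rank-deficient marker design; dropping marker(s): %s",
                    paste(colnames(X)[drop_idx], collapse = ", ")))
    markers <- setdiff(markers, colnames(X)[drop_idx])
    X <- X[, -drop_idx, drop = FALSE]
    qrX <- qr(X)
  }
  cpgs <- rownames(x$beta)
  Y <- t(x$beta[, keep, drop = FALSE])             # samples x cpgs
  complete <- colSums(is.na(Y)) == 0
  n <- length(keep)
  m <- ncol(X) - 1
  coef <- matrix(NA_real_, ncol(X), length(cpgs),
                 dimnames = list(colnames(X), cpgs))
  r2 <- stats::setNames(rep(NA_real_, length(cpgs)), cpgs)
  pval <- stats::setNames(rep(NA_real_, length(cpgs)), cpgs)
  if (any(complete)) {
    Yc <- Y[, complete, drop = FALSE]
    B <- qr.coef(qrX, Yc)
    fitted <- X %*% B
    rss <- colSums((Yc - fitted)^2)
    tss <- colSums(sweep(Yc, 2, colMeans(Yc))^2)
    r2c <- ifelse(tss > 0, pmax(0, pmin(1, 1 - rss / tss)), 0)
    fstat <- (r2c / m) / pmax((1 - r2c) / (n - m - 1), .Machine$double.eps)
    pc <- ifelse(tss > 0, stats::pf(fstat, m, n - m - 1, lower.tail = FALSE), 1)
    coef[, complete] <- B
    r2[complete] <- r2c
    pval[complete] <- pc
  }
  affected <- !is.na(pval) & pval < affected_p
  affected[markers] <- FALSE   # markers are the adjusters, never adjusted
  structure(list(markers = markers, coef = coef, r2 = r2, p.value = pval,
                 affected = affected, excluded_samples = exclude_samples,
                 n_samples = n, affected_p = affected_p),
            class = "MarkerFit")
}

#' @export
print.MarkerFit <- function(x, ...) {
  cat(sprintf("MarkerFit: marker(s) %s, %d CpGs, %d affected (P < %g), %d samples\n",
              paste(x$markers, collapse = "+"), length(x$affected),
              sum(x$affected), x$affected_p, x$n_samples))
  invisible(x)
}

#' Select the marker CpG with the best cohort-wide linear fit
#'
#' Fits single-marker models for each candidate and scores it by the
#' number of CpGs whose regression passes the affected rule; the
#' candidate explaining composition for the largest number of CpGs wins.
#' Ties are broken by candidate order with a warning.
#'
#' @param x a [beta_matrix()].
#' @param candidates character vector of candidate marker CpGs (e.g. from
#'   [screen_discriminative()]).
#' @param exclude_samples samples excluded from fitting.
#' @param affected_p regression P threshold of the scoring rule.
#' @return list with `marker` (chosen identifier) and `scores` (named
#'   integer vector per candidate).
#' @export
select_marker <- function(x, candidates, exclude_samples = character(),
                          affected_p = 0.01) {
  stop_if(length(candidates) < 1, "need at least one candidate")
  scores <- vapply(candidates, function(m) {
    fit <- fit_marker_models(x, m, exclude_samples = exclude_samples,
                             affected_p = affected_p)
    sum(fit$affected)
  }, integer(1))
  best <- which(scores == max(scores))
  if (length(best) > 1)
    warning("tie in marker selection; keeping the first candidate")
  list(marker = candidates[best[1]], scores = scores)
}

#' Classify CpGs by correlation with a marker CpG
#'
#' Computes the Pearson correlation of every CpG with the marker across
#' samples and counts the field's conventional classes: strong
#' (`|r| > 0.8`), moderate (`0.4 <= |r| <= 0.8`) and weak (otherwise).
#' The marker itself is excluded; zero-variance CpGs get `NA` correlation,
#' class weak, and are counted separately as `undefined`.
#'
#' @param x a [beta_matrix()] with at least 3 samples.
#' @param marker marker CpG identifier.
#' @return list with `r` (named vector over non-marker CpGs) and `counts`
#'   (named vector `strong`, `moderate`, `weak`, `undefined`).
#' @export
classify_marker_correlation <- function(x, marker) {
  stopifnot(inherits(x, "BetaMatrix"))
  stop_if(ncol(x$beta) < 3, "need at least 3 samples")
  stop_if(!marker %in% rownames(x$beta), sprintf("marker '%s' not in matrix", marker))
  m <- x$beta[marker, ]
  others <- setdiff(rownames(x$beta), marker)
  r <- suppressWarnings(
    stats::cor(t(x$beta[others, , drop = FALSE]), m,
               use = "pairwise.complete.obs")[, 1])
  strong <- sum(abs(r) > 0.8, na.rm = TRUE)
  moderate <- sum(abs(r) >= 0.4 & abs(r) <= 0.8, na.rm = TRUE)
  undefined <- sum(is.na(r))
  weak <- length(r) - strong - moderate - undefined
  list(r = r, counts = c(strong = strong, moderate = moderate,
                         weak = weak + undefined, undefined = undefined))
}

#' Flag samples (and their pairs) with outlying marker values
#'
#' The marker beta is a proxy for cell-type composition; samples whose
#' marker value is more extreme than `median +/- n_mad * MAD` indicate an
#' extreme composition that the linear model cannot accommodate and are
#' excluded. When a flagged sample belongs to a pair in `design`, the
#' whole pair is excluded.
#'
#' @param x a [beta_matrix()].
#' @param marker marker CpG identifier.
#' @param design optional [twin_design()]; flags propagate to the co-twin.
#' @param n_mad MAD multiplier of the rule (default 3); `Inf` disables.
#' @return character vector of excluded sample identifiers (possibly
#'   empty).
#' @export
detect_outlier_samples <- function(x, marker, design = NULL, n_mad = 3) {
  stopifnot(inherits(x, "BetaMatrix"))
  stop_if(!marker %in% rownames(x$beta), sprintf("marker '%s' not in matrix", marker))
  if (!is.finite(n_mad)) return(character(0))
  m <- x$beta[marker, ]
  med <- stats::median(m, na.rm = TRUE)
  s <- stats::mad(m, na.rm = TRUE)
  flagged <- names(m)[!is.na(m) & s > 0 & abs(m - med) > n_mad * s]
  if (!is.null(design) && length(flagged) > 0) {
    hit <- design$heavy %in% flagged | design$light %in% flagged
    flagged <- union(flagged, c(design$heavy[hit], design$light[hit]))
  }
  sort(flagged)
}

#' Selectively adjust composition-affected CpGs
#'
#' For every CpG flagged affected in `fit`, subtracts the fitted
#' composition component: `beta_adj = beta - sum_k slope_k *
#' (marker_k - anchor_k)`, where the anchor is the reference composition
#' at which values are re-expressed (default: mean marker beta over the
#' non-excluded samples, keeping adjusted values on the observed beta
#' scale). Results are truncated to \[0, 1\] (truncations counted).
#' Non-affected CpGs and the marker CpGs themselves are copied unchanged.
#'
#' @param x the [beta_matrix()] the fit was computed on.
#' @param fit a [fit_marker_models()] result.
#' @param reference_point optional numeric vector of anchor marker
#'   values (one per marker, each in \[0, 1\]).
#' @return object of class `AdjustedMatrix`: list with `beta` (the
#'   adjusted [beta_matrix()]), `adjusted` (named logical mask),
#'   `markers`, `anchor`, `excluded_samples`, `n_truncated`.
#' @export
adjust_for_composition <- function(x, fit, reference_point = NULL) {
  stopifnot(inherits(x, "BetaMatrix"), inherits(fit, "MarkerFit"))
  stop_if(!all(names(fit$affected) %in% rownames(x$beta)),
          "fit does not match this matrix")
  keep <- setdiff(colnames(x$beta), fit$excluded_samples)
  M <- x$beta[fit$markers, , drop = FALSE]          # markers x all samples
  anchor <- if (is.null(reference_point)) {
    rowMeans(M[, keep, drop = FALSE])
  } else {
    stop_if(length(reference_point) != length(fit$markers),
            "'reference_point' needs one value per marker")
    check_fraction(reference_point, "reference_point")
    stats::setNames(as.numeric(reference_point), fit$markers)
  }
  beta <- x$beta
  aff <- names(fit$affected)[fit$affected]
  n_trunc <- 0L
  if (length(aff) > 0) {
    slopes <- t(fit$coef[fit$markers, aff, drop = FALSE])  # cpgs x markers
    shift <- slopes %*% (M - anchor)                       # cpgs x samples
    adj <- beta[aff, , drop = FALSE] - shift
    adj <- truncate01(adj)
    n_trunc <- attr(adj, "n_truncated")
    attr(adj, "n_truncated") <- NULL
    beta[aff, ] <- adj
  }
  mask <- stats::setNames(rownames(beta) %in% aff, rownames(beta))
  structure(list(beta = beta_matrix(beta, detp = x$detp, anno = x$anno),
                 adjusted = mask, markers = fit$markers, anchor = anchor,
                 excluded_samples = fit$excluded_samples,
                 n_truncated = n_trunc),
            class = "AdjustedMatrix")
}

#' @export
print.AdjustedMatrix <- function(x, ...) {
  cat(sprintf("AdjustedMatrix: %d/%d CpGs adjusted (marker %s), %d truncated value(s), %d sample(s) excluded\n",
              sum(x$adjusted), length(x$adjusted),
              paste(x$markers, collapse = "+"), x$n_truncated,
              length(x$excluded_samples)))
  invisible(x)
}
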