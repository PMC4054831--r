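# Independent oracles and small fixture builders used across tests.

# Brute-force two-sided signed-rank P by enumerating all 2^n sign
# assignments of the absolute differences (midranks, zeros dropped,
# doubling convention). Independent of the package's convolution path.
bf_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  ws <- apply(signs, 1, function(s) sum(r[s]))
  p_le <- mean(ws <= w_obs + 1e-9)
  p_ge <- mean(ws >= w_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# Closed-form two-sided Fisher P for a 2x2 table: sum of hypergeometric
# probabilities not exceeding the observed one.
fisher_2x2_oracle <- function(tab) {
  rs <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)
  ks <- max(0, cs[1] - rs[2]):min(rs[1], cs[1])
  probs <- stats::dhyper(ks, cs[1], n - cs[1], rs[1])
  p_obs <- stats::dhyper(tab[1, 1], cs[1], n - cs[1], rs[1])
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# tiny beta matrix with arbitrary values
toy_beta <- function(values, cpgs = NULL, samples = NULL, ...) {
  m <- as.matrix(values)
  if (is.null(cpgs)) cpgs <- sprintf("cg%02d", seq_len(nrow(m)))
  if (is.null(samples)) samples <- sprintf("s%02d", seq_len(ncol(m)))
  dimnames(m) <- list(cpgs, samples)
  beta_matrix(m, ...)
}

# two-cell-type panel from explicit per-type vectors
toy_panel <- function(buccal, blood, cpgs = NULL) {
  m <- cbind(buccal = buccal, blood = blood)
  if (is.null(cpgs)) cpgs <- sprintf("cg%02d", seq_len(nrow(m)))
  rownames(m) <- cpgs
  reference_panel(m)
}
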