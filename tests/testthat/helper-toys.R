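# Small deterministic builders shared across test files.

# A balanced paired study from an explicit per-batch (control, ethanol)
# log2 value matrix: rows probes, columns c(ctrl_b1..,etoh_b1..).
toy_study <- function(log2_ctrl, log2_etoh) {
  b <- ncol(log2_ctrl)
  signals <- 2^cbind(log2_ctrl, log2_etoh)
  colnames(signals) <- c(sprintf("c%d", 1:b), sprintf("e%d", 1:b))
  rownames(signals) <- rownames(log2_ctrl) %||%
    sprintf("p%02d", seq_len(nrow(log2_ctrl)))
  design <- data.frame(sample_id = colnames(signals),
                       treatment = rep(c("control", "ethanol"), each = b),
                       batch = rep(sprintf("b%d", 1:b), 2),
                       stringsAsFactors = FALSE)
  expression_study(signals, design)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Closed-form paired t-test p-value (the independent oracle for the
# randomized-block treatment F test).
paired_t_p <- function(diffs) {
  b <- length(diffs)
  tt <- mean(diffs) / (sd(diffs) / sqrt(b))
  2 * pt(-abs(tt), b - 1)
}

# Brute-force upper-tail hypergeometric via binomial coefficients only
# (independent of phyper/dhyper).
hyper_upper_brute <- function(k, K, n, N) {
  if (k == 0) return(1)
  j <- k:min(K, n)
  sum(exp(lchoose(K, j) + lchoose(N - K, n - j) - lchoose(N, n)))
}

# Random small PWM count matrix (integer counts, no all-zero rows).
random_counts <- function(width, seed) {
  set.seed(seed)
  m <- matrix(rpois(width * 4, lambda = 5), width, 4)
  m[rowSums(m) == 0, 1] <- 1
  m
}

# Exhaustive-enumeration p-values over all 4^w words for a built model:
# returns function(iscore) -> exact P(score >= iscore) under bg.
enum_pvalue_fun <- function(model, strand = "+") {
  ilo <- if (strand == "+") model$ilo else model$ilo_rc
  w <- nrow(ilo)
  words <- as.matrix(expand.grid(rep(list(1:4), w)))
  iscores <- rowSums(vapply(seq_len(w), function(i) ilo[i, words[, i]],
                            numeric(nrow(words))))
  probs <- exp(rowSums(vapply(seq_len(w), function(i) log(model$bg[words[, i]]),
                              numeric(nrow(words)))))
  o <- order(iscores, decreasing = TRUE)
  s_sorted <- iscores[o]
  cum <- cumsum(probs[o])
  function(s) {
    idx <- findInterval(-s, -s_sorted)  # last position with score >= s
    ifelse(idx == 0, 0, cum[pmax(idx, 1)])
  }
}

rand_dna <- function(n, seed, freqs = rep(0.25, 4)) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = freqs),
        collapse = "")
}
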