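test_that("log-odds entries match the hand-computed formula", {
  rec <- pwm_record("toy", rbind(c(3, 1, 0, 0), c(0, 0, 2, 2)))
  m <- build_pwm_model(rec, bg = rep(0.25, 4), pseudocount = 0.1)
  # s(i,a) = log2((c + 0.1*0.25) / (rowsum + 0.1)) - log2(0.25), by hand:
  expect_equal(unname(m$log_odds[1, 1]), log2(3.025 / 4.1) + 2, tolerance = 1e-12)
  expect_equal(unname(m$log_odds[1, 2]), log2(1.025 / 4.1) + 2, tolerance = 1e-12)
  expect_equal(unname(m$log_odds[1, 3]), log2(0.025 / 4.1) + 2, tolerance = 1e-12)
  expect_equal(unname(m$log_odds[2, 3]), log2(2.025 / 4.1) + 2, tolerance = 1e-12)
  expect_true(all(is.finite(m$log_odds)))
  expect_lte(sum(m$bg * t(m$log_odds)) / nrow(rec$counts), 0)  # E[score] <= 0

  # uniform counts + uniform bg: every entry and every window scores 0
  u <- build_pwm_model(pwm_record("u", matrix(5, 3, 4)), bg = rep(0.25, 4))
  expect_true(all(u$log_odds == 0))
  expect_equal(scan_promoter(u, "ACGTACGT", alpha = 1)$score, rep(0, 12))

  expect_error(build_pwm_model(rec, pseudocount = 0), "pseudocount")
})

test_that("width-1 null distribution is exactly the four column masses", {
  rec <- pwm_record("w1", matrix(c(2, 1, 1, 0), 1, 4))
  bg <- c(0.4, 0.1, 0.2, 0.3)
  m <- build_pwm_model(rec, bg = bg, granularity = 0.01)
  nd <- null_distribution(m)
  expect_equal(sum(nd$mass), 1, tolerance = 1e-12)
  support <- (nd$smin:nd$smax)[nd$mass > 0]
  expect_setequal(support, unique(as.integer(m$ilo)))
  for (a in 1:4) {
    expect_equal(sum(nd$mass[support - nd$smin + 1][support == m$ilo[1, a]]),
                 sum(bg[m$ilo[1, ] == m$ilo[1, a]]), tolerance = 1e-12)
  }
})

test_that("DP p-values agree with exhaustive enumeration for widths <= 8", {
  set.seed(77)
  for (rep in 1:6) {
    w <- sample(4:8, 1)
    rec <- pwm_record(sprintf("r%d", rep), random_counts(w, 700 + rep))
    bg <- as.numeric(stats::rgamma(4, 5)); bg <- bg / sum(bg)
    m <- build_pwm_model(rec, bg = bg, granularity = 0.01)
    enum_p <- enum_pvalue_fun(m)
    nd <- null_distribution(m)
    s_grid <- nd$smin:nd$smax
    expect_equal(nd$sf, enum_p(s_grid), tolerance = 1e-9)
    # consensus word p equals P(consensus under bg) for a strict-consensus matrix
  }
  strict <- pwm_record("cons", 100 * diag(4)[c(1, 3, 2, 4), ])
  bg <- c(0.3, 0.2, 0.25, 0.25)
  mc <- build_pwm_model(strict, bg = bg, pseudocount = 1e-4)
  ndc <- null_distribution(mc)
  expect_equal(ndc$sf[length(ndc$sf)], bg[1] * bg[3] * bg[2] * bg[4],
               tolerance = 1e-9)
})

test_that("scanning finds planted consensus sites and honors strand and N policy", {
  rec <- simulate_pwm(8, concentration = Inf, seed = 15, motif_id = "cons")
  m <- build_pwm_model(rec, bg = rep(0.25, 4))
  probs <- rec$counts / rowSums(rec$counts)
  consensus <- paste(c("A", "C", "G", "T")[max.col(probs)], collapse = "")

  seqv <- rand_dna(200, seed = 16)
  substr(seqv, 8, 15) <- consensus  # plant at offset 7 (0-based)
  hits <- scan_promoter(m, seqv, alpha = 1e-4)
  expect_true(any(hits$offset == 7 & hits$strand == "+"))

  # '-'-strand site is only seen when both strands are scanned
  rc_site <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(consensus)))
  seq2 <- rand_dna(200, seed = 17)
  substr(seq2, 101, 108) <- rc_site
  h_fwd <- scan_promoter(m, seq2, alpha = 1e-4, both_strands = FALSE)
  h_both <- scan_promoter(m, seq2, alpha = 1e-4, both_strands = TRUE)
  expect_false(any(h_fwd$offset == 100))
  expect_true(any(h_both$offset == 100 & h_both$strand == "-"))

  expect_equal(nrow(scan_promoter(m, strrep("N", 50), alpha = 1)), 0)
  # windows overlapping an interior N are skipped, flanks still scanned
  h_n <- scan_promoter(m, paste0(consensus, "N", consensus), alpha = 1e-4)
  expect_setequal(h_n$offset[h_n$strand == "+"], c(0, 9))
})

test_that("reverse-complement symmetry: hits map 1:1 under coordinate reflection", {
  rec <- pwm_record("asym", random_counts(6, 91))
  bg <- c(0.35, 0.15, 0.2, 0.3)  # deliberately strand-asymmetric background
  m <- build_pwm_model(rec, bg = bg)
  s <- rand_dna(120, seed = 92, freqs = bg)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  L <- nchar(s); w <- m$width
  h1 <- scan_promoter(m, s, alpha = 1)
  h2 <- scan_promoter(m, rc, alpha = 1)
  key <- function(h, flip) {
    off <- if (flip) L - w - h$offset else h$offset
    strand <- if (flip) c("+" = "-", "-" = "+")[h$strand] else h$strand
    sort(sprintf("%d%s|%.6f|%.6g", off, strand, h$score, h$p_value))
  }
  expect_identical(key(h1, FALSE), key(h2, TRUE))
})

test_that("window p-values are superuniform on background-only sequence", {
  cfg <- sim_config(n_genes = 150, promoter_length = 500, tf_count = 1,
                    planted_target_fraction = 0, seed = 51)
  rec <- simulate_pwm(8, concentration = 12, seed = 52)
  pr <- simulate_promoters(cfg, list(rec), seed = 53)
  m <- build_pwm_model(rec, bg = rep(0.25, 4))
  alpha <- 1e-3
  hits <- scan_promoter_set(m, pr$promoters, alpha = alpha)
  n_windows <- 2 * 150 * (500 - m$width + 1)
  frac <- nrow(hits) / n_windows
  expect_lte(frac, alpha + 3 * sqrt(alpha / n_windows))
})

test_that("granularity refinement only reorders windows within discretization error", {
  # entrywise rounding can perturb a window score by at most w * g / 2, so
  # coarse and fine scans may only disagree on pairs closer than w * g
  rec <- pwm_record("g", random_counts(7, 61))
  g_coarse <- 0.05
  s <- rand_dna(80, seed = 62)
  coarse <- scan_promoter(build_pwm_model(rec, granularity = g_coarse), s,
                          alpha = 1, both_strands = FALSE)
  fine <- scan_promoter(build_pwm_model(rec, granularity = 0.001), s, alpha = 1,
                        both_strands = FALSE)
  sc <- coarse$score[order(coarse$offset)]
  sf <- fine$score[order(fine$offset)]
  expect_lt(max(abs(sc - sf)), 7 * g_coarse / 2 + 1e-9)
  pairs <- utils::combn(length(sc), 2)
  d_c <- sc[pairs[1, ]] - sc[pairs[2, ]]
  d_f <- sf[pairs[1, ]] - sf[pairs[2, ]]
  bad <- d_c * d_f < 0 & abs(d_f) > 7 * g_coarse
  expect_false(any(bad))
})

test_that("target calling is idempotent, complete under saturation, and near background rate on nulls", {
  cfg <- sim_config(n_genes = 80, promoter_length = 300, tf_count = 1,
                    planted_target_fraction = 1, seed = 71)
  rec <- simulate_pwm(8, concentration = 60, seed = 72, motif_id = "sat")
  pr <- simulate_promoters(cfg, list(rec), consensus_only = TRUE, seed = 73)
  m <- build_pwm_model(rec, bg = rep(0.25, 4))
  tc1 <- call_targets(list(m), pr$promoters, alpha = 1e-4)
  tc2 <- call_targets(list(m), pr$promoters, alpha = 1e-4)
  expect_identical(tc1$calls, tc2$calls)
  expect_equal(unname(tc1$K["sat"]), 80)  # all genes planted -> K = N

  # background-only: K close to the analytic per-promoter hit probability
  cfg0 <- sim_config(n_genes = 400, promoter_length = 500, tf_count = 1,
                     planted_target_fraction = 0, seed = 74)
  pr0 <- simulate_promoters(cfg0, list(rec), seed = 75)
  alpha <- 1e-3
  tc0 <- call_targets(list(m), pr0$promoters, alpha = alpha)
  nd <- null_distribution(m)
  achieved <- max(nd$sf[nd$sf <= alpha], 0)  # discrete attained level
  n_win <- 500 - m$width + 1
  p_gene <- 1 - (1 - achieved)^(2 * n_win)
  expected_K <- 400 * p_gene
  expect_lt(abs(tc0$K[[1]] - expected_K), 3 * sqrt(400 * p_gene * (1 - p_gene)) + 3)
})
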