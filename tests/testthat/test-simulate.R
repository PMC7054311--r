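test_that("expression generator is seed-deterministic and honors zero-noise limits", {
  cfg <- sim_config(n_genes = 40, seed = 9)
  a <- simulate_expression(cfg)
  b <- simulate_expression(cfg)
  expect_identical(a, b)

  quiet <- sim_config(n_genes = 30, de_fraction = 0, batch_sd = 0, noise_sd = 0,
                      seed = 2)
  sim <- simulate_expression(quiet)
  ctrl <- sim$study$design$treatment == "control"
  expect_equal(sim$study$signals[, ctrl], sim$study$signals[, !ctrl],
               ignore_attr = TRUE)

  expect_error(simulate_expression(sim_config(n_batches = 1)), "replication")
})

test_that("planted fold changes are recovered exactly at zero noise", {
  cfg <- sim_config(n_genes = 60, de_fraction = 0.2, batch_sd = 0.4,
                    noise_sd = 0, seed = 5)
  sim <- simulate_expression(cfg)
  fc <- signed_fold_change(sim$study)
  truth <- setNames(sim$truth$signed_fc, sim$truth$gene)
  # one probe per gene: probe g0001_at1 carries gene g0001's effect;
  # linear floor at 1.0 never binds at these baselines
  est <- fc[paste0(sim$truth$gene, "_at1")]
  expect_equal(unname(est), unname(truth), tolerance = 1e-9)
})

test_that("ground truth is consistent: planted sites match promoters at recorded offsets", {
  cfg <- sim_config(n_genes = 50, promoter_length = 300, tf_count = 3,
                    planted_target_fraction = 0.3, seed = 21)
  pwms <- lapply(1:3, function(i)
    simulate_pwm(6, concentration = 10, seed = 30 + i,
                 motif_id = sprintf("TF%d", i)))
  pr <- simulate_promoters(cfg, pwms, seed = 22)
  sites <- pr$truth$planted_sites
  expect_gt(nrow(sites), 0)
  for (i in seq_len(nrow(sites))) {
    s <- sites[i, ]
    w <- nchar(s$site)
    window <- substr(pr$promoters$seq[pr$promoters$gene_id == s$gene],
                     s$offset + 1, s$offset + w)
    planted <- if (s$strand == "+") s$site else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(s$site)))
    expect_identical(window, planted)
  }
  # every mapped target has at least one recorded site
  for (tf in names(pr$truth$tf_target_map)) {
    expect_true(all(pr$truth$tf_target_map[[tf]] %in%
                      sites$gene[sites$tf == tf]))
  }
})

test_that("simulated PWM concentration controls information content and is deterministic", {
  cons <- simulate_pwm(6, concentration = Inf, seed = 4)
  expect_true(all(apply(cons$counts, 1, function(r) sum(r > 0)) == 1))

  flat <- simulate_pwm(6, concentration = 0.001, seed = 4)
  probs <- flat$counts / rowSums(flat$counts)
  ic <- sum(apply(probs, 1, function(p) {
    p <- p[p > 0]; 2 + sum(p * log2(p))
  }))
  expect_lt(ic, 0.1)

  expect_identical(simulate_pwm(7, 5, seed = 11), simulate_pwm(7, 5, seed = 11))
})

test_that("null simulations feed the ANOVA uniform p-values", {
  for (seed in 1:3) {
    cfg <- sim_config(n_genes = 800, de_fraction = 0, seed = seed)
    sim <- simulate_expression(cfg)
    p <- anova_treatment(sim$study)
    expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
  }
})

test_that("qPCR generator recovers truth through the ddCT route", {
  fcs <- c(target = 0.5, ref = 1)
  ct <- simulate_qpcr(fcs, "ref", ct_noise_sd = 0, seed = 8)
  expect_identical(ct, simulate_qpcr(fcs, "ref", ct_noise_sd = 0, seed = 8))
  r <- ddct_fold_change(ct, "target", "ref")
  expect_equal(r$fold_change, 0.5, tolerance = 1e-12)
  expect_equal(r$signed_fc, -2, tolerance = 1e-12)

  # noise 0.1 over 3 experiments x triplicates: mean recovery within 10%
  recovered <- vapply(1:20, function(s) {
    ddct_fold_change(simulate_qpcr(fcs, "ref", ct_noise_sd = 0.1, seed = 100 + s),
                     "target", "ref")$fold_change
  }, 0)
  expect_lt(abs(mean(recovered) - 0.5) / 0.5, 0.1)

  expect_error(simulate_qpcr(c(a = 2, ref = 1.5), "ref"), "fold change 1")
})
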