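test_that("detection filter applies the >= 0.50 in-either-treatment rule", {
  b <- 6
  signals <- matrix(100, 3, 2 * b,
                    dimnames = list(c("p1", "p2", "p3"),
                                    c(sprintf("c%d", 1:b), sprintf("e%d", 1:b))))
  design <- data.frame(sample_id = colnames(signals),
                       treatment = rep(c("control", "ethanol"), each = b),
                       batch = rep(sprintf("b%d", 1:b), 2))
  flags <- rbind(c(rep(TRUE, 3), rep(FALSE, 3), rep(FALSE, 6)),  # 3/6 and 0/6
                 c(rep(TRUE, 2), rep(FALSE, 4), rep(TRUE, 2), rep(FALSE, 4)),  # 2/6, 2/6
                 rep(TRUE, 12))
  dimnames(flags) <- dimnames(signals)
  study <- expression_study(signals, design, detection_flags = flags)
  kept <- filter_detected(study)
  expect_equal(rownames(kept$signals), c("p1", "p3"))  # 3/6 = 0.50 retained
  expect_equal(attr(kept, "n_removed"), 1L)

  all_present <- expression_study(signals, design,
                                  detection_flags = matrix(TRUE, 3, 12,
                                                           dimnames = dimnames(signals)))
  expect_equal(rownames(filter_detected(all_present)$signals), rownames(signals))

  none <- expression_study(signals, design,
                           detection_flags = matrix(FALSE, 3, 12,
                                                    dimnames = dimnames(signals)))
  expect_error(filter_detected(none), "no probes")
})

test_that("treatment ANOVA equals the paired t-test and degenerates to p = 1", {
  set.seed(31)
  b <- 6
  ctrl <- matrix(rnorm(5 * b, 8, 1), 5, b)
  etoh <- ctrl + matrix(rep(c(0, 0.2, 0.5, -0.4, 1), b), 5, b) +
    matrix(rnorm(5 * b, 0, 0.1), 5, b)
  study <- toy_study(ctrl, etoh)
  p_anova <- anova_treatment(study)
  for (i in 1:5) {
    expect_equal(unname(p_anova[i]), paired_t_p(etoh[i, ] - ctrl[i, ]),
                 tolerance = 1e-12)
  }
  # cross-check against aov() on one probe
  y <- log2(study$signals)[2, ]
  df <- data.frame(v = y, tr = factor(study$design$treatment),
                   bt = factor(study$design$batch))
  expect_equal(unname(p_anova[2]),
               summary(stats::aov(v ~ tr + bt, df))[[1]]["tr", "Pr(>F)"],
               tolerance = 1e-12)

  same <- toy_study(ctrl, ctrl)
  expect_true(all(anova_treatment(same) == 1))

  unbalanced <- study
  unbalanced$design$batch[1] <- "b2"
  expect_error(anova_treatment(unbalanced), "b1|b2")
})

test_that("signed fold change follows the signed-ratio convention and is antisymmetric", {
  ctrl <- matrix(log2(c(100, 100, 100)), 3, 4)
  etoh <- matrix(log2(c(50, 100, 182)), 3, 4)
  study <- toy_study(ctrl, etoh)
  fc <- signed_fold_change(study)
  expect_equal(unname(fc), c(-2, 1, 1.82), tolerance = 1e-12)

  swapped <- study
  swapped$design$treatment <- rev(swapped$design$treatment)
  fc_sw <- signed_fold_change(swapped)
  expect_equal(unname(fc_sw[c(1, 3)]), -unname(fc[c(1, 3)]), tolerance = 1e-12)
  expect_true(all(abs(fc) >= 1))
})

test_that("Storey q-values reduce to BH at pi0 = 1 and behave at the boundaries", {
  for (seed in 1:25) {
    set.seed(seed)
    p <- runif(200)^runif(1, 0.5, 2)
    expect_identical(storey_qvalue(p, pi0 = 1)$qvalues, p.adjust(p, "BH"))
  }
  expect_true(all(storey_qvalue(rep(1, 50))$qvalues == 1))
  expect_error(storey_qvalue(numeric(0)), "empty")
  # q is monotone nondecreasing in p
  set.seed(3); p <- runif(300)
  q <- storey_qvalue(p)$qvalues
  expect_true(all(diff(q[order(p)]) >= -1e-15))
})

test_that("pi0 estimation on uniform nulls stays in [0.9, 1] for most seeds", {
  hits <- vapply(1:20, function(s) {
    set.seed(1000 + s)
    pi0 <- storey_qvalue(runif(10000))$pi0
    pi0 >= 0.9 && pi0 <= 1
  }, TRUE)
  expect_gte(sum(hits), 18)
})

test_that("dysregulation call uses the printed boundary semantics", {
  fc <- c(-1.25, 1.24, -3, 2)
  p <- c(0.029, 0.001, 0.03, 0.0001)
  q <- c(0.15, 0.01, 0.1, 0.01)
  expect_identical(select_dysregulated(fc, p, q), c(TRUE, FALSE, FALSE, TRUE))
})

test_that("probe collapse keeps the best probe and counts the mapping loss", {
  probe_table <- data.frame(
    probe_id = c("pA1", "pA2", "pB1", "pX"),
    signed_fc = c(1.5, -2.0, 1.3, 3.0),
    p = c(0.01, 0.01, 0.2, 0.001),
    q = c(0.05, 0.05, 0.4, 0.01),
    dysregulated = c(TRUE, TRUE, FALSE, TRUE),
    stringsAsFactors = FALSE)
  map <- data.frame(probe_id = c("pA1", "pA2", "pB1"),
                    gene_id = c("geneA", "geneA", "geneB"),
                    stringsAsFactors = FALSE)
  out <- collapse_probes_to_genes(probe_table, map)
  expect_equal(out$gene_id, c("geneA", "geneB"))
  # tie on p broken by larger |fc|
  expect_equal(out$probe_id[out$gene_id == "geneA"], "pA2")
  expect_equal(attr(out, "counts"),
               c(probes_in = 4, probes_mapped = 3, genes_out = 2))
})

test_that("TF annotation is case-sensitive membership; fixture symbols flag 61 genes", {
  gt <- data.frame(gene_id = c("sox2", "SOX2", "her7"), stringsAsFactors = FALSE)
  expect_identical(annotate_tfs(gt, "sox2")$is_tf, c(TRUE, FALSE, FALSE))
  expect_false(any(annotate_tfs(gt, character(0))$is_tf))

  t2 <- table2_fixture()
  universe <- data.frame(gene_id = c(unique(t2$gene_symbol),
                                     sprintf("other%02d", 1:40)),
                         stringsAsFactors = FALSE)
  flagged <- annotate_tfs(universe, t2$gene_symbol)
  expect_equal(sum(flagged$is_tf), 61)
})

test_that("planted-truth recovery: realized FDP stays within the nominal FDR", {
  fd <- 0L; calls <- 0L
  for (seed in 1:20) {
    cfg <- sim_config(n_genes = 400, de_fraction = 0.1, seed = 4000 + seed)
    sim <- simulate_expression(cfg)
    res <- run_diffexpr(sim$study, sim$probe2gene)
    called <- res$gene_table$gene_id[res$gene_table$dysregulated]
    truth <- sim$truth$gene[sim$truth$is_de]
    fd <- fd + length(setdiff(called, truth))
    calls <- calls + length(called)
  }
  fdp <- fd / max(calls, 1)
  tol <- 1.96 * sqrt(0.15 * 0.85 / max(calls, 1))
  expect_lte(fdp, 0.15 + tol)
  expect_gt(calls, 100)  # the stage actually detects signal
})
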