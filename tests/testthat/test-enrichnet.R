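test_that("upper-tail hypergeometric matches brute-force combinatorics", {
  expect_equal(hypergeom_upper_tail(0, 5, 5, 20), 1)
  expect_equal(hypergeom_upper_tail(2, 2, 2, 4), 1 / 6, tolerance = 1e-12)
  expect_equal(hypergeom_upper_tail(7, 25, 7, 25), 1)  # K = N: all are targets

  # randomized spot grid against the lchoose oracle
  set.seed(12)
  for (i in 1:200) {
    N <- sample(2:40, 1); K <- sample(0:N, 1); n <- sample(0:N, 1)
    k <- sample(0:min(K, n), 1)
    expect_equal(hypergeom_upper_tail(k, K, n, N), hyper_upper_brute(k, K, n, N),
                 tolerance = 1e-10)
  }
  expect_error(hypergeom_upper_tail(3, 2, 5, 10), "k <= min")
  expect_error(hypergeom_upper_tail(1, 11, 5, 10), "K <= N")
})

test_that("enrichment table is sorted, bounded, and prints Table-3-style rounding", {
  targets <- list(tfA = c("g1", "g2", "g3"), tfB = c("g4", "g5"),
                  tfC = c("g1", "g2"))
  universe <- sprintf("g%d", 1:20)
  de <- c("g1", "g2", "g3")
  enr <- enrich_all(targets, de, universe)
  expect_equal(enr$tf[1], "tfA")                 # targets == DE set: smallest p
  expect_equal(enr$k[enr$tf == "tfA"], 3)
  expect_true(all(diff(enr$p_value) >= 0))
  expect_true(all(enr$k <= pmin(enr$K, enr$n)))
  expect_equal(enr$neglog10_p, -log10(enr$p_value), tolerance = 1e-9)

  fmt <- format_enrichment(data.frame(tf = "x", K = 10, k = 5, n = 20, N = 100,
                                      p_value = 0.056693,
                                      neglog10_p = -log10(0.056693)))
  expect_equal(fmt$p_value, "0.0567")
  expect_equal(fmt$neglog10_p, "1.2465")
  expect_equal(round(10^(-as.numeric(fmt$neglog10_p)), 4),
               as.numeric(fmt$p_value))

  expect_error(enrich_all(targets, character(0), universe), "empty")
  expect_error(enrich_all(targets, "not_there", universe), "universe")
})

test_that("null enrichment p-values are superuniform", {
  set.seed(42)
  universe <- sprintf("g%03d", 1:300)
  de <- sample(universe, 40)
  pvals <- replicate(300, {
    targets <- list(tf = sample(universe, 30))  # independent of DE status
    enrich_all(targets, de, universe)$p_value
  })
  for (a in c(0.05, 0.1, 0.25)) {
    expect_lte(mean(pvals <= a), a + 3 * sqrt(a * (1 - a) / length(pvals)))
  }
})

test_that("three-way overlap counts match brute-force classification", {
  expect_equal(unname(overlap3(c("a", "b"), c("c"), c("d"))[4:10]),
               c(2, 1, 1, 0, 0, 0, 0))
  same <- c("x", "y", "z")
  o <- overlap3(same, same, same)
  expect_equal(unname(o[["ABC"]]), 3)
  expect_equal(sum(o[4:10]), 3)

  set.seed(5)
  ids <- sprintf("i%02d", 1:40)
  A <- sample(ids, 15); B <- sample(ids, 20); C <- sample(ids, 10)
  o <- overlap3(A, B, C)
  brute <- table(factor(paste0(ifelse(ids %in% A, "A", ""),
                               ifelse(ids %in% B, "B", ""),
                               ifelse(ids %in% C, "C", "")),
                        levels = c("A", "B", "C", "AB", "AC", "BC", "ABC")))
  expect_equal(unname(o[4:10]), as.integer(brute))
  expect_equal(sum(o[4:10]), length(unique(c(A, B, C))))
})

test_that("network assembly restricts edges to dysregulated nodes and recounts consistently", {
  gt <- data.frame(gene_id = c("tf1", "tf2", "g1", "g2", "g3"),
                   dysregulated = c(TRUE, TRUE, TRUE, TRUE, FALSE),
                   is_tf = c(TRUE, TRUE, FALSE, FALSE, FALSE),
                   stringsAsFactors = FALSE)
  targets <- list(tf1 = c("g1", "g3", "tf1"), tf2 = c("g1", "g2"))
  net <- build_network(targets, gt)
  # g3 not dysregulated -> excluded; tf1 self-edge kept and flagged
  expect_equal(net$summary,
               c(n_edges = 4, n_tfs = 2, n_targets = 3))
  expect_true(net$edges$self[net$edges$tf == "tf1" & net$edges$target == "tf1"])
  expect_equal(unname(net$in_degree["g1"]), 2L)

  prof <- shared_target_profile(net)
  expect_equal(sum(vapply(prof$regulators, length, 0L)),
               unname(net$summary["n_edges"]))  # handshake identity

  none <- build_network(targets, transform(gt, dysregulated = FALSE))
  expect_equal(unname(none$summary), c(0, 0, 0))

  # summary triple survives an export/import round trip
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_edge_table(net$edges, tsv)
  back <- read_edge_table(tsv)
  expect_equal(c(nrow(back), length(unique(back$tf)), length(unique(back$target))),
               unname(net$summary))
})

test_that("fully connected bipartite toy has uniform in-degrees", {
  tfs <- c("t1", "t2", "t3"); tg <- c("a", "b", "c", "d")
  gt <- data.frame(gene_id = c(tfs, tg), dysregulated = TRUE,
                   is_tf = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
                   stringsAsFactors = FALSE)
  net <- build_network(setNames(rep(list(tg), 3), tfs), gt)
  expect_true(all(net$in_degree == 3))
  expect_equal(unname(net$summary["n_edges"]), 12)
})
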