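# Synthetic-data generators. These define the study conditions the test
# suite and worked examples run under: a paired control/ethanol design with
# 6 batches, log2-scale batch and residual noise, a planted DE fraction
# with signed fold changes >= 1.25, 2 kb promoters with motif sites planted
# in a controlled fraction of genes per TF, and triplicated qPCR Ct values.

#' Simulation configuration
#'
#' Defaults emulate the motivating study design: 2000 genes, 6 paired
#' control/ethanol batches (12 arrays), a 10% dysregulated fraction with
#' signed fold-change magnitudes drawn uniformly from \[1.25, 3\],
#' log2-scale batch effects (SD 0.3) shared by the two samples of a batch,
#' residual log2 noise (SD 0.25), 2000-base promoters, 5 transcription
#' factors each planting sites in 10% of genes, with dysregulated genes
#' 3-fold more likely to be chosen as planted targets (so TF-target
#' enrichment in the DE set is real but not trivial).
#'
#' @param n_genes number of genes.
#' @param n_probes_per_gene probes per gene: a single integer, or a vector
#'   of per-gene probe counts (length `n_genes`).
#' @param n_batches paired batches; each contributes one control and one
#'   ethanol sample.
#' @param de_fraction fraction of genes with a planted treatment effect.
#' @param fc_range range of planted fold-change magnitudes (signed-ratio
#'   scale; sign is random).
#' @param batch_sd SD of the additive log2 batch effect.
#' @param noise_sd SD of the residual log2 noise.
#' @param baseline_range range of per-gene log2 baselines.
#' @param promoter_length promoter window length in bases.
#' @param tf_count number of simulated transcription factors / PWMs.
#' @param planted_target_fraction fraction of genes that receive at least
#'   one planted site per TF.
#' @param de_target_weight relative sampling weight of a dysregulated gene
#'   (vs a null gene) when planted targets are drawn; 1 = independent.
#' @param background_freqs promoter background base frequencies (A,C,G,T).
#' @param seed integer RNG seed.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000L, n_probes_per_gene = 1L, n_batches = 6L,
                       de_fraction = 0.1, fc_range = c(1.25, 3.0),
                       batch_sd = 0.3, noise_sd = 0.25,
                       baseline_range = c(6, 12),
                       promoter_length = 2000L, tf_count = 5L,
                       planted_target_fraction = 0.1, de_target_weight = 3,
                       background_freqs = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                       seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              n_probes_per_gene = n_probes_per_gene,
              n_batches = as.integer(n_batches),
              de_fraction = de_fraction, fc_range = fc_range,
              batch_sd = batch_sd, noise_sd = noise_sd,
              baseline_range = baseline_range,
              promoter_length = as.integer(promoter_length),
              tf_count = as.integer(tf_count),
              planted_target_fraction = planted_target_fraction,
              de_target_weight = de_target_weight,
              background_freqs = check_bg(background_freqs),
              seed = as.integer(seed))
  if (cfg$de_fraction < 0 || cfg$de_fraction > 1) abort("de_fraction must be in [0,1]")
  if (cfg$planted_target_fraction < 0 || cfg$planted_target_fraction > 1) {
    abort("planted_target_fraction must be in [0,1]")
  }
  if (cfg$batch_sd < 0 || cfg$noise_sd < 0) abort("SDs must be >= 0")
  if (any(cfg$fc_range < 1)) abort("fc_range magnitudes must be >= 1")
  if (cfg$de_target_weight <= 0) abort("de_target_weight must be > 0")
  class(cfg) <- "sim_config"
  cfg
}

gene_ids <- function(n) sprintf("g%04d", seq_len(n))

#' Simulate a paired control/ethanol expression study
#'
#' Log2 signal = gene baseline + batch effect (shared by the batch's two
#' samples) + treatment effect (log2 of the planted fold change, ethanol
#' samples of DE genes only) + residual noise. Signals are exported on the
#' linear scale, floored at 1.0, to mimic MAS5-style input.
#'
#' @param config a [sim_config()].
#' @return List with `study` (an [expression_study()]), `probe2gene`
#'   (data frame), and `truth` (data frame of `gene`, `signed_fc`,
#'   `is_de`).
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_batches < 2) abort("n_batches must be >= 2 (the ANOVA needs replication)")
  set.seed(config$seed)

  genes <- gene_ids(config$n_genes)
  nprobe <- if (length(config$n_probes_per_gene) == 1) {
    rep(as.integer(config$n_probes_per_gene), config$n_genes)
  } else {
    as.integer(rep_len(config$n_probes_per_gene, config$n_genes))
  }
  probe_gene <- rep(genes, nprobe)
  probe_id <- paste0(probe_gene, "_at",
                     unlist(lapply(nprobe, seq_len)))
  n_probes <- length(probe_id)

  n_de <- round(config$de_fraction * config$n_genes)
  de_genes <- if (n_de > 0) sample(genes, n_de) else character(0)
  fc_mag <- runif(n_de, config$fc_range[1], config$fc_range[2])
  fc_sign <- sample(c(-1, 1), n_de, replace = TRUE)
  signed_fc <- setNames(ifelse(fc_sign > 0, fc_mag, -fc_mag), de_genes)
  log2_effect <- setNames(fc_sign * log2(fc_mag), de_genes)

  baseline <- setNames(runif(config$n_genes, config$baseline_range[1],
                             config$baseline_range[2]), genes)
  batch_eff <- rnorm(config$n_batches, 0, config$batch_sd)

  b <- config$n_batches
  sample_id <- c(sprintf("ctrl_b%d", seq_len(b)), sprintf("etoh_b%d", seq_len(b)))
  design <- data.frame(sample_id = sample_id,
                       treatment = rep(c("control", "ethanol"), each = b),
                       batch = rep(sprintf("b%d", seq_len(b)), 2),
                       stringsAsFactors = FALSE)

  eff <- ifelse(probe_gene %in% de_genes, log2_effect[probe_gene], 0)
  m <- matrix(baseline[probe_gene], n_probes, 2 * b)
  m <- m + matrix(rep(batch_eff, 2), n_probes, 2 * b, byrow = TRUE)
  m[, (b + 1):(2 * b)] <- m[, (b + 1):(2 * b)] + eff
  m <- m + matrix(rnorm(n_probes * 2 * b, 0, config$noise_sd), n_probes)
  signals <- pmax(2^m, 1.0)
  dimnames(signals) <- list(probe_id, sample_id)

  truth <- data.frame(gene = genes,
                      signed_fc = ifelse(genes %in% de_genes, signed_fc[genes], 1),
                      is_de = genes %in% de_genes,
                      stringsAsFactors = FALSE)
  list(study = expression_study(signals, design),
       probe2gene = data.frame(probe_id = probe_id, gene_id = probe_gene,
                               stringsAsFactors = FALSE),
       truth = truth)
}

#' Simulate a PWM with controlled information content
#'
#' Per column, one preferred base is drawn and the column probabilities are
#' the mixture `(uniform + concentration * onehot) / (1 + concentration)`,
#' scaled to `nsites` counts. `concentration -> Inf` gives a consensus-only
#' matrix; `concentration -> 0` a near-uniform one (information content
#' -> 0).
#'
#' @param width motif width (>= 4).
#' @param concentration nonnegative sharpness parameter.
#' @param seed integer RNG seed.
#' @param nsites count total per column.
#' @param motif_id motif name.
#' @return A [pwm_record()].
#' @export
simulate_pwm <- function(width, concentration = 10, seed = 1L, nsites = 100L,
                         motif_id = sprintf("sim_w%d_s%d", width, seed)) {
  if (width < 4) abort("width must be >= 4")
  set.seed(seed)
  pref <- sample.int(4, width, replace = TRUE)
  w <- if (is.finite(concentration)) concentration / (1 + concentration) else 1
  probs <- matrix((1 - w) / 4, width, 4)
  probs[cbind(seq_len(width), pref)] <- probs[cbind(seq_len(width), pref)] + w
  counts <- round(probs * nsites)
  counts[rowSums(counts) == 0, ] <- 1  # guard vs pathological rounding
  pwm_record(motif_id, counts, "synthetic")
}

#' Simulate promoters with planted motif sites
#'
#' Background sequence is i.i.d. under `config$background_freqs`. For each
#' TF, `planted_target_fraction` of the genes receive one site sampled from
#' the PWM's per-position base distribution (or its consensus when
#' `consensus_only = TRUE`) at a uniform random non-overlapping position on
#' a uniform random strand. If `de_genes` is supplied, dysregulated genes
#' are `de_target_weight`-times as likely to be chosen as planted targets,
#' which makes downstream TF-target enrichment in the DE set real.
#'
#' @param config a [sim_config()].
#' @param pwms list of [pwm_record()]s (one per TF).
#' @param de_genes optional character vector of dysregulated gene ids.
#' @param consensus_only plant exact consensus sites (for recall tests).
#' @param seed RNG seed (defaults to `config$seed + 1`).
#' @return List with `promoters` (a [promoter_set()]) and `truth`: a list
#'   with `tf_target_map` (named list) and `planted_sites` (data frame of
#'   tf, gene, offset, strand, site).
#' @export
simulate_promoters <- function(config, pwms, de_genes = NULL,
                               consensus_only = FALSE, seed = config$seed + 1L) {
  stopifnot(inherits(config, "sim_config"))
  if (length(pwms) == 0) abort("pwms must be nonempty")
  set.seed(seed)
  L <- config$promoter_length
  genes <- gene_ids(config$n_genes)
  bg <- config$background_freqs

  seqs <- vapply(genes, function(g) {
    paste(sample(DNA_BASES, L, replace = TRUE, prob = bg), collapse = "")
  }, "")
  occupied <- lapply(genes, function(g) integer(0))  # used positions per gene
  names(occupied) <- genes

  sites <- list()
  tf_map <- list()
  for (p in pwms) {
    w <- nrow(p$counts)
    if (w > L) abort("promoter length %d too short for motif %s (width %d)", L, p$motif_id, w)
    probs <- p$counts / rowSums(p$counts)
    n_t <- round(config$planted_target_fraction * config$n_genes)
    wts <- rep(1, config$n_genes)
    if (!is.null(de_genes)) wts[genes %in% de_genes] <- config$de_target_weight
    targets <- if (n_t > 0) sample(genes, n_t, prob = wts) else character(0)
    tf_map[[p$motif_id]] <- targets
    for (g in targets) {
      site <- if (consensus_only) {
        paste(DNA_BASES[max.col(probs, ties.method = "first")], collapse = "")
      } else {
        paste(vapply(seq_len(w), function(i) sample(DNA_BASES, 1, prob = probs[i, ]), ""),
              collapse = "")
      }
      strand <- sample(c("+", "-"), 1)
      ins <- if (strand == "+") site else revcomp_chr(site)
      # non-overlapping placement so every recorded site survives later plants
      for (try in 1:100) {
        off <- sample.int(L - w + 1, 1) - 1L
        if (!any((off:(off + w - 1)) %in% occupied[[g]])) break
        off <- NA_integer_
      }
      if (is.na(off)) next  # promoter too crowded; skip this plant
      substr(seqs[g], off + 1, off + w) <- ins
      occupied[[g]] <- c(occupied[[g]], off:(off + w - 1))
      sites[[length(sites) + 1]] <- data.frame(
        tf = p$motif_id, gene = g, offset = off, strand = strand,
        site = site, stringsAsFactors = FALSE)
    }
  }
  planted <- if (length(sites)) do.call(rbind, sites) else {
    data.frame(tf = character(), gene = character(), offset = integer(),
               strand = character(), site = character(), stringsAsFactors = FALSE)
  }
  # genes whose plant was skipped (crowding) drop out of the target map
  for (id in names(tf_map)) {
    tf_map[[id]] <- intersect(tf_map[[id]], planted$gene[planted$tf == id])
  }
  list(promoters = promoter_set(genes, seqs),
       truth = list(tf_target_map = tf_map, planted_sites = planted))
}

#' Simulate a qPCR Ct table under perfect amplification efficiency
#'
#' Ct = per-gene baseline - log2(expression) + per-(group, experiment)
#' sample offset + replicate noise. The sample offset models loading
#' differences and cancels exactly under reference-gene normalization. The
#' reference gene must have true fold change 1.
#'
#' @param true_fold_changes named vector of linear-scale treated/control
#'   expression ratios (e.g. 0.5 for 2-fold down), reference gene included
#'   with value 1.
#' @param reference_gene id of the reference (internal-control) gene.
#' @param ct_noise_sd replicate-level Ct noise SD (cycles).
#' @param seed RNG seed.
#' @param n_experiments independent experiments (default 3).
#' @param n_replicates technical replicates per sample (default 3).
#' @param sample_offset_sd SD of the per-sample global Ct offset.
#' @return A Ct data frame (columns gene, sample_group, experiment,
#'   replicate, ct).
#' @export
simulate_qpcr <- function(true_fold_changes, reference_gene, ct_noise_sd = 0,
                          seed = 1L, n_experiments = 3L, n_replicates = 3L,
                          sample_offset_sd = 0.5) {
  if (!reference_gene %in% names(true_fold_changes)) {
    abort("reference gene '%s' missing from true_fold_changes", reference_gene)
  }
  if (abs(true_fold_changes[[reference_gene]] - 1) > 1e-12) {
    abort("reference gene must have true fold change 1")
  }
  set.seed(seed)
  genes <- names(true_fold_changes)
  base_ct <- setNames(runif(length(genes), 18, 28), genes)
  rows <- expand.grid(gene = genes, sample_group = c("control", "treated"),
                      experiment = seq_len(n_experiments),
                      replicate = seq_len(n_replicates),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  off <- matrix(rnorm(2 * n_experiments, 0, sample_offset_sd), 2, n_experiments)
  expr <- ifelse(rows$sample_group == "treated",
                 true_fold_changes[rows$gene], 1)
  rows$ct <- base_ct[rows$gene] - log2(expr) +
    off[cbind(match(rows$sample_group, c("control", "treated")), rows$experiment)] +
    rnorm(nrow(rows), 0, ct_noise_sd)
  rows[c_order(rows$gene, rows$sample_group, rows$experiment, rows$replicate), ,
       drop = FALSE]
}
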