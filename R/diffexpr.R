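# Differential-expression stage: detection filtering, two-factor
# (treatment + batch) ANOVA on log2 signals, signed fold changes on the
# linear scale, Storey q-values, and the 1.25 / 0.15 / 0.03 selection rule.

#' Construct an expression study
#'
#' @param signals positive probe x sample matrix on the linear scale;
#'   column names must match `design$sample_id`.
#' @param design data frame with columns `sample_id`, `treatment`
#'   (control/ethanol), `batch`; every batch must contain both treatments.
#' @param detection_flags optional logical probe x sample matrix of
#'   present/absent calls; when absent, [filter_detected()] applies a
#'   signal-floor surrogate.
#' @return An object of class `ExpressionStudy`.
#' @export
expression_study <- function(signals, design, detection_flags = NULL) {
  signals <- as.matrix(signals)
  if (is.null(colnames(signals)) || !identical(sort(colnames(signals)),
                                               sort(design$sample_id))) {
    abort("signal column names must match design sample ids")
  }
  signals <- signals[, design$sample_id, drop = FALSE]
  if (any(!is.finite(signals)) || any(signals <= 0)) {
    abort("signals must be finite and > 0 (linear scale)")
  }
  if (!all(design$treatment %in% c("control", "ethanol"))) {
    abort("treatment must be 'control' or 'ethanol'")
  }
  tab <- table(design$batch, design$treatment)
  bad <- rownames(tab)[tab[, "control"] == 0 | tab[, "ethanol"] == 0]
  if (length(bad)) {
    abort("batch(es) missing a treatment arm: %s", paste(bad, collapse = ", "))
  }
  if (!is.null(detection_flags)) {
    detection_flags <- as.matrix(detection_flags)[, design$sample_id, drop = FALSE]
    stopifnot(identical(dim(detection_flags), dim(signals)))
  }
  structure(list(signals = signals, design = design,
                 detection_flags = detection_flags),
            class = "ExpressionStudy")
}

#' @export
print.ExpressionStudy <- function(x, ...) {
  cat(sprintf("ExpressionStudy: %d probes x %d samples (%d batches)\n",
              nrow(x$signals), ncol(x$signals), length(unique(x$design$batch))))
  invisible(x)
}

#' Detection-fraction filter
#'
#' Retains probes whose fraction of present calls is at least
#' `detect_frac` within the control samples or within the ethanol samples.
#' When the study carries no detection flags, a surrogate call is used: a
#' probe is present in a sample when its signal exceeds that array's
#' `floor_quantile` signal quantile.
#'
#' @param study an [expression_study()].
#' @param detect_frac minimum present fraction in at least one treatment
#'   (default 0.50).
#' @param floor_quantile per-array quantile defining the surrogate
#'   presence floor (default 0.20).
#' @return The filtered study; attribute `n_removed` counts dropped probes.
#' @export
filter_detected <- function(study, detect_frac = 0.5, floor_quantile = 0.2) {
  flags <- study$detection_flags
  if (is.null(flags)) {
    floors <- apply(study$signals, 2, quantile, probs = floor_quantile, names = FALSE)
    flags <- sweep(study$signals, 2, floors, ">")
  }
  ctrl <- study$design$treatment == "control"
  frac_c <- rowMeans(flags[, ctrl, drop = FALSE])
  frac_e <- rowMeans(flags[, !ctrl, drop = FALSE])
  keep <- frac_c >= detect_frac | frac_e >= detect_frac
  if (!any(keep)) abort("no probes pass the detection filter")
  out <- expression_study(study$signals[keep, , drop = FALSE], study$design,
                          if (!is.null(study$detection_flags))
                            study$detection_flags[keep, , drop = FALSE])
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Per-probe treatment p-values from a two-factor ANOVA
#'
#' Fits the additive model log2(signal) ~ treatment + batch per probe and
#' returns the p-value of the treatment factor. For the balanced paired
#' design (one sample per treatment x batch cell) this is the randomized
#' complete block F test with (1, b-1) degrees of freedom, numerically
#' identical to the square of the paired t statistic -- an equivalence the
#' test suite asserts. Computed in closed form over the whole matrix.
#'
#' @param study an [expression_study()]; the design must have exactly one
#'   sample per treatment x batch cell.
#' @return Named numeric vector of p-values (one per probe).
#' @export
anova_treatment <- function(study) {
  d <- study$design
  tab <- table(d$batch, d$treatment)
  if (any(tab != 1)) {
    bad <- rownames(tab)[apply(tab != 1, 1, any)]
    abort("design must have exactly one sample per treatment x batch cell (batches: %s)",
          paste(bad, collapse = ", "))
  }
  y <- log2(study$signals)
  b <- nrow(tab)
  ctrl <- d$treatment == "control"
  batches <- sort(unique(d$batch))

  grand <- rowMeans(y)
  m_c <- rowMeans(y[, ctrl, drop = FALSE])
  m_e <- rowMeans(y[, !ctrl, drop = FALSE])
  ss_treat <- (b / 2) * (m_e - m_c)^2
  batch_means <- sapply(batches, function(bb)
    rowMeans(y[, d$batch == bb, drop = FALSE]))
  if (is.null(dim(batch_means))) batch_means <- matrix(batch_means, nrow = 1)
  # residuals computed directly (not by SS subtraction) to avoid
  # catastrophic cancellation when the fit is near-perfect
  fitted <- batch_means[, match(d$batch, batches), drop = FALSE]
  fitted[, ctrl] <- fitted[, ctrl] + (m_c - grand)
  fitted[, !ctrl] <- fitted[, !ctrl] + (m_e - grand)
  ss_err <- rowSums((y - fitted)^2)
  df_err <- b - 1
  f <- ifelse(ss_err > 0, ss_treat / (ss_err / df_err), ifelse(ss_treat > 0, Inf, 0))
  p <- pf(f, 1, df_err, lower.tail = FALSE)
  setNames(p, rownames(y))
}

#' Signed fold change on the linear scale
#'
#' Per probe, r = mean(ethanol) / mean(control) of the linear signals;
#' reported as r when r >= 1 and as -1/r otherwise, the signed-ratio
#' convention in which there are no values strictly inside (-1, 1).
#'
#' @param study an [expression_study()].
#' @return Named numeric vector of signed fold changes.
#' @export
signed_fold_change <- function(study) {
  ctrl <- study$design$treatment == "control"
  mc <- rowMeans(study$signals[, ctrl, drop = FALSE])
  me <- rowMeans(study$signals[, !ctrl, drop = FALSE])
  if (any(mc == 0) || any(me == 0)) abort("zero mean signal encountered")
  r <- me / mc
  setNames(ifelse(r >= 1, r, -1 / r), rownames(study$signals))
}

#' Storey q-values
#'
#' Estimates the null proportion pi0 on a lambda grid (0.05 to 0.95, step
#' 0.05) with the smoother method (a df-3 smoothing spline through
#' pi0(lambda), evaluated at the largest lambda, clamped to (0, 1\]), then
#' computes q_i = min over p_j >= p_i of pi0 * m * p_j / rank(p_j). With
#' `pi0 = 1` this reduces exactly to Benjamini-Hochberg adjusted p-values.
#'
#' @param pvals p-values in \[0, 1\].
#' @param pi0 optional fixed null proportion; when NULL it is estimated.
#' @param lambda grid for pi0 estimation.
#' @return List with `qvalues` (same order as `pvals`) and `pi0`.
#' @export
storey_qvalue <- function(pvals, pi0 = NULL, lambda = seq(0.05, 0.95, by = 0.05)) {
  if (length(pvals) == 0) abort("empty p-value vector")
  if (any(!is.finite(pvals)) || any(pvals < 0) || any(pvals > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  m <- length(pvals)
  if (is.null(pi0)) {
    pi0_l <- vapply(lambda, function(l) mean(pvals > l) / (1 - l), 0)
    if (all(pi0_l == 0)) {
      pi0 <- max(1 / m, min(1, pi0_l[length(pi0_l)]))
    } else {
      fit <- smooth.spline(lambda, pi0_l, df = 3)
      pi0 <- predict(fit, x = max(lambda))$y
      pi0 <- min(1, max(pi0, 1 / m))  # clamp; tiny floor keeps q > 0 sensible
    }
  }
  o <- order(pvals, decreasing = TRUE)
  ro <- order(o)
  q <- pmin(1, cummin(pi0 * m / (m:1) * pvals[o]))[ro]
  list(qvalues = q, pi0 = pi0)
}

#' Dysregulation call at the published thresholds
#'
#' A probe/gene is dysregulated iff |signed fold change| >= `fc_min` AND
#' q <= `q_max` AND p < `p_max`. Boundary semantics are as printed in the
#' source analysis: inclusive for the fold-change and FDR cutoffs, strict
#' for the p-value cutoff.
#'
#' @param signed_fc,p,q aligned numeric vectors.
#' @param fc_min fold-change magnitude cutoff (default 1.25, inclusive).
#' @param q_max FDR cutoff (default 0.15, inclusive).
#' @param p_max p-value cutoff (default 0.03, strict).
#' @return Logical vector.
#' @export
select_dysregulated <- function(signed_fc, p, q, fc_min = 1.25, q_max = 0.15,
                                p_max = 0.03) {
  abs(signed_fc) >= fc_min & q <= q_max & p < p_max
}

#' Collapse a probe-level table to gene level
#'
#' Unmapped probes are dropped (and counted); multiple probes per gene are
#' collapsed to the probe with the smallest p-value, ties broken by larger
#' |fold change|, then by lexicographic probe id.
#'
#' @param probe_table data frame with columns `probe_id`, `signed_fc`,
#'   `p`, `q`, `dysregulated`.
#' @param probe2gene data frame with columns `probe_id`, `gene_id`
#'   (possibly partial, many-to-one).
#' @return Gene-level data frame (`gene_id` plus the probe columns);
#'   attribute `counts` records (probes_in, probes_mapped, genes_out).
#' @export
collapse_probes_to_genes <- function(probe_table, probe2gene) {
  n_in <- nrow(probe_table)
  merged <- merge(probe_table, probe2gene, by = "probe_id")
  n_mapped <- nrow(merged)
  if (n_mapped == 0) {
    out <- data.frame(gene_id = character(), probe_id = character(),
                      signed_fc = numeric(), p = numeric(), q = numeric(),
                      dysregulated = logical(), stringsAsFactors = FALSE)
    attr(out, "counts") <- c(probes_in = n_in, probes_mapped = 0, genes_out = 0)
    return(out)
  }
  o <- order(merged$gene_id, merged$p, -abs(merged$signed_fc), merged$probe_id,
             method = "radix")
  merged <- merged[o, , drop = FALSE]
  best <- merged[!duplicated(merged$gene_id), , drop = FALSE]
  out <- best[c_order(best$gene_id),
              c("gene_id", "probe_id", "signed_fc", "p", "q", "dysregulated"),
              drop = FALSE]
  rownames(out) <- NULL
  attr(out, "counts") <- c(probes_in = n_in, probes_mapped = n_mapped,
                           genes_out = nrow(out))
  out
}

#' Flag transcription factors by list membership
#'
#' @param gene_table gene-level data frame with a `gene_id` column.
#' @param tf_list character vector of TF gene ids (case-sensitive).
#' @return `gene_table` with a logical `is_tf` column appended.
#' @export
annotate_tfs <- function(gene_table, tf_list) {
  gene_table$is_tf <- gene_table$gene_id %in% tf_list
  gene_table
}

#' Run the full differential-expression stage
#'
#' Detection filter, log2 two-factor ANOVA, signed fold change, Storey
#' q-values, dysregulation call, probe-to-gene collapse, TF annotation.
#'
#' @param study an [expression_study()].
#' @param probe2gene probe-to-gene map (data frame).
#' @param tf_list character vector of TF gene ids.
#' @param fc_min,q_max,p_max,detect_frac selection thresholds (defaults
#'   1.25, 0.15, 0.03, 0.50).
#' @return List with `gene_table` (gene-level data frame with `is_tf`),
#'   `probe_table`, `pi0`, and `counts`: named vector
#'   (probes_total, probes_filtered, probes_selected, probes_mapped,
#'   genes, genes_dysregulated, tfs_dysregulated) mirroring the
#'   selected -> mapped -> genes -> TFs narrative of the source analysis.
#' @export
run_diffexpr <- function(study, probe2gene, tf_list = character(),
                         fc_min = 1.25, q_max = 0.15, p_max = 0.03,
                         detect_frac = 0.5) {
  n_total <- nrow(study$signals)
  study <- filter_detected(study, detect_frac = detect_frac)
  p <- anova_treatment(study)
  fc <- signed_fold_change(study)
  st <- storey_qvalue(p)
  dys <- select_dysregulated(fc, p, st$qvalues, fc_min, q_max, p_max)
  probe_table <- data.frame(probe_id = rownames(study$signals),
                            signed_fc = unname(fc), p = unname(p),
                            q = st$qvalues, dysregulated = dys,
                            stringsAsFactors = FALSE)
  gene_table <- collapse_probes_to_genes(probe_table, probe2gene)
  gene_table <- annotate_tfs(gene_table, tf_list)
  sel <- probe_table[probe_table$dysregulated, , drop = FALSE]
  sel_gene <- collapse_probes_to_genes(sel, probe2gene)
  cnt_sel <- attr(sel_gene, "counts")
  counts <- c(probes_total = n_total,
              probes_filtered = nrow(probe_table),
              probes_selected = unname(cnt_sel["probes_in"]),
              probes_mapped = unname(cnt_sel["probes_mapped"]),
              genes = unname(cnt_sel["genes_out"]),
              genes_dysregulated = sum(gene_table$dysregulated),
              tfs_dysregulated = sum(gene_table$dysregulated & gene_table$is_tf))
  list(gene_table = gene_table, probe_table = probe_table, pi0 = st$pi0,
       counts = counts)
}
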