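# Comparative-CT (delta-delta-CT) relative quantification with
# reference-gene normalization, and the unpaired two-tailed t-test used
# for control-vs-treated comparisons.

#' Delta-delta-CT fold change for one gene
#'
#' Technical replicates are averaged within (gene, group, experiment)
#' first; then per (group, experiment) dCT = Ct_gene - Ct_reference; per
#' experiment ddCT = dCT_treated - dCT_control and FC_e = 2^(-ddCT)
#' (amplification efficiency fixed at 2). The reported fold change is the
#' mean of the per-experiment FCs, with the control group normalized to 1
#' by construction. The two-group test compares -dCT values (log2 relative
#' expression) between groups across experiments with
#' [two_group_ttest()].
#'
#' @param ct_table Ct data frame (columns gene, sample_group, experiment,
#'   replicate, ct).
#' @param gene gene to quantify.
#' @param reference_gene internal-control gene; must be present in every
#'   (group, experiment) cell.
#' @return List of class `FoldChangeResult`: `gene`, `fold_change` (linear
#'   ratio, treated vs control), `signed_fc` (signed-ratio convention for
#'   display alongside array fold changes), `per_experiment_fc`,
#'   `p_value`.
#' @export
ddct_fold_change <- function(ct_table, gene, reference_gene) {
  for (g in c(gene, reference_gene)) {
    if (!g %in% ct_table$gene) abort("gene '%s' absent from the Ct table", g)
  }
  avg <- stats::aggregate(ct ~ gene + sample_group + experiment,
                          data = ct_table[ct_table$gene %in% c(gene, reference_gene), ],
                          FUN = mean)
  cells <- expand.grid(sample_group = c("control", "treated"),
                       experiment = unique(ct_table$experiment),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  get_ct <- function(g, grp, ex) {
    v <- avg$ct[avg$gene == g & avg$sample_group == grp & avg$experiment == ex]
    if (length(v) != 1) {
      abort("reference/target Ct missing for gene '%s' in (%s, experiment %s)",
            g, grp, ex)
    }
    v
  }
  dct <- mapply(function(grp, ex) {
    get_ct(gene, grp, ex) - get_ct(reference_gene, grp, ex)
  }, cells$sample_group, cells$experiment)
  ctrl <- cells$sample_group == "control"
  exps <- unique(cells$experiment)
  ddct <- vapply(exps, function(ex) {
    dct[!ctrl & cells$experiment == ex] - dct[ctrl & cells$experiment == ex]
  }, 0)
  fc_e <- 2^(-ddct)
  fc <- mean(fc_e)
  p <- two_group_ttest(-dct[ctrl], -dct[!ctrl])
  structure(list(gene = gene, fold_change = fc,
                 signed_fc = if (fc >= 1) fc else -1 / fc,
                 per_experiment_fc = setNames(fc_e, paste0("exp", exps)),
                 p_value = p),
            class = "FoldChangeResult")
}

#' @export
print.FoldChangeResult <- function(x, ...) {
  cat(sprintf("%s: fold change %.3f (signed %.2f), t-test p = %.4g [per-experiment: %s]\n",
              x$gene, x$fold_change, x$signed_fc, x$p_value,
              paste(sprintf("%.3f", x$per_experiment_fc), collapse = ", ")))
  invisible(x)
}

#' Unpaired two-tailed equal-variance t-test
#'
#' Classical two-sample Student t. Degenerate inputs follow a documented
#' convention: zero variance in both groups with equal means gives p = 1
#' (no evidence of difference); zero pooled variance with unequal means
#' gives p = 0.
#'
#' @param values_control,values_treated numeric vectors (>= 2 values
#'   each).
#' @return Two-tailed p-value.
#' @export
two_group_ttest <- function(values_control, values_treated) {
  if (length(values_control) < 2 || length(values_treated) < 2) {
    abort("each group needs >= 2 values")
  }
  sp2 <- (sum((values_control - mean(values_control))^2) +
          sum((values_treated - mean(values_treated))^2))
  if (sp2 == 0) {
    return(if (mean(values_control) == mean(values_treated)) 1 else 0)
  }
  t.test(values_control, values_treated, var.equal = TRUE)$p.value
}
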