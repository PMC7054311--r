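# End-to-end pipeline: simulate (or load) -> differential expression ->
# promoter scan -> enrichment -> network, with a resolved config, a run
# log, and a machine-readable summary written beside every output.

#' Pipeline configuration
#'
#' Mirrors every stage's defaults in one serializable list. `simulate =
#' TRUE` generates the inputs with [sim_config()]; otherwise paths to a
#' signal matrix, design, probe-to-gene map, promoter FASTA, PWM library
#' and TF list must be supplied.
#'
#' @param simulate generate inputs synthetically (default TRUE).
#' @param sim arguments forwarded to [sim_config()] (list).
#' @param fc_min,q_max,p_max,detect_frac differential-expression
#'   thresholds (defaults 1.25, 0.15, 0.03, 0.50).
#' @param alpha motif occurrence p-value threshold (default 1e-4).
#' @param bg background mode: `"promoter"`, `"uniform"`, or a 4-vector.
#' @param pseudocount,granularity PWM model parameters.
#' @param both_strands scan both strands (default TRUE).
#' @param seed master RNG seed (also the simulation seed).
#' @param inputs named list of file paths (`signals`, `design`,
#'   `probe2gene`, `promoters`, `pwms`, `pwm_dialect`, `tf_list`) when
#'   `simulate = FALSE`.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = TRUE, sim = list(),
                            fc_min = 1.25, q_max = 0.15, p_max = 0.03,
                            detect_frac = 0.5, alpha = 1e-4, bg = "promoter",
                            pseudocount = 0.1, granularity = 0.01,
                            both_strands = TRUE, seed = 1L, inputs = list()) {
  cfg <- list(simulate = simulate, sim = sim, fc_min = fc_min, q_max = q_max,
              p_max = p_max, detect_frac = detect_frac, alpha = alpha, bg = bg,
              pseudocount = pseudocount, granularity = granularity,
              both_strands = both_strands, seed = as.integer(seed),
              inputs = inputs)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

#' @rdname read_pipeline_config
#' @param config a [pipeline_config()].
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the full pipeline
#'
#' Stages: input simulation (or loading), differential expression, target
#' calling by promoter scanning, enrichment, network assembly. Writes
#' `de_table.tsv`, `hits.tsv`, `targets.gmt`, `enrichment.tsv`,
#' `network.sif`, `edges.tsv`, `summary.json`, `run.log` and the resolved
#' `config.yaml` into `out_dir`. Any stage failure aborts with the stage
#' name; outputs of completed stages are preserved.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return Invisibly, the summary list (also serialized as
#'   `summary.json`).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(out_dir, "run.log")
  cat("", file = logf)
  log_msg <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    cat(msg, "\n", file = logf, append = TRUE, sep = "")
    message(msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
  }
  write_pipeline_config(config, file.path(out_dir, "config.yaml"))

  # --- inputs -----------------------------------------------------------
  dat <- stage("inputs", {
    if (isTRUE(config$simulate)) {
      scfg <- do.call(sim_config, c(config$sim, list(seed = config$seed)))
      expr <- simulate_expression(scfg)
      pwms <- lapply(seq_len(scfg$tf_count), function(i)
        simulate_pwm(width = 8, concentration = 15, seed = scfg$seed + 100L + i,
                     motif_id = sprintf("TF%02d", i)))
      de_truth <- expr$truth$gene[expr$truth$is_de]
      prom <- simulate_promoters(scfg, pwms, de_genes = de_truth,
                                 seed = scfg$seed + 1L)
      list(study = expr$study, probe2gene = expr$probe2gene,
           promoters = prom$promoters, pwms = pwms,
           tf_list = character(0), truth = list(expression = expr$truth,
                                                promoters = prom$truth))
    } else {
      ins <- config$inputs
      list(study = expression_study(read_signal_matrix(ins$signals),
                                    read_design(ins$design)),
           probe2gene = read_probe2gene(ins$probe2gene),
           promoters = read_fasta(ins$promoters),
           pwms = read_pwm_library(ins$pwms, ins$pwm_dialect %||% "meme-minimal"),
           tf_list = if (!is.null(ins$tf_list)) readLines(ins$tf_list) else character(0),
           truth = NULL)
    }
  })
  log_msg("inputs: %d probes, %d samples, %d promoters, %d PWMs",
          nrow(dat$study$signals), ncol(dat$study$signals),
          length(dat$promoters), length(dat$pwms))

  # --- differential expression -----------------------------------------
  # In simulation mode, each PWM is attributed to a dysregulated TF gene
  # so the network stage has TF nodes: the k-th PWM is renamed to the k-th
  # dysregulated gene (post-hoc aliasing changes labels only, not calls).
  de <- stage("diffexpr", {
    run_diffexpr(dat$study, dat$probe2gene, tf_list = dat$tf_list,
                 fc_min = config$fc_min, q_max = config$q_max,
                 p_max = config$p_max, detect_frac = config$detect_frac)
  })
  log_msg("diffexpr: %d/%d probes selected -> %d mapped -> %d genes (%d dysregulated)",
          de$counts["probes_selected"], de$counts["probes_filtered"],
          de$counts["probes_mapped"], de$counts["genes"],
          de$counts["genes_dysregulated"])

  if (isTRUE(config$simulate)) {
    dys_genes <- de$gene_table$gene_id[de$gene_table$dysregulated]
    n_alias <- min(length(dat$pwms), length(dys_genes))
    alias <- setNames(dys_genes[seq_len(n_alias)],
                      vapply(dat$pwms, `[[`, "", "motif_id")[seq_len(n_alias)])
    for (i in seq_len(n_alias)) dat$pwms[[i]]$motif_id <- alias[[i]]
    dat$tf_list <- unname(alias)
    de$gene_table <- annotate_tfs(de$gene_table, dat$tf_list)
    de$counts["tfs_dysregulated"] <-
      sum(de$gene_table$dysregulated & de$gene_table$is_tf)
    log_msg("diffexpr: %d dysregulated TFs (simulated PWMs aliased to DE genes)",
            de$counts["tfs_dysregulated"])
  }
  gt <- de$gene_table
  write.table(gt, file.path(out_dir, "de_table.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  # --- scanning + target calls -----------------------------------------
  tc <- stage("scan", {
    call_targets(dat$pwms, dat$promoters, alpha = config$alpha,
                 both_strands = config$both_strands, bg = config$bg,
                 pseudocount = config$pseudocount,
                 granularity = config$granularity)
  })
  write.table(tc$calls, file.path(out_dir, "hits.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_gmt(tc$targets, file.path(out_dir, "targets.gmt"))
  log_msg("scan: per-TF genomic target counts K = %s",
          paste(sprintf("%s:%d", names(tc$K), tc$K), collapse = ", "))

  # --- enrichment -------------------------------------------------------
  universe <- dat$promoters$gene_id
  dys_in_universe <- intersect(gt$gene_id[gt$dysregulated], universe)
  enr <- stage("enrich", enrich_all(tc, dys_in_universe, universe))
  write.table(format_enrichment(enr), file.path(out_dir, "enrichment.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  log_msg("enrich: N = %d (scannable universe), n = %d dysregulated; top p = %.3g",
          length(universe), length(dys_in_universe), min(enr$p_value))

  # --- network ----------------------------------------------------------
  net <- stage("network", build_network(tc, gt))
  write_network_sif(net$edges, file.path(out_dir, "network.sif"))
  write_edge_table(net$edges, file.path(out_dir, "edges.tsv"))
  log_msg("network: %d interactions, %d TFs targeting %d genes",
          net$summary["n_edges"], net$summary["n_tfs"], net$summary["n_targets"])

  summary <- list(
    counts = as.list(de$counts), pi0 = de$pi0,
    universe_N = length(universe), dysregulated_n = length(dys_in_universe),
    per_tf = lapply(setNames(enr$tf, enr$tf), function(tf) {
      r <- enr[enr$tf == tf, ]
      list(K = r$K, k = r$k, p_value = r$p_value)
    }),
    network = as.list(net$summary),
    alpha = config$alpha, seed = config$seed
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}
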