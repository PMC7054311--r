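#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study all downstream stages consume.
#
# Emulates the motivating design: 6 paired control/ethanol batches, a 10%
# dysregulated fraction with |fold change| >= 1.25, 4 transcription
# factors with PWMs, promoters carrying planted motif sites (dysregulated
# genes 3x as likely to be planted targets). Every input is written as the
# plain-text format the io layer reads, so stages 02-05 run from files
# alone. 800 genes and 1 kb promoters keep the worked example fast; the
# statistical structure is unchanged by the scale.

suppressPackageStartupMessages(library(etohnet))

out <- "results/simulated"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(n_genes = 800, promoter_length = 1000, tf_count = 4,
                  planted_target_fraction = 0.12, seed = 1)

expr <- simulate_expression(cfg)
truth_de <- expr$truth$gene[expr$truth$is_de]

# The simulated TFs are themselves dysregulated genes (as in the study,
# where the network's regulators come from the dysregulated TF table):
# name each PWM after a planted-DE gene.
tf_genes <- sort(truth_de)[seq_len(cfg$tf_count)]
pwms <- lapply(seq_len(cfg$tf_count), function(i)
  simulate_pwm(8, concentration = 15, seed = 100 + i, motif_id = tf_genes[i]))

prom <- simulate_promoters(cfg, pwms, de_genes = truth_de, seed = 2)

write_signal_matrix(expr$study$signals, file.path(out, "signals.tsv"))
write.table(expr$study$design, file.path(out, "design.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(expr$probe2gene, file.path(out, "probe2gene.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
writeLines(tf_genes, file.path(out, "tf_list.txt"))
write_fasta(prom$promoters, file.path(out, "promoters.fa"))
write_pwm_library(pwms, file.path(out, "pwms.meme"), "meme-minimal")
write.table(expr$truth, file.path(out, "truth_expression.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(prom$truth$planted_sites, file.path(out, "truth_planted_sites.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write_gmt(prom$truth$tf_target_map, file.path(out, "truth_targets.gmt"))

cat(sprintf("simulated %d genes x %d samples; %d planted DE genes (%.0f%%)\n",
            cfg$n_genes, ncol(expr$study$signals), length(truth_de),
            100 * mean(expr$truth$is_de)))
cat(sprintf("TFs (aliased to planted-DE genes): %s\n",
            paste(tf_genes, collapse = ", ")))
cat(sprintf("planted sites: %d across %d promoters\n",
            nrow(prom$truth$planted_sites), length(prom$promoters)))
cat(sprintf("inputs written under %s\n", out))
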