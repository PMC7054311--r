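#!/usr/bin/env Rscript
# Stage 4: hypergeometric enrichment of each TF's predicted targets in
# the dysregulated gene set (the published-table analysis), a three-way
# overlap of the dysregulated set with one TF's predicted targets and the
# planted-truth targets, and the bipartite TF-target network with its
# (edges, TFs, targets) summary triple. Also verifies the shipped
# published tables' internal consistency.

suppressPackageStartupMessages(library(etohnet))

out <- "results"
gt <- read.delim(file.path(out, "de_table.tsv"))
targets <- read_gmt(file.path(out, "targets.gmt"))
promoters <- read_fasta(file.path("results/simulated", "promoters.fa"))

universe <- promoters$gene_id  # genes with a scannable promoter
de <- intersect(gt$gene_id[gt$dysregulated], universe)
cat(sprintf("universe N = %d (scannable promoters), dysregulated n = %d\n",
            length(universe), length(de)))

enr <- enrich_all(targets, de, universe)
write.table(format_enrichment(enr), file.path(out, "enrichment.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("TF-target enrichment (sorted by p):\n")
print(format_enrichment(enr)[, c("tf", "K", "k", "p_value", "neglog10_p")],
      row.names = FALSE)

# three-way overlap: dysregulated set vs the top TF's predicted targets
# vs its planted-truth targets
truth <- read_gmt(file.path("results/simulated", "truth_targets.gmt"))
top_tf <- enr$tf[1]
ov <- overlap3(de, targets[[top_tf]], truth[[top_tf]],
               names = c("dysregulated", "predicted", "planted"))
cat(sprintf("\nthree-way overlap for %s:\n", top_tf))
print(ov)

net <- build_network(targets, gt)
write_network_sif(net$edges, file.path(out, "network.sif"))
write_edge_table(net$edges, file.path(out, "edges.tsv"))
s <- net$summary
cat(sprintf("\nnetwork: %d interactions, %d TFs targeting %d dysregulated genes\n",
            s["n_edges"], s["n_tfs"], s["n_targets"]))
prof <- shared_target_profile(net)
cat("in-degree histogram (targets shared by k TFs):\n")
print(prof$histogram)

# shipped published tables: structural self-consistency
t2 <- table2_fixture(); t3 <- table3_fixture()
cat(sprintf("\nfixture check: %d unique TF symbols over %d rows; %d non-sox2 PWM rows\n",
            length(unique(t2$gene_symbol)), nrow(t2),
            sum(t2$pwm_available & t2$gene_symbol != "sox2")))
cat(sprintf("fixture check: %d/%d enrichment rows satisfy round(10^-x, 4) == p\n",
            sum(check_p_neglog10_consistency(t3)), sum(t3$p_value > 0)))
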