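# Hypergeometric enrichment of predicted TF targets in the dysregulated
# gene set, three-way set overlaps, and the bipartite TF-target network.

#' Upper-tail hypergeometric probability
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): drawing n dysregulated genes
#' from a universe of N containing K TF targets. Evaluated through
#' `phyper()` with `log.p` in the extreme tail for numerical stability;
#' k = 0 returns exactly 1.
#'
#' @param k observed overlap (targets among dysregulated genes).
#' @param K TF's genomic target count in the universe.
#' @param n dysregulated gene count in the universe.
#' @param N universe size.
#' @return The upper-tail probability, in (0, 1\].
#' @export
hypergeom_upper_tail <- function(k, K, n, N) {
  if (k < 0) abort("bound violated: k >= 0 (k = %d)", k)
  if (K > N) abort("bound violated: K <= N (K = %d, N = %d)", K, N)
  if (n > N) abort("bound violated: n <= N (n = %d, N = %d)", n, N)
  if (k > min(K, n)) abort("bound violated: k <= min(K, n) (k = %d, K = %d, n = %d)",
                           k, K, n)
  if (k == 0) return(1)
  lp <- phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE)
  min(exp(lp), 1)
}

#' Per-TF enrichment of predicted targets in the dysregulated set
#'
#' One row per TF with a PWM: the TF's genomic target count K (targets
#' intersected with the universe), the overlap k with the dysregulated
#' set, the dysregulated count n, the universe size N, the upper-tail
#' hypergeometric p, and -log10(p). Rows are sorted by ascending p.
#'
#' @param target_calls a [call_targets()] result, or a named list of
#'   target gene vectors per TF.
#' @param de_genes character vector of dysregulated gene ids (must be a
#'   subset of `universe`, nonempty).
#' @param universe character vector of gene ids over which targets were
#'   callable (genes with a scannable promoter).
#' @return Data frame with columns `tf`, `K`, `k`, `n`, `N`, `p_value`,
#'   `neglog10_p` (full precision; see [format_enrichment()] for the
#'   4-decimal export convention).
#' @export
enrich_all <- function(target_calls, de_genes, universe) {
  targets <- if (inherits(target_calls, "TargetCallSet")) target_calls$targets
             else target_calls
  de_genes <- unique(de_genes)
  universe <- unique(universe)
  if (length(de_genes) == 0) abort("dysregulated gene set is empty")
  if (!all(de_genes %in% universe)) {
    abort("dysregulated genes outside the universe: %s",
          paste(head(setdiff(de_genes, universe), 5), collapse = ", "))
  }
  N <- length(universe)
  n <- length(de_genes)
  rows <- lapply(names(targets), function(tf) {
    tg <- intersect(targets[[tf]], universe)
    K <- length(tg)
    k <- length(intersect(tg, de_genes))
    p <- hypergeom_upper_tail(k, K, n, N)
    data.frame(tf = tf, K = K, k = k, n = n, N = N, p_value = p,
               neglog10_p = -log10(p), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$p_value, out$tf, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Format an enrichment table for export
#'
#' Rounds `p_value` and `neglog10_p` to 4 decimals (the convention of the
#' published table) while keeping the full-precision values in companion
#' columns `p_full` and `neglog10_full`.
#'
#' @param enrichment an [enrich_all()] table.
#' @return Data frame ready for `write.table()`.
#' @export
format_enrichment <- function(enrichment) {
  data.frame(tf = enrichment$tf, K = enrichment$K, k = enrichment$k,
             n = enrichment$n, N = enrichment$N,
             p_value = sprintf("%.4f", enrichment$p_value),
             neglog10_p = sprintf("%.4f", enrichment$neglog10_p),
             p_full = enrichment$p_value,
             neglog10_full = enrichment$neglog10_p,
             stringsAsFactors = FALSE)
}

#' Three-way set overlap (Venn regions)
#'
#' @param setA,setB,setC character vectors over a shared id space.
#' @param names region name prefixes (default A, B, C).
#' @return Named integer vector: the three set sizes (`A`, `B`, `C`) and
#'   the seven exclusive region counts (`A_only`, `B_only`, `C_only`,
#'   `AB_only`, `AC_only`, `BC_only`, `ABC`).
#' @export
overlap3 <- function(setA, setB, setC, names = c("A", "B", "C")) {
  setA <- unique(setA); setB <- unique(setB); setC <- unique(setC)
  all_ids <- unique(c(setA, setB, setC))
  inA <- all_ids %in% setA; inB <- all_ids %in% setB; inC <- all_ids %in% setC
  region <- paste0(ifelse(inA, "A", ""), ifelse(inB, "B", ""), ifelse(inC, "C", ""))
  cnt <- function(r) sum(region == r)
  out <- c(length(setA), length(setB), length(setC),
           cnt("A"), cnt("B"), cnt("C"), cnt("AB"), cnt("AC"), cnt("BC"), cnt("ABC"))
  names(out) <- c(names,
                  paste0(names[1], "_only"), paste0(names[2], "_only"),
                  paste0(names[3], "_only"),
                  paste0(names[1], names[2], "_only"),
                  paste0(names[1], names[3], "_only"),
                  paste0(names[2], names[3], "_only"),
                  paste0(names[1], names[2], names[3]))
  out
}

#' Assemble the bipartite TF-target regulatory network
#'
#' Edge (tf -> gene) iff the TF is a dysregulated, PWM-backed TF (i.e. has
#' target calls), the gene is dysregulated, and the gene is among the TF's
#' predicted targets. A TF targeting its own promoter yields a flagged
#' self-edge. A gene may be both TF and target.
#'
#' @param target_calls a [call_targets()] result or named list of target
#'   vectors.
#' @param gene_table gene-level data frame with columns `gene_id`,
#'   `dysregulated`, `is_tf`.
#' @return Object of class `RegulatoryNetwork`: `edges` (data frame `tf`,
#'   `target`, `self`), `summary` (n_edges, n_tfs, n_targets),
#'   `in_degree` (named vector per target).
#' @export
build_network <- function(target_calls, gene_table) {
  targets <- if (inherits(target_calls, "TargetCallSet")) target_calls$targets
             else target_calls
  dys <- gene_table$gene_id[gene_table$dysregulated]
  dys_tfs <- gene_table$gene_id[gene_table$dysregulated & gene_table$is_tf]
  active_tfs <- intersect(names(targets), dys_tfs)
  edges <- lapply(active_tfs, function(tf) {
    tg <- intersect(targets[[tf]], dys)
    if (!length(tg)) return(NULL)
    data.frame(tf = tf, target = tg, self = tg == tf, stringsAsFactors = FALSE)
  })
  edges <- if (length(edges)) do.call(rbind, edges) else NULL
  if (is.null(edges)) {
    edges <- data.frame(tf = character(), target = character(), self = logical(),
                        stringsAsFactors = FALSE)
  }
  edges <- unique(edges)
  edges <- edges[c_order(edges$tf, edges$target), , drop = FALSE]
  rownames(edges) <- NULL
  indeg <- if (nrow(edges)) table(edges$target) else table(character(0))
  structure(list(edges = edges,
                 summary = c(n_edges = nrow(edges),
                             n_tfs = length(unique(edges$tf)),
                             n_targets = length(unique(edges$target))),
                 in_degree = setNames(as.integer(indeg), names(indeg))),
            class = "RegulatoryNetwork")
}

#' @export
print.RegulatoryNetwork <- function(x, ...) {
  s <- x$summary
  cat(sprintf("RegulatoryNetwork: %d interactions, %d TFs targeting %d genes\n",
              s["n_edges"], s["n_tfs"], s["n_targets"]))
  invisible(x)
}

#' Per-target regulator profile
#'
#' For each target, the set of TFs regulating it and the histogram of
#' in-degrees (how many targets are shared by 1, 2, ... TFs). The sum of
#' in-degrees equals the edge count.
#'
#' @param network a [build_network()] result.
#' @return List with `regulators` (named list: target -> TF vector) and
#'   `histogram` (table of in-degree frequencies).
#' @export
shared_target_profile <- function(network) {
  e <- network$edges
  regulators <- split(e$tf, e$target)
  indeg <- vapply(regulators, length, 0L)
  list(regulators = regulators, histogram = table(indeg))
}
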