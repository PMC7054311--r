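# Tabular readers/writers: expression matrix + design, probe->gene map,
# GMT gene sets, network exports, Ct tables. All TSV, all written with a
# deterministic row order so repeated runs are byte-identical.

#' Read a signal matrix (probes x samples, TSV)
#'
#' First column is the probe id; remaining columns are samples on the
#' linear (MAS5-style) scale.
#'
#' @param path TSV file.
#' @return Numeric matrix with probe rownames and sample colnames.
#' @export
read_signal_matrix <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' @rdname read_signal_matrix
#' @param signals probe x sample matrix.
#' @export
write_signal_matrix <- function(signals, path) {
  df <- data.frame(probe_id = rownames(signals), signals,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample design table (sample_id, treatment, batch)
#'
#' @param path TSV with columns `sample_id`, `treatment`
#'   (control/ethanol), `batch`.
#' @return Data frame.
#' @export
read_design <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "treatment", "batch")
  if (!all(need %in% names(df))) {
    abort("design file must have columns %s", paste(need, collapse = ", "))
  }
  if (!all(df$treatment %in% c("control", "ethanol"))) {
    abort("treatment must be 'control' or 'ethanol'")
  }
  df
}

#' Read a probe-to-gene annotation table
#'
#' @param path TSV with columns `probe_id`, `gene_id`; the mapping may be
#'   partial (unmapped probes simply absent) and many-to-one.
#' @return Data frame.
#' @export
read_probe2gene <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("probe_id", "gene_id") %in% names(df))) {
    abort("probe2gene file must have columns probe_id, gene_id")
  }
  df
}

#' Read / write GMT gene-set files
#'
#' Standard GMT: one set per line, `name <TAB> description <TAB> genes...`.
#'
#' @param path GMT file.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(ln) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    f[-(1:2)]
  })
  names(sets) <- vapply(lines, function(ln) strsplit(ln, "\t", fixed = TRUE)[[1]][1], "")
  sets
}

#' @rdname read_gmt
#' @param sets named list of character vectors.
#' @param descriptions optional character vector of set descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  descriptions <- descriptions %||% rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sort(sets[[i]], method = "radix")),
          collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Export a TF-target edge list as SIF
#'
#' One line per edge: `tf <TAB> targets <TAB> gene`, sorted by TF then
#' target (C-locale lexicographic) for deterministic output.
#'
#' @param edges data frame with columns `tf`, `target` (optional `score`).
#' @param path output file.
#' @export
write_network_sif <- function(edges, path) {
  o <- c_order(edges$tf, edges$target)
  writeLines(paste(edges$tf[o], "targets", edges$target[o], sep = "\t"), path)
  invisible(path)
}

#' @rdname write_network_sif
#' @export
write_edge_table <- function(edges, path) {
  o <- c_order(edges$tf, edges$target)
  df <- data.frame(tf = edges$tf[o], target = edges$target[o],
                   score = if ("score" %in% names(edges)) edges$score[o]
                           else rep(NA_real_, length(o)),
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_network_sif
#' @export
read_edge_table <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' Read / write qPCR Ct tables
#'
#' Columns: `gene`, `sample_group` (control/treated), `experiment`,
#' `replicate`, `ct`.
#'
#' @param path TSV file.
#' @return Data frame.
#' @export
read_ct_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "sample_group", "experiment", "replicate", "ct")
  if (!all(need %in% names(df))) {
    abort("Ct table must have columns %s", paste(need, collapse = ", "))
  }
  if (any(!is.finite(df$ct)) || any(df$ct <= 0)) abort("Ct values must be finite and > 0")
  df
}

#' @rdname read_ct_table
#' @param ct_table data frame as returned by [read_ct_table()].
#' @export
write_ct_table <- function(ct_table, path) {
  write.table(ct_table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
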