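#' Construct a promoter set
#'
#' A `PromoterSet` is the unit the motif scanner consumes: one uppercase
#' DNA sequence per gene, with an optional truncation flag for promoters
#' clipped at contig edges and optional source coordinates.
#'
#' @param gene_id character vector of unique gene identifiers.
#' @param seq character vector of DNA sequences over A,C,G,T,N (any case;
#'   stored uppercase).
#' @param truncated logical vector: promoter shorter than the requested
#'   window because of contig clipping. Recycled if length 1.
#' @param coords optional data frame of source coordinates with columns
#'   `chrom`, `start`, `end`, `strand` (0-based half-open).
#' @return An object of class `PromoterSet`.
#' @export
promoter_set <- function(gene_id, seq, truncated = FALSE, coords = NULL) {
  gene_id <- as.character(gene_id)
  seq <- toupper(as.character(seq))
  if (length(gene_id) != length(seq)) abort("gene_id and seq lengths differ")
  dup <- gene_id[duplicated(gene_id)]
  if (length(dup)) abort("duplicate gene id(s): %s", paste(unique(dup), collapse = ", "))
  bad <- grepl("[^ACGTN]", seq)
  if (any(bad)) {
    abort("sequence for %s contains characters outside A,C,G,T,N",
          gene_id[which(bad)[1]])
  }
  truncated <- rep_len(as.logical(truncated), length(seq))
  structure(
    list(gene_id = gene_id, seq = seq, truncated = truncated, coords = coords),
    class = "PromoterSet"
  )
}

#' @export
length.PromoterSet <- function(x) length(x$gene_id)

#' @export
print.PromoterSet <- function(x, ...) {
  cat(sprintf("PromoterSet: %d promoters, lengths %d-%d%s\n",
              length(x), min(nchar(x$seq)), max(nchar(x$seq)),
              if (any(x$truncated)) sprintf(" (%d truncated)", sum(x$truncated)) else ""))
  invisible(x)
}

#' Read promoter sequences from a FASTA file
#'
#' The token before the first whitespace in each header is the gene id.
#' Lowercase bases are uppercased; `N` bases are retained (the scanner
#' skips windows that cover them).
#'
#' @param path FASTA file.
#' @return A [promoter_set()].
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort("file not found: %s", path)
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0) abort("empty FASTA file: %s", path)
  ids <- sub("\\s.*$", "", names(seqs))
  promoter_set(ids, as.character(seqs))
}

#' Write a promoter set as FASTA
#'
#' @param promoters a [promoter_set()].
#' @param path output file.
#' @export
write_fasta <- function(promoters, path) {
  seqs <- Biostrings::DNAStringSet(promoters$seq)
  names(seqs) <- promoters$gene_id
  Biostrings::writeXStringSet(seqs, path, width = 70L)
  invisible(path)
}

#' Extract upstream promoter windows from a genome
#'
#' For a `+`-strand gene the promoter is the `window` bases immediately
#' upstream of the transcription start site, `[tss - window, tss)` on the
#' forward strand; for a `-`-strand gene it is the reverse complement of
#' `[tss, tss + window)`. Coordinates are 0-based half-open; the BED
#' `start` field is taken as the TSS. Windows running off a contig edge
#' are clipped, kept, and flagged truncated. Genes on contigs absent from
#' the genome are skipped with a warning and counted in the
#' `n_skipped` attribute.
#'
#' @param genome_fasta path to a genome FASTA, or a named character vector
#'   of contig sequences.
#' @param tss_bed path to a 6-column BED file (`chrom start end name score
#'   strand`), or a data frame with those columns.
#' @param window promoter length in bases (default 2000, i.e. "2 kb
#'   upstream").
#' @return A [promoter_set()] with source coordinates.
#' @export
extract_promoters <- function(genome_fasta, tss_bed, window = 2000L) {
  window <- as.integer(window)
  if (window < 1) abort("window must be >= 1")
  genome <- if (is.character(genome_fasta) && length(genome_fasta) == 1 &&
                file.exists(genome_fasta)) {
    s <- Biostrings::readDNAStringSet(genome_fasta)
    names(s) <- sub("\\s.*$", "", names(s))
    setNames(as.character(s), names(s))
  } else {
    toupper(genome_fasta)
  }
  bed <- if (is.data.frame(tss_bed)) tss_bed else {
    read.delim(tss_bed, header = FALSE, stringsAsFactors = FALSE,
               col.names = c("chrom", "start", "end", "name", "score", "strand"))
  }
  names(bed)[1:6] <- c("chrom", "start", "end", "name", "score", "strand")
  if (!all(bed$strand %in% c("+", "-"))) abort("BED strand must be '+' or '-'")

  missing <- !(bed$chrom %in% names(genome))
  if (any(missing)) {
    warning(sprintf("%d gene(s) on contigs absent from the genome were skipped: %s",
                    sum(missing),
                    paste(head(unique(bed$chrom[missing]), 5), collapse = ", ")))
    bed <- bed[!missing, , drop = FALSE]
  }
  if (nrow(bed) == 0) abort("no genes left after contig filtering")

  out <- vector("list", nrow(bed))
  trunc <- logical(nrow(bed))
  starts <- ends <- integer(nrow(bed))
  for (i in seq_len(nrow(bed))) {
    contig <- genome[[bed$chrom[i]]]
    clen <- nchar(contig)
    tss <- as.integer(bed$start[i])
    if (bed$strand[i] == "+") {
      s <- max(0L, tss - window); e <- min(tss, clen)
    } else {
      s <- max(0L, tss); e <- min(tss + window, clen)
    }
    if (e <= s) { s <- e <- min(max(s, 0L), clen) }  # empty window at edge
    frag <- if (e > s) substr(contig, s + 1L, e) else ""
    if (bed$strand[i] == "-" && nchar(frag)) frag <- revcomp_chr(frag)
    out[[i]] <- frag
    trunc[i] <- nchar(frag) < window
    starts[i] <- s; ends[i] <- e
  }
  keep <- nchar(unlist(out)) > 0
  if (!any(keep)) abort("all promoter windows were empty")
  promoter_set(
    bed$name[keep], unlist(out)[keep], truncated = trunc[keep],
    coords = data.frame(chrom = bed$chrom[keep], start = starts[keep],
                        end = ends[keep], strand = bed$strand[keep],
                        stringsAsFactors = FALSE)
  )
}
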