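#' Construct a PWM count-matrix record
#'
#' @param motif_id motif identifier.
#' @param counts numeric width x 4 matrix of nonnegative base counts,
#'   columns in A,C,G,T order.
#' @param source_dialect the file dialect the record came from
#'   (`"transfac-like"`, `"meme-minimal"`, or `"synthetic"`).
#' @return An object of class `PWMRecord`.
#' @export
pwm_record <- function(motif_id, counts, source_dialect = "synthetic") {
  counts <- as.matrix(counts)
  if (ncol(counts) != 4) abort("PWM '%s': counts must have 4 columns (A,C,G,T)", motif_id)
  if (nrow(counts) < 1) abort("PWM '%s': width must be >= 1", motif_id)
  if (any(!is.finite(counts)) || any(counts < 0)) {
    abort("PWM '%s': counts must be finite and nonnegative", motif_id)
  }
  if (any(rowSums(counts) <= 0)) {
    abort("PWM '%s': every position must have a positive count sum (all-zero row at position %d)",
          motif_id, which(rowSums(counts) <= 0)[1])
  }
  dimnames(counts) <- list(NULL, DNA_BASES)
  structure(list(motif_id = as.character(motif_id), counts = counts,
                 source_dialect = source_dialect),
            class = "PWMRecord")
}

#' @export
print.PWMRecord <- function(x, ...) {
  probs <- x$counts / rowSums(x$counts)
  consensus <- paste(DNA_BASES[max.col(probs, ties.method = "first")], collapse = "")
  cat(sprintf("PWMRecord %s: width %d, consensus %s (%s)\n",
              x$motif_id, nrow(x$counts), consensus, x$source_dialect))
  invisible(x)
}

#' Read a PWM library
#'
#' Two dialects are supported. `"transfac-like"`: motif blocks delimited by
#' `//`, an `ID` (or `NA`/`DE`) line naming the motif, a `P0` header giving
#' the base column order, and numbered count rows (`01 ... NN`). Columns are
#' reordered to A,C,G,T internally whatever the header order.
#' `"meme-minimal"`: MEME minimal motif format; each `MOTIF` block's
#' letter-probability matrix is rescaled to counts by its declared `nsites`
#' (default 20 when absent).
#'
#' @param path motif file.
#' @param dialect `"transfac-like"` or `"meme-minimal"`.
#' @return A list of [pwm_record()]s, named by motif id.
#' @export
read_pwm_library <- function(path, dialect = c("transfac-like", "meme-minimal")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  recs <- if (dialect == "transfac-like") parse_transfac(lines) else parse_meme_minimal(lines)
  if (length(recs) == 0) abort("no motifs found in %s", path)
  names(recs) <- vapply(recs, `[[`, "", "motif_id")
  recs
}

parse_transfac <- function(lines) {
  recs <- list()
  id <- NULL; ord <- NULL; rows <- list()
  flush <- function() {
    if (length(rows) == 0) return(NULL)
    widths <- lengths(rows)
    if (length(unique(widths)) != 1 || widths[1] != 4) {
      abort("PWM '%s': ragged count matrix", id %||% "<unnamed>")
    }
    m <- do.call(rbind, rows)
    colnames(m) <- ord
    pwm_record(id %||% sprintf("motif%d", length(recs) + 1),
               m[, DNA_BASES, drop = FALSE], "transfac-like")
  }
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "" ) next
    if (startsWith(ln, "//")) {
      r <- flush(); if (!is.null(r)) recs[[length(recs) + 1]] <- r
      id <- NULL; ord <- NULL; rows <- list()
    } else if (grepl("^(ID|NA|DE)\\s", ln)) {
      if (is.null(id)) id <- strsplit(ln, "\\s+")[[1]][2]
    } else if (grepl("^P0\\s", ln) || grepl("^PO\\s", ln)) {
      ord <- toupper(strsplit(ln, "\\s+")[[1]][-1])[1:4]
      if (!setequal(ord, DNA_BASES)) abort("P0 header must name A,C,G,T (got %s)",
                                           paste(ord, collapse = ","))
    } else if (grepl("^[0-9]+\\s", ln)) {
      tok <- strsplit(ln, "\\s+")[[1]][-1]
      # trailing consensus letter is optional in TRANSFAC rows
      num <- suppressWarnings(as.numeric(tok))
      rows[[length(rows) + 1]] <- num[!is.na(num)]
      if (is.null(ord)) ord <- DNA_BASES
    }
  }
  r <- flush(); if (!is.null(r)) recs[[length(recs) + 1]] <- r
  recs
}

parse_meme_minimal <- function(lines) {
  recs <- list()
  i <- 1
  while (i <= length(lines)) {
    ln <- trimws(lines[i])
    if (grepl("^MOTIF\\s", ln)) {
      id <- strsplit(ln, "\\s+")[[1]][2]
      # find the letter-probability header
      j <- i + 1
      while (j <= length(lines) && !grepl("letter-probability matrix", lines[j])) j <- j + 1
      if (j > length(lines)) abort("MOTIF %s has no letter-probability matrix", id)
      hdr <- lines[j]
      w <- as.integer(sub(".*w=\\s*([0-9]+).*", "\\1", hdr))
      nsites <- if (grepl("nsites=", hdr)) {
        as.numeric(sub(".*nsites=\\s*([0-9.]+).*", "\\1", hdr))
      } else 20
      rows <- list()
      k <- j + 1
      while (k <= length(lines) && length(rows) < w) {
        rl <- trimws(lines[k])
        if (rl != "") {
          num <- suppressWarnings(as.numeric(strsplit(rl, "\\s+")[[1]]))
          if (any(is.na(num)) || length(num) != 4) {
            abort("MOTIF %s: ragged or non-numeric probability row '%s'", id, rl)
          }
          rows[[length(rows) + 1]] <- num
        }
        k <- k + 1
      }
      if (length(rows) != w) abort("MOTIF %s: expected %d rows, found %d", id, w, length(rows))
      m <- do.call(rbind, rows) * nsites
      recs[[length(recs) + 1]] <- pwm_record(id, m, "meme-minimal")
      i <- k
    } else i <- i + 1
  }
  recs
}

#' Write a PWM library
#'
#' Inverse of [read_pwm_library()]; a write-read round trip reproduces the
#' count matrices (exactly for `transfac-like`, to formatting precision for
#' `meme-minimal`, whose probabilities are written with 6 decimals).
#'
#' @param pwms list of [pwm_record()]s.
#' @param path output file.
#' @param dialect `"transfac-like"` or `"meme-minimal"`.
#' @export
write_pwm_library <- function(pwms, path, dialect = c("transfac-like", "meme-minimal")) {
  dialect <- match.arg(dialect)
  if (inherits(pwms, "PWMRecord")) pwms <- list(pwms)
  con <- file(path, "w"); on.exit(close(con))
  if (dialect == "transfac-like") {
    for (p in pwms) {
      writeLines(c(sprintf("ID %s", p$motif_id), "P0 A C G T"), con)
      for (i in seq_len(nrow(p$counts))) {
        writeLines(sprintf("%02d %s", i,
                           paste(format(p$counts[i, ], trim = TRUE, scientific = FALSE),
                                 collapse = " ")), con)
      }
      writeLines("//", con)
    }
  } else {
    writeLines(c("MEME version 4", "", "ALPHABET= ACGT", ""), con)
    for (p in pwms) {
      ns <- rowSums(p$counts)[1]
      writeLines(sprintf("MOTIF %s", p$motif_id), con)
      writeLines(sprintf("letter-probability matrix: alength= 4 w= %d nsites= %s E= 0",
                         nrow(p$counts), format(ns, trim = TRUE, scientific = FALSE)), con)
      probs <- p$counts / rowSums(p$counts)
      for (i in seq_len(nrow(probs))) {
        writeLines(paste(sprintf("%.6f", probs[i, ]), collapse = " "), con)
      }
      writeLines("", con)
    }
  }
  invisible(path)
}
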