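# FIMO-style PWM scanning: log-odds scoring of every promoter window on
# both strands, with per-window p-values from the exact null distribution
# of the (discretized) score under a 0-order background, computed by
# dynamic programming (position-wise convolution of column score masses).

#' Build a scoring model from a PWM count matrix
#'
#' Log-odds entries are
#' `s(i, a) = log2((counts(i,a) + pseudocount * bg_a) / (rowsum + pseudocount)) - log2(bg_a)`.
#' Scores are discretized to integer multiples of `granularity` (bits);
#' window scores and the DP null distribution both use the discretized
#' matrix, so reported p-values are exact for the scores actually used.
#' Scanning the reverse strand scores the reverse-complemented matrix,
#' which equals scoring the window's reverse complement with the forward
#' matrix; the p-value of a hit on either strand is therefore the
#' probability that a random background word attains that forward-matrix
#' score, i.e. one null distribution serves both strands. This makes
#' forward-scanning of revcomp(S) and reverse-strand scanning of S exactly
#' equivalent.
#'
#' @param record a [pwm_record()].
#' @param bg background base frequencies (A,C,G,T), positive, summing to 1.
#' @param pseudocount positive pseudocount distributed by `bg` (default
#'   0.1).
#' @param granularity score discretization step in bits (default 0.01).
#' @return An object of class `PWMModel` holding the log-odds matrices,
#'   integer score matrices and null survival functions for both strands.
#' @export
build_pwm_model <- function(record, bg = rep(0.25, 4), pseudocount = 0.1,
                            granularity = 0.01) {
  stopifnot(inherits(record, "PWMRecord"))
  bg <- check_bg(bg)
  if (pseudocount <= 0) abort("pseudocount must be > 0 (zero risks infinite log-odds)")
  if (granularity <= 0) abort("granularity must be > 0")
  counts <- record$counts
  w <- nrow(counts)
  rs <- rowSums(counts)
  probs <- (counts + matrix(pseudocount * bg, w, 4, byrow = TRUE)) / (rs + pseudocount)
  lo <- log2(probs) - matrix(log2(bg), w, 4, byrow = TRUE)
  ilo <- round(lo / granularity)
  storage.mode(ilo) <- "integer"

  # warn when discretization merges the top two distinct window scores
  top2 <- function(m) {
    mx <- apply(m, 1, max)
    gap <- apply(m, 1, function(r) { s <- sort(r, decreasing = TRUE); s[1] - s[2] })
    c(best = sum(mx), second = sum(mx) - min(gap[gap > 0], Inf))
  }
  ct <- top2(lo); ci <- top2(ilo)
  if (is.finite(ct["second"]) && ct["best"] > ct["second"] && ci["best"] == ci["second"]) {
    warning(sprintf("granularity %.3g merges the top two scores of motif %s",
                    granularity, record$motif_id))
  }

  ilo_rc <- ilo[w:1, 4:1, drop = FALSE]
  dimnames(ilo_rc) <- dimnames(ilo)
  structure(list(motif_id = record$motif_id, width = w, counts = counts,
                 log_odds = lo, ilo = ilo, ilo_rc = ilo_rc, bg = bg,
                 pseudocount = pseudocount, granularity = granularity,
                 null = score_null(ilo, bg),
                 max_score = sum(apply(lo, 1, max))),
            class = "PWMModel")
}

# Exact distribution of the integer window score under the 0-order
# background: convolve the 4-point column distributions position by
# position. Returns support bounds and the survival function
# sf[s - smin + 1] = P(S >= s).
score_null <- function(ilo, bg) {
  smin <- 0L; smax <- 0L; mass <- 1
  for (i in seq_len(nrow(ilo))) {
    r <- ilo[i, ]
    nmin <- smin + min(r); nmax <- smax + max(r)
    nm <- numeric(nmax - nmin + 1)
    for (a in 1:4) {
      idx <- (smin + r[a] - nmin + 1):(smax + r[a] - nmin + 1)
      nm[idx] <- nm[idx] + mass * bg[a]
    }
    mass <- nm; smin <- nmin; smax <- nmax
  }
  sf <- rev(cumsum(rev(mass)))
  list(smin = smin, smax = smax, mass = mass, sf = sf)
}

#' Exact null distribution of a model's window score
#'
#' The distribution of the forward-matrix score of a random background
#' word; by the reverse-complement scoring identity it prices hits on
#' both strands.
#'
#' @param model a [build_pwm_model()].
#' @return List with integer support bounds `smin`, `smax`, probability
#'   `mass` per score bin (sums to 1), and survival function `sf`
#'   (`sf[s - smin + 1] = P(S >= s)`, nonincreasing). Scores are in units
#'   of `granularity` bits.
#' @export
null_distribution <- function(model) {
  stopifnot(inherits(model, "PWMModel"))
  model$null
}

# p-value of integer scores s under a score_null() object.
null_pvalue <- function(null, s) {
  p <- numeric(length(s))
  below <- s < null$smin
  above <- s > null$smax
  inside <- !below & !above
  p[below] <- 1
  p[above] <- 0          # unreachable scores; never produced by scanning
  p[inside] <- null$sf[s[inside] - null$smin + 1]
  p
}

# Integer window scores of an encoded sequence (NA where a window covers
# an ambiguous base). Vectorized: w passes over the sequence.
window_scores <- function(code, ilo) {
  w <- nrow(ilo)
  nw <- length(code) - w + 1
  if (nw < 1) return(integer(0))
  s <- integer(nw)
  for (i in seq_len(w)) {
    s <- s + ilo[i, ][code[i:(i + nw - 1)]]
  }
  s
}

#' Scan one promoter sequence for motif occurrences
#'
#' Every window is scored on the forward strand and, when
#' `both_strands`, against the reverse-complemented matrix (equivalent to
#' scanning the reverse complement of the sequence). Windows containing
#' N are skipped. Hits are windows with p <= `alpha`, sorted by p, then
#' offset, then strand ('+' first). Offsets are 0-based starts of the
#' w-base window on the forward strand for both strands.
#'
#' @param model a [build_pwm_model()].
#' @param sequence promoter DNA string.
#' @param alpha occurrence p-value threshold (default 1e-4).
#' @param both_strands scan the reverse strand too (default TRUE).
#' @param gene_id id recorded in the hit table.
#' @return Data frame of hits: `gene_id`, `offset`, `strand`, `score`
#'   (bits), `p_value`.
#' @export
scan_promoter <- function(model, sequence, alpha = 1e-4, both_strands = TRUE,
                          gene_id = NA_character_) {
  stopifnot(inherits(model, "PWMModel"))
  code <- encode_dna(toupper(sequence))
  hits <- scan_codes(model, code, alpha, both_strands)
  if (nrow(hits)) hits$gene_id <- gene_id
  hits[, c("gene_id", "offset", "strand", "score", "p_value")]
}

scan_codes <- function(model, code, alpha, both_strands) {
  empty <- data.frame(gene_id = character(), offset = integer(),
                      strand = character(), score = numeric(),
                      p_value = numeric(), stringsAsFactors = FALSE)
  collect <- function(ilo, null, strand) {
    s <- window_scores(code, ilo)
    ok <- which(!is.na(s))
    if (!length(ok)) return(NULL)
    p <- null_pvalue(null, s[ok])
    hit <- p <= alpha
    if (!any(hit)) return(NULL)
    data.frame(gene_id = NA_character_, offset = ok[hit] - 1L, strand = strand,
               score = s[ok][hit] * model$granularity, p_value = p[hit],
               stringsAsFactors = FALSE)
  }
  res <- collect(model$ilo, model$null, "+")
  if (both_strands) res <- rbind(res, collect(model$ilo_rc, model$null, "-"))
  if (is.null(res) || nrow(res) == 0) return(empty)
  res[order(res$p_value, res$offset, res$strand, method = "radix"), , drop = FALSE]
}

#' Scan a whole promoter set
#'
#' The promoters are concatenated with N spacers and scanned in a few
#' vectorized passes; windows straddling two promoters cover an N and are
#' skipped automatically.
#'
#' @param model a [build_pwm_model()].
#' @param promoters a [promoter_set()].
#' @param alpha occurrence p-value threshold (default 1e-4).
#' @param both_strands scan the reverse strand too (default TRUE).
#' @return Data frame of hits (`gene_id`, `offset`, `strand`, `score`,
#'   `p_value`), sorted by gene, p, offset, strand.
#' @export
scan_promoter_set <- function(model, promoters, alpha = 1e-4, both_strands = TRUE) {
  stopifnot(inherits(promoters, "PromoterSet"))
  w <- model$width
  lens <- nchar(promoters$seq)
  sep <- w  # N spacer long enough that no window spans two promoters
  starts <- cumsum(c(1, lens + sep))[seq_along(lens)]
  big <- paste(promoters$seq, collapse = strrep("N", sep))
  code <- encode_dna(big)
  hits <- scan_codes(model, code, alpha, both_strands)
  if (nrow(hits) == 0) return(hits)
  idx <- findInterval(hits$offset + 1L, starts)
  hits$gene_id <- promoters$gene_id[idx]
  hits$offset <- hits$offset - (starts[idx] - 1L)
  hits <- hits[hits$offset + w <= lens[idx], , drop = FALSE]  # safety
  hits[order(hits$gene_id, hits$p_value, hits$offset, hits$strand,
             method = "radix"), , drop = FALSE]
}

#' Call TF targets across a promoter set
#'
#' A gene is a predicted target of a TF iff its promoter has at least one
#' occurrence at p <= `alpha`. Per (TF, gene) the best hit is retained:
#' smallest p, ties broken by smallest offset, then '+' strand.
#'
#' @param models list of [build_pwm_model()]s (one per TF), or a list of
#'   [pwm_record()]s plus `bg`/`pseudocount`/`granularity` to build them.
#' @param promoters a [promoter_set()].
#' @param alpha occurrence p-value threshold (default 1e-4).
#' @param both_strands scan the reverse strand too (default TRUE).
#' @param bg,pseudocount,granularity passed to [build_pwm_model()] when
#'   `models` are raw records; `bg = "promoter"` estimates 0-order
#'   frequencies from the scanned set, `"uniform"` uses 0.25 each.
#' @return Object of class `TargetCallSet`: list with `calls` (data frame
#'   `tf`, `gene`, `offset`, `strand`, `score`, `p_value`: best hit per
#'   pair), `targets` (named list of target gene vectors per TF), `K`
#'   (named integer vector of per-TF genomic target counts), `alpha`,
#'   `universe` (scanned gene ids).
#' @export
call_targets <- function(models, promoters, alpha = 1e-4, both_strands = TRUE,
                         bg = "promoter", pseudocount = 0.1, granularity = 0.01) {
  stopifnot(inherits(promoters, "PromoterSet"))
  if (length(promoters) == 0) abort("promoter set is empty")
  if (length(models) && inherits(models[[1]], "PWMRecord")) {
    bgv <- if (identical(bg, "promoter")) bg_from_promoters(promoters)
           else if (identical(bg, "uniform")) rep(0.25, 4) else check_bg(bg)
    models <- lapply(models, build_pwm_model, bg = bgv,
                     pseudocount = pseudocount, granularity = granularity)
  }
  calls <- list()
  for (m in models) {
    h <- scan_promoter_set(m, promoters, alpha = alpha, both_strands = both_strands)
    if (nrow(h) == 0) next
    h <- h[order(h$gene_id, h$p_value, h$offset,
                 match(h$strand, c("+", "-")), method = "radix"), , drop = FALSE]
    best <- h[!duplicated(h$gene_id), , drop = FALSE]
    calls[[m$motif_id]] <- data.frame(tf = m$motif_id, gene = best$gene_id,
                                      offset = best$offset, strand = best$strand,
                                      score = best$score, p_value = best$p_value,
                                      stringsAsFactors = FALSE)
  }
  calls_df <- if (length(calls)) do.call(rbind, calls) else {
    data.frame(tf = character(), gene = character(), offset = integer(),
               strand = character(), score = numeric(), p_value = numeric(),
               stringsAsFactors = FALSE)
  }
  rownames(calls_df) <- NULL
  ids <- vapply(models, `[[`, "", "motif_id")
  targets <- lapply(setNames(ids, ids), function(id)
    sort(calls_df$gene[calls_df$tf == id], method = "radix"))
  structure(list(calls = calls_df, targets = targets,
                 K = vapply(targets, length, 0L), alpha = alpha,
                 universe = promoters$gene_id),
            class = "TargetCallSet")
}

#' @export
print.TargetCallSet <- function(x, ...) {
  cat(sprintf("TargetCallSet: %d TFs over %d promoters (alpha %.2g); K = %s\n",
              length(x$targets), length(x$universe), x$alpha,
              paste(sprintf("%s:%d", names(x$K), x$K), collapse = ", ")))
  invisible(x)
}

#' 0-order background frequencies of a promoter set
#'
#' @param promoters a [promoter_set()].
#' @return Frequencies of A,C,G,T over all promoters (N ignored).
#' @export
bg_from_promoters <- function(promoters) {
  tab <- table(factor(unlist(strsplit(promoters$seq, "", fixed = TRUE),
                             use.names = FALSE), levels = DNA_BASES))
  f <- as.numeric(tab) / sum(tab)
  if (any(f == 0)) f <- (as.numeric(tab) + 1) / (sum(tab) + 4)  # degenerate sets
  setNames(f, DNA_BASES)
}
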