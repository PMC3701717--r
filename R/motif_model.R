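#' Build a position weight matrix from aligned motif instances
#'
#' Columnwise base frequencies with an additive pseudocount, and the
#' derived log2 odds against an i.i.d. background. This is the motif model
#' consumed by [score_window()], [exact_pvalues()] and [scan_motif()].
#'
#' @param instances character vector of equal-length DNA strings (ACGT).
#' @param pseudocount count added to every cell before normalization.
#' @param background length-4 base probabilities (A, C, G, T order).
#' @return an object of class `pwm`: a list with `width`, `probs`
#'   (4 x width matrix, rows A/C/G/T), `background`, `pseudocount` and
#'   `log_odds` (4 x width, log2(probs / background)).
#' @examples
#' pwm <- build_pwm(c("ACGT", "ACGT", "ACGA"), pseudocount = 0.1)
#' consensus(pwm)
#' @export
build_pwm <- function(instances, pseudocount = 0.1,
                      background = rep(0.25, 4)) {
  if (length(instances) < 1L) stop("need at least one motif instance")
  w <- unique(nchar(instances))
  if (length(w) != 1L) stop("motif instances must all have the same length")
  if (any(grepl("[^ACGT]", instances))) {
    stop("motif instances must contain only A, C, G, T")
  }
  stopifnot(length(background) == 4, all(background > 0),
            abs(sum(background) - 1) < 1e-6, pseudocount >= 0)
  n <- length(instances)
  counts <- matrix(0, nrow = 4, ncol = w, dimnames = list(DNA_BASES, NULL))
  codes <- lapply(instances, dna_codes)
  for (cd in codes) {
    counts[cbind(cd, seq_len(w))] <- counts[cbind(cd, seq_len(w))] + 1
  }
  probs <- (counts + pseudocount) / (n + 4 * pseudocount)
  log_odds <- log2(probs / background)
  structure(list(width = w, probs = probs,
                 background = as.numeric(background),
                 pseudocount = pseudocount, log_odds = log_odds),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("PWM of width %d (pseudocount %g)\nconsensus: %s\n",
              x$width, x$pseudocount, consensus(x)))
  invisible(x)
}

#' Consensus sequence of a PWM
#'
#' @param pwm a [build_pwm()] object.
#' @return character scalar: the per-column argmax base.
#' @export
consensus <- function(pwm) {
  paste(DNA_BASES[apply(pwm$probs, 2, which.max)], collapse = "")
}

#' Reverse-complement a PWM
#'
#' Probability columns are reversed and rows complemented; log odds are
#' recomputed against the same (forward-strand) background.
#' @param pwm a `pwm` object.
#' @return a `pwm` modelling the reverse complement of the motif.
#' @export
reverse_complement_pwm <- function(pwm) {
  probs <- pwm$probs[4:1, pwm$width:1, drop = FALSE]
  rownames(probs) <- DNA_BASES
  log_odds <- log2(probs / pwm$background)
  structure(list(width = pwm$width, probs = probs,
                 background = pwm$background,
                 pseudocount = pwm$pseudocount, log_odds = log_odds),
            class = "pwm")
}

#' Score one window against a PWM
#'
#' Sum over columns of the log2-odds of the observed base. The base N (or
#' any non-ACGT letter) contributes 0 — neutral with respect to the
#' background.
#'
#' @param pwm a `pwm` object.
#' @param window DNA string of length `pwm$width`.
#' @return numeric log2-odds score.
#' @export
score_window <- function(pwm, window) {
  if (nchar(window) != pwm$width) {
    stop(sprintf("window length %d != PWM width %d", nchar(window), pwm$width))
  }
  lo5 <- rbind(pwm$log_odds, 0)
  sum(lo5[cbind(dna_codes(window), seq_len(pwm$width))])
}

# round half away from zero
.round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# 5-row quantized cell matrix (integer multiples of granularity, N row = 0)
.quantized_cells <- function(pwm, granularity) {
  q <- .round_half_away(pwm$log_odds / granularity)
  rbind(q, 0)
}

#' Exact background score distribution of a PWM
#'
#' Quantizes each log-odds cell to integer multiples of `granularity`
#' (rounding half away from zero) and builds, by columnwise convolution,
#' the exact distribution of the quantized window score under an i.i.d.
#' background. The returned table maps any achievable quantized score s to
#' the tail probability P(random background window scores >= s) — the
#' motif p-value semantics used for scanning.
#'
#' @param pwm a `pwm` object.
#' @param granularity score quantum in log2 units (default 0.01).
#' @param background length-4 background base probabilities; defaults to
#'   the PWM's own background.
#' @return an object of class `score_pvalue_table`: list with
#'   `granularity`, integer score bounds `qmin`/`qmax`, `min_score`/
#'   `max_score` on the log2 scale, and `tail` (tail probabilities indexed
#'   from qmin).
#' @export
exact_pvalues <- function(pwm, granularity = 0.01,
                          background = pwm$background) {
  stopifnot(granularity > 0, length(background) == 4,
            abs(sum(background) - 1) < 1e-6)
  qc <- .round_half_away(pwm$log_odds / granularity)
  finite <- is.finite(qc)
  if (!all(finite)) {
    # cells with zero probability (pseudocount 0) can never beat any
    # finite score; their mass is dropped from the finite tail
    qc[!finite] <- NA
  }
  dist <- 1
  dmin <- 0L
  for (j in seq_len(pwm$width)) {
    vals <- qc[, j]
    keep <- !is.na(vals)
    vals <- vals[keep]
    bg <- background[keep]
    vmin <- min(vals); vmax <- max(vals)
    nd <- numeric(length(dist) + vmax - vmin)
    for (b in seq_along(vals)) {
      off <- vals[b] - vmin
      idx <- seq.int(off + 1L, off + length(dist))
      nd[idx] <- nd[idx] + dist * bg[b]
    }
    dist <- nd
    dmin <- dmin + as.integer(vmin)
  }
  tail <- rev(cumsum(rev(dist)))
  qmin <- dmin
  qmax <- dmin + length(dist) - 1L
  structure(list(granularity = granularity, qmin = qmin, qmax = qmax,
                 min_score = qmin * granularity,
                 max_score = qmax * granularity,
                 tail = tail, background = as.numeric(background)),
            class = "score_pvalue_table")
}

#' Look up a motif p-value for a score
#'
#' @param table a [exact_pvalues()] table.
#' @param score numeric log2-odds score(s); quantized internally with the
#'   table's granularity.
#' @return tail probability P(background window score >= score).
#' @export
pvalue_at <- function(table, score) {
  q <- .round_half_away(score / table$granularity)
  .pvalue_at_q(table, q)
}

.pvalue_at_q <- function(table, q) {
  p <- numeric(length(q))
  p[q < table$qmin] <- 1
  p[q > table$qmax] <- 0
  inb <- q >= table$qmin & q <= table$qmax
  p[inb] <- table$tail[q[inb] - table$qmin + 1L]
  p
}

# smallest quantized score whose tail probability is <= p_threshold,
# or NA if no achievable score reaches it
.score_cutoff_q <- function(table, p_threshold) {
  i <- which(table$tail <= p_threshold)
  if (length(i) == 0L) return(NA_integer_)
  table$qmin + min(i) - 1L
}

# quantized window scores of a code vector under a 5-row quantized cell
# matrix; returns numeric vector of length length(codes) - w + 1
.window_scores_q <- function(codes, q5) {
  w <- ncol(q5)
  np <- length(codes) - w + 1L
  if (np < 1L) return(numeric(0))
  s <- numeric(np)
  for (j in seq_len(w)) {
    s <- s + q5[codes[j:(j + np - 1L)], j]
  }
  s
}

#' Scan sequences for motif hits on both strands
#'
#' Every window whose exact background p-value is at or below
#' `p_threshold` is reported; minus-strand hits (matches of the reverse
#' complement of the motif) are reported in forward-strand coordinates
#' with strand "-". Overlapping hits and ties are kept. The p-value is
#' one-strand: scanning both strands doubles the effective number of
#' tests. Reported scores are quantized at the p-value table's
#' granularity so that score and p-value are mutually consistent.
#'
#' @param seqs a named character vector or `Biostrings::DNAStringSet`.
#' @param pwm a `pwm` object.
#' @param p_threshold motif p-value threshold (default 1e-4).
#' @param granularity score quantum for the exact p-value tables.
#' @return data.frame with columns `seq_id`, `start`, `end` (0-based
#'   half-open, forward strand), `strand`, `score`, `pvalue`.
#' @export
scan_motif <- function(seqs, pwm, p_threshold = 1e-4, granularity = 0.01) {
  stopifnot(p_threshold > 0, p_threshold <= 1)
  if (methods::is(seqs, "DNAStringSet")) seqs <- as.character(seqs)
  ids <- names(seqs) %||% as.character(seq_along(seqs))
  seqs <- unname(as.character(seqs))
  w <- pwm$width
  lens <- nchar(seqs)

  pwm_rc <- reverse_complement_pwm(pwm)
  tbl_f <- exact_pvalues(pwm, granularity)
  tbl_r <- exact_pvalues(pwm_rc, granularity)
  cut_f <- .score_cutoff_q(tbl_f, p_threshold)
  cut_r <- .score_cutoff_q(tbl_r, p_threshold)

  # concatenate with N spacers of length w; windows touching a spacer are
  # discarded, so per-sequence results are exact
  spacer <- strrep("N", w)
  big <- paste(seqs, collapse = spacer)
  codes <- dna_codes(big)
  starts0 <- cumsum(c(0L, lens + w))[seq_along(seqs)]  # 0-based seq origins

  hit1 <- function(q5, cutoff, tbl, strand) {
    if (is.na(cutoff)) return(NULL)
    s <- .window_scores_q(codes, q5)
    idx <- which(s >= cutoff)  # 1-based window starts in `big`
    if (length(idx) == 0L) return(NULL)
    si <- findInterval(idx - 1L, starts0)
    pos0 <- (idx - 1L) - starts0[si]
    ok <- pos0 >= 0L & (pos0 + w) <= lens[si]
    idx <- idx[ok]; si <- si[ok]; pos0 <- pos0[ok]
    if (length(idx) == 0L) return(NULL)
    q <- s[idx]
    data.frame(seq_id = ids[si], start = pos0, end = pos0 + w,
               strand = strand, score = q * tbl$granularity,
               pvalue = .pvalue_at_q(tbl, q),
               stringsAsFactors = FALSE)
  }

  res <- rbind(
    hit1(.quantized_cells(pwm, granularity), cut_f, tbl_f, "+"),
    hit1(.quantized_cells(pwm_rc, granularity), cut_r, tbl_r, "-")
  )
  if (is.null(res)) {
    res <- data.frame(seq_id = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      score = numeric(0), pvalue = numeric(0),
                      stringsAsFactors = FALSE)
  } else {
    res <- res[order(match(res$seq_id, ids), res$start, res$strand), ]
    rownames(res) <- NULL
  }
  res
}

#' Locate a motif and its reverse complement in a transcript
#'
#' Convenience wrapper around [scan_motif()] for a single (c)DNA sequence;
#' the reported strand distinguishes occurrences of the motif itself ("+")
#' from its reverse complement ("-").
#'
#' @param transcript a single DNA string.
#' @param pwm a `pwm` object.
#' @param p_threshold motif p-value threshold.
#' @return hit data.frame as from [scan_motif()] with `seq_id` =
#'   "transcript".
#' @export
find_motif_in_transcript <- function(transcript, pwm, p_threshold = 1e-4) {
  scan_motif(c(transcript = as.character(transcript)), pwm, p_threshold)
}

#' Mutate a fixed fraction of motif positions
#'
#' Exactly `round(fraction * nchar(motif))` positions, chosen uniformly
#' without replacement, are substituted, each to a uniformly chosen
#' different base. Models single-base mutagenesis of a motif at a given
#' severity (e.g. 25%, 33% or 100% of a 48-bp element).
#'
#' @param motif DNA string over ACGT.
#' @param fraction fraction of positions to substitute, in \[0,1\].
#' @param seed integer RNG seed.
#' @return mutated DNA string of the same length.
#' @export
mutate_motif <- function(motif, fraction, seed) {
  stopifnot(fraction >= 0, fraction <= 1)
  if (grepl("[^ACGT]", motif)) stop("motif must contain only A, C, G, T")
  n <- nchar(motif)
  k <- round(fraction * n)
  if (k == 0) return(motif)
  set.seed(as.integer(seed))
  pos <- sample.int(n, k)
  chars <- strsplit(motif, "", fixed = TRUE)[[1]]
  chars[pos] <- vapply(chars[pos], function(b) {
    sample(setdiff(DNA_BASES, b), 1L)
  }, character(1))
  paste(chars, collapse = "")
}
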