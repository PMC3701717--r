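#' Chop sequences into fixed-size pieces
#'
#' Consecutive non-overlapping pieces from each sequence's start; a
#' trailing remainder shorter than `piece` is discarded. This is the unit
#' of resampling for the occurrence bootstrap.
#'
#' @param seqs named character vector, `DNAStringSet` or `promoter_set`.
#' @param piece piece length in nt (default 100).
#' @param groups optional group label per sequence; defaults to the
#'   sequences' `group` metadata column when present.
#' @return data.frame with `seq_id`, `offset` (0-based start in the
#'   parent), `seq` and `group`.
#' @export
chop_sequences <- function(seqs, piece = 100, groups = NULL) {
  stopifnot(piece >= 1)
  if (inherits(seqs, "promoter_set")) seqs <- seqs$sequences
  if (methods::is(seqs, "DNAStringSet")) {
    if (is.null(groups)) {
      g <- S4Vectors::mcols(seqs)$group
      if (!is.null(g)) groups <- as.character(g)
    }
    seqs <- as.character(seqs)
  }
  ids <- names(seqs) %||% as.character(seq_along(seqs))
  groups <- groups %||% rep(NA_character_, length(seqs))
  out <- lapply(seq_along(seqs), function(i) {
    n <- nchar(seqs[[i]]) %/% piece
    if (n == 0L) return(NULL)
    off <- (seq_len(n) - 1L) * piece
    data.frame(seq_id = ids[i], offset = off,
               seq = substring(seqs[[i]], off + 1L, off + piece),
               group = groups[i], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(seq_id = character(0), offset = integer(0),
                      seq = character(0), group = character(0),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Motif hit count per chop
#'
#' Both-strand motif hits at the scan threshold, counted once per chop and
#' intended to be cached for resampling (bootstrapping on cached counts is
#' equivalent to re-scanning each draw).
#'
#' @param chops data.frame from [chop_sequences()].
#' @param pwm a `pwm` object.
#' @param p_threshold motif p-value threshold (default 1e-4).
#' @return integer vector of hit counts, one per chop row.
#' @export
per_chop_hit_counts <- function(chops, pwm, p_threshold = 1e-4) {
  if (nrow(chops) == 0L) return(integer(0))
  seqs <- stats::setNames(chops$seq, sprintf("c%07d", seq_len(nrow(chops))))
  hits <- scan_motif(seqs, pwm, p_threshold)
  counts <- integer(nrow(chops))
  if (nrow(hits) > 0) {
    idx <- as.integer(sub("^c", "", hits$seq_id))
    tab <- table(idx)
    counts[as.integer(names(tab))] <- as.integer(tab)
  }
  counts
}

#' Bootstrap motif occurrence by resampling chops
#'
#' Per repetition and group, draws `n_per_draw` chops uniformly without
#' replacement (independently across repetitions) and records the summed
#' hit count, yielding one occurrence total per repetition. Each group's
#' draws restart from the same seed, so identical chop multisets give
#' identical vectors.
#'
#' @param counts_by_group named list of per-chop hit-count vectors (one
#'   element per group), or an unnamed integer vector combined with
#'   `groups`.
#' @param groups group label per count when `counts_by_group` is a plain
#'   vector.
#' @param n_per_draw chops per draw (default 250).
#' @param repetitions number of repetitions (default 1000).
#' @param seed integer RNG seed.
#' @return object of class `bootstrap_result`: list with `totals` (named
#'   list of numeric vectors of length `repetitions`) and `params`.
#' @export
bootstrap_occurrences <- function(counts_by_group, groups = NULL,
                                  n_per_draw = 250, repetitions = 1000,
                                  seed = 1L) {
  if (!is.list(counts_by_group)) {
    if (is.null(groups)) stop("supply counts as a named list or give 'groups'")
    counts_by_group <- split(counts_by_group, groups)
  }
  small <- names(counts_by_group)[
    vapply(counts_by_group, length, integer(1)) < n_per_draw]
  if (length(small)) {
    stop(sprintf("group(s) smaller than n_per_draw = %d: %s",
                 n_per_draw, paste(small, collapse = ", ")))
  }
  totals <- lapply(counts_by_group, function(cnt) {
    set.seed(as.integer(seed))
    n <- length(cnt)
    vapply(seq_len(repetitions), function(r) {
      sum(cnt[sample.int(n, n_per_draw)])
    }, numeric(1))
  })
  structure(list(totals = totals,
                 params = list(n_per_draw = n_per_draw,
                               repetitions = repetitions, seed = seed)),
            class = "bootstrap_result")
}

#' Compare two bootstrap occurrence distributions
#'
#' Two-sample Kolmogorov-Smirnov test on the per-repetition occurrence
#' totals: D is the supremum absolute difference of the two empirical
#' CDFs, with the standard asymptotic p-value.
#'
#' @param vecA,vecB numeric vectors of per-repetition totals.
#' @return list with `D` and `p`.
#' @export
compare_occurrences <- function(vecA, vecB) {
  stopifnot(length(vecA) > 0, length(vecB) > 0)
  kt <- suppressWarnings(stats::ks.test(vecA, vecB, exact = FALSE))
  list(D = unname(kt$statistic), p = min(1, max(0, kt$p.value)))
}

#' All pairwise group comparisons of a bootstrap result
#'
#' @param result a [bootstrap_occurrences()] result.
#' @return data.frame with `group_a`, `group_b`, `D`, `p`.
#' @export
compare_all_groups <- function(result) {
  gs <- names(result$totals)
  if (length(gs) < 2) stop("need at least two groups to compare")
  prs <- utils::combn(gs, 2)
  out <- apply(prs, 2, function(pr) {
    cc <- compare_occurrences(result$totals[[pr[1]]],
                              result$totals[[pr[2]]])
    data.frame(group_a = pr[1], group_b = pr[2], D = cc$D, p = cc$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("bootstrap_result: %d repetitions x %d chops per draw; groups: %s\n",
              x$params$repetitions, x$params$n_per_draw,
              paste(names(x$totals), collapse = ", ")))
  invisible(x)
}

#' Keep hits that match planted truth intervals
#'
#' A hit matches a truth interval when both lie on the same sequence and
#' strand and overlap by at least one base. With `per_truth = TRUE`
#' (default) at most one hit — the best-scoring one — is kept per truth
#' interval, so the result counts recovered planted copies.
#'
#' @param hits hit data.frame from [scan_motif()].
#' @param truth planted-truth data.frame (see [generate_promoter_set()]).
#' @param per_truth deduplicate to one hit per recovered truth interval.
#' @return subset of `hits`.
#' @export
truth_matched_hits <- function(hits, truth, per_truth = TRUE) {
  if (nrow(hits) == 0L || nrow(truth) == 0L) return(hits[0, , drop = FALSE])
  gh <- GenomicRanges::GRanges(hits$seq_id,
                               IRanges::IRanges(hits$start + 1L, hits$end),
                               strand = hits$strand)
  gt <- GenomicRanges::GRanges(truth$seq_id,
                               IRanges::IRanges(truth$start + 1L, truth$end),
                               strand = truth$strand)
  ov <- GenomicRanges::findOverlaps(gh, gt, ignore.strand = FALSE)
  if (length(ov) == 0L) return(hits[0, , drop = FALSE])
  qh <- S4Vectors::queryHits(ov)
  th <- S4Vectors::subjectHits(ov)
  if (!per_truth) return(hits[sort(unique(qh)), , drop = FALSE])
  sc <- hits$score[qh]
  ord <- order(th, -sc)
  keep <- qh[ord][!duplicated(th[ord])]
  hits[sort(keep), , drop = FALSE]
}

#' Motif occurrences per 5 kb of promoter, by group
#'
#' Per group: total hits divided by total promoter length, scaled to a
#' 5-kb promoter. Groups with no promoters are reported as absent.
#'
#' @param hits hit data.frame (must reference promoter ids).
#' @param promoters `promoter_set` or grouped `DNAStringSet`.
#' @return named numeric vector of per-5-kb occurrence densities.
#' @export
occurrences_per_5kb <- function(hits, promoters) {
  seqs <- if (inherits(promoters, "promoter_set")) promoters$sequences
          else promoters
  groups <- promoter_groups(seqs)
  lens <- Biostrings::width(seqs)
  hit_group <- groups[match(hits$seq_id, names(seqs))]
  out <- vapply(unique(groups), function(g) {
    tot_len <- sum(lens[groups == g])
    sum(hit_group == g, na.rm = TRUE) / tot_len * 5000
  }, numeric(1))
  out
}
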