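#' Average fold change versus control
#'
#' Per transcript, the mean over case lines of the ratio of the case
#' intensity to the mean control intensity (mean of per-line ratios, not
#' ratio of means). Transcripts whose mean control intensity is zero are
#' excluded with a message.
#'
#' @param expr an `expression_matrix` (see [simulate_expression()]) or a
#'   list with `values` (matrix) and `roles` (named character vector of
#'   "case"/"control").
#' @return data.frame with `transcript_id` and `avg_fc`.
#' @export
average_fold_change <- function(expr) {
  v <- expr$values
  roles <- expr$roles[colnames(v)]
  if (!any(roles == "case") || !any(roles == "control")) {
    stop("need at least one case and one control sample")
  }
  if (any(v < 0)) stop("intensities must be non-negative")
  ctrl <- rowMeans(v[, roles == "control", drop = FALSE])
  bad <- ctrl == 0
  if (any(bad)) {
    message(sprintf("excluding %d transcript(s) with zero mean control intensity",
                    sum(bad)))
  }
  keep <- !bad
  fc <- rowMeans(v[keep, roles == "case", drop = FALSE] / ctrl[keep])
  data.frame(transcript_id = rownames(v)[keep], avg_fc = unname(fc),
             stringsAsFactors = FALSE)
}

#' Classify transcripts by average fold change
#'
#' The trans-regulation filter: average fold change below `low` is "down",
#' above `high` is "up", anything else (boundaries included) is "not".
#'
#' @param fcs data.frame from [average_fold_change()], or a named numeric
#'   vector of fold changes.
#' @param low,high strict fold-change thresholds (defaults 0.5 and 2).
#' @return data.frame with `transcript_id`, `avg_fc` and `label` in
#'   \{"up","down","not"\}.
#' @export
classify_transcripts <- function(fcs, low = 0.5, high = 2) {
  stopifnot(low < high)
  if (is.numeric(fcs)) {
    fcs <- data.frame(transcript_id = names(fcs) %||%
                        as.character(seq_along(fcs)),
                      avg_fc = unname(fcs), stringsAsFactors = FALSE)
  }
  label <- ifelse(fcs$avg_fc < low, "down",
                  ifelse(fcs$avg_fc > high, "up", "not"))
  data.frame(transcript_id = fcs$transcript_id, avg_fc = fcs$avg_fc,
             label = label, stringsAsFactors = FALSE)
}

#' Extract strand-aware promoters around TSSs
#'
#' A plus-strand gene's promoter is the forward-strand sequence of
#' `[tss - span, tss)`; a minus-strand gene's is the reverse complement of
#' `[tss, tss + span)`. Promoters truncated at sequence boundaries keep
#' their actual length, which is recorded.
#'
#' @param genes data.frame with `gene_id`, `seq_id`, `tss` (0-based),
#'   `strand`, and optionally `group`.
#' @param genome a `Biostrings::DNAStringSet` (names = seq ids).
#' @param span promoter span in bp (default 5000).
#' @param labels optional data.frame from [classify_transcripts()] whose
#'   `label` column supplies the group per `gene_id` (overrides
#'   `genes$group`).
#' @return `DNAStringSet` named by gene id with metadata columns `group`
#'   (possibly NA), `length` and `truncated`.
#' @export
extract_promoters <- function(genes, genome, span = 5000, labels = NULL) {
  stopifnot(span > 0)
  lens <- stats::setNames(Biostrings::width(genome), names(genome))
  grp <- genes$group %||% rep(NA_character_, nrow(genes))
  if (!is.null(labels)) {
    grp <- labels$label[match(genes$gene_id, labels$transcript_id)]
  }
  keep <- genes$seq_id %in% names(genome) &
    genes$tss >= 0 & genes$tss <= lens[genes$seq_id]
  if (any(!keep)) {
    warning(sprintf("skipping %d gene(s) with TSS outside the genome",
                    sum(!keep)))
  }
  genes <- genes[keep, , drop = FALSE]
  grp <- grp[keep]
  out <- character(nrow(genes))
  plen <- integer(nrow(genes))
  for (i in seq_len(nrow(genes))) {
    L <- lens[[genes$seq_id[i]]]
    tss <- genes$tss[i]
    s <- genome[[genes$seq_id[i]]]
    if (genes$strand[i] == "+") {
      a <- max(0L, tss - span)
      frag <- if (tss > a) as.character(Biostrings::subseq(s, a + 1L, tss))
              else ""
    } else {
      b <- min(L, tss + span)
      frag <- if (b > tss) {
        as.character(Biostrings::reverseComplement(
          Biostrings::subseq(s, tss + 1L, b)))
      } else ""
    }
    out[i] <- frag
    plen[i] <- nchar(frag)
  }
  res <- Biostrings::DNAStringSet(stats::setNames(out, genes$gene_id))
  S4Vectors::mcols(res)$group <- grp
  S4Vectors::mcols(res)$length <- plen
  S4Vectors::mcols(res)$truncated <- plen < span
  res
}

#' Gene-set enrichment of regulated transcripts (one-sided Fisher test)
#'
#' For each gene set, the hypergeometric upper-tail probability of the
#' observed overlap between set members and regulated (up or down)
#' transcripts, against the labeled universe. Set members outside the
#' universe are dropped with a message.
#'
#' @param labels data.frame from [classify_transcripts()].
#' @param sets named list of character vectors (gene sets, e.g. from
#'   [read_gmt()]).
#' @param adjust if TRUE, add Benjamini-Hochberg adjusted p-values.
#' @return data.frame with `set`, `set_size` (in-universe), `regulated`,
#'   `overlap`, `pvalue` (and `padj` if requested).
#' @export
gene_set_enrichment <- function(labels, sets, adjust = FALSE) {
  universe <- unique(labels$transcript_id)
  if (length(universe) == 0) stop("empty labeled universe")
  regulated <- labels$transcript_id[labels$label %in% c("up", "down")]
  N <- length(universe)
  K <- length(unique(regulated))
  res <- lapply(names(sets), function(nm) {
    members <- unique(sets[[nm]])
    inun <- members[members %in% universe]
    dropped <- length(members) - length(inun)
    if (dropped > 0) {
      message(sprintf("set '%s': dropped %d member(s) outside the universe",
                      nm, dropped))
    }
    m <- length(inun)
    k <- sum(inun %in% regulated)
    p <- if (m == 0) 1 else
      phyper(k - 1, K, N - K, m, lower.tail = FALSE)
    data.frame(set = nm, set_size = m, regulated = K, overlap = k,
               pvalue = p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  if (adjust) res$padj <- stats::p.adjust(res$pvalue, method = "BH")
  rownames(res) <- NULL
  res
}
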