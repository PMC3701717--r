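#' Write sequences as FASTA
#'
#' @param seqs `DNAStringSet`, `promoter_set` or named character vector.
#'   Group labels, when present, are encoded in the record ids as
#'   `<id>|group=<group>`.
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  if (inherits(seqs, "promoter_set")) seqs <- seqs$sequences
  if (!methods::is(seqs, "DNAStringSet")) {
    seqs <- Biostrings::DNAStringSet(seqs)
  }
  g <- S4Vectors::mcols(seqs)$group
  out <- seqs
  if (!is.null(g) && !all(is.na(g))) {
    names(out) <- paste0(names(seqs), "|group=", g)
  }
  Biostrings::writeXStringSet(out, path)
  invisible(path)
}

#' Read a FASTA file, recovering group labels from record ids
#'
#' Record ids of the form `<id>|group=<group>` (as written by
#' [write_fasta()]) are split back into a name and a `group` metadata
#' column.
#'
#' @param path FASTA file.
#' @return `DNAStringSet`, with a `group` metadata column when encoded.
#' @export
read_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  nm <- sub("\\s.*$", "", names(seqs))
  has_grp <- grepl("\\|group=", nm)
  if (any(has_grp)) {
    grp <- ifelse(has_grp, sub("^.*\\|group=", "", nm), NA_character_)
    names(seqs) <- sub("\\|group=.*$", "", nm)
    S4Vectors::mcols(seqs)$group <- grp
  } else {
    names(seqs) <- nm
  }
  seqs
}

# data.frame of 0-based half-open intervals -> GRanges (1-based)
.df_to_granges <- function(df, name = NULL, score = 0) {
  gr <- GenomicRanges::GRanges(
    df$seq_id, IRanges::IRanges(df$start + 1L, df$end),
    strand = df$strand)
  S4Vectors::mcols(gr)$name <- if (is.null(name)) "." else
    as.character(name)
  S4Vectors::mcols(gr)$score <- score
  gr
}

#' Write 0-based intervals as BED6
#'
#' Used for planted truth (name column = family id) and motif-anchor
#' intervals. Coordinates in the data.frame are 0-based half-open, as in
#' the BED file itself.
#'
#' @param df data.frame with `seq_id`, `start`, `end`, `strand` and
#'   optionally `family_id`.
#' @param path output file.
#' @export
write_bed6 <- function(df, path) {
  name <- df$family_id %||% rep(".", nrow(df))
  gr <- .df_to_granges(df, name = name, score = 0)
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read a BED6 file into a 0-based interval data.frame
#'
#' @param path BED file.
#' @return data.frame with `seq_id`, `start`, `end` (0-based half-open),
#'   `strand` and `family_id` (integer where the name column is numeric).
#' @export
read_bed6 <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  nm <- S4Vectors::mcols(gr)$name
  fam <- suppressWarnings(as.integer(nm))
  data.frame(
    seq_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    family_id = fam, stringsAsFactors = FALSE)
}

#' Write motif hits as BED6
#'
#' The BED score column is `round(1000 * min(1, -log10(pvalue)) / 10)`.
#' @param hits hit data.frame from [scan_motif()].
#' @param path output file.
#' @export
write_hits_bed <- function(hits, path) {
  score <- round(1000 * pmin(1, -log10(pmax(hits$pvalue, 1e-300))) / 10)
  gr <- .df_to_granges(hits, name = sprintf("hit_%d", seq_len(nrow(hits))),
                       score = score)
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Write motif hits as TSV with full-precision scores
#' @param hits hit data.frame.
#' @param path output file.
#' @export
write_hits_tsv <- function(hits, path) {
  write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialize a PWM as a minimal text matrix
#'
#' Two comment lines carry the background and pseudocount; then 4 rows
#' (A, C, G, T) by width columns of probabilities.
#' @param pwm a `pwm` object.
#' @param path output file.
#' @export
write_pwm <- function(pwm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("#background\t", paste(format(pwm$background, digits = 17),
                                  collapse = "\t")),
    paste0("#pseudocount\t", format(pwm$pseudocount, digits = 17))), con)
  write.table(format(pwm$probs, digits = 17), con, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a PWM written by [write_pwm()]
#' @param path PWM text file.
#' @return a `pwm` object.
#' @export
read_pwm <- function(path) {
  lines <- readLines(path)
  bg <- as.numeric(strsplit(lines[1], "\t")[[1]][-1])
  pc <- as.numeric(strsplit(lines[2], "\t")[[1]][2])
  probs <- as.matrix(read.table(text = lines[-(1:2)], sep = "\t"))
  dimnames(probs) <- list(DNA_BASES, NULL)
  structure(list(width = ncol(probs), probs = probs, background = bg,
                 pseudocount = pc, log_odds = log2(probs / bg)),
            class = "pwm")
}

#' Write alignment records as the tab-separated alignment table
#' @param records alignment record data.frame.
#' @param path output file.
#' @export
write_alignments <- function(records, path) {
  write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read alignment records from TSV or SAM
#'
#' The TSV dialect has a header `read_id seq_id start strand read_length
#' n_best` with 0-based starts. For SAM, `n_best` is taken from the NH
#' tag; records sharing a QNAME are one read's best-hit set (when NH is
#' absent, the QNAME multiplicity is used).
#'
#' @param path input file.
#' @param format "tsv" or "sam" (guessed from the extension by default).
#' @return alignment record data.frame.
#' @export
read_alignments <- function(path, format = c("auto", "tsv", "sam")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.sam$", path, ignore.case = TRUE)) "sam" else "tsv"
  }
  if (format == "tsv") {
    df <- read.table(path, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
    need <- c("read_id", "seq_id", "start", "strand", "read_length",
              "n_best")
    if (!all(need %in% names(df))) {
      stop("alignment table must have columns: ",
           paste(need, collapse = ", "))
    }
    return(df[, need])
  }
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "rname", "pos", "strand", "qwidth"), tag = "NH")
  x <- Rsamtools::scanBam(bam, param = p)[[1]]
  nh <- x$tag$NH
  df <- data.frame(read_id = x$qname, seq_id = as.character(x$rname),
                   start = x$pos - 1L, strand = as.character(x$strand),
                   read_length = x$qwidth, stringsAsFactors = FALSE)
  if (is.null(nh) || all(is.na(nh))) {
    tab <- table(df$read_id)
    df$n_best <- as.integer(tab[df$read_id])
  } else {
    df$n_best <- as.integer(nh)
  }
  df
}

#' Write an expression matrix as TSV
#'
#' Header row is `transcript_id` followed by the sample ids; sample roles
#' are carried in the column names (prefixes `case_` / `control_`).
#' @param expr an `expression_matrix`.
#' @param path output file.
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(transcript_id = rownames(expr$values), expr$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an expression matrix written by [write_expression()]
#'
#' @param path TSV file.
#' @param roles optional named character vector of sample roles; by
#'   default inferred from the `case_` / `control_` column-name prefixes.
#' @return an `expression_matrix` (without truth labels).
#' @export
read_expression <- function(path, roles = NULL) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- df$transcript_id
  if (is.null(roles)) {
    roles <- ifelse(grepl("^control", colnames(values)), "control", "case")
    names(roles) <- colnames(values)
  }
  structure(list(values = values, roles = roles, truth = NULL),
            class = "expression_matrix")
}

#' Write a coverage track as fixed-step WIG
#'
#' 1-based, step 1, span 1 — the dialect produced by ChIP-seq pipelines
#' before meta-profiling.
#' @param track a [coverage_track()].
#' @param path output file.
#' @export
write_wig <- function(track, path) {
  gr <- GenomicRanges::GRanges(
    names(track$seqlengths),
    IRanges::IRanges(1L, unname(track$seqlengths)))
  gp <- GenomicRanges::GPos(gr)
  S4Vectors::mcols(gp)$score <- unlist(track$values, use.names = FALSE)
  rtracklayer::export(gp, path, format = "wig")
  invisible(path)
}

#' Read gene sets from a GMT file
#' @param path GMT file.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Write a bootstrap result as long-format TSV
#' @param result a [bootstrap_occurrences()] result.
#' @param path output file.
#' @export
write_bootstrap <- function(result, path) {
  df <- do.call(rbind, lapply(names(result$totals), function(g) {
    data.frame(repetition = seq_along(result$totals[[g]]), group = g,
               count = result$totals[[g]], stringsAsFactors = FALSE)
  }))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an anchored profile as TSV (offset, mean, n)
#' @param profile an [anchored_profile()].
#' @param path output file.
#' @export
write_profile <- function(profile, path) {
  write.table(as.data.frame(profile), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
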