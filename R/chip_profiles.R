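#' Resolve alignment records into weighted placements
#'
#' Implements the two read policies for repetitive regions. Under the
#' "multi" (multiple-matching) policy each of a read's `n_best` equally
#' best alignments becomes a placement of weight `1/n_best`, so a read
#' always contributes total mass 1 (a full-weight variant is available for
#' sensitivity analysis). Under the strict "unique" policy only reads with
#' a single best alignment are retained, at weight 1.
#'
#' @param records data.frame of alignment records (`read_id`, `seq_id`,
#'   `start`, `strand`, `read_length`, `n_best`).
#' @param policy "multi" or "unique".
#' @param full_weight if TRUE under "multi", each placement gets weight 1
#'   instead of `1/n_best`.
#' @param validate check that every read has exactly `n_best` records all
#'   agreeing on `n_best`.
#' @return object of class `placement_set`: list with `placements`
#'   (data.frame `seq_id`, `start`, `end`, `weight`), `total_weight`
#'   (total retained read mass) and `policy`.
#' @export
resolve_placements <- function(records, policy = c("multi", "unique"),
                               full_weight = FALSE, validate = TRUE) {
  policy <- match.arg(policy)
  if (validate && nrow(records) > 0) {
    f <- factor(records$read_id)
    nrec <- tabulate(f)
    nb_min <- tapply(records$n_best, f, min)
    nb_max <- tapply(records$n_best, f, max)
    if (any(nb_min != nb_max)) {
      bad <- levels(f)[which(nb_min != nb_max)[1]]
      stop(sprintf("inconsistent n_best across records of read '%s'", bad))
    }
    if (any(nrec != nb_min)) {
      i <- which(nrec != nb_min)[1]
      stop(sprintf("read '%s' has %d records but n_best = %d",
                   levels(f)[i], nrec[i], nb_min[[i]]))
    }
  }
  if (policy == "multi") {
    w <- if (full_weight) rep(1, nrow(records)) else 1 / records$n_best
    pl <- data.frame(seq_id = records$seq_id, start = records$start,
                     end = records$start + records$read_length,
                     weight = w, stringsAsFactors = FALSE)
  } else {
    keep <- records$n_best == 1L
    pl <- data.frame(seq_id = records$seq_id[keep],
                     start = records$start[keep],
                     end = records$start[keep] + records$read_length[keep],
                     weight = rep(1, sum(keep)), stringsAsFactors = FALSE)
  }
  structure(list(placements = pl, total_weight = sum(pl$weight),
                 policy = policy), class = "placement_set")
}

#' Per-base coverage track from weighted placements
#'
#' Pileup of placement weights over `[start, end)` per sequence. RPM
#' normalization divides by the total retained read mass and multiplies by
#' one million, matching "reads per million mapped reads".
#'
#' @param placements a `placement_set` (or a data.frame with `seq_id`,
#'   `start`, `end`, `weight`, in which case `total_weight` must be given).
#' @param seqlengths named integer vector of sequence lengths.
#' @param normalize "RPM" or "raw".
#' @param total_weight total retained read mass (taken from the
#'   `placement_set` when available).
#' @return object of class `coverage_track`: list with `values` (named
#'   list of per-base numeric vectors), `normalization`,
#'   `total_retained_weight` and `seqlengths`.
#' @export
coverage_track <- function(placements, seqlengths,
                           normalize = c("RPM", "raw"),
                           total_weight = NULL) {
  normalize <- match.arg(normalize)
  if (inherits(placements, "placement_set")) {
    total_weight <- placements$total_weight
    pl <- placements$placements
  } else {
    pl <- placements
    if (is.null(total_weight)) total_weight <- sum(pl$weight)
  }
  if (nrow(pl) > 0) {
    bad <- !(pl$seq_id %in% names(seqlengths)) | pl$start < 0 |
      pl$end > seqlengths[pl$seq_id]
    if (any(bad)) {
      i <- which(bad)[1]
      stop(sprintf("placement out of bounds: %s:[%d,%d)", pl$seq_id[i],
                   pl$start[i], pl$end[i]))
    }
  }
  if (normalize == "RPM" && total_weight <= 0) {
    stop("cannot RPM-normalize a track with zero retained read mass")
  }
  scale <- if (normalize == "RPM") 1e6 / total_weight else 1
  values <- lapply(names(seqlengths), function(s) numeric(seqlengths[[s]]))
  names(values) <- names(seqlengths)
  if (nrow(pl) > 0) {
    for (s in unique(pl$seq_id)) {
      rows <- pl$seq_id == s
      L <- seqlengths[[s]]
      delta <- numeric(L + 1L)
      st <- pl$start[rows] + 1L
      en <- pl$end[rows] + 1L
      w <- pl$weight[rows] * scale
      add_s <- tapply(w, st, sum)
      add_e <- tapply(w, en, sum)
      delta[as.integer(names(add_s))] <- delta[as.integer(names(add_s))] + add_s
      delta[as.integer(names(add_e))] <- delta[as.integer(names(add_e))] - add_e
      values[[s]] <- cumsum(delta[seq_len(L)])
    }
  }
  structure(list(values = values, normalization = normalize,
                 total_retained_weight = total_weight,
                 seqlengths = seqlengths), class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("coverage_track (%s): %d sequence(s), %.0f bp, total retained weight %.1f\n",
              x$normalization, length(x$values),
              sum(as.numeric(x$seqlengths)), x$total_retained_weight))
  invisible(x)
}

#' Anchors at motif (or truth) interval starts
#'
#' The anchor point is the interval's start on its own strand: the
#' forward-strand `start` for "+" intervals and `end - 1` for "-"
#' intervals, with the interval's strand as orientation.
#'
#' @param intervals data.frame with `seq_id`, `start`, `end` (0-based
#'   half-open) and `strand` — motif hits or planted truth.
#' @return data.frame with `seq_id`, `position` (0-based), `orientation`.
#' @export
anchors_from_intervals <- function(intervals) {
  data.frame(
    seq_id = intervals$seq_id,
    position = ifelse(intervals$strand == "+", intervals$start,
                      intervals$end - 1L),
    orientation = intervals$strand, stringsAsFactors = FALSE)
}

#' Random anchors as a control
#'
#' Positions uniform over the genome (length-weighted across sequences),
#' orientations uniform; reproducible per seed. Serves as the random-DNA
#' control against motif-anchored enrichment.
#'
#' @param seqlengths named integer vector of sequence lengths.
#' @param n number of anchors.
#' @param seed integer RNG seed.
#' @return anchor data.frame (`seq_id`, `position`, `orientation`).
#' @export
random_anchor_control <- function(seqlengths, n, seed = 1L) {
  stopifnot(n >= 1)
  set.seed(as.integer(seed))
  si <- sample.int(length(seqlengths), n, replace = TRUE,
                   prob = seqlengths)
  pos <- floor(runif(n) * seqlengths[si])
  data.frame(seq_id = names(seqlengths)[si], position = as.integer(pos),
             orientation = sample(c("+", "-"), n, replace = TRUE),
             stringsAsFactors = FALSE)
}

#' Direction-aware meta-profile around anchors
#'
#' For a "+" anchor at position p, offset o reads the track at p + o; for
#' a "-" anchor, at p - o — so positive offsets are always downstream in
#' the anchor's own orientation. The per-offset mean is taken over the
#' anchors whose sampled position is in bounds; anchors are excluded per
#' offset, not globally.
#'
#' @param track a [coverage_track()].
#' @param anchors anchor data.frame (`seq_id`, `position`, `orientation`).
#' @param span flank on each side in bp (default 10000); the window is
#'   `2*span/resolution + 1` points.
#' @param resolution offset step in bp (default 1).
#' @return object of class `anchored_profile`: data.frame with `offset`,
#'   `mean` (NA where no anchor is in bounds) and `n`, with `span` and
#'   `resolution` attributes.
#' @export
anchored_profile <- function(track, anchors, span = 10000, resolution = 1) {
  if (nrow(anchors) == 0L) stop("no anchors supplied")
  if (any(!(anchors$seq_id %in% names(track$values)))) {
    stop("anchors reference sequences absent from the track")
  }
  offsets <- seq(-span, span, by = resolution)
  m <- length(offsets)
  sums <- numeric(m)
  n <- integer(m)
  for (i in seq_len(nrow(anchors))) {
    v <- track$values[[anchors$seq_id[i]]]
    dir <- if (anchors$orientation[i] == "+") 1L else -1L
    pos <- anchors$position[i] + dir * offsets
    inb <- pos >= 0L & pos < length(v)
    sums[inb] <- sums[inb] + v[pos[inb] + 1L]
    n[inb] <- n[inb] + 1L
  }
  mean <- ifelse(n > 0, sums / pmax(n, 1L), NA_real_)
  out <- data.frame(offset = offsets, mean = mean, n = n)
  attr(out, "span") <- span
  attr(out, "resolution") <- resolution
  class(out) <- c("anchored_profile", "data.frame")
  out
}

#' Peak offset of an anchored profile
#'
#' Moving-average smoothing (window truncated at the edges and at missing
#' offsets) followed by the offset of the global maximum; ties resolve to
#' the smallest absolute offset. An all-flat (or all-missing) profile
#' returns offset 0 with `flat = TRUE`.
#'
#' @param profile an [anchored_profile()].
#' @param smooth_window moving-average window in profile points (default
#'   25).
#' @return list with `offset` (bp), `flat` (logical) and `smoothed`
#'   (numeric vector).
#' @export
estimate_peak_offset <- function(profile, smooth_window = 25) {
  stopifnot(nrow(profile) > 0, smooth_window >= 1)
  x <- profile$mean
  n <- length(x)
  half <- (smooth_window - 1) %/% 2
  val <- ifelse(is.na(x), 0, x)
  cnt <- as.numeric(!is.na(x))
  cv <- cumsum(val)
  cc <- cumsum(cnt)
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  sm_sum <- cv[hi] - c(0, cv)[lo]
  sm_cnt <- cc[hi] - c(0, cc)[lo]
  sm <- ifelse(sm_cnt > 0, sm_sum / sm_cnt, NA_real_)
  fin <- which(!is.na(sm))
  if (length(fin) == 0L ||
      diff(range(sm[fin])) < .Machine$double.eps * 100) {
    return(list(offset = 0, flat = TRUE, smoothed = sm))
  }
  mx <- max(sm[fin])
  cand <- fin[sm[fin] >= mx - .Machine$double.eps * max(1, abs(mx)) * 10]
  off <- profile$offset[cand]
  list(offset = off[which.min(abs(off))], flat = FALSE, smoothed = sm)
}

#' TSS-anchored profiles per regulation group
#'
#' One direction-aware meta-profile per group, anchored at each gene's
#' transcription start site with the gene's strand as orientation.
#'
#' @param track a [coverage_track()].
#' @param genes data.frame with `gene_id`, `seq_id`, `tss`, `strand` and
#'   `group`.
#' @param span,resolution as in [anchored_profile()].
#' @return named list of `anchored_profile` objects, one per group.
#' @export
tss_profile <- function(track, genes, span = 10000, resolution = 1) {
  if (is.null(genes$group)) stop("genes must carry a 'group' column")
  grp <- split(genes, genes$group)
  if (any(vapply(grp, nrow, integer(1)) == 0L)) stop("empty gene group")
  lapply(grp, function(gg) {
    anchors <- data.frame(seq_id = gg$seq_id, position = gg$tss,
                          orientation = gg$strand,
                          stringsAsFactors = FALSE)
    anchored_profile(track, anchors, span = span, resolution = resolution)
  })
}

#' Plot an anchored profile
#'
#' @param x an `anchored_profile`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.anchored_profile <- function(x, ...) {
  graphics::plot(x$offset, x$mean, type = "l",
                 xlab = "offset from anchor (bp)", ylab = "mean signal",
                 ...)
  invisible(x)
}
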