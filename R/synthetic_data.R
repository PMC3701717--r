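#' Simulation configuration
#'
#' All parameters of the synthetic-data generator: grouped Alu-planted
#' promoters, multi-mapping read families, enriched ChIP alignments and
#' planted expression matrices. Defaults encode the study conditions the
#' analysis targets: three promoter groups (up-, down-, not-regulated)
#' with planting densities of 4, 4 and 6 Alu copies per 5-kb promoter,
#' ChIP enrichment centred 150 bp downstream of the motif, and a
#' fold-change of 3 for regulated transcripts.
#'
#' @param seed master integer seed; per-stage RNG streams are derived from
#'   it by fixed offsets.
#' @param n_promoters named integer vector: promoters per group.
#' @param promoter_length promoter length in bp (default 5000).
#' @param planting_density named numeric: expected planted Alu copies per
#'   5 kb for each group (defaults 4 regulated / 6 not-regulated).
#' @param divergence per-base substitution probability applied to each
#'   planted copy (default 0.01).
#' @param gc background GC fraction (default 0.41, human-like).
#' @param chip list overriding ChIP defaults: `offset_bp` (150, bp
#'   downstream of the motif where fragment centres concentrate),
#'   `spread_sd` (40 bp), `enriched_fraction` (0.5), `n_reads` (200000),
#'   `read_length` (36), `family_size` (3), `family_fraction` (0.2).
#' @param expr list overriding expression defaults: `n_transcripts`
#'   (2000), `n_case_lines` (4), `n_control_lines` (1), `frac_up` (0.1),
#'   `frac_down` (0.1), `log2_effect` (log2(3)), `noise_sd` (0.2, log2
#'   units), `baseline_meanlog` (log(100)), `baseline_sdlog` (1).
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_promoters = c(up = 1000L, down = 1000L,
                                              not = 1000L),
                              promoter_length = 5000L,
                              planting_density = c(up = 4, down = 4,
                                                   not = 6),
                              divergence = 0.01,
                              gc = 0.41,
                              chip = list(),
                              expr = list()) {
  chip_def <- list(offset_bp = 150, spread_sd = 40, enriched_fraction = 0.5,
                   n_reads = 200000L, read_length = 36L,
                   family_size = 3L, family_fraction = 0.2)
  expr_def <- list(n_transcripts = 2000L, n_case_lines = 4L,
                   n_control_lines = 1L, frac_up = 0.1, frac_down = 0.1,
                   log2_effect = log2(3), noise_sd = 0.2,
                   baseline_meanlog = log(100), baseline_sdlog = 1)
  chip <- utils::modifyList(chip_def, chip)
  expr <- utils::modifyList(expr_def, expr)
  stopifnot(
    length(n_promoters) >= 1, all(n_promoters >= 0),
    promoter_length > 0,
    identical(sort(names(n_promoters)), sort(names(planting_density))),
    all(planting_density >= 0),
    divergence >= 0, divergence <= 1, gc >= 0, gc <= 1,
    chip$enriched_fraction >= 0, chip$enriched_fraction <= 1,
    chip$family_fraction >= 0, chip$family_fraction <= 1,
    chip$n_reads >= 0, chip$read_length > 0,
    chip$family_size >= 1, chip$spread_sd >= 0,
    expr$frac_up >= 0, expr$frac_down >= 0,
    expr$frac_up + expr$frac_down <= 1,
    expr$noise_sd >= 0, expr$n_case_lines >= 1, expr$n_control_lines >= 1
  )
  structure(list(seed = as.integer(seed), n_promoters = n_promoters,
                 promoter_length = as.integer(promoter_length),
                 planting_density = planting_density,
                 divergence = divergence, gc = gc,
                 chip = chip, expr = expr),
            class = "simulation_config")
}

#' Build an Alu-like repeat template
#'
#' A repeat of length `flank_5 + nchar(core) + flank_3` whose core region
#' is the input core motif with each position independently substituted
#' (to a different base) with probability `divergence`; flanks are
#' i.i.d. background DNA of the given GC fraction.
#'
#' @param core DNA string over ACGT (e.g. [alu_core()]).
#' @param flank_5,flank_3 flank lengths (defaults 100 and 175, giving a
#'   300-bp Alu-sized template for the 25-nt core).
#' @param divergence per-base substitution probability for the core.
#' @param seed integer RNG seed.
#' @param gc background GC fraction for the flanks.
#' @param name template label.
#' @return object of class `repeat_template`: list with `sequence`,
#'   `core_start`, `core_end` (0-based half-open) and `name`.
#' @export
make_alu_repeat <- function(core, flank_5 = 100, flank_3 = 175,
                            divergence = 0, seed = 1L, gc = 0.41,
                            name = "Alu-DEIN") {
  if (nchar(core) == 0 || grepl("[^ACGT]", core)) {
    stop("core must be a non-empty DNA string over A, C, G, T")
  }
  stopifnot(divergence >= 0, divergence <= 1, flank_5 >= 0, flank_3 >= 0)
  set.seed(as.integer(seed))
  left <- random_dna(flank_5, gc)
  right <- random_dna(flank_3, gc)
  core_div <- mutate_bases(core, divergence)
  structure(list(sequence = paste0(left, core_div, right),
                 core_start = as.integer(flank_5),
                 core_end = as.integer(flank_5 + nchar(core)),
                 name = name),
            class = "repeat_template")
}

# sample k non-overlapping 0-based starts for intervals of length ilen in
# [0, plen - ilen], uniformly over all non-overlapping configurations:
# draw k offsets in the free space, sort, and add cumulative interval
# lengths. Never fails while the packing is feasible.
.place_nonoverlapping <- function(k, plen, ilen) {
  if (k == 0L) return(integer(0))
  free <- plen - k * ilen
  if (free < 0L) {
    stop(sprintf(
      "cannot place %d non-overlapping copies of length %d in %d bp",
      k, ilen, plen))
  }
  gaps <- sort(floor(runif(k) * (free + 1)))
  as.integer(gaps + (seq_len(k) - 1L) * ilen)
}

#' Generate a grouped, Alu-planted promoter set with ground truth
#'
#' For each group, `n_promoters` background sequences of
#' `promoter_length`; the number of planted repeat copies per promoter is
#' Poisson(density x length/5000), positions uniform without overlap,
#' strands uniform. A fraction `family_fraction` of copies is assigned to
#' identical-copy families of size `family_size` (members byte-identical,
#' placed in distinct promoters; divergence applied once per family);
#' remaining copies diverge independently. The truth table records every
#' planted core-motif interval.
#'
#' @param cfg a [simulation_config()].
#' @param template a [make_alu_repeat()] template.
#' @return list of class `promoter_set`: `sequences`
#'   (`Biostrings::DNAStringSet`, group in `S4Vectors::mcols()$group`) and
#'   `truth` (data.frame `seq_id`, `start`, `end` 0-based half-open,
#'   `strand`, `family_id`; family_id 0 marks a unique copy).
#' @export
generate_promoter_set <- function(cfg, template) {
  stopifnot(inherits(cfg, "simulation_config"),
            inherits(template, "repeat_template"))
  set.seed(derive_seed(cfg$seed, 1L))
  plen <- cfg$promoter_length
  tlen <- nchar(template$sequence)
  clen <- template$core_end - template$core_start

  seq_list <- character(0)
  grp_list <- character(0)
  truth <- list()
  fam_counter <- 0L

  for (g in names(cfg$n_promoters)) {
    ng <- cfg$n_promoters[[g]]
    if (ng == 0L) next
    dens <- cfg$planting_density[[g]]
    ids <- sprintf("%s_%04d", g, seq_len(ng))
    backs <- vapply(seq_len(ng), function(i) random_dna(plen, cfg$gc),
                    character(1))
    kcopies <- rpois(ng, dens * plen / 5000)
    placements <- list()
    for (i in seq_len(ng)) {
      if (kcopies[i] == 0L) next
      st <- .place_nonoverlapping(kcopies[i], plen, tlen)
      placements[[length(placements) + 1L]] <-
        data.frame(prom = i, pos = st)
    }
    if (length(placements) > 0L) {
      pl <- do.call(rbind, placements)
      n_cop <- nrow(pl)
      # family assignment: greedy over a shuffled pool, members in
      # distinct promoters; incomplete families fall back to unique copies
      n_fam <- floor(cfg$chip$family_fraction * n_cop / cfg$chip$family_size)
      pl$family <- 0L
      if (n_fam > 0L) {
        pool <- sample.int(n_cop)
        for (f in seq_len(n_fam)) {
          sel <- integer(0)
          proms <- integer(0)
          for (j in pool) {
            if (!(pl$prom[j] %in% proms)) {
              sel <- c(sel, j); proms <- c(proms, pl$prom[j])
              if (length(sel) == cfg$chip$family_size) break
            }
          }
          if (length(sel) < cfg$chip$family_size) break
          fam_counter <- fam_counter + 1L
          pl$family[sel] <- fam_counter
          pool <- setdiff(pool, sel)
        }
      }
      # per-family / per-copy sequence and strand
      pl$strand <- NA_character_
      pl$frag <- NA_character_
      for (f in setdiff(unique(pl$family), 0L)) {
        rows <- which(pl$family == f)
        strand <- sample(c("+", "-"), 1L)
        fseq <- mutate_bases(template$sequence, cfg$divergence)
        ins <- if (strand == "+") fseq else revcomp(fseq)
        pl$strand[rows] <- strand
        pl$frag[rows] <- ins
      }
      uniq <- which(pl$family == 0L)
      for (j in uniq) {
        strand <- sample(c("+", "-"), 1L)
        cseq <- mutate_bases(template$sequence, cfg$divergence)
        pl$strand[j] <- strand
        pl$frag[j] <- if (strand == "+") cseq else revcomp(cseq)
      }
      # splice fragments into promoter backgrounds
      for (r in seq_len(n_cop)) {
        i <- pl$prom[r]; s <- pl$pos[r]
        substr(backs[i], s + 1L, s + tlen) <- pl$frag[r]
      }
      # truth: forward-strand coordinates of the planted core
      core_start <- ifelse(pl$strand == "+",
                           pl$pos + template$core_start,
                           pl$pos + tlen - template$core_end)
      truth[[length(truth) + 1L]] <- data.frame(
        seq_id = ids[pl$prom], start = as.integer(core_start),
        end = as.integer(core_start + clen), strand = pl$strand,
        family_id = pl$family, stringsAsFactors = FALSE)
    }
    names(backs) <- ids
    seq_list <- c(seq_list, backs)
    grp_list <- c(grp_list, rep(g, ng))
  }

  seqs <- Biostrings::DNAStringSet(seq_list)
  S4Vectors::mcols(seqs)$group <- grp_list
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(seq_id = character(0), start = integer(0), end = integer(0),
               strand = character(0), family_id = integer(0),
               stringsAsFactors = FALSE)
  truth <- truth[order(match(truth$seq_id, names(seqs)), truth$start), ]
  rownames(truth) <- NULL
  structure(list(sequences = seqs, truth = truth), class = "promoter_set")
}

#' @export
print.promoter_set <- function(x, ...) {
  grp <- table(S4Vectors::mcols(x$sequences)$group)
  cat(sprintf("promoter_set: %d sequences (%s); %d planted truth intervals\n",
              length(x$sequences),
              paste(sprintf("%s=%d", names(grp), grp), collapse = ", "),
              nrow(x$truth)))
  invisible(x)
}

#' Group labels of a promoter set or grouped DNAStringSet
#' @param x a `promoter_set` or a `DNAStringSet` with a `group` metadata
#'   column.
#' @return character vector of group labels, one per sequence.
#' @export
promoter_groups <- function(x) {
  seqs <- if (inherits(x, "promoter_set")) x$sequences else x
  g <- S4Vectors::mcols(seqs)$group
  if (is.null(g)) stop("no 'group' metadata column on the sequences")
  as.character(g)
}

#' Simulate ChIP-seq alignment records with planted enrichment
#'
#' A fraction `enriched_fraction` of reads is assigned to a random planted
#' Alu copy; the fragment centre is drawn Normal(offset_bp, spread_sd)
#' downstream of the copy's core start along the copy's orientation (for
#' minus-strand copies the offset extends toward lower coordinates and the
#' record strand is flipped). Remaining reads are placed uniformly. A read
#' simulated from a member of an identical-copy family yields one record
#' per family member (homologous position, shared read id) with `n_best`
#' equal to the family size; all other reads have `n_best = 1`. Reads that
#' would extend beyond a sequence end are resampled, never truncated.
#'
#' @param promoters a `promoter_set` or `DNAStringSet`.
#' @param truth planted-truth data.frame (see [generate_promoter_set()]);
#'   defaults to the promoter set's own truth.
#' @param cfg a [simulation_config()]; the `chip` block is used.
#' @return data.frame of alignment records: `read_id`, `seq_id`, `start`
#'   (0-based leftmost), `strand`, `read_length`, `n_best`.
#' @export
simulate_chip_alignments <- function(promoters, truth = NULL, cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  seqs <- if (inherits(promoters, "promoter_set")) promoters$sequences
          else promoters
  if (is.null(truth) && inherits(promoters, "promoter_set")) {
    truth <- promoters$truth
  }
  truth <- truth %||%
    data.frame(seq_id = character(0), start = integer(0), end = integer(0),
               strand = character(0), family_id = integer(0))
  lens <- stats::setNames(Biostrings::width(seqs), names(seqs))
  if (nrow(truth) > 0 &&
      (any(!(truth$seq_id %in% names(lens))) ||
       any(truth$end > lens[truth$seq_id]) || any(truth$start < 0))) {
    stop("truth intervals must lie within the promoter sequences")
  }
  ch <- cfg$chip
  rl <- ch$read_length
  half <- rl %/% 2L
  set.seed(derive_seed(cfg$seed, 2L))

  n_enr <- if (nrow(truth) > 0) round(ch$enriched_fraction * ch$n_reads)
           else 0L
  n_uni <- ch$n_reads - n_enr

  rec <- list()
  if (n_enr > 0) {
    anchor <- ifelse(truth$strand == "+", truth$start, truth$end - 1L)
    dirsgn <- ifelse(truth$strand == "+", 1, -1)
    tlen_v <- lens[truth$seq_id]
    fam_members <- split(seq_len(nrow(truth)), truth$family_id)
    fam_members[["0"]] <- NULL

    src <- sample.int(nrow(truth), n_enr, replace = TRUE)
    delta <- rnorm(n_enr, ch$offset_bp, ch$spread_sd)
    # a read is valid only if it (and, for family copies, every homologous
    # member placement) lies fully inside its sequence
    start_for <- function(rows, dl) {
      as.integer(round(anchor[rows] + dirsgn[rows] * dl)) - half
    }
    valid1 <- function(rows, st) st >= 0L & (st + rl) <= tlen_v[rows]
    ok <- logical(n_enr)
    st0 <- start_for(src, delta)
    ok <- valid1(src, st0)
    fam_of <- truth$family_id[src]
    fam_reads <- which(fam_of > 0L)
    for (i in fam_reads) {
      if (!ok[i]) next
      mem <- fam_members[[as.character(fam_of[i])]]
      stm <- start_for(mem, delta[i])
      ok[i] <- all(valid1(mem, stm))
    }
    tries <- 0L
    while (any(!ok) && tries < 200L) {
      bad <- which(!ok)
      delta[bad] <- rnorm(length(bad), ch$offset_bp, ch$spread_sd)
      if (tries >= 50L) {
        src[bad] <- sample.int(nrow(truth), length(bad), replace = TRUE)
      }
      st0[bad] <- start_for(src[bad], delta[bad])
      ok[bad] <- valid1(src[bad], st0[bad])
      fam_of[bad] <- truth$family_id[src[bad]]
      for (i in bad) {
        if (!ok[i] || fam_of[i] == 0L) next
        mem <- fam_members[[as.character(fam_of[i])]]
        stm <- start_for(mem, delta[i])
        ok[i] <- all(valid1(mem, stm))
      }
      tries <- tries + 1L
    }
    if (any(!ok)) stop("failed to place enriched reads within bounds")

    rid <- sprintf("r%07d", seq_len(n_enr))
    # unique-copy reads: one record each
    u <- which(fam_of == 0L)
    if (length(u)) {
      rec[[length(rec) + 1L]] <- data.frame(
        read_id = rid[u], seq_id = truth$seq_id[src[u]], start = st0[u],
        strand = truth$strand[src[u]], read_length = rl, n_best = 1L,
        stringsAsFactors = FALSE)
    }
    # family reads: one record per member, n_best = family size
    for (i in fam_reads) {
      mem <- fam_members[[as.character(fam_of[i])]]
      stm <- start_for(mem, delta[i])
      rec[[length(rec) + 1L]] <- data.frame(
        read_id = rid[i], seq_id = truth$seq_id[mem], start = stm,
        strand = truth$strand[mem], read_length = rl,
        n_best = length(mem), stringsAsFactors = FALSE)
    }
  }
  if (n_uni > 0) {
    si <- sample.int(length(lens), n_uni, replace = TRUE, prob = lens)
    st <- floor(runif(n_uni) * (lens[si] - rl + 1))
    rec[[length(rec) + 1L]] <- data.frame(
      read_id = sprintf("u%07d", seq_len(n_uni)),
      seq_id = names(lens)[si], start = as.integer(st),
      strand = sample(c("+", "-"), n_uni, replace = TRUE),
      read_length = rl, n_best = 1L, stringsAsFactors = FALSE)
  }
  out <- if (length(rec)) do.call(rbind, rec) else
    data.frame(read_id = character(0), seq_id = character(0),
               start = integer(0), strand = character(0),
               read_length = integer(0), n_best = integer(0),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Simulate an expression matrix with planted regulation
#'
#' Control lines follow a log-normal baseline; case lines multiply
#' truth-up transcripts by `2^log2_effect` and truth-down transcripts by
#' `2^-log2_effect`; every measurement carries multiplicative log-normal
#' noise of `noise_sd` log2 units.
#'
#' @param cfg a [simulation_config()]; the `expr` block is used.
#' @return list of class `expression_matrix`: `values` (transcripts x
#'   samples matrix), `roles` (named character: "case" / "control" per
#'   sample) and `truth` (data.frame `transcript_id`, `label`).
#' @export
simulate_expression <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  e <- cfg$expr
  set.seed(derive_seed(cfg$seed, 3L))
  n <- e$n_transcripts
  n_up <- round(e$frac_up * n)
  n_down <- round(e$frac_down * n)
  label <- c(rep("up", n_up), rep("down", n_down),
             rep("not", n - n_up - n_down))
  label <- sample(label)  # scatter across transcript ids
  ids <- sprintf("t%05d", seq_len(n))
  base <- rlnorm(n, e$baseline_meanlog, e$baseline_sdlog)
  eff <- ifelse(label == "up", e$log2_effect,
                ifelse(label == "down", -e$log2_effect, 0))
  ctrl <- matrix(base * 2^rnorm(n * e$n_control_lines, 0, e$noise_sd),
                 nrow = n)
  case <- matrix(base * 2^eff *
                   2^rnorm(n * e$n_case_lines, 0, e$noise_sd),
                 nrow = n)
  values <- cbind(ctrl, case)
  colnames(values) <- c(sprintf("control_%d", seq_len(e$n_control_lines)),
                        sprintf("case_%d", seq_len(e$n_case_lines)))
  rownames(values) <- ids
  roles <- stats::setNames(
    c(rep("control", e$n_control_lines), rep("case", e$n_case_lines)),
    colnames(values))
  structure(list(values = values, roles = roles,
                 truth = data.frame(transcript_id = ids, label = label,
                                    stringsAsFactors = FALSE)),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d transcripts x %d samples (%d case, %d control)\n",
              nrow(x$values), ncol(x$values), sum(x$roles == "case"),
              sum(x$roles == "control")))
  invisible(x)
}
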