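#' Build a pipeline configuration
#'
#' Collects every knob of the end-to-end analysis: generator settings,
#' scan threshold, bootstrap sizes, profile geometry, classification
#' thresholds and the read policy. `generator` entries are passed to
#' [simulation_config()] (its `seed` is the master seed given here).
#'
#' @param seed master integer seed for every stochastic stage.
#' @param outdir output directory for persisted intermediates and the run
#'   report, or NULL to keep everything in memory.
#' @param generator list of [simulation_config()] overrides.
#' @param scan list: `p_threshold` (1e-4), `granularity` (0.01).
#' @param bootstrap list: `n_per_draw` (250), `repetitions` (1000).
#' @param profile list: `span` (10000), `resolution` (1), `smooth_window`
#'   (25).
#' @param classify list: `low` (0.5), `high` (2).
#' @param policy read policy for the headline profile: "multi" or
#'   "unique" (both are always computed for the policy contrast).
#' @param gene_sets path to a GMT file, a named list of gene sets, or
#'   NULL to build two illustrative sets (one regulated-biased, one
#'   random) from the simulated labels.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, outdir = NULL, generator = list(),
                            scan = list(), bootstrap = list(),
                            profile = list(), classify = list(),
                            policy = c("multi", "unique"),
                            gene_sets = NULL) {
  policy <- match.arg(policy)
  cfg <- list(
    seed = as.integer(seed), outdir = outdir, generator = generator,
    scan = utils::modifyList(list(p_threshold = 1e-4, granularity = 0.01),
                             scan),
    bootstrap = utils::modifyList(list(n_per_draw = 250,
                                       repetitions = 1000), bootstrap),
    profile = utils::modifyList(list(span = 10000, resolution = 1,
                                     smooth_window = 25), profile),
    classify = utils::modifyList(list(low = 0.5, high = 2), classify),
    policy = policy, gene_sets = gene_sets)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Load a pipeline configuration from YAML
#' @param path YAML file whose top-level keys match the
#'   [pipeline_config()] arguments.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

#' Run the full analysis pipeline
#'
#' Simulate grouped Alu-planted promoters, expression and ChIP reads;
#' classify transcripts; scan promoters for the Alu motif; run the
#' chop/bootstrap occurrence test with pairwise KS comparisons; build RPM
#' coverage under both read policies and direction-aware motif-anchored
#' profiles with peak-offset estimates; run the gene-set enrichment. The
#' run is deterministic given the config; intermediates and a
#' machine-readable JSON report are persisted when `outdir` is set.
#'
#' @param config a [pipeline_config()] or the path to a YAML config.
#' @return the run report (list), invisibly also written to
#'   `<outdir>/report.json`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  stage <- function(msg) {
    message(sprintf("[%.1fs] %s",
                    as.numeric(difftime(Sys.time(), t0, units = "secs")),
                    msg))
  }
  out <- config$outdir
  if (!is.null(out) && !dir.exists(out)) {
    dir.create(out, recursive = TRUE)
  }

  stage("simulate: promoter set")
  gen <- do.call(simulation_config,
                 c(list(seed = config$seed), config$generator))
  template <- make_alu_repeat(alu_core(), divergence = 0,
                              seed = derive_seed(config$seed, 10L),
                              gc = gen$gc)
  ps <- generate_promoter_set(gen, template)
  groups <- promoter_groups(ps)

  stage("simulate: expression")
  expr <- simulate_expression(gen)
  fcs <- average_fold_change(expr)
  labels <- classify_transcripts(fcs, low = config$classify$low,
                                 high = config$classify$high)
  label_counts <- table(labels$label)
  label_agreement <- mean(labels$label ==
    expr$truth$label[match(labels$transcript_id,
                           expr$truth$transcript_id)])

  stage("scan: promoter motif hits")
  pwm <- default_alu_pwm()
  hits <- scan_motif(ps$sequences, pwm,
                     p_threshold = config$scan$p_threshold,
                     granularity = config$scan$granularity)
  matched <- truth_matched_hits(hits, ps$truth)
  density_all <- occurrences_per_5kb(hits, ps)
  density_matched <- occurrences_per_5kb(matched, ps)

  stage("bootstrap: chop occurrence test")
  chops <- chop_sequences(ps)
  counts <- per_chop_hit_counts(chops, pwm,
                                p_threshold = config$scan$p_threshold)
  grp_counts <- split(counts, chops$group)
  grp_counts$regulated <- counts[chops$group %in% c("up", "down")]
  boot <- bootstrap_occurrences(grp_counts,
                                n_per_draw = config$bootstrap$n_per_draw,
                                repetitions = config$bootstrap$repetitions,
                                seed = derive_seed(config$seed, 20L))
  ks <- compare_all_groups(boot)

  stage("chip: simulate alignments, coverage, profiles")
  aln <- simulate_chip_alignments(ps, cfg = gen)
  seqlens <- stats::setNames(Biostrings::width(ps$sequences),
                             names(ps$sequences))
  anchors <- anchors_from_intervals(ps$truth)
  peak <- list()
  profiles <- list()
  for (pol in c("multi", "unique")) {
    plc <- resolve_placements(aln, policy = pol, validate = FALSE)
    trk <- coverage_track(plc, seqlens, normalize = "RPM")
    prof <- anchored_profile(trk, anchors, span = config$profile$span,
                             resolution = config$profile$resolution)
    pk <- estimate_peak_offset(prof,
                               smooth_window = config$profile$smooth_window)
    profiles[[pol]] <- prof
    peak[[pol]] <- list(offset = pk$offset, flat = pk$flat,
                        height = max(pk$smoothed, na.rm = TRUE))
  }
  ctrl_anchors <- random_anchor_control(seqlens, n = nrow(ps$truth),
                                        seed = derive_seed(config$seed, 30L))
  plc <- resolve_placements(aln, policy = config$policy, validate = FALSE)
  trk <- coverage_track(plc, seqlens, normalize = "RPM")
  profiles$control <- anchored_profile(trk, ctrl_anchors,
                                       span = config$profile$span,
                                       resolution = config$profile$resolution)

  stage("enrich: gene sets")
  sets <- config$gene_sets
  if (is.character(sets)) sets <- read_gmt(sets)
  if (is.null(sets)) {
    set.seed(derive_seed(config$seed, 40L))
    reg <- labels$transcript_id[labels$label != "not"]
    n_set <- min(50L, max(1L, length(reg) %/% 2L))
    sets <- list(
      regulated_biased = sample(reg, n_set),
      random = sample(labels$transcript_id, n_set))
  }
  enrich <- gene_set_enrichment(labels, sets)

  report <- list(
    params = list(seed = config$seed,
                  generator = gen[setdiff(names(gen), "seed")],
                  scan = config$scan, bootstrap = config$bootstrap,
                  profile = config$profile, classify = config$classify,
                  policy = config$policy),
    n_promoters = as.list(table(groups)),
    n_planted = nrow(ps$truth),
    label_counts = as.list(label_counts),
    label_truth_agreement = label_agreement,
    occurrence_per_5kb = as.list(density_matched),
    occurrence_per_5kb_all_hits = as.list(density_all),
    ks = ks,
    peak_offset = peak,
    enrichment = enrich)

  if (!is.null(out)) {
    write_fasta(ps, file.path(out, "promoters.fa"))
    write_bed6(ps$truth, file.path(out, "truth.bed"))
    write_alignments(aln, file.path(out, "alignments.tsv"))
    write_expression(expr, file.path(out, "expression.tsv"))
    write.table(labels, file.path(out, "labels.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write_hits_tsv(hits, file.path(out, "hits.tsv"))
    write_hits_bed(hits, file.path(out, "hits.bed"))
    write_pwm(pwm, file.path(out, "pwm.txt"))
    write_bootstrap(boot, file.path(out, "bootstrap.tsv"))
    for (nm in names(profiles)) {
      write_profile(profiles[[nm]],
                    file.path(out, sprintf("profile_%s.tsv", nm)))
    }
    yaml::write_yaml(list(seed = config$seed, policy = config$policy,
                          scan = config$scan,
                          bootstrap = config$bootstrap,
                          profile = config$profile,
                          classify = config$classify),
                     file.path(out, "config.yaml"))
    jsonlite::write_json(report, file.path(out, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  stage("done")
  report
}
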