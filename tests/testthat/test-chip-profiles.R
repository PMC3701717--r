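rec <- function(read_id, seq_id, start, n_best, rl = 36, strand = "+") {
  data.frame(read_id = read_id, seq_id = seq_id, start = start,
             strand = strand, read_length = rl, n_best = n_best,
             stringsAsFactors = FALSE)
}

test_that("read policies weight and retain placements as defined", {
  records <- rbind(
    rec("r1", c("a", "b", "c"), c(0, 10, 20), n_best = 3),
    rec("r2", "a", 50, n_best = 1))
  multi <- resolve_placements(records, "multi")
  expect_equal(nrow(multi$placements), 4)
  expect_equal(multi$placements$weight, c(1/3, 1/3, 1/3, 1))
  expect_equal(multi$total_weight, 2)  # sum of weights = number of reads

  uniq <- resolve_placements(records, "unique")
  expect_equal(nrow(uniq$placements), 1)
  expect_equal(uniq$placements$weight, 1)
  expect_equal(uniq$total_weight, 1)

  fw <- resolve_placements(records, "multi", full_weight = TRUE)
  expect_equal(fw$placements$weight, rep(1, 4))

  bad <- rbind(rec("r1", "a", 0, n_best = 3), rec("r1", "b", 0, n_best = 2))
  expect_error(resolve_placements(bad, "multi"), "inconsistent n_best")
  bad2 <- rec("r1", "a", 0, n_best = 2)
  expect_error(resolve_placements(bad2, "multi"), "has 1 records")
})

test_that("coverage pileup conserves mass and RPM-normalizes", {
  records <- rbind(rec("r1", "s", 0, 1), rec("r2", "s", 100, 1))
  pl <- resolve_placements(records, "multi")
  rpm <- coverage_track(pl, c(s = 200), normalize = "RPM")
  expect_equal(rpm$values$s[1], 1e6 / 2)
  expect_equal(rpm$values$s[50], 0)

  raw <- coverage_track(pl, c(s = 200), normalize = "raw")
  expect_equal(sum(raw$values$s), 2 * 36)

  out_of_bounds <- resolve_placements(rec("r1", "s", 190, 1), "multi")
  expect_error(coverage_track(out_of_bounds, c(s = 200)), "out of bounds")

  empty <- resolve_placements(records[0, ], "multi")
  raw0 <- coverage_track(empty, c(s = 200), normalize = "raw")
  expect_true(all(raw0$values$s == 0))
  expect_error(coverage_track(empty, c(s = 200), normalize = "RPM"),
               "zero retained")
})

test_that("raw coverage totals equal weight x read length under both policies", {
  fx <- tiny_promoter_set(seed = 51, n = 20,
                          chip = list(n_reads = 3000L))
  aln <- simulate_chip_alignments(fx$ps, cfg = fx$cfg)
  lens <- stats::setNames(Biostrings::width(fx$ps$sequences),
                          names(fx$ps$sequences))
  for (pol in c("multi", "unique")) {
    pl <- resolve_placements(aln, pol, validate = FALSE)
    trk <- coverage_track(pl, lens, normalize = "raw")
    expect_equal(sum(unlist(lapply(trk$values, sum))),
                 sum(pl$placements$weight * 36))
  }
})

test_that("duplicating every read leaves the RPM track invariant", {
  records <- rbind(rec("r1", "s", 0, 1), rec("r2", "s", 50, 1))
  dup <- rbind(records,
               transform(records, read_id = paste0(read_id, "_dup")))
  t1 <- coverage_track(resolve_placements(records, "multi"), c(s = 200))
  t2 <- coverage_track(resolve_placements(dup, "multi"), c(s = 200))
  expect_equal(t1$values$s, t2$values$s)
})

test_that("anchored profiles are direction-aware at base resolution", {
  vals <- numeric(1000)
  vals[501 + 150] <- 7  # impulse at position 650 (0-based)
  trk <- structure(list(values = list(s = vals), normalization = "raw",
                        total_retained_weight = 1, seqlengths = c(s = 1000)),
                   class = "coverage_track")
  plus <- data.frame(seq_id = "s", position = 500, orientation = "+")
  prof <- anchored_profile(trk, plus, span = 300)
  expect_equal(prof$offset[which.max(prof$mean)], 150)

  vals2 <- numeric(1000)
  vals2[501 - 150] <- 7
  trk2 <- trk; trk2$values$s <- vals2
  minus <- data.frame(seq_id = "s", position = 500, orientation = "-")
  prof2 <- anchored_profile(trk2, minus, span = 300)
  expect_equal(prof2$offset[which.max(prof2$mean)], 150)

  # mean over anchors: impulses of height 2 and 4 at the same offset
  vals3 <- numeric(1000)
  vals3[101 + 50] <- 2
  vals3[601 + 50] <- 4
  trk3 <- trk; trk3$values$s <- vals3
  two <- data.frame(seq_id = c("s", "s"), position = c(100, 600),
                    orientation = "+")
  prof3 <- anchored_profile(trk3, two, span = 60)
  expect_equal(prof3$mean[prof3$offset == 50], 3)
  expect_equal(prof3$n[prof3$offset == 50], 2)

  expect_error(anchored_profile(trk, plus[0, ], span = 10), "no anchors")
})

test_that("out-of-bounds anchors are excluded per offset, not globally", {
  vals <- seq(0, 99)
  trk <- structure(list(values = list(s = vals), normalization = "raw",
                        total_retained_weight = 1, seqlengths = c(s = 100)),
                   class = "coverage_track")
  edge <- data.frame(seq_id = "s", position = 10, orientation = "+")
  prof <- anchored_profile(trk, edge, span = 20)
  expect_equal(prof$n[prof$offset == -15], 0)
  expect_true(is.na(prof$mean[prof$offset == -15]))
  expect_equal(prof$mean[prof$offset == 0], 10)
  expect_equal(prof$n[prof$offset == 20], 1)
})

test_that("negating every anchor orientation reverses the profile", {
  set.seed(52)
  vals <- runif(2000)
  trk <- structure(list(values = list(s = vals), normalization = "raw",
                        total_retained_weight = 1, seqlengths = c(s = 2000)),
                   class = "coverage_track")
  anch <- data.frame(seq_id = "s", position = c(600, 1200, 900),
                     orientation = c("+", "-", "+"))
  flip <- anch
  flip$orientation <- ifelse(anch$orientation == "+", "-", "+")
  p1 <- anchored_profile(trk, anch, span = 400)
  p2 <- anchored_profile(trk, flip, span = 400)
  expect_equal(p1$mean, rev(p2$mean))
  expect_equal(p1$n, rev(p2$n))
})

test_that("random anchor controls are reproducible and length-weighted", {
  a1 <- random_anchor_control(c(s1 = 1000, s2 = 9000), n = 500, seed = 9)
  a2 <- random_anchor_control(c(s1 = 1000, s2 = 9000), n = 500, seed = 9)
  expect_identical(a1, a2)
  expect_equal(nrow(a1), 500)
  expect_gt(sum(a1$seq_id == "s2"), sum(a1$seq_id == "s1"))
  expect_true(all(a1$position >= 0))
  expect_true(all(a1$position < c(s1 = 1000, s2 = 9000)[a1$seq_id]))
})

test_that("peak-offset estimation smooths, breaks ties inward and flags flats", {
  prof <- data.frame(offset = -200:200, mean = 0, n = 1)
  class(prof) <- c("anchored_profile", "data.frame")
  prof$mean[prof$offset == 150] <- 5
  expect_equal(estimate_peak_offset(prof, smooth_window = 1)$offset, 150)
  # under a wide smoother the impulse becomes a plateau whose tie
  # resolves toward the anchor
  sm <- estimate_peak_offset(prof, smooth_window = 25)
  expect_lte(abs(sm$offset - 150), 12)

  flat <- data.frame(offset = -50:50, mean = 1, n = 1)
  class(flat) <- c("anchored_profile", "data.frame")
  res <- estimate_peak_offset(flat)
  expect_equal(res$offset, 0)
  expect_true(res$flat)

  # equal-height twin peaks: tie resolves to the smaller absolute offset
  twin <- data.frame(offset = -100:100, mean = 0, n = 1)
  class(twin) <- c("anchored_profile", "data.frame")
  twin$mean[twin$offset %in% c(-80, 40)] <- 3
  expect_equal(estimate_peak_offset(twin, smooth_window = 1)$offset, 40)
})

test_that("multi beats unique at the planted peak when families exist", {
  heights <- vapply(1:10, function(s) {
    fx <- tiny_promoter_set(seed = 300 + s, n = 25,
                            density = c(up = 4, not = 6),
                            chip = list(n_reads = 20000L))
    aln <- simulate_chip_alignments(fx$ps, cfg = fx$cfg)
    lens <- stats::setNames(Biostrings::width(fx$ps$sequences),
                            names(fx$ps$sequences))
    anch <- anchors_from_intervals(fx$ps$truth)
    h <- vapply(c("multi", "unique"), function(pol) {
      trk <- coverage_track(resolve_placements(aln, pol, validate = FALSE),
                            lens)
      prof <- anchored_profile(trk, anch, span = 1000)
      pk <- estimate_peak_offset(prof)
      pk$smoothed[prof$offset == 150]
    }, numeric(1))
    h
  }, numeric(2))
  expect_true(all(heights["multi", ] > heights["unique", ]))
})

test_that("with no repeat families the two policies give identical tracks", {
  fx <- tiny_promoter_set(seed = 61, n = 20,
                          chip = list(family_fraction = 0,
                                      n_reads = 5000L))
  aln <- simulate_chip_alignments(fx$ps, cfg = fx$cfg)
  expect_true(all(aln$n_best == 1))
  lens <- stats::setNames(Biostrings::width(fx$ps$sequences),
                          names(fx$ps$sequences))
  t_m <- coverage_track(resolve_placements(aln, "multi"), lens)
  t_u <- coverage_track(resolve_placements(aln, "unique"), lens)
  expect_equal(t_m$values, t_u$values)
})

test_that("motif-anchored enrichment is specific versus random anchors", {
  sharper <- vapply(1:10, function(s) {
    fx <- tiny_promoter_set(seed = 400 + s, n = 20,
                            density = c(up = 4, not = 6),
                            chip = list(n_reads = 20000L))
    aln <- simulate_chip_alignments(fx$ps, cfg = fx$cfg)
    lens <- stats::setNames(Biostrings::width(fx$ps$sequences),
                            names(fx$ps$sequences))
    trk <- coverage_track(resolve_placements(aln, "multi",
                                             validate = FALSE), lens)
    ratio <- function(prof) {
      max(prof$mean, na.rm = TRUE) / mean(prof$mean, na.rm = TRUE)
    }
    p_mot <- anchored_profile(trk, anchors_from_intervals(fx$ps$truth),
                              span = 1000)
    p_ctl <- anchored_profile(
      trk, random_anchor_control(lens, n = nrow(fx$ps$truth),
                                 seed = 500 + s), span = 1000)
    ratio(p_mot) > ratio(p_ctl)
  }, logical(1))
  expect_true(all(sharper))
})

test_that("TSS profiles respect groups, symmetry and zero coverage", {
  # symmetric bump at the TSS of a single plus-strand gene
  vals <- numeric(1000)
  vals[401:601] <- c(1:101, 100:1)
  trk <- structure(list(values = list(s = vals), normalization = "raw",
                        total_retained_weight = 1, seqlengths = c(s = 1000)),
                   class = "coverage_track")
  genes <- data.frame(gene_id = "g", seq_id = "s", tss = 500,
                      strand = "+", group = "not",
                      stringsAsFactors = FALSE)
  pr <- tss_profile(trk, genes, span = 90)
  expect_equal(pr$not$mean, rev(pr$not$mean))

  # zero coverage gives an all-zero profile
  trk0 <- trk; trk0$values$s <- numeric(1000)
  pr0 <- tss_profile(trk0, genes, span = 50)
  expect_true(all(pr0$not$mean == 0))

  expect_error(tss_profile(trk, genes[, -5], span = 10), "group")
})

test_that("extra enriched reads in not-regulated promoters depress the up profile", {
  fx <- tiny_promoter_set(seed = 71, n = 40,
                          density = c(up = 2, not = 8),
                          chip = list(n_reads = 30000L,
                                      offset_bp = 0, spread_sd = 100))
  aln <- simulate_chip_alignments(fx$ps, cfg = fx$cfg)
  lens <- stats::setNames(Biostrings::width(fx$ps$sequences),
                          names(fx$ps$sequences))
  trk <- coverage_track(resolve_placements(aln, "multi", validate = FALSE),
                        lens)
  groups <- promoter_groups(fx$ps)
  genes <- data.frame(gene_id = names(lens), seq_id = names(lens),
                      tss = 2500, strand = "+", group = groups,
                      stringsAsFactors = FALSE)
  pr <- tss_profile(trk, genes, span = 1000)
  expect_gt(mean(pr$not$mean, na.rm = TRUE),
            mean(pr$up$mean, na.rm = TRUE))
})
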