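test_that("build_pwm computes columnwise frequencies with pseudocounts", {
  pwm <- build_pwm(rep("ACGT", 4), pseudocount = 0)
  expect_equal(pwm$width, 4)
  expect_equal(diag(pwm$probs[1:4, ]), rep(1, 4),
               ignore_attr = TRUE)
  expect_equal(colSums(pwm$probs), rep(1, 4), tolerance = 1e-9)

  pwm2 <- build_pwm(rep("AA", 4), pseudocount = 1)
  expect_equal(unname(pwm2$probs["A", ]), c(5 / 8, 5 / 8))

  expect_error(build_pwm(character(0)), "at least one")
  expect_error(build_pwm(c("ACGT", "ACG")), "same length")
  expect_error(build_pwm("ACGN"), "only A, C, G, T")
})

test_that("the bundled Alu-DEIN instance set has the core motif as consensus", {
  pwm <- default_alu_pwm()
  expect_identical(consensus(pwm), "CACGCCTGTAATCCCAGCACTTTGG")
  expect_equal(pwm$width, 25)
})

test_that("score_window is a log-odds sum maximized by the consensus, N neutral", {
  pwm <- default_alu_pwm()
  cons_score <- score_window(pwm, consensus(pwm))
  expect_equal(cons_score, sum(apply(pwm$log_odds, 2, max)))
  set.seed(1)
  for (i in 1:20) {
    w <- random_dna(25)
    expect_lte(score_window(pwm, w), cons_score)
  }
  expect_equal(score_window(pwm, strrep("N", 25)), 0)
  expect_error(score_window(pwm, "ACGT"), "width")
})

test_that("exact_pvalues matches a single-column hand calculation", {
  pwm <- build_pwm(c("A", "A", "C", "G"), pseudocount = 0)
  tbl <- exact_pvalues(pwm, granularity = 0.01)
  # top base A has probability 0.5 > all others; tail at its score = P(A)
  top <- max(pwm$log_odds[is.finite(pwm$log_odds)])
  expect_equal(pvalue_at(tbl, top), 0.25)
  # the T cell has probability zero (score -Inf), so the tail at the
  # lowest finite score excludes its background mass ...
  expect_equal(pvalue_at(tbl, tbl$min_score), 0.75)
  # ... while anything below the finite range has tail 1
  expect_equal(pvalue_at(tbl, tbl$min_score - 1), 1)

  # with a pseudocount every score is finite and the minimum has tail 1
  pwm2 <- build_pwm(c("A", "A", "C", "G"), pseudocount = 0.5)
  tbl2 <- exact_pvalues(pwm2, granularity = 0.01)
  expect_equal(pvalue_at(tbl2, tbl2$min_score), 1)
})

test_that("exact_pvalues equals exhaustive enumeration for widths up to 6", {
  for (w in 2:6) {
    bg <- if (w %% 2 == 0) rep(0.25, 4) else c(0.2, 0.3, 0.3, 0.2)
    pwm <- random_pwm(w, seed = 100 + w, background = bg)
    tbl <- exact_pvalues(pwm, granularity = 0.01)
    oracle <- brute_force_tail(pwm, granularity = 0.01)
    for (i in seq_along(oracle$score)) {
      expect_equal(pvalue_at(tbl, oracle$score[i] * 0.01),
                   oracle$tail[i], tolerance = 1e-12)
    }
  }
})

test_that("p-value tables are non-increasing with unit mass at the minimum", {
  pwm <- default_alu_pwm()
  tbl <- exact_pvalues(pwm)
  expect_true(all(diff(tbl$tail) <= 1e-15))
  expect_equal(tbl$tail[1], 1)
  expect_equal(pvalue_at(tbl, tbl$max_score + 1), 0)
})

test_that("scan reports planted matches on both strands in forward coordinates", {
  pwm <- default_alu_pwm()
  set.seed(7)
  bg <- random_dna(1000)
  fwd <- bg
  substr(fwd, 401, 425) <- alu_core()
  h <- scan_motif(c(s = fwd), pwm)
  expect_true(any(h$start == 400 & h$strand == "+"))

  rev <- bg
  substr(rev, 401, 425) <- revcomp(alu_core())
  h2 <- scan_motif(c(s = rev), pwm)
  expect_true(any(h2$start == 400 & h2$strand == "-"))
  expect_true(all(h2$end - h2$start == pwm$width))

  # shorter than the motif: no hits, no error
  expect_equal(nrow(scan_motif(c(tiny = "ACGT"), pwm)), 0)
})

test_that("scanning the reverse complement reflects hits and flips strands", {
  pwm <- default_alu_pwm()
  set.seed(11)
  s <- random_dna(2000)
  substr(s, 301, 325) <- alu_core()
  substr(s, 1201, 1225) <- revcomp(alu_core())
  h_f <- scan_motif(c(x = s), pwm)
  h_r <- scan_motif(c(x = revcomp(s)), pwm)
  expect_equal(nrow(h_f), nrow(h_r))
  L <- nchar(s)
  mapped <- data.frame(start = L - h_r$end,
                       strand = ifelse(h_r$strand == "+", "-", "+"),
                       score = h_r$score)
  mapped <- mapped[order(mapped$start, mapped$strand), ]
  orig <- h_f[order(h_f$start, h_f$strand), c("start", "strand", "score")]
  expect_equal(mapped$start, orig$start)
  expect_equal(mapped$strand, orig$strand)
  expect_equal(mapped$score, orig$score)
})

test_that("hits at a stricter threshold are a subset of hits at a looser one", {
  pwm <- default_alu_pwm()
  set.seed(13)
  seqs <- stats::setNames(
    vapply(1:5, function(i) random_dna(5000, gc = 0.5), character(1)),
    paste0("b", 1:5))
  strict <- scan_motif(seqs, pwm, p_threshold = 1e-5)
  loose <- scan_motif(seqs, pwm, p_threshold = 1e-3)
  key <- function(h) paste(h$seq_id, h$start, h$strand)
  expect_true(all(key(strict) %in% key(loose)))
  expect_true(all(strict$pvalue <= 1e-5))
  expect_true(all(loose$pvalue <= 1e-3))
})

test_that("background hit counts match the 2*L*p expectation", {
  pwm <- default_alu_pwm()
  tot <- 0
  for (s in 1:10) {
    set.seed(s)
    seqs <- stats::setNames(
      vapply(1:5, function(i) random_dna(10000, gc = 0.5), character(1)),
      paste0("b", 1:5))
    tot <- tot + nrow(scan_motif(seqs, pwm))
  }
  expected <- 2 * 10 * 50000 * 1e-4
  expect_lt(abs(tot - expected), 3 * sqrt(expected))
})

test_that("mutate_motif substitutes exactly the requested fraction of positions", {
  m48 <- alu_motif_48()
  expect_equal(nchar(m48), 48)
  expect_identical(mutate_motif(m48, 0, seed = 1), m48)
  expect_equal(hamming(mutate_motif(m48, 1, seed = 2), m48), 48)
  expect_equal(hamming(mutate_motif(m48, 0.25, seed = 3), m48), 12)
  expect_equal(hamming(mutate_motif(m48, 0.33, seed = 4), m48), 16)
  expect_equal(nchar(mutate_motif(m48, 0.5, seed = 5)), 48)
})

test_that("find_motif_in_transcript distinguishes core from reverse complement", {
  pwm <- default_alu_pwm()
  set.seed(21)
  base <- random_dna(500)
  fwd <- paste0(substr(base, 1, 250), alu_core(), substr(base, 251, 500))
  h <- find_motif_in_transcript(fwd, pwm)
  expect_equal(nrow(h), 1)
  expect_equal(h$strand, "+")
  expect_equal(h$start, 250)

  rev <- paste0(substr(base, 1, 250), revcomp(alu_core()),
                substr(base, 251, 500))
  h2 <- find_motif_in_transcript(rev, pwm)
  expect_equal(h2$strand, "-")

  expect_equal(nrow(find_motif_in_transcript(strrep("A", 200), pwm)), 0)
})
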