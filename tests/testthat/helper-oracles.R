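# Independent oracles and small fixtures shared across test files.

# Exhaustive-enumeration oracle for the exact p-value table: enumerate all
# 4^width windows, quantize cells exactly as the implementation defines
# (round half away from zero), and accumulate tail probabilities under the
# i.i.d. background.
brute_force_tail <- function(pwm, granularity, background = pwm$background) {
  w <- pwm$width
  qc <- sign(pwm$log_odds / granularity) *
    floor(abs(pwm$log_odds / granularity) + 0.5)
  grids <- rep(list(1:4), w)
  combos <- as.matrix(expand.grid(grids))
  score <- numeric(nrow(combos))
  prob <- numeric(nrow(combos))
  for (i in seq_len(nrow(combos))) {
    b <- combos[i, ]
    score[i] <- sum(qc[cbind(b, seq_len(w))])
    prob[i] <- prod(background[b])
  }
  agg <- tapply(prob, score, sum)
  s <- as.numeric(names(agg))
  ord <- order(s)
  s <- s[ord]
  mass <- as.numeric(agg)[ord]
  tail <- rev(cumsum(rev(mass)))
  list(score = s, tail = tail)
}

# Brute-force two-sample KS statistic: sup of |ECDF_A - ECDF_B| over all
# breakpoints.
ecdf_sup_diff <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  max(abs(vapply(pts, function(x) mean(a <= x) - mean(b <= x), numeric(1))))
}

# A small random PWM for property tests.
random_pwm <- function(width, seed, background = rep(0.25, 4)) {
  set.seed(seed)
  inst <- vapply(1:8, function(i) {
    paste(sample(c("A", "C", "G", "T"), width, replace = TRUE),
          collapse = "")
  }, character(1))
  build_pwm(inst, pseudocount = 0.25, background = background)
}

# A small grouped promoter set for integration-style tests.
tiny_promoter_set <- function(seed = 1, n = 40, divergence = 0,
                              density = c(up = 4, down = 4, not = 6),
                              chip = list()) {
  cfg <- simulation_config(
    seed = seed,
    n_promoters = stats::setNames(rep(as.integer(n), length(density)),
                                  names(density)),
    planting_density = density, divergence = divergence, chip = chip)
  tpl <- make_alu_repeat(alu_core(), divergence = 0, seed = seed + 1)
  list(cfg = cfg, template = tpl,
       ps = generate_promoter_set(cfg, tpl))
}

# Hamming distance between equal-length strings.
hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}
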