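test_that("word scoring is the log2 likelihood ratio against background", {
  # PWM identical to background scores 0 everywhere
  flat <- new_pwm("flat", matrix(1, 4, 6), pseudocount = 0)
  expect_equal(score_word(flat, "ACGTAC"), 0)
  # single-position hand arithmetic: P(A) = 0.97 vs bg 0.25
  one <- new_pwm("one", matrix(c(97, 1, 1, 1), 4, 1), pseudocount = 0)
  expect_equal(score_word(one, "A"), log2(0.97 / 0.25), tolerance = 1e-12)
  expect_equal(round(score_word(one, "A"), 3), 1.956)
  # N contributes zero
  two <- new_pwm("two", matrix(c(97, 1, 1, 1), 4, 2), pseudocount = 0)
  expect_equal(score_word(two, "AN"), score_word(one, "A"))
  # palindromic PWM scores strands equally
  pal_counts <- cbind(c(8, 0, 0, 0), c(0, 8, 0, 0), c(0, 0, 8, 0),
                      c(0, 0, 0, 8))  # ACGT is its own reverse complement
  pal <- new_pwm("pal", pal_counts)
  for (wd in c("ACGT", "TTTT", "GATC")) {
    expect_equal(score_word(pal, wd, "+"), score_word(pal, wd, "-"))
  }
})

test_that("window scanning equals the exhaustive per-position oracle", {
  set.seed(23)
  pwm <- make_fixture_pwm("M", 9L, seed = 24)
  thr <- 3  # permissive threshold so both routes see plenty of hits
  pwm$threshold <- thr
  for (rep in 1:50) {
    win <- random_consensus(60L)
    got <- scan_window(win, pwm)
    want <- naive_scan_oracle(win, pwm, thr)
    expect_equal(nrow(got), nrow(want))
    if (nrow(got)) {
      got <- got[order(got$pos, got$strand), ]
      want <- want[order(want$pos, want$strand), ]
      expect_equal(got$pos, want$pos)
      expect_equal(got$strand, want$strand)
      expect_equal(got$score, want$score, tolerance = 1e-9)
    }
  }
})

test_that("a planted maximum-probability word is recovered at its offset", {
  pwm <- make_fixture_pwm("M", 10L, seed = 25)
  pwm <- calibrate_threshold(pwm, n_mc = 2000L, seed = 26)
  win <- random_consensus(200L, seed = 27)
  substr(win, 38L, 47L) <- max_prob_word(pwm)  # offset 37, 0-based
  hits <- scan_window(win, pwm)
  expect_true(any(hits$pos == 37L & hits$strand == "+"))
  # an unattainable threshold yields no hits
  expect_equal(nrow(scan_window(win, pwm,
                                threshold = score_word(pwm, max_prob_word(pwm)) + 1)),
               0L)
  # a window shorter than the matrix yields an empty result
  expect_equal(nrow(scan_window("ACGT", pwm)), 0L)
})

test_that("strand closure: a window and its reverse complement mirror hits", {
  pwm <- make_fixture_pwm("M", 8L, seed = 28)
  pwm$threshold <- 4
  win <- random_consensus(80L, seed = 29)
  rc <- texapt:::revcomp(win)
  fwd <- scan_window(win, pwm)
  rev <- scan_window(rc, pwm)
  expect_equal(nrow(fwd), nrow(rev))
  mirrored <- data.frame(pos = nchar(win) - pwm$width - rev$pos,
                         strand = ifelse(rev$strand == "+", "-", "+"),
                         score = rev$score)
  mirrored <- mirrored[order(mirrored$pos, mirrored$strand), ]
  fwd <- fwd[order(fwd$pos, fwd$strand), ]
  expect_equal(fwd$pos, mirrored$pos)
  expect_equal(fwd$strand, mirrored$strand)
  expect_equal(fwd$score, mirrored$score, tolerance = 1e-9)
})

test_that("calibration achieves the target random-sequence hit rate", {
  bg <- c(A = 0.3, C = 0.2, G = 0.2, T = 0.3)
  pwm <- make_fixture_pwm("M", 11L, seed = 31)
  pwm <- calibrate_threshold(pwm, bg, target_rate = 0.01, n_mc = 5000L,
                             seed = 32)
  rate <- random_hit_rate(pwm, n = 5000L, seed = 33)
  se <- sqrt(0.01 * 0.99 / 5000)
  expect_lt(abs(rate - 0.01), 3 * se)
  # hit rate is non-increasing in the threshold
  grid <- seq(pwm$threshold - 2, pwm$threshold + 2, length.out = 20)
  rates <- vapply(grid, function(t) {
    p <- pwm; p$threshold <- t
    random_hit_rate(p, n = 1000L, seed = 34)
  }, numeric(1))
  expect_true(all(diff(rates) <= 0))
  # below the global minimum score every window is a hit
  p_all <- pwm; p_all$threshold <- -1e6
  expect_equal(random_hit_rate(p_all, n = 200L, seed = 35), 1)
})

test_that("TAS is the carrying fraction of peak-overlapping instances", {
  pwm <- make_fixture_pwm("TF1", 10L, seed = 41)
  pwm <- calibrate_threshold(pwm, n_mc = 2000L, seed = 42)
  cons <- plant_motif_combination(random_consensus(160L, seed = 43), pwm,
                                  offset_a = 60L)
  g <- generate_genome(c(chr1 = 400000L), seed = 44)
  pf <- plant_te_family(g, "MER41B", "LTR/ERV1", cons, 30L, divergence = 0,
                        seed = 45)
  pk <- generate_peaks(pf$genome, pf$tes, c(MER41B = 10), n_peaks = 300L,
                       seed = 46)
  tas <- compute_tas(pk, pf$tes, pf$genome, pwm)
  # with zero divergence every overlapping instance carries the planted site
  # whenever the window covers it; window placement guarantees >=1 bp overlap
  # only, so assert a high fraction rather than exactly 1
  expect_gt(tas$tas, 0.5)
  expect_true(tas$tas >= 0 && tas$tas <= 1)
  expect_equal(tas$tas, tas$n_carrying / tas$n_instances)
})

test_that("TAS on a motif-free family approximates the calibrated rate", {
  pwm <- make_fixture_pwm("TF1", 12L, seed = 51)
  pwm <- calibrate_threshold(pwm, n_mc = 4000L, seed = 52)
  g <- generate_genome(c(chr1 = 1500000L), seed = 53)
  pf <- plant_te_family(g, "FAM", "CL", random_consensus(180L, seed = 54),
                        120L, divergence = 0, seed = 55)
  pk <- generate_peaks(pf$genome, pf$tes, c(FAM = 20), n_peaks = 600L,
                       seed = 56)
  tas <- compute_tas(pk, pf$tes, pf$genome, pwm)
  expect_gte(tas$n_instances, 100L)
  expect_lte(tas$tas, 0.05)
})

test_that("TAS matrix, interactor calls, and clustering are well-behaved", {
  rec <- data.frame(
    te_name = rep(c("MIRb", "MIR3", "MER41B"), each = 3),
    tf_id = rep(c("ER", "GATA3", "ERR"), 3),
    n_instances = 20L,
    n_carrying = c(4L, 0L, 1L, 2L, 2L, 0L, 0L, 6L, 10L),
    stringsAsFactors = FALSE)
  rec$tas <- rec$n_carrying / rec$n_instances
  tm <- tas_matrix(rec, tas_min = 0.10)
  expect_equal(dim(tm$matrix), c(3L, 3L))
  # 0.10 exactly is included (inclusive threshold)
  expect_true("GATA3" %in% tm$interactors)  # 6/20 = 0.3
  expect_true("ER" %in% tm$interactors)     # 4/20 = 0.2
  expect_true("ERR" %in% tm$interactors)    # 10/20 = 0.5
  rec2 <- rec[rec$tf_id == "ER", ]
  rec2$tas <- c(0.05, 0.08, 0)  # all below the 10% cutoff
  tm2 <- tas_matrix(rec2, tas_min = 0.10)
  expect_equal(tm2$interactors, character(0))
  # exactly-at-threshold inclusion
  rec3 <- data.frame(te_name = "A", tf_id = "X", n_instances = 10L,
                     n_carrying = 1L, tas = 0.10, stringsAsFactors = FALSE)
  expect_equal(tas_matrix(rec3)$interactors, "X")
  # permutation invariance of the matrix values
  tm3 <- tas_matrix(rec[sample(nrow(rec)), ], tas_min = 0.10)
  expect_identical(tm3$matrix, tm$matrix)
})
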