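test_that("generated genomes hit the requested GC and are seed-deterministic", {
  g <- generate_genome(c(chr1 = 100000L), gc_content = 0.5, seed = 1)
  codes <- texapt:::encode_dna(g$sequences[["chr1"]])
  gc <- mean(codes %in% 2:3)
  expect_gt(gc, 0.48)
  expect_lt(gc, 0.52)
  g2 <- generate_genome(c(chr1 = 100000L), gc_content = 0.5, seed = 1)
  expect_identical(g$sequences, g2$sequences)
  g3 <- generate_genome(c(chr1 = 5000L), gc_content = 1, seed = 2)
  expect_true(grepl("^[GC]+$", g3$sequences[["chr1"]]))
})

test_that("planted TE copies decay at the configured divergence rate", {
  cons <- random_consensus(200L, seed = 5)
  g <- generate_genome(c(chr1 = 500000L), seed = 6)
  pf <- plant_te_family(g, "MIRb", "SINE/MIR", cons, 100L, divergence = 0.1,
                        seed = 7)
  ident <- vapply(seq_len(nrow(pf$tes)), function(i) {
    s <- texapt:::genome_seq(pf$genome, pf$tes$chrom[i], pf$tes$start[i],
                             pf$tes$end[i])
    mean(strsplit(s, "")[[1]] == strsplit(cons, "")[[1]])
  }, numeric(1))
  # binomial oracle: per-copy identity ~ 1 - Bin(200, 0.1)/200
  expect_gt(mean(ident), 0.88)
  expect_lt(mean(ident), 0.92)
  # divergence 0 reproduces the consensus exactly; copy number 0 is a no-op
  pf0 <- plant_te_family(g, "X", "Y", cons, 5L, divergence = 0, seed = 8)
  s <- texapt:::genome_seq(pf0$genome, pf0$tes$chrom[1], pf0$tes$start[1],
                           pf0$tes$end[1])
  expect_identical(s, cons)
  pfz <- plant_te_family(g, "X", "Y", cons, 0L)
  expect_equal(nrow(pfz$tes), 0L)
  expect_identical(pfz$genome$sequences, g$sequences)
})

test_that("planted instances never overlap each other", {
  g <- generate_genome(c(chr1 = 50000L), seed = 9)
  p1 <- plant_te_family(g, "A", "C1", random_consensus(300L, seed = 1), 30L,
                        seed = 10)
  p2 <- plant_te_family(p1$genome, "B", "C1", random_consensus(300L, seed = 2),
                        30L, seed = 11, occupied = p1$occupied)
  tes <- rbind(p1$tes, p2$tes)
  tes <- tes[order(tes$start), ]
  expect_true(all(tes$start[-1] >= tes$end[-nrow(tes)]))
})

test_that("motif pairs are planted at the exact start-to-start distance", {
  pa <- make_fixture_pwm("A", 10L, seed = 21)
  pb <- make_fixture_pwm("B", 8L, seed = 22)
  cons <- plant_motif_combination(random_consensus(120L, seed = 23), pa, pb,
                                  offset_a = 20L, distance = 24L)
  expect_identical(substr(cons, 21L, 30L), max_prob_word(pa))
  expect_identical(substr(cons, 45L, 52L), max_prob_word(pb))
  expect_error(plant_motif_combination(random_consensus(120L, seed = 23),
                                       pa, pb, offset_a = 20L, distance = 0L),
               "overlap")
})

test_that("planted max-probability words beat thresholds calibrated at 0.01", {
  pa <- make_fixture_pwm("A", 10L, seed = 31)
  pa <- calibrate_threshold(pa, n_mc = 2000L, seed = 32)
  expect_gt(score_word(pa, max_prob_word(pa)), pa$threshold)
})

test_that("peak generation hits the targeted overlap rate and is reproducible", {
  g <- generate_genome(c(chr1 = 2000000L), seed = 41, with_sequence = FALSE)
  # synthetic family footprint placed by hand: 50 instances of 400 bp
  start <- seq(10000L, by = 39000L, length.out = 50L)
  tes <- data.frame(instance_id = sprintf("t%02d", 1:50), chrom = "chr1",
                    start = start, end = start + 400L, strand = "+",
                    name = "FAM", te_class = "CL", stringsAsFactors = FALSE)
  b <- 50 * (400 + 199) / 2e6  # background window-overlap probability
  k <- 4
  pk <- generate_peaks(g, tes, c(FAM = k), n_peaks = 5000L, seed = 42)
  ov <- interval_overlaps_any(pk, tes)
  p_hat <- mean(ov)
  se <- sqrt(k * b * (1 - k * b) / 5000)
  expect_lt(abs(p_hat - k * b), 4 * se)
  # multiplier 1 reduces to the background rate
  pk1 <- generate_peaks(g, tes, c(FAM = 1), n_peaks = 5000L, seed = 43)
  p_null <- mean(interval_overlaps_any(pk1, tes))
  expect_lt(abs(p_null - b), 4 * sqrt(b * (1 - b) / 5000))
  # determinism
  pk2 <- generate_peaks(g, tes, c(FAM = k), n_peaks = 5000L, seed = 42)
  expect_identical(pk, pk2)
})

test_that("gene TSS placement respects the near-TE fraction", {
  g <- generate_genome(c(chr1 = 1000000L), seed = 51, with_sequence = FALSE)
  start <- seq(5000L, by = 19000L, length.out = 50L)
  tes <- data.frame(instance_id = sprintf("t%02d", 1:50), chrom = "chr1",
                    start = start, end = start + 300L, strand = "+",
                    name = "FAM", te_class = "CL", stringsAsFactors = FALSE)
  near_te <- function(genes) {
    vapply(genes$tss, function(t) {
      any(abs((tes$start + tes$end) %/% 2L - t) <= 2000L)
    }, logical(1))
  }
  g1 <- generate_genes(g, tes, 200L, tss_near_te_fraction = 1, seed = 52)
  expect_true(all(near_te(g1)))
  g0 <- generate_genes(g, tes, 500L, tss_near_te_fraction = 0.3, seed = 53)
  truth <- attr(g0, "truth")
  expect_lt(abs(sum(truth$near_te) - 150), 4 * sqrt(500 * 0.3 * 0.7))
  expect_true(all(near_te(g0)[truth$near_te]))
})

test_that("identity synteny reproduces the genome and conserves every TE", {
  g <- generate_genome(c(chr1 = 20000L), seed = 61)
  pf <- plant_te_family(g, "MIRb", "SINE/MIR", random_consensus(150L, seed = 1),
                        10L, seed = 62)
  syn <- generate_synteny(pf$genome, pf$tes, n_blocks = 1L,
                          inversion_fraction = 0, conserved_te_fraction = 1,
                          seed = 63)
  expect_identical(unname(syn$genome_b$sequences[[1]]),
                   unname(pf$genome$sequences[[1]]))
  expect_equal(nrow(syn$pairs_truth), 10L)
  syn0 <- generate_synteny(pf$genome, pf$tes, n_blocks = 1L,
                           conserved_te_fraction = 0, seed = 64)
  expect_equal(nrow(syn0$pairs_truth), 0L)
})

test_that("conserved TE coordinates round-trip through the block table", {
  g <- generate_genome(c(chr1 = 50000L, chr2 = 30000L), seed = 71)
  pf <- plant_te_family(g, "MIRb", "SINE/MIR", random_consensus(120L, seed = 2),
                        25L, seed = 72)
  syn <- generate_synteny(pf$genome, pf$tes, n_blocks = 10L,
                          inversion_fraction = 0.5, conserved_te_fraction = 1,
                          seed = 73)
  for (i in seq_len(nrow(syn$pairs_truth))) {
    ta <- pf$tes[pf$tes$instance_id == syn$pairs_truth$te_a[i], ]
    tb <- syn$tes_b[syn$tes_b$instance_id == syn$pairs_truth$te_b[i], ]
    bl <- syn$blocks[syn$blocks$block_id == syn$pairs_truth$block_id[i], ]
    proj <- project_interval(bl, ta[c("chrom", "start", "end")])
    expect_equal(proj$start, tb$start)
    expect_equal(proj$end, tb$end)
    back <- texapt:::project_interval_back(bl, proj)
    expect_equal(back$start, ta$start)
    expect_equal(back$end, ta$end)
  }
})

test_that("FASTA round-trip preserves the genome", {
  g <- generate_genome(c(chrA = 5000L, chrB = 3000L), seed = 81)
  tmp <- withr::local_tempfile(fileext = ".fa")
  write_genome_fasta(g, tmp)
  g2 <- read_genome_fasta(tmp)
  expect_identical(g2$sequences[["chrA"]], unname(g$sequences[["chrA"]]))
  expect_equal(unname(g2$chrom_lengths), unname(g$chrom_lengths))
})
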