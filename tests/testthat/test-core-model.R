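test_that("peak windows are 200 bp and centered on the interval midpoint", {
  tmp <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t1000\t1400", "chr1\t1000\t1001"), tmp)
  pk <- read_peaks(tmp, "bed")
  expect_equal(pk$win_start, c(1100L, 900L))
  expect_equal(pk$win_end, c(1300L, 1100L))
  expect_equal(pk$win_end - pk$win_start, c(200L, 200L))
})

test_that("peak ids are auto-assigned in input order and bad rows are logged", {
  tmp <- withr::local_tempfile(fileext = ".bed")
  rows <- sprintf("chr1\t%d\t%d", seq(1000, 20000, by = 1000),
                  seq(1000, 20000, by = 1000) + 300)
  writeLines(c(rows, "chr1\t500\t400"), tmp)  # last row malformed
  pk <- read_peaks(tmp, "bed")
  expect_equal(nrow(pk), 20L)
  expect_equal(pk$id[c(1, 20)], c("peak_0001", "peak_0020"))
  expect_equal(attr(pk, "report")$rows_skipped, 1L)
  empty <- withr::local_tempfile(fileext = ".bed")
  writeLines(character(0), empty)
  expect_error(read_peaks(empty, "bed"), "empty")
})

test_that("windows past a chromosome end are clipped and flagged", {
  g <- genome_model(c(chr1 = 1000L))
  pk <- make_peaks(data.frame(chrom = "chr1", start = 940L, end = 960L),
                   genome = g)
  expect_true(pk$clipped)
  expect_equal(pk$win_end, 1000L)
})

test_that("RepeatMasker .out coordinates convert to 0-based half-open", {
  tmp <- withr::local_tempfile(fileext = ".out")
  hdr <- c("   SW   perc perc perc  query    position in query",
           "score   div. del. ins.  sequence  begin  end",
           "")
  rows <- sprintf("  463   11.5  0.0  0.0  chr1  %d  %d  (0)  %s  MIRb  SINE/MIR  1  100  (0)  %d",
                  seq(1001, by = 500, length.out = 10),
                  seq(1100, by = 500, length.out = 10),
                  rep(c("+", "C"), 5), 1:10)
  writeLines(c(hdr, rows), tmp)
  tes <- read_repeatmasker(tmp, "rm_out")
  expect_equal(nrow(tes), 10L)
  expect_equal(tes$start[1], 1000L)
  expect_equal(tes$end[1], 1100L)
  expect_equal(tes$strand[1:2], c("+", "-"))
  expect_equal(unique(tes$name), "MIRb")
  expect_equal(unique(tes$te_class), "SINE/MIR")
})

test_that("bed_name_class dialect captures name and class verbatim", {
  tmp <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr2\t500\t700\tMIRb\tSINE/MIR", tmp)
  tes <- read_repeatmasker(tmp, "bed_name_class")
  expect_equal(tes$name, "MIRb")
  expect_equal(tes$te_class, "SINE/MIR")
  expect_equal(tes$start, 500L)
  tmp2 <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr2\t500\t700\tMIRb", tmp2)
  expect_error(read_repeatmasker(tmp2, "bed_name_class"), "class")
})

test_that("JASPAR and TRANSFAC matrices normalise with pseudocount 0.25", {
  tmp <- withr::local_tempfile(fileext = ".jaspar")
  writeLines(c(">M1 test", "A [ 8 0 ]", "C [ 0 8 ]", "G [ 0 0 ]",
               "T [ 0 0 ]",
               ">M2 other", "A [ 1 ]", "C [ 1 ]", "G [ 1 ]", "T [ 1 ]",
               ">M3 third", "A [ 4 ]", "C [ 0 ]", "G [ 0 ]", "T [ 0 ]"), tmp)
  pwms <- read_pwms(tmp, "jaspar")
  expect_length(pwms, 3L)
  expect_equal(unname(pwms$M1$probs["A", 1]), (8 + 0.25) / 9)
  expect_equal(pwms$M1$width, 2L)
  tmp2 <- withr::local_tempfile(fileext = ".transfac")
  writeLines(c("ID T1", "P0  A  C  G  T", "01  2  2  2  2", "02  0  0  0  8",
               "//"), tmp2)
  tf <- read_pwms(tmp2, "transfac")
  expect_equal(unname(tf$T1$probs[, 1]), rep(0.25, 4))
  expect_equal(unname(tf$T1$probs["T", 2]), 8.25 / 9)
})

test_that("interval overlap follows the half-open convention", {
  a <- data.frame(chrom = "chr1", start = 100L, end = 200L)
  expect_true(interval_overlaps(a, data.frame(chrom = "chr1", start = 199L,
                                              end = 300L)))
  expect_false(interval_overlaps(a, data.frame(chrom = "chr1", start = 200L,
                                               end = 300L)))
  expect_false(interval_overlaps(a, data.frame(chrom = "chr2", start = 100L,
                                               end = 200L)))
})

test_that("overlap agrees with the per-base membership oracle", {
  set.seed(7)
  for (rep in 1:100) {
    a <- random_interval_df(1)
    b <- random_interval_df(1)
    expect_identical(unname(interval_overlaps(a, b)),
                     overlap_per_base_oracle(a, b))
  }
  # symmetry on a vectorised batch
  a <- random_interval_df(200)
  b <- random_interval_df(200)
  expect_identical(interval_overlaps(a, b), interval_overlaps(b, a))
})

test_that("peak-set partition is exact and reports per-side multiplicity", {
  g <- genome_model(c(chr1 = 10000L))
  a <- make_peaks(data.frame(chrom = "chr1", start = 0L, end = 200L),
                  window_size = 200L)
  b <- make_peaks(data.frame(chrom = "chr1",
                             start = c(100L, 150L), end = c(300L, 350L)),
                  window_size = 200L)
  pt <- partition_peaksets(a, b)
  expect_equal(unname(pt$counts["a_and_b_from_a"]), 1L)
  expect_equal(unname(pt$counts["a_and_b_from_b"]), 2L)
  # disjoint sets
  d <- make_peaks(data.frame(chrom = "chr1", start = 5000L, end = 5200L))
  pt2 <- partition_peaksets(a, d)
  expect_equal(nrow(pt2$a_only), 1L)
  expect_equal(nrow(pt2$b_only), 1L)
  expect_equal(nrow(pt2$a_in_b), 0L)
})

test_that("partition matches the all-pairs oracle and partitions exactly", {
  set.seed(11)
  mk <- function() {
    iv <- random_interval_df(50, max_pos = 5000L)
    make_peaks(iv)
  }
  a <- mk(); b <- mk()
  pt <- partition_peaksets(a, b)
  in_b <- vapply(seq_len(nrow(a)), function(i) {
    any(vapply(seq_len(nrow(b)), function(j) {
      a$chrom[i] == b$chrom[j] &&
        max(a$win_start[i], b$win_start[j]) < min(a$win_end[i], b$win_end[j])
    }, logical(1)))
  }, logical(1))
  expect_equal(unname(pt$counts["a_and_b_from_a"]), sum(in_b))
  expect_equal(nrow(pt$a_only) + nrow(pt$a_in_b), nrow(a))
  expect_equal(nrow(pt$b_only) + nrow(pt$b_in_a), nrow(b))
})

test_that("BED write-then-read round-trips interval collections", {
  set.seed(3)
  iv <- random_interval_df(25)
  iv$name <- sprintf("f%02d", seq_len(25))
  tmp <- withr::local_tempfile(fileext = ".bed")
  write_bed(iv, tmp)
  back <- read_bed(tmp)
  expect_equal(back$chrom, iv$chrom)
  expect_equal(back$start, iv$start)
  expect_equal(back$end, iv$end)
  expect_equal(back$name, iv$name)
})

test_that("genome model validates background and sequence lengths", {
  expect_error(genome_model(c(chr1 = 100L),
                            background = c(A = 0.5, C = 0.5, G = 0.5, T = 0.5)))
  expect_error(genome_model(c(chr1 = 100L),
                            sequences = c(chr1 = "ACGT")))
  g <- genome_model(c(chr1 = 8L), sequences = c(chr1 = "AACCGGTT"))
  expect_equal(sum(g$background), 1)
  expect_equal(g$background[["A"]], g$background[["T"]])
})
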