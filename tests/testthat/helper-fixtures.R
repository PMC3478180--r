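# Fixture builders and independent brute-force oracles used across the suite.
# Oracles deliberately avoid the package's GRanges/vectorised code paths.

# A count matrix resembling a real TF motif: one dominant base per position,
# with the information content varying across positions (as in observed
# motifs), so scores take many distinct values rather than a few tied levels.
# Against a non-uniform background the consensus is biased toward the rarer
# bases (as real GC-rich motifs are in AT-rich genomes); for short matrices
# this keeps the achievable per-window hit rates finely spaced, which a 1%
# calibration target for an 8-mer requires.
make_fixture_pwm <- function(id, width, seed, n_obs = 20,
                             conc_range = c(0.55, 0.95),
                             background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  set.seed(seed)
  consensus <- sample(1:4, width, replace = TRUE,
                      prob = (1 / background[c("A", "C", "G", "T")])^2)
  conc <- runif(width, conc_range[1], conc_range[2])
  rest <- vapply(seq_len(width), function(j) {
    w <- rexp(3)
    (1 - conc[j]) * w / sum(w)
  }, numeric(3))
  counts <- matrix(0, 4, width)
  counts[cbind(consensus, seq_len(width))] <- conc * n_obs
  for (j in seq_len(width)) counts[-consensus[j], j] <- rest[, j] * n_obs
  new_pwm(id, counts, background = background)
}

random_interval_df <- function(n, chroms = c("chr1", "chr2"), max_pos = 1000L,
                               max_len = 120L) {
  start <- sample.int(max_pos, n, replace = TRUE) - 1L
  len <- sample.int(max_len, n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start, end = start + len, stringsAsFactors = FALSE)
}

# Per-base membership oracle for interval overlap.
overlap_per_base_oracle <- function(a, b) {
  if (a$chrom != b$chrom) return(FALSE)
  length(intersect(seq(a$start, a$end - 1L), seq(b$start, b$end - 1L))) > 0L
}

# Nested-loop oracle for distinct-instance TE overlap counts.
count_overlaps_oracle <- function(peaks, tes) {
  hit <- rep(FALSE, nrow(tes))
  for (i in seq_len(nrow(tes))) {
    for (j in seq_len(nrow(peaks))) {
      if (tes$chrom[i] == peaks$chrom[j] &&
          max(tes$start[i], peaks$win_start[j]) <
          min(tes$end[i], peaks$win_end[j])) {
        hit[i] <- TRUE
        break
      }
    }
  }
  fam <- table(factor(tes$name[hit], levels = unique(tes$name)))
  stats::setNames(as.integer(fam), names(fam))
}

# Exhaustive single-window scan: score every start on both strands by
# per-position arithmetic, independent of the package's matrix scanner.
naive_scan_oracle <- function(sequence, pwm, threshold) {
  L <- nchar(sequence)
  w <- pwm$width
  out <- list()
  for (p in 0:(L - w)) {
    word <- substr(sequence, p + 1L, p + w)
    for (s in c("+", "-")) {
      wd <- if (s == "-") {
        chartr("ACGT", "TGCA", paste(rev(strsplit(word, "")[[1]]), collapse = ""))
      } else word
      sc <- 0
      for (k in seq_len(w)) {
        base <- substr(wd, k, k)
        sc <- sc + if (base %in% c("A", "C", "G", "T")) {
          log2(pwm$probs[base, k] / pwm$background[[base]])
        } else 0
      }
      if (sc >= threshold) out[[length(out) + 1L]] <-
          data.frame(pos = p, strand = s, score = sc)
    }
  }
  if (length(out) == 0L)
    return(data.frame(pos = integer(0), strand = character(0),
                      score = numeric(0)))
  do.call(rbind, out)
}

# All-pairs oracle for signed start-to-start distance counts.
pair_distance_oracle <- function(hits, tf_a, tf_b) {
  counts <- integer(0)
  for (w in unique(hits$peak_id)) {
    a <- hits[hits$peak_id == w & hits$pwm_id == tf_a, ]
    b <- hits[hits$peak_id == w & hits$pwm_id == tf_b, ]
    for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
      if (tf_a == tf_b && a$pos[i] == b$pos[j] &&
          a$strand[i] == b$strand[j]) next
      key <- as.character(b$pos[j] - a$pos[i])
      counts[key] <- if (key %in% names(counts)) counts[[key]] + 1L else 1L
    }
  }
  counts[order(as.integer(names(counts)))]
}

# Whether each peak window overlaps at least one TE instance (plain loop).
interval_overlaps_any <- function(peaks, tes) {
  vapply(seq_len(nrow(peaks)), function(j) {
    any(tes$chrom == peaks$chrom[j] &
          pmax(tes$start, peaks$win_start[j]) <
          pmin(tes$end, peaks$win_end[j]))
  }, logical(1))
}

# Double-loop oracle for TSS-window gene assignment (midpoint containment).
gene_assignment_oracle <- function(peaks, genes, half_window) {
  out <- list()
  for (i in seq_len(nrow(genes))) for (j in seq_len(nrow(peaks))) {
    mid <- (peaks$start[j] + peaks$end[j]) %/% 2L
    if (genes$chrom[i] == peaks$chrom[j] &&
        abs(mid - genes$tss[i]) <= half_window) {
      out[[length(out) + 1L]] <- data.frame(gene_id = genes$gene_id[i],
                                            peak_id = peaks$id[j])
    }
  }
  if (length(out) == 0L)
    return(data.frame(gene_id = character(0), peak_id = character(0)))
  do.call(rbind, out)
}

# Small simulated study shared by several tests: one enriched family, one
# decoy of the same class, genes, and sequences.
small_study <- function(seed = 101L, n_peaks = 400L, multiplier = 5) {
  g <- generate_genome(c(chr1 = 300000L, chr2 = 200000L), gc_content = 0.45,
                       seed = seed)
  p1 <- plant_te_family(g, "MIRb", "SINE/MIR",
                        random_consensus(180L, seed = seed + 1L),
                        40L, divergence = 0.08, seed = seed + 2L)
  p2 <- plant_te_family(p1$genome, "MIR3", "SINE/MIR",
                        random_consensus(180L, seed = seed + 3L),
                        40L, divergence = 0.08, seed = seed + 4L,
                        occupied = p1$occupied)
  tes <- rbind(p1$tes, p2$tes)
  genome <- p2$genome
  peaks <- generate_peaks(genome, tes, c(MIRb = multiplier), n_peaks,
                          seed = seed + 5L)
  list(genome = genome, tes = tes, peaks = peaks)
}
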