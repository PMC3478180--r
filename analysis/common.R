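# Shared settings for the analysis drivers: study-scale constants and the
# fixture motif builder.  Each numbered script sources this file.

library(texapt)

SIM_DIR <- "results/sim"
RES_DIR <- "results"

STUDY <- list(
  chrom_lengths = c(chr1 = 2000000L, chr2 = 1500000L),
  gc_content = 0.4,            # mammalian-like base composition
  consensus_len = 250L,
  copies = 40L,
  divergence = 0.08,           # ancient-repeat decay
  n_peaks = 1500L,
  n_random = 200L,
  enriched = c(MIRb = 5, MER41B = 5),   # families bound above background
  n_genes = 400L,
  tss_near_te_fraction = 0.4,
  spacing_d = 24L,             # planted GATA3-ERR start-to-start distance
  n_blocks = 12L,
  inversion_fraction = 0.5,
  conserved_te_fraction = 0.3,
  seed = 20260101L
)

# Families: two enriched (one SINE/MIR, one LTR/ERV1) plus same-class decoys.
FAMILIES <- data.frame(
  name = c("MIRb", "MIR3", "MIRc", "MER41B", "MER41A", "AluY", "L2a"),
  te_class = c("SINE/MIR", "SINE/MIR", "SINE/MIR", "LTR/ERV1", "LTR/ERV1",
               "SINE/Alu", "LINE/L2"),
  stringsAsFactors = FALSE
)

# Fixture motifs standing in for the TF matrices the affinity stage scans
# (an estrogen-receptor-like palinduplet, its half site, and cofactors).
# Consensus bases lean toward the background's rarer bases, as real GC-rich
# motifs do in AT-rich genomes; short matrices need this for a 1% per-window
# threshold target to be attainable.
MOTIFS <- data.frame(
  id = c("ER", "halfERE", "GATA3", "ERR", "FOXA1", "AP1"),
  width = c(15L, 8L, 10L, 9L, 12L, 11L),
  seed = 9000L + 1:6,
  stringsAsFactors = FALSE
)

make_motif <- function(id, width, seed, background, n_obs = 20) {
  set.seed(seed)
  consensus <- sample(1:4, width, replace = TRUE,
                      prob = (1 / background[c("A", "C", "G", "T")])^2)
  conc <- runif(width, 0.55, 0.95)
  counts <- matrix(0, 4, width)
  counts[cbind(consensus, seq_len(width))] <- conc * n_obs
  for (j in seq_len(width)) {
    w <- rexp(3)
    counts[-consensus[j], j] <- (1 - conc[j]) * w / sum(w) * n_obs
  }
  new_pwm(id, counts)
}

build_motifs <- function(background) {
  out <- lapply(seq_len(nrow(MOTIFS)), function(i) {
    make_motif(MOTIFS$id[i], MOTIFS$width[i], MOTIFS$seed[i], background)
  })
  names(out) <- MOTIFS$id
  out
}

write_pwms_jaspar <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pwms) {
    writeLines(paste0(">", p$id), con)
    counts <- round(p$probs * 1000, 3)
    for (b in c("A", "C", "G", "T")) {
      writeLines(sprintf("%s [ %s ]", b,
                         paste(counts[b, ], collapse = " ")), con)
    }
  }
  invisible(path)
}
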