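#!/usr/bin/env Rscript
# Fixed-distance TFBS-pair correlators within TE-overlapping peak windows,
# with a permutation null, plus the conserved-core alignment report for the
# MIR-like instances.

source("analysis/common.R")

genome <- read_genome_fasta(file.path(SIM_DIR, "genome_a.fa"))
peaks <- read_peaks(file.path(SIM_DIR, "peaks.bed"), "bed", genome = genome)
tes <- read_repeatmasker(file.path(SIM_DIR, "tes_a.bed"), "bed_name_class")
pwms <- read_pwms(file.path(SIM_DIR, "motifs.jaspar"), "jaspar")
pwms <- lapply(pwms, calibrate_threshold, background = genome$background,
               n_mc = 10000L, seed = STUDY$seed + 600L)

hits <- scan_peak_windows(peaks, genome, pwms)

pairs <- list(c("GATA3", "ERR"), c("halfERE", "halfERE"), c("GATA3", "AP1"))
rows <- list()
hist_rows <- list()
for (pr in pairs) {
  h <- pair_distance_counts(hits, pr[1], pr[2],
                            widths = c(a = pwms[[pr[1]]]$width,
                                       b = pwms[[pr[2]]]$width))
  if (sum(h$counts$count) == 0) {
    message(sprintf("  %s~%s: no co-occurring hits", pr[1], pr[2]))
    next
  }
  sp <- detect_spacing_peak(h, n_permutations = 1000L,
                            seed = STUDY$seed + 700L)
  message(sprintf("  %s~%s: d* = %d, count %d (%.1fx background), p = %.4g",
                  pr[1], pr[2], sp$d_star, sp$count_at_peak,
                  sp$enrichment_ratio, sp$empirical_p))
  rows[[length(rows) + 1L]] <- data.frame(
    tf_a = pr[1], tf_b = pr[2], d_star = sp$d_star,
    count = sp$count_at_peak, enrichment = sp$enrichment_ratio,
    p = sp$empirical_p, stringsAsFactors = FALSE)
  hist_rows[[length(hist_rows) + 1L]] <-
    data.frame(tf_a = pr[1], tf_b = pr[2], h$counts,
               stringsAsFactors = FALSE)
}
texapt:::write_tsv_hash(do.call(rbind, hist_rows),
                        file.path(RES_DIR, "spacing_histograms.tsv"))
texapt:::write_tsv_hash(do.call(rbind, rows),
                        file.path(RES_DIR, "spacing_peaks.tsv"),
                        comment = "permutation null, 1000 redraws")

# conserved-core alignment of the peak-overlapping MIR-like instances
core <- readLines(file.path(SIM_DIR, "mir_core.txt"))[1]
ov <- count_te_overlaps(peaks, tes)
mir <- tes[ov$overlapped, ]
mir <- mir[grepl("^MIR", mir$name), ]
seqs <- vapply(seq_len(nrow(mir)), function(i) {
  texapt:::genome_seq(genome, mir$chrom[i],
                      mir$start[i] + 60L, mir$start[i] + 130L)
}, character(1))
names(seqs) <- mir$instance_id
rep <- core_alignment_report(seqs, core, pwms = pwms["halfERE"])
texapt:::write_tsv_hash(rep$positions,
                        file.path(RES_DIR, "mir_core_alignment.tsv"))
texapt:::write_tsv_hash(rep$site_creating,
                        file.path(RES_DIR, "mir_core_site_creating.tsv"))
message(sprintf(paste0("core alignment: %d MIR-like instances, mean ",
                       "identity %.3f; %d site-creating mutation(s)"),
                length(seqs), mean(rep$positions$identity, na.rm = TRUE),
                nrow(rep$site_creating)))
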