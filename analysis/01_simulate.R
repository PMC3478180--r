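#!/usr/bin/env Rscript
# Build the synthetic study: a two-chromosome genome carrying decayed TE
# families, an enriched-peak set, planted motif combinations (a GATA3-ERR
# pair at a fixed 24 bp spacing in MER41B; a half-ERE at the start of a
# 70 bp core shared by the MIR-like families), genes near TEs, and a
# syntenic second genome.  Everything downstream reads the plain-text
# files written here; the ground truth is recorded alongside.

source("analysis/common.R")
dir.create(SIM_DIR, recursive = TRUE, showWarnings = FALSE)
set.seed(STUDY$seed)

message("genome: ", paste(names(STUDY$chrom_lengths), collapse = ", "),
        " at ", STUDY$gc_content * 100, "% GC")
genome <- generate_genome(STUDY$chrom_lengths, STUDY$gc_content,
                          seed = STUDY$seed)
motifs <- build_motifs(genome$background)

# family consensus sequences; MIR-like families share a 70 bp core that
# carries a half-ERE at its 5' end, and MER41B carries GATA3 + ERR at a
# fixed start-to-start distance
core <- plant_motif_combination(random_consensus(70L, seed = STUDY$seed + 1L),
                                motifs$halfERE, offset_a = 2L)
consensi <- list()
for (i in seq_len(nrow(FAMILIES))) {
  f <- FAMILIES$name[i]
  cons <- random_consensus(STUDY$consensus_len, seed = STUDY$seed + 10L + i)
  if (FAMILIES$te_class[i] == "SINE/MIR") {
    substr(cons, 61L, 130L) <- core   # shared conserved core at offset 60
  }
  if (f == "MER41B") {
    cons <- plant_motif_combination(cons, motifs$GATA3, motifs$ERR,
                                    offset_a = 50L,
                                    distance = STUDY$spacing_d)
  }
  consensi[[f]] <- cons
}

occupied <- NULL
tes <- list()
for (i in seq_len(nrow(FAMILIES))) {
  f <- FAMILIES$name[i]
  pf <- plant_te_family(genome, f, FAMILIES$te_class[i], consensi[[f]],
                        STUDY$copies, divergence = STUDY$divergence,
                        seed = STUDY$seed + 100L + i, occupied = occupied)
  genome <- pf$genome
  occupied <- pf$occupied
  tes[[f]] <- pf$tes
}
tes <- do.call(rbind, tes)
message(nrow(tes), " TE instances planted across ", nrow(FAMILIES),
        " families")

peaks <- generate_peaks(genome, tes, STUDY$enriched, STUDY$n_peaks,
                        seed = STUDY$seed + 200L)
truth_pk <- attr(peaks, "truth")
message(STUDY$n_peaks, " peaks; planted overlap targets: ",
        paste(sprintf("%s=%.3f", names(truth_pk$target_fraction),
                      truth_pk$target_fraction), collapse = ", "))

genes <- generate_genes(genome, tes, STUDY$n_genes,
                        STUDY$tss_near_te_fraction,
                        seed = STUDY$seed + 300L)

syn <- generate_synteny(genome, tes, STUDY$n_blocks,
                        STUDY$inversion_fraction,
                        STUDY$conserved_te_fraction,
                        seed = STUDY$seed + 400L)
message(nrow(syn$pairs_truth), " TE instances conserved into the second genome")

# ---- outputs ----------------------------------------------------------
write_genome_fasta(genome, file.path(SIM_DIR, "genome_a.fa"))
write_genome_fasta(syn$genome_b, file.path(SIM_DIR, "genome_b.fa"))
write_bed(tes, file.path(SIM_DIR, "tes_a.bed"))
write_bed(syn$tes_b, file.path(SIM_DIR, "tes_b.bed"))
write_bed(peaks, file.path(SIM_DIR, "peaks.bed"))
write_synteny_blocks(syn$blocks, file.path(SIM_DIR, "blocks.tsv"))
write_pwms_jaspar(motifs, file.path(SIM_DIR, "motifs.jaspar"))
writeLines(core, file.path(SIM_DIR, "mir_core.txt"))
texapt:::write_tsv_hash(genes, file.path(SIM_DIR, "genes.tsv"))
texapt:::write_tsv_hash(
  data.frame(peak_id = peaks$id,
             planted_family = ifelse(is.na(truth_pk$planted_family), "",
                                     truth_pk$planted_family)),
  file.path(SIM_DIR, "truth_peaks.tsv"))
texapt:::write_tsv_hash(attr(genes, "truth"),
                        file.path(SIM_DIR, "truth_genes.tsv"))
pt <- syn$pairs_truth
ia <- match(pt$te_a, tes$instance_id)
ib <- match(pt$te_b, syn$tes_b$instance_id)
pt <- cbind(pt,
            a_chrom = tes$chrom[ia], a_start = tes$start[ia],
            a_end = tes$end[ia],
            b_chrom = syn$tes_b$chrom[ib], b_start = syn$tes_b$start[ib],
            b_end = syn$tes_b$end[ib])
texapt:::write_tsv_hash(pt, file.path(SIM_DIR, "truth_conserved_pairs.tsv"))
message("wrote simulation inputs and ground truth under ", SIM_DIR)
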