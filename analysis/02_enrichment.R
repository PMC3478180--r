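#!/usr/bin/env Rscript
# TE-family and class enrichment of the peak set against locally matched
# Monte Carlo peak resampling (1 Mb windows), z = (x - mu)/sqrt(s).

source("analysis/common.R")

genome <- read_genome_fasta(file.path(SIM_DIR, "genome_a.fa"))
peaks <- read_peaks(file.path(SIM_DIR, "peaks.bed"), "bed", genome = genome)
tes <- read_repeatmasker(file.path(SIM_DIR, "tes_a.bed"), "bed_name_class")

res <- enrichment_zscores(peaks, tes, genome, n_random = STUDY$n_random,
                          seed = STUDY$seed + 500L)
texapt:::write_tsv_hash(res, file.path(RES_DIR, "enrichment_zscores.tsv"),
                        comment = sprintf("n_random = %d", STUDY$n_random))

enriched <- filter_enriched(res, z_min = 3)
texapt:::write_tsv_hash(rbind(enriched$family, enriched$class),
                        file.path(RES_DIR, "enriched_z3.tsv"),
                        comment = "units with z > 3")

message("family-level z-scores:")
fam <- res[res$level == "family", ]
for (i in order(-fam$z)) {
  message(sprintf("  %-8s x=%3d mu=%6.1f z=%6.2f", fam$unit[i], fam$x[i],
                  fam$mu[i], fam$z[i]))
}
message("enriched at z > 3: ",
        paste(enriched$family$unit, collapse = ", "), " (families); ",
        paste(enriched$class$unit, collapse = ", "), " (classes)")
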