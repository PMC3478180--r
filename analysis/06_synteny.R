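#!/usr/bin/env Rscript
# Conserved TE identification: project genome-A TE spans through the
# syntenic block table into genome B, match same-family annotations at
# reciprocal overlap >= 0.5, and compare against the simulation's truth.

source("analysis/common.R")

tes_a <- read_repeatmasker(file.path(SIM_DIR, "tes_a.bed"), "bed_name_class")
tes_b <- read_repeatmasker(file.path(SIM_DIR, "tes_b.bed"), "bed_name_class")
blocks <- read_synteny_blocks(file.path(SIM_DIR, "blocks.tsv"))
truth <- texapt:::read_tsv_hash(file.path(SIM_DIR, "truth_conserved_pairs.tsv"))

pairs <- find_conserved_te_pairs(tes_a, tes_b, blocks,
                                 min_reciprocal_overlap = 0.5)
texapt:::write_tsv_hash(pairs, file.path(RES_DIR, "conserved_pairs.tsv"))

# instance ids are reassigned on read, so evaluate through coordinates
coord_key <- function(ca, sa, ea, cb, sb, eb) {
  paste(ca, sa, ea, cb, sb, eb)
}
ia <- match(pairs$te_a, tes_a$instance_id)
ib <- match(pairs$te_b, tes_b$instance_id)
got <- coord_key(tes_a$chrom[ia], tes_a$start[ia], tes_a$end[ia],
                 tes_b$chrom[ib], tes_b$start[ib], tes_b$end[ib])
want <- coord_key(truth$a_chrom, truth$a_start, truth$a_end,
                  truth$b_chrom, truth$b_start, truth$b_end)
tp <- sum(got %in% want)
message(sprintf("%d pairs recovered, %d in truth: precision %.3f, recall %.3f",
                length(got), length(want), tp / length(got),
                tp / length(want)))
by_fam <- table(pairs$name)
message("per family: ",
        paste(sprintf("%s=%d", names(by_fam), by_fam), collapse = ", "))
message(sprintf("fraction of MIR-like instances with a conserved partner: %.2f",
                sum(grepl("^MIR", pairs$name)) / sum(grepl("^MIR", tes_a$name))))
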