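#!/usr/bin/env Rscript
# Peak-to-gene assignment in +/- 20 kb TSS windows, TE-to-nearest-TSS
# distance histogram, and a hypergeometric category-enrichment pass over
# randomly assigned categories (a null control: nothing should light up).

source("analysis/common.R")

genome <- read_genome_fasta(file.path(SIM_DIR, "genome_a.fa"))
peaks <- read_peaks(file.path(SIM_DIR, "peaks.bed"), "bed", genome = genome)
tes <- read_repeatmasker(file.path(SIM_DIR, "tes_a.bed"), "bed_name_class")
genes <- texapt:::read_tsv_hash(file.path(SIM_DIR, "genes.tsv"))

links <- assign_peaks_to_genes(peaks, genes, half_window = 20000L, tes = tes)
texapt:::write_tsv_hash(links, file.path(RES_DIR, "gene_peak_links.tsv"))
message(nrow(links), " gene-peak links (",
        length(unique(links$gene_id)), " genes, ",
        length(unique(links$peak_id)), " peaks)")

ov <- count_te_overlaps(peaks, tes)
hist <- te_tss_distance_hist(tes[ov$overlapped, ], genes, bin_width = 2000L)
texapt:::write_tsv_hash(hist$hist, file.path(RES_DIR, "te_tss_distances.tsv"))
mode_bin <- hist$hist[which.max(hist$hist$count), ]
message(sprintf("nearest-TSS histogram mode: [%d, %d) with %d TEs",
                mode_bin$bin_start, mode_bin$bin_end, mode_bin$count))

# random categories over the linked-gene background: a null control for the
# enrichment machinery (the paper's real run used curated annotation, which
# is out of reach here)
set.seed(STUDY$seed + 800L)
background <- unique(links$gene_id)
cats <- data.frame(gene_id = rep(background, 2L),
                   category = sample(sprintf("CAT%02d", 1:20),
                                     2L * length(background), replace = TRUE),
                   stringsAsFactors = FALSE)
mir_genes <- unique(links$gene_id[grepl("MIR", links$te_families)])
fe <- functional_enrichment(mir_genes, cats, background)
texapt:::write_tsv_hash(fe, file.path(RES_DIR, "category_enrichment.tsv"),
                        comment = "random categories: null control")
message(sprintf(paste0("category enrichment over %d MIR-linked genes: ",
                       "min q = %.3f (random categories; expected ~1)"),
                length(mir_genes), min(fe$q)))
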