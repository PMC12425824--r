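#!/usr/bin/env Rscript
# Stage 1 -- generate the synthetic multiome under the study conditions:
# four epithelial cell types (basal, L1, L2 and the proliferative IM state),
# 2,000 GC-heterogeneous peaks, per-type peak programs at 4x, and a candidate
# motif (STAT3) whose co-occurrence with the ETS family is amplified 2-fold
# in IM cells. A matched bulk cohort carries a log(2.5)-per-SD signature
# hazard. All outputs are written as plain text under results/data/.

suppressMessages(library(motifdev))
seed <- 1L
outdir <- "results/data"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(seed = seed)
atac <- generate_atac(cfg)
rna <- generate_rna(cfg)
cohort <- generate_cohort(cfg)

write_sparse_matrix(atac$counts, file.path(outdir, "atac"))
write_sparse_matrix(rna$counts, file.path(outdir, "rna"))
write_peaks(atac$peaks, file.path(outdir, "peaks.bed"),
            file.path(outdir, "peaks_annot.tsv"))
write_motif_membership(atac$motifs, file.path(outdir, "motifs.tsv"))
write_cohort(cohort, file.path(outdir, "cohort.csv"))
write.table(atac$cells, file.path(outdir, "atac_cells.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(rna$cells, file.path(outdir, "rna_cells.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
writeLines(rownames(rna$counts)[rna$mito_mask],
           file.path(outdir, "mito_genes.tsv"))
write_signatures(lapply(names(rna$marker_sets), function(t)
  signature_set(t, rna$marker_sets[[t]])),
  file.path(outdir, "lineage_signatures.tsv"))

message(sprintf("ATAC: %d peaks x %d cells (%d motifs); RNA: %d genes x %d cells; cohort: %d samples",
                nrow(atac$counts), ncol(atac$counts), ncol(atac$motifs),
                nrow(rna$counts), ncol(rna$counts), nrow(cohort)))
message("wrote inputs under ", outdir)
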