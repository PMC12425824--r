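#!/usr/bin/env Rscript
# Stage 4 -- motif accessibility deviations. For every motif, the per-cell
# deviation of its peak set from the depth-expected counts is bias-corrected
# against B = 50 background peak sets matched on GC content and mean
# accessibility (k = 50 nearest neighbours), giving a Z score per cell.

suppressMessages(library(motifdev))
datadir <- "results/data"
seed <- 1L

atac <- read_sparse_matrix(file.path(datadir, "atac"))
kept <- readLines(file.path(datadir, "kept_atac_barcodes.tsv"))
atac <- atac[, kept]
peaks <- read_peaks(file.path(datadir, "peaks.bed"),
                    file.path(datadir, "peaks_annot.tsv"))
peaks$mean_accessibility <- Matrix::rowMeans(atac)
M <- read_motif_membership(file.path(datadir, "motifs.tsv"))

bg <- sample_background_peaks(peaks, k = 50, B = 50, seed = seed)
ds <- compute_deviations(atac, M, bg)

write.table(data.frame(motif = rownames(ds$z), ds$z, check.names = FALSE),
            "results/deviation_z.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(data.frame(motif = rownames(ds$z), is.na(ds$z) * 1L,
                       check.names = FALSE),
            "results/deviation_z_missing.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message(sprintf("deviations for %d motifs x %d cells; %d undefined Z values",
                nrow(ds$z), ncol(ds$z), sum(is.na(ds$z))))
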