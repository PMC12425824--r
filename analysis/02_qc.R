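#!/usr/bin/env Rscript
# Stage 2 -- cell-level quality control. RNA cells are kept with 500-100,000
# transcripts and mitochondrial fraction below 40%; ATAC cells with TSS
# enrichment >= 4, at least 1,000 fragments and at most 1 million reads.

suppressMessages(library(motifdev))
datadir <- "results/data"

rna <- read_sparse_matrix(file.path(datadir, "rna"))
mito_genes <- readLines(file.path(datadir, "mito_genes.tsv"))
kept_rna <- filter_rna_cells(rna, rownames(rna) %in% mito_genes)
writeLines(kept_rna, file.path(datadir, "kept_rna_barcodes.tsv"))

atac_cells <- read.delim(file.path(datadir, "atac_cells.tsv"))
kept_atac <- filter_atac_cells(atac_cells$fragments, atac_cells$reads,
                               atac_cells$tss_enrichment,
                               cell_ids = atac_cells$cell_id)
writeLines(kept_atac, file.path(datadir, "kept_atac_barcodes.tsv"))

message(sprintf("kept %d/%d RNA cells and %d/%d ATAC cells",
                length(kept_rna), ncol(rna),
                length(kept_atac), nrow(atac_cells)))
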