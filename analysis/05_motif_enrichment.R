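#!/usr/bin/env Rscript
# Stage 5 -- per-cell-type motif enrichment with retention filters. A cell
# is motif-accessible when its deviation Z is positive; enrichment of
# accessible cells within each cell type is tested hypergeometrically with
# BH correction (display rule FDR < 1e-20). Motifs are then retained only
# where their gene's normalized mean expression exceeds 1 in the cell type
# and their Z correlates positively (Spearman) with the gene's expression.

suppressMessages(library(motifdev))
datadir <- "results/data"

z <- read.delim("results/deviation_z.tsv", check.names = FALSE)
zm <- as.matrix(z[, -1]); rownames(zm) <- z$motif
atac_cells <- read.delim(file.path(datadir, "atac_cells.tsv"))
labels <- atac_cells$cell_type[match(colnames(zm), atac_cells$cell_id)]

enr <- celltype_motif_enrichment(zm, labels)
write.table(enr, "results/motif_enrichment.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message(sprintf("%d (motif, cell type) pairs tested; %d pass the display rule",
                nrow(enr), sum(enr$reported)))

# retention filters against the RNA modality (shared barcodes)
rna <- read_sparse_matrix(file.path(datadir, "rna"))
norm <- normalize_cp10k(rna)
map <- data.frame(motif = c("ETS", "STAT3", "NFATC1"),
                  gene = c("basal_mk01", "IM_mk01", "basal_mk02"))
rna_cells <- read.delim(file.path(datadir, "rna_cells.tsv"))
mean_expr <- vapply(split(seq_len(ncol(norm)),
                          rna_cells$cluster[match(colnames(norm),
                                                  rna_cells$cell_id)]),
                    function(j) Matrix::rowMeans(norm[, j, drop = FALSE]),
                    numeric(nrow(norm)))
ef <- expression_filter(map, mean_expr)
write.table(ef, "results/expression_filter.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

shared <- intersect(colnames(zm), colnames(norm))
cf <- do.call(rbind, lapply(seq_len(nrow(map)), function(i) {
  r <- correlation_filter(zm[map$motif[i], shared],
                          as.numeric(norm[map$gene[i], shared]))
  data.frame(motif = map$motif[i], gene = map$gene[i], rho = r$rho,
             retained = r$retained, n = r$n)
}))
write.table(cf, "results/correlation_filter.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message(sprintf("expression filter retains %d pairs; Spearman filter retains %d motifs",
                sum(ef$retained), sum(cf$retained)))
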