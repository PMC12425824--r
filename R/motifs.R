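#' Collapse a motif family into one membership column
#'
#' Adds a family column that is the logical OR of the member motif columns
#' (e.g. ERG/ETS/ETV/FLI collapsed into a single "ETS" identifier). Member
#' columns are retained.
#'
#' @param M Binary peaks x motifs matrix with motif column names.
#' @param members Motif names to collapse; all must exist.
#' @param family Name of the new column.
#' @return The membership matrix with one added column.
#' @export
reduce_motif_family <- function(M, members, family) {
  missing <- setdiff(members, colnames(M))
  if (length(missing))
    stop_input("unknown motif(s): ", paste(missing, collapse = ", "))
  fam <- as.integer(rowSums(M[, members, drop = FALSE] != 0) > 0)
  out <- cbind(M, fam)
  colnames(out)[ncol(out)] <- family
  out
}

#' Per-cell-type motif enrichment by hypergeometric test
#'
#' A cell is called motif-accessible iff its deviation Z score exceeds
#' \code{z_threshold} (default 0). For each (motif, cell type) pair the
#' upper-tail hypergeometric p is the probability of drawing at least the
#' observed number of accessible cells when sampling the cell type's size
#' from the population of cells with defined Z. P values are
#' Benjamini-Hochberg adjusted across all pairs; the \code{reported} flag
#' applies the display rule FDR < \code{report_fdr} (default 1e-20) used when
#' presenting enriched motifs, without removing rows.
#'
#' @param dev A [compute_deviations()] result (or a bare motifs x cells Z
#'   matrix).
#' @param labels Cell-type label per cell (matching the Z columns).
#' @param z_threshold Accessibility binarization cutoff on Z.
#' @param report_fdr Display cutoff for the \code{reported} flag.
#' @return Data frame: motif, cell_type, overlap, cell_type_size,
#'   accessible, population, p, fdr, reported.
#' @export
celltype_motif_enrichment <- function(dev, labels, z_threshold = 0,
                                      report_fdr = 1e-20) {
  z <- if (inherits(dev, "deviation_set")) dev$z else as.matrix(dev)
  if (ncol(z) != length(labels))
    stop_input("'labels' must have one entry per cell")
  types <- unique(as.character(labels))
  empty <- types[!types %in% labels]
  if (length(empty)) warning("cell type(s) with 0 cells skipped")
  rows <- list()
  for (m in rownames(z)) {
    zi <- z[m, ]
    defined <- !is.na(zi)
    acc <- defined & zi > z_threshold
    N <- sum(defined); K <- sum(acc)
    for (t in types) {
      in_t <- defined & labels == t
      n_t <- sum(in_t)
      if (n_t == 0L) next
      q <- sum(acc & in_t)
      p <- phyper(q - 1, K, N - K, n_t, lower.tail = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        motif = m, cell_type = t, overlap = q, cell_type_size = n_t,
        accessible = K, population = N, p = p, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$fdr <- p.adjust(out$p, method = "BH")
  out$reported <- out$fdr < report_fdr
  rownames(out) <- NULL
  out
}

#' Retain motifs whose gene is expressed in a cell type
#'
#' A motif is retained in a cell type iff its gene's normalized mean
#' expression there is strictly greater than \code{threshold} (default 1).
#' Motifs whose gene is absent from the expression matrix are dropped in all
#' cell types with a warning.
#'
#' @param motif_genes Data frame with columns \code{motif}, \code{gene} (one
#'   gene per motif).
#' @param mean_expr Genes x cell-types matrix of normalized mean expression.
#' @param threshold Strict retention cutoff.
#' @return Data frame: motif, gene, cell_type, mean_expression, retained.
#' @export
expression_filter <- function(motif_genes, mean_expr, threshold = 1) {
  stopifnot(all(c("motif", "gene") %in% names(motif_genes)))
  absent <- !motif_genes$gene %in% rownames(mean_expr)
  if (any(absent))
    warning("motif(s) with gene absent from the expression matrix dropped: ",
            paste(motif_genes$motif[absent], collapse = ", "))
  present <- motif_genes[!absent, , drop = FALSE]
  out <- do.call(rbind, lapply(seq_len(nrow(present)), function(i) {
    e <- mean_expr[present$gene[i], ]
    data.frame(motif = present$motif[i], gene = present$gene[i],
               cell_type = colnames(mean_expr), mean_expression = as.numeric(e),
               retained = as.numeric(e) > threshold, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Retain motifs with positive Spearman correlation to their gene score
#'
#' Computes the Spearman rank correlation between a motif's per-cell
#' deviation Z and the per-cell score of the motif's gene; the motif is
#' retained iff the correlation is strictly positive. Pairs where either
#' value is undefined are excluded; at least \code{min_cells} complete pairs
#' are required. Constant vectors give an undefined correlation and drop the
#' motif with a warning.
#'
#' @param z Per-cell deviation Z for one motif.
#' @param gene_score Per-cell gene score (expression or ATAC-derived gene
#'   activity; either is accepted).
#' @param min_cells Minimum complete pairs.
#' @return List: \code{rho}, \code{retained}, \code{n} (pairs used).
#' @export
correlation_filter <- function(z, gene_score, min_cells = 10L) {
  if (length(z) != length(gene_score))
    stop_input("'z' and 'gene_score' must have equal length")
  ok <- !is.na(z) & !is.na(gene_score)
  if (sum(ok) < min_cells)
    stop_input("fewer than ", min_cells, " cells with both values defined")
  x <- z[ok]; y <- gene_score[ok]
  if (sd(x) == 0 || sd(y) == 0) {
    warning("constant vector: Spearman correlation undefined, motif dropped")
    return(list(rho = NA_real_, retained = FALSE, n = sum(ok)))
  }
  rho <- cor(x, y, method = "spearman")
  list(rho = rho, retained = rho > 0, n = sum(ok))
}

#' Differentially accessible regions between two cell groups
#'
#' Depth-normalizes the counts (counts per 10,000 per cell, no log), then per
#' peak runs a two-sample Wilcoxon rank-sum test between the groups and
#' computes the log2 fold change of group means with a pseudocount. A peak is
#' a DAR iff its Benjamini-Hochberg FDR is below 0.05 and its log2 fold
#' change is at least 0.5.
#'
#' @param X Peaks x cells count matrix.
#' @param cells_a,cells_b Disjoint cell identifier vectors (column names),
#'   each of at least 3 cells.
#' @param pseudocount Added to both group means.
#' @param fdr_cutoff,lfc_cutoff DAR rule: \code{fdr < fdr_cutoff} and
#'   \code{log2FC >= lfc_cutoff}.
#' @return Data frame: peak, log2FC, p, fdr, dar.
#' @export
differential_accessibility <- function(X, cells_a, cells_b, pseudocount = 1,
                                       fdr_cutoff = 0.05, lfc_cutoff = 0.5) {
  if (length(intersect(cells_a, cells_b)))
    stop_input("cell groups overlap")
  if (length(cells_a) < 3L || length(cells_b) < 3L)
    stop_input("each group needs at least 3 cells")
  miss <- setdiff(c(cells_a, cells_b), colnames(X))
  if (length(miss)) stop_input("unknown cell(s): ", paste(miss, collapse = ", "))
  depth <- col_sums(X)
  Xn <- as.matrix(scale_columns(X, ifelse(depth > 0, 1e4 / depth, 0)))
  A <- Xn[, cells_a, drop = FALSE]
  B <- Xn[, cells_b, drop = FALSE]
  p <- vapply(seq_len(nrow(Xn)), function(i)
    wilcox.test(A[i, ], B[i, ], exact = FALSE)$p.value, numeric(1))
  lfc <- log2((rowMeans(A) + pseudocount) / (rowMeans(B) + pseudocount))
  fdr <- p.adjust(p, method = "BH")
  data.frame(peak = rownames(Xn) %||% as.character(seq_len(nrow(Xn))),
             log2FC = lfc, p = p, fdr = fdr,
             dar = fdr < fdr_cutoff & lfc >= lfc_cutoff,
             stringsAsFactors = FALSE, row.names = NULL)
}
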