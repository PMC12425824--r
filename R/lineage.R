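#' Log-normalize a count matrix to counts per 10,000
#'
#' Each cell's counts are scaled to a common library size of 10,000 and
#' log1p-transformed. Cells with zero total counts stay all-zero.
#'
#' @param counts Features x cells count matrix, sparse or dense.
#' @param scale_factor Library size to scale to.
#' @return Matrix of the same shape and class family (sparsity preserved).
#' @export
normalize_cp10k <- function(counts, scale_factor = 1e4) {
  depth <- col_sums(counts)
  f <- ifelse(depth > 0, scale_factor / depth, 0)
  out <- scale_columns(counts, f)
  if (is(out, "sparseMatrix")) {
    out <- as(out, "CsparseMatrix")
    out@x <- log1p(out@x)
  } else {
    out <- log1p(out)
  }
  out
}

#' Construct a gene signature set
#'
#' @param name Signature label.
#' @param genes Character vector of gene identifiers; duplicates are dropped.
#' @param allow_empty Permit an empty signature (used when a derived
#'   signature has no genes passing its cutoffs).
#' @export
signature_set <- function(name, genes, allow_empty = FALSE) {
  stopifnot(is.character(name), length(name) == 1L)
  genes <- unique(as.character(genes))
  if (!allow_empty && length(genes) == 0L)
    stop_input("signature '", name, "' has no genes")
  structure(list(name = name, genes = genes), class = "signature_set")
}

#' Identify Epcam-positive cells
#'
#' A cell is Epcam-positive iff its raw Epcam count is at least 1 (the
#' simplest detectable-transcript rule; configurable).
#'
#' @param counts Genes x cells raw count matrix with gene row names.
#' @param gene Epcam gene identifier.
#' @param min_count Positivity threshold on the raw count.
#' @return Named logical vector per cell.
#' @export
epcam_positive_cells <- function(counts, gene = "Epcam", min_count = 1L) {
  if (!gene %in% rownames(counts))
    stop_input("gene '", gene, "' not found in the matrix")
  setNames(as.vector(counts[gene, ] >= min_count), colnames(counts))
}

#' Flag epithelial clusters by Epcam-positive fraction
#'
#' A cluster is flagged epithelial iff at least \code{threshold} of its cells
#' are Epcam-positive (default 50\%, inclusive).
#'
#' @param clusters Cluster label per cell.
#' @param epcam_positive Logical per cell.
#' @param threshold Inclusive fraction cutoff.
#' @return Character vector of flagged cluster labels.
#' @export
flag_epithelial_clusters <- function(clusters, epcam_positive, threshold = 0.5) {
  if (length(clusters) != length(epcam_positive))
    stop_input("'clusters' and 'epcam_positive' must have equal length")
  if (anyNA(clusters)) stop_input("every cell must have a cluster label")
  threshold <- check_fraction(threshold, "threshold")
  cl <- as.factor(clusters)
  empty <- setdiff(levels(cl), unique(as.character(cl)))
  if (length(empty))
    warning("empty cluster(s) excluded: ", paste(empty, collapse = ", "))
  frac <- tapply(epcam_positive, as.character(cl), mean)
  names(frac)[frac >= threshold]
}

#' Score cells against a gene signature
#'
#' The score of a cell is the mean, over signature genes present in the
#' matrix, of the per-gene z-score of its (log-normalized) expression across
#' cells. Genes with zero variance contribute 0. Signature genes absent from
#' the matrix are dropped with a warning; if none remain the call errors.
#'
#' @param norm Log-normalized genes x cells matrix (see [normalize_cp10k()]).
#' @param signature A [signature_set()].
#' @return Named numeric score per cell.
#' @export
score_signature <- function(norm, signature) {
  stopifnot(inherits(signature, "signature_set"))
  present <- intersect(signature$genes, rownames(norm))
  missing <- setdiff(signature$genes, present)
  if (length(missing))
    warning("signature '", signature$name, "': ", length(missing),
            " gene(s) absent from the matrix dropped")
  if (length(present) == 0L)
    stop_input("no gene of signature '", signature$name,
               "' is present in the matrix")
  x <- as.matrix(norm[present, , drop = FALSE])
  m <- rowMeans(x)
  n <- ncol(x)
  s <- if (n > 1) sqrt(rowSums((x - m)^2) / (n - 1)) else rep(0, nrow(x))
  z <- (x - m) / ifelse(s > 0, s, 1)
  z[s == 0, ] <- 0
  setNames(colMeans(z), colnames(norm))
}

#' Assign cell types from signature scores within flagged epithelial clusters
#'
#' Cells in flagged clusters get the label with the strict maximum score;
#' exact ties and cells outside flagged clusters are "unassigned". Only
#' assigned cells are marked confident epithelial.
#'
#' @param scores Cells x labels numeric matrix (one column per signature).
#' @param epithelial Logical per cell: does the cell sit in a flagged
#'   epithelial cluster?
#' @return Data frame: cell_id, one column per label score, label,
#'   epithelial_confident.
#' @export
assign_cell_type <- function(scores, epithelial) {
  scores <- as.matrix(scores)
  if (nrow(scores) != length(epithelial))
    stop_input("'epithelial' must have one entry per cell")
  if (is.null(colnames(scores)))
    stop_input("'scores' must have signature labels as column names")
  top <- apply(scores, 1L, max)
  n_top <- rowSums(scores == top)
  label <- colnames(scores)[apply(scores, 1L, which.max)]
  label[n_top > 1L | !epithelial] <- "unassigned"
  out <- data.frame(
    cell_id = rownames(scores) %||% as.character(seq_len(nrow(scores))),
    scores, label = label,
    epithelial_confident = epithelial & label != "unassigned",
    stringsAsFactors = FALSE, check.names = FALSE)
  rownames(out) <- NULL
  out
}

#' Rank marker genes per cell-type label
#'
#' For each label with at least \code{min_cells} cells, each gene is tested
#' label-vs-rest with a two-sample Wilcoxon rank-sum test on the normalized
#' values; the log2 fold change compares group means on the expression scale
#' (the log1p-normalized values are de-logged first) with a pseudocount.
#' P values are Benjamini-Hochberg adjusted within label, and significant
#' genes (FDR < 0.05) are ranked by average log2 fold change.
#'
#' @param norm Log-normalized genes x cells matrix (see [normalize_cp10k()]).
#' @param labels Cell-type label per cell.
#' @param pseudocount Added to both group means before the ratio.
#' @param min_cells Labels with fewer cells are skipped with a warning.
#' @return Data frame: label, gene, avg_log2FC, p, fdr, rank (NA when not
#'   FDR-significant).
#' @export
derive_markers <- function(norm, labels, pseudocount = 1, min_cells = 3L) {
  if (length(labels) != ncol(norm))
    stop_input("'labels' must have one entry per cell")
  tab <- table(labels)
  small <- names(tab)[tab < min_cells]
  if (length(small))
    warning("label(s) with fewer than ", min_cells, " cells skipped: ",
            paste(small, collapse = ", "))
  use <- setdiff(names(tab), small)
  if (length(use) < 2L)
    stop_input("need at least two labels with >= ", min_cells, " cells")
  x <- as.matrix(norm)
  xe <- expm1(x)  # expression scale for fold changes
  res <- lapply(use, function(lab) {
    in_grp <- labels == lab
    p <- apply(x, 1L, function(g)
      wilcox.test(g[in_grp], g[!in_grp], exact = FALSE)$p.value)
    lfc <- log2((rowMeans(xe[, in_grp, drop = FALSE]) + pseudocount) /
                (rowMeans(xe[, !in_grp, drop = FALSE]) + pseudocount))
    fdr <- p.adjust(p, method = "BH")
    d <- data.frame(label = lab, gene = rownames(x), avg_log2FC = lfc,
                    p = p, fdr = fdr, stringsAsFactors = FALSE)
    d <- d[order(-d$avg_log2FC), ]
    d$rank <- NA_integer_
    sig <- d$fdr < 0.05
    d$rank[sig] <- seq_len(sum(sig))
    d
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Derive a gene signature from a ranked marker table
#'
#' Keeps genes with FDR strictly below \code{padj_cutoff} and fold change
#' strictly above \code{fc_cutoff} (on the linear scale, i.e.
#' \code{2^avg_log2FC > fc_cutoff}), ordered by rank.
#'
#' @param markers Output of [derive_markers()], optionally pre-filtered to
#'   one label.
#' @param label Label to extract (required when the table has several).
#' @param padj_cutoff,fc_cutoff Strict cutoffs (defaults 0.05 and 2).
#' @param name Signature name; defaults to the label.
#' @return A [signature_set()]; empty (with a warning) when nothing passes.
#' @export
signature_from_markers <- function(markers, label = NULL,
                                   padj_cutoff = 0.05, fc_cutoff = 2,
                                   name = NULL) {
  if (!is.null(label)) markers <- markers[markers$label == label, , drop = FALSE]
  if (length(unique(markers$label)) > 1L)
    stop_input("marker table has several labels; pass 'label'")
  name <- name %||% (if (nrow(markers)) markers$label[1L] else "signature")
  keep <- markers$fdr < padj_cutoff & 2^markers$avg_log2FC > fc_cutoff
  kept <- markers[keep, , drop = FALSE]
  kept <- kept[order(kept$rank), , drop = FALSE]
  if (nrow(kept) == 0L) {
    warning("no gene passes padj < ", padj_cutoff, " and FC > ", fc_cutoff,
            " for '", name, "'; returning an empty signature")
    return(signature_set(name, character(0), allow_empty = TRUE))
  }
  signature_set(name, kept$gene)
}
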