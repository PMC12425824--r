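#' RNA cell-quality thresholds
#'
#' Defaults follow the standard rules for droplet scRNA-seq of prostate
#' tissue: cells with fewer than 500 transcripts are poor quality, cells with
#' more than 100,000 transcripts are putative multiplets, and cells with 40\%
#' or more mitochondrial reads are removed.
#'
#' @param min_transcripts Minimum total transcripts (kept if total >= this).
#' @param max_transcripts Maximum total transcripts (kept if total <= this).
#' @param max_mito_fraction Cells with mitochondrial fraction >= this are
#'   removed (strict: exactly 0.40 is removed at the default).
#' @export
rna_qc_thresholds <- function(min_transcripts = 500L,
                              max_transcripts = 100000L,
                              max_mito_fraction = 0.40) {
  min_transcripts <- check_count(min_transcripts, "min_transcripts")
  max_transcripts <- check_count(max_transcripts, "max_transcripts")
  if (min_transcripts >= max_transcripts)
    stop_input("'min_transcripts' must be below 'max_transcripts'")
  max_mito_fraction <- check_fraction(max_mito_fraction, "max_mito_fraction")
  structure(list(min_transcripts = min_transcripts,
                 max_transcripts = max_transcripts,
                 max_mito_fraction = max_mito_fraction),
            class = "rna_qc_thresholds")
}

#' ATAC cell-quality thresholds
#'
#' Cells with TSS enrichment below 4 or fewer than 1,000 unique nuclear
#' fragments are low quality; cells with more than 1 million reads are
#' putative multiplets.
#'
#' @param min_tss_enrichment Kept if TSS enrichment >= this.
#' @param min_fragments Kept if unique fragments >= this.
#' @param max_reads Kept if total reads <= this.
#' @export
atac_qc_thresholds <- function(min_tss_enrichment = 4,
                               min_fragments = 1000L,
                               max_reads = 1000000L) {
  min_tss_enrichment <- check_positive(min_tss_enrichment, "min_tss_enrichment")
  min_fragments <- check_count(min_fragments, "min_fragments")
  max_reads <- check_count(max_reads, "max_reads")
  structure(list(min_tss_enrichment = min_tss_enrichment,
                 min_fragments = min_fragments, max_reads = max_reads),
            class = "atac_qc_thresholds")
}

#' Filter RNA cells on transcript totals and mitochondrial fraction
#'
#' A cell is kept iff its total transcript count is within
#' \code{[min_transcripts, max_transcripts]} and its mitochondrial fraction
#' (mitochondrial transcripts over total) is strictly below
#' \code{max_mito_fraction}. Cells with zero transcripts have their fraction
#' treated as 1 and are removed with a message rather than an error.
#'
#' @param counts Genes x cells count matrix (sparse or dense) with column
#'   names.
#' @param mito_mask Logical vector, one entry per gene, TRUE for
#'   mitochondrial genes.
#' @param thresholds An [rna_qc_thresholds()].
#' @return Character vector of kept cell identifiers, in input order.
#' @export
filter_rna_cells <- function(counts, mito_mask,
                             thresholds = rna_qc_thresholds()) {
  stopifnot(inherits(thresholds, "rna_qc_thresholds"))
  if (length(mito_mask) != nrow(counts))
    stop_input("'mito_mask' length must equal the number of genes")
  if (is.null(colnames(counts)))
    stop_input("'counts' must have cell identifiers as column names")
  totals <- col_sums(counts)
  mito <- col_sums(counts[mito_mask, , drop = FALSE])
  zero <- totals == 0
  if (any(zero))
    message(sum(zero), " cell(s) with zero transcripts removed ",
            "(mitochondrial fraction treated as 1)")
  frac <- ifelse(zero, 1, mito / pmax(totals, 1))
  keep <- totals >= thresholds$min_transcripts &
    totals <= thresholds$max_transcripts &
    frac < thresholds$max_mito_fraction
  message("RNA QC removed ", sum(!keep), " of ", length(keep), " cells")
  colnames(counts)[keep]
}

#' Filter ATAC cells on TSS enrichment, fragment count and read count
#'
#' A cell is kept iff TSS enrichment >= \code{min_tss_enrichment}, unique
#' fragments >= \code{min_fragments} and reads <= \code{max_reads}.
#'
#' @param fragments,reads,tss_enrichment Equal-length per-cell vectors; all
#'   values must be nonnegative.
#' @param thresholds An [atac_qc_thresholds()].
#' @param cell_ids Optional identifiers; defaults to the names of
#'   \code{fragments} or the cell index.
#' @return Kept cell identifiers, in input order.
#' @export
filter_atac_cells <- function(fragments, reads, tss_enrichment,
                              thresholds = atac_qc_thresholds(),
                              cell_ids = NULL) {
  stopifnot(inherits(thresholds, "atac_qc_thresholds"))
  n <- length(fragments)
  if (length(reads) != n || length(tss_enrichment) != n)
    stop_input("per-cell QC vectors must have equal length")
  if (any(fragments < 0) || any(reads < 0) || any(tss_enrichment < 0))
    stop_input("QC metrics must be nonnegative")
  cell_ids <- cell_ids %||% names(fragments) %||% as.character(seq_len(n))
  keep <- tss_enrichment >= thresholds$min_tss_enrichment &
    fragments >= thresholds$min_fragments &
    reads <= thresholds$max_reads
  message("ATAC QC removed ", sum(!keep), " of ", n, " cells")
  cell_ids[keep]
}
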