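#' Write a sparse count matrix as Matrix Market plus feature/barcode TSVs
#'
#' Writes \code{matrix.mtx} (1-based coordinates per the Matrix Market
#' standard), \code{features.tsv} and \code{barcodes.tsv} into \code{dir}.
#'
#' @param X Features x cells matrix with dimnames.
#' @param dir Output directory (created if needed).
#' @export
write_sparse_matrix <- function(X, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(rownames(X)) || is.null(colnames(X)))
    stop_input("matrix must have feature and cell identifiers as dimnames")
  Matrix::writeMM(as(as(X, "CsparseMatrix"), "generalMatrix"),
                  file.path(dir, "matrix.mtx"))
  writeLines(rownames(X), file.path(dir, "features.tsv"))
  writeLines(colnames(X), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Read a sparse count matrix written by [write_sparse_matrix()]
#'
#' Validates that the MTX header dimensions match the feature and barcode
#' files before assigning identifiers.
#'
#' @param dir Directory holding matrix.mtx, features.tsv, barcodes.tsv.
#' @return Sparse features x cells matrix (dgCMatrix) with dimnames.
#' @export
read_sparse_matrix <- function(dir) {
  paths <- file.path(dir, c("matrix.mtx", "features.tsv", "barcodes.tsv"))
  for (p in paths) if (!file.exists(p)) stop_input("missing file: ", p)
  X <- tryCatch(Matrix::readMM(paths[1]),
                error = function(e) stop_input("malformed MTX '", paths[1],
                                               "': ", conditionMessage(e)))
  features <- readLines(paths[2])
  barcodes <- readLines(paths[3])
  if (nrow(X) != length(features))
    stop_input("MTX declares ", nrow(X), " features but features.tsv has ",
               length(features), " lines")
  if (ncol(X) != length(barcodes))
    stop_input("MTX declares ", ncol(X), " cells but barcodes.tsv has ",
               length(barcodes), " lines")
  X <- as(X, "CsparseMatrix")
  dimnames(X) <- list(features, barcodes)
  X
}

#' Write peaks as BED (0-based half-open) plus an annotation TSV
#'
#' @param peaks Peak table (chrom, start, end, peak_id, gc_fraction,
#'   mean_accessibility).
#' @param bed,annot Output paths.
#' @export
write_peaks <- function(peaks, bed, annot) {
  write.table(peaks[, c("chrom", "start", "end", "peak_id")], bed,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  write.table(peaks[, c("peak_id", "gc_fraction", "mean_accessibility")],
              annot, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(bed)
}

#' Read peaks from BED plus annotation TSV
#'
#' Intervals are 0-based half-open; identifiers are \code{chrom:start-end}.
#' Start must be below end, GC fractions must lie in \code{[0, 1]} and
#' identifiers must be unique.
#'
#' @param bed BED path (chrom, start, end, optional name).
#' @param annot Annotation TSV with header (peak_id, gc_fraction,
#'   mean_accessibility).
#' @return Peak table in file order with a \code{width} column.
#' @export
read_peaks <- function(bed, annot) {
  b <- read.delim(bed, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(b) < 3L) stop_input("BED needs at least 3 columns")
  names(b)[1:3] <- c("chrom", "start", "end")
  bad <- which(b$start >= b$end)
  if (length(bad))
    stop_input("start >= end at BED line ", bad[1])
  peak_id <- sprintf("%s:%d-%d", b$chrom, b$start, b$end)
  if (anyDuplicated(peak_id))
    stop_input("duplicate peak identifier: ", peak_id[duplicated(peak_id)][1])
  a <- read.delim(annot, stringsAsFactors = FALSE)
  if (!all(c("peak_id", "gc_fraction") %in% names(a)))
    stop_input("annotation TSV needs peak_id and gc_fraction columns")
  if (any(a$gc_fraction < 0 | a$gc_fraction > 1))
    stop_input("gc_fraction outside [0, 1]")
  m <- match(peak_id, a$peak_id)
  if (anyNA(m)) stop_input("peak(s) missing from the annotation TSV")
  data.frame(chrom = b$chrom, start = b$start, end = b$end,
             peak_id = peak_id, width = b$end - b$start,
             gc_fraction = a$gc_fraction[m],
             mean_accessibility = if ("mean_accessibility" %in% names(a))
               a$mean_accessibility[m] else NA_real_,
             stringsAsFactors = FALSE)
}

#' Write / read binary motif membership as TSV
#'
#' One row per peak (\code{peak_id} column) and one 0/1 column per motif.
#'
#' @param M Binary peaks x motifs matrix with dimnames.
#' @param path TSV path.
#' @export
write_motif_membership <- function(M, path) {
  d <- data.frame(peak_id = rownames(M), as.data.frame(as.matrix(M)),
                  check.names = FALSE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_motif_membership
#' @return \code{read_motif_membership}: integer matrix, peaks x motifs.
#' @export
read_motif_membership <- function(path) {
  d <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  M <- as.matrix(d[, -1, drop = FALSE])
  if (!all(M %in% c(0L, 1L))) stop_input("membership values must be 0/1")
  storage.mode(M) <- "integer"
  rownames(M) <- d$peak_id
  M
}

#' Write / read gene signatures as two-column TSV (set name, gene)
#'
#' @param signatures A [signature_set()] or list of them.
#' @param path TSV path.
#' @export
write_signatures <- function(signatures, path) {
  if (inherits(signatures, "signature_set")) signatures <- list(signatures)
  d <- do.call(rbind, lapply(signatures, function(s)
    if (length(s$genes) == 0L)
      data.frame(set = character(0), gene = character(0))
    else data.frame(set = s$name, gene = s$genes, stringsAsFactors = FALSE)))
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_signatures
#' @return \code{read_signatures}: named list of [signature_set()] objects.
#' @export
read_signatures <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("set", "gene") %in% names(d)))
    stop_input("signature TSV needs 'set' and 'gene' columns")
  by_set <- split(d$gene, d$set)
  setNames(lapply(names(by_set), function(n) signature_set(n, by_set[[n]])),
           names(by_set))
}

#' Write / read a bulk cohort table as CSV
#'
#' Columns: sample_id, score, time, event, erg_status.
#'
#' @param cohort Cohort data frame.
#' @param path CSV path.
#' @export
write_cohort <- function(cohort, path) {
  write.csv(cohort, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "score", "time", "event", "erg_status")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop_input("cohort CSV missing column(s): ",
                               paste(miss, collapse = ", "))
  if (any(d$time <= 0)) stop_input("survival times must be positive")
  if (!all(d$event %in% c(0, 1))) stop_input("events must be 0/1")
  d
}
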