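#' Partition peaks by candidate/ETS motif co-occurrence
#'
#' Splits the peaks carrying the candidate motif or the ETS family column
#' into three disjoint sets: \code{both} (candidate and ETS), \code{cand_only}
#' (candidate without ETS) and \code{ets_only} (ETS without the candidate).
#' An empty \code{both} set leaves the co-occurrence test undefined and is an
#' error.
#'
#' @param M Binary peaks x motifs membership matrix.
#' @param candidate Candidate motif column name.
#' @param family Family column name (default "ETS"; see
#'   [reduce_motif_family()]).
#' @return Object of class \code{"peak_partition"}: list with integer peak
#'   index vectors \code{both}, \code{cand_only}, \code{ets_only} plus the
#'   candidate name.
#' @export
partition_peaks <- function(M, candidate, family = "ETS") {
  for (col in c(candidate, family))
    if (!col %in% colnames(M)) stop_input("motif column '", col, "' not found")
  cand <- M[, candidate] != 0
  fam <- M[, family] != 0
  both <- unname(which(cand & fam))
  if (length(both) == 0L)
    stop_input("no co-occurring peaks for '", candidate,
               "': co-occurrence test undefined")
  structure(list(candidate = candidate, family = family,
                 both = both, cand_only = unname(which(cand & !fam)),
                 ets_only = unname(which(fam & !cand))),
            class = "peak_partition")
}

#' One-sided Wilcoxon rank-sum test
#'
#' Exact p by enumeration of rank assignments when the combined sample size
#' is at most 20 and there are no ties; otherwise the normal approximation
#' with tie correction and (optionally) continuity correction.
#'
#' @param x,y Non-empty numeric samples.
#' @param alternative Test direction (default \code{"greater"}: x tends to
#'   exceed y).
#' @param continuity Apply the continuity correction in the normal
#'   approximation.
#' @param exact_max Combined sample size at or below which the exact null
#'   distribution is used (ties force the approximation).
#' @return List: \code{U} (Mann-Whitney statistic), \code{p}, \code{exact}.
#' @export
wilcoxon_rank_sum <- function(x, y, alternative = "greater",
                              continuity = TRUE, exact_max = 20L) {
  if (length(x) == 0L || length(y) == 0L)
    stop_input("both samples must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- (length(x) + length(y)) <= exact_max && !ties
  wt <- suppressWarnings(wilcox.test(x, y, alternative = alternative,
                                     exact = exact, correct = continuity))
  list(U = unname(wt$statistic), p = wt$p.value, exact = exact)
}

#' Motif co-occurrence co-accessibility test
#'
#' For each candidate motif, treats the \code{both}, \code{ets_only} and
#' \code{cand_only} peak sets of its [partition_peaks()] partition as peak
#' sets, computes each set's per-cell deviation Z score (see
#' [deviation_z()]), restricts to the named cell subset, and asks whether the
#' co-occurring peaks are more accessible than peaks carrying exclusively one
#' motif: one-sided ("greater") rank-sum tests of \code{z_both} versus
#' \code{z_ets_only} and \code{z_both} versus \code{z_cand_only}. P values
#' are Benjamini-Hochberg adjusted across candidates within each comparison
#' direction. Cells with undefined Z are dropped per set; a set with zero
#' expected mass (or no defined Z) skips its comparison and is reported as
#' such.
#'
#' @param X Peaks x cells count matrix.
#' @param partitions A single [partition_peaks()] result or a list of them
#'   (one per candidate).
#' @param backgrounds A [sample_background_peaks()] result on the same peaks.
#' @param cells Cell identifiers (or indices) of the subset to test, e.g. the
#'   IM cells of one genotype; at least 2 cells. Deviations are computed on
#'   all cells by default so background correction sees the full
#'   accessibility profile, then restricted to the subset.
#' @param mode \code{"all"} (compute deviations on all cells, then subset) or
#'   \code{"subset"} (compute deviations on the subset only).
#' @return Data frame, two rows per candidate (one per comparison):
#'   candidate, comparison, n_both, n_other, U, p, fdr, skipped.
#' @export
coaccessibility_test <- function(X, partitions, backgrounds, cells,
                                 mode = c("all", "subset")) {
  mode <- match.arg(mode)
  if (inherits(partitions, "peak_partition")) partitions <- list(partitions)
  if (is.character(cells)) {
    idx <- match(cells, colnames(X))
    if (anyNA(idx)) stop_input("unknown cell(s) in 'cells'")
    cells <- idx
  }
  if (length(cells) < 2L)
    stop_input("cell subset must contain at least 2 cells (rank test ",
               "undefined otherwise)")
  Xd <- if (mode == "subset") X[, cells, drop = FALSE] else X
  sub <- if (mode == "subset") seq_along(cells) else cells

  zset <- function(members) {
    if (length(members) == 0L) return(NULL)
    dv <- tryCatch(suppressMessages(deviation_z(Xd, members, backgrounds)),
                   error = function(e) NULL)
    if (is.null(dv)) return(NULL)
    z <- dv$z[sub]
    z <- z[!is.na(z)]
    if (length(z) == 0L) NULL else z
  }

  rows <- list()
  for (pp in partitions) {
    stopifnot(inherits(pp, "peak_partition"))
    z_both <- zset(pp$both)
    for (cmp in c("both_vs_ets_only", "both_vs_cand_only")) {
      other <- if (cmp == "both_vs_ets_only") pp$ets_only else pp$cand_only
      z_other <- zset(other)
      skipped <- is.null(z_both) || is.null(z_other)
      if (skipped) {
        rows[[length(rows) + 1L]] <- data.frame(
          candidate = pp$candidate, comparison = cmp,
          n_both = length(pp$both), n_other = length(other),
          U = NA_real_, p = NA_real_, skipped = TRUE,
          stringsAsFactors = FALSE)
      } else {
        wt <- wilcoxon_rank_sum(z_both, z_other, alternative = "greater")
        rows[[length(rows) + 1L]] <- data.frame(
          candidate = pp$candidate, comparison = cmp,
          n_both = length(pp$both), n_other = length(other),
          U = wt$U, p = wt$p, skipped = FALSE, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  out$fdr <- NA_real_
  for (cmp in unique(out$comparison)) {
    sel <- out$comparison == cmp & !out$skipped
    out$fdr[sel] <- p.adjust(out$p[sel], method = "BH")
  }
  rownames(out) <- NULL
  out
}
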