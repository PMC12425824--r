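#' Expected counts under uniform accessibility
#'
#' The expectation used by accessibility deviations: cell depth spread over
#' peaks proportionally to each peak's total accessibility,
#' \eqn{E_{ij} = r_i c_j / T} with \eqn{r} the peak totals, \eqn{c} the cell
#' totals and \eqn{T} the grand total. Both margins of \eqn{E} match those of
#' \eqn{X} exactly.
#'
#' @param X Peaks x cells count matrix.
#' @return Dense matrix of expected counts, same dimnames as \code{X}.
#' @export
expected_counts <- function(X) {
  r <- row_sums(X)
  c_ <- col_sums(X)
  tot <- sum(c_)
  if (tot == 0) stop_input("all-zero matrix: expected counts undefined")
  E <- outer(r, c_) / tot
  dimnames(E) <- dimnames(X)
  E
}

#' Raw accessibility deviation of a peak set
#'
#' Per cell \eqn{j}: \eqn{y_j = (\sum_{i \in S} X_{ij} - \sum_{i \in S}
#' E_{ij}) / \sum_{i \in S} E_{ij}}. Cells with zero expected mass in the set
#' get \code{NA}.
#'
#' @param X Peaks x cells count matrix.
#' @param E Expected matrix from [expected_counts()].
#' @param members Peak indices, logical mask, or peak identifiers (matched
#'   against row names); must be non-empty.
#' @return Numeric deviation per cell (named when \code{X} has column names).
#' @export
raw_deviation <- function(X, E, members) {
  idx <- resolve_peaks(members, X)
  obs <- col_sums(X[idx, , drop = FALSE])
  exp_ <- col_sums(E[idx, , drop = FALSE])
  y <- ifelse(exp_ > 0, (obs - exp_) / exp_, NA_real_)
  setNames(as.numeric(y), colnames(X))
}

resolve_peaks <- function(members, X) {
  if (is.logical(members)) {
    if (length(members) != nrow(X))
      stop_input("logical 'members' must have one entry per peak")
    members <- which(members)
  } else if (is.character(members)) {
    idx <- match(members, rownames(X))
    if (anyNA(idx)) stop_input("unknown peak identifier(s) in 'members'")
    members <- idx
  }
  if (length(members) == 0L) stop_input("'members' must be non-empty")
  if (any(members < 1L | members > nrow(X)))
    stop_input("'members' out of range")
  as.integer(members)
}

#' Sample GC- and accessibility-matched background peaks
#'
#' For each peak, \code{B} background peaks are drawn uniformly with
#' replacement from its \code{k} nearest neighbours in the standardized
#' (GC fraction, log1p mean accessibility) plane. Ties at the \code{k}-th
#' distance are resolved by sampling uniformly over the whole tied set, so
#' that when many peaks are equidistant (e.g. identical covariates) the
#' draws are uniform over all of them. The sampling is deterministic under
#' \code{seed}.
#'
#' @param peaks Peak table with columns \code{gc_fraction} and
#'   \code{mean_accessibility} (see [generate_atac()] / [read_peaks()]).
#' @param k Neighbour count; reduced with a warning when fewer than
#'   \code{k + 1} peaks exist. A peak is its own nearest neighbour.
#' @param B Background iterations.
#' @param seed RNG seed for tie-breaking and sampling.
#' @return Object of class \code{"background_sets"}: list with \code{map}
#'   (peaks x B matrix of background peak indices), \code{neighbors} (per
#'   peak, the tie-closed nearest-neighbour candidate set), \code{k},
#'   \code{B}, \code{seed}.
#' @export
sample_background_peaks <- function(peaks, k = 50L, B = 50L, seed = 1L) {
  stopifnot(all(c("gc_fraction", "mean_accessibility") %in% names(peaks)))
  n <- nrow(peaks)
  k <- check_count(k, "k"); B <- check_count(B, "B")
  seed <- check_count(seed, "seed")
  if (n < k + 1L) {
    k <- n - 1L
    warning("fewer peaks than k + 1; k reduced to ", k)
  }
  if (k < 1L) stop_input("need at least 2 peaks for background matching")

  feat <- cbind(peaks$gc_fraction, log1p(peaks$mean_accessibility))
  if (anyNA(feat)) stop_input("peaks have undefined matching covariates")
  for (j in 1:2) {
    s <- sd(feat[, j])
    feat[, j] <- if (s > 0) (feat[, j] - mean(feat[, j])) / s else 0
  }
  D <- as.matrix(dist(feat))

  set.seed(seed)
  neighbors <- vector("list", n)
  map <- matrix(0L, n, B)
  for (i in seq_len(n)) {
    d <- D[i, ]
    dk <- sort.int(d, partial = k)[k]  # k-th smallest distance (self included)
    cand <- which(d <= dk)  # tie closure: all peaks within the k-th distance
    neighbors[[i]] <- cand
    map[i, ] <- cand[sample.int(length(cand), B, replace = TRUE)]
  }
  structure(list(map = map, neighbors = neighbors, k = k, B = B, seed = seed),
            class = "background_sets")
}

# set deviation sums computed from margins, never materializing E
set_deviation <- function(obs_fun, r, c_, tot, idx) {
  exp_mass <- sum(r[idx]) * c_ / tot
  obs <- obs_fun(idx)
  ifelse(exp_mass > 0, (obs - exp_mass) / exp_mass, NA_real_)
}

#' Bias-corrected deviation and Z score for one peak set
#'
#' Computes the raw deviation \eqn{y} of the member set, then, for each
#' background iteration \eqn{b}, the deviation \eqn{\tilde y^{(b)}} of the
#' member set mapped through background \eqn{b} (duplicate mapped peaks count
#' with multiplicity). The bias-corrected deviation is
#' \eqn{d_j = y_j - \mathrm{mean}_b \tilde y_j^{(b)}} and the Z score
#' \eqn{z_j = d_j / \mathrm{sd}_b(\tilde y_j^{(b)})} with the sample (n-1)
#' standard deviation. Cells whose background standard deviation is zero get
#' \code{NA} Z and are counted in the \code{n_undefined} field.
#'
#' @param X Peaks x cells count matrix.
#' @param members Peak set (indices, mask or identifiers).
#' @param backgrounds A [sample_background_peaks()] result on the same peaks.
#' @return List: \code{y}, \code{d}, \code{z} per cell, \code{n_undefined}.
#' @export
deviation_z <- function(X, members, backgrounds) {
  stopifnot(inherits(backgrounds, "background_sets"))
  if (nrow(backgrounds$map) != nrow(X))
    stop_input("'backgrounds' was computed on a different peak set")
  idx <- resolve_peaks(members, X)
  r <- row_sums(X); c_ <- col_sums(X); tot <- sum(c_)
  if (tot == 0) stop_input("all-zero matrix")
  obs_fun <- function(ii) col_sums(X[ii, , drop = FALSE])

  y <- set_deviation(obs_fun, r, c_, tot, idx)
  B <- backgrounds$B
  bg <- matrix(NA_real_, B, ncol(X))
  for (b in seq_len(B)) {
    bg[b, ] <- set_deviation(obs_fun, r, c_, tot, backgrounds$map[idx, b])
  }
  mu <- colMeans(bg)
  s <- apply(bg, 2L, sd)
  d <- y - mu
  z <- ifelse(!is.na(s) & s > 0, d / s, NA_real_)
  n_undef <- sum(is.na(z))
  if (n_undef > 0)
    message(n_undef, " cell(s) with undefined Z (zero background sd or ",
            "zero expected mass)")
  list(y = setNames(as.numeric(y), colnames(X)),
       d = setNames(as.numeric(d), colnames(X)),
       z = setNames(as.numeric(z), colnames(X)),
       n_undefined = n_undef)
}

#' Deviations and Z scores for every motif of a membership matrix
#'
#' Applies [deviation_z()] to each motif column's peak set.
#'
#' @param X Peaks x cells count matrix.
#' @param M Binary peaks x motifs membership matrix.
#' @param backgrounds A [sample_background_peaks()] result.
#' @return Object of class \code{"deviation_set"}: list with motif x cell
#'   matrices \code{y}, \code{d}, \code{z}, plus \code{B} and \code{seed}.
#' @export
compute_deviations <- function(X, M, backgrounds) {
  if (nrow(M) != nrow(X)) stop_input("'M' must have one row per peak")
  motifs <- colnames(M) %||% as.character(seq_len(ncol(M)))
  out <- lapply(seq_len(ncol(M)), function(j) {
    mem <- which(M[, j] != 0)
    if (length(mem) == 0L)
      return(list(y = rep(NA_real_, ncol(X)), d = rep(NA_real_, ncol(X)),
                  z = rep(NA_real_, ncol(X))))
    suppressMessages(deviation_z(X, mem, backgrounds))
  })
  mk <- function(f) {
    m <- do.call(rbind, lapply(out, `[[`, f))
    dimnames(m) <- list(motifs, colnames(X))
    m
  }
  structure(list(y = mk("y"), d = mk("d"), z = mk("z"),
                 B = backgrounds$B, seed = backgrounds$seed),
            class = "deviation_set")
}
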