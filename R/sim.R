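#' Default motif specification table
#'
#' Three motifs: an ETS family column, a candidate ("STAT3") whose
#' co-occurrence with ETS is amplified in IM-type cells, and a second
#' candidate ("NFATC1") that co-occurs with ETS but carries no amplification.
#'
#' @return A data frame with columns \code{motif}, \code{prob} (per-peak
#'   Bernoulli membership probability), \code{partner} (forced co-occurrence
#'   partner, or \code{NA}), \code{amplification} (accessibility rate
#'   multiplier, applied only in peaks where the motif and its partner both
#'   match and only in \code{target_type} cells) and \code{target_type}.
#' @export
default_motif_specs <- function() {
  data.frame(
    motif         = c("ETS", "STAT3", "NFATC1"),
    prob          = c(0.15, 0.10, 0.10),
    partner       = c(NA, "ETS", "ETS"),
    amplification = c(1, 2, 1),
    target_type   = c(NA, "IM", NA),
    stringsAsFactors = FALSE
  )
}

#' Configuration for the synthetic multiome generator
#'
#' Bundles and validates every knob of the seeded generator. The defaults
#' describe the study conditions the pipeline is exercised under: four
#' epithelial cell types of 50 cells each (basal, two luminal states and the
#' proliferative IM intermediate), 2,000 GC-heterogeneous peaks, disjoint
#' per-type peak programs at a 4x accessibility multiplier, and one candidate
#' motif whose co-occurrence with the ETS family is amplified 2-fold in IM
#' cells only.
#'
#' @param seed Integer seed; identical configurations give bit-identical
#'   output.
#' @param n_cells_per_type Named integer vector, cells per cell type. For RNA
#'   the same labels double as cluster labels.
#' @param n_peaks,n_genes Feature counts for the ATAC and RNA matrices.
#' @param gc_range Interval in \code{[0, 1]}; peak GC fractions are drawn
#'   uniformly from it.
#' @param motif_specs Data frame as returned by [default_motif_specs()]. A
#'   motif with \code{amplification > 1} must name both a \code{partner} and a
#'   \code{target_type}.
#' @param base_rate Expected fragments per peak per cell before multipliers.
#' @param program_peaks_per_type Peaks in each type's private accessibility
#'   program (disjoint across types); default 5\% of \code{n_peaks}.
#' @param program_multiplier Accessibility multiplier on a type's program
#'   peaks in cells of that type.
#' @param co_occur_fraction For a motif with a partner, the fraction of its
#'   member peaks whose partner membership is forced to 1.
#' @param markers_per_type,marker_multiplier,base_gene_rate RNA marker-gene
#'   structure: each type gets \code{markers_per_type} private marker genes
#'   whose Poisson rate is \code{marker_multiplier} times the
#'   \code{base_gene_rate} shared by all genes.
#' @param n_mito_genes Number of mitochondrial ("mt-") genes.
#' @param epcam_fraction Named vector (or single value recycled across types):
#'   fraction of each cluster's cells forced Epcam-positive (raw count >= 1).
#' @param mito_fraction_dist List \code{(shape1, shape2)} of the Beta
#'   distribution per-cell mitochondrial fractions are drawn from.
#' @param n_low_count_cells,n_high_count_cells,n_high_mito_cells Cells planted
#'   to fail the RNA QC rules (total < 500, total > 100,000, mitochondrial
#'   fraction >= 0.40). Planted cells occupy the first positions of the cell
#'   ordering, in that order, and are marked in the cell metadata.
#' @param cohort_n Bulk cohort size (>= 8).
#' @param cohort_log_hazard_per_sd Log hazard ratio per standard deviation of
#'   the signature score in the survival simulation.
#' @param censor_rate Probability that a sample is censored (uniformly before
#'   its event time).
#' @param erg_positive_fraction Probability a cohort sample is ERG-positive.
#' @return A validated list of class \code{"sim_config"}.
#' @export
sim_config <- function(seed = 1L,
                       n_cells_per_type = c(basal = 50L, L1 = 50L, L2 = 50L, IM = 50L),
                       n_peaks = 2000L,
                       n_genes = 200L,
                       gc_range = c(0.3, 0.7),
                       motif_specs = default_motif_specs(),
                       base_rate = 0.5,
                       program_peaks_per_type = NULL,
                       program_multiplier = 4,
                       co_occur_fraction = 0.5,
                       markers_per_type = 10L,
                       marker_multiplier = 6,
                       base_gene_rate = 10,
                       n_mito_genes = 10L,
                       epcam_fraction = 0.9,
                       mito_fraction_dist = list(shape1 = 2, shape2 = 18),
                       n_low_count_cells = 0L,
                       n_high_count_cells = 0L,
                       n_high_mito_cells = 0L,
                       cohort_n = 200L,
                       cohort_log_hazard_per_sd = log(2.5),
                       censor_rate = 0.2,
                       erg_positive_fraction = 0.5) {
  seed <- check_count(seed, "seed")
  if (is.null(names(n_cells_per_type)) || any(names(n_cells_per_type) == ""))
    stop_input("'n_cells_per_type' must be a named vector")
  n_cells_per_type <- vapply(seq_along(n_cells_per_type), function(i)
    check_count(n_cells_per_type[[i]], "n_cells_per_type"), integer(1)) |>
    setNames(names(n_cells_per_type))
  n_peaks <- check_count(n_peaks, "n_peaks")
  n_genes <- check_count(n_genes, "n_genes")
  if (length(gc_range) != 2L || any(gc_range < 0) || any(gc_range > 1) ||
      gc_range[1] > gc_range[2])
    stop_input("'gc_range' must be an ordered interval within [0, 1]")

  req <- c("motif", "prob", "partner", "amplification", "target_type")
  if (!is.data.frame(motif_specs) || !all(req %in% names(motif_specs)))
    stop_input("'motif_specs' must have columns ", paste(req, collapse = ", "))
  if (anyDuplicated(motif_specs$motif))
    stop_input("duplicate motif names in 'motif_specs'")
  for (i in seq_len(nrow(motif_specs))) {
    check_fraction(motif_specs$prob[i], "motif_specs$prob")
    if (motif_specs$amplification[i] < 1)
      stop_input("'amplification' must be >= 1")
    p <- motif_specs$partner[i]
    if (!is.na(p) && !p %in% motif_specs$motif)
      stop_input("co-occurrence partner '", p, "' is not a listed motif")
    if (motif_specs$amplification[i] > 1) {
      if (is.na(p))
        stop_input("motif '", motif_specs$motif[i],
                   "' has amplification > 1 but no co_occurrence partner")
      if (is.na(motif_specs$target_type[i]) ||
          !motif_specs$target_type[i] %in% names(n_cells_per_type))
        stop_input("motif '", motif_specs$motif[i],
                   "' has amplification > 1 but no valid target cell type")
    }
  }

  base_rate <- check_positive(base_rate, "base_rate")
  program_peaks_per_type <- check_count(
    program_peaks_per_type %||% max(1L, floor(0.05 * n_peaks)),
    "program_peaks_per_type")
  if (program_peaks_per_type * length(n_cells_per_type) > n_peaks)
    stop_input("per-type peak programs do not fit in 'n_peaks'")
  program_multiplier <- check_positive(program_multiplier, "program_multiplier")
  co_occur_fraction <- check_fraction(co_occur_fraction, "co_occur_fraction")

  markers_per_type <- check_count(markers_per_type, "markers_per_type")
  marker_multiplier <- check_positive(marker_multiplier, "marker_multiplier")
  base_gene_rate <- check_positive(base_gene_rate, "base_gene_rate")
  n_mito_genes <- check_count(n_mito_genes, "n_mito_genes")

  if (length(epcam_fraction) == 1L && is.null(names(epcam_fraction)))
    epcam_fraction <- setNames(rep(epcam_fraction, length(n_cells_per_type)),
                               names(n_cells_per_type))
  if (!all(names(n_cells_per_type) %in% names(epcam_fraction)))
    stop_input("'epcam_fraction' must cover every cell type")
  for (f in epcam_fraction) check_fraction(f, "epcam_fraction")

  if (!is.list(mito_fraction_dist) ||
      !all(c("shape1", "shape2") %in% names(mito_fraction_dist)))
    stop_input("'mito_fraction_dist' must be list(shape1 = , shape2 = )")
  check_positive(mito_fraction_dist$shape1, "mito_fraction_dist$shape1")
  check_positive(mito_fraction_dist$shape2, "mito_fraction_dist$shape2")

  plant <- function(x, name) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x != round(x))
      stop_input(sprintf("'%s' must be a nonnegative integer", name))
    as.integer(x)
  }
  n_low_count_cells <- plant(n_low_count_cells, "n_low_count_cells")
  n_high_count_cells <- plant(n_high_count_cells, "n_high_count_cells")
  n_high_mito_cells <- plant(n_high_mito_cells, "n_high_mito_cells")
  if (n_low_count_cells + n_high_count_cells + n_high_mito_cells >
      sum(n_cells_per_type))
    stop_input("more planted QC failures than cells")

  cohort_n <- check_count(cohort_n, "cohort_n")
  if (!is.numeric(cohort_log_hazard_per_sd) || length(cohort_log_hazard_per_sd) != 1L)
    stop_input("'cohort_log_hazard_per_sd' must be a single number")
  censor_rate <- check_fraction(censor_rate, "censor_rate")
  erg_positive_fraction <- check_fraction(erg_positive_fraction,
                                          "erg_positive_fraction")

  structure(list(
    seed = seed, n_cells_per_type = n_cells_per_type,
    n_peaks = n_peaks, n_genes = n_genes, gc_range = as.numeric(gc_range),
    motif_specs = motif_specs, base_rate = base_rate,
    program_peaks_per_type = program_peaks_per_type,
    program_multiplier = program_multiplier,
    co_occur_fraction = co_occur_fraction,
    markers_per_type = markers_per_type,
    marker_multiplier = marker_multiplier,
    base_gene_rate = base_gene_rate, n_mito_genes = n_mito_genes,
    epcam_fraction = epcam_fraction,
    mito_fraction_dist = mito_fraction_dist,
    n_low_count_cells = n_low_count_cells,
    n_high_count_cells = n_high_count_cells,
    n_high_mito_cells = n_high_mito_cells,
    cohort_n = cohort_n,
    cohort_log_hazard_per_sd = as.numeric(cohort_log_hazard_per_sd),
    censor_rate = censor_rate,
    erg_positive_fraction = erg_positive_fraction
  ), class = "sim_config")
}

sim_cell_ids <- function(n) sprintf("cell%05d", seq_len(n))

sim_cell_types <- function(config) {
  rep(names(config$n_cells_per_type), config$n_cells_per_type)
}

#' Generate a synthetic scATAC count matrix with planted motif structure
#'
#' Fragment counts are Poisson with rate \code{base_rate}, multiplied by
#' \code{program_multiplier} on the cell type's private program peaks and by a
#' motif's \code{amplification} factor in peaks where the motif and its
#' co-occurrence partner both match -- the latter only in cells of the motif's
#' target type. Peak GC fractions are uniform on \code{gc_range}; motif
#' membership is Bernoulli per (peak, motif) followed by forced co-occurrence
#' for motifs with a declared partner. All draws come from one RNG seeded with
#' \code{config$seed} in a fixed order (GC, membership, co-occurrence forcing,
#' program assignment, counts by type, per-cell QC metrics), so the output is
#' reproducible bit for bit.
#'
#' @param config A [sim_config()].
#' @return List with \code{counts} (sparse peaks x cells integer matrix),
#'   \code{peaks} (data frame: chrom, start, end, peak_id, gc_fraction,
#'   mean_accessibility), \code{motifs} (binary peaks x motifs matrix),
#'   \code{cells} (cell_id, cell_type, fragments, reads, tss_enrichment) and
#'   \code{programs} (ground-truth program peak indices per cell type).
#' @export
generate_atac <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)

  n_peaks <- config$n_peaks
  types <- sim_cell_types(config)
  n_cells <- length(types)
  specs <- config$motif_specs

  gc <- runif(n_peaks, config$gc_range[1], config$gc_range[2])

  start <- (seq_len(n_peaks) - 1L) * 1000L
  end <- start + 500L
  peak_id <- sprintf("chr1:%d-%d", start, end)

  M <- matrix(0L, n_peaks, nrow(specs),
              dimnames = list(peak_id, specs$motif))
  for (j in seq_len(nrow(specs)))
    M[, j] <- rbinom(n_peaks, 1L, specs$prob[j])
  for (j in seq_len(nrow(specs))) {
    p <- specs$partner[j]
    if (is.na(p)) next
    mem <- which(M[, j] == 1L)
    forced <- mem[runif(length(mem)) < config$co_occur_fraction]
    M[forced, p] <- 1L
  }

  perm <- sample.int(n_peaks)
  type_names <- names(config$n_cells_per_type)
  program <- setNames(vector("list", length(type_names)), type_names)
  off <- 0L
  for (t in type_names) {
    program[[t]] <- perm[(off + 1L):(off + config$program_peaks_per_type)]
    off <- off + config$program_peaks_per_type
  }

  X <- matrix(0L, n_peaks, n_cells)
  for (t in type_names) {
    lam <- rep(config$base_rate, n_peaks)
    lam[program[[t]]] <- lam[program[[t]]] * config$program_multiplier
    for (j in seq_len(nrow(specs))) {
      if (specs$amplification[j] <= 1 || is.na(specs$target_type[j]) ||
          specs$target_type[j] != t) next
      both <- M[, specs$motif[j]] == 1L & M[, specs$partner[j]] == 1L
      lam[both] <- lam[both] * specs$amplification[j]
    }
    idx <- which(types == t)
    X[, idx] <- rpois(n_peaks * length(idx), lam)
  }
  dimnames(X) <- list(peak_id, sim_cell_ids(n_cells))

  fragments <- colSums(X)
  reads <- round(fragments * runif(n_cells, 2.2, 2.6))
  tss <- pmax(rnorm(n_cells, mean = 8, sd = 1.5), 0.1)

  list(
    counts = as(Matrix::Matrix(X, sparse = TRUE), "CsparseMatrix"),
    peaks = data.frame(
      chrom = "chr1", start = start, end = end, peak_id = peak_id,
      gc_fraction = gc, mean_accessibility = rowMeans(X),
      stringsAsFactors = FALSE),
    motifs = M,
    cells = data.frame(
      cell_id = colnames(X), cell_type = types,
      fragments = fragments, reads = reads, tss_enrichment = tss,
      stringsAsFactors = FALSE),
    programs = program
  )
}

#' Generate a synthetic scRNA count matrix with marker, Epcam and QC structure
#'
#' Every gene has Poisson rate \code{base_gene_rate}; each cluster's private
#' marker genes are elevated \code{marker_multiplier}-fold in that cluster.
#' Epcam positivity (raw count >= 1) is forced in an \code{epcam_fraction} of
#' each cluster's cells and set to zero elsewhere. Per-cell mitochondrial
#' fractions are Beta-distributed and realised by allocating matching "mt-"
#' gene counts. Optionally, cells are planted below/above the transcript-count
#' QC bounds or above the mitochondrial-fraction bound; planted cells sit at
#' the head of the cell ordering and are labelled in the metadata.
#'
#' @param config A [sim_config()]. Errors if \code{n_genes} cannot hold the
#'   marker, Epcam and mitochondrial genes.
#' @return List with \code{counts} (sparse genes x cells), \code{cells}
#'   (cell_id, cell_type, cluster, planted_qc), \code{mito_mask} (logical per
#'   gene) and \code{marker_sets} (named list of each cluster's marker genes,
#'   the ground-truth signatures).
#' @export
generate_rna <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)

  types <- sim_cell_types(config)
  n_cells <- length(types)
  type_names <- names(config$n_cells_per_type)

  marker_genes <- lapply(type_names, function(t)
    sprintf("%s_mk%02d", t, seq_len(config$markers_per_type)))
  names(marker_genes) <- type_names
  mito_genes <- sprintf("mt-%02d", seq_len(config$n_mito_genes))
  special <- c(unlist(marker_genes), "Epcam", mito_genes)
  if (config$n_genes < length(special))
    stop_input("'n_genes' (", config$n_genes, ") is smaller than the ",
               length(special), " marker/Epcam/mitochondrial genes required")
  filler <- sprintf("gene%04d", seq_len(config$n_genes - length(special)))
  genes <- c(special, filler)

  mito_frac <- rbeta(n_cells, config$mito_fraction_dist$shape1,
                     config$mito_fraction_dist$shape2)
  mito_frac <- pmin(mito_frac, 0.95)

  ordinary <- setdiff(genes, c("Epcam", mito_genes))
  X <- matrix(0L, length(genes), n_cells, dimnames = list(genes, sim_cell_ids(n_cells)))
  for (t in type_names) {
    lam <- rep(config$base_gene_rate, length(ordinary))
    names(lam) <- ordinary
    lam[marker_genes[[t]]] <- lam[marker_genes[[t]]] * config$marker_multiplier
    idx <- which(types == t)
    X[ordinary, idx] <- rpois(length(ordinary) * length(idx), lam)
  }

  epcam_pos <- runif(n_cells) < config$epcam_fraction[types]
  X["Epcam", ] <- ifelse(epcam_pos, rpois(n_cells, 2) + 1L, 0L)

  t0 <- colSums(X)
  mito_total <- round(mito_frac / (1 - mito_frac) * t0)
  for (j in seq_len(n_cells)) {
    if (mito_total[j] > 0)
      X[mito_genes, j] <- rmultinom(1L, mito_total[j],
                                    rep(1, length(mito_genes)))[, 1L]
  }

  planted <- rep("none", n_cells)
  i <- 0L
  if (config$n_low_count_cells > 0L) {
    cells <- i + seq_len(config$n_low_count_cells); i <- i + config$n_low_count_cells
    planted[cells] <- "low_count"
    target <- sample(100:499, length(cells), replace = TRUE)
    for (k in seq_along(cells)) {
      j <- cells[k]
      X[, j] <- rmultinom(1L, target[k], pmax(X[, j], 1e-8))[, 1L]
    }
  }
  if (config$n_high_count_cells > 0L) {
    cells <- i + seq_len(config$n_high_count_cells); i <- i + config$n_high_count_cells
    planted[cells] <- "high_count"
    extra <- sample(1:1000, length(cells), replace = TRUE)
    for (k in seq_along(cells)) {
      j <- cells[k]
      g <- if (length(filler)) filler[1L] else ordinary[1L]
      X[g, j] <- X[g, j] + (100000L - sum(X[, j])) + extra[k]
    }
  }
  if (config$n_high_mito_cells > 0L) {
    cells <- i + seq_len(config$n_high_mito_cells); i <- i + config$n_high_mito_cells
    planted[cells] <- "high_mito"
    f <- runif(length(cells), 0.45, 0.60)
    for (k in seq_along(cells)) {
      j <- cells[k]
      nonmito <- sum(X[, j]) - sum(X[mito_genes, j])
      need <- ceiling(f[k] / (1 - f[k]) * nonmito)
      X[mito_genes, j] <- rmultinom(1L, need, rep(1, length(mito_genes)))[, 1L]
    }
  }

  list(
    counts = as(Matrix::Matrix(X, sparse = TRUE), "CsparseMatrix"),
    cells = data.frame(
      cell_id = colnames(X), cell_type = types, cluster = types,
      planted_qc = planted, stringsAsFactors = FALSE),
    mito_mask = genes %in% mito_genes,
    marker_sets = marker_genes
  )
}

#' Generate a synthetic bulk cohort with signature-linked hazards
#'
#' Per-sample signature scores are standard normal; survival times are
#' exponential with log hazard \code{cohort_log_hazard_per_sd} times the
#' score. With probability \code{censor_rate} a sample is censored at a
#' uniform time before its event. ERG status is Bernoulli per sample.
#'
#' @param config A [sim_config()] with \code{cohort_n >= 8}.
#' @return Data frame: sample_id, score, time, event (1 = event, 0 =
#'   censored), erg_status ("positive"/"negative").
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$cohort_n < 8L) stop_input("'cohort_n' must be at least 8")
  set.seed(config$seed + 2L)

  n <- config$cohort_n
  score <- rnorm(n)
  t_event <- rexp(n, rate = exp(config$cohort_log_hazard_per_sd * score))
  censored <- runif(n) < config$censor_rate
  time <- ifelse(censored, runif(n) * t_event, t_event)
  erg <- ifelse(runif(n) < config$erg_positive_fraction, "positive", "negative")

  data.frame(
    sample_id = sprintf("sample%04d", seq_len(n)),
    score = score, time = time, event = as.integer(!censored),
    erg_status = erg, stringsAsFactors = FALSE
  )
}
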