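#' Default pipeline configuration
#'
#' A nested, YAML-serializable list holding every stage's thresholds (at the
#' analysis defaults: RNA kept in [500, 100,000] transcripts with
#' mitochondrial fraction < 0.40; ATAC kept with TSS enrichment >= 4,
#' fragments >= 1,000, reads <= 1,000,000; epithelial flagging at >= 50%
#' Epcam-positive; DAR and signature cutoffs; background matching k = 50,
#' B = 50) plus the simulation settings and the master seed.
#'
#' @param seed Master seed; every stage's randomness derives from it.
#' @return List of class \code{"pipeline_config"}.
#' @export
default_pipeline_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    simulate = list(enabled = TRUE),
    sim = list(
      n_cells_per_type = list(basal = 50L, L1 = 50L, L2 = 50L, IM = 50L),
      n_peaks = 2000L, n_genes = 200L, gc_range = c(0.3, 0.7),
      base_rate = 0.5, program_multiplier = 4, co_occur_fraction = 0.5,
      cohort_n = 200L, cohort_log_hazard_per_sd = log(2.5),
      censor_rate = 0.2),
    inputs = list(),
    qc = list(
      rna = list(min_transcripts = 500L, max_transcripts = 100000L,
                 max_mito_fraction = 0.40),
      atac = list(min_tss_enrichment = 4, min_fragments = 1000L,
                  max_reads = 1000000L)),
    lineage = list(epcam_gene = "Epcam", epcam_min_count = 1L,
                   epcam_threshold = 0.5),
    deviations = list(k = 50L, B = 50L),
    enrichment = list(z_threshold = 0, report_fdr = 1e-20,
                      expression_threshold = 1),
    coaccess = list(cell_type = "IM", mode = "all"),
    survival = list(by_erg_status = TRUE)
  ), class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML path.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- unclass(default_pipeline_config())
  cfg <- utils::modifyList(base, cfg)
  structure(cfg, class = "pipeline_config")
}

#' @rdname read_pipeline_config
#' @param config A pipeline configuration list.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

config_to_sim <- function(config) {
  s <- config$sim
  do.call(sim_config, c(list(seed = config$seed),
                        list(n_cells_per_type = unlist(s$n_cells_per_type)),
                        s[setdiff(names(s), "n_cells_per_type")]))
}

#' Run the full analysis pipeline
#'
#' Executes simulate (or input loading) -> QC -> lineage -> deviations ->
#' enrichment -> co-accessibility -> survival, writing every stage's table
#' under \code{outdir} and a \code{manifest.json} recording output file
#' hashes, seeds, thresholds and the package version. Rerunning with an
#' identical configuration reproduces byte-identical outputs. A failing
#' stage aborts with the stage name and cause; when simulation is disabled,
#' all input paths are validated before any stage runs.
#'
#' @param config A [default_pipeline_config()] /
#'   [read_pipeline_config()] result.
#' @param outdir Output directory.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config = default_pipeline_config(), outdir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package = "motifdev",
                   version = as.character(packageVersion("motifdev")),
                   seed = config$seed,
                   thresholds = config[c("qc", "lineage", "deviations",
                                         "enrichment", "coaccess")],
                   files = list())
  outputs <- character(0)

  run_stage <- function(name, expr) {
    message("[", name, "] ...")
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  if (!isTRUE(config$simulate$enabled)) {
    need <- unlist(config$inputs)
    missing <- need[!file.exists(need)]
    if (length(missing))
      stop_input("missing input path(s): ", paste(missing, collapse = ", "))
  }

  # --- simulate -------------------------------------------------------------
  if (isTRUE(config$simulate$enabled)) {
    sim <- run_stage("simulate", {
      cfg <- config_to_sim(config)
      atac <- generate_atac(cfg)
      rna <- generate_rna(cfg)
      cohort <- generate_cohort(cfg)
      write_sparse_matrix(atac$counts, file.path(outdir, "atac"))
      write_sparse_matrix(rna$counts, file.path(outdir, "rna"))
      write_peaks(atac$peaks, file.path(outdir, "peaks.bed"),
                  file.path(outdir, "peaks_annot.tsv"))
      write_motif_membership(atac$motifs, file.path(outdir, "motifs.tsv"))
      write_cohort(cohort, file.path(outdir, "cohort.csv"))
      write_pipeline_config(config, file.path(outdir, "config.yaml"))
      list(cfg = cfg, atac = atac, rna = rna, cohort = cohort)
    })
    outputs <- c(outputs, file.path(outdir, c(
      "atac/matrix.mtx", "atac/features.tsv", "atac/barcodes.tsv",
      "rna/matrix.mtx", "rna/features.tsv", "rna/barcodes.tsv",
      "peaks.bed", "peaks_annot.tsv", "motifs.tsv", "cohort.csv",
      "config.yaml")))
  } else {
    sim <- run_stage("load_inputs", {
      atac_counts <- read_sparse_matrix(config$inputs$atac_dir)
      rna_counts <- read_sparse_matrix(config$inputs$rna_dir)
      peaks <- read_peaks(config$inputs$peaks_bed, config$inputs$peaks_annot)
      motifs <- read_motif_membership(config$inputs$motifs_tsv)
      cohort <- read_cohort(config$inputs$cohort_csv)
      meta <- read.delim(config$inputs$cell_metadata, stringsAsFactors = FALSE)
      list(cfg = NULL,
           atac = list(counts = atac_counts, peaks = peaks, motifs = motifs,
                       cells = meta[match(colnames(atac_counts), meta$cell_id), ]),
           rna = list(counts = rna_counts,
                      cells = meta[match(colnames(rna_counts), meta$cell_id), ],
                      mito_mask = grepl("^mt-", rownames(rna_counts)),
                      marker_sets = NULL),
           cohort = cohort)
    })
  }

  # --- qc -------------------------------------------------------------------
  kept <- run_stage("qc", {
    thr_r <- do.call(rna_qc_thresholds, config$qc$rna)
    thr_a <- do.call(atac_qc_thresholds, config$qc$atac)
    rna_keep <- filter_rna_cells(sim$rna$counts, sim$rna$mito_mask, thr_r)
    atac_keep <- filter_atac_cells(sim$atac$cells$fragments,
                                   sim$atac$cells$reads,
                                   sim$atac$cells$tss_enrichment, thr_a,
                                   cell_ids = sim$atac$cells$cell_id)
    writeLines(rna_keep, file.path(outdir, "kept_rna_barcodes.tsv"))
    writeLines(atac_keep, file.path(outdir, "kept_atac_barcodes.tsv"))
    list(rna = rna_keep, atac = atac_keep)
  })
  outputs <- c(outputs, file.path(outdir, c("kept_rna_barcodes.tsv",
                                            "kept_atac_barcodes.tsv")))

  # --- lineage --------------------------------------------------------------
  lineage <- run_stage("lineage", {
    rna <- sim$rna$counts[, kept$rna, drop = FALSE]
    meta <- sim$rna$cells[match(kept$rna, sim$rna$cells$cell_id), ]
    norm <- normalize_cp10k(rna)
    epcam <- epcam_positive_cells(rna, config$lineage$epcam_gene,
                                  config$lineage$epcam_min_count)
    flagged <- flag_epithelial_clusters(meta$cluster, epcam,
                                        config$lineage$epcam_threshold)
    sigs <- lapply(names(sim$rna$marker_sets), function(t)
      signature_set(t, sim$rna$marker_sets[[t]]))
    scores <- vapply(sigs, function(s) score_signature(norm, s),
                     numeric(ncol(norm)))
    colnames(scores) <- vapply(sigs, `[[`, "", "name")
    rownames(scores) <- colnames(norm)
    calls <- assign_cell_type(scores, meta$cluster %in% flagged)
    write.table(calls, file.path(outdir, "lineage_calls.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    markers <- derive_markers(norm, meta$cluster)
    write.table(markers, file.path(outdir, "markers.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    list(norm = norm, meta = meta, calls = calls, markers = markers,
         flagged = flagged)
  })
  outputs <- c(outputs, file.path(outdir, c("lineage_calls.tsv", "markers.tsv")))

  # --- deviations -----------------------------------------------------------
  dev <- run_stage("deviations", {
    atac <- sim$atac$counts[, kept$atac, drop = FALSE]
    peaks <- sim$atac$peaks
    peaks$mean_accessibility <- row_means(atac)
    bg <- sample_background_peaks(peaks, k = config$deviations$k,
                                  B = config$deviations$B,
                                  seed = config$seed)
    ds <- compute_deviations(atac, sim$atac$motifs, bg)
    zt <- data.frame(motif = rownames(ds$z), ds$z, check.names = FALSE)
    write.table(zt, file.path(outdir, "deviation_z.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    mask <- data.frame(motif = rownames(ds$z), is.na(ds$z) * 1L,
                       check.names = FALSE)
    write.table(mask, file.path(outdir, "deviation_z_missing.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    list(atac = atac, peaks = peaks, bg = bg, ds = ds)
  })
  outputs <- c(outputs, file.path(outdir, c("deviation_z.tsv",
                                            "deviation_z_missing.tsv")))

  # --- enrichment -----------------------------------------------------------
  run_stage("enrichment", {
    labels <- sim$atac$cells$cell_type[match(kept$atac,
                                             sim$atac$cells$cell_id)]
    enr <- celltype_motif_enrichment(dev$ds, labels,
                                     z_threshold = config$enrichment$z_threshold,
                                     report_fdr = config$enrichment$report_fdr)
    write.table(enr, file.path(outdir, "motif_enrichment.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    # motif -> gene map: target type's first marker where declared
    if (!is.null(sim$cfg)) {
      specs <- sim$cfg$motif_specs
      first_type <- names(sim$cfg$n_cells_per_type)[1]
      map <- data.frame(
        motif = specs$motif,
        gene = sprintf("%s_mk01", ifelse(is.na(specs$target_type),
                                         first_type, specs$target_type)),
        stringsAsFactors = FALSE)
      mean_expr <- vapply(split(seq_len(ncol(lineage$norm)),
                                lineage$meta$cluster),
                          function(j) row_means(lineage$norm[, j, drop = FALSE]),
                          numeric(nrow(lineage$norm)))
      ef <- expression_filter(map, mean_expr,
                              threshold = config$enrichment$expression_threshold)
      write.table(ef, file.path(outdir, "expression_filter.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      # Spearman retention on cells present in both modalities
      shared <- intersect(colnames(dev$ds$z), colnames(lineage$norm))
      cf <- do.call(rbind, lapply(seq_len(nrow(map)), function(i) {
        m <- map$motif[i]
        r <- tryCatch(correlation_filter(
          dev$ds$z[m, shared],
          as.numeric(lineage$norm[map$gene[i], shared])),
          error = function(e) list(rho = NA_real_, retained = FALSE, n = 0L))
        data.frame(motif = m, gene = map$gene[i], rho = r$rho,
                   retained = r$retained, n = r$n, stringsAsFactors = FALSE)
      }))
      write.table(cf, file.path(outdir, "correlation_filter.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    }
    invisible(NULL)
  })
  outputs <- c(outputs, file.path(outdir, "motif_enrichment.tsv"))
  if (!is.null(sim$cfg))
    outputs <- c(outputs, file.path(outdir, c("expression_filter.tsv",
                                              "correlation_filter.tsv")))

  # --- coaccessibility ------------------------------------------------------
  run_stage("coaccess", {
    M <- sim$atac$motifs
    fam <- if ("ETS" %in% colnames(M)) "ETS" else colnames(M)[1]
    candidates <- setdiff(colnames(M), fam)
    parts <- list()
    for (cand in candidates) {
      pp <- tryCatch(partition_peaks(M, cand, fam), error = function(e) NULL)
      if (!is.null(pp)) parts[[cand]] <- pp
    }
    labels <- sim$atac$cells$cell_type[match(kept$atac,
                                             sim$atac$cells$cell_id)]
    target <- config$coaccess$cell_type
    if (!target %in% labels) target <- labels[1]
    cells <- kept$atac[labels == target]
    res <- coaccessibility_test(dev$atac, parts, dev$bg, cells,
                                mode = config$coaccess$mode)
    res$cell_subset <- target
    write.table(res, file.path(outdir, "coaccessibility.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    invisible(NULL)
  })
  outputs <- c(outputs, file.path(outdir, "coaccessibility.tsv"))

  # --- survival -------------------------------------------------------------
  run_stage("survival", {
    surv <- survival_by_quartile(sim$cohort,
                                 by_erg_status = config$survival$by_erg_status)
    write.table(surv, file.path(outdir, "survival_logrank.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    invisible(NULL)
  })
  outputs <- c(outputs, file.path(outdir, "survival_logrank.tsv"))

  manifest$files <- lapply(sort(outputs), function(f)
    list(path = sub(paste0("^", outdir, "/?"), "", f),
         md5 = unname(tools::md5sum(f))))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  message("pipeline complete: ", length(outputs), " output files")
  invisible(manifest)
}
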