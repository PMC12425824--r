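test_that("generators are bit-identical under the same configuration", {
  cfg <- tiny_sim_config(seed = 7L)
  expect_identical(generate_atac(cfg), generate_atac(cfg))
  expect_identical(generate_rna(cfg), generate_rna(cfg))
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
  cfg2 <- tiny_sim_config(seed = 8L)
  expect_false(identical(generate_atac(cfg)$counts, generate_atac(cfg2)$counts))
})

test_that("configuration invariants are enforced", {
  specs <- default_motif_specs()
  specs$partner[2] <- NA  # amplified motif loses its partner
  expect_error(tiny_sim_config(motif_specs = specs), "partner")
  expect_error(sim_config(censor_rate = 1.2), "censor_rate")
  expect_error(sim_config(gc_range = c(0.8, 0.2)), "gc_range")
  expect_error(sim_config(n_genes = 10L) |> generate_rna(), "smaller")
  expect_error(generate_cohort(tiny_sim_config(cohort_n = 4L)), "at least 8")
})

test_that("unamplified counts match the analytic Poisson mean within 3 MC SE", {
  cfg <- tiny_sim_config(seed = 11L, motif_specs = null_motif_specs(),
                         n_peaks = 1000L, program_peaks_per_type = 50L)
  a <- generate_atac(cfg)
  X <- as.matrix(a$counts)
  prog <- sort(unlist(a$programs))
  bulk <- X[-prog, ]
  n <- length(bulk)
  se <- sqrt(cfg$base_rate / n)  # Poisson MC standard error of the mean
  expect_lt(abs(mean(bulk) - cfg$base_rate), 3 * se)
  # program peaks in their own type run at base_rate * multiplier
  types <- a$cells$cell_type
  for (t in names(a$programs)) {
    own <- X[a$programs[[t]], types == t]
    mu <- cfg$base_rate * cfg$program_multiplier
    expect_lt(abs(mean(own) - mu), 3 * sqrt(mu / length(own)))
  }
})

test_that("motif membership fraction falls in the binomial 99% interval", {
  specs <- data.frame(motif = "M1", prob = 0.2, partner = NA,
                      amplification = 1, target_type = NA)
  cfg <- tiny_sim_config(seed = 5L, n_peaks = 1000L, motif_specs = specs)
  a <- generate_atac(cfg)
  n_mem <- sum(a$motifs[, "M1"])
  bounds <- qbinom(c(0.005, 0.995), 1000L, 0.2)
  expect_gte(n_mem, bounds[1])
  expect_lte(n_mem, bounds[2])
})

test_that("forced co-occurrence and amplification reach the target cells only", {
  cfg <- tiny_sim_config(seed = 3L)
  a <- generate_atac(cfg)
  both <- a$motifs[, "STAT3"] == 1 & a$motifs[, "ETS"] == 1
  expect_gt(sum(both), 0)
  # amplified peaks are 2x more accessible in IM cells than in other types
  im <- a$cells$cell_type == "IM"
  m_im <- mean(as.matrix(a$counts)[both, im])
  m_rest <- mean(as.matrix(a$counts)[both, !im])
  expect_gt(m_im / m_rest, 1.5)
})

test_that("Epcam forcing is exact at fraction 1 and absent at fraction 0", {
  cfg <- tiny_sim_config(seed = 2L, epcam_fraction = c(basal = 1, L1 = 0,
                                                       L2 = 0.5, IM = 0.5))
  r <- generate_rna(cfg)
  epcam <- as.vector(r$counts["Epcam", ])
  expect_true(all(epcam[r$cells$cell_type == "basal"] >= 1))
  expect_true(all(epcam[r$cells$cell_type == "L1"] == 0))
})

test_that("planted QC failures are exactly the cells failing the RNA predicate", {
  cfg <- tiny_sim_config(seed = 9L, n_low_count_cells = 10L,
                         n_high_count_cells = 3L, n_high_mito_cells = 4L,
                         mito_fraction_dist = list(shape1 = 2, shape2 = 58))
  r <- generate_rna(cfg)
  kept <- suppressMessages(filter_rna_cells(r$counts, r$mito_mask))
  failed <- setdiff(colnames(r$counts), kept)
  planted <- r$cells$cell_id[r$cells$planted_qc != "none"]
  expect_setequal(failed, planted)
  low <- r$cells$cell_id[r$cells$planted_qc == "low_count"]
  expect_true(all(Matrix::colSums(r$counts[, low, drop = FALSE]) < 500))
  high <- r$cells$cell_id[r$cells$planted_qc == "high_count"]
  expect_true(all(Matrix::colSums(r$counts[, high, drop = FALSE]) > 100000))
})

test_that("cohort obeys censoring and effect-size settings", {
  co0 <- generate_cohort(tiny_sim_config(seed = 4L, censor_rate = 0))
  expect_true(all(co0$event == 1))
  expect_true(all(co0$time > 0))
  co <- generate_cohort(tiny_sim_config(seed = 4L, cohort_n = 2000L,
                                        censor_rate = 0.3))
  expect_lt(abs(mean(co$event == 0) - 0.3), 0.04)
  expect_lt(abs(mean(co$score)), 0.1)
  expect_lt(abs(sd(co$score) - 1), 0.1)
})
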