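test_that("family reduction is the OR of member columns", {
  M <- cbind(FLI = c(1L, 0L, 0L, 1L), ERG = c(0L, 0L, 1L, 1L),
             OTHER = c(1L, 1L, 1L, 1L))
  rownames(M) <- paste0("p", 1:4)
  out <- reduce_motif_family(M, c("FLI", "ERG"), "ETS")
  expect_identical(unname(out[, "ETS"]), c(1L, 0L, 1L, 1L))
  expect_true(all(colnames(M) %in% colnames(out)))  # members retained
  expect_gte(sum(out[, "ETS"]), max(sum(M[, "FLI"]), sum(M[, "ERG"])))
  expect_error(reduce_motif_family(M, "NOPE", "X"), "unknown")
})

test_that("hypergeometric enrichment matches exact enumeration", {
  # population 10, cell type of 5, 5 accessible, overlap 5 -> 1/252
  z <- matrix(c(rep(1, 5), rep(-1, 5)), 1,
              dimnames = list("m", paste0("c", 1:10)))
  labels <- rep(c("T", "rest"), each = 5)
  enr <- celltype_motif_enrichment(z, labels)
  row_t <- enr[enr$cell_type == "T", ]
  expect_equal(row_t$p, 1 / choose(10, 5), tolerance = 1e-12)
  expect_equal(row_t$p, bf_hypergeom_upper(5, 5, 10, 5), tolerance = 1e-12)
  # all cells accessible -> p = 1 everywhere
  z_all <- matrix(1, 1, 10, dimnames = list("m", paste0("c", 1:10)))
  enr_all <- celltype_motif_enrichment(z_all, labels)
  expect_true(all(enr_all$p == 1))
  # random configurations against the enumeration oracle, populations <= 30
  set.seed(5)
  for (rep in 1:20) {
    N <- sample(8:30, 1)
    lab <- sample(c("A", "B"), N, replace = TRUE)
    if (length(unique(lab)) < 2) next
    zz <- matrix(rnorm(N), 1, dimnames = list("m", paste0("c", seq_len(N))))
    enr2 <- celltype_motif_enrichment(zz, lab)
    K <- sum(zz > 0)
    for (i in seq_len(nrow(enr2))) {
      expect_equal(enr2$p[i],
                   bf_hypergeom_upper(enr2$overlap[i], K, N,
                                      enr2$cell_type_size[i]),
                   tolerance = 1e-12)
    }
  }
})

test_that("enrichment is invariant to cell and motif ordering", {
  set.seed(8)
  z <- matrix(rnorm(40), 2, 20, dimnames = list(c("m1", "m2"), paste0("c", 1:20)))
  labels <- sample(c("A", "B"), 20, replace = TRUE)
  e1 <- celltype_motif_enrichment(z, labels)
  perm <- sample(20)
  e2 <- celltype_motif_enrichment(z[, perm], labels[perm])
  e2 <- e2[match(paste(e1$motif, e1$cell_type),
                 paste(e2$motif, e2$cell_type)), ]
  expect_equal(e1$p, e2$p, tolerance = 1e-12)
  e3 <- celltype_motif_enrichment(z[c(2, 1), ], labels)
  e3 <- e3[match(paste(e1$motif, e1$cell_type),
                 paste(e3$motif, e3$cell_type)), ]
  expect_equal(e1$p, e3$p, tolerance = 1e-12)
})

test_that("expression retention uses a strict > 1 rule", {
  expr <- matrix(c(1.01, 1.00, 0, 0, 2, 0), 3, 2, byrow = TRUE,
                 dimnames = list(c("gA", "gB", "gC"), c("T1", "T2")))
  map <- data.frame(motif = c("mA", "mB", "mC"), gene = c("gA", "gB", "gC"))
  out <- expression_filter(map, expr)
  expect_true(out$retained[out$motif == "mA" & out$cell_type == "T1"])
  expect_false(out$retained[out$motif == "mA" & out$cell_type == "T2"])
  expect_false(any(out$retained[out$motif == "mB"]))  # 1.00 and 0: dropped
  expect_identical(out$cell_type[out$motif == "mC" & out$retained], "T1")
  expect_warning(
    expression_filter(data.frame(motif = "mX", gene = "missing"), expr),
    "absent")
})

test_that("Spearman retention keeps positive correlations only", {
  set.seed(3)
  z <- rnorm(12)
  expect_equal(correlation_filter(z, z)$rho, 1, tolerance = 1e-12)
  expect_true(correlation_filter(z, z)$retained)
  neg <- correlation_filter(z, -z)
  expect_equal(neg$rho, -1, tolerance = 1e-12)
  expect_false(neg$retained)
  g <- rnorm(12)
  expect_equal(correlation_filter(z, g)$rho, bf_spearman(z, g),
               tolerance = 1e-12)
  expect_warning(out <- correlation_filter(z, rep(1, 12)), "constant")
  expect_false(out$retained)
  expect_error(correlation_filter(rnorm(5), rnorm(5)), "fewer than")
})

test_that("differential accessibility applies the strict DAR rule", {
  set.seed(6)
  n <- 100
  X <- matrix(rpois(200 * n, 2), 200, n,
              dimnames = list(sprintf("p%03d", 1:200),
                              sprintf("c%03d", 1:n)))
  a_cells <- colnames(X)[1:50]; b_cells <- colnames(X)[51:100]
  X[1, 1:50] <- rpois(50, 8)  # planted 4x peak in group A
  da <- differential_accessibility(X, a_cells, b_cells)
  expect_true(da$dar[1])
  expect_error(differential_accessibility(X, a_cells, a_cells), "overlap")
  expect_error(differential_accessibility(X, a_cells[1:2], b_cells), "at least 3")
  # the flag is exactly the conjunction of the two strict rules: a peak with
  # tiny FDR but log2FC below 0.5 is not a DAR
  expect_identical(da$dar, da$fdr < 0.05 & da$log2FC >= 0.5)
  X2 <- X
  X2[2, 1:50] <- rpois(50, 2 * 2^0.3)  # lift below the 0.5 log2FC bar
  da2 <- differential_accessibility(X2, a_cells, b_cells)
  if (da2$log2FC[2] < 0.5) expect_false(da2$dar[2])
})

test_that("identical groups produce few DARs across seeds", {
  hits <- 0L
  for (s in 1:20) {
    set.seed(s)
    X <- matrix(rpois(100 * 40, 3), 100, 40,
                dimnames = list(sprintf("p%03d", 1:100),
                                sprintf("c%02d", 1:40)))
    da <- differential_accessibility(X, colnames(X)[1:20], colnames(X)[21:40])
    hits <- hits + any(da$dar)
  }
  expect_lte(hits, 2L)
})
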