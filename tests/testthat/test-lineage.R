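test_that("epithelial flagging applies the >= 50% Epcam-positive rule exactly", {
  clusters <- rep(c("c1", "c2", "c3"), each = 10)
  epcam <- c(rep(TRUE, 5), rep(FALSE, 5),   # c1: 5/10 -> flagged
             rep(TRUE, 4), rep(FALSE, 6),   # c2: 4/10 -> not flagged
             rep(TRUE, 10))                 # c3: all  -> flagged
  expect_setequal(flag_epithelial_clusters(clusters, epcam), c("c1", "c3"))
  # invariance to cell order and to cluster renaming
  perm <- sample(seq_along(clusters))
  expect_setequal(flag_epithelial_clusters(clusters[perm], epcam[perm]),
                  c("c1", "c3"))
  renamed <- setNames(c("x", "y", "z"), c("c1", "c2", "c3"))[clusters]
  expect_setequal(flag_epithelial_clusters(renamed, epcam), c("x", "z"))
  # saturation: all positive -> every cluster flagged
  expect_setequal(flag_epithelial_clusters(clusters, rep(TRUE, 30)),
                  c("c1", "c2", "c3"))
  # empty cluster level warns
  expect_warning(flag_epithelial_clusters(factor(clusters,
                                                 levels = c("c1", "c2", "c3", "c4")),
                                          epcam), "empty")
})

test_that("signature scores equal the mean per-gene z-score", {
  # hand-computed toy: 3 genes x 4 cells
  X <- matrix(c(1, 2, 3, 4,
                0, 0, 0, 0,
                2, 2, 4, 4), 3, 4, byrow = TRUE,
              dimnames = list(c("g1", "g2", "g3"), paste0("c", 1:4)))
  sig <- signature_set("toy", c("g1", "g2", "g3"))
  got <- score_signature(X, sig)
  z1 <- (c(1, 2, 3, 4) - 2.5) / sd(c(1, 2, 3, 4))
  z3 <- (c(2, 2, 4, 4) - 3) / sd(c(2, 2, 4, 4))
  expect_equal(unname(got), (z1 + 0 + z3) / 3, tolerance = 1e-12)
  # constant matrix -> all zero
  C <- matrix(5, 3, 4, dimnames = dimnames(X))
  expect_true(all(score_signature(C, sig) == 0))
  # gene expressed in one cell only -> that cell has the strict max
  M <- matrix(0, 1, 4, dimnames = list("g1", paste0("c", 1:4)))
  M[1, 2] <- 3
  s <- score_signature(M, signature_set("one", "g1"))
  expect_identical(names(which.max(s)), "c2")
  expect_true(all(s[2] > s[-2]))
  # shift invariance: adding a constant leaves scores unchanged
  expect_equal(score_signature(X + 3, sig), got, tolerance = 1e-12)
  # absent genes warn; fully absent errors naming the signature
  expect_warning(score_signature(X, signature_set("s", c("g1", "nope"))),
                 "absent")
  suppressWarnings(
    expect_error(score_signature(X, signature_set("ghost", "nope")), "ghost"))
})

test_that("cell-type assignment takes the strict maximum in flagged clusters", {
  scores <- rbind(c(2, 0, 0, 0), c(1, 1, 1, 1), c(0, 3, 1, 0))
  colnames(scores) <- c("basal", "L1", "L2", "L3")
  rownames(scores) <- c("a", "b", "c")
  calls <- assign_cell_type(scores, epithelial = c(TRUE, TRUE, FALSE))
  expect_identical(calls$label, c("basal", "unassigned", "unassigned"))
  expect_identical(calls$epithelial_confident, c(TRUE, FALSE, FALSE))
})

test_that("marker derivation recovers a planted marker and is order-invariant", {
  set.seed(42)
  n <- 40
  labels <- rep(c("A", "B"), each = n / 2)
  X <- matrix(rpois(20 * n, 5), 20, n,
              dimnames = list(sprintf("g%02d", 1:20), sprintf("c%02d", 1:n)))
  X["g01", labels == "A"] <- X["g01", labels == "A"] + 30  # planted marker
  norm <- normalize_cp10k(X)
  mk <- derive_markers(norm, labels)
  top_a <- mk[which(mk$label == "A" & mk$rank == 1), ]
  expect_identical(top_a$gene, "g01")
  expect_lt(top_a$fdr, 0.05)
  # permuting cell order leaves the table unchanged
  perm <- sample(n)
  mk2 <- derive_markers(norm[, perm], labels[perm])
  expect_equal(mk, mk2, tolerance = 1e-12)
})

test_that("null groups yield no FDR-significant marker in most seeds", {
  hits <- 0L
  for (s in 1:20) {
    set.seed(s)
    X <- matrix(rpois(20 * 30, 5), 20, 30,
                dimnames = list(sprintf("g%02d", 1:20), NULL))
    labels <- rep(c("A", "B"), each = 15)  # identical distributions
    mk <- derive_markers(normalize_cp10k(X), labels)
    hits <- hits + any(mk$fdr < 0.05)
  }
  expect_lte(hits, 2L)  # >= 90% of seeds clean
})

test_that("signature derivation applies strict padj and fold-change cutoffs", {
  tab <- data.frame(
    label = "A",
    gene = c("in", "fdr_out", "fc_edge", "fc_in"),
    avg_log2FC = c(log2(2.1), log2(3), 1, log2(2.1)),  # fc_edge: FC exactly 2
    p = c(0.001, 0.002, 0.001, 0.001),
    fdr = c(0.049, 0.051, 0.01, 0.010),
    rank = c(2L, 1L, 3L, 4L))
  sig <- signature_from_markers(tab)
  expect_setequal(sig$genes, c("in", "fc_in"))
  expect_identical(sig$genes, c("in", "fc_in"))  # ordered by rank
  expect_warning(
    empty <- signature_from_markers(tab[tab$fdr > 0.5, , drop = FALSE],
                                    name = "none"),
    "empty")
  expect_length(empty$genes, 0)
})

test_that("planted lineage identities are recovered at >= 95% accuracy", {
  cfg <- sim_config(seed = 31L,
                    n_cells_per_type = c(basal = 50L, L1 = 50L,
                                         L2 = 50L, L3 = 50L),
                    motif_specs = null_motif_specs())
  r <- generate_rna(cfg)
  norm <- normalize_cp10k(r$counts)
  epcam <- epcam_positive_cells(r$counts)
  flagged <- flag_epithelial_clusters(r$cells$cluster, epcam)
  scores <- vapply(names(r$marker_sets), function(t)
    score_signature(norm, signature_set(t, r$marker_sets[[t]])),
    numeric(ncol(norm)))
  rownames(scores) <- colnames(norm)
  calls <- assign_cell_type(scores, r$cells$cluster %in% flagged)
  expect_gte(mean(calls$label == r$cells$cell_type), 0.95)
})
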