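test_that("expected counts preserve margins and handle degenerate input", {
  X <- matrix(c(2, 2, 2, 2), 2)
  expect_equal(expected_counts(X), matrix(2, 2, 2), tolerance = 1e-12)
  X2 <- matrix(c(4, 0, 0, 4), 2)
  expect_equal(expected_counts(X2), matrix(2, 2, 2), tolerance = 1e-12)
  set.seed(1)
  X3 <- matrix(rpois(20, 3), 5, 4)
  E <- expected_counts(X3)
  expect_equal(sum(E), sum(X3), tolerance = 1e-12)
  expect_equal(rowSums(E), rowSums(X3), tolerance = 1e-12)
  expect_equal(colSums(E), colSums(X3), tolerance = 1e-12)
  expect_error(expected_counts(matrix(0, 2, 2)), "all-zero")
})

test_that("raw deviation follows the ratio formula and its closed forms", {
  X <- matrix(c(4, 0, 0, 4), 2)
  E <- expected_counts(X)
  expect_equal(unname(raw_deviation(X, E, 1L)), c(1, -1), tolerance = 1e-12)
  # all-peaks member set: column sums cancel exactly
  set.seed(2)
  X2 <- matrix(rpois(30, 2) + 1, 6, 5)
  expect_equal(unname(raw_deviation(X2, expected_counts(X2), 1:6)),
               rep(0, 5), tolerance = 0)
  # ratio statistic: global rescaling leaves y unchanged
  y1 <- raw_deviation(X2, expected_counts(X2), c(1L, 3L))
  y2 <- raw_deviation(X2 * 7L, expected_counts(X2 * 7L), c(1L, 3L))
  expect_equal(y1, y2, tolerance = 1e-12)
  expect_error(raw_deviation(X2, expected_counts(X2), integer(0)), "non-empty")
})

test_that("background sampling is deterministic and respects the kNN bound", {
  peaks <- data.frame(gc_fraction = runif(100), mean_accessibility = runif(100))
  b1 <- sample_background_peaks(peaks, k = 10, B = 20, seed = 5)
  b2 <- sample_background_peaks(peaks, k = 10, B = 20, seed = 5)
  expect_identical(b1, b2)
  # every sampled background lies within the k-th neighbour distance
  feat <- cbind(scale(peaks$gc_fraction), scale(log1p(peaks$mean_accessibility)))
  D <- as.matrix(dist(feat))
  for (i in seq_len(100)) {
    dk <- sort(D[i, ])[b1$k]  # k-th smallest including self
    expect_true(all(D[i, b1$map[i, ]] <= dk + 1e-12))
  }
  expect_warning(sample_background_peaks(peaks[1:5, ], k = 10, B = 5, seed = 1),
                 "reduced")
})

test_that("identical peaks give uniform background draws", {
  peaks <- data.frame(gc_fraction = rep(0.5, 40),
                      mean_accessibility = rep(1, 40))
  bg <- sample_background_peaks(peaks, k = 20, B = 250, seed = 3)
  draws <- as.vector(bg$map)  # 40 * 250 = 10,000 draws
  obs <- tabulate(draws, nbins = 40)
  chi <- sum((obs - length(draws) / 40)^2 / (length(draws) / 40))
  expect_lt(chi, qchisq(0.99, df = 39))
})

test_that("deviation Z matches a brute-force oracle on toy inputs", {
  set.seed(7)
  X <- matrix(rpois(24, 3) + 1, 6, 4)
  map <- matrix(sample.int(6, 18, replace = TRUE), 6, 3)  # B = 3 fixed maps
  bgs <- structure(list(map = map, neighbors = NULL, k = 6L, B = 3L,
                        seed = 0L), class = "background_sets")
  members <- c(2L, 5L)
  got <- suppressMessages(deviation_z(X, members, bgs))
  want <- bf_deviation_z(X, members, map)
  expect_equal(unname(got$y), want$y, tolerance = 1e-12)
  expect_equal(unname(got$d), want$d, tolerance = 1e-12)
  expect_equal(unname(got$z), want$z, tolerance = 1e-12)
})

test_that("full pipeline equals brute force on random small matrices", {
  for (s in 1:5) {
    set.seed(s)
    n_p <- sample(5:10, 1); n_c <- sample(4:10, 1)
    X <- matrix(rpois(n_p * n_c, 4) + 1, n_p, n_c)
    B <- 6L
    map <- matrix(sample.int(n_p, n_p * B, replace = TRUE), n_p, B)
    bgs <- structure(list(map = map, neighbors = NULL, k = n_p, B = B,
                          seed = 0L), class = "background_sets")
    members <- sort(sample.int(n_p, 3))
    got <- suppressMessages(deviation_z(X, members, bgs))
    want <- bf_deviation_z(X, members, map)
    expect_equal(unname(got$z), want$z, tolerance = 1e-12)
  }
})

test_that("degenerate backgrounds behave as closed forms predict", {
  set.seed(9)
  X <- matrix(rpois(40, 3) + 1, 8, 5)
  idb <- identity_backgrounds(8, B = 4)
  got <- suppressMessages(deviation_z(X, c(1L, 4L), idb))
  expect_equal(unname(got$d), rep(0, 5), tolerance = 1e-12)
  expect_true(all(is.na(got$z)))  # zero background sd
  # all-peaks member set under measure-preserving (permutation) backgrounds:
  # every background deviation is exactly zero, so d is exactly zero
  pb <- permutation_backgrounds(8, B = 4, seed = 2)
  all_peaks <- suppressMessages(deviation_z(X, 1:8, pb))
  expect_equal(unname(all_peaks$y), rep(0, 5), tolerance = 0)
  expect_equal(unname(all_peaks$d), rep(0, 5), tolerance = 0)
})

test_that("a peak set amplified in a cell subset shows elevated Z there", {
  set.seed(11)
  n_p <- 300; n_c <- 200
  lam <- matrix(1, n_p, n_c)
  members <- 1:30
  hot <- 1:100  # amplified cells
  lam[members, hot] <- 2
  X <- matrix(rpois(n_p * n_c, lam), n_p, n_c,
              dimnames = list(sprintf("p%03d", 1:n_p),
                              sprintf("c%03d", 1:n_c)))
  peaks <- data.frame(gc_fraction = runif(n_p),
                      mean_accessibility = rowMeans(X))
  bg <- sample_background_peaks(peaks, k = 50, B = 50, seed = 11)
  z <- suppressMessages(deviation_z(X, members, bg))$z
  wt <- wilcox.test(z[hot], z[-hot], alternative = "greater")
  expect_lt(wt$p.value, 0.01)
})

test_that("compute_deviations returns aligned motif x cell matrices", {
  cfg <- tiny_sim_config(seed = 13L)
  a <- generate_atac(cfg)
  bg <- sample_background_peaks(a$peaks, k = 20, B = 20, seed = 13)
  ds <- compute_deviations(a$counts, a$motifs, bg)
  expect_identical(dim(ds$z), c(ncol(a$motifs), ncol(a$counts)))
  expect_identical(rownames(ds$z), colnames(a$motifs))
  one <- suppressMessages(deviation_z(a$counts, which(a$motifs[, "ETS"] == 1), bg))
  expect_equal(ds$z["ETS", ], one$z, tolerance = 1e-12)
})
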