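make_taxa <- function(n_samples, cols) {
  m <- do.call(cbind, cols)
  rownames(m) <- sprintf("s%03d", seq_len(n_samples))
  m
}

test_that("core filter drops by below-threshold prevalence, literal rule", {
  n <- 100
  always_high <- rep(5, n)                       # never below threshold -> kept
  mostly_zero <- c(rep(0, 15), rep(1, 85))       # below in 15% >= 10% -> dropped
  edge_kept <- c(rep(0.009, 9), rep(1, 91))      # below in 9% < 10% -> kept
  taxa <- make_taxa(n, list(a = always_high, b = mostly_zero, c = edge_kept))
  res <- filter_core_microbiota(taxa)
  expect_setequal(res$kept_taxa, c("a", "c"))
  expect_equal(res$dropped_taxa, "b")
  expect_setequal(c(res$kept_taxa, res$dropped_taxa), colnames(taxa))

  # converse convention keeps taxa present above threshold often enough
  res2 <- filter_core_microbiota(taxa, rule = "keep_prevalent")
  expect_true("b" %in% res2$kept_taxa)  # >= 0.01% in 85% of samples
})

test_that("core filter is invariant to sample and taxa order", {
  set.seed(8)
  taxa <- matrix(rexp(300) * (runif(300) > 0.2), 30, 10,
                 dimnames = list(sprintf("s%02d", 1:30), letters[1:10]))
  ref <- filter_core_microbiota(taxa)
  perm <- filter_core_microbiota(taxa[sample(30), sample(10)])
  expect_setequal(perm$kept_taxa, ref$kept_taxa)
})

test_that("Shannon index matches its closed forms and direct summation", {
  expect_equal(shannon_index(c(0, 7, 0)), 0)
  expect_equal(shannon_index(rep(100 / 36, 36)), log(36))
  set.seed(12)
  for (i in 1:10) {
    v <- rexp(10) * (runif(10) > 0.2)
    if (sum(v) == 0) v[1] <- 1
    expect_equal(shannon_index(v), shannon_brute(v))
    expect_equal(shannon_index(3.7 * v), shannon_index(v))  # scale invariance
  }
  expect_error(shannon_index(rep(0, 5)), class = "amediate_validation_error")
})

test_that("Bray-Curtis matches the defining formula", {
  taxa <- make_taxa(3, list(a = c(60, 40, 10), b = c(40, 60, 90)))
  d <- bray_curtis_matrix(taxa)
  expect_equal(d["s001", "s002"], 0.2)  # |60-40| + |40-60| over 200
  expect_equal(diag(d), setNames(rep(0, 3), rownames(taxa)))
  expect_equal(d, t(d))

  same <- make_taxa(2, list(a = c(5, 5), b = c(95, 95)))
  expect_equal(bray_curtis_matrix(same)[1, 2], 0)
  disjoint <- make_taxa(2, list(a = c(50, 0), b = c(0, 50)))
  expect_equal(bray_curtis_matrix(disjoint)[1, 2], 1)

  set.seed(14)
  m <- matrix(rexp(40), 4, 10, dimnames = list(paste0("s", 1:4), NULL))
  m <- 100 * m / rowSums(m)
  d <- bray_curtis_matrix(m)
  for (i in 1:3) for (j in (i + 1):4)
    expect_equal(d[i, j], bray_brute(m[i, ], m[j, ]))

  bad <- make_taxa(2, list(a = c(0, 1), b = c(0, 1)))
  expect_error(bray_curtis_matrix(bad), "s001",
               class = "amediate_validation_error")
})

test_that("PCoA recovers exact Euclidean configurations", {
  # collinear points at mutual distances 1, 1, 2
  D <- rbind(c(0, 1, 2), c(1, 0, 1), c(2, 1, 0))
  ord <- pcoa_ordination(D, axes_kept = 3)
  expect_equal(sort(ord$coordinates[, 1]), c(-1, 0, 1), tolerance = 1e-8)
  expect_equal(ord$axes_kept, 1L)  # second eigenvalue is zero
  expect_lt(max(abs(colMeans(ord$coordinates))), 1e-10)
  expect_equal(ord$eigenvalues, sort(ord$eigenvalues, decreasing = TRUE))

  # duplicated samples get identical coordinates
  D2 <- rbind(c(0, 0, 1), c(0, 0, 1), c(1, 1, 0))
  ord2 <- pcoa_ordination(D2, axes_kept = 2)
  expect_equal(ord2$coordinates[1, ], ord2$coordinates[2, ], tolerance = 1e-10)

  # distances from random Euclidean points are reproduced within 1e-8
  set.seed(17)
  pts <- matrix(rnorm(8 * 3), 8, 3)
  D3 <- as.matrix(dist(pts))
  ord3 <- pcoa_ordination(D3, axes_kept = 8)
  expect_equal(as.matrix(dist(ord3$coordinates)), D3,
               tolerance = 1e-8, ignore_attr = TRUE)

  expect_error(pcoa_ordination(matrix(c(0, 1, 2, 0), 2, 2)),
               class = "amediate_validation_error")
})

test_that("PCoA agrees with a dense eigendecomposition oracle", {
  set.seed(19)
  for (i in 1:5) {
    m <- matrix(rexp(8 * 12), 8, 12,
                dimnames = list(paste0("s", 1:8), NULL))
    m <- 100 * m / rowSums(m)
    D <- bray_curtis_matrix(m)
    ord <- suppressWarnings(pcoa_ordination(D, axes_kept = 7))
    oracle <- pcoa_brute(D, 7)
    # positive-axis reconstructed inter-point distances must agree
    expect_equal(as.matrix(dist(ord$coordinates)),
                 as.matrix(dist(oracle$coords[, seq_len(ord$axes_kept)])),
                 tolerance = 1e-6, ignore_attr = TRUE)
    k <- ord$axes_kept
    expect_equal(ord$eigenvalues[seq_len(k)], oracle$values[seq_len(k)],
                 tolerance = 1e-6)
  }
})

test_that("sign convention puts the largest-magnitude coordinate positive", {
  set.seed(23)
  m <- matrix(rexp(60), 6, 10, dimnames = list(paste0("s", 1:6), NULL))
  ord <- suppressWarnings(pcoa_ordination(bray_curtis_matrix(100 * m / rowSums(m))))
  for (j in seq_len(ncol(ord$coordinates)))
    expect_gt(ord$coordinates[which.max(abs(ord$coordinates[, j])), j], 0)
})
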