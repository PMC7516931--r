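test_that("plug-in mutual information on hand-computed tables", {
  x <- rep(c(0, 1), each = 5)
  expect_identical(mutualInformation(x, x), 1.0)   # H of a balanced binary
  # empirical joint equal to product of marginals: exactly zero
  xf <- c(0, 0, 1, 1)
  yf <- c(0, 1, 0, 1)
  expect_identical(mutualInformation(xf, yf), 0)
  # joint counts [[4,1],[1,4]] over 10 samples
  x2 <- c(rep(0, 5), rep(1, 5))
  y2 <- c(rep(0, 4), 1, 0, rep(1, 4))
  pj <- c(0.4, 0.1, 0.1, 0.4)
  hand <- sum(pj * log2(pj / c(0.25, 0.25, 0.25, 0.25)))
  expect_equal(mutualInformation(x2, y2), hand, tolerance = 1e-12)
  # symmetry, non-negativity, relabelling invariance on random inputs
  set.seed(1)
  for (r in 1:10) {
    a <- sample(0:2, 60, TRUE)
    b <- sample(0:3, 60, TRUE)
    expect_identical(mutualInformation(a, b), mutualInformation(b, a))
    expect_gte(mutualInformation(a, b), 0)
    expect_equal(mutualInformation(10 - a, b), mutualInformation(a, b),
                 tolerance = 1e-12)
  }
  expect_error(mutualInformation(1:4, 1:5), "equal length")
})

test_that("equal-frequency discretisation is rank-based and order-preserving", {
  # already-discrete input: order-preserving relabelling
  x <- c(5, 2, 9, 2, 5)
  expect_identical(discretize(x, 4), c(2L, 1L, 3L, 1L, 2L))
  # 100 distinct values into 4 bins of 25
  set.seed(2)
  y <- rnorm(100)
  codes <- discretize(y, 4)
  expect_identical(as.vector(table(codes)), rep(25L, 4))
  # invariance under a strictly increasing transform
  expect_identical(discretize(exp(y), 4), codes)
  expect_warning(out <- discretize(rep(3, 10), 4), "constant")
  expect_identical(out, rep(1L, 10))
  expect_error(discretize(y, 1), "nBins")
})

test_that("the MI hypermatrix masks self-pairs but keeps cross-layer duplicates", {
  set.seed(3)
  n <- 400
  vals <- array(sample(0:1, n * 3 * 2, TRUE), dim = c(n, 3, 2))
  vals[, 2, 2] <- vals[, 2, 1]  # layer II copies variable 2 of layer I
  st <- sampleTensor(vals)
  mi <- miMatrix(st)
  v <- hmValues(mi)
  # bi-diagonal forced to zero although I(X,X) = H(X) > 0
  for (i in 1:3) for (h in 1:2) expect_identical(v[i, i, h, h], 0)
  # the duplicated variable shows its entropy across layers
  H <- mutualInformation(vals[, 2, 1], vals[, 2, 1])
  expect_equal(v[2, 2, 1, 2], H, tolerance = 1e-12)
  expect_gt(v[2, 2, 1, 2], 0)
  # tensor symmetry holds exactly
  expect_identical(v, aperm(v, c(2, 1, 4, 3)))
})

test_that("independent columns give uniformly small plug-in MI", {
  set.seed(4)
  vals <- array(sample(0:1, 1000 * 3 * 2, TRUE), dim = c(1000, 3, 2))
  v <- hmValues(miMatrix(sampleTensor(vals)))
  offdiag <- v[v > 0]
  expect_lt(max(offdiag), 0.1)
})

test_that("Heaviside thresholding is strict and monotone", {
  set.seed(5)
  vals <- array(rnorm(200 * 2 * 2), dim = c(200, 2, 2))
  vals[, 1, 2] <- vals[, 1, 1]
  mi <- miMatrix(sampleTensor(vals), nBins = 4)
  # i0 = 0 keeps the support
  a0 <- adjacencyHypermatrix(mi, 0)
  expect_identical(hmValues(a0), (hmValues(mi) > 0) + 0)
  # i0 at the maximum removes everything (strict exceedance)
  expect_identical(sum(hmValues(adjacencyHypermatrix(mi, max(hmValues(mi))))), 0)
  # raising the threshold never adds entries
  grid <- sort(unique(as.vector(hmValues(mi))))
  prev <- sum(hmValues(a0))
  for (t in grid) {
    cur <- sum(hmValues(adjacencyHypermatrix(mi, t)))
    expect_lte(cur, prev)
    prev <- cur
  }
  expect_error(adjacencyHypermatrix(mi, -1), "non-negative")
})

test_that("the strength hypermatrix is MI on the adjacency support", {
  set.seed(6)
  vals <- array(sample(0:1, 300 * 3 * 2, TRUE), dim = c(300, 3, 2))
  vals[, 1, 2] <- vals[, 1, 1]
  mi <- miMatrix(sampleTensor(vals))
  a <- adjacencyHypermatrix(mi, 0.2)
  w <- strengthHypermatrix(a, mi)
  expect_identical(hmValues(w), hmValues(a) * hmValues(mi))
  expect_true(all(hmValues(w)[hmValues(a) == 0] == 0))
  expect_identical(hmValues(w)[hmValues(a) == 1], hmValues(mi)[hmValues(a) == 1])
  # all-ones adjacency off the bi-diagonal returns MI itself
  ones <- adjacencyHypermatrix(mi, 0)
  ones@values[hmValues(mi) > 0] <- 1
  expect_identical(hmValues(strengthHypermatrix(ones, mi)), hmValues(mi))
})

test_that("the permutation threshold separates planted dependence from noise", {
  set.seed(7)
  n <- 400
  vals <- array(sample(0:1, n * 2 * 2, TRUE), dim = c(n, 2, 2))
  vals[, 1, 2] <- ifelse(runif(n) < 0.9, vals[, 1, 1], 1 - vals[, 1, 1])
  st <- sampleTensor(vals)
  thr <- permutationThreshold(st, nPerm = 100, alpha = 0.05, seed = 11)
  expect_identical(thr, permutationThreshold(st, nPerm = 100, alpha = 0.05,
                                             seed = 11))
  expect_gt(mutualInformation(vals[, 1, 1], vals[, 1, 2]), thr)
  # the threshold is a genuine quantile: nearly alpha of null MIs exceed it
  expect_gt(thr, 0)
  expect_error(permutationThreshold(st, nPerm = 5), "at least 20")
})

test_that("edge-list and coordinate writers emit canonical TSV", {
  set.seed(8)
  vals <- array(sample(0:1, 200 * 2 * 2, TRUE), dim = c(200, 2, 2))
  vals[, 1, 2] <- vals[, 1, 1]
  st <- sampleTensor(vals)
  fit <- inferNetwork(st, i0 = 0.3)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeMIEdges(fit$mi, fit$adjacency, path)
  df <- read.table(path, sep = "\t", header = TRUE)
  expect_identical(names(df), c("var_a", "layer_a", "var_b", "layer_b",
                                "mi", "adjacency"))
  expect_true(all(df$adjacency == 1))
  expect_identical(nrow(df), as.integer(sum(hmValues(fit$adjacency)) / 2))
  writeHypermatrixCoords(fit$strength, path)
  co <- read.table(path, sep = "\t", header = TRUE)
  expect_identical(names(co), c("i", "j", "h", "k", "value"))
  for (r in seq_len(nrow(co))) {
    expect_equal(hmValues(fit$strength)[co$i[r], co$j[r], co$h[r], co$k[r]],
                 co$value[r], tolerance = 1e-6)
  }
})
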