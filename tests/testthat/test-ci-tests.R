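test_that("conditional kernels normalise and reduce to marginals", {
  p <- randomJoint(5, seed = 21)
  # conditioning on nothing gives the marginal of the target
  k0 <- conditionalKernel(p, integer(0), c(2, 4))
  expect_equal(as.vector(kernelTable(k0)), marginalProbability(p, c(2, 4)),
               tolerance = 1e-12)
  for (s in 1:5) {
    p <- randomJoint(5, seed = s)
    k <- conditionalKernel(p, c(1, 3), c(2, 5))
    expect_lt(max(abs(rowSums(kernelTable(k)) - 1)), 1e-10)
  }
  # independent joint: rows identical
  marg <- list(c(0.3, 0.7), c(0.6, 0.4))
  ind <- jointTable(as.vector(outer(marg[[1]], marg[[2]])), 2, 1, binaryLabels())
  ki <- kernelTable(conditionalKernel(ind, 1L, 2L))
  expect_lt(max(abs(ki[1, ] - ki[2, ])), 1e-12)
  expect_error(conditionalKernel(p, c(1, 2), c(2, 3)), "overlap")
})

test_that("the kernel recursion C_A(D|C) = C_A(CD)/C_A(C) holds exactly", {
  for (s in 1:6) {
    p <- randomJoint(5, seed = s + 50)
    a <- c(1L, 2L); cset <- 3L; d <- c(4L, 5L)
    kcd <- kernelTable(conditionalKernel(p, a, c(cset, d)))
    kc <- kernelTable(conditionalKernel(p, a, cset))
    # left side computed independently: condition on A union C, target D
    lhs <- kernelTable(conditionalKernel(p, c(a, cset), d))
    # align: row of lhs indexed by (A-config, C-config); C varies after A
    nS <- 2L
    for (ai in seq_len(nS^2)) for (ci in seq_len(nS)) {
      # in C_A(CD), target configs order (C, D) little-endian: C fastest
      rhs <- kcd[ai, ci + nS * (seq_len(nS^2) - 1L)] / kc[ai, ci]
      # in C_{A u C}(D) rows order (A, C) little-endian: A block fastest
      expect_lt(max(abs(rhs - lhs[ai + nS^2 * (ci - 1L), ])), 1e-10)
    }
  }
})

test_that("product-form CI detects forks and direct coupling", {
  # fork u <- s -> v built from explicit kernels: P(s) P(u|s) P(v|s)
  ps <- c(0.4, 0.6)
  pu <- rbind(c(0.8, 0.2), c(0.3, 0.7))   # P(u | s)
  pv <- rbind(c(0.1, 0.9), c(0.6, 0.4))   # P(v | s)
  w <- numeric(8)  # vertices (u=1, v=2, s=3), little-endian
  for (u in 1:2) for (v in 1:2) for (s in 1:2) {
    w[u + 2 * (v - 1) + 4 * (s - 1)] <- ps[s] * pu[s, u] * pv[s, v]
  }
  p <- jointTable(w, 3, 1, binaryLabels())
  expect_true(ciHolds(ciGivenSet(p, 1L, 2L, 3L)))
  expect_false(ciHolds(ciGivenSet(p, 1L, 2L)))  # marginally dependent
  # directly coupled pair with no conditioning
  fp <- gibbsField(mlGraph(2, 1, cbind(1, 2)), binaryLabels(),
                   list(potential(c(1, 2), matrix(c(3, 1, 1, 3), 2))))
  expect_false(ciHolds(ciGivenSet(toJointTable(fp), 1L, 2L)))
  # conditioning on everything else reproduces ciGivenRest
  p5 <- randomJoint(5, seed = 77)
  st1 <- ciGivenSet(p5, 2L, 4L, c(1L, 3L, 5L))
  st2 <- ciGivenRest(p5, 2L, 4L)
  expect_identical(ciDeviation(st1), ciDeviation(st2))
  expect_error(ciGivenSet(p5, 2L, 2L), "distinct")
})

test_that("pairwise Markov relations mirror the planted graph structure", {
  chain <- mlGraph(3, 1, edges = rbind(c(1, 2), c(2, 3)))
  f <- randomGibbsField(chain, strength = 1.2, seed = 9)
  p <- toJointTable(f)
  expect_true(ciHolds(ciGivenRest(p, 1L, 3L)))
  expect_false(ciHolds(ciGivenRest(p, 1L, 2L)))
  expect_false(ciHolds(ciGivenRest(p, 2L, 3L)))
  # independent joint: every pair conditionally independent
  marg <- list(c(0.3, 0.7), c(0.6, 0.4), c(0.25, 0.75))
  ind <- jointTable(as.vector(outer(outer(marg[[1]], marg[[2]]), marg[[3]])),
                    3, 1, binaryLabels())
  for (pr in list(c(1, 2), c(1, 3), c(2, 3))) {
    expect_true(ciHolds(ciGivenRest(ind, pr[1], pr[2])))
  }
  # vertices with no connecting path are CI given the rest (both directions)
  for (s in 1:5) {
    f <- randomField(3, 2, seed = s + 200, pIntra = 0.25, pInter = 0.15)
    p <- toJointTable(f)
    ig <- f@graph
    prs <- t(combn(6, 2))
    for (r in seq_len(nrow(prs))) {
      u <- prs[r, 1]; v <- prs[r, 2]
      if (separates(ig, u, v, setdiff(1:6, c(u, v)))) {
        noPath <- separates(ig, u, v, integer(0))
        # no direct edge => CI given the rest (pairwise Markov)
        st <- ciGivenRest(p, u, v)
        ek <- paste(edgeSet(ig)[, 1], edgeSet(ig)[, 2])
        if (!(paste(u, v) %in% ek)) expect_true(ciHolds(st))
      }
    }
  }
})

test_that("the count of pairwise sigma-algebra tests is choose(NL, 2)", {
  expect_identical(countPairwiseTests(4, 2), 28L)
  expect_identical(countPairwiseTests(1, 1), 0L)
  expect_identical(countPairwiseTests(3, 3), 36L)
  # equals the size of an all-pairs sweep
  p <- randomJoint(4, seed = 3, nVars = 2, nLayers = 2)
  sweep <- combn(4, 2, function(pr) ciDeviation(ciGivenRest(p, pr[1], pr[2])))
  expect_identical(length(sweep), as.integer(countPairwiseTests(2, 2)))
})

test_that("independence maps certify global Markov separations", {
  # the complete graph is an I-map of every positive distribution
  full <- mlGraph(2, 2, edges = t(combn(4, 2)))
  expect_true(isIndependenceMap(full, randomJoint(4, seed = 4))$pass)
  # the edgeless graph is an I-map only of a fully independent joint
  empty3 <- mlGraph(3, 1)
  marg <- list(c(0.3, 0.7), c(0.6, 0.4), c(0.25, 0.75))
  ind <- jointTable(as.vector(outer(outer(marg[[1]], marg[[2]]), marg[[3]])),
                    3, 1, binaryLabels())
  expect_true(isIndependenceMap(empty3, ind)$pass)
  dep <- toJointTable(randomGibbsField(mlGraph(3, 1, cbind(1, 2)), seed = 2))
  res <- isIndependenceMap(empty3, dep)
  expect_false(res$pass)
  expect_identical(sort(c(res$counterexample$a, res$counterexample$b)), c(1L, 2L))
  # planted fields: their own graph is an I-map (exhaustive check, 6 vertices)
  for (s in 1:3) {
    f <- randomField(3, 2, seed = s + 300)
    r <- isIndependenceMap(f@graph, toJointTable(f))
    expect_true(r$pass)
    expect_identical(r$mode, "exhaustive")
  }
  # reduced mode engages above the exhaustive limit and still passes
  f8 <- randomField(4, 2, seed = 11)
  r8 <- isIndependenceMap(f8@graph, toJointTable(f8))
  expect_identical(r8$mode, "reduced")
  expect_true(r8$pass)
  expect_error(isIndependenceMap(f8@graph, toJointTable(f8), maxVertices = 4),
               "guard")
})

test_that("perfect maps require both directions of the CI correspondence", {
  marg <- list(c(0.3, 0.7), c(0.6, 0.4), c(0.25, 0.75))
  ind <- jointTable(as.vector(outer(outer(marg[[1]], marg[[2]]), marg[[3]])),
                    3, 1, binaryLabels())
  expect_true(isPerfectMap(mlGraph(3, 1), ind))
  # an edge the distribution does not use breaks perfection (but not I-mapness)
  g1 <- mlGraph(3, 1, edges = cbind(1, 2))
  expect_false(isPerfectMap(g1, ind))
  expect_true(isIndependenceMap(g1, ind)$pass)
  chain <- mlGraph(3, 1, edges = rbind(c(1, 2), c(2, 3)))
  f <- randomGibbsField(chain, strength = 1.2, seed = 13)
  expect_true(isPerfectMap(chain, toJointTable(f)))
})

test_that("empirical CI testing distinguishes planted conditional structure", {
  # copied column: decisively dependent
  set.seed(31)
  vals <- array(sample(0:1, 600 * 2 * 2, TRUE), dim = c(600, 2, 2))
  vals[, 2, 1] <- vals[, 1, 1]
  st <- sampleTensor(vals)
  expect_false(ciHolds(empiricalCITest(st, 1L, 2L, seed = 5)))
  # u <- s -> v fork: u, v dependent marginally, independent given s
  n <- 1500
  holds <- logical(10)
  for (rep in 1:10) {
    set.seed(rep)
    s <- sample(0:1, n, TRUE)
    u <- ifelse(runif(n) < 0.85, s, 1 - s)
    v <- ifelse(runif(n) < 0.85, s, 1 - s)
    vals <- array(0, dim = c(n, 3, 1))
    vals[, 1, 1] <- u; vals[, 2, 1] <- v; vals[, 3, 1] <- s
    st <- sampleTensor(vals)
    expect_false(ciHolds(empiricalCITest(st, 1L, 2L, nPerm = 100, seed = rep)))
    holds[rep] <- ciHolds(empiricalCITest(st, 1L, 2L, s = 3L, nPerm = 100,
                                          seed = rep))
  }
  expect_gte(mean(holds), 0.8)
  expect_error(empiricalCITest(st, 1L, 2L, s = c(3L, 4L, 5L, 6L)), "guard")
})
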