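test_that("partition function and measure on hand-checkable fields", {
  # all potentials unit, 3 binary vertices: Z = |Omega| = 8, P uniform
  f <- gibbsField(mlGraph(3, 1), binaryLabels())
  expect_equal(partitionFunction(f), 8)
  expect_equal(gibbsProbability(f, c(1, 2, 1)), 1 / 8)
  expect_equal(energy(f, c(2, 2, 2)), 0)
  # single vertex, phi(s1) = 2, phi(s2) = 3
  f1 <- gibbsField(mlGraph(1, 1), binaryLabels(), list(potential(1L, c(2, 3))))
  expect_equal(partitionFunction(f1), 5)
  expect_equal(gibbsProbability(f1, 1L), 0.4)
  jt <- toJointTable(f1)
  expect_equal(jointProb(jt), c(0.4, 0.6))
  # matching pair potential phi = e contributes energy -1
  fp <- gibbsField(mlGraph(2, 1, cbind(1, 2)), binaryLabels(),
                   list(potential(c(1, 2),
                                  matrix(c(exp(1), 1, 1, exp(1)), 2))))
  expect_equal(energy(fp, c(1, 1)), -1)
  expect_equal(energy(fp, c(1, 2)), 0)
  # uniform 2-vertex table: four entries of 1/4
  expect_equal(jointProb(toJointTable(gibbsField(mlGraph(2, 1), binaryLabels()))),
               rep(0.25, 4))
})

test_that("exact joints match brute-force products and normalise", {
  for (s in 1:8) {
    f <- randomField(3, 2, seed = s)
    jt <- toJointTable(f)
    expect_equal(sum(jointProb(jt)), 1, tolerance = 1e-12)
    expect_equal(jointProb(jt), bruteJoint(f), tolerance = 1e-12)
    # energy/measure duality: P = exp(-U)/Z
    Z <- partitionFunction(f)
    set.seed(s)
    for (r in 1:4) {
      cfg <- sample(1:2, 6, TRUE)
      m <- 1 + sum((cfg - 1) * 2^(0:5))
      expect_equal(gibbsProbability(f, cfg), exp(-energy(f, cfg)) / Z,
                   tolerance = 1e-10)
      expect_equal(gibbsProbability(f, cfg), jointProb(jt)[m],
                   tolerance = 1e-12)
    }
  }
})

test_that("local characteristics equal full-joint conditionals and are local", {
  for (s in 1:10) {
    f <- randomField(3, 2, seed = s + 100)
    pr <- jointProb(toJointTable(f))
    set.seed(s)
    for (r in 1:3) {
      cfg <- sample(1:2, 6, TRUE)
      for (v in 1:6) {
        lc <- localCharacteristic(f, v, cfg)
        expect_lt(max(abs(lc - bruteConditional(pr, 6, 2, v, cfg))), 1e-10)
        expect_equal(sum(lc), 1, tolerance = 1e-12)
        # locality: perturbing any non-neighbour leaves the distribution unchanged
        outside <- setdiff(1:6, c(v, neighborsOf(f@graph, v)))
        if (length(outside)) {
          cfg2 <- cfg
          cfg2[outside[1L]] <- 3L - cfg2[outside[1L]]
          expect_identical(lc, localCharacteristic(f, v, cfg2))
        }
      }
    }
  }
  # isolated vertex with no potentials: uniform over labels
  f0 <- gibbsField(mlGraph(2, 1), binaryLabels())
  expect_equal(unname(localCharacteristic(f0, 1L, c(NA, 2L))), c(0.5, 0.5))
  # attractive pair potential, neighbour fixed at label 1: P(1) = e/(e+1)
  fp <- gibbsField(mlGraph(2, 1, cbind(1, 2)), binaryLabels(),
                   list(potential(c(1, 2),
                                  matrix(c(exp(1), 1, 1, exp(1)), 2))))
  expect_equal(unname(localCharacteristic(fp, 1L, c(NA, 1L))[1L]),
               exp(1) / (exp(1) + 1), tolerance = 1e-12)
})

test_that("exact sampling is reproducible and matches the joint", {
  f <- gibbsField(mlGraph(2, 1), binaryLabels())
  expect_identical(nSamples(exactSample(f, 0L, seed = 1)), 0L)
  s1 <- exactSample(f, 50L, seed = 42)
  s2 <- exactSample(f, 50L, seed = 42)
  expect_identical(stValues(s1), stValues(s2))
  # uniform field: each of the 4 configurations within 4 binomial SEs of 1/4
  big <- stValues(exactSample(f, 10000L, seed = 7))
  cfgKey <- big[, 1, 1] + 2 * big[, 2, 1]
  freq <- as.vector(table(cfgKey)) / 10000
  se <- sqrt(0.25 * 0.75 / 10000)
  expect_true(all(abs(freq - 0.25) < 4 * se))
})

test_that("the enumeration guard refuses oversized spaces", {
  f <- gibbsField(mlGraph(5, 1), binaryLabels())
  expect_error(partitionFunction(f, maxConfigs = 16), "guard")
  expect_error(toJointTable(f, maxConfigs = 16), "guard")
  expect_error(exactSample(f, 1L, seed = 1, maxConfigs = 16), "guard")
})

test_that("field documents round-trip exactly", {
  f <- randomField(3, 2, seed = 3)
  path <- withr::local_tempfile(fileext = ".txt")
  writeGibbsField(f, path)
  f2 <- readGibbsField(path)
  expect_same_graph(f@graph, f2@graph)
  expect_identical(f@labels@labels, f2@labels@labels)
  expect_identical(f@labels@defaultLabel, f2@labels@defaultLabel)
  expect_equal(jointProb(toJointTable(f2)), jointProb(toJointTable(f)),
               tolerance = 1e-12)
})

test_that("configuration and potential validation fails loudly", {
  f <- gibbsField(mlGraph(2, 1), binaryLabels())
  expect_error(energy(f, c(1L)), "assign all")
  expect_error(energy(f, c(1L, 5L)), "outside the label set")
  expect_error(potential(1L, c(1, 0)), "strictly positive")
  # a non-clique potential is rejected by the field validity check
  expect_error(gibbsField(mlGraph(2, 1), binaryLabels(),
                          list(potential(c(1, 2), matrix(1.5, 2, 2)))),
               "not a clique")
})

test_that("the heat-bath sampler approximates an enumerable field", {
  # single attractive edge: matched configurations are more likely
  fp <- gibbsField(mlGraph(2, 1, cbind(1, 2)), binaryLabels(),
                   list(potential(c(1, 2),
                                  matrix(c(exp(1), 1, 1, exp(1)), 2))))
  draws <- stValues(gibbsSample(fp, 300L, seed = 5, burnIn = 50L))
  agree <- mean(draws[, 1, 1] == draws[, 2, 1])
  # exact agreement probability is e/(e+1) ~ 0.731
  expect_gt(agree, 0.6)
  expect_identical(stValues(gibbsSample(fp, 10L, seed = 9, burnIn = 10L)),
                   stValues(gibbsSample(fp, 10L, seed = 9, burnIn = 10L)))
})
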