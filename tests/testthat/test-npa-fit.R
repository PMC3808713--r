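test_that("hand-checkable fits: star and two-node toy network", {
  # star b1 ->(+) g1, b1 ->(-) g2, beta = (2, -2): minimiser of
  # (2 - f)^2 + (-2 + f)^2 is f = 2
  ps <- fitBackboneValues(starNet(), contrastData(c("g1", "g2"), c(2, -2)))
  expect_equal(unname(nodeValues(ps)), 2)

  # toy network: stationarity 6 f1 - 2 f2 = 4, 4 f2 - 2 f1 = 1
  net <- toyNet()
  prof <- fitBackboneValues(net, toyContrast())
  expect_equal(nodeValues(prof), c(b1 = 0.9, b2 = 0.7))
  expect_equal(npaScore(net, prof), 0.04)
})

test_that("zero boundary gives zero harmonic extension and zero score", {
  for (net in list(toyNet(), toyXenobioticNetwork())) {
    ct <- contrastData(geneNodes(net), rep(0, length(geneNodes(net))),
                       varLog2fc = rep(0.01, length(geneNodes(net))))
    prof <- fitBackboneValues(net, ct)
    expect_equal(unname(nodeValues(prof)),
                 rep(0, length(backboneNodes(net))))
    expect_equal(npaScore(net, prof), 0)
    expect_true(all(nodeVariances(prof) >= 0))
  }
})

test_that("solver agrees with the QR least-squares oracle to 1e-8", {
  worst <- 0
  for (seed in 1:25) {
    net <- randomSmallNetwork(seed)
    ct <- randomContrastFor(net, seed + 500)
    fitted <- nodeValues(fitBackboneValues(net, ct))
    oracle <- oracleFitQR(net, ct)
    worst <- max(worst, max(abs(fitted - oracle[names(fitted)])))
  }
  expect_lt(worst, 1e-8)
})

test_that("solver agrees with direct BFGS minimisation of the energy", {
  for (seed in c(2, 9, 23)) {
    net <- randomSmallNetwork(seed)
    ct <- randomContrastFor(net, seed + 700)
    fitted <- nodeValues(fitBackboneValues(net, ct))
    oracle <- oracleFitOptim(net, ct)
    expect_equal(unname(fitted), unname(oracle[names(fitted)]),
                 tolerance = 1e-6)
    # and the fitted energy is no larger than the optimiser's
    expect_lte(energyOf(net, ct, unname(fitted)),
               energyOf(net, ct, unname(oracle[names(fitted)])) + 1e-10)
  }
})

test_that("fit and score are linear / degree-2 homogeneous in beta", {
  net <- toyNet()
  base <- toyContrast()
  f1 <- nodeValues(fitBackboneValues(net, base))
  for (c0 in c(2, -0.5, 3.25)) {
    scaled <- contrastData(geneIds(base), c0 * base@log2fc)
    fc <- nodeValues(fitBackboneValues(net, scaled))
    expect_equal(fc, c0 * f1)
    expect_equal(npaScore(net, fitBackboneValues(net, scaled)),
                 c0^2 * 0.04)
  }
  # doubling beta doubles f and quadruples the score: 0.04 -> 0.16
  doubled <- contrastData(geneIds(base), 2 * base@log2fc)
  expect_equal(npaScore(net, fitBackboneValues(net, doubled)), 0.16)
})

test_that("gauge invariance: flipping one node's incident signs and value", {
  for (seed in c(4, 31)) {
    net <- randomSmallNetwork(seed)
    ct <- randomContrastFor(net, seed + 900)
    v <- withr::with_seed(seed, sample(backboneNodes(net), 1L))

    flipped <- net
    be <- backboneEdges(net)
    hit <- be$source == v | be$target == v
    be$sign[hit] <- -be$sign[hit]
    ee <- evidenceEdges(net)
    hitE <- ee$source == v
    ee$sign[hitE] <- -ee$sign[hitE]
    flipped@backboneEdges <- be
    flipped@evidenceEdges <- ee

    f0 <- nodeValues(fitBackboneValues(net, ct))
    f1 <- nodeValues(fitBackboneValues(flipped, ct))
    expected <- f0; expected[v] <- -expected[v]
    expect_equal(f1, expected, tolerance = 1e-10)
    expect_equal(npaScore(flipped, fitBackboneValues(flipped, ct)),
                 npaScore(net, fitBackboneValues(net, ct)),
                 tolerance = 1e-10)
    expect_equal(energyOf(flipped, ct, unname(f1)),
                 energyOf(net, ct, unname(f0)), tolerance = 1e-10)
  }
})

test_that("semi-norm: non-negative, zero iff sign-consistent across edges", {
  for (seed in c(6, 13, 27)) {
    net <- randomSmallNetwork(seed)
    ct <- randomContrastFor(net, seed + 1100)
    prof <- fitBackboneValues(net, ct)
    s <- npaScore(net, prof)
    expect_gte(s, 0)
    be <- backboneEdges(net)
    f <- nodeValues(prof)
    residuals <- f[be$source] - be$sign * f[be$target]
    if (s < 1e-14) expect_true(all(abs(residuals) < 1e-7))
    if (any(abs(residuals) > 1e-6)) expect_gt(s, 0)
  }
})

test_that("an evidence edge matching the fitted prediction changes nothing", {
  net <- toyNet()
  ct <- toyContrast()
  f <- nodeValues(fitBackboneValues(net, ct))
  # new gene on b2 with negative sign whose beta equals s * f(b2)
  aug <- rbind(toyEdges(), data.frame(
    source = "b2", relation = "decreases", target = "g4",
    layer = "evidence"))
  netAug <- parseNetwork(aug)
  ctAug <- contrastData(c(geneIds(ct), "g4"),
                        c(ct@log2fc, -1 * unname(f["b2"])))
  fAug <- nodeValues(fitBackboneValues(netAug, ctAug))
  expect_equal(fAug, f, tolerance = 1e-12)
})

test_that("unmeasured genes drop edges with a warning; singularity errors", {
  net <- toyNet()
  partial <- contrastData(c("g1", "g2"), c(1, -1))  # g3 unmeasured
  expect_warning(prof <- fitBackboneValues(net, partial),
                 "without measurement")
  expect_true(all(is.finite(nodeValues(prof))))

  # a second component whose only gene is unmeasured becomes singular
  twoComp <- rbind(toyEdges(), data.frame(
    source = c("c1", "c1"), relation = "increases",
    target = c("c2", "h1"), layer = c("backbone", "evidence")))
  net2 <- parseNetwork(twoComp)
  expect_error(
    suppressWarnings(fitBackboneValues(net2, toyContrast())),
    "singular.*c1")
})

test_that("degenerate norm without backbone edges needs the ridge term", {
  net <- starNet()
  ct <- contrastData(c("g1", "g2"), c(2, -2))
  prof <- fitBackboneValues(net, ct)
  expect_error(npaScore(net, prof), "alphaRidge")
  # with the ridge the score is alpha * mean(f^2) = 0.5 * 4
  expect_equal(npaScore(net, prof, alphaRidge = 0.5), 2)
})
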