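test_that("CI width is zero for exact fold changes and brackets Monte Carlo", {
  net <- toyNet()
  exact <- contrastData(c("g1", "g2", "g3"), c(1, -1, 0.5),
                        varLog2fc = rep(0, 3L))
  ci0 <- npaConfidenceInterval(net, exact)
  expect_equal(unname(ci0), c(0.04, 0.04))

  # Monte-Carlo oracle: resample beta ~ N(beta_hat, 0.01 I), recompute the
  # NPA through an independent fit route, compare percentile interval
  ct <- toyContrast(varBeta = rep(0.01, 3L))
  ci <- npaConfidenceInterval(net, ct)
  nMC <- 1e5L
  scores <- withr::with_seed(42, {
    B <- matrix(rnorm(3L * nMC, mean = c(1, -1, 0.5), sd = 0.1), nrow = 3L)
    # closed-form fit for this network: f1 = (4 b~)/..., use the QR oracle
    apply(B, 2L, function(b) {
      f <- oracleFitQR(net, contrastData(c("g1", "g2", "g3"), b))
      (f["b1"] - f["b2"])^2
    })
  })
  emp <- unname(stats::quantile(scores, c(0.025, 0.975)))
  emp[1L] <- max(0, emp[1L])
  formulaWidth <- ci[2L] - ci[1L]
  empWidth <- emp[2L] - emp[1L]
  expect_lt(abs(formulaWidth - empWidth) / empWidth, 0.15)
  # the formula interval brackets the empirical one within that slack
  expect_lt(ci[1L], emp[1L] + 0.15 * empWidth)
  expect_gt(ci[2L], emp[2L] - 0.15 * empWidth)
})

test_that("null beta gives a CI containing zero", {
  net <- toyNet()
  ct <- contrastData(c("g1", "g2", "g3"), rep(0, 3L),
                     varLog2fc = rep(0.01, 3L))
  ci <- npaConfidenceInterval(net, ct)
  expect_equal(unname(ci[1L]), 0)  # truncated lower bound
  expect_gte(ci[2L], 0)
})

test_that("*O: degenerate inputs give p = 1 with a warning", {
  net <- toyNet()
  ct0 <- contrastData(c("g1", "g2", "g3"), rep(0, 3L),
                      varLog2fc = rep(0.01, 3L))
  expect_warning(p <- permutationTestO(net, ct0, nPerm = 99, seed = 1),
                 "degenerate")
  expect_equal(as.numeric(p), 1)
})

test_that("*O detects a strong coherent signal and is reproducible", {
  cfg <- simulationConfig(noiseSd = 0.05, seed = 1L)
  net <- generateNetwork(cfg)
  truth <- simulateContrast(
    net, withr::with_seed(2, rnorm(length(backboneNodes(net)))),
    noiseSd = 0.05, nReplicates = 3L, seed = 3L)
  p1 <- permutationTestO(net, truth@contrast, nPerm = 500L, seed = 1L)
  expect_lte(as.numeric(p1), 0.05)
  # bit-for-bit reproducible given (seed, nPerm)
  p2 <- permutationTestO(net, truth@contrast, nPerm = 500L, seed = 1L)
  expect_identical(as.numeric(p1), as.numeric(p2))
  expect_identical(attr(p1, "permScores"), attr(p2, "permScores"))
  p3 <- permutationTestO(net, truth@contrast, nPerm = 500L, seed = 2L)
  expect_false(identical(attr(p1, "permScores"), attr(p3, "permScores")))
})

test_that("K*: degenerate two-node backbone warns and returns p = 1", {
  net <- toyNet()  # 2 backbone nodes, 1 backbone edge, all-positive signs
  expect_warning(p <- permutationTestK(net, toyContrast(), nPerm = 50,
                                       seed = 1),
                 "single configuration")
  expect_equal(as.numeric(p), 1)
})

test_that("K*: null scores are non-negative and an incoherent profile sits in the upper tail", {
  net <- toyXenobioticNetwork()
  # truth constructed to violate backbone sign-consistency edge by edge:
  # the regime in which the wiring genuinely contributes to the amplitude
  truth <- antiSmoothTruth(net)
  sim <- simulateContrast(net, truth, noiseSd = 0.05, nReplicates = 3L,
                          seed = 11L)
  p <- permutationTestK(net, sim@contrast, nPerm = 200L, seed = 5L)
  scores <- attr(p, "permScores")
  expect_true(all(scores >= 0))
  obs <- npaScore(net, fitBackboneValues(net, sim@contrast))
  expect_gt(obs, stats::quantile(scores, 0.9))
  expect_lte(as.numeric(p), 0.05)
  # reproducibility
  p2 <- permutationTestK(net, sim@contrast, nPerm = 200L, seed = 5L)
  expect_identical(as.numeric(p), as.numeric(p2))
})

test_that("significance verdict combines CI and both permutation tests", {
  expect_equal(significanceCall(c(0.1, 0.5), 0.01, 0.02),
               "significant_and_specific")
  expect_equal(significanceCall(c(0.1, 0.5), 0.20, 0.02),
               "significant_not_specific")
  expect_equal(significanceCall(c(-0.05, 0.30), 0.001, 0.001),
               "not_significant")
  expect_equal(significanceCall(c(0, 0.30), 0.001, 0.001),
               "not_significant")  # truncated-at-zero lower bound
  expect_equal(significanceCall(c(NA, NA), 0.001, 0.001),
               "not_significant")
})

test_that("the full analysis wrapper is coherent on the toy fixture", {
  net <- toyNet()
  res <- suppressWarnings(npa(net, toyContrast(), nPerm = 99L, seed = 7L))
  expect_s4_class(res$profile, "BackboneProfile")
  expect_s4_class(res$result, "NPAResult")
  expect_equal(npaScoreValue(res$result), 0.04)
  expect_identical(res$result@verdict,
                   significanceCall(c(res$result@ciLow, res$result@ciHigh),
                                    res$result@pO, res$result@pK))
})
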