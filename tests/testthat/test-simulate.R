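test_that("generation is deterministic under seed, down to the TSV bytes", {
  cfg <- simulationConfig(nBackbone = 2L, nGenes = 3L, seed = 13L)
  n1 <- generateNetwork(cfg)
  n2 <- generateNetwork(cfg)
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeNetwork(n1, f1); writeNetwork(n2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("sign probability zero gives all-positive edges", {
  cfg <- simulationConfig(nBackbone = 5L, nGenes = 20L,
                          negativeSignProb = 0, seed = 3L)
  net <- generateNetwork(cfg)
  expect_true(all(backboneEdges(net)$sign == 1))
  expect_true(all(evidenceEdges(net)$sign == 1))
})

test_that("every generated network is identifiable by construction", {
  for (seed in 1:100) {
    cfg <- withr::with_seed(seed, simulationConfig(
      nBackbone = sample(2:15, 1L),
      nGenes = sample(15:60, 1L),
      backboneEdgeProb = runif(1, 0, 0.6),
      negativeSignProb = runif(1, 0, 1),
      genesPerBackbone = sample(1:6, 1L),
      seed = seed))
    net <- generateNetwork(cfg)
    expect_true(isValid(validateNetwork(net)))
    expect_true(all(backboneNodes(net) %in%
                      unique(evidenceEdges(net)$source)))
  }
})

test_that("noiseless limit recovers signed parent activity exactly", {
  cfg <- simulationConfig(nBackbone = 6L, nGenes = 30L,
                          genesPerBackbone = 5L, seed = 5L)
  net <- generateNetwork(cfg)
  truth <- withr::with_seed(6, rnorm(6))
  sim <- simulateContrast(net, truth, noiseSd = 1e-9, nReplicates = 3L,
                          seed = 7L)
  # single-parent genes carry s * f*(parent)
  ee <- evidenceEdges(net)
  nParents <- table(ee$target)
  single <- names(nParents)[nParents == 1L]
  eeS <- ee[ee$target %in% single, ]
  expected <- setNames(eeS$sign * sim@trueBackboneValues[eeS$source],
                       eeS$target)
  got <- log2fc(sim@contrast)[names(expected)]
  expect_lt(max(abs(got - expected)), 1e-6)
  # and matches the recorded expected fold change for every gene
  expect_lt(max(abs(log2fc(sim@contrast) -
                      sim@expectedGeneFc[geneIds(sim@contrast)])), 1e-6)
})

test_that("simulated contrast variance follows sampling theory", {
  cfg <- simulationConfig(nBackbone = 10L, nGenes = 2000L,
                          genesPerBackbone = 200L, seed = 15L)
  net <- generateNetwork(cfg)
  truth <- withr::with_seed(16, rnorm(10))
  noiseSd <- 0.2; nRep <- 4L
  sim <- simulateContrast(net, truth, noiseSd = noiseSd,
                          nReplicates = nRep, seed = 17L)
  expected <- 2 * noiseSd^2 / nRep
  observed <- mean(varLog2fc(sim@contrast))
  expect_lt(abs(observed - expected) / expected, 0.10)
})

test_that("null simulations rarely reach a significant verdict", {
  net <- toyXenobioticNetwork()
  zero <- setNames(rep(0, length(backboneNodes(net))), backboneNodes(net))
  notSig <- 0L
  nRuns <- 100L
  for (seed in seq_len(nRuns)) {
    sim <- simulateContrast(net, zero, noiseSd = 0.1, seed = seed)
    ci <- npaConfidenceInterval(net, sim@contrast)
    if (!(ci[1L] > 0)) notSig <- notSig + 1L
  }
  expect_gte(notSig, 0.9 * nRuns)
})

test_that("recovery: accurate at default noise, degrades monotonically", {
  res <- recoveryExperiment(simulationConfig(), nPerm = 100L)
  expect_gte(res$recoveryPearson, 0.9)
  expect_s4_class(res$npaResult, "NPAResult")

  medianRecovery <- function(noiseSd) {
    r <- vapply(1:20, function(seed) {
      cfg <- simulationConfig(noiseSd = noiseSd, seed = seed)
      net <- generateNetwork(cfg)
      truth <- withr::with_seed(cfg$seed + 1L,
                                rnorm(length(backboneNodes(net))))
      sim <- simulateContrast(net, truth, noiseSd = noiseSd,
                              nReplicates = 3L, seed = cfg$seed + 2L)
      cor(truth, unname(nodeValues(fitBackboneValues(net, sim@contrast))))
    }, numeric(1L))
    median(r)
  }
  expect_gt(medianRecovery(0.1), medianRecovery(2.0))
})

test_that("recovery improves with denser gene coverage", {
  medianAt <- function(gpb, nGenes) {
    r <- vapply(1:20, function(seed) {
      cfg <- simulationConfig(nGenes = nGenes, genesPerBackbone = gpb,
                              noiseSd = 0.75, seed = seed)
      net <- generateNetwork(cfg)
      truth <- withr::with_seed(seed + 1L,
                                rnorm(length(backboneNodes(net))))
      sim <- simulateContrast(net, truth, noiseSd = 0.75,
                              nReplicates = 3L, seed = seed + 2L)
      cor(truth, unname(nodeValues(fitBackboneValues(net, sim@contrast))))
    }, numeric(1L))
    median(r)
  }
  expect_gt(medianAt(20L, 200L), medianAt(2L, 20L))
})

test_that("null truth gives an uninformative recovery and null verdict", {
  cfg <- simulationConfig(trueBackboneValues = "zero", seed = 19L)
  res <- recoveryExperiment(cfg, nPerm = 50L)
  expect_true(is.na(res$recoveryPearson))
  expect_equal(res$npaResult@verdict, "not_significant")
})
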