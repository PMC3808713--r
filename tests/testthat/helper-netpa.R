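# Shared fixtures and independent oracles for the test suite.

# 2 backbone nodes, 3 genes, 1 backbone edge; fit has the closed form
# 6 f1 - 2 f2 = 4, 4 f2 - 2 f1 = 1 at beta = (1, -1, 0.5) => f = (0.9, 0.7)
toyEdges <- function() {
  data.frame(
    source = c("b1", "b1", "b2", "b1"),
    relation = c("increases", "decreases", "increases", "increases"),
    target = c("g1", "g2", "g3", "b2"),
    layer = c("evidence", "evidence", "evidence", "backbone"),
    stringsAsFactors = FALSE
  )
}

toyNet <- function() parseNetwork(toyEdges(), name = "toy")

toyContrast <- function(beta = c(1, -1, 0.5), varBeta = rep(0.01, 3)) {
  contrastData(c("g1", "g2", "g3"), beta, varLog2fc = varBeta,
               label = "toy contrast")
}

starNet <- function() {
  parseNetwork(data.frame(
    source = "b1", relation = c("increases", "decreases"),
    target = c("g1", "g2"), layer = "evidence"), name = "star")
}

# random small identifiable network: <= 6 backbone nodes, <= 12 genes
randomSmallNetwork <- function(seed) {
  cfg <- withr::with_seed(seed, {
    m <- sample(2:6, 1L)
    ng <- sample(m:12L, 1L)
    simulationConfig(
      nBackbone = m, nGenes = ng,
      backboneEdgeProb = runif(1, 0.2, 0.7),
      negativeSignProb = runif(1, 0, 0.6),
      genesPerBackbone = max(1L, round(1.5 * ng / m)),
      noiseSd = 0.1, seed = seed)
  })
  generateNetwork(cfg)
}

randomContrastFor <- function(net, seed, sd = 1) {
  genes <- geneNodes(net)
  withr::with_seed(seed, contrastData(
    genes, rnorm(length(genes), 0, sd),
    varLog2fc = runif(length(genes), 0.005, 0.05),
    label = paste0("random-", seed)))
}

# Independent solver oracle: every energy term is one residual row of an
# overdetermined linear system solved by QR least squares -- a different
# algorithmic route than the package's normal-equation sparse solve.
oracleFitQR <- function(net, contrast) {
  bb <- backboneNodes(net)
  idx <- setNames(seq_along(bb), bb)
  beta <- log2fc(contrast)
  ee <- evidenceEdges(net)
  ee <- ee[ee$target %in% names(beta), , drop = FALSE]
  be <- backboneEdges(net)
  nr <- nrow(be) + nrow(ee)
  X <- matrix(0, nr, length(bb))
  y <- numeric(nr)
  r <- 0L
  if (nrow(be)) for (k in seq_len(nrow(be))) {
    r <- r + 1L
    X[r, idx[be$source[k]]] <- 1
    X[r, idx[be$target[k]]] <- X[r, idx[be$target[k]]] - be$sign[k]
  }
  for (k in seq_len(nrow(ee))) {
    r <- r + 1L
    X[r, idx[ee$source[k]]] <- ee$sign[k]
    y[r] <- beta[ee$target[k]]
  }
  setNames(as.numeric(qr.coef(qr(X), y)), bb)
}

# Second oracle: direct numerical minimisation of the energy by BFGS
# (generic quasi-Newton; looser agreement than the QR route).
energyOf <- function(net, contrast, f) {
  f <- setNames(f, backboneNodes(net))
  beta <- log2fc(contrast)
  be <- backboneEdges(net)
  ee <- evidenceEdges(net)
  ee <- ee[ee$target %in% names(beta), , drop = FALSE]
  e <- 0
  if (nrow(be))
    e <- e + sum((f[be$source] - be$sign * f[be$target])^2)
  e + sum((beta[ee$target] - ee$sign * f[ee$source])^2)
}

oracleFitOptim <- function(net, contrast) {
  m <- length(backboneNodes(net))
  fit <- optim(rep(0, m), function(f) energyOf(net, contrast, f),
               method = "BFGS",
               control = list(reltol = 1e-15, maxit = 5000))
  setNames(fit$par, backboneNodes(net))
}

# a truth vector that maximally violates backbone sign-consistency:
# f*_x = -s f*_y along a spanning traversal, the regime the K* rewiring
# test is designed to detect
antiSmoothTruth <- function(net, magnitude = 2) {
  bb <- backboneNodes(net)
  f <- setNames(rep(NA_real_, length(bb)), bb)
  be <- backboneEdges(net)
  f[bb[1L]] <- magnitude
  repeat {
    done <- TRUE
    for (k in seq_len(nrow(be))) {
      s <- be$source[k]; t <- be$target[k]; sg <- be$sign[k]
      if (!is.na(f[s]) && is.na(f[t])) { f[t] <- -sg * f[s]; done <- FALSE }
      if (is.na(f[s]) && !is.na(f[t])) { f[s] <- -sg * f[t]; done <- FALSE }
    }
    if (done) break
  }
  f[is.na(f)] <- magnitude
  f
}
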