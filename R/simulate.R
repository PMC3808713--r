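#' Simulation configuration
#'
#' Bundles and validates the parameters of the synthetic two-layer study:
#' a signed backbone graph, genes attached to one or more backbone nodes
#' with signs, a known true backbone-activity vector, and two-group
#' replicate log2 expression with Gaussian noise. Defaults mirror a small
#' transcriptomic exposure study: triplicate groups, log2-scale noise sd
#' 0.1, microarray-like baselines, and a 10-node backbone driving 200
#' genes (about 20 genes per backbone node).
#'
#' @param nBackbone number of backbone nodes (>= 2).
#' @param nGenes number of genes (>= nBackbone).
#' @param backboneEdgeProb directed Erdos-Renyi edge probability for the
#'   backbone layer (connectivity is patched afterwards).
#' @param negativeSignProb probability of a -1 sign, both layers.
#' @param genesPerBackbone mean number of genes attached per backbone node;
#'   extra parents per gene are Poisson with mean
#'   `max(0, genesPerBackbone * nBackbone / nGenes - 1)`.
#' @param trueBackboneValues `"gaussian(sd)"` (e.g. `"gaussian(1)"`),
#'   `"zero"` (the all-zero null), or a numeric vector of length
#'   `nBackbone`.
#' @param noiseSd replicate noise sd on the log2 scale (> 0).
#' @param nReplicates samples per group (>= 2).
#' @param seed integer seed; all generation is deterministic given the
#'   config (R's default Mersenne-Twister RNG).
#' @return a validated `simulationConfig` list.
#' @export
simulationConfig <- function(nBackbone = 10L, nGenes = 200L,
                             backboneEdgeProb = 0.25,
                             negativeSignProb = 0.3,
                             genesPerBackbone = 20L,
                             trueBackboneValues = "gaussian(1)",
                             noiseSd = 0.1, nReplicates = 3L, seed = 7L) {
  stopifnot(nBackbone >= 2L, nGenes >= nBackbone,
            backboneEdgeProb >= 0, backboneEdgeProb <= 1,
            negativeSignProb >= 0, negativeSignProb <= 1,
            genesPerBackbone >= 1, noiseSd > 0, nReplicates >= 2L)
  if (is.numeric(trueBackboneValues) &&
      length(trueBackboneValues) != nBackbone)
    stop("trueBackboneValues vector must have length nBackbone")
  if (is.character(trueBackboneValues) &&
      !grepl("^(zero|gaussian\\([0-9.]+\\))$", trueBackboneValues))
    stop("trueBackboneValues spec must be 'zero' or 'gaussian(sd)'")
  structure(list(
    nBackbone = as.integer(nBackbone), nGenes = as.integer(nGenes),
    backboneEdgeProb = backboneEdgeProb,
    negativeSignProb = negativeSignProb,
    genesPerBackbone = genesPerBackbone,
    trueBackboneValues = trueBackboneValues,
    noiseSd = noiseSd, nReplicates = as.integer(nReplicates),
    seed = as.integer(seed), rng = "Mersenne-Twister"
  ), class = "simulationConfig")
}

.resolveTrueValues <- function(config, nodes) {
  tv <- config$trueBackboneValues
  if (is.numeric(tv)) return(setNames(as.numeric(tv), nodes))
  if (identical(tv, "zero")) return(setNames(rep(0, length(nodes)), nodes))
  sd <- as.numeric(sub("^gaussian\\(([0-9.]+)\\)$", "\\1", tv))
  setNames(rnorm(length(nodes), 0, sd), nodes)
}

#' Generate a random identifiable two-layer network
#'
#' Backbone: directed Erdos-Renyi at `backboneEdgeProb`, then patched to a
#' single connected component by adding spanning edges between components;
#' signs are -1 with probability `negativeSignProb`. Evidence: the first
#' `nBackbone` genes are dealt one per backbone node so every node carries
#' at least one gene (hence the network is always identifiable), remaining
#' genes draw a uniform parent; each gene gains Poisson-distributed extra
#' parents (mean chosen so the average attachment matches
#' `genesPerBackbone`). Deterministic under the config seed.
#'
#' @param config a [simulationConfig()].
#' @return a [TwoLayerNetwork-class] that passes [validateNetwork()].
#' @export
generateNetwork <- function(config) {
  stopifnot(inherits(config, "simulationConfig"))
  withr::with_seed(config$seed, .generateNetworkImpl(config))
}

.generateNetworkImpl <- function(config) {
  m <- config$nBackbone
  ng <- config$nGenes
  bb <- sprintf("B%02d", seq_len(m))
  gg <- sprintf("G%04d", seq_len(ng))

  # directed ER backbone
  pairs <- expand.grid(s = seq_len(m), t = seq_len(m))
  pairs <- pairs[pairs$s != pairs$t, ]
  keep <- runif(nrow(pairs)) < config$backboneEdgeProb
  es <- pairs[keep, , drop = FALSE]
  # drop anti-parallel duplicates of the same unordered pair: one energy
  # term per causal link keeps the fit's edge weighting uniform
  unord <- paste(pmin(es$s, es$t), pmax(es$s, es$t))
  es <- es[!duplicated(unord), , drop = FALSE]

  # patch to connectivity with spanning edges between components
  repeat {
    g <- igraph::graph_from_edgelist(
      cbind(bb[es$s], bb[es$t]), directed = FALSE)
    g <- igraph::add_vertices(g, length(setdiff(bb, igraph::V(g)$name)),
                              name = setdiff(bb, igraph::V(g)$name))
    comp <- igraph::components(g)$membership[bb]
    if (max(comp) == 1L) break
    a <- which(comp == 1L)[1L]
    b <- which(comp == min(setdiff(comp, comp[a])))[1L]
    es <- rbind(es, data.frame(s = a, t = b))
  }
  beSign <- ifelse(runif(nrow(es)) < config$negativeSignProb, -1, 1)
  be <- data.frame(source = bb[es$s], target = bb[es$t], sign = beSign,
                   stringsAsFactors = FALSE)

  # evidence layer: guaranteed coverage, then uniform attachment
  parent1 <- c(seq_len(m), sample.int(m, ng - m, replace = TRUE))
  lambdaExtra <- max(0, config$genesPerBackbone * m / ng - 1)
  ee <- data.frame(gene = seq_len(ng), parent = parent1)
  if (lambdaExtra > 0) {
    nExtra <- rpois(ng, lambdaExtra)
    for (gi in which(nExtra > 0)) {
      others <- setdiff(seq_len(m), ee$parent[ee$gene == gi])
      k <- min(nExtra[gi], length(others))
      if (k > 0) {
        picked <- others[sample.int(length(others), k)]
        ee <- rbind(ee, data.frame(gene = gi, parent = picked))
      }
    }
  }
  eeSign <- ifelse(runif(nrow(ee)) < config$negativeSignProb, -1, 1)
  evidence <- data.frame(source = bb[ee$parent], target = gg[ee$gene],
                         sign = eeSign, stringsAsFactors = FALSE)

  ord <- function(e) {
    e <- e[order(e$source, e$target), , drop = FALSE]
    rownames(e) <- NULL
    e
  }
  net <- new("TwoLayerNetwork", backboneNodes = bb, geneNodes = gg,
             backboneEdges = ord(be), evidenceEdges = ord(evidence),
             name = sprintf("simulated-%d", config$seed))
  validObject(net)
  net
}

#' Simulate a two-group contrast with known backbone truth
#'
#' Implements the generative counterpart of the two-layer model: each
#' gene's expected log2 fold change is the mean over its evidence edges of
#' sign times the true parent activity (the mean, not the sum, matches the
#' least-squares geometry of the fit, so noiseless recovery is exact).
#' Per-gene baselines are drawn once from Normal(7, 1) (microarray-like
#' log2 intensities); control replicates are baseline + noise, treated
#' replicates baseline + expected fold change + noise, with iid
#' Normal(0, noiseSd^2) noise. The contrast is then computed with
#' [computeContrast()], exactly as a user would from real data.
#'
#' @param net a [TwoLayerNetwork-class].
#' @param trueValues named numeric of true backbone activities (names =
#'   backbone nodes), or unnamed in backbone-node order.
#' @param noiseSd replicate noise sd (> 0).
#' @param nReplicates samples per group (>= 2).
#' @param seed integer seed.
#' @return a [SimulationTruth-class].
#' @export
simulateContrast <- function(net, trueValues, noiseSd = 0.1,
                             nReplicates = 3L, seed = 7L) {
  stopifnot(is(net, "TwoLayerNetwork"), noiseSd > 0, nReplicates >= 2L)
  bb <- net@backboneNodes
  if (length(trueValues) != length(bb))
    stop("trueValues must have one entry per backbone node")
  if (is.null(names(trueValues))) names(trueValues) <- bb
  if (!setequal(names(trueValues), bb))
    stop("trueValues names must match the backbone nodes")
  trueValues <- trueValues[bb]

  ee <- net@evidenceEdges
  contrib <- ee$sign * trueValues[ee$source]
  expectedFc <- tapply(contrib, factor(ee$target, levels = net@geneNodes),
                       mean)
  expectedFc <- setNames(as.numeric(expectedFc), net@geneNodes)
  expectedFc[is.na(expectedFc)] <- 0

  ng <- length(net@geneNodes)
  withr::with_seed(seed, {
    baseline <- rnorm(ng, 7, 1)
    noise <- matrix(rnorm(ng * 2L * nReplicates, 0, noiseSd), nrow = ng)
    ctl <- baseline + noise[, seq_len(nReplicates), drop = FALSE]
    trt <- baseline + expectedFc +
      noise[, nReplicates + seq_len(nReplicates), drop = FALSE]
    expr <- cbind(ctl, trt)
    rownames(expr) <- net@geneNodes
    colnames(expr) <- c(sprintf("ctl_%d", seq_len(nReplicates)),
                        sprintf("trt_%d", seq_len(nReplicates)))
    groups <- rep(c("control", "treated"), each = nReplicates)
    contrast <- computeContrast(expr, groups,
                                label = sprintf("simulated (seed %d)", seed))
    new("SimulationTruth", network = net, trueBackboneValues = trueValues,
        expectedGeneFc = expectedFc, expression = expr, groups = groups,
        contrast = contrast)
  })
}

#' End-to-end parameter-recovery experiment
#'
#' Runs generate -> simulate -> fit -> score -> permutation tests under a
#' single configuration and reports how well the fitted backbone values
#' recover the simulated truth. This is the package's own validation
#' harness: on identifiable networks with informative gene coverage the
#' fitted profile should correlate strongly with the truth, and the NPA
#' verdict should track whether a true perturbation was present.
#'
#' @param config a [simulationConfig()].
#' @param nPerm permutations for the *O and K* tests, default 200.
#' @return list with `recoveryPearson` (Pearson correlation of true vs
#'   fitted backbone values; `NA` when the truth is constant, e.g. the
#'   all-zero null), `npaResult` (an [NPAResult-class]), `profile`,
#'   `truth` (a [SimulationTruth-class]) and `config`.
#' @export
recoveryExperiment <- function(config = simulationConfig(), nPerm = 200L) {
  stopifnot(inherits(config, "simulationConfig"))
  net <- generateNetwork(config)
  trueValues <- withr::with_seed(config$seed + 1L,
                                 .resolveTrueValues(config,
                                                    net@backboneNodes))
  truth <- simulateContrast(net, trueValues, noiseSd = config$noiseSd,
                            nReplicates = config$nReplicates,
                            seed = config$seed + 2L)
  res <- npa(net, truth@contrast, nPerm = nPerm, seed = config$seed + 3L)
  fitted <- nodeValues(res$profile)[net@backboneNodes]
  recovery <- if (sd(trueValues) == 0 || sd(fitted) == 0) NA_real_
              else cor(trueValues, fitted)
  list(recoveryPearson = recovery, npaResult = res$result,
       profile = res$profile, truth = truth, config = config)
}

#' Packaged toy xenobiotic-style network
#'
#' A small deterministic 12-backbone / 150-gene two-layer network used in
#' documentation and golden tests, loosely shaped like a xenobiotic
#' metabolism model: a receptor-activity hub (`AHR`) feeding phase I/II/III
#' response nodes, and a repressor node (`AHRR`) attached through negative
#' edges. Built in code (no file access); the same network ships as TSV
#' under `inst/extdata/toy_network.tsv`.
#'
#' @return a [TwoLayerNetwork-class].
#' @export
toyXenobioticNetwork <- function() {
  bb <- c("AHR", "AHRR", "CAR", "PXR", "NRF2", "OxidativeStress",
          "PhaseI_oxidation", "PhaseII_conjugation", "PhaseIII_transport",
          "GSH_synthesis", "NicotineMetabolism", "PAH_activation")
  be <- data.frame(
    source = c("AHR", "AHR", "AHRR", "AHR", "AHR", "CAR", "PXR",
               "NRF2", "NRF2", "OxidativeStress", "PhaseI_oxidation",
               "PhaseI_oxidation", "PhaseII_conjugation", "CAR"),
    target = c("AHRR", "PhaseI_oxidation", "AHR", "PAH_activation",
               "NicotineMetabolism", "PhaseI_oxidation",
               "PhaseIII_transport", "PhaseII_conjugation",
               "GSH_synthesis", "NRF2", "OxidativeStress",
               "PAH_activation", "PhaseIII_transport", "PXR"),
    sign = c(1, 1, -1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1),
    stringsAsFactors = FALSE
  )
  # 150 genes dealt round-robin over the 12 nodes; every 7th edge negative,
  # AHRR targets mostly repressed
  nGenes <- 150L
  parent <- rep(seq_along(bb), length.out = nGenes)
  gene <- sprintf("%s_g%02d", bb[parent],
                  stats::ave(parent, parent, FUN = seq_along))
  sign <- ifelse(seq_len(nGenes) %% 7L == 0L, -1, 1)
  sign[bb[parent] == "AHRR"] <- -1
  ee <- data.frame(source = bb[parent], target = gene, sign = sign,
                   stringsAsFactors = FALSE)
  # a few multi-parent genes: first gene of each phase node also listens
  # to AHR
  extra <- ee$target[ee$source %in% c("PhaseI_oxidation",
                                      "PhaseII_conjugation",
                                      "PhaseIII_transport")][1:3]
  ee <- rbind(ee, data.frame(source = "AHR", target = extra, sign = 1,
                             stringsAsFactors = FALSE))
  ord <- function(e) {
    e <- e[order(e$source, e$target), , drop = FALSE]
    rownames(e) <- NULL
    e
  }
  net <- new("TwoLayerNetwork", backboneNodes = sort(bb),
             geneNodes = sort(unique(ee$target)),
             backboneEdges = ord(be), evidenceEdges = ord(ee),
             name = "toy-xenobiotic")
  validObject(net)
  net
}
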