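# --- internal energy model -------------------------------------------------
#
# The fit minimises, over backbone values f with gene values fixed at the
# measured log2 fold changes beta,
#
#   E(f) = sum over backbone edges (x,y,s): (f_x - s f_y)^2
#        + sum over evidence edges (b,g,s): (beta_g - s f_b)^2
#
# Stationarity gives the sparse SPD system K f = S beta, where K is the
# backbone block of the signed-graph Laplacian of the full two-layer graph
# (backbone Laplacian plus the evidence-degree diagonal) and S the signed
# backbone x gene evidence incidence. Equivalently f = M beta with
# M = K^-1 S, which is what variance propagation and the permutation tests
# reuse.
#
# `genes` fixes the measured-gene order; identifiability (every backbone
# component reached by >= 1 retained evidence edge) must be checked by the
# caller before solving.
.energyModel <- function(net, genes, alphaRidge = 0) {
  bb <- net@backboneNodes
  m <- length(bb)
  bIdx <- setNames(seq_len(m), bb)
  gIdx <- setNames(seq_along(genes), genes)

  be <- net@backboneEdges
  ee <- net@evidenceEdges
  ee <- ee[ee$target %in% genes, , drop = FALSE]

  # backbone-only signed Laplacian (shared by K and the scoring form Q)
  i <- integer(); j <- integer(); x <- numeric()
  if (nrow(be)) {
    sI <- bIdx[be$source]; tI <- bIdx[be$target]
    i <- c(sI, tI, sI, tI)
    j <- c(sI, tI, tI, sI)
    x <- c(rep(1, 2L * nrow(be)), -be$sign, -be$sign)
  }
  Lbb <- Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(m, m))

  evidDeg <- numeric(m)
  if (nrow(ee)) {
    tab <- table(factor(ee$source, levels = bb))
    evidDeg <- as.numeric(tab)
  }
  K <- Lbb + Matrix::Diagonal(m, evidDeg)

  S <- Matrix::sparseMatrix(
    i = if (nrow(ee)) unname(bIdx[ee$source]) else integer(),
    j = if (nrow(ee)) unname(gIdx[ee$target]) else integer(),
    x = if (nrow(ee)) ee$sign else numeric(),
    dims = c(m, length(genes))
  )

  nE <- nrow(be)
  Q <- if (nE > 0L) Lbb / nE else Matrix::sparseMatrix(i = integer(),
                                                       j = integer(),
                                                       x = numeric(),
                                                       dims = c(m, m))
  if (alphaRidge > 0) Q <- Q + Matrix::Diagonal(m, alphaRidge / m)

  list(backbone = bb, genes = genes, K = K, S = S, Q = Q, Lbb = Lbb,
       nBackboneEdges = nE, evidenceEdges = ee, alphaRidge = alphaRidge)
}

# restrict a contrast to the network's measured genes; warn on dropped
# network genes and error if any backbone component loses all its evidence
.matchContrast <- function(net, contrast, warnDropped = TRUE) {
  measured <- intersect(net@geneNodes, contrast@geneIds)
  dropped <- setdiff(net@geneNodes, measured)
  if (length(dropped) && warnDropped)
    warning(length(dropped), " network gene(s) without measurement; ",
            "their evidence edges are dropped (e.g. ", dropped[1L], ")")
  ee <- net@evidenceEdges
  withEvid <- unique(ee$source[ee$target %in% measured])
  for (comp in .backboneComponents(net)) {
    if (!any(comp %in% withEvid))
      stop("singular system: backbone component {",
           paste(comp, collapse = ", "),
           "} has no measured evidence gene")
  }
  idx <- match(measured, contrast@geneIds)
  list(genes = measured,
       beta = contrast@log2fc[idx],
       varBeta = if (is.null(contrast@varLog2fc)) NULL
                 else contrast@varLog2fc[idx])
}

#' Fit differential backbone values by signed harmonic extension
#'
#' Infers the activity change of every backbone node from the gene log2
#' fold changes: the fitted values are the smoothest function on the signed
#' backbone graph subject to the transcriptional boundary, i.e. the unique
#' minimiser of the quadratic energy that penalises (i) signed disagreement
#' across backbone edges and (ii) signed disagreement between a backbone
#' node and each of its evidence genes. Genes in the contrast but not in
#' the network are ignored; network genes without a measurement drop their
#' evidence edges with a warning, and the fit errors if that leaves any
#' backbone component without boundary information.
#'
#' Per-node variances are the diagonal of M Sigma M' with
#' Sigma = diag(var_log2fc) and f = M beta; the 95% CI is value +/-
#' z(0.975) * sd. When the contrast carries no variances the values are
#' returned with variance/CI marked unavailable.
#'
#' @param net a [TwoLayerNetwork-class].
#' @param contrast a [ContrastData-class].
#' @return a [BackboneProfile-class] over all backbone nodes.
#' @examples
#' edges <- data.frame(
#'   source = c("b1", "b1", "b2", "b1"),
#'   relation = c("increases", "decreases", "increases", "increases"),
#'   target = c("g1", "g2", "g3", "b2"),
#'   layer = c("evidence", "evidence", "evidence", "backbone")
#' )
#' net <- parseNetwork(edges)
#' ct <- contrastData(c("g1", "g2", "g3"), c(1, -1, 0.5))
#' nodeValues(fitBackboneValues(net, ct)) # b1 = 0.9, b2 = 0.7
#' @export
fitBackboneValues <- function(net, contrast) {
  stopifnot(is(net, "TwoLayerNetwork"), is(contrast, "ContrastData"))
  mc <- .matchContrast(net, contrast)
  em <- .energyModel(net, mc$genes)
  f <- as.numeric(Matrix::solve(em$K, em$S %*% mc$beta))
  if (!is.null(mc$varBeta)) {
    M <- as.matrix(Matrix::solve(em$K, as.matrix(em$S)))
    vf <- as.numeric((M * M) %*% mc$varBeta)
    vf[vf < 0] <- 0
    z <- qnorm(0.975)
    new("BackboneProfile", nodeIds = em$backbone, values = f,
        variances = vf, ciLow = f - z * sqrt(vf), ciHigh = f + z * sqrt(vf),
        contrastLabel = contrast@label)
  } else {
    new("BackboneProfile", nodeIds = em$backbone, values = f,
        variances = NULL, ciLow = NULL, ciHigh = NULL,
        contrastLabel = contrast@label)
  }
}

#' Network perturbation amplitude score
#'
#' Summarises a backbone profile as a non-negative quadratic form on the
#' signed backbone graph — a Sobolev-type (semi-)norm:
#' `(1/|E|) * sum over backbone edges (f_x - s f_y)^2 +
#'  alphaRidge * (1/|V|) * sum f_v^2`.
#' With `alphaRidge = 0` (the default) this is the pure Dirichlet semi-norm
#' term, zero exactly when the fitted values are sign-consistent across
#' every backbone edge; the `1/|E|` normalisation makes scores comparable
#' across network sizes. A network without backbone edges has a degenerate
#' semi-norm and requires `alphaRidge > 0`.
#'
#' @param net a [TwoLayerNetwork-class].
#' @param profile a [BackboneProfile-class] whose nodes equal the network's
#'   backbone nodes.
#' @param alphaRidge non-negative ridge weight on the node-amplitude term.
#' @return single non-negative numeric score.
#' @export
npaScore <- function(net, profile, alphaRidge = 0) {
  stopifnot(is(net, "TwoLayerNetwork"), is(profile, "BackboneProfile"),
            alphaRidge >= 0)
  if (!setequal(profile@nodeIds, net@backboneNodes))
    stop("profile node set must equal the network backbone nodes")
  nE <- nrow(net@backboneEdges)
  if (nE == 0L && alphaRidge == 0)
    stop("degenerate norm: no backbone edges; use alphaRidge > 0")
  f <- setNames(profile@values, profile@nodeIds)
  score <- 0
  if (nE > 0L) {
    be <- net@backboneEdges
    score <- sum((f[be$source] - be$sign * f[be$target])^2) / nE
  }
  if (alphaRidge > 0)
    score <- score + alphaRidge * mean(f^2)
  unname(score)
}

# A = M' Q M so that NPA = beta' A beta; shared by CI and the *O test
.npaQuadraticForm <- function(net, genes, alphaRidge = 0) {
  em <- .energyModel(net, genes, alphaRidge = alphaRidge)
  M <- as.matrix(Matrix::solve(em$K, as.matrix(em$S)))
  A <- t(M) %*% as.matrix(em$Q) %*% M
  list(A = A, M = M, em = em)
}

#' Confidence interval for the NPA score
#'
#' The NPA is a quadratic form of the gene fold changes, NPA = beta' A
#' beta, so its sampling variance under beta ~ Normal(beta_hat, Sigma)
#' (central-limit approximation for the estimated fold changes, Sigma =
#' diag(var_log2fc)) has the closed form
#' `Var = 4 beta_hat' A Sigma A beta_hat + 2 tr((A Sigma)^2)`.
#' The interval is score +/- z(level) * sd with the lower bound truncated
#' at 0.
#'
#' @param net a [TwoLayerNetwork-class].
#' @param contrast a [ContrastData-class]; must carry variances.
#' @param level confidence level, default 0.95.
#' @param alphaRidge ridge weight passed to the scoring form.
#' @return numeric `c(lower, upper)`.
#' @export
npaConfidenceInterval <- function(net, contrast, level = 0.95,
                                  alphaRidge = 0) {
  stopifnot(is(net, "TwoLayerNetwork"), is(contrast, "ContrastData"),
            level > 0, level < 1)
  if (is.null(contrast@varLog2fc))
    stop("contrast carries no variances; CI unavailable")
  mc <- .matchContrast(net, contrast, warnDropped = FALSE)
  if (nrow(net@backboneEdges) == 0L && alphaRidge == 0)
    stop("degenerate norm: no backbone edges; use alphaRidge > 0")
  qf <- .npaQuadraticForm(net, mc$genes, alphaRidge = alphaRidge)
  beta <- mc$beta
  score <- as.numeric(beta %*% qf$A %*% beta)
  ASig <- sweep(qf$A, 2L, mc$varBeta, `*`)   # A %*% diag(varBeta)
  v <- 4 * as.numeric(beta %*% ASig %*% (qf$A %*% beta)) +
    2 * sum(ASig * t(ASig))
  z <- qnorm(1 - (1 - level) / 2)
  half <- z * sqrt(max(v, 0))
  c(lower = max(0, score - half), upper = score + half)
}

# (count of permuted >= observed + 1) / (n + 1); one-sided because the NPA
# is a magnitude
.permPvalue <- function(permScores, observed) {
  (sum(permScores >= observed - 1e-12) + 1) / (length(permScores) + 1)
}

#' Evidence-specificity permutation test (*O statistic)
#'
#' Tests whether the NPA is specific to the observed assignment of fold
#' changes to the network's genes: each permutation shuffles the measured
#' fold-change values uniformly over the network's gene labels, refits the
#' backbone and rescores. The one-sided p-value uses the
#' (count + 1)/(n + 1) rule so it is never zero. Because the network (and
#' hence the map beta -> NPA) is fixed, each permutation is a single
#' quadratic-form evaluation.
#'
#' @param net a [TwoLayerNetwork-class].
#' @param contrast a [ContrastData-class].
#' @param nPerm number of permutations (>= 1), default 500.
#' @param seed integer seed; the test is bit-reproducible given
#'   `(seed, nPerm)`.
#' @param alphaRidge ridge weight for the score.
#' @return numeric p-value in (0, 1], with attribute `"permScores"`.
#' @export
permutationTestO <- function(net, contrast, nPerm = 500L, seed = 1L,
                             alphaRidge = 0) {
  stopifnot(nPerm >= 1L)
  mc <- .matchContrast(net, contrast, warnDropped = FALSE)
  if (length(unique(mc$beta)) < 2L) {
    warning("fewer than 2 distinct fold-change values; permutation ",
            "distribution is degenerate, p = 1")
    return(structure(1, permScores = numeric()))
  }
  qf <- .npaQuadraticForm(net, mc$genes, alphaRidge = alphaRidge)
  observed <- as.numeric(mc$beta %*% qf$A %*% mc$beta)
  permScores <- withr::with_seed(seed, {
    vapply(seq_len(nPerm), function(k) {
      b <- sample(mc$beta)
      as.numeric(b %*% qf$A %*% b)
    }, numeric(1L))
  })
  structure(.permPvalue(permScores, observed), permScores = permScores)
}

#' Backbone-wiring permutation test (K* statistic)
#'
#' Tests whether the cause-and-effect (backbone) layer contributes to the
#' perturbation amplitude: each permutation rewires the backbone edges —
#' endpoints redrawn uniformly among distinct backbone node pairs (no
#' self-loops, no duplicate pairs) and signs redrawn independently with the
#' observed negative-sign frequency — leaving the evidence layer untouched,
#' then refits and rescores. Rewirings that strand a backbone component
#' without evidence (singular fit) are rejected and resampled. If the
#' rewiring space has a single configuration the test is degenerate: a
#' warning is issued and p = 1.
#'
#' @inheritParams permutationTestO
#' @return numeric p-value in (0, 1], with attribute `"permScores"`.
#' @export
permutationTestK <- function(net, contrast, nPerm = 500L, seed = 1L,
                             alphaRidge = 0) {
  stopifnot(nPerm >= 1L)
  be <- net@backboneEdges
  if (nrow(be) < 1L) stop("K* test needs at least one backbone edge")
  mc <- .matchContrast(net, contrast, warnDropped = FALSE)
  em <- .energyModel(net, mc$genes, alphaRidge = alphaRidge)
  m <- length(em$backbone)
  nE <- nrow(be)
  nPairs <- m * (m - 1L) / 2L
  fNeg <- mean(be$sign < 0)
  if (choose(nPairs, nE) <= 1 && fNeg %in% c(0, 1)) {
    warning("backbone graph too small to rewire (single configuration); ",
            "p = 1")
    return(structure(1, permScores = numeric()))
  }

  obsProfile <- as.numeric(Matrix::solve(em$K, em$S %*% mc$beta))
  observed <- .scoreOnEdges(obsProfile, em$backbone, be, em$alphaRidge)

  evidDeg <- Matrix::diag(em$K) - Matrix::diag(em$Lbb)
  rhs <- em$S %*% mc$beta
  allPairs <- which(upper.tri(matrix(0, m, m)), arr.ind = TRUE)

  permScores <- withr::with_seed(seed, {
    vapply(seq_len(nPerm), function(k) {
      for (try in seq_len(100L)) {
        pick <- allPairs[sample.int(nPairs, nE), , drop = FALSE]
        signs <- ifelse(runif(nE) < fNeg, -1, 1)
        beP <- data.frame(source = em$backbone[pick[, 1L]],
                          target = em$backbone[pick[, 2L]],
                          sign = signs)
        KP <- .laplacianFromEdges(beP, em$backbone) +
          Matrix::Diagonal(m, evidDeg)
        fP <- tryCatch(as.numeric(Matrix::solve(KP, rhs)),
                       error = function(e) NULL)
        if (!is.null(fP) && all(is.finite(fP)))
          return(.scoreOnEdges(fP, em$backbone, beP, em$alphaRidge))
      }
      stop("could not draw an identifiable backbone rewiring in 100 tries")
    }, numeric(1L))
  })
  structure(.permPvalue(permScores, observed), permScores = permScores)
}

.laplacianFromEdges <- function(edges, nodes) {
  m <- length(nodes)
  idx <- setNames(seq_len(m), nodes)
  sI <- unname(idx[edges$source]); tI <- unname(idx[edges$target])
  Matrix::sparseMatrix(
    i = c(sI, tI, sI, tI), j = c(sI, tI, tI, sI),
    x = c(rep(1, 2L * nrow(edges)), -edges$sign, -edges$sign),
    dims = c(m, m))
}

.scoreOnEdges <- function(f, nodes, edges, alphaRidge) {
  f <- setNames(f, nodes)
  s <- sum((f[edges$source] - edges$sign * f[edges$target])^2) / nrow(edges)
  if (alphaRidge > 0) s <- s + alphaRidge * mean(f^2)
  unname(s)
}

#' Significance verdict for an NPA result
#'
#' The perturbation is called significant when the confidence interval is
#' greater than zero (lower bound > 0), and specific when both companion
#' permutation p-values (*O and K*) are below the alpha level. The verdict
#' encodes both: `significant_and_specific`, `significant_not_specific`,
#' or `not_significant` (CI spans zero, regardless of the p-values).
#'
#' @param scoreCI numeric `c(lower, upper)`.
#' @param pO,pK permutation p-values.
#' @param alphaLevel significance level for the permutation tests,
#'   default 0.05.
#' @return character verdict.
#' @export
significanceCall <- function(scoreCI, pO, pK, alphaLevel = 0.05) {
  stopifnot(length(scoreCI) == 2L)
  if (any(is.na(scoreCI)) || !(scoreCI[1L] > 0)) return("not_significant")
  if (is.finite(pO) && is.finite(pK) && pO < alphaLevel && pK < alphaLevel)
    "significant_and_specific"
  else
    "significant_not_specific"
}

#' Full NPA analysis for one contrast
#'
#' Convenience wrapper running the backbone fit, the NPA score, the
#' confidence interval (when the contrast carries variances) and both
#' permutation tests, and combining them into the significance verdict.
#' The *O test uses `seed` and the K* test `seed + 1` so the two null
#' distributions are independent but jointly reproducible.
#'
#' @inheritParams permutationTestO
#' @param level confidence level for the score CI.
#' @param alphaLevel significance level for the verdict.
#' @return list with elements `profile` (a [BackboneProfile-class]) and
#'   `result` (an [NPAResult-class]).
#' @export
npa <- function(net, contrast, nPerm = 500L, seed = 1L, alphaRidge = 0,
                level = 0.95, alphaLevel = 0.05) {
  profile <- fitBackboneValues(net, contrast)
  score <- npaScore(net, profile, alphaRidge = alphaRidge)
  ci <- if (!is.null(contrast@varLog2fc))
    npaConfidenceInterval(net, contrast, level = level,
                          alphaRidge = alphaRidge)
  else c(lower = NA_real_, upper = NA_real_)
  pO <- suppressWarnings(
    permutationTestO(net, contrast, nPerm = nPerm, seed = seed,
                     alphaRidge = alphaRidge))
  pK <- suppressWarnings(
    permutationTestK(net, contrast, nPerm = nPerm, seed = seed + 1L,
                     alphaRidge = alphaRidge))
  verdict <- significanceCall(ci, as.numeric(pO), as.numeric(pK),
                              alphaLevel = alphaLevel)
  result <- new("NPAResult", score = score,
                ciLow = unname(ci[1L]), ciHigh = unname(ci[2L]),
                pO = as.numeric(pO), pK = as.numeric(pK),
                nPermutations = as.integer(nPerm), verdict = verdict,
                seed = as.integer(seed))
  list(profile = profile, result = result)
}
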