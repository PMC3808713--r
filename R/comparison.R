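.comparisonStats <- function(a, b, labels) {
  n <- length(a)
  if (n < 3L) stop("need >= 3 paired observations for comparison statistics")
  if (sd(a) == 0 || sd(b) == 0)
    stop("zero variance in a profile; correlation undefined")
  ct <- cor.test(a, b, method = "pearson")
  st <- suppressWarnings(cor.test(a, b, method = "spearman",
                                  exact = n <= 9L))
  fit <- lm(b ~ a)
  # a perfect fit (e.g. a profile against itself) is legitimate here;
  # summary.lm's reliability warning is noise for that case
  sm <- suppressWarnings(summary(fit))
  pReg <- unname(pf(sm$fstatistic[1L], sm$fstatistic[2L], sm$fstatistic[3L],
                    lower.tail = FALSE))
  r <- unname(ct$estimate)
  new("ComparisonStats",
      pearsonR = r, spearmanRho = unname(st$estimate), rSquared = r^2,
      slope = unname(coef(fit)[2L]), intercept = unname(coef(fit)[1L]),
      pPearson = ct$p.value, pSpearman = st$p.value, pRegression = pReg,
      nNodes = as.integer(n), labels = labels)
}

#' Compare two backbone profiles
#'
#' Correlation and regression statistics between two differential backbone
#' profiles, computed on the intersection of their node sets (>= 3 nodes):
#' Pearson product-moment r with its two-sided t-based p-value, Spearman
#' rho on average ranks (exact permutation p only for n <= 9, t
#' approximation otherwise), and the least-squares regression of the second
#' profile on the first with its F-test p-value; R^2 is the squared
#' Pearson r. Backbone values are not independent draws, so the p-values
#' are descriptive, not exact tests.
#'
#' @param a,b [BackboneProfile-class] objects with >= 3 common nodes.
#' @return a [ComparisonStats-class].
#' @export
compareProfiles <- function(a, b) {
  stopifnot(is(a, "BackboneProfile"), is(b, "BackboneProfile"))
  common <- intersect(a@nodeIds, b@nodeIds)
  if (length(common) < 3L)
    stop("profiles share fewer than 3 backbone nodes")
  va <- nodeValues(a)[common]
  vb <- nodeValues(b)[common]
  .comparisonStats(unname(va), unname(vb),
                   labels = c(a@contrastLabel, b@contrastLabel))
}

#' Gene-permutation negative control for profile correlation
#'
#' Assesses whether the correlation between two fitted backbone profiles
#' could be produced by the dimension-reduction effect of the fit alone:
#' for each permutation the fold-change values of the network's measured
#' genes are shuffled independently for each contrast, both profiles are
#' refitted, and their Pearson correlation recorded. The two-sided p-value
#' is (count of |r_perm| >= |r_obs| + 1)/(nPerm + 1).
#'
#' @param net a [TwoLayerNetwork-class].
#' @param contrastA,contrastB [ContrastData-class] objects, both fitting
#'   on `net`.
#' @param nPerm number of permutations, default 1000.
#' @param seed integer seed; bit-reproducible given `(seed, nPerm)`.
#' @param statistic correlation permuted, `"pearson"` (default, also used
#'   for `observedR`) or `"spearman"`.
#' @return a [NegativeControlResult-class].
#' @export
negativeControlPermutation <- function(net, contrastA, contrastB,
                                       nPerm = 1000L, seed = 1L,
                                       statistic = c("pearson", "spearman")) {
  statistic <- match.arg(statistic)
  stopifnot(nPerm >= 1L)
  mcA <- .matchContrast(net, contrastA, warnDropped = FALSE)
  mcB <- .matchContrast(net, contrastB, warnDropped = FALSE)
  emA <- .energyModel(net, mcA$genes)
  emB <- .energyModel(net, mcB$genes)
  MA <- as.matrix(Matrix::solve(emA$K, as.matrix(emA$S)))
  MB <- as.matrix(Matrix::solve(emB$K, as.matrix(emB$S)))
  corFun <- function(x, y) cor(x, y, method = statistic)
  observed <- corFun(as.numeric(MA %*% mcA$beta), as.numeric(MB %*% mcB$beta))
  permutedR <- withr::with_seed(seed, {
    vapply(seq_len(nPerm), function(k) {
      fA <- MA %*% sample(mcA$beta)
      fB <- MB %*% sample(mcB$beta)
      corFun(as.numeric(fA), as.numeric(fB))
    }, numeric(1L))
  })
  p <- (sum(abs(permutedR) >= abs(observed) - 1e-12) + 1) / (nPerm + 1)
  new("NegativeControlResult", observedR = observed, permutedR = permutedR,
      pTwoSided = p, nPerm = as.integer(nPerm), seed = as.integer(seed))
}

#' Compare two contrasts at both network layers
#'
#' Runs the backbone fit for both contrasts and returns comparison
#' statistics at the functional layer (fitted backbone values) and at the
#' transcriptional layer (log2 fold changes of the genes shared by both
#' contrasts and present in the network). The two layers answer different
#' questions: backbone values integrate and denoise the gene signal, so a
#' smooth shared perturbation can correlate strongly at the backbone layer
#' while gene-level fold changes correlate weakly.
#'
#' @param net a [TwoLayerNetwork-class].
#' @param contrastA,contrastB [ContrastData-class] objects.
#' @return list with elements `backbone` (a [ComparisonStats-class]) and
#'   `genes` (a [ComparisonStats-class], or the error condition when the
#'   gene-level comparison is impossible, e.g. disjoint gene sets — the
#'   backbone layer is still returned in that case).
#' @export
compareContrasts <- function(net, contrastA, contrastB) {
  pa <- suppressWarnings(fitBackboneValues(net, contrastA))
  pb <- suppressWarnings(fitBackboneValues(net, contrastB))
  backbone <- compareProfiles(pa, pb)
  genes <- tryCatch({
    shared <- intersect(intersect(contrastA@geneIds, contrastB@geneIds),
                        net@geneNodes)
    if (length(shared) < 3L)
      stop("fewer than 3 network genes shared by both contrasts")
    ga <- log2fc(contrastA)[shared]
    gb <- log2fc(contrastB)[shared]
    .comparisonStats(unname(ga), unname(gb),
                     labels = c(contrastA@label, contrastB@label))
  }, error = function(e) e)
  list(backbone = backbone, genes = genes)
}
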