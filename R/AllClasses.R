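#' @import methods
#' @importFrom stats qnorm pnorm rnorm rpois var sd cor cor.test lm coef
#'   pf pt p.adjust setNames rbinom runif
#' @importFrom utils read.delim write.table head
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' Two-layer signed causal network
#'
#' Represents a causal biological network with a functional backbone layer
#' (unmeasured node activities connected by signed causal edges) and a
#' transcriptional evidence layer (measured genes attached to backbone nodes
#' by signed edges). Gene fold changes act as boundary conditions for the
#' backbone fit; a gene may be regulated by more than one backbone node.
#'
#' @slot backboneNodes character vector of backbone node identifiers
#'   (lexicographically sorted).
#' @slot geneNodes character vector of gene identifiers (sorted).
#' @slot backboneEdges data.frame with columns `source`, `target`, `sign`
#'   (+1/-1) over backbone nodes.
#' @slot evidenceEdges data.frame with columns `source` (backbone), `target`
#'   (gene), `sign`.
#' @slot name single character label.
#'
#' @seealso [parseNetwork()], [validateNetwork()], [fitBackboneValues()]
#' @export
setClass("TwoLayerNetwork",
  representation(
    backboneNodes = "character",
    geneNodes = "character",
    backboneEdges = "data.frame",
    evidenceEdges = "data.frame",
    name = "character"
  )
)

.edgeFrameOk <- function(df) {
  all(c("source", "target", "sign") %in% names(df)) &&
    (nrow(df) == 0L || all(df$sign %in% c(-1, 1)))
}

setValidity("TwoLayerNetwork", function(object) {
  msg <- character()
  bb <- object@backboneNodes
  gg <- object@geneNodes
  be <- object@backboneEdges
  ee <- object@evidenceEdges
  if (length(object@name) != 1L) msg <- c(msg, "'name' must be length 1")
  if (anyDuplicated(bb)) msg <- c(msg, "duplicate backbone node ids")
  if (anyDuplicated(gg)) msg <- c(msg, "duplicate gene node ids")
  if (length(intersect(bb, gg)))
    msg <- c(msg, "a node id occurs in both layers")
  if (!.edgeFrameOk(be)) msg <- c(msg, "malformed backbone edge table")
  if (!.edgeFrameOk(ee)) msg <- c(msg, "malformed evidence edge table")
  if (.edgeFrameOk(be) && nrow(be)) {
    if (!all(be$source %in% bb) || !all(be$target %in% bb))
      msg <- c(msg, "backbone edge endpoint is not a declared backbone node")
    if (any(be$source == be$target)) msg <- c(msg, "self-loop in backbone layer")
    if (anyDuplicated(paste(be$source, be$target)))
      msg <- c(msg, "duplicate backbone edge")
  }
  if (.edgeFrameOk(ee) && nrow(ee)) {
    if (!all(ee$source %in% bb))
      msg <- c(msg, "evidence edge source is not a backbone node")
    if (!all(ee$target %in% gg))
      msg <- c(msg, "evidence edge target is not a gene node")
    if (anyDuplicated(paste(ee$source, ee$target)))
      msg <- c(msg, "duplicate evidence edge")
  }
  if (length(msg)) msg else TRUE
})

#' Network validation report
#'
#' Diagnosis of whether the backbone fit is well posed: every connected
#' component of the backbone graph must carry at least one evidence edge,
#' otherwise the Dirichlet system is singular on that component.
#'
#' @slot isValid logical; `TRUE` iff no errors and no unidentifiable
#'   components.
#' @slot identifiableComponents list of character vectors of backbone nodes.
#' @slot unidentifiableComponents list of character vectors.
#' @slot warnings,errors character vectors of diagnostics.
#' @export
setClass("ValidationReport",
  representation(
    isValid = "logical",
    identifiableComponents = "list",
    unidentifiableComponents = "list",
    warnings = "character",
    errors = "character"
  )
)

#' Per-gene differential-expression contrast
#'
#' One comparison (e.g. smoker vs nonsmoker) as per-gene log2 fold changes
#' with estimated variances. The variance column is a variance (not a
#' standard error). Variances and p-values may be absent (`NULL`);
#' downstream operations that need them refuse to run.
#'
#' @slot geneIds unique character gene identifiers.
#' @slot log2fc numeric, treated minus control on log2 scale.
#' @slot varLog2fc numeric variances (>= 0), or `NULL` when unavailable.
#' @slot pvalue,adjPvalue numeric in \[0, 1\] or `NULL`.
#' @slot label single character contrast label.
#' @export
setClass("ContrastData",
  representation(
    geneIds = "character",
    log2fc = "numeric",
    varLog2fc = "numericOrNULL",
    pvalue = "numericOrNULL",
    adjPvalue = "numericOrNULL",
    label = "character"
  )
)

setValidity("ContrastData", function(object) {
  msg <- character()
  n <- length(object@geneIds)
  if (anyDuplicated(object@geneIds)) msg <- c(msg, "duplicate gene ids")
  if (length(object@log2fc) != n) msg <- c(msg, "log2fc length mismatch")
  if (any(!is.finite(object@log2fc))) msg <- c(msg, "non-finite log2fc")
  if (!is.null(object@varLog2fc)) {
    if (length(object@varLog2fc) != n) msg <- c(msg, "varLog2fc length mismatch")
    else if (any(!is.finite(object@varLog2fc)) || any(object@varLog2fc < 0))
      msg <- c(msg, "varLog2fc must be finite and >= 0")
  }
  for (s in c("pvalue", "adjPvalue")) {
    p <- slot(object, s)
    if (!is.null(p)) {
      if (length(p) != n) msg <- c(msg, paste(s, "length mismatch"))
      else if (any(!is.na(p) & (p < 0 | p > 1)))
        msg <- c(msg, paste(s, "outside [0, 1]"))
    }
  }
  if (!is.null(object@pvalue) && !is.null(object@adjPvalue)) {
    ok <- is.na(object@pvalue) | is.na(object@adjPvalue) |
      object@adjPvalue >= object@pvalue - 1e-12
    if (!all(ok)) msg <- c(msg, "adjPvalue < pvalue")
  }
  if (length(object@label) != 1L) msg <- c(msg, "'label' must be length 1")
  if (length(msg)) msg else TRUE
})

#' Differential backbone profile
#'
#' Inferred activity changes of the backbone nodes for one contrast, with
#' per-node variances and normal 95% confidence intervals propagated from
#' the fold-change variances. Variance/CI slots are `NULL` when the contrast
#' carried no variances.
#'
#' @slot nodeIds character backbone node identifiers.
#' @slot values numeric fitted differential backbone values.
#' @slot variances numeric (>= 0) or `NULL`.
#' @slot ciLow,ciHigh numeric or `NULL`.
#' @slot contrastLabel single character.
#' @export
setClass("BackboneProfile",
  representation(
    nodeIds = "character",
    values = "numeric",
    variances = "numericOrNULL",
    ciLow = "numericOrNULL",
    ciHigh = "numericOrNULL",
    contrastLabel = "character"
  )
)

setValidity("BackboneProfile", function(object) {
  msg <- character()
  n <- length(object@nodeIds)
  if (anyDuplicated(object@nodeIds)) msg <- c(msg, "duplicate node ids")
  if (length(object@values) != n) msg <- c(msg, "values length mismatch")
  if (any(!is.finite(object@values))) msg <- c(msg, "non-finite values")
  if (!is.null(object@variances)) {
    if (length(object@variances) != n || any(object@variances < -1e-12))
      msg <- c(msg, "variances invalid")
  }
  if (!is.null(object@ciLow) && !is.null(object@ciHigh)) {
    if (any(object@ciLow > object@values + 1e-9) ||
        any(object@ciHigh < object@values - 1e-9))
      msg <- c(msg, "CI does not bracket value")
  }
  if (length(msg)) msg else TRUE
})

#' Network perturbation amplitude result
#'
#' The NPA score for one contrast on one network, its confidence interval,
#' the evidence-specificity permutation p-value (*O), the backbone-wiring
#' permutation p-value (K*), and the verdict combining them: the
#' perturbation is significant when the CI lower bound exceeds 0 and
#' specific when both permutation p-values fall below the alpha level.
#'
#' @slot score non-negative NPA score.
#' @slot ciLow,ciHigh confidence bounds (lower truncated at 0); `NA` when
#'   variances were unavailable.
#' @slot pO,pK permutation p-values in (0, 1].
#' @slot nPermutations integer.
#' @slot verdict one of `"significant_and_specific"`,
#'   `"significant_not_specific"`, `"not_significant"`.
#' @slot seed integer seed used for the permutations.
#' @export
setClass("NPAResult",
  representation(
    score = "numeric",
    ciLow = "numeric",
    ciHigh = "numeric",
    pO = "numeric",
    pK = "numeric",
    nPermutations = "integer",
    verdict = "character",
    seed = "integer"
  )
)

setValidity("NPAResult", function(object) {
  msg <- character()
  if (object@score < 0) msg <- c(msg, "score must be >= 0")
  for (s in c("pO", "pK")) {
    p <- slot(object, s)
    if (!is.na(p) && (p <= 0 || p > 1)) msg <- c(msg, paste(s, "not in (0, 1]"))
  }
  if (!object@verdict %in% c("significant_and_specific",
                             "significant_not_specific",
                             "not_significant"))
    msg <- c(msg, "unknown verdict")
  if (length(msg)) msg else TRUE
})

#' Backbone-profile comparison statistics
#'
#' Correlation and least-squares regression summary between two backbone
#' profiles (or two gene-level fold-change vectors), computed on the node
#' intersection. The regression is of the second profile on the first; R^2
#' equals the squared Pearson correlation for this simple regression. The
#' p-values treat node values as independent draws, which backbone values
#' are not; they are reported as conventional descriptive statistics.
#'
#' @slot pearsonR,spearmanRho,rSquared numeric.
#' @slot slope,intercept numeric (B regressed on A).
#' @slot pPearson,pSpearman,pRegression numeric in (0, 1].
#' @slot nNodes integer number of paired observations.
#' @slot labels character(2), labels of A and B.
#' @export
setClass("ComparisonStats",
  representation(
    pearsonR = "numeric",
    spearmanRho = "numeric",
    rSquared = "numeric",
    slope = "numeric",
    intercept = "numeric",
    pPearson = "numeric",
    pSpearman = "numeric",
    pRegression = "numeric",
    nNodes = "integer",
    labels = "character"
  )
)

setValidity("ComparisonStats", function(object) {
  msg <- character()
  if (abs(object@pearsonR) > 1 + 1e-12) msg <- c(msg, "pearsonR outside [-1,1]")
  if (abs(object@spearmanRho) > 1 + 1e-12) msg <- c(msg, "spearmanRho outside [-1,1]")
  if (length(object@labels) != 2L) msg <- c(msg, "labels must be length 2")
  if (length(msg)) msg else TRUE
})

#' Gene-permutation negative control
#'
#' Tests whether the correlation between two fitted backbone profiles could
#' arise from the dimension-reduction effect alone: gene labels underlying
#' the network are shuffled independently for each contrast, profiles are
#' refitted, and the correlation recomputed.
#'
#' @slot observedR Pearson correlation of the unpermuted profiles.
#' @slot permutedR numeric vector of length `nPerm`.
#' @slot pTwoSided (count of |r_perm| >= |r_obs| + 1) / (nPerm + 1).
#' @slot nPerm,seed integers.
#' @export
setClass("NegativeControlResult",
  representation(
    observedR = "numeric",
    permutedR = "numeric",
    pTwoSided = "numeric",
    nPerm = "integer",
    seed = "integer"
  )
)

setValidity("NegativeControlResult", function(object) {
  msg <- character()
  if (length(object@permutedR) != object@nPerm)
    msg <- c(msg, "permutedR length != nPerm")
  if (object@pTwoSided <= 0 || object@pTwoSided > 1)
    msg <- c(msg, "pTwoSided not in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' Simulation ground truth bundle
#'
#' Everything a simulated experiment knows about itself: the generated
#' network, the true backbone activity vector, the expected gene fold
#' changes implied by the two-layer model (mean of signed parent
#' activities), the replicate log2 expression matrix with group labels, and
#' the contrast computed from it.
#'
#' @slot network a [TwoLayerNetwork-class].
#' @slot trueBackboneValues named numeric over backbone nodes.
#' @slot expectedGeneFc named numeric over genes.
#' @slot expression numeric matrix, genes x samples.
#' @slot groups character vector over samples, `"control"`/`"treated"`.
#' @slot contrast a [ContrastData-class].
#' @export
setClass("SimulationTruth",
  representation(
    network = "TwoLayerNetwork",
    trueBackboneValues = "numeric",
    expectedGeneFc = "numeric",
    expression = "matrix",
    groups = "character",
    contrast = "ContrastData"
  )
)
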