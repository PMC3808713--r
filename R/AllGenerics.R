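#' Accessors for netpa classes
#'
#' Small accessor generics so user code never touches slots directly.
#'
#' @param x an object of the documented class.
#' @return The corresponding component (character vector, numeric vector or
#'   data.frame).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("backboneNodes", function(x) standardGeneric("backboneNodes"))
#' @rdname accessors
#' @export
setGeneric("geneNodes", function(x) standardGeneric("geneNodes"))
#' @rdname accessors
#' @export
setGeneric("backboneEdges", function(x) standardGeneric("backboneEdges"))
#' @rdname accessors
#' @export
setGeneric("evidenceEdges", function(x) standardGeneric("evidenceEdges"))
#' @rdname accessors
#' @export
setGeneric("networkName", function(x) standardGeneric("networkName"))
#' @rdname accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))
#' @rdname accessors
#' @export
setGeneric("log2fc", function(x) standardGeneric("log2fc"))
#' @rdname accessors
#' @export
setGeneric("varLog2fc", function(x) standardGeneric("varLog2fc"))
#' @rdname accessors
#' @export
setGeneric("contrastLabel", function(x) standardGeneric("contrastLabel"))
#' @rdname accessors
#' @export
setGeneric("nodeValues", function(x) standardGeneric("nodeValues"))
#' @rdname accessors
#' @export
setGeneric("nodeVariances", function(x) standardGeneric("nodeVariances"))
#' @rdname accessors
#' @export
setGeneric("npaScoreValue", function(x) standardGeneric("npaScoreValue"))
#' @rdname accessors
#' @export
setGeneric("isValid", function(x) standardGeneric("isValid"))

#' @rdname accessors
#' @export
setMethod("backboneNodes", "TwoLayerNetwork", function(x) x@backboneNodes)
#' @rdname accessors
#' @export
setMethod("geneNodes", "TwoLayerNetwork", function(x) x@geneNodes)
#' @rdname accessors
#' @export
setMethod("backboneEdges", "TwoLayerNetwork", function(x) x@backboneEdges)
#' @rdname accessors
#' @export
setMethod("evidenceEdges", "TwoLayerNetwork", function(x) x@evidenceEdges)
#' @rdname accessors
#' @export
setMethod("networkName", "TwoLayerNetwork", function(x) x@name)

#' @rdname accessors
#' @export
setMethod("geneIds", "ContrastData", function(x) x@geneIds)
#' @rdname accessors
#' @export
setMethod("log2fc", "ContrastData", function(x) setNames(x@log2fc, x@geneIds))
#' @rdname accessors
#' @export
setMethod("varLog2fc", "ContrastData", function(x) {
  if (is.null(x@varLog2fc)) NULL else setNames(x@varLog2fc, x@geneIds)
})
#' @rdname accessors
#' @export
setMethod("contrastLabel", "ContrastData", function(x) x@label)

#' @rdname accessors
#' @export
setMethod("backboneNodes", "BackboneProfile", function(x) x@nodeIds)
#' @rdname accessors
#' @export
setMethod("nodeValues", "BackboneProfile",
          function(x) setNames(x@values, x@nodeIds))
#' @rdname accessors
#' @export
setMethod("nodeVariances", "BackboneProfile", function(x) {
  if (is.null(x@variances)) NULL else setNames(x@variances, x@nodeIds)
})
#' @rdname accessors
#' @export
setMethod("contrastLabel", "BackboneProfile", function(x) x@contrastLabel)

#' @rdname accessors
#' @export
setMethod("npaScoreValue", "NPAResult", function(x) x@score)

#' @rdname accessors
#' @export
setMethod("isValid", "ValidationReport", function(x) x@isValid)

#' Convert a backbone profile to a data.frame
#'
#' @param x a [BackboneProfile-class].
#' @param row.names,optional,... ignored; present for generic compatibility.
#' @return data.frame with columns `node`, `value`, `variance`, `ci_low`,
#'   `ci_high` (variance/CI columns `NA` when unavailable).
#' @export
as.data.frame.BackboneProfile <- function(x, row.names = NULL,
                                          optional = FALSE, ...) {
  n <- length(x@nodeIds)
  data.frame(
    node = x@nodeIds,
    value = x@values,
    variance = if (is.null(x@variances)) rep(NA_real_, n) else x@variances,
    ci_low = if (is.null(x@ciLow)) rep(NA_real_, n) else x@ciLow,
    ci_high = if (is.null(x@ciHigh)) rep(NA_real_, n) else x@ciHigh,
    stringsAsFactors = FALSE
  )
}

setMethod("show", "TwoLayerNetwork", function(object) {
  cat("TwoLayerNetwork '", object@name, "'\n", sep = "")
  cat("  backbone: ", length(object@backboneNodes), " nodes, ",
      nrow(object@backboneEdges), " signed edges\n", sep = "")
  cat("  evidence: ", length(object@geneNodes), " genes, ",
      nrow(object@evidenceEdges), " signed edges\n", sep = "")
})

setMethod("show", "ValidationReport", function(object) {
  cat("ValidationReport: ", if (object@isValid) "valid" else "INVALID", "\n",
      sep = "")
  cat("  identifiable components:   ", length(object@identifiableComponents),
      "\n  unidentifiable components: ",
      length(object@unidentifiableComponents), "\n", sep = "")
  if (length(object@warnings))
    cat("  warnings: ", paste(object@warnings, collapse = "; "), "\n", sep = "")
  if (length(object@errors))
    cat("  errors: ", paste(object@errors, collapse = "; "), "\n", sep = "")
})

setMethod("show", "ContrastData", function(object) {
  cat("ContrastData '", object@label, "': ", length(object@geneIds),
      " genes", sep = "")
  cat(if (is.null(object@varLog2fc)) ", no variances" else ", with variances")
  cat(if (is.null(object@pvalue)) "" else ", with p-values", "\n", sep = "")
})

setMethod("show", "BackboneProfile", function(object) {
  cat("BackboneProfile '", object@contrastLabel, "': ",
      length(object@nodeIds), " backbone nodes\n", sep = "")
  print(head(as.data.frame(object), 5L))
  if (length(object@nodeIds) > 5L)
    cat("  ... and ", length(object@nodeIds) - 5L, " more\n", sep = "")
})

setMethod("show", "NPAResult", function(object) {
  cat(sprintf("NPAResult: score = %.5g, %s\n", object@score, object@verdict))
  cat(sprintf("  CI: [%.5g, %.5g]\n", object@ciLow, object@ciHigh))
  cat(sprintf("  *O p = %.4g, K* p = %.4g (%d permutations, seed %d)\n",
              object@pO, object@pK, object@nPermutations, object@seed))
})

setMethod("show", "ComparisonStats", function(object) {
  cat("ComparisonStats (", object@labels[1L], " vs ", object@labels[2L],
      "), n = ", object@nNodes, "\n", sep = "")
  cat(sprintf("  Pearson r = %.4g (p = %.3g), Spearman rho = %.4g (p = %.3g)\n",
              object@pearsonR, object@pPearson, object@spearmanRho,
              object@pSpearman))
  cat(sprintf("  R^2 = %.4g; B ~ A: slope %.4g, intercept %.4g (p = %.3g)\n",
              object@rSquared, object@slope, object@intercept,
              object@pRegression))
})

setMethod("show", "NegativeControlResult", function(object) {
  cat(sprintf(
    "NegativeControlResult: observed r = %.4g, two-sided p = %.4g (%d permutations, seed %d)\n",
    object@observedR, object@pTwoSided, object@nPerm, object@seed))
})

setMethod("show", "SimulationTruth", function(object) {
  cat("SimulationTruth:\n  ")
  show(object@network)
  cat("  expression: ", nrow(object@expression), " genes x ",
      ncol(object@expression), " samples (",
      sum(object@groups == "control"), " control / ",
      sum(object@groups == "treated"), " treated)\n", sep = "")
})
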