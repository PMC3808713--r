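#' Construct a contrast object
#'
#' @param geneIds character gene identifiers (unique).
#' @param log2fc numeric log2 fold changes (treated minus control).
#' @param varLog2fc numeric variances of the log2 fold changes, or `NULL`
#'   when unavailable (CI and permutation-variance operations will refuse).
#' @param pvalue,adjPvalue optional numeric vectors in \[0, 1\].
#' @param label contrast label.
#' @return a [ContrastData-class].
#' @export
contrastData <- function(geneIds, log2fc, varLog2fc = NULL, pvalue = NULL,
                         adjPvalue = NULL, label = "contrast") {
  new("ContrastData", geneIds = as.character(geneIds),
      log2fc = as.numeric(log2fc),
      varLog2fc = if (is.null(varLog2fc)) NULL else as.numeric(varLog2fc),
      pvalue = if (is.null(pvalue)) NULL else as.numeric(pvalue),
      adjPvalue = if (is.null(adjPvalue)) NULL else as.numeric(adjPvalue),
      label = label)
}

#' Read / write a per-gene contrast table
#'
#' TSV with header `gene_id<TAB>log2fc<TAB>var_log2fc[<TAB>pvalue[<TAB>adj_pvalue]]`;
#' `var_log2fc` holds variances, not standard errors. A missing
#' `var_log2fc` column loads with variances marked absent. Rows with
#' non-finite log2fc, duplicate gene ids and negative variances are errors.
#'
#' @param path file path.
#' @param label contrast label (defaults to the file name).
#' @return `readContrast()` a [ContrastData-class]; `writeContrast()`
#'   invisibly `path`.
#' @export
readContrast <- function(path, label = basename(path)) {
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("gene_id", "log2fc") %in% names(df)))
    stop("contrast table must have columns gene_id and log2fc")
  df$gene_id <- as.character(df$gene_id)
  if (anyDuplicated(df$gene_id))
    stop("duplicate gene_id: ", df$gene_id[duplicated(df$gene_id)][1L])
  bad <- which(!is.finite(df$log2fc))
  if (length(bad))
    stop("non-finite log2fc for gene '", df$gene_id[bad[1L]], "' (row ",
         bad[1L], ")")
  v <- if ("var_log2fc" %in% names(df)) df$var_log2fc else NULL
  if (!is.null(v) && any(!is.finite(v) | v < 0))
    stop("var_log2fc must be finite and >= 0")
  contrastData(df$gene_id, df$log2fc, varLog2fc = v,
               pvalue = if ("pvalue" %in% names(df)) df$pvalue else NULL,
               adjPvalue = if ("adj_pvalue" %in% names(df)) df$adj_pvalue
                           else NULL,
               label = label)
}

#' @rdname readContrast
#' @param contrast a [ContrastData-class].
#' @export
writeContrast <- function(contrast, path) {
  stopifnot(is(contrast, "ContrastData"))
  df <- data.frame(gene_id = contrast@geneIds, log2fc = contrast@log2fc)
  if (!is.null(contrast@varLog2fc)) df$var_log2fc <- contrast@varLog2fc
  if (!is.null(contrast@pvalue)) df$pvalue <- contrast@pvalue
  if (!is.null(contrast@adjPvalue)) df$adj_pvalue <- contrast@adjPvalue
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Two-group log2 contrast with pooled variance
#'
#' The simplest case of a per-gene linear model: for each gene,
#' log2fc = mean(treated) - mean(control), with variance
#' s2_pooled * (1/n_t + 1/n_c) where s2_pooled pools the within-group
#' sample variances with their degrees of freedom. A two-sided p-value
#' comes from the equal-variance t statistic on n_t + n_c - 2 degrees of
#' freedom, and adjusted p-values from the Benjamini-Hochberg step-up
#' procedure. Each group needs at least 2 samples.
#'
#' @param expr numeric matrix of log2 intensities, genes x samples, with
#'   gene row names.
#' @param groups character/factor over columns with levels `"control"` and
#'   `"treated"`.
#' @param label contrast label.
#' @return a [ContrastData-class] with variances and (adjusted) p-values.
#' @examples
#' expr <- rbind(g1 = c(5.0, 5.2, 6.0, 6.6))
#' computeContrast(expr, c("control", "control", "treated", "treated"))
#' @export
computeContrast <- function(expr, groups, label = "two-group contrast") {
  expr <- as.matrix(expr)
  if (is.null(rownames(expr))) stop("expression matrix needs gene row names")
  if (any(!is.finite(expr))) stop("expression matrix has non-finite entries")
  groups <- as.character(groups)
  if (length(groups) != ncol(expr))
    stop("groups length must match the number of samples")
  if (!all(groups %in% c("control", "treated")))
    stop("groups must be 'control' or 'treated'")
  nc <- sum(groups == "control"); nt <- sum(groups == "treated")
  if (nc < 2L || nt < 2L)
    stop("each group needs >= 2 samples for variance estimation")

  ctl <- expr[, groups == "control", drop = FALSE]
  trt <- expr[, groups == "treated", drop = FALSE]
  mC <- rowMeans(ctl); mT <- rowMeans(trt)
  vC <- apply(ctl, 1L, var); vT <- apply(trt, 1L, var)
  df <- nc + nt - 2L
  s2 <- ((nc - 1L) * vC + (nt - 1L) * vT) / df
  lfc <- mT - mC
  vfc <- s2 * (1 / nt + 1 / nc)
  tstat <- ifelse(vfc > 0, lfc / sqrt(vfc), ifelse(lfc == 0, 0, Inf))
  p <- 2 * pt(-abs(tstat), df = df)
  contrastData(rownames(expr), lfc, varLog2fc = vfc, pvalue = p,
               adjPvalue = benjaminiHochberg(p), label = label)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Validates that the inputs are finite probabilities and applies the
#' standard step-up false-discovery-rate adjustment (via
#' [stats::p.adjust()] with `method = "BH"`): p(i) * m / i with
#' monotonicity enforced from the largest p downwards, capped at 1.
#'
#' @param pvalues numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values, same length and order; never smaller than the
#'   input, ranking preserved.
#' @examples
#' benjaminiHochberg(c(0.01, 0.04))            # 0.02, 0.04
#' benjaminiHochberg(c(0.01, 0.02, 0.03, 0.04)) # all 0.04
#' @export
benjaminiHochberg <- function(pvalues) {
  pvalues <- as.numeric(pvalues)
  if (any(!is.finite(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must be finite and in [0, 1]")
  p.adjust(pvalues, method = "BH")
}
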