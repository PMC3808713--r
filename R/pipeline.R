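# atomic write: render to a temp file in the target directory, then rename
.atomically <- function(path, writer) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".part")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  file.rename(tmp, path)
  invisible(path)
}

.writeJSON <- function(obj, path) {
  .atomically(path, function(tmp)
    jsonlite::write_json(obj, tmp, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE))
}

.writeTSV <- function(df, path) {
  .atomically(path, function(tmp)
    write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE))
}

.runConfig <- function(command, params) {
  c(list(command = command,
         tool = "netpa",
         version = as.character(utils::packageVersion("netpa"))),
    params)
}

.npaResultAsList <- function(result) {
  list(score = result@score, ci_low = result@ciLow, ci_high = result@ciHigh,
       p_O = result@pO, p_K = result@pK,
       n_permutations = result@nPermutations, verdict = result@verdict,
       seed = result@seed)
}

.comparisonStatsAsList <- function(cs) {
  list(pearson_r = cs@pearsonR, spearman_rho = cs@spearmanRho,
       r_squared = cs@rSquared, slope = cs@slope, intercept = cs@intercept,
       p_pearson = cs@pPearson, p_spearman = cs@pSpearman,
       p_regression = cs@pRegression, n = cs@nNodes,
       labels = as.list(cs@labels))
}

.log <- function(..., verbose = TRUE) {
  if (verbose) message("[netpa] ", ...)
}

#' Score a contrast on a network (pipeline command)
#'
#' Reads a network TSV and a contrast TSV, runs the full NPA analysis
#' ([npa()]) and writes `out` (a JSON file holding the run configuration,
#' the backbone profile and the NPA result) plus a TSV twin of the profile
#' (`<out>.profile.tsv` with columns node, value, variance, ci_low,
#' ci_high). Inputs are never mutated; outputs are written atomically.
#'
#' @param networkFile path to a network TSV (see [readNetwork()]).
#' @param contrastFile path to a contrast TSV (see [readContrast()]).
#' @param out path of the result JSON.
#' @param nPerm,seed,alphaRidge,level passed to [npa()].
#' @param verbose emit progress messages to stderr.
#' @return invisibly, the result list of [npa()].
#' @export
pipelineScore <- function(networkFile, contrastFile, out, nPerm = 500L,
                          seed = 17L, alphaRidge = 0, level = 0.95,
                          verbose = TRUE) {
  net <- readNetwork(networkFile)
  contrast <- readContrast(contrastFile)
  .log("score: network '", net@name, "' (",
       length(net@backboneNodes), " backbone nodes), contrast '",
       contrast@label, "' (", length(contrast@geneIds), " genes), seed ",
       seed, verbose = verbose)
  dropped <- setdiff(net@geneNodes, contrast@geneIds)
  if (length(dropped))
    .log("score: ", length(dropped),
         " network gene(s) without measurement dropped",
         verbose = verbose)
  res <- withCallingHandlers(
    npa(net, contrast, nPerm = nPerm, seed = seed,
        alphaRidge = alphaRidge, level = level),
    warning = function(w) {
      .log("score: warning: ", conditionMessage(w), verbose = verbose)
      invokeRestart("muffleWarning")
    })
  obj <- list(
    config = .runConfig("score", list(
      network = networkFile, contrast = contrastFile, n_perm = nPerm,
      seed = seed, alpha_ridge = alphaRidge, level = level,
      dropped_genes = length(dropped))),
    profile = as.data.frame(res$profile),
    npa = .npaResultAsList(res$result))
  .writeJSON(obj, out)
  .writeTSV(as.data.frame(res$profile), paste0(out, ".profile.tsv"))
  .log("score: NPA = ", format(res$result@score, digits = 6), ", verdict ",
       res$result@verdict, verbose = verbose)
  invisible(res)
}

#' Compare two contrasts on a network (pipeline command)
#'
#' Fits both contrasts, computes comparison statistics at the backbone and
#' gene layers ([compareContrasts()]) and the gene-permutation negative
#' control ([negativeControlPermutation()]), and writes a result JSON plus
#' a TSV of paired backbone values with per-node CIs
#' (`<out>.paired.tsv`) for plotting.
#'
#' @param networkFile,out as in [pipelineScore()].
#' @param contrastFileA,contrastFileB contrast TSV paths.
#' @param nPerm,seed passed to the negative control.
#' @param verbose emit progress messages to stderr.
#' @return invisibly, list with `comparison` and `negativeControl`.
#' @export
pipelineCompare <- function(networkFile, contrastFileA, contrastFileB, out,
                            nPerm = 1000L, seed = 17L, verbose = TRUE) {
  net <- readNetwork(networkFile)
  ca <- readContrast(contrastFileA)
  cb <- readContrast(contrastFileB)
  .log("compare: '", ca@label, "' vs '", cb@label, "' on network '",
       net@name, "', seed ", seed, verbose = verbose)
  cmp <- suppressWarnings(compareContrasts(net, ca, cb))
  if (inherits(cmp$genes, "error"))
    stop("comparison stage failed at gene layer: ",
         conditionMessage(cmp$genes))
  nc <- suppressWarnings(
    negativeControlPermutation(net, ca, cb, nPerm = nPerm, seed = seed))
  pa <- suppressWarnings(fitBackboneValues(net, ca))
  pb <- suppressWarnings(fitBackboneValues(net, cb))
  dfa <- as.data.frame(pa); dfb <- as.data.frame(pb)
  paired <- data.frame(
    node = dfa$node,
    value_a = dfa$value, ci_low_a = dfa$ci_low, ci_high_a = dfa$ci_high,
    value_b = dfb$value, ci_low_b = dfb$ci_low, ci_high_b = dfb$ci_high)
  obj <- list(
    config = .runConfig("compare", list(
      network = networkFile, contrast_a = contrastFileA,
      contrast_b = contrastFileB, n_perm = nPerm, seed = seed)),
    backbone = .comparisonStatsAsList(cmp$backbone),
    genes = .comparisonStatsAsList(cmp$genes),
    negative_control = list(observed_r = nc@observedR,
                            p_two_sided = nc@pTwoSided,
                            n_perm = nc@nPerm, seed = nc@seed))
  .writeJSON(obj, out)
  .writeTSV(paired, paste0(out, ".paired.tsv"))
  .log("compare: backbone r = ", format(cmp$backbone@pearsonR, digits = 4),
       ", gene r = ", format(cmp$genes@pearsonR, digits = 4),
       ", negative-control p = ", format(nc@pTwoSided, digits = 4),
       verbose = verbose)
  invisible(list(comparison = cmp, negativeControl = nc))
}

#' Simulate a study and write its fixtures (pipeline command)
#'
#' Generates a network and a two-group replicate experiment with known
#' backbone truth ([generateNetwork()], [simulateContrast()]) and writes,
#' under `outDir`: `network.tsv`, `expression.tsv` (first column gene_id),
#' `samples.tsv` (columns sample, group), `contrast.tsv`, and
#' `truth.json` (config, true backbone values, expected gene fold
#' changes).
#'
#' @param config a [simulationConfig()].
#' @param outDir output directory (created if needed).
#' @param verbose emit progress messages to stderr.
#' @return invisibly, the [SimulationTruth-class].
#' @export
pipelineSimulate <- function(config = simulationConfig(), outDir,
                             verbose = TRUE) {
  stopifnot(inherits(config, "simulationConfig"))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  net <- generateNetwork(config)
  trueValues <- withr::with_seed(config$seed + 1L,
                                 .resolveTrueValues(config,
                                                    net@backboneNodes))
  truth <- simulateContrast(net, trueValues, noiseSd = config$noiseSd,
                            nReplicates = config$nReplicates,
                            seed = config$seed + 2L)
  .log("simulate: ", length(net@backboneNodes), " backbone nodes, ",
       length(net@geneNodes), " genes, seed ", config$seed,
       verbose = verbose)
  .atomically(file.path(outDir, "network.tsv"),
              function(tmp) writeNetwork(net, tmp))
  exprDf <- data.frame(gene_id = rownames(truth@expression),
                       truth@expression, check.names = FALSE)
  .writeTSV(exprDf, file.path(outDir, "expression.tsv"))
  .writeTSV(data.frame(sample = colnames(truth@expression),
                       group = truth@groups),
            file.path(outDir, "samples.tsv"))
  .atomically(file.path(outDir, "contrast.tsv"),
              function(tmp) writeContrast(truth@contrast, tmp))
  .writeJSON(list(config = unclass(config),
                  true_backbone_values = as.list(truth@trueBackboneValues),
                  expected_gene_fc = as.list(truth@expectedGeneFc)),
             file.path(outDir, "truth.json"))
  invisible(truth)
}
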