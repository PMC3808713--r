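.RELATION_SIGNS <- c(
  increases = 1, directlyIncreases = 1,
  decreases = -1, directlyDecreases = -1
)

#' Parse a two-layer signed network from an edge list
#'
#' Builds a [TwoLayerNetwork-class] from BEL-style edge records. The four
#' accepted relation tokens are `increases`/`directlyIncreases` (sign +1)
#' and `decreases`/`directlyDecreases` (sign -1); any other token is an
#' error, never a guessed sign. Node sets are inferred from the edges and
#' sorted lexicographically so all downstream linear algebra has a
#' deterministic node order. Duplicate edges with a consistent sign are
#' collapsed with a warning; duplicates with conflicting signs are an error
#' (the energy functional would be ill posed); self-loops are an error.
#'
#' @param edgeRecords data.frame with columns `source`, `relation`,
#'   `target`, `layer` (`layer` in `backbone`/`evidence`).
#' @param name label for the network.
#' @return a validated [TwoLayerNetwork-class].
#' @examples
#' edges <- data.frame(
#'   source = c("b1", "b1", "b2", "b1"),
#'   relation = c("increases", "decreases", "increases", "increases"),
#'   target = c("g1", "g2", "g3", "b2"),
#'   layer = c("evidence", "evidence", "evidence", "backbone")
#' )
#' parseNetwork(edges, name = "toy")
#' @export
parseNetwork <- function(edgeRecords, name = "network") {
  df <- as.data.frame(edgeRecords, stringsAsFactors = FALSE)
  req <- c("source", "relation", "target", "layer")
  if (!all(req %in% names(df)))
    stop("edge records must have columns: ", paste(req, collapse = ", "))
  if (!nrow(df)) stop("empty edge list")
  for (col in req) df[[col]] <- trimws(as.character(df[[col]]))

  bad <- which(!df$relation %in% names(.RELATION_SIGNS))
  if (length(bad))
    stop("unknown relation token '", df$relation[bad[1L]], "' in row ",
         bad[1L])
  bad <- which(!df$layer %in% c("backbone", "evidence"))
  if (length(bad))
    stop("unknown layer token '", df$layer[bad[1L]], "' in row ", bad[1L])
  loops <- which(df$source == df$target)
  if (length(loops))
    stop("self-loop '", df$source[loops[1L]], "' in row ", loops[1L])

  df$sign <- unname(.RELATION_SIGNS[df$relation])

  key <- paste(df$source, df$target, df$layer, sep = "\r")
  if (anyDuplicated(key)) {
    signsPerKey <- tapply(df$sign, key, function(s) length(unique(s)))
    if (any(signsPerKey > 1L)) {
      off <- names(signsPerKey)[which(signsPerKey > 1L)[1L]]
      stop("contradictory signs for duplicated edge: ",
           gsub("\r", " -> ", off))
    }
    dupKeys <- unique(key[duplicated(key)])
    warning(length(dupKeys), " duplicate edge(s) collapsed, e.g. ",
            gsub("\r", " -> ", dupKeys[1L]))
    df <- df[!duplicated(key), , drop = FALSE]
  }

  be <- df[df$layer == "backbone", c("source", "target", "sign")]
  ee <- df[df$layer == "evidence", c("source", "target", "sign")]
  bb <- sort(unique(c(be$source, be$target, ee$source)))
  gg <- sort(unique(ee$target))
  if (length(intersect(bb, gg)))
    stop("node(s) used both as backbone and gene: ",
         paste(intersect(bb, gg), collapse = ", "))

  ord <- function(e) e[order(e$source, e$target), , drop = FALSE]
  be <- ord(be); rownames(be) <- NULL
  ee <- ord(ee); rownames(ee) <- NULL
  new("TwoLayerNetwork", backboneNodes = bb, geneNodes = gg,
      backboneEdges = be, evidenceEdges = ee, name = name)
}

#' Read / write a network as TSV
#'
#' The file format is a UTF-8 TSV with header
#' `source<TAB>relation<TAB>target<TAB>layer`; lines starting with `#` are
#' ignored. `writeNetwork()` emits `increases`/`decreases` tokens, so a
#' read/write round trip reproduces the same node sets, edges and signs.
#'
#' @param path file path.
#' @param name network label (defaults to the file name).
#' @return `readNetwork()` a [TwoLayerNetwork-class]; `writeNetwork()`
#'   invisibly `path`.
#' @export
readNetwork <- function(path, name = basename(path)) {
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                   colClasses = "character")
  parseNetwork(df, name = name)
}

#' @rdname readNetwork
#' @param net a [TwoLayerNetwork-class].
#' @export
writeNetwork <- function(net, path) {
  stopifnot(is(net, "TwoLayerNetwork"))
  rel <- function(s) ifelse(s > 0, "increases", "decreases")
  be <- net@backboneEdges
  ee <- net@evidenceEdges
  df <- rbind(
    if (nrow(be)) data.frame(source = be$source, relation = rel(be$sign),
                             target = be$target, layer = "backbone"),
    if (nrow(ee)) data.frame(source = ee$source, relation = rel(ee$sign),
                             target = ee$target, layer = "evidence")
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a network as JSON
#'
#' JSON serialization mirroring the [TwoLayerNetwork-class] fields:
#' `name`, `backbone_nodes`, `gene_nodes`, `backbone_edges`,
#' `evidence_edges` (edge objects with `source`, `target`, `sign`).
#'
#' @param net a [TwoLayerNetwork-class].
#' @param path file path.
#' @return `readNetworkJSON()` a [TwoLayerNetwork-class];
#'   `writeNetworkJSON()` invisibly `path`.
#' @export
writeNetworkJSON <- function(net, path) {
  stopifnot(is(net, "TwoLayerNetwork"))
  obj <- list(
    name = net@name,
    backbone_nodes = net@backboneNodes,
    gene_nodes = net@geneNodes,
    backbone_edges = net@backboneEdges,
    evidence_edges = net@evidenceEdges
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' @rdname writeNetworkJSON
#' @export
readNetworkJSON <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  toDf <- function(x) {
    if (is.null(x) || length(x) == 0L)
      return(data.frame(source = character(), target = character(),
                        sign = numeric()))
    data.frame(source = as.character(x$source),
               target = as.character(x$target),
               sign = as.numeric(x$sign), stringsAsFactors = FALSE)
  }
  new("TwoLayerNetwork",
      backboneNodes = sort(as.character(obj$backbone_nodes)),
      geneNodes = sort(as.character(obj$gene_nodes)),
      backboneEdges = toDf(obj$backbone_edges),
      evidenceEdges = toDf(obj$evidence_edges),
      name = as.character(obj$name))
}

#' Validate identifiability of the backbone fit
#'
#' Computes the connected components of the backbone graph (edges taken as
#' unordered) and classifies each as identifiable (at least one node in the
#' component carries an evidence edge, so boundary information reaches every
#' node of the component along backbone edges) or unidentifiable (no
#' evidence anywhere in the component, so the Dirichlet system is singular
#' there). Diagnoses are returned, never thrown.
#'
#' @param net a [TwoLayerNetwork-class].
#' @return a [ValidationReport-class]; `isValid` is `TRUE` iff there are no
#'   unidentifiable components and no errors.
#' @export
validateNetwork <- function(net) {
  stopifnot(is(net, "TwoLayerNetwork"))
  bb <- net@backboneNodes
  comps <- .backboneComponents(net)
  withEvidence <- unique(net@evidenceEdges$source[
    net@evidenceEdges$target %in% net@geneNodes])
  ident <- list(); unident <- list()
  for (comp in comps) {
    if (any(comp %in% withEvidence)) ident <- c(ident, list(comp))
    else unident <- c(unident, list(comp))
  }
  errs <- character()
  warns <- character()
  if (length(unident))
    warns <- c(warns, paste0(
      "backbone component(s) without evidence: ",
      paste(vapply(unident, function(x) paste(x, collapse = ","), ""),
            collapse = "; ")))
  if (!length(bb)) errs <- c(errs, "network has no backbone nodes")
  new("ValidationReport",
      isValid = length(errs) == 0L && length(unident) == 0L,
      identifiableComponents = ident,
      unidentifiableComponents = unident,
      warnings = warns, errors = errs)
}

# connected components of the backbone graph, as sorted character vectors
# in deterministic order
.backboneComponents <- function(net) {
  bb <- net@backboneNodes
  if (!length(bb)) return(list())
  be <- net@backboneEdges
  g <- igraph::graph_from_data_frame(
    d = if (nrow(be)) be[, c("source", "target")] else
      data.frame(source = character(), target = character()),
    directed = FALSE,
    vertices = data.frame(name = bb)
  )
  mem <- igraph::components(g)$membership
  comps <- split(names(mem), mem)
  comps <- lapply(comps, function(x) sort(unname(x)))
  comps <- comps[order(vapply(comps, `[`, "", 1L))]
  unname(comps)
}
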