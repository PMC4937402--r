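#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#' @importFrom S4Vectors metadata
#' @importFrom stats cor pt qt rnorm rpois runif sd setNames t.test var
#' @importFrom utils combn read.delim write.table packageVersion
#' @exportMethod show
NULL

.FEATURE_KINDS <- c("otu", "metabolite", "diversity_order")

#' FeatureTable: a features x samples abundance matrix
#'
#' Thin extension of \link[SummarizedExperiment]{SummarizedExperiment}
#' holding one assay named \code{"abundance"} (rows = features, columns =
#' samples) plus a declared feature kind. The same container serves OTU
#' count tables (integer-valued) and metabolite abundance tables
#' (arbitrary non-negative values).
#'
#' Validity requires: unique, non-empty feature and sample identifiers;
#' no negative values; no missing values; a known feature kind.
#'
#' @slot featureKind one of \code{"otu"}, \code{"metabolite"},
#'   \code{"diversity_order"}.
#' @export
setClass("FeatureTable",
  contains = "SummarizedExperiment",
  slots = c(featureKind = "character")
)

setValidity("FeatureTable", function(object) {
  msgs <- character()
  if (length(object@featureKind) != 1L ||
      !object@featureKind %in% .FEATURE_KINDS) {
    msgs <- c(msgs, sprintf("featureKind must be one of: %s",
                            paste(.FEATURE_KINDS, collapse = ", ")))
  }
  if (!"abundance" %in% SummarizedExperiment::assayNames(object)) {
    msgs <- c(msgs, "assay 'abundance' is required")
  } else {
    m <- SummarizedExperiment::assay(object, "abundance")
    if (is.null(rownames(m)) || is.null(colnames(m))) {
      msgs <- c(msgs, "feature and sample identifiers are required")
    } else {
      if (anyDuplicated(rownames(m)))
        msgs <- c(msgs, "duplicate feature identifiers")
      if (anyDuplicated(colnames(m)))
        msgs <- c(msgs, "duplicate sample identifiers")
    }
    if (anyNA(m))
      msgs <- c(msgs, "missing values are not permitted")
    else if (any(m < 0))
      msgs <- c(msgs, "negative abundance values are not permitted")
  }
  if (length(msgs)) msgs else TRUE
})

#' SignedNetwork: an undirected signed correlation graph
#'
#' Wraps a simple undirected \pkg{igraph} graph. Vertices carry
#' \code{name}, \code{kind} (otu / metabolite / diversity_order) and
#' \code{abundance} (total abundance over the samples used for
#' inference; may be \code{NA}). Edges carry the Pearson coefficient
#' \code{r}, its two-sided p-value \code{p}, and \code{sign}
#' (\code{"pos"} iff \code{r > 0}). \code{r} and \code{p} may be
#' \code{NA} for networks re-read from sign-only formats such as SIF.
#'
#' @slot graph an \pkg{igraph} object.
#' @export
setClass("SignedNetwork", slots = c(graph = "ANY"))

setValidity("SignedNetwork", function(object) {
  g <- object@graph
  if (!igraph::is_igraph(g)) return("graph slot must hold an igraph object")
  msgs <- character()
  if (igraph::is_directed(g)) msgs <- c(msgs, "graph must be undirected")
  if (!igraph::is_simple(g))
    msgs <- c(msgs, "graph must be simple (no loops or multi-edges)")
  va <- igraph::vertex_attr_names(g)
  for (a in c("name", "kind", "abundance"))
    if (!a %in% va) msgs <- c(msgs, sprintf("missing vertex attribute '%s'", a))
  if ("name" %in% va && anyDuplicated(igraph::V(g)$name))
    msgs <- c(msgs, "duplicate node names")
  if ("kind" %in% va && !all(igraph::V(g)$kind %in% .FEATURE_KINDS))
    msgs <- c(msgs, "unknown node kind")
  if (igraph::ecount(g) > 0) {
    ea <- igraph::edge_attr_names(g)
    for (a in c("r", "p", "sign"))
      if (!a %in% ea) msgs <- c(msgs, sprintf("missing edge attribute '%s'", a))
    if (all(c("r", "p", "sign") %in% ea)) {
      sgn <- igraph::E(g)$sign
      r <- igraph::E(g)$r
      p <- igraph::E(g)$p
      if (!all(sgn %in% c("pos", "neg")))
        msgs <- c(msgs, "edge sign must be 'pos' or 'neg'")
      ok <- is.na(r) | (r >= -1 & r <= 1 & r != 0)
      if (!all(ok)) msgs <- c(msgs, "edge r must lie in [-1,1] and be nonzero")
      ok <- is.na(r) | (sgn == ifelse(r > 0, "pos", "neg"))
      if (!all(ok)) msgs <- c(msgs, "edge sign inconsistent with r")
      if (!all(is.na(p) | (p >= 0 & p <= 1)))
        msgs <- c(msgs, "edge p must lie in [0,1]")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' ClusterResult: a dense module of a SignedNetwork
#'
#' A set of member nodes together with the number of edges internal to
#' the set and the module score, defined as internal edges divided by
#' member nodes. The induced subgraph must be connected.
#'
#' @slot members character vector of member node names.
#' @slot nNodes,nEdges integer counts of members and internal edges.
#' @slot score numeric, \code{nEdges / nNodes}.
#' @slot rank integer rank by descending score (NA if unranked).
#' @export
setClass("ClusterResult",
  slots = c(members = "character", nNodes = "integer", nEdges = "integer",
            score = "numeric", rank = "integer")
)

setValidity("ClusterResult", function(object) {
  msgs <- character()
  if (length(object@members) != object@nNodes)
    msgs <- c(msgs, "nNodes must equal length(members)")
  if (anyDuplicated(object@members))
    msgs <- c(msgs, "duplicate member names")
  if (object@nEdges < 0L) msgs <- c(msgs, "nEdges must be non-negative")
  if (object@nNodes > 0L &&
      !isTRUE(all.equal(object@score, object@nEdges / object@nNodes)))
    msgs <- c(msgs, "score must equal nEdges / nNodes")
  if (length(msgs)) msgs else TRUE
})
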