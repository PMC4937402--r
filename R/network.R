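#' Pearson correlation with a two-sided p-value
#'
#' Standard product-moment correlation; the p-value comes from the
#' t-transform \eqn{t = r\sqrt{(n-2)/(1-r^2)}} referred to the t
#' distribution with n - 2 degrees of freedom, two-sided.
#'
#' @param x,y numeric vectors of equal length n >= 3.
#' @return list with elements \code{r} and \code{p}. If either vector
#'   is constant the correlation is undefined and both are \code{NA}
#'   (callers treat this as "no edge").
#' @export
pearsonWithP <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3L) stop("need at least 3 paired observations")
  if (sd(x) == 0 || sd(y) == 0) return(list(r = NA_real_, p = NA_real_))
  r <- cor(x, y)
  list(r = r, p = .pFromR(r, n))
}

.pFromR <- function(r, n) {
  r <- pmin(pmax(r, -1), 1)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  2 * pt(-abs(tstat), df = n - 2)
}

.asValueMatrix <- function(x) {
  if (is(x, "FeatureTable")) abundances(x) else as.matrix(x)
}

.kindOf <- function(x, default) {
  if (is(x, "FeatureTable")) featureKind(x) else default
}

#' Build a signed Pearson correlation network
#'
#' Tests pairwise Pearson correlations and keeps an edge when the
#' two-sided p-value is at most \code{alpha}; the edge sign is
#' \code{"pos"} iff r > 0. With one table, all unordered feature pairs
#' within it are tested (a species interaction network when the table
#' holds OTUs) and every feature becomes a node, connected or not.
#' With two tables, only cross pairs (a feature of \code{tableA}
#' against one of \code{tableB}) are tested and nodes touching no edge
#' are dropped, so the result shows only associated features
#' (metabolite-OTU networks are built this way). Samples are matched
#' by id and the intersection is used; at least 3 shared samples are
#' required. Constant features yield undefined correlations and
#' participate in no edge.
#'
#' No multiple-testing correction is applied by default -- the raw
#' p <= alpha rule is the classical construction for these
#' co-occurrence networks -- but \code{adjust = "BH"} switches the
#' threshold to Benjamini-Hochberg adjusted p-values.
#'
#' @param tableA a \linkS4class{FeatureTable} (or matrix, features x
#'   samples).
#' @param tableB optional second table for cross-correlation mode.
#' @param alpha retention threshold on the (possibly adjusted)
#'   p-value, default 0.05 (non-strict).
#' @param relative correlate per-sample relative abundances instead of
#'   raw values (columns rescaled to sum 1). Off by default; raw
#'   abundances are the classical choice, at the cost of
#'   compositionality caveats.
#' @param adjust \code{"none"} (default) or \code{"BH"}.
#' @return a \linkS4class{SignedNetwork}. Node attribute
#'   \code{abundance} is the feature's total over the shared samples.
#' @export
buildNetwork <- function(tableA, tableB = NULL, alpha = 0.05,
                         relative = FALSE, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  stopifnot(alpha > 0, alpha <= 1)
  a <- .asValueMatrix(tableA)
  cross <- !is.null(tableB)
  b <- if (cross) .asValueMatrix(tableB) else a
  shared <- intersect(colnames(a), colnames(b))
  if (length(shared) < 3L) stop("need at least 3 shared samples")
  a <- a[, shared, drop = FALSE]
  b <- b[, shared, drop = FALSE]
  if (cross) {
    clash <- intersect(rownames(a), rownames(b))
    if (length(clash))
      stop("feature ids shared across tables: ", paste(clash, collapse = ", "))
  }
  totA <- rowSums(a)
  totB <- rowSums(b)
  if (relative) {
    a <- sweep(a, 2, colSums(a), "/")
    b <- if (cross) sweep(b, 2, colSums(b), "/") else a
  }
  n <- length(shared)
  R <- suppressWarnings(cor(t(a), t(b)))   # constant rows give NA
  P <- .pFromR(R, n)
  kindA <- .kindOf(tableA, "otu")
  kindB <- if (cross) .kindOf(tableB, "otu") else kindA

  if (cross) {
    idx <- which(!is.na(R), arr.ind = TRUE)
  } else {
    idx <- which(upper.tri(R) & !is.na(R), arr.ind = TRUE)
  }
  pv <- P[idx]
  crit <- if (adjust == "BH") stats::p.adjust(pv, "BH") else pv
  keep <- which(crit <= alpha & R[idx] != 0)
  ea <- rownames(a)[idx[keep, 1L]]
  eb <- rownames(b)[idx[keep, 2L]]
  er <- R[idx[keep, , drop = FALSE]]
  ep <- pv[keep]

  if (cross) {
    nodes <- c(intersect(rownames(a), unique(ea)),
               intersect(rownames(b), unique(eb)))
    kinds <- c(rep(kindA, sum(rownames(a) %in% ea)),
               rep(kindB, sum(rownames(b) %in% eb)))
    abund <- c(totA[intersect(rownames(a), unique(ea))],
               totB[intersect(rownames(b), unique(eb))])
  } else {
    nodes <- rownames(a)
    kinds <- rep(kindA, length(nodes))
    abund <- totA
  }
  g <- igraph::make_empty_graph(n = length(nodes), directed = FALSE)
  igraph::V(g)$name <- nodes
  igraph::V(g)$kind <- kinds
  igraph::V(g)$abundance <- unname(abund)
  if (length(ea))
    g <- igraph::add_edges(g, rbind(match(ea, nodes), match(eb, nodes)))
  igraph::E(g)$r <- er
  igraph::E(g)$p <- ep
  igraph::E(g)$sign <- ifelse(er > 0, "pos", "neg")
  new("SignedNetwork", graph = g)
}

#' Build the diversity-metabolite network (DMN)
#'
#' Computes each sample's Hill-number profile from the OTU table,
#' treats every diversity order q as one node (labelled \code{q0},
#' \code{q1}, ...), and cross-correlates the per-sample diversity
#' values against metabolite abundances with \code{\link{buildNetwork}}.
#' Metabolites touching no significant edge are dropped, so the graph
#' partitions retained metabolites into those positively and those
#' negatively associated with diversity.
#'
#' @param otuTable OTU \linkS4class{FeatureTable}.
#' @param metaboliteTable metabolite \linkS4class{FeatureTable}.
#' @param q diversity-order grid (default 0:4).
#' @param alpha edge retention threshold (default 0.05).
#' @param ... further arguments to \code{\link{buildNetwork}}.
#' @return a \linkS4class{SignedNetwork} whose nodes are diversity
#'   orders and metabolites.
#' @export
buildDMN <- function(otuTable, metaboliteTable, q = 0:4, alpha = 0.05, ...) {
  prof <- diversityProfile(otuTable, q)
  divTable <- FeatureTable(t(prof), "diversity_order")
  buildNetwork(divTable, metaboliteTable, alpha = alpha, ...)
}

# ---- SignedNetwork accessors -------------------------------------------

#' SignedNetwork accessors
#'
#' \code{asIgraph} unwraps the underlying \pkg{igraph} object;
#' \code{edgeTable} and \code{nodeTable} return the graph as plain
#' data frames; \code{nNodes} / \code{nEdges} count elements.
#'
#' @param net a \linkS4class{SignedNetwork}.
#' @return see individual descriptions.
#' @export
asIgraph <- function(net) {
  stopifnot(is(net, "SignedNetwork"))
  net@graph
}

#' @rdname asIgraph
#' @export
edgeTable <- function(net) {
  g <- asIgraph(net)
  if (igraph::ecount(g) == 0)
    return(data.frame(node_a = character(), node_b = character(),
                      r = numeric(), p = numeric(), sign = character()))
  el <- igraph::as_edgelist(g, names = TRUE)
  data.frame(node_a = el[, 1L], node_b = el[, 2L], r = igraph::E(g)$r,
             p = igraph::E(g)$p, sign = igraph::E(g)$sign,
             stringsAsFactors = FALSE)
}

#' @rdname asIgraph
#' @export
nodeTable <- function(net) {
  g <- asIgraph(net)
  data.frame(name = igraph::V(g)$name, kind = igraph::V(g)$kind,
             abundance = igraph::V(g)$abundance, degree = igraph::degree(g),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' @rdname asIgraph
#' @export
nNodes <- function(net) igraph::vcount(asIgraph(net))

#' @rdname asIgraph
#' @export
nEdges <- function(net) igraph::ecount(asIgraph(net))

setMethod("show", "SignedNetwork", function(object) {
  g <- object@graph
  sgn <- igraph::E(g)$sign
  cat(sprintf("SignedNetwork: %d nodes, %d edges (%d pos / %d neg)\n",
              igraph::vcount(g), igraph::ecount(g),
              sum(sgn == "pos"), sum(sgn == "neg")))
  kinds <- table(igraph::V(g)$kind)
  cat("  node kinds: ",
      paste(sprintf("%s=%d", names(kinds), kinds), collapse = ", "), "\n",
      sep = "")
})
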