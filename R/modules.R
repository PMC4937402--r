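#' Construct a ClusterResult from a network and a member set
#'
#' Counts the edges internal to \code{members} in the parent graph and
#' computes the module score, internal edges divided by member nodes.
#' The edges-per-node score is the module-strength statistic reported
#' alongside each detected cluster: a k-clique scores (k-1)/2 and any
#' tree scores just under 1, so it rewards dense interconnection.
#'
#' @param net a \linkS4class{SignedNetwork}.
#' @param members character vector of node names inducing a connected
#'   subgraph.
#' @param rank optional integer rank.
#' @return a \linkS4class{ClusterResult}.
#' @examples
#' # a module of 16 nodes with 110 internal edges scores 110/16 = 6.875
#' @export
clusterResult <- function(net, members, rank = NA_integer_) {
  g <- asIgraph(net)
  if (!all(members %in% igraph::V(g)$name))
    stop("cluster members must be network nodes")
  sub <- igraph::induced_subgraph(g, members)
  if (length(members) > 1L && !igraph::is_connected(sub))
    stop("cluster members must induce a connected subgraph")
  ne <- as.integer(igraph::ecount(sub))
  new("ClusterResult", members = as.character(members),
      nNodes = length(members), nEdges = ne,
      score = ne / length(members), rank = as.integer(rank))
}

#' @rdname clusterResult
#' @param x a \code{ClusterResult}.
#' @export
clusterScore <- function(x) {
  stopifnot(is(x, "ClusterResult"))
  x@score
}

#' @rdname clusterResult
#' @export
clusterMembers <- function(x) {
  stopifnot(is(x, "ClusterResult"))
  x@members
}

setMethod("show", "ClusterResult", function(object) {
  cat(sprintf("ClusterResult: %d nodes, %d edges, score %.3f%s\n",
              object@nNodes, object@nEdges, object@score,
              if (is.na(object@rank)) "" else sprintf(" (rank %d)",
                                                      object@rank)))
})

.density <- function(g) {
  nv <- igraph::vcount(g)
  if (nv < 2L) return(0)
  2 * igraph::ecount(g) / (nv * (nv - 1))
}

.mcodeWeights <- function(g, degreeCutoff) {
  deg <- igraph::degree(g)
  vapply(seq_len(igraph::vcount(g)), function(v) {
    if (deg[v] < degreeCutoff) return(0)
    nb <- c(v, as.integer(igraph::neighbors(g, v)))
    sub <- igraph::induced_subgraph(g, nb)
    core <- igraph::coreness(sub)
    kmax <- max(core)
    if (kmax < 1L) return(0)
    top <- igraph::induced_subgraph(sub, which(core == kmax))
    kmax * .density(top)
  }, numeric(1))
}

#' MCODE-style dense-module detection
#'
#' Finds highly interconnected regions of a graph by the classical
#' molecular-complex-detection procedure: (1) each vertex is weighted
#' by the density of the highest k-core of its closed neighborhood,
#' multiplied by that core's k (vertices below \code{degreeCutoff}
#' weigh 0); (2) complexes grow outward from the highest-weighted
#' unused seed, admitting neighbors whose weight exceeds the seed
#' weight times (1 - \code{nodeScoreCutoff}), to at most
#' \code{maxDepth} levels, with every admitted vertex excluded from
#' later complexes; (3) complexes lacking a \code{kCore}-core are
#' discarded and, with \code{haircut}, trimmed to their 2-core;
#' \code{fluff} optionally re-admits neighborhood vertices whose
#' closed-neighborhood density exceeds \code{fluffDensityCutoff}
#' (fluffed members may overlap between complexes). Each complex is
#' reported with score = internal edges / nodes and ranked by
#' descending score; ties break by size then by first member name, so
#' the output is deterministic for a fixed graph and parameters.
#'
#' Defaults are the published defaults of the procedure.
#'
#' @param net a \linkS4class{SignedNetwork}.
#' @param degreeCutoff minimum degree for a nonzero vertex weight
#'   (default 2).
#' @param nodeScoreCutoff admission slack as a fraction of the seed
#'   weight (default 0.2).
#' @param kCore minimum core a complex must contain (default 2).
#' @param maxDepth maximum expansion depth from the seed (default 100).
#' @param haircut trim each complex to its 2-core (default TRUE).
#' @param fluff grow complexes by dense neighbors (default FALSE).
#' @param fluffDensityCutoff density threshold used by fluff.
#' @return list of \linkS4class{ClusterResult}, ordered by rank;
#'   empty list for an empty graph.
#' @export
mcodeClusters <- function(net, degreeCutoff = 2, nodeScoreCutoff = 0.2,
                          kCore = 2, maxDepth = 100, haircut = TRUE,
                          fluff = FALSE, fluffDensityCutoff = 0.5) {
  g <- asIgraph(net)
  nv <- igraph::vcount(g)
  if (nv == 0L) return(list())
  w <- .mcodeWeights(g, degreeCutoff)
  names(w) <- igraph::V(g)$name
  ord <- order(-w, igraph::V(g)$name)
  used <- rep(FALSE, nv)
  complexes <- list()
  adj <- igraph::adjacent_vertices(g, igraph::V(g))
  for (seed in ord) {
    if (used[seed] || w[seed] <= 0) next
    threshold <- w[seed] * (1 - nodeScoreCutoff)
    members <- seed
    used[seed] <- TRUE
    frontier <- seed
    depth <- 0L
    while (length(frontier) && depth < maxDepth) {
      nxt <- integer()
      for (v in frontier) {
        for (u in as.integer(adj[[v]])) {
          if (!used[u] && w[u] > threshold) {
            used[u] <- TRUE
            nxt <- c(nxt, u)
          }
        }
      }
      members <- c(members, nxt)
      frontier <- nxt
      depth <- depth + 1L
    }
    if (length(members) > 1L) complexes <- c(complexes, list(members))
  }

  nbDensity <- function(v) {
    nb <- c(v, as.integer(adj[[v]]))
    .density(igraph::induced_subgraph(g, nb))
  }
  results <- list()
  for (members in complexes) {
    sub <- igraph::induced_subgraph(g, members)
    if (max(igraph::coreness(sub)) < kCore) next
    if (fluff) {
      cand <- setdiff(unique(unlist(lapply(members,
                                           function(v) as.integer(adj[[v]])))),
                      members)
      extra <- cand[vapply(cand, nbDensity, numeric(1)) > fluffDensityCutoff]
      members <- c(members, extra)
      sub <- igraph::induced_subgraph(g, members)
    }
    if (haircut) {
      core <- igraph::coreness(sub)
      keepNames <- igraph::V(sub)$name[core >= 2]
      if (length(keepNames) < 2L) next
      members <- match(keepNames, igraph::V(g)$name)
      sub <- igraph::induced_subgraph(g, members)
    }
    # expansion can straddle components; keep each connected piece
    comp <- igraph::components(sub)
    for (ci in seq_len(comp$no)) {
      piece <- igraph::V(sub)$name[comp$membership == ci]
      if (length(piece) < 2L) next
      results <- c(results, list(clusterResult(net, piece)))
    }
  }
  if (!length(results)) return(list())
  sc <- vapply(results, clusterScore, numeric(1))
  sz <- vapply(results, function(x) x@nNodes, integer(1))
  first <- vapply(results, function(x) sort(x@members)[1L], character(1))
  o <- order(-sc, -sz, first)
  results <- results[o]
  for (i in seq_along(results)) results[[i]]@rank <- i
  results
}

#' Negative links internal to a cluster
#'
#' Lists every negative-signed edge whose both endpoints belong to the
#' cluster. Healthy co-occurrence networks typically carry negative
#' links inside their strongest module while perturbed ones may carry
#' none, so this inventory is reported per detected cluster.
#'
#' @param net a \linkS4class{SignedNetwork}.
#' @param cluster a \linkS4class{ClusterResult} (or character vector
#'   of member node names).
#' @return data.frame with columns \code{node_a}, \code{node_b},
#'   \code{r}, \code{p}; zero rows when the cluster is all-positive.
#' @export
negativeLinksInCluster <- function(net, cluster) {
  members <- if (is(cluster, "ClusterResult")) cluster@members
             else as.character(cluster)
  g <- asIgraph(net)
  if (!all(members %in% igraph::V(g)$name))
    stop("cluster members must be network nodes")
  sub <- igraph::induced_subgraph(g, members)
  keep <- igraph::E(sub)$sign == "neg"
  if (!any(keep))
    return(data.frame(node_a = character(), node_b = character(),
                      r = numeric(), p = numeric()))
  el <- igraph::as_edgelist(sub, names = TRUE)[keep, , drop = FALSE]
  data.frame(node_a = el[, 1L], node_b = el[, 2L],
             r = igraph::E(sub)$r[keep], p = igraph::E(sub)$p[keep],
             stringsAsFactors = FALSE)
}
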