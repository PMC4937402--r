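#' Positive-to-negative link ratio of a signed network
#'
#' The number of positive-correlation edges divided by the number of
#' negative-correlation edges. The ratio is the headline contrast
#' between healthy and perturbed co-occurrence networks: loss of
#' negative interactions inflates it by an order of magnitude.
#'
#' @param net a \linkS4class{SignedNetwork}.
#' @return a numeric ratio; \code{Inf} when there are positive edges
#'   but no negative ones (the distinguished "no negative links"
#'   value), \code{NaN} for an empty edge set.
#' @examples
#' # 270 positive and 3 negative links give a ratio of 90
#' @export
pnRatio <- function(net) {
  sgn <- igraph::E(asIgraph(net))$sign
  npos <- sum(sgn == "pos")
  nneg <- sum(sgn == "neg")
  if (npos + nneg == 0L) return(NaN)
  if (nneg == 0L) return(Inf)
  npos / nneg
}

#' Summary panel of basic network properties
#'
#' One row of unweighted, undirected graph statistics: node and edge
#' counts, average degree (2E/N), average local clustering coefficient
#' (nodes of degree < 2 contribute 0), diameter and average shortest
#' path length (computed on the largest connected component, the only
#' finite-valued convention for fragmented graphs), number of
#' communities and modularity from the configured community detection
#' algorithm, density (2E/(N(N-1))), signed-edge counts and the P/N
#' ratio.
#'
#' Community structure is not uniquely defined; the default is
#' deterministic greedy modularity maximization, with seeded Louvain
#' as an alternative. Given the same \code{communityMethod} and
#' \code{seed} the summary is fully reproducible.
#'
#' @param net a nonempty \linkS4class{SignedNetwork}.
#' @param communityMethod \code{"fast_greedy"} (default,
#'   deterministic) or \code{"louvain"}.
#' @param seed integer seed used by stochastic community methods.
#' @return one-row data.frame with columns \code{n_nodes},
#'   \code{n_edges}, \code{average_degree},
#'   \code{average_local_clustering}, \code{diameter},
#'   \code{average_path_length}, \code{n_communities}, \code{density},
#'   \code{modularity}, \code{n_positive}, \code{n_negative},
#'   \code{pn_ratio}.
#' @export
summarizeNetwork <- function(net, communityMethod = c("fast_greedy",
                                                      "louvain"),
                             seed = 1L) {
  communityMethod <- match.arg(communityMethod)
  g <- asIgraph(net)
  nv <- igraph::vcount(g)
  ne <- igraph::ecount(g)
  if (nv == 0L) stop("empty network")
  lc <- igraph::transitivity(g, type = "local", isolates = "zero")
  comp <- igraph::components(g)
  big <- igraph::induced_subgraph(
    g, which(comp$membership == which.max(comp$csize)))
  diam <- igraph::diameter(big, unconnected = FALSE)
  apl <- igraph::mean_distance(big, unconnected = FALSE)
  comm <- switch(communityMethod,
    fast_greedy = igraph::cluster_fast_greedy(g),
    louvain = { set.seed(seed); igraph::cluster_louvain(g) })
  sgn <- igraph::E(g)$sign
  data.frame(
    n_nodes = nv,
    n_edges = ne,
    average_degree = 2 * ne / nv,
    average_local_clustering = mean(lc),
    diameter = diam,
    average_path_length = apl,
    n_communities = length(comm),
    density = if (nv > 1L) 2 * ne / (nv * (nv - 1)) else 0,
    modularity = igraph::modularity(comm),
    n_positive = sum(sgn == "pos"),
    n_negative = sum(sgn == "neg"),
    pn_ratio = pnRatio(net)
  )
}

#' Flag hub and most-abundant nodes
#'
#' Hubs are the nodes with the top-k highest degrees; MAO ("most
#' abundant OTUs") are the top-k nodes by total abundance. A node can
#' hold both roles ("dual"). Ties at rank k are all flagged, so either
#' set may exceed k; dropping tied nodes arbitrarily would make the
#' annotation depend on input order.
#'
#' @param net a \linkS4class{SignedNetwork}.
#' @param otuTable optional \linkS4class{FeatureTable} supplying
#'   abundance totals; defaults to the network's own \code{abundance}
#'   node attribute.
#' @param k number of top ranks to flag (default 3).
#' @return data.frame with columns \code{name}, \code{degree},
#'   \code{abundance}, \code{hub}, \code{mao}, \code{role}
#'   (\code{"hub"}, \code{"mao"}, \code{"dual"} or \code{""}).
#' @export
annotateHubsMao <- function(net, otuTable = NULL, k = 3) {
  g <- asIgraph(net)
  deg <- igraph::degree(g)
  abund <- igraph::V(g)$abundance
  if (!is.null(otuTable)) {
    tot <- rowSums(abundances(otuTable))
    hit <- igraph::V(g)$name %in% names(tot)
    abund[hit] <- tot[igraph::V(g)$name[hit]]
  }
  topk <- function(v) {
    if (all(is.na(v))) return(rep(FALSE, length(v)))
    cut <- sort(v, decreasing = TRUE)[min(k, sum(!is.na(v)))]
    !is.na(v) & v >= cut
  }
  hub <- topk(deg)
  mao <- topk(abund)
  role <- ifelse(hub & mao, "dual", ifelse(hub, "hub", ifelse(mao, "mao", "")))
  data.frame(name = igraph::V(g)$name, degree = unname(deg),
             abundance = abund, hub = hub, mao = mao, role = role,
             stringsAsFactors = FALSE, row.names = NULL)
}
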