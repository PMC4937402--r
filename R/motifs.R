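#' Motif classes for connected undirected subgraphs of size 3 and 4
#'
#' Size 3 has two connected isomorphism classes (path, triangle); size
#' 4 has six (path, star, cycle, tadpole, diamond, clique). Classes
#' are identified by edge count plus sorted degree sequence, which is
#' a complete invariant at these sizes.
#' @noRd
.motifClassName <- function(g) {
  ne <- igraph::ecount(g)
  ds <- paste(sort(igraph::degree(g)), collapse = "")
  key <- paste0(igraph::vcount(g), ":", ne, ":", ds)
  switch(key,
    "3:2:112" = "path",
    "3:3:222" = "triangle",
    "4:3:1122" = "path",
    "4:3:1113" = "star",
    "4:4:2222" = "cycle",
    "4:4:1223" = "tadpole",
    "4:5:2233" = "diamond",
    "4:6:3333" = "clique",
    NA_character_)
}

.motifClassMap <- function(size) {
  nclass <- if (size == 3L) 4L else 11L
  nm <- vapply(seq_len(nclass) - 1L, function(i) {
    gi <- igraph::graph_from_isomorphism_class(size, i, directed = FALSE)
    if (!igraph::is_connected(gi)) return(NA_character_)
    .motifClassName(gi)
  }, character(1))
  nm
}

#' Census of connected 3- or 4-node motifs
#'
#' Counts induced connected subgraphs of the given size, partitioned
#' by isomorphism class. Edge signs are ignored; the census is purely
#' topological. Counting is induced-subgraph semantics: a triangle
#' contributes to the triangle class only, not also to the path class.
#'
#' @param net a \linkS4class{SignedNetwork} (or an \pkg{igraph}
#'   graph).
#' @param size 3 or 4.
#' @return named integer vector of counts. For size 3 the classes are
#'   \code{path}, \code{triangle}; for size 4 they are \code{path},
#'   \code{star}, \code{cycle}, \code{tadpole} (triangle with a
#'   pendant edge), \code{diamond} (4-clique minus one edge) and
#'   \code{clique}.
#' @export
motifCensus <- function(net, size) {
  g <- if (is(net, "SignedNetwork")) asIgraph(net) else net
  if (!igraph::is_igraph(g)) stop("net must be a SignedNetwork or igraph")
  size <- as.integer(size)
  if (!size %in% c(3L, 4L)) stop("motif size must be 3 or 4")
  classes <- if (size == 3L) c("path", "triangle")
             else c("path", "star", "cycle", "tadpole", "diamond", "clique")
  out <- setNames(integer(length(classes)), classes)
  if (igraph::vcount(g) >= size) {
    counts <- igraph::motifs(g, size = size)
    nm <- .motifClassMap(size)
    for (i in seq_along(nm)) {
      if (!is.na(nm[i]) && is.finite(counts[i]))
        out[nm[i]] <- out[nm[i]] + as.integer(counts[i])
    }
  }
  out
}
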