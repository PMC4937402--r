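# Fixtures are built in code; nothing is read from disk except the
# package's own bundled reference table.

# wrap an igraph object as a SignedNetwork, filling default attributes
asSignedNet <- function(g, r = NULL, sign = NULL) {
  if (is.null(igraph::V(g)$name))
    igraph::V(g)$name <- paste0("n", seq_len(igraph::vcount(g)))
  if (is.null(igraph::V(g)$kind)) igraph::V(g)$kind <- "otu"
  if (is.null(igraph::V(g)$abundance))
    igraph::V(g)$abundance <- rep(1, igraph::vcount(g))
  ne <- igraph::ecount(g)
  if (is.null(r)) r <- rep(0.9, ne)
  if (is.null(sign)) sign <- ifelse(r > 0, "pos", "neg")
  igraph::E(g)$r <- r
  igraph::E(g)$p <- rep(0.01, ne)
  igraph::E(g)$sign <- sign
  methods::new("SignedNetwork", graph = g)
}

randomSignedNet <- function(n, m, seed, nNeg = 0) {
  set.seed(seed)
  g <- igraph::sample_gnm(n, m)
  r <- runif(m, 0.1, 0.99)
  if (nNeg > 0) r[sample.int(m, nNeg)] <- -runif(nNeg, 0.1, 0.99)
  asSignedNet(g, r = r)
}

# independent motif oracle: enumerate every k-subset, classify connected
# induced subgraphs by sorted degree sequence
bruteMotifCensus <- function(g, size) {
  classes <- if (size == 3L) c("112" = "path", "222" = "triangle")
    else c("1122" = "path", "1113" = "star", "2222" = "cycle",
           "1223" = "tadpole", "2233" = "diamond", "3333" = "clique")
  out <- setNames(integer(length(unique(classes))), unique(classes))
  nv <- igraph::vcount(g)
  if (nv < size) return(out)
  for (S in utils::combn(nv, size, simplify = FALSE)) {
    sub <- igraph::induced_subgraph(g, S)
    if (!igraph::is_connected(sub)) next
    key <- paste(sort(igraph::degree(sub)), collapse = "")
    out[classes[[key]]] <- out[classes[[key]]] + 1L
  }
  out
}

# tiny OTU fixture written to a temp TSV
writeTinyTable <- function(values, path, transpose = FALSE) {
  m <- if (transpose) t(values) else values
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  names(df)[1] <- if (transpose) "sample_id" else "otu_id"
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

tinyCounts <- function() {
  matrix(c(10, 0, 3, 5, 2, 8), nrow = 3,
         dimnames = list(c("otuA", "otuB", "otuC"), c("s1", "s2")))
}
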