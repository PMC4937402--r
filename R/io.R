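#' Read a feature table from a tab-separated file
#'
#' The canonical layout is features as rows: first column feature ids,
#' header row sample ids. Files in the transposed dialect (samples as
#' rows) are handled by the orientation hint and yield an identical
#' table. Parsing is strict: duplicate identifiers, negative values,
#' missing cells and non-numeric cells are hard errors (the offending
#' row/column is named); silent coercion on tiny sample sizes would
#' corrupt downstream correlation estimates.
#'
#' @param path TSV file path.
#' @param featureKind \code{"otu"} or \code{"metabolite"}.
#' @param orientation \code{"features-as-rows"} (default) or
#'   \code{"samples-as-rows"}.
#' @return a \linkS4class{FeatureTable}.
#' @export
readFeatureTable <- function(path,
                             featureKind = c("otu", "metabolite"),
                             orientation = c("features-as-rows",
                                             "samples-as-rows")) {
  featureKind <- match.arg(featureKind)
  orientation <- match.arg(orientation)
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character", strip.white = TRUE)
  if (ncol(df) < 2L) stop("table must have an id column and >= 1 data column")
  ids <- df[[1L]]
  raw <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(raw), nrow = nrow(raw),
                                 dimnames = list(ids, colnames(raw))))
  bad <- which(is.na(num) | raw == "", arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-numeric or missing cell at row '%s', column '%s'",
                 ids[bad[1L, 1L]], colnames(raw)[bad[1L, 2L]]))
  }
  neg <- which(num < 0, arr.ind = TRUE)
  if (nrow(neg)) {
    stop(sprintf("negative value at row '%s', column '%s'",
                 ids[neg[1L, 1L]], colnames(num)[neg[1L, 2L]]))
  }
  if (orientation == "samples-as-rows") num <- t(num)
  if (anyDuplicated(rownames(num)))
    stop("duplicate feature identifiers: ",
         paste(unique(rownames(num)[duplicated(rownames(num))]), collapse = ", "))
  if (anyDuplicated(colnames(num)))
    stop("duplicate sample identifiers: ",
         paste(unique(colnames(num)[duplicated(colnames(num))]), collapse = ", "))
  FeatureTable(num, featureKind)
}

#' Write a feature table as TSV (features as rows)
#'
#' @param x a \linkS4class{FeatureTable}.
#' @param path output file.
#' @param idColumn name for the leading identifier column.
#' @export
writeFeatureTable <- function(x, path, idColumn = "feature_id") {
  m <- abundances(x)
  df <- data.frame(id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- idColumn
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a BIOM (JSON dialect) OTU table
#'
#' Requires the \pkg{biomformat} package.
#'
#' @param path BIOM file path.
#' @return a \linkS4class{FeatureTable} of kind \code{"otu"}.
#' @export
readBiomTable <- function(path) {
  if (!requireNamespace("biomformat", quietly = TRUE))
    stop("the biomformat package is required to read BIOM files")
  b <- biomformat::read_biom(path)
  m <- as.matrix(biomformat::biom_data(b))
  FeatureTable(m, "otu")
}

#' Read sample-to-group assignments
#'
#' Two-column TSV (sample_id, group), with or without a header line.
#'
#' @param path TSV file path.
#' @param samples optional character vector; if given, every assigned
#'   sample must be a member (assignments to unknown samples error).
#' @return named character vector mapping sample id to group label.
#' @export
readGroupFile <- function(path, samples = NULL) {
  df <- read.delim(path, header = FALSE, sep = "\t", check.names = FALSE,
                   colClasses = "character", strip.white = TRUE)
  if (ncol(df) < 2L) stop("group file must have two columns: sample_id, group")
  if (identical(tolower(df[1L, 1L]), "sample_id")) df <- df[-1L, , drop = FALSE]
  g <- setNames(df[[2L]], df[[1L]])
  if (anyDuplicated(names(g))) stop("duplicate sample ids in group file")
  if (any(!nzchar(g))) stop("empty group labels")
  if (!is.null(samples)) {
    missing <- setdiff(names(g), samples)
    if (length(missing))
      stop("group file assigns unknown samples: ",
           paste(missing, collapse = ", "))
  }
  g
}

#' Write a group assignment file
#' @param groups named character vector (names = sample ids).
#' @param path output TSV.
#' @export
writeGroupFile <- function(groups, path) {
  write.table(data.frame(sample_id = names(groups), group = unname(groups)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.num17 <- function(x) {
  ifelse(is.na(x), "NA", formatC(x, digits = 17, format = "g"))
}

#' Write a SignedNetwork to disk
#'
#' Three Cytoscape-consumable formats are supported. GraphML and the
#' edge-list TSV preserve the edge attributes \code{r}, \code{p} and
#' \code{sign} at full double precision; SIF encodes only the edge sign
#' in the interaction-type token (\code{pos} / \code{neg}) and writes
#' isolated nodes as single-token lines. GraphML additionally preserves
#' node kind and abundance.
#'
#' @param net a \linkS4class{SignedNetwork}.
#' @param path output file.
#' @param format one of \code{"graphml"}, \code{"sif"},
#'   \code{"edge-tsv"}.
#' @return \code{path}, invisibly.
#' @export
writeNetwork <- function(net, path, format = c("graphml", "sif", "edge-tsv")) {
  stopifnot(is(net, "SignedNetwork"))
  format <- match.arg(format)
  switch(format,
    "graphml" = .writeGraphml(net, path),
    "sif" = .writeSif(net, path),
    "edge-tsv" = .writeEdgeTsv(net, path))
  invisible(path)
}

.writeGraphml <- function(net, path) {
  g <- net@graph
  doc <- xml2::xml_new_root("graphml",
    xmlns = "http://graphml.graphdrawing.org/xmlns")
  keys <- list(
    c("k_name", "node", "name", "string"),
    c("k_kind", "node", "kind", "string"),
    c("k_abund", "node", "abundance", "double"),
    c("k_r", "edge", "r", "double"),
    c("k_p", "edge", "p", "double"),
    c("k_sign", "edge", "sign", "string"))
  for (k in keys) {
    xml2::xml_add_child(doc, "key", id = k[1L], "for" = k[2L],
                        "attr.name" = k[3L], "attr.type" = k[4L])
  }
  graph <- xml2::xml_add_child(doc, "graph", id = "G",
                               edgedefault = "undirected")
  nm <- igraph::V(g)$name
  for (i in seq_along(nm)) {
    nd <- xml2::xml_add_child(graph, "node", id = sprintf("n%d", i))
    xml2::xml_add_child(nd, "data", key = "k_name", nm[i])
    xml2::xml_add_child(nd, "data", key = "k_kind", igraph::V(g)$kind[i])
    xml2::xml_add_child(nd, "data", key = "k_abund",
                        .num17(igraph::V(g)$abundance[i]))
  }
  if (igraph::ecount(g) > 0) {
    el <- igraph::as_edgelist(g, names = FALSE)
    for (i in seq_len(nrow(el))) {
      ed <- xml2::xml_add_child(graph, "edge",
                                source = sprintf("n%d", el[i, 1L]),
                                target = sprintf("n%d", el[i, 2L]))
      xml2::xml_add_child(ed, "data", key = "k_r", .num17(igraph::E(g)$r[i]))
      xml2::xml_add_child(ed, "data", key = "k_p", .num17(igraph::E(g)$p[i]))
      xml2::xml_add_child(ed, "data", key = "k_sign", igraph::E(g)$sign[i])
    }
  }
  xml2::write_xml(doc, path)
}

.writeSif <- function(net, path) {
  g <- net@graph
  lines <- character()
  if (igraph::ecount(g) > 0) {
    el <- igraph::as_edgelist(g, names = TRUE)
    lines <- sprintf("%s\t%s\t%s", el[, 1L], igraph::E(g)$sign, el[, 2L])
  }
  iso <- igraph::V(g)$name[igraph::degree(g) == 0]
  writeLines(c(lines, iso), path)
}

.writeEdgeTsv <- function(net, path) {
  g <- net@graph
  kinds <- setNames(igraph::V(g)$kind, igraph::V(g)$name)
  if (igraph::ecount(g) > 0) {
    el <- igraph::as_edgelist(g, names = TRUE)
    df <- data.frame(node_a = el[, 1L], node_b = el[, 2L],
                     r = .num17(igraph::E(g)$r), p = .num17(igraph::E(g)$p),
                     sign = igraph::E(g)$sign,
                     kind_a = kinds[el[, 1L]], kind_b = kinds[el[, 2L]],
                     stringsAsFactors = FALSE)
  } else {
    df <- data.frame(node_a = character(), node_b = character(),
                     r = character(), p = character(), sign = character(),
                     kind_a = character(), kind_b = character())
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a SignedNetwork written by writeNetwork
#'
#' @param path input file.
#' @param format one of \code{"graphml"}, \code{"sif"},
#'   \code{"edge-tsv"}. SIF carries no \code{r}/\code{p} values and no
#'   node metadata, so those come back as \code{NA} / kind
#'   \code{"otu"}; the edge TSV restores node kinds but not
#'   abundances.
#' @return a \linkS4class{SignedNetwork}.
#' @export
readNetwork <- function(path, format = c("graphml", "sif", "edge-tsv")) {
  format <- match.arg(format)
  switch(format,
    "graphml" = .readGraphml(path),
    "sif" = .readSif(path),
    "edge-tsv" = .readEdgeTsv(path))
}

.readGraphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  ab <- igraph::V(g)$abundance
  if (is.character(ab))
    igraph::V(g)$abundance <- suppressWarnings(as.numeric(ab))
  g <- igraph::delete_vertex_attr(g, "id")
  new("SignedNetwork", graph = g)
}

.readSif <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t")
  edges <- Filter(function(p) length(p) >= 3L, parts)
  singles <- unlist(lapply(Filter(function(p) length(p) == 1L, parts), `[[`, 1L))
  ea <- vapply(edges, `[[`, "", 1L)
  sgn <- vapply(edges, `[[`, "", 2L)
  eb <- vapply(edges, `[[`, "", 3L)
  nodes <- unique(c(ea, eb, singles))
  g <- igraph::make_empty_graph(n = length(nodes), directed = FALSE)
  igraph::V(g)$name <- nodes
  if (length(ea))
    g <- igraph::add_edges(g, rbind(match(ea, nodes), match(eb, nodes)))
  igraph::V(g)$kind <- "otu"
  igraph::V(g)$abundance <- NA_real_
  igraph::E(g)$r <- NA_real_
  igraph::E(g)$p <- NA_real_
  igraph::E(g)$sign <- sgn
  new("SignedNetwork", graph = g)
}

.readEdgeTsv <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character")
  nodes <- unique(c(df$node_a, df$node_b))
  kinds <- c(setNames(df$kind_a, df$node_a), setNames(df$kind_b, df$node_b))
  g <- igraph::make_empty_graph(n = length(nodes), directed = FALSE)
  igraph::V(g)$name <- nodes
  if (nrow(df))
    g <- igraph::add_edges(g, rbind(match(df$node_a, nodes),
                                    match(df$node_b, nodes)))
  igraph::V(g)$kind <- if (length(nodes)) unname(kinds[nodes]) else character()
  igraph::V(g)$abundance <- NA_real_
  igraph::E(g)$r <- as.numeric(df$r)
  igraph::E(g)$p <- as.numeric(df$p)
  igraph::E(g)$sign <- df$sign
  new("SignedNetwork", graph = g)
}
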