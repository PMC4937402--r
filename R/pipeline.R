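#' Default pipeline configuration
#'
#' @param otu path to the OTU count TSV.
#' @param metabolites optional path to the metabolite TSV.
#' @param groups path to the two-column sample-to-group TSV.
#' @param outDir output directory.
#' @param ... overrides for the remaining settings: \code{alpha}
#'   (edge p-value threshold), \code{minTotal} (OTU low-total
#'   filter), \code{q} (diversity-order grid),
#'   \code{communityMethod}, \code{mcode} (list of
#'   \code{\link{mcodeClusters}} arguments), \code{seed},
#'   \code{relative}.
#' @return a named list; see \code{\link{runPipeline}}.
#' @export
pipelineConfig <- function(otu, groups, outDir, metabolites = NULL, ...) {
  cfg <- list(otu = otu, metabolites = metabolites, groups = groups,
              outDir = outDir, alpha = 0.05, minTotal = 5, q = 0:4,
              communityMethod = "fast_greedy", mcode = list(), seed = 1L,
              relative = FALSE)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown config settings: ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  cfg
}

.readPipelineConfig <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    y <- yaml::read_yaml(config)
    config <- do.call(pipelineConfig,
                      c(y[intersect(names(y),
                                    c("otu", "groups", "outDir",
                                      "metabolites"))],
                        y[setdiff(names(y), c("otu", "groups", "outDir",
                                              "metabolites"))]))
  }
  stopifnot(is.list(config))
  for (f in c("otu", "groups")) {
    if (is.null(config[[f]]) || !file.exists(config[[f]]))
      stop(sprintf("config field '%s' must name an existing file", f))
  }
  if (!is.null(config$metabolites) && !file.exists(config$metabolites))
    stop("metabolite table file not found")
  stopifnot(config$alpha > 0, config$alpha <= 1, all(config$q >= 0))
  config
}

.stage <- function(name, expr) {
  t0 <- Sys.time()
  res <- tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE))
  message(sprintf("[hillnet] %-22s %6.2fs", name,
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  res
}

#' Run the full diversity-network workflow
#'
#' Orchestrates the complete analysis: low-total OTU filtering per
#' group, per-sample Hill-number profiles with group means and
#' pairwise t-tests, one signed species interaction network (SIN) per
#' group with its summary panel, hub/MAO annotation, motif census and
#' MCODE-style clusters (with their internal negative links), and --
#' when a metabolite table is supplied -- the diversity-metabolite
#' network (DMN) and metabolite-OTU network (MON). All result tables
#' are written as TSV, networks as GraphML, plus a JSON run manifest
#' recording inputs, parameters, package version and seed so a rerun
#' reproduces every numeric output. Reruns with identical inputs and
#' seed are byte-identical.
#'
#' @param config a list from \code{\link{pipelineConfig}} or a path
#'   to a YAML file with the same fields.
#' @return invisibly, a list with the in-memory results (profiles,
#'   group means, t-tests, per-group networks, summaries, clusters,
#'   motifs, DMN, MON, manifest).
#' @export
runPipeline <- function(config) {
  cfg <- .readPipelineConfig(config)
  dir.create(cfg$outDir, recursive = TRUE, showWarnings = FALSE)
  outfile <- function(...) file.path(cfg$outDir, ...)
  tsv <- function(df, name) {
    write.table(df, outfile(name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }

  otu <- .stage("read otu table", readFeatureTable(cfg$otu, "otu"))
  groups <- .stage("read groups",
                   readGroupFile(cfg$groups, samples = sampleIds(otu)))
  met <- if (!is.null(cfg$metabolites))
    .stage("read metabolites", readFeatureTable(cfg$metabolites,
                                                "metabolite"))

  profiles <- .stage("diversity profiles", diversityProfile(otu, cfg$q))
  tsv(data.frame(sample_id = rownames(profiles),
                 group = unname(groups[rownames(profiles)]), profiles,
                 check.names = FALSE),
      "diversity_profiles.tsv")
  gm <- groupMeanProfile(profiles, groups)
  tsv(data.frame(group = rownames(gm), gm, check.names = FALSE),
      "diversity_group_means.tsv")
  pairs <- utils::combn(sort(unique(groups)), 2, simplify = FALSE)
  tt <- do.call(rbind, lapply(pairs, function(pr) {
    res <- compareGroupsT(profiles, groups, pr[1L], pr[2L])
    cbind(group_a = pr[1L], group_b = pr[2L], res)
  }))
  tsv(tt, "diversity_t_tests.tsv")

  sins <- list(); summaries <- list(); clusters <- list()
  motifs <- list(); negatives <- list(); annotations <- list()
  for (gname in sort(unique(groups))) {
    sub <- otu[, names(groups)[groups == gname]]
    sub <- filterLowTotal(sub, cfg$minTotal)
    net <- .stage(paste("SIN", gname),
                  buildNetwork(sub, alpha = cfg$alpha,
                               relative = cfg$relative))
    sins[[gname]] <- net
    writeNetwork(net, outfile(sprintf("sin_%s.graphml", gname)), "graphml")
    summaries[[gname]] <- cbind(group = gname,
      summarizeNetwork(net, cfg$communityMethod, seed = cfg$seed))
    annotations[[gname]] <- cbind(group = gname, annotateHubsMao(net, sub))
    motifs[[gname]] <- do.call(rbind, lapply(c(3L, 4L), function(k) {
      cs <- motifCensus(net, k)
      data.frame(group = gname, size = k, motif = names(cs),
                 count = unname(cs))
    }))
    cl <- do.call(mcodeClusters, c(list(net), cfg$mcode))
    clusters[[gname]] <- do.call(rbind, lapply(cl, function(x)
      data.frame(group = gname, rank = x@rank, score = x@score,
                 n_nodes = x@nNodes, n_edges = x@nEdges,
                 members = paste(x@members, collapse = ","))))
    negatives[[gname]] <- do.call(rbind, lapply(cl, function(x) {
      nl <- negativeLinksInCluster(net, x)
      if (nrow(nl)) cbind(group = gname, cluster_rank = x@rank, nl)
    }))
  }
  tsv(do.call(rbind, summaries), "network_summaries.tsv")
  tsv(do.call(rbind, annotations), "hub_mao_annotations.tsv")
  tsv(do.call(rbind, motifs), "motif_counts.tsv")
  clTab <- do.call(rbind, clusters)
  if (is.null(clTab))
    clTab <- data.frame(group = character(), rank = integer(),
                        score = numeric(), n_nodes = integer(),
                        n_edges = integer(), members = character())
  tsv(clTab, "clusters.tsv")
  negTab <- do.call(rbind, negatives)
  if (is.null(negTab))
    negTab <- data.frame(group = character(), cluster_rank = integer(),
                         node_a = character(), node_b = character(),
                         r = numeric(), p = numeric())
  tsv(negTab, "cluster_negative_links.tsv")

  dmn <- mon <- NULL
  if (!is.null(met)) {
    otuF <- filterLowTotal(otu, cfg$minTotal)
    dmn <- .stage("DMN", buildDMN(otuF, met, q = cfg$q, alpha = cfg$alpha))
    writeNetwork(dmn, outfile("dmn.graphml"), "graphml")
    mon <- .stage("MON", buildNetwork(met, otuF, alpha = cfg$alpha,
                                      relative = cfg$relative))
    writeNetwork(mon, outfile("mon.graphml"), "graphml")
  }

  manifest <- list(
    package = "hillnet",
    version = as.character(packageVersion("hillnet")),
    inputs = list(otu = cfg$otu, metabolites = cfg$metabolites,
                  groups = cfg$groups),
    parameters = cfg[c("alpha", "minTotal", "q", "communityMethod",
                       "mcode", "seed", "relative")],
    outputs = list.files(cfg$outDir))
  jsonlite::write_json(manifest, outfile("manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  invisible(list(profiles = profiles, groupMeans = gm, tTests = tt,
                 sins = sins, summaries = do.call(rbind, summaries),
                 clusters = clTab, motifs = do.call(rbind, motifs),
                 negativeLinks = negTab, dmn = dmn, mon = mon,
                 manifest = manifest))
}
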