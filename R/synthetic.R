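#' @name synthetic
#' @rdname generateOtuTable
NULL

# loading on the shared latent factor that yields a target Pearson r
# between two log-normal abundances with total log-variance tau^2
.loadingForR <- function(r, tau) {
  s <- expm1(tau^2)
  if (abs(r) >= 1) stop("target |r| must be < 1")
  arg <- 1 + r * s
  if (arg <= 1e-9)
    stop("target negative correlation infeasible at this noise level")
  l2 <- abs(log(arg))
  if (l2 > tau^2 + 1e-12)
    stop(sprintf("target r = %.2f infeasible at logNoiseSd = %.2f", r, tau))
  sqrt(l2)
}

#' Generate a synthetic OTU count table with planted correlations
#'
#' Draws counts from a log-normal-Poisson model: OTU i in sample j has
#' latent log-mean \eqn{\log(depth\,w_i) + \lambda_i z_{k(i),j} +
#' \sqrt{\tau^2-\lambda_i^2}\,u_{ij} - \tau^2/2}, with counts Poisson
#' around the exponentiated mean. Baseline weights \eqn{w_i} follow a
#' ranked log-normal species abundance distribution whose width is the
#' \code{dominance} parameter: 0 gives a perfectly even community and
#' larger values concentrate abundance in few OTUs, so Hill-number
#' profiles fall more steeply with q. Each planted pair shares a
#' standard-normal latent factor z with equal-magnitude loadings,
#' same-signed for a positive pair and opposite-signed for a negative
#' pair; loadings are solved so that the Pearson correlation of the
#' latent abundances equals the target r (Poisson noise attenuates the
#' realized correlation slightly). All other OTUs carry independent
#' log-normal noise of standard deviation \code{logNoiseSd}. Poisson
#' (rather than multinomial) count noise is used deliberately: the
#' downstream inference is plain Pearson correlation on abundances,
#' and the generator stays aligned with that model rather than adding
#' compositional closure it does not assume.
#'
#' Planted pairs occupy the most-abundant baseline ranks (features
#' \code{OTU_001, OTU_002} form pair 1, and so on), keeping their
#' counts well above the Poisson noise floor; background OTUs fill the
#' remaining ranks.
#'
#' @param nSamples number of samples (>= 3).
#' @param nOtus number of OTUs; must allow 2 features per planted
#'   pair.
#' @param planted data.frame with columns \code{sign} ("pos"/"neg")
#'   and \code{r} (target magnitude in (0,1), sign implied), one row
#'   per planted pair; \code{NULL} for none.
#' @param dominance log-normal SAD width (>= 0).
#' @param depth expected total reads per sample.
#' @param logNoiseSd total log-scale noise sd \eqn{\tau} (default
#'   0.4).
#' @param seed integer seed; identical inputs give bit-identical
#'   tables.
#' @param prefix feature-id prefix.
#' @return list with \code{table} (an OTU \linkS4class{FeatureTable})
#'   and \code{truth} (list: \code{plantedEdges} data.frame with
#'   \code{feature_a}, \code{feature_b}, \code{sign}, \code{r};
#'   \code{dominance}; \code{seed}).
#' @export
generateOtuTable <- function(nSamples, nOtus, planted = NULL,
                             dominance = 1.5, depth = 20000,
                             logNoiseSd = 0.4, seed = 1L,
                             prefix = "OTU") {
  stopifnot(nSamples >= 3, nOtus >= 1, dominance >= 0, logNoiseSd > 0)
  nPairs <- if (is.null(planted)) 0L else nrow(planted)
  if (2L * nPairs > nOtus)
    stop("more planted pair features than OTUs")
  if (nPairs > 0L) {
    stopifnot(all(planted$sign %in% c("pos", "neg")),
              all(planted$r > 0), all(planted$r < 1))
  }
  set.seed(seed)
  tau <- logNoiseSd
  ids <- sprintf("%s_%03d", prefix, seq_len(nOtus))
  smp <- sprintf("S%02d", seq_len(nSamples))
  # ranked log-normal SAD, most abundant first
  w <- exp(dominance * stats::qnorm((seq_len(nOtus) - 0.5) / nOtus))
  w <- sort(w / sum(w), decreasing = TRUE)

  lambda <- numeric(nOtus)
  factorOf <- integer(nOtus)
  signOf <- numeric(nOtus)
  edges <- NULL
  if (nPairs > 0L) {
    rs <- ifelse(planted$sign == "pos", planted$r, -planted$r)
    for (k in seq_len(nPairs)) {
      ia <- 2L * k - 1L
      ib <- 2L * k
      l <- .loadingForR(rs[k], tau)
      lambda[c(ia, ib)] <- l
      factorOf[c(ia, ib)] <- k
      signOf[ia] <- 1
      signOf[ib] <- if (planted$sign[k] == "pos") 1 else -1
    }
    edges <- data.frame(feature_a = ids[2L * seq_len(nPairs) - 1L],
                        feature_b = ids[2L * seq_len(nPairs)],
                        sign = planted$sign, r = planted$r,
                        stringsAsFactors = FALSE)
  }
  z <- matrix(rnorm(max(nPairs, 1L) * nSamples), nrow = max(nPairs, 1L))
  u <- matrix(rnorm(nOtus * nSamples), nrow = nOtus)
  resid <- sqrt(pmax(tau^2 - lambda^2, 0))
  shared <- matrix(0, nOtus, nSamples)
  if (nPairs > 0L) {
    pl <- which(factorOf > 0L)
    shared[pl, ] <- (signOf[pl] * lambda[pl]) * z[factorOf[pl], , drop = FALSE]
  }
  mu <- log(depth * w) + shared + resid * u - tau^2 / 2
  counts <- matrix(rpois(length(mu), exp(mu)), nOtus, nSamples,
                   dimnames = list(ids, smp))
  list(table = FeatureTable(counts, "otu"),
       truth = list(plantedEdges = edges, dominance = dominance,
                    seed = seed))
}

#' Generate metabolite abundances coupled to community diversity
#'
#' Each coupled metabolite is a linear response to the per-sample
#' first-order Hill number (exponential Shannon) of the OTU table:
#' standardized \eqn{{}^1D} times a signed effect size, plus Gaussian
#' noise of sd \code{noiseSd}, shifted to be positive. With unit noise
#' the population correlation with \eqn{{}^1D} is
#' \eqn{\pm effect/\sqrt{effect^2+1}}; \code{noiseSd = 0} gives a
#' perfect +/-1 correlation. Uncoupled metabolites are independent
#' noise.
#'
#' @param otuTable OTU \linkS4class{FeatureTable} supplying the
#'   per-sample diversity.
#' @param effects data.frame with columns \code{name}, \code{sign}
#'   ("pos"/"neg") and \code{effect} (>= 0); \code{NULL} for none.
#' @param nNoise number of additional uncoupled metabolites.
#' @param noiseSd Gaussian noise sd on coupled metabolites (default
#'   1).
#' @param seed integer seed.
#' @return list with \code{table} (metabolite
#'   \linkS4class{FeatureTable} over the same samples) and
#'   \code{truth} (the effects table).
#' @export
generateMetaboliteTable <- function(otuTable, effects = NULL, nNoise = 0,
                                    noiseSd = 1, seed = 1L) {
  stopifnot(is(otuTable, "FeatureTable"), nNoise >= 0, noiseSd >= 0)
  set.seed(seed)
  n <- ncol(otuTable)
  d1 <- diversityProfile(otuTable, q = 1)[, "q1"]
  zd <- as.numeric(scale(d1))
  rows <- list()
  if (!is.null(effects) && nrow(effects)) {
    stopifnot(all(effects$sign %in% c("pos", "neg")),
              all(effects$effect >= 0))
    for (i in seq_len(nrow(effects))) {
      s <- if (effects$sign[i] == "pos") 1 else -1
      v <- s * effects$effect[i] * zd + noiseSd * rnorm(n)
      rows[[effects$name[i]]] <- v - min(v) + 1
    }
  }
  if (nNoise > 0) {
    for (i in seq_len(nNoise)) {
      v <- rnorm(n)
      rows[[sprintf("Met_noise_%02d", i)]] <- v - min(v) + 1
    }
  }
  if (!length(rows)) stop("no metabolites requested")
  m <- do.call(rbind, rows)
  colnames(m) <- colnames(otuTable)
  list(table = FeatureTable(m, "metabolite"),
       truth = list(diversityEffects = effects, seed = seed))
}

#' Simulate the milk-study design
#'
#' A preset emulating the cohort layout and statistical structure of
#' the milk microbiome chemotherapy study the package's workflow is
#' built around: three groups (8 pre-chemotherapy and 8
#' post-chemotherapy samples from one longitudinal series, 9 healthy
#' samples), around 60-70 OTUs per group surviving the low-total
#' filter, steeply declining Hill-number profiles with patient groups
#' markedly less diverse than healthy ones, group-specific planted
#' positive and negative OTU-OTU correlations (the pre-chemotherapy
#' group carries almost no negative pairs, so its inferred network
#' shows an inflated P/N ratio), and nine metabolites coupled to
#' diversity (4 positively: DHA, Inositol, Threitol, PUFA; 5
#' negatively: Butanal, Xlmonopalmitin, DecanoicAcid, Arabinose,
#' MyristicAcid) among background noise metabolites.
#'
#' @param seed integer seed driving every random draw.
#' @param outDir optional directory; when given, writes
#'   \code{otu.tsv}, \code{metabolites.tsv}, \code{groups.tsv} and
#'   \code{truth.json} there.
#' @return list with \code{otu} (FeatureTable over all 25 samples),
#'   \code{metabolites} (FeatureTable), \code{groups} (named vector)
#'   and \code{truth} (per-group planted edges and metabolite
#'   effects).
#' @export
simulateMilkStudy <- function(seed = 1L, outDir = NULL) {
  layout <- list(
    pre     = list(n = 8L, dominance = 2.6, planted = .plantSpec(11L, 1L)),
    post    = list(n = 8L, dominance = 2.4, planted = .plantSpec(8L, 4L)),
    healthy = list(n = 9L, dominance = 1.6, planted = .plantSpec(7L, 5L)))
  tabs <- list()
  groups <- character()
  truthEdges <- list()
  off <- 0L
  for (gname in names(layout)) {
    cfg <- layout[[gname]]
    sim <- generateOtuTable(cfg$n, nOtus = 70L, planted = cfg$planted,
                            dominance = cfg$dominance, depth = 20000,
                            seed = seed + off)
    m <- abundances(sim$table)
    colnames(m) <- sprintf("%s_%02d", gname, seq_len(ncol(m)))
    tabs[[gname]] <- m
    groups <- c(groups, setNames(rep(gname, ncol(m)), colnames(m)))
    ed <- sim$truth$plantedEdges
    ed$group <- gname
    truthEdges[[gname]] <- ed
    off <- off + 1L
  }
  otu <- FeatureTable(do.call(cbind, tabs), "otu")
  met <- generateMetaboliteTable(otu, effects = milkMetaboliteEffects(),
                                 nNoise = 11L, noiseSd = 0.5,
                                 seed = seed + 100L)
  truth <- list(plantedEdges = do.call(rbind, truthEdges),
                diversityEffects = met$truth$diversityEffects,
                dominance = vapply(layout, `[[`, numeric(1), "dominance"),
                seed = seed)
  out <- list(otu = otu, metabolites = met$table, groups = groups,
              truth = truth)
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    writeFeatureTable(otu, file.path(outDir, "otu.tsv"), "otu_id")
    writeFeatureTable(met$table, file.path(outDir, "metabolites.tsv"),
                      "metabolite")
    writeGroupFile(groups, file.path(outDir, "groups.tsv"))
    jsonlite::write_json(truth, file.path(outDir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  out
}

.plantSpec <- function(nPos, nNeg, r = 0.8) {
  data.frame(sign = c(rep("pos", nPos), rep("neg", nNeg)),
             r = r, stringsAsFactors = FALSE)
}

#' @rdname simulateMilkStudy
#' @export
milkMetaboliteEffects <- function() {
  data.frame(
    name = c("DHA", "Inositol", "Threitol", "PUFA",
             "Butanal", "Xlmonopalmitin", "DecanoicAcid", "Arabinose",
             "MyristicAcid"),
    sign = c(rep("pos", 4L), rep("neg", 5L)),
    effect = 3,
    stringsAsFactors = FALSE)
}
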