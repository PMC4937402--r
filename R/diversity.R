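#' Hill number (effective number of species) of order q
#'
#' For a relative-abundance vector p (all entries positive, summing to
#' one) the diversity of order q is
#' \deqn{{}^qD = \left(\sum_i p_i^q\right)^{1/(1-q)},}
#' with the q = 1 singularity resolved by its limit, the exponential of
#' Shannon entropy \eqn{\exp(-\sum_i p_i \ln p_i)} (natural logarithm;
#' the exp/ln pairing is what makes the result an effective species
#' count). Orders within 1e-9 of 1 are routed to the limit formula for
#' numerical stability. At q = 0 the value is species richness; at
#' q = 2 it is the reciprocal of the Simpson index \eqn{1/\sum_i p_i^2}.
#' The result is interpreted as the number of equally abundant species
#' that would give the same diversity.
#'
#' @param p numeric vector of relative abundances; every entry must be
#'   strictly positive and the vector must sum to 1 (tolerance 1e-9).
#'   Use \code{\link{diversityProfile}} to go from raw counts.
#' @param q diversity order(s), finite and >= 0; vectorized.
#' @return numeric vector of effective species numbers, one per order.
#' @examples
#' hillNumber(rep(0.25, 4), q = 0:4)     # 4 at every order
#' hillNumber(c(0.5, 0.3, 0.2), q = 2)   # 1 / 0.38
#' @export
hillNumber <- function(p, q) {
  if (length(p) == 0L) stop("empty abundance vector")
  if (any(!is.finite(p)) || any(p <= 0))
    stop("all relative abundances must be strictly positive and finite")
  if (abs(sum(p) - 1) > 1e-9)
    stop("relative abundances must sum to 1 (normalize counts first)")
  if (any(!is.finite(q)) || any(q < 0)) stop("q must be finite and >= 0")
  vapply(q, function(qi) {
    if (abs(qi - 1) < 1e-9) exp(-sum(p * log(p)))
    else sum(p^qi)^(1 / (1 - qi))
  }, numeric(1))
}

#' Per-sample Hill-number diversity profiles
#'
#' Converts each sample's counts to relative abundances (zero-count
#' features are dropped first; they carry no abundance information and
#' richness counts only features present) and evaluates
#' \code{\link{hillNumber}} over a grid of orders.
#'
#' @param x a \linkS4class{FeatureTable}, or a numeric matrix with
#'   features as rows and samples as columns.
#' @param q grid of diversity orders (default 0:4).
#' @return numeric matrix, samples x orders, with column names
#'   \code{"q0"}, \code{"q1"}, ... Errors if any sample is all-zero.
#' @export
diversityProfile <- function(x, q = 0:4) {
  m <- if (is(x, "FeatureTable")) abundances(x) else as.matrix(x)
  if (is.null(colnames(m))) colnames(m) <- paste0("S", seq_len(ncol(m)))
  zero <- colSums(m) == 0
  if (any(zero))
    stop("all-zero sample(s): ", paste(colnames(m)[zero], collapse = ", "))
  out <- vapply(seq_len(ncol(m)), function(j) {
    v <- m[, j]
    v <- v[v > 0]
    hillNumber(v / sum(v), q)
  }, numeric(length(q)))
  out <- t(matrix(out, nrow = length(q)))
  dimnames(out) <- list(colnames(m), paste0("q", q))
  out
}

.checkGroups <- function(profiles, groups) {
  if (is.null(names(groups))) stop("groups must be a named vector")
  missing <- setdiff(rownames(profiles), names(groups))
  if (length(missing))
    stop("samples without group assignment: ", paste(missing, collapse = ", "))
  factor(groups[rownames(profiles)])
}

#' Group mean diversity profiles
#'
#' Arithmetic mean of per-sample Hill numbers within each group, per
#' order.
#'
#' @param profiles samples x orders matrix from
#'   \code{\link{diversityProfile}} (or any matrix of per-sample
#'   diversity values with sample rownames).
#' @param groups named vector mapping sample id to group label; every
#'   profiled sample must be assigned.
#' @return numeric matrix, groups x orders.
#' @export
groupMeanProfile <- function(profiles, groups) {
  f <- .checkGroups(profiles, groups)
  out <- apply(profiles, 2, function(col) tapply(col, f, mean))
  if (nlevels(f) == 1L) out <- matrix(out, nrow = 1L,
                                      dimnames = list(levels(f),
                                                      colnames(profiles)))
  out
}

#' Two-sample Student's t-tests on diversity values
#'
#' Classical two-sided pooled-variance (equal-variance) t-test on the
#' per-sample Hill numbers of two groups, one test per diversity
#' order. \code{exclude} removes named samples beforehand, for
#' sensitivity analyses (e.g. dropping a longitudinal series' baseline
#' sample); nothing is excluded by default.
#'
#' @param profiles samples x orders matrix.
#' @param groups named sample-to-group vector.
#' @param groupA,groupB the two group labels to compare.
#' @param exclude character vector of sample ids to drop first.
#' @return data.frame with one row per order: \code{q}, \code{meanA},
#'   \code{meanB}, \code{t}, \code{p}.
#' @export
compareGroupsT <- function(profiles, groups, groupA, groupB,
                           exclude = character()) {
  profiles <- profiles[!rownames(profiles) %in% exclude, , drop = FALSE]
  f <- .checkGroups(profiles, groups)
  if (!groupA %in% levels(f) || !groupB %in% levels(f))
    stop("both groups must be present among the profiled samples")
  a <- profiles[f == groupA, , drop = FALSE]
  b <- profiles[f == groupB, , drop = FALSE]
  if (nrow(a) < 2L || nrow(b) < 2L)
    stop("each group needs at least two samples")
  res <- lapply(colnames(profiles), function(qn) {
    tt <- t.test(a[, qn], b[, qn], var.equal = TRUE)
    data.frame(q = qn, meanA = mean(a[, qn]), meanB = mean(b[, qn]),
               t = unname(tt$statistic), p = tt$p.value)
  })
  do.call(rbind, res)
}

#' Bundled per-sample milk microbiome diversity profiles
#'
#' Per-sample Hill numbers (orders q = 0..4) for 25 human milk
#' microbiome samples: a longitudinal series from one donor sampled
#' before (8 samples) and after (8 samples) chemotherapy for Hodgkin's
#' lymphoma, and 9 samples from healthy donors. Shipped as a
#' plain-text reference dataset for group comparison examples.
#'
#' @return list with \code{profiles} (25 x 5 matrix) and \code{groups}
#'   (named character vector with levels \code{pre}, \code{post},
#'   \code{healthy}).
#' @export
milkDiversityData <- function() {
  path <- system.file("extdata", "milk_hill_profiles.tsv",
                      package = "hillnet", mustWork = TRUE)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  profiles <- as.matrix(df[, paste0("q", 0:4)])
  rownames(profiles) <- df$sample_id
  list(profiles = profiles, groups = setNames(df$group, df$sample_id))
}
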