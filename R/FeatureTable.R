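#' Construct a FeatureTable
#'
#' @param values numeric matrix, features as rows and samples as
#'   columns, with rownames (feature ids) and colnames (sample ids).
#' @param featureKind \code{"otu"}, \code{"metabolite"} or
#'   \code{"diversity_order"}.
#' @return a \linkS4class{FeatureTable}.
#' @examples
#' m <- matrix(1:6, nrow = 3, dimnames = list(paste0("f", 1:3), c("s1", "s2")))
#' ft <- FeatureTable(m, "otu")
#' dim(ft)
#' @export
FeatureTable <- function(values, featureKind = c("otu", "metabolite",
                                                 "diversity_order")) {
  featureKind <- match.arg(featureKind)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(abundance = values))
  new("FeatureTable", se, featureKind = featureKind)
}

#' @rdname FeatureTable
#' @param x,object a \code{FeatureTable}.
#' @export
abundances <- function(x) {
  stopifnot(is(x, "FeatureTable"))
  SummarizedExperiment::assay(x, "abundance")
}

#' @rdname FeatureTable
#' @export
featureIds <- function(x) rownames(x)

#' @rdname FeatureTable
#' @export
sampleIds <- function(x) colnames(x)

#' @rdname FeatureTable
#' @export
featureKind <- function(x) {
  stopifnot(is(x, "FeatureTable"))
  x@featureKind
}

setMethod("show", "FeatureTable", function(object) {
  cat(sprintf("FeatureTable (%s): %d features x %d samples\n",
              object@featureKind, nrow(object), ncol(object)))
  cat("  features: ", .abbrev(featureIds(object)), "\n", sep = "")
  cat("  samples:  ", .abbrev(sampleIds(object)), "\n", sep = "")
})

.abbrev <- function(x, k = 4) {
  if (length(x) <= k) paste(x, collapse = ", ")
  else paste0(paste(x[seq_len(k)], collapse = ", "), ", ... (", length(x), ")")
}

#' Drop features whose within-table total is below a threshold
#'
#' Low-total features in a count table are likely spurious reads; they
#' are removed before network inference. A feature is kept iff its
#' total over all samples is \code{>= minTotal} (a total exactly equal
#' to the threshold is kept). Feature order is preserved.
#'
#' @param x a \linkS4class{FeatureTable}.
#' @param minTotal minimum total abundance (default 5).
#' @return the filtered \code{FeatureTable}; warns if it is empty, and
#'   if an OTU table contains non-integer counts.
#' @export
filterLowTotal <- function(x, minTotal = 5) {
  stopifnot(is(x, "FeatureTable"), minTotal >= 0)
  m <- abundances(x)
  if (featureKind(x) == "otu" && any(m != round(m)))
    warning("OTU table contains non-integer counts")
  keep <- rowSums(m) >= minTotal
  if (!any(keep)) warning("all features fall below the total threshold")
  x[keep, ]
}
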