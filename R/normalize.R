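#' Median-of-ratios size factors
#'
#' Per-sample scaling constants making libraries comparable: for each gene
#' with a strictly positive geometric mean across samples (i.e. no zero
#' count), the ratio of its count in sample *j* to that geometric mean is
#' formed, and the size factor \eqn{s_j} is the median of those ratios.
#' Geometric means are accumulated in log space; the median uses the midpoint
#' convention for an even number of reference genes.
#'
#' @param counts count matrix (genes x samples) or a [DuxExperiment-class].
#' @return Named numeric vector of positive size factors, one per sample.
#' @export
#' @examples
#' m <- matrix(c(1, 2, 4, 8, 2, 4, 8, 16), 4, 2,
#'             dimnames = list(paste0("g", 1:4), c("a", "b")))
#' computeSizeFactors(m)  # (1/sqrt(2), sqrt(2))
computeSizeFactors <- function(counts) {
  if (methods::is(counts, "DuxExperiment"))
    counts <- SummarizedExperiment::assay(counts, "counts")
  counts <- as.matrix(counts)
  gm <- .rowGeoMean(counts)
  ref <- which(!is.na(gm) & gm > 0)
  if (length(ref) == 0L)
    stop("degenerate input: no gene has positive counts in every sample")
  ratios <- counts[ref, , drop = FALSE] / gm[ref]
  sf <- apply(ratios, 2L, stats::median)
  if (any(!is.finite(sf) | sf <= 0))
    stop("degenerate input: non-positive size factor")
  sf
}

#' Divide counts by size factors
#'
#' @param counts count matrix or [DuxExperiment-class].
#' @param sizeFactors named positive vector from [computeSizeFactors()]; when
#'   `NULL`, computed from `counts`. Names must match the sample ids.
#' @return Matrix of normalized counts (counts / s_j, zeros stay zero).
#' @export
normalizeCounts <- function(counts, sizeFactors = NULL) {
  if (methods::is(counts, "DuxExperiment"))
    counts <- SummarizedExperiment::assay(counts, "counts")
  counts <- as.matrix(counts)
  if (is.null(sizeFactors)) sizeFactors <- computeSizeFactors(counts)
  if (!is.null(names(sizeFactors))) {
    if (!setequal(names(sizeFactors), colnames(counts)))
      stop("size factor names do not match sample ids")
    sizeFactors <- sizeFactors[colnames(counts)]
  } else if (length(sizeFactors) != ncol(counts)) {
    stop("size factor length does not match number of samples")
  }
  if (any(sizeFactors <= 0)) stop("size factors must be positive")
  sweep(counts, 2L, sizeFactors, "/")
}

#' Log2 transform with pseudocount
#'
#' The scale on which the composite activity scores operate:
#' \code{log2(x + pseudocount)}.
#'
#' @param x non-negative matrix (normalized counts).
#' @param pseudocount positive offset, default 1.
#' @return Matrix of the same shape.
#' @export
logTransform <- function(x, pseudocount = 1) {
  if (!is.numeric(pseudocount) || length(pseudocount) != 1 ||
      !is.finite(pseudocount) || pseudocount <= 0)
    stop("pseudocount must be a positive number")
  log2(x + pseudocount)
}

#' qPCR relative expression from CT values
#'
#' Implements the delta-CT rule \eqn{r = 2^{CT_{ref} - CT_{marker}}} (reference
#' gene: cyclophilin A / PPIA in this assay design), optionally rescaled by
#' the mean vehicle value so vehicle averages 1. Undetermined CTs (NA, or a
#' sentinel such as 40 passed via `undetermined`) are flagged
#' below-detection and returned as NA with a warning.
#'
#' @param ctRef reference-gene CT value(s), cycles.
#' @param ctMarker marker-gene CT value(s), cycles (recycled against `ctRef`).
#' @param vehicleMean optional positive scalar; when given the result is
#'   `r / vehicleMean`.
#' @param undetermined optional sentinel CT value treated as below detection.
#' @return Numeric vector of relative expression values.
#' @export
#' @examples
#' qpcrRelativeExpression(20, 25)        # 2^-5 = 0.03125
#' qpcrRelativeExpression(20, 20)        # 1
#' qpcrRelativeExpression(20, 22, vehicleMean = 0.5)
qpcrRelativeExpression <- function(ctRef, ctMarker, vehicleMean = NULL,
                                   undetermined = NULL) {
  bad <- !is.finite(ctRef) | !is.finite(ctMarker)
  if (!is.null(undetermined))
    bad <- bad | ctRef == undetermined | ctMarker == undetermined
  if (any(bad))
    warning(sum(bad), " observation(s) below detection excluded (NA)")
  r <- 2^(ctRef - ctMarker)
  r[bad] <- NA_real_
  if (!is.null(vehicleMean)) {
    if (!is.numeric(vehicleMean) || vehicleMean <= 0)
      stop("vehicleMean must be positive")
    r <- r / vehicleMean
  }
  r
}
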