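# internal validation / numeric helpers

.checkCountMatrix <- function(counts) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("count matrix needs gene (row) and sample (column) names")
  if (anyDuplicated(rownames(counts))) stop("duplicate gene ids")
  if (anyDuplicated(colnames(counts))) stop("duplicate sample ids")
  if (!is.numeric(counts)) stop("counts must be numeric")
  if (any(!is.finite(counts))) stop("counts must be finite")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(counts != round(counts))) stop("counts must be integral")
  storage.mode(counts) <- "double"
  counts
}

# geometric mean per row in log space; rows containing a zero get NA
.rowGeoMean <- function(m) {
  lg <- log(m)
  lg[!is.finite(lg)] <- NA
  gm <- exp(rowMeans(lg))
  gm[apply(m, 1L, function(r) any(r <= 0))] <- NA
  gm
}

.stopIfNot <- function(cond, msg) if (!cond) stop(msg, call. = FALSE)

# standard error of the mean
.sem <- function(x) stats::sd(x) / sqrt(length(x))
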