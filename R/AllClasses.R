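#' @import methods
#' @importFrom S4Vectors DataFrame SimpleList metadata `metadata<-`
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

.SAMPLE_STATES <- c("myoblast", "myotube")

#' Container for an FSHD muscle-cell counting experiment
#'
#' `DuxExperiment` extends [SummarizedExperiment::SummarizedExperiment] with a
#' `"counts"` assay of non-negative integers and a column annotation carrying
#' the sample sheet (`sample_id`, `state`, `treatment`, `dose`, `replicate`).
#' It is the central input object of the pipeline: myoblast and myotube
#' samples, vehicle and drug-treated, each in replicate.
#'
#' @slot .. see [SummarizedExperiment::SummarizedExperiment]; no extra slots.
#'
#' @aliases DuxExperiment-class
#' @exportClass DuxExperiment
setClass("DuxExperiment", contains = "SummarizedExperiment")

.validDuxExperiment <- function(object) {
  msg <- NULL
  if (!("counts" %in% SummarizedExperiment::assayNames(object)))
    msg <- c(msg, "assay 'counts' is required")
  else {
    m <- SummarizedExperiment::assay(object, "counts")
    if (any(m < 0)) msg <- c(msg, "counts must be non-negative")
    if (any(m != round(m))) msg <- c(msg, "counts must be integral")
  }
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "duplicate gene ids")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "duplicate sample ids")
  cd <- SummarizedExperiment::colData(object)
  need <- c("sample_id", "state", "treatment", "dose", "replicate")
  miss <- setdiff(need, colnames(cd))
  if (length(miss))
    msg <- c(msg, paste0("sample sheet columns missing: ",
                         paste(miss, collapse = ", ")))
  else {
    if (!all(cd$state %in% .SAMPLE_STATES))
      msg <- c(msg, "state must be 'myoblast' or 'myotube'")
    if (any(cd$dose < 0)) msg <- c(msg, "dose must be >= 0")
    if (any(cd$treatment == "vehicle" & cd$dose != 0))
      msg <- c(msg, "vehicle samples must have dose 0")
    if (!identical(as.character(cd$sample_id), colnames(object)))
      msg <- c(msg, "colData sample_id must match column names in order")
  }
  if (is.null(msg)) TRUE else msg
}

setValidity("DuxExperiment", .validDuxExperiment)

#' Construct a DuxExperiment from a count matrix and a sample sheet
#'
#' @param counts integer matrix, genes in rows (rownames = gene ids), samples
#'   in columns (colnames = sample ids).
#' @param sampleSheet `data.frame` or `DataFrame` with columns `sample_id`,
#'   `state` (`"myoblast"`/`"myotube"`), `treatment`, `dose` (micromolar,
#'   0 for vehicle) and `replicate`; rows must cover exactly the columns of
#'   `counts` (matched by `sample_id`, reordered if necessary).
#'
#' @return A validated [DuxExperiment-class] object.
#' @export
#' @examples
#' cm <- matrix(rpois(12, 10), 4, 3,
#'              dimnames = list(paste0("g", 1:4), paste0("s", 1:3)))
#' sh <- data.frame(sample_id = paste0("s", 1:3), state = "myotube",
#'                  treatment = "vehicle", dose = 0, replicate = 1:3)
#' DuxExperiment(cm, sh)
DuxExperiment <- function(counts, sampleSheet) {
  counts <- .checkCountMatrix(counts)
  sampleSheet <- as.data.frame(sampleSheet)
  if (anyDuplicated(sampleSheet$sample_id))
    stop("duplicate sample_id in sample sheet")
  if (!setequal(sampleSheet$sample_id, colnames(counts)))
    stop("sample sheet and count matrix disagree on sample ids")
  sampleSheet <- sampleSheet[match(colnames(counts), sampleSheet$sample_id), ,
                             drop = FALSE]
  rownames(sampleSheet) <- sampleSheet$sample_id
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(sampleSheet))
  new("DuxExperiment", se)
}

#' @describeIn DuxExperiment Sample sheet stored in the column annotation.
#' @param x,object a `DuxExperiment`
#' @export
sampleSheet <- function(x) {
  as.data.frame(SummarizedExperiment::colData(x))
}

setMethod("show", "DuxExperiment", function(object) {
  cd <- SummarizedExperiment::colData(object)
  cat("DuxExperiment:", nrow(object), "genes x", ncol(object), "samples\n")
  cat("  states:    ", paste(names(table(cd$state)),
                             table(cd$state), sep = ":", collapse = " "), "\n")
  cat("  treatments:", paste(unique(cd$treatment), collapse = ", "), "\n")
})

#' Named collection of gene sets
#'
#' Holds named, non-empty gene-id sets (e.g. the three published DUX4
#' target-gene programs and the PAX7 up/down programs) together with their
#' one-line descriptions, as carried by GMT files.
#'
#' @slot sets named list of character vectors of gene ids.
#' @slot descriptions named character vector, parallel to `sets`.
#'
#' @aliases GeneSetCollection-class
#' @exportClass GeneSetCollection
setClass("GeneSetCollection",
         representation(sets = "list", descriptions = "character"))

setValidity("GeneSetCollection", function(object) {
  msg <- NULL
  if (is.null(names(object@sets)) || anyDuplicated(names(object@sets)))
    msg <- c(msg, "set names must be present and unique")
  if (any(!vapply(object@sets, is.character, logical(1))))
    msg <- c(msg, "each set must be a character vector of gene ids")
  if (any(lengths(object@sets) == 0L))
    msg <- c(msg, "each set must be non-empty")
  if (any(vapply(object@sets, function(s) any(!nzchar(s)), logical(1))))
    msg <- c(msg, "gene ids must be non-empty strings")
  if (length(object@descriptions) != length(object@sets))
    msg <- c(msg, "descriptions must parallel sets")
  if (is.null(msg)) TRUE else msg
})

#' Construct a GeneSetCollection
#'
#' @param sets named list of character vectors of gene ids; duplicates within
#'   a set are removed with a warning.
#' @param descriptions optional character vector of per-set descriptions.
#' @return A [GeneSetCollection-class].
#' @export
GeneSetCollection <- function(sets, descriptions = NULL) {
  ndup <- vapply(sets, anyDuplicated, integer(1))
  if (any(ndup > 0)) {
    warning("duplicate gene ids removed in set(s): ",
            paste(names(sets)[ndup > 0], collapse = ", "))
    sets <- lapply(sets, unique)
  }
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  names(descriptions) <- names(sets)
  new("GeneSetCollection", sets = sets, descriptions = descriptions)
}

#' @describeIn GeneSetCollection the named list of gene-id vectors
#' @param x,object a `GeneSetCollection`
#' @export
geneSets <- function(x) x@sets

#' @export
setMethod("length", "GeneSetCollection", function(x) length(x@sets))

#' @export
setMethod("names", "GeneSetCollection", function(x) names(x@sets))

#' @export
setMethod("[[", "GeneSetCollection", function(x, i) x@sets[[i]])

setMethod("show", "GeneSetCollection", function(object) {
  cat("GeneSetCollection of", length(object@sets), "sets\n")
  n <- utils::head(names(object@sets), 5)
  for (s in n)
    cat("  ", s, " (", length(object@sets[[s]]), " genes)\n", sep = "")
  if (length(object@sets) > 5) cat("  ...\n")
})

#' Four-parameter logistic dose-response fit
#'
#' Result of fitting the variable-slope inhibition model
#' \deqn{y = bottom + (top - bottom) / (1 + 10^{hill (\log_{10} x - \log_{10} IC_{50})})}
#' to a dose series, as used for IC50 extraction.
#'
#' @slot bottom,top fitted asymptotes (response units).
#' @slot ic50 fitted half-maximal inhibitory concentration (micromolar).
#' @slot hill fitted (positive) slope factor.
#' @slot rss residual sum of squares at the optimum.
#' @slot converged logical; optimizer convergence flag.
#' @slot extrapolated logical; TRUE when the fitted IC50 lies outside the
#'   tested dose span (reported as a "> max dose" sentinel downstream).
#'
#' @aliases DoseResponseFit-class
#' @exportClass DoseResponseFit
setClass("DoseResponseFit",
         representation(bottom = "numeric", top = "numeric", ic50 = "numeric",
                        hill = "numeric", rss = "numeric",
                        converged = "logical", extrapolated = "logical"))

setValidity("DoseResponseFit", function(object) {
  if (length(object@ic50) == 1 && is.finite(object@ic50) && object@ic50 <= 0)
    "ic50 must be positive" else TRUE
})

setMethod("show", "DoseResponseFit", function(object) {
  cat(sprintf(
    "4PL fit: IC50 = %.4g uM%s, hill = %.3g, bottom = %.3g, top = %.3g\n",
    object@ic50, if (object@extrapolated) " (beyond top dose)" else "",
    object@hill, object@bottom, object@top))
  cat(sprintf("  rss = %.4g, converged: %s\n", object@rss, object@converged))
})

#' @describeIn DoseResponseFit fitted IC50 in micromolar
#' @param x,object a `DoseResponseFit`
#' @export
ic50 <- function(x) x@ic50

#' @describeIn DoseResponseFit fitted parameters as a named vector
#' @export
fitParameters <- function(x) {
  c(bottom = x@bottom, top = x@top, ic50 = x@ic50, hill = x@hill,
    rss = x@rss)
}

#' Synthetic experiment with its ground truth
#'
#' Returned by [simulateExperiment()]: the simulated counting experiment, the
#' simulated program memberships, and a truth ledger (latent per-sample DUX4
#' activities, true per-gene log2 fold-changes, true IC50s, seed) against which
#' the analysis layer can be validated.
#'
#' @slot experiment a [DuxExperiment-class].
#' @slot geneSets a [GeneSetCollection-class] with the simulated programs.
#' @slot truth named list: `activity` (per-sample latent DUX4 activity in
#'   \[0,1\]), `pax7_activity`, `burst` (per-sample 0/1), `log2fc` (per-gene
#'   true effects per contrast), `drugs` (true IC50/hill per drug),
#'   `size_factors`, `baseline_mean`, `dispersion`, `seed`.
#'
#' @aliases DuxSimulation-class
#' @exportClass DuxSimulation
setClass("DuxSimulation",
         representation(experiment = "DuxExperiment",
                        geneSets = "GeneSetCollection",
                        truth = "list"))

setMethod("show", "DuxSimulation", function(object) {
  cat("DuxSimulation (seed", object@truth$seed, ")\n")
  show(object@experiment)
  cat("  programs:", paste(names(object@geneSets), collapse = ", "), "\n")
})

#' @describeIn DuxSimulation the simulated experiment
#' @param x,object a `DuxSimulation`
#' @export
experiment <- function(x) x@experiment

#' @describeIn DuxSimulation the simulated program memberships
#' @export
simGeneSets <- function(x) x@geneSets

#' @describeIn DuxSimulation the ground-truth ledger
#' @export
simTruth <- function(x) x@truth
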