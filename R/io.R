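#' Read a gene-by-sample count matrix
#'
#' Two dialects are supported. `"tsv"`: tab-separated, header row of sample
#' ids, first column (named `gene_id`) of gene ids, no quoting. `"mtx"`:
#' MatrixMarket coordinate triplet (1-based indices; absent entries are zero)
#' with sidecar plain-text row-name and column-name files, one id per line
#' (defaults: `<path>.rownames` / `<path>.colnames`).
#'
#' Gene identifiers are treated as opaque case-sensitive strings; the order of
#' genes and samples is preserved exactly as found in the file.
#'
#' @param path file to read.
#' @param format `"tsv"` or `"mtx"`.
#' @param rownamesPath,colnamesPath sidecar id files for the mtx dialect.
#' @return A numeric matrix of validated counts with dimnames.
#' @export
readCounts <- function(path, format = c("tsv", "mtx"),
                       rownamesPath = paste0(path, ".rownames"),
                       colnamesPath = paste0(path, ".colnames")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tsv") {
    df <- utils::read.delim(path, check.names = FALSE, quote = "",
                            colClasses = NA, stringsAsFactors = FALSE)
    if (ncol(df) < 2) stop("counts TSV needs a gene_id column and >=1 sample")
    genes <- as.character(df[[1L]])
    m <- as.matrix(df[, -1L, drop = FALSE])
    rownames(m) <- genes
  } else {
    mm <- Matrix::readMM(path)
    rn <- readLines(rownamesPath)
    cn <- readLines(colnamesPath)
    if (nrow(mm) != length(rn) || ncol(mm) != length(cn))
      stop("sidecar name files do not match matrix dimensions")
    m <- as.matrix(mm)
    dimnames(m) <- list(rn, cn)
  }
  .checkCountMatrix(m)
}

#' Write a count matrix
#'
#' Inverse of [readCounts()]; the TSV dialect uses a literal `gene_id` first
#' column header so the file round-trips unambiguously.
#'
#' @param counts matrix with dimnames.
#' @param path destination file.
#' @inheritParams readCounts
#' @return Invisibly, `path`.
#' @export
writeCounts <- function(counts, path, format = c("tsv", "mtx"),
                        rownamesPath = paste0(path, ".rownames"),
                        colnamesPath = paste0(path, ".colnames")) {
  format <- match.arg(format)
  counts <- .checkCountMatrix(counts)
  if (format == "tsv") {
    df <- data.frame(gene_id = rownames(counts), counts,
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    Matrix::writeMM(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                "generalMatrix"), path)
    writeLines(rownames(counts), rownamesPath)
    writeLines(colnames(counts), colnamesPath)
  }
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' Each line is tab-separated: set name, description, then one or more gene
#' ids. Duplicate ids within a set are dropped with a warning; a duplicate
#' set name or a line with fewer than three fields is a format error.
#'
#' @param path GMT file.
#' @return A [GeneSetCollection-class].
#' @export
readGMT <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(fields) < 3L
  if (any(short))
    stop("GMT line(s) with fewer than 3 fields: ",
         paste(which(short), collapse = ", "))
  nm <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(nm))
    stop("duplicate gene set name(s): ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- nm
  desc <- vapply(fields, `[[`, character(1), 2L)
  GeneSetCollection(sets, desc)
}

#' Write a GeneSetCollection as GMT
#'
#' @param gsc a [GeneSetCollection-class].
#' @param path destination file.
#' @return Invisibly, `path`.
#' @export
writeGMT <- function(gsc, path) {
  lines <- vapply(names(gsc), function(nm) {
    paste(c(nm, gsc@descriptions[[nm]], gsc@sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a sample sheet CSV
#'
#' Required columns: `sample_id`, `state` (myoblast/myotube), `treatment`,
#' `dose` (micromolar, 0 for vehicle), `replicate`.
#'
#' @param path CSV file.
#' @return A validated `data.frame`.
#' @export
readSampleSheet <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "state", "treatment", "dose", "replicate")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("sample sheet missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id")
  bad <- setdiff(unique(df$state), .SAMPLE_STATES)
  if (length(bad))
    stop("unknown state label(s): ", paste(bad, collapse = ", "))
  df$dose <- as.numeric(df$dose)
  if (any(is.na(df$dose) | df$dose < 0)) stop("dose must be a number >= 0")
  if (any(df$treatment == "vehicle" & df$dose != 0))
    stop("vehicle rows must have dose 0")
  df$replicate <- as.integer(df$replicate)
  if (any(is.na(df$replicate) | df$replicate < 1))
    stop("replicate must be a positive integer")
  df
}

#' Write a result table as TSV
#'
#' Writes any tabular result (DE tables, score tables, enrichment tables) with
#' a header, the column order of the input, and full double precision (numbers
#' survive a read/write round trip bit-for-bit via \code{format(digits=17)}).
#' An empty table produces a header-only file with a warning.
#'
#' @param records `data.frame`-like table.
#' @param path destination file.
#' @return Invisibly, `path`.
#' @export
writeResultTable <- function(records, path) {
  records <- as.data.frame(records)
  if (nrow(records) == 0L)
    warning("writing header-only file: no records")
  out <- records
  num <- vapply(out, is.numeric, logical(1)) &
    !vapply(out, is.integer, logical(1))
  out[num] <- lapply(out[num], function(x) {
    s <- sprintf("%.17g", x)
    s[is.na(x)] <- "NA"
    s
  })
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a TSV result table written by [writeResultTable()]
#'
#' @param path TSV file.
#' @return A `data.frame`.
#' @export
readResultTable <- function(path) {
  utils::read.delim(path, check.names = FALSE, quote = "",
                    stringsAsFactors = FALSE)
}
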