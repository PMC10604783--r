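#' Myofusion index from nuclei count tables
#'
#' The myofusion index (MI) of a sample is the percentage of nuclei residing
#' in myosin-heavy-chain-positive multinucleated cells; imaging fields are
#' pooled per sample before the ratio (so large fields weigh more than small
#' ones), and the MI is additionally reported relative to the mean vehicle
#' MI.
#'
#' @param table `data.frame` with columns `sample_id`, `image_id`,
#'   `n_nuclei_total`, `n_nuclei_fused` (fused <= total, both >= 0).
#' @param sheet sample sheet with `sample_id` and `treatment`.
#' @param vehicle treatment label of the vehicle group (default
#'   `"vehicle"`).
#' @return `data.frame` with columns `sample_id`, `treatment`, `n_images`,
#'   `n_total`, `n_fused`, `mi` (percent) and `mi_relative`
#'   (mi / mean vehicle mi; the vehicle group averages 1 by construction).
#' @export
#' @examples
#' tab <- data.frame(sample_id = "s1", image_id = 1:3,
#'                   n_nuclei_total = c(10, 10, 10),
#'                   n_nuclei_fused = c(6, 6, 6))
#' sh <- data.frame(sample_id = "s1", treatment = "vehicle")
#' myofusionIndex(tab, sh)$mi  # 60
myofusionIndex <- function(table, sheet, vehicle = "vehicle") {
  need <- c("sample_id", "image_id", "n_nuclei_total", "n_nuclei_fused")
  .stopIfNot(all(need %in% colnames(table)),
             "fusion table needs sample_id, image_id, n_nuclei_total, n_nuclei_fused")
  .stopIfNot(all(table$n_nuclei_total >= 0) && all(table$n_nuclei_fused >= 0),
             "nuclei counts must be >= 0")
  .stopIfNot(all(table$n_nuclei_fused <= table$n_nuclei_total),
             "fused nuclei cannot exceed total nuclei")
  tot <- tapply(table$n_nuclei_total, table$sample_id, sum)
  fus <- tapply(table$n_nuclei_fused, table$sample_id, sum)
  nim <- tapply(table$image_id, table$sample_id, length)
  if (any(tot == 0))
    stop("degenerate input: zero total nuclei for sample(s) ",
         paste(names(tot)[tot == 0], collapse = ", "))
  ids <- names(tot)
  trt <- sheet$treatment[match(ids, sheet$sample_id)]
  .stopIfNot(!any(is.na(trt)), "sample missing from the sample sheet")
  .stopIfNot(vehicle %in% trt, "vehicle group absent")
  mi <- 100 * as.numeric(fus) / as.numeric(tot)
  rel <- mi / mean(mi[trt == vehicle])
  data.frame(sample_id = ids, treatment = trt,
             n_images = as.integer(nim), n_total = as.integer(tot),
             n_fused = as.integer(fus), mi = mi, mi_relative = rel,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Vehicle-normalized assay readouts
#'
#' Divides per-well assay signals (MTS viability, caspase 3/7 luminescence,
#' ...) by the mean vehicle signal and summarizes each treatment group as
#' mean +/- SEM of the relative values.
#'
#' @param values numeric assay signal per well, named by sample id (or in
#'   sample-sheet order).
#' @param sheet sample sheet with `sample_id` and `treatment`.
#' @param vehicle vehicle treatment label (default `"vehicle"`).
#' @return List with `relative` (per-well relative readouts, named) and
#'   `groups` (`data.frame`: `treatment`, `n`, `mean`, `sem`).
#' @export
normalizeReadout <- function(values, sheet, vehicle = "vehicle") {
  if (is.null(names(values))) {
    .stopIfNot(length(values) == nrow(sheet),
               "unnamed values must match the sample sheet row for row")
    names(values) <- sheet$sample_id
  }
  trt <- sheet$treatment[match(names(values), sheet$sample_id)]
  .stopIfNot(!any(is.na(trt)), "sample missing from the sample sheet")
  .stopIfNot(vehicle %in% trt, "vehicle group absent")
  vm <- mean(values[trt == vehicle])
  if (!is.finite(vm) || vm <= 0) stop("vehicle mean must be positive")
  rel <- values / vm
  groups <- do.call(rbind, lapply(unique(trt), function(g) {
    x <- rel[trt == g]
    data.frame(treatment = g, n = length(x), mean = mean(x),
               sem = if (length(x) > 1) .sem(x) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(groups) <- NULL
  list(relative = rel, groups = groups)
}
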