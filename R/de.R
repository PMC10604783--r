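#' Method-of-moments NB dispersion estimates with a fitted trend
#'
#' Per-gene negative-binomial dispersions from within-group residual moments:
#' with pooled within-group variance \eqn{\hat v_g} and overall normalized
#' mean \eqn{\hat\mu_g}, the gene-wise estimate is
#' \eqn{\hat\alpha_g = \max(\alpha_{floor}, (\hat v_g - \hat\mu_g)/\hat\mu_g^2)}
#' (NB variance law \eqn{v = \mu + \alpha\mu^2}). A mean-dispersion trend
#' \eqn{\alpha(\mu) = a_0/\mu + a_1} is fit to the gene-wise estimates by
#' least squares (coefficients clamped at 0), and the final dispersion is a
#' log-scale midpoint shrink of the gene-wise estimate toward the trend.
#'
#' This is a deliberately simple estimator (no adjusted profile likelihood,
#' no empirical-Bayes weighting); it targets the same quantity as the
#' standard count-based DE tools at desk scale.
#'
#' @param counts count matrix (genes x samples) or [DuxExperiment-class].
#' @param sizeFactors per-sample size factors; computed when `NULL`.
#' @param groups group label per sample (each group needs >= 2 samples).
#' @param alphaFloor lower bound for the dispersion (default 1e-8).
#' @param shrink weight of the trend in the log-scale midpoint (default 0.5;
#'   0 = pure gene-wise, 1 = pure trend).
#' @return List with `alpha` (final per-gene dispersions), `genewise`,
#'   `trend` (fitted values), `coef` (`a0`, `a1`), `mu` (normalized means),
#'   `alphaFloor`.
#' @export
estimateNBDispersions <- function(counts, sizeFactors = NULL, groups,
                                  alphaFloor = 1e-8, shrink = 0.5) {
  if (methods::is(counts, "DuxExperiment"))
    counts <- SummarizedExperiment::assay(counts, "counts")
  counts <- as.matrix(counts)
  if (is.null(sizeFactors)) sizeFactors <- computeSizeFactors(counts)
  groups <- as.character(groups)
  .stopIfNot(length(groups) == ncol(counts),
             "groups must have one label per sample")
  sizes <- table(groups)
  if (any(sizes < 2))
    stop("degenerate input: group(s) with < 2 samples: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  q <- sweep(counts, 2L, sizeFactors, "/")
  mu <- rowMeans(q)
  # pooled within-group residual variance
  ssq <- 0
  for (gl in names(sizes)) {
    qg <- q[, groups == gl, drop = FALSE]
    ssq <- ssq + rowSums((qg - rowMeans(qg))^2)
  }
  v <- ssq / (ncol(q) - length(sizes))
  genewise <- pmax(alphaFloor, (v - mu) / mu^2)
  genewise[!is.finite(genewise)] <- alphaFloor  # mu = 0 genes
  use <- mu > 0
  fit <- stats::lm(genewise[use] ~ I(1 / mu[use]))
  a1 <- max(0, unname(stats::coef(fit)[1L]))
  a0 <- max(0, unname(stats::coef(fit)[2L]))
  trend <- pmax(alphaFloor, a0 / mu + a1)
  trend[!is.finite(trend)] <- alphaFloor
  alpha <- exp((1 - shrink) * log(genewise) + shrink * log(trend))
  alpha <- pmax(alphaFloor, alpha)
  names(alpha) <- rownames(counts)
  list(alpha = alpha, genewise = genewise, trend = trend,
       coef = c(a0 = a0, a1 = a1), mu = mu, alphaFloor = alphaFloor)
}

# vectorized Newton MLE of log mean q per gene for one group:
# counts y (genes x n), size factors s, fixed dispersion alpha per gene.
# model mu_gj = s_j * exp(beta_g). Returns beta and observed information.
.nbGroupFit <- function(y, s, alpha, maxit = 50L, tol = 1e-10) {
  tot <- rowSums(y)
  beta <- log(pmax(tot, 0.5) / sum(s))  # moment start; 0.5 guards log(0)
  zero <- tot == 0
  for (it in seq_len(maxit)) {
    mu <- exp(beta) %o% s
    U <- rowSums((y - mu) / (1 + alpha * mu))
    I <- rowSums(mu * (1 + alpha * y) / (1 + alpha * mu)^2)
    step <- U / pmax(I, 1e-12)
    step <- pmin(pmax(step, -5), 5)  # damp; likelihood is concave in beta
    beta <- beta + step
    if (max(abs(step[!zero]), 0) < tol) break
  }
  mu <- exp(beta) %o% s
  info <- rowSums(mu * (1 + alpha * y) / (1 + alpha * mu)^2)
  beta[zero] <- -Inf
  info[zero] <- NA_real_
  list(beta = beta, info = info, zero = zero)
}

#' Negative-binomial Wald test between two groups
#'
#' Per gene, the NB mean is fitted by maximum likelihood separately in each
#' group with the dispersion held fixed and per-sample offsets
#' \eqn{\log s_j}; the log2 fold-change is \eqn{\log_2(\hat\mu_B/\hat\mu_A)},
#' its standard error comes from the observed Fisher information of the two
#' group fits, and the Wald statistic is referred to the standard normal
#' (two-sided).
#'
#' Genes with zero counts in both groups get `log2FC = 0`, `p = 1` and are
#' flagged; genes with zero counts in exactly one group get an infinite
#' `log2FC`, `p = 1` and the flag (no shrinkage prior is applied).
#'
#' @param counts count matrix or [DuxExperiment-class].
#' @param sizeFactors per-sample size factors; computed when `NULL`.
#' @param dispersions per-gene dispersion vector, or the list returned by
#'   [estimateNBDispersions()].
#' @param groupA,groupB disjoint character vectors of sample ids (>= 2 each);
#'   fold-changes are B relative to A.
#' @return `data.frame` with columns `gene`, `base_mean`, `log2FC`, `se`,
#'   `wald`, `p`, `flag` (`"ok"`, `"all_zero"`, `"zero_in_one_group"`).
#' @export
nbWaldTest <- function(counts, sizeFactors = NULL, dispersions,
                       groupA, groupB) {
  if (methods::is(counts, "DuxExperiment"))
    counts <- SummarizedExperiment::assay(counts, "counts")
  counts <- as.matrix(counts)
  if (is.null(sizeFactors)) sizeFactors <- computeSizeFactors(counts)
  if (is.list(dispersions)) dispersions <- dispersions$alpha
  .stopIfNot(length(dispersions) == nrow(counts),
             "one dispersion per gene required")
  .stopIfNot(length(intersect(groupA, groupB)) == 0,
             "groups must be disjoint")
  .stopIfNot(length(groupA) >= 2 && length(groupB) >= 2,
             "each group needs >= 2 samples")
  .stopIfNot(all(c(groupA, groupB) %in% colnames(counts)),
             "unknown sample id in groups")
  sf <- if (!is.null(names(sizeFactors)))
    sizeFactors[colnames(counts)] else stats::setNames(sizeFactors,
                                                       colnames(counts))
  fa <- .nbGroupFit(counts[, groupA, drop = FALSE], sf[groupA], dispersions)
  fb <- .nbGroupFit(counts[, groupB, drop = FALSE], sf[groupB], dispersions)
  l2 <- log(2)
  lfc <- (fb$beta - fa$beta) / l2
  se <- sqrt(1 / fa$info + 1 / fb$info) / l2
  wald <- lfc / se
  p <- 2 * stats::pnorm(-abs(wald))
  flag <- rep("ok", nrow(counts))
  both0 <- fa$zero & fb$zero
  one0 <- xor(fa$zero, fb$zero)
  lfc[both0] <- 0; wald[both0] <- 0; se[both0] <- NA_real_
  wald[one0] <- NA_real_; se[one0] <- NA_real_
  p[both0 | one0] <- 1
  flag[both0] <- "all_zero"
  flag[one0] <- "zero_in_one_group"
  qn <- sweep(counts[, c(groupA, groupB), drop = FALSE], 2L,
              sf[c(groupA, groupB)], "/")
  data.frame(gene = rownames(counts), base_mean = rowMeans(qn),
             log2FC = lfc, se = se, wald = wald, p = p, flag = flag,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment with monotonicity enforcement (ties preserved).
#'
#' @param p vector of p-values in \[0, 1\].
#' @return Vector of adjusted p-values.
#' @export
adjustBH <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must be finite and within [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Apply the significance calling rule
#'
#' A gene is called `up` iff `log2FC > lfcCut` and `padj < fdrCut`, `down`
#' iff `log2FC < -lfcCut` and `padj < fdrCut`, otherwise `ns`. Inequalities
#' are strict, so a gene at exactly the fold-change or FDR threshold is not
#' called.
#'
#' @param results `data.frame` from [nbWaldTest()]; a `padj` column is added
#'   via [adjustBH()] if absent.
#' @param lfcCut absolute log2 fold-change threshold (default 1.0).
#' @param fdrCut adjusted-p threshold (default 0.05).
#' @return The input with `padj` and `call` columns; attribute `"n_called"`
#'   holds the up/down tallies.
#' @export
callDE <- function(results, lfcCut = 1.0, fdrCut = 0.05) {
  if (!("padj" %in% colnames(results)))
    results$padj <- adjustBH(results$p)
  call <- rep("ns", nrow(results))
  sig <- results$padj < fdrCut
  call[sig & results$log2FC > lfcCut] <- "up"
  call[sig & results$log2FC < -lfcCut] <- "down"
  results$call <- call
  attr(results, "n_called") <- c(up = sum(call == "up"),
                                 down = sum(call == "down"))
  results
}

#' Venn-partition counts of significant gene lists
#'
#' Counts every intersection region across the named lists (the numbers in a
#' Venn diagram of shared up- or downregulated genes between treatments).
#'
#' @param callSets named list (>= 2 entries) of character vectors of gene
#'   ids; a duplicated gene within one list is an input error.
#' @return `data.frame` with columns `region` (member set names joined by
#'   `"&"`, every non-empty combination) and `count`; genes in no set are not
#'   represented. `sum(count[grepl(set, region)])` equals that set's length.
#' @export
overlapSummary <- function(callSets) {
  .stopIfNot(length(callSets) >= 2, "need >= 2 named sets")
  .stopIfNot(!is.null(names(callSets)) && all(nzchar(names(callSets))),
             "sets must be named")
  dup <- vapply(callSets, anyDuplicated, integer(1)) > 0
  if (any(dup))
    stop("duplicate genes within set(s): ",
         paste(names(callSets)[dup], collapse = ", "))
  nm <- names(callSets)
  genes <- unique(unlist(callSets))
  member <- vapply(callSets, function(s) genes %in% s,
                   logical(length(genes)))
  if (length(genes) == 1L) member <- matrix(member, nrow = 1L,
                                            dimnames = list(NULL, nm))
  # all non-empty membership patterns in deterministic order
  k <- length(nm)
  patterns <- expand.grid(rep(list(c(FALSE, TRUE)), k))[-1L, , drop = FALSE]
  colnames(patterns) <- nm
  region <- apply(patterns, 1L, function(r) paste(nm[as.logical(r)],
                                                  collapse = "&"))
  count <- apply(patterns, 1L, function(r)
    sum(apply(member, 1L, function(g) all(g == as.logical(r)))))
  data.frame(region = region, count = as.integer(count),
             row.names = NULL, stringsAsFactors = FALSE)
}
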