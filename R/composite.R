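#' Per-sample composite DUX4 activity score
#'
#' Summarizes a DUX4 target-gene program as one number per sample: each
#' program gene present in the matrix is z-scored across the samples of the
#' comparison, and the score of sample *j* is the mean z-score over the genes
#' used. Units are therefore arbitrary and relative to the samples included
#' in the comparison; a higher score indicates stronger DUX4 program activity
#' (more severe disease phenotype).
#'
#' Set genes absent from the matrix are dropped (`n_genes_used` records how
#' many remained); genes with zero cross-sample variance are dropped with a
#' warning. With `zscore = FALSE` the plain mean of the (log-normalized)
#' expression values is returned instead.
#'
#' @param expr log-normalized expression matrix (genes x samples), restricted
#'   to the samples of one comparison; needs >= 2 samples.
#' @param sets a [GeneSetCollection-class], a named list of gene-id vectors,
#'   or a single character vector of gene ids (scored as set `"set1"`).
#' @param zscore z-score genes across samples before averaging (default TRUE).
#' @return `data.frame` with columns `sample_id`, `set_name`, `score`,
#'   `n_genes_used`. Within each set the scores sum to zero over the samples
#'   of the comparison (a z-score identity).
#' @export
dux4Score <- function(expr, sets, zscore = TRUE) {
  expr <- as.matrix(expr)
  .stopIfNot(ncol(expr) >= 2,
             "degenerate input: need >= 2 samples to z-score across samples")
  if (methods::is(sets, "GeneSetCollection")) sets <- geneSets(sets)
  if (is.character(sets)) sets <- list(set1 = sets)
  z <- if (zscore) .zscoreRows(expr) else expr
  out <- lapply(names(sets), function(nm) {
    genes <- intersect(sets[[nm]], rownames(z))
    if (length(genes) == 0L)
      stop("no gene of set '", nm, "' is present in the matrix")
    zg <- z[genes, , drop = FALSE]
    keep <- apply(zg, 1L, function(r) all(is.finite(r)))
    if (any(!keep))
      warning(sum(!keep), " zero-variance gene(s) dropped from set '",
              nm, "'")
    zg <- zg[keep, , drop = FALSE]
    if (nrow(zg) == 0L)
      stop("all genes of set '", nm, "' have zero variance")
    data.frame(sample_id = colnames(z), set_name = nm,
               score = colMeans(zg), n_genes_used = nrow(zg),
               row.names = NULL, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# z-score each row across columns; zero-variance rows become NaN
.zscoreRows <- function(m) {
  mu <- rowMeans(m)
  sdv <- apply(m, 1L, stats::sd)
  (m - mu) / sdv
}

#' Per-sample PAX7 activity score
#'
#' The PAX7 composite score of a sample is the t statistic comparing the
#' z-scored expression of the PAX7-upregulated target genes against the
#' PAX7-downregulated target genes within that sample. The score is inversely
#' related to disease severity: higher = healthier. Genes are z-scored across
#' the comparison's samples first, so the units are comparison-relative.
#'
#' @param expr log-normalized expression matrix (genes x samples), >= 2
#'   samples.
#' @param upSet,downSet gene-id vectors of the up- and downregulated PAX7
#'   target programs; >= 2 genes of each must be present.
#' @param welch use the Welch (unequal variance) t statistic (default); with
#'   `FALSE`, the pooled-variance Student t.
#' @return `data.frame` with columns `sample_id`, `set_name` (`"pax7"`),
#'   `score`, `n_genes_used` (genes used across both groups).
#' @export
pax7Score <- function(expr, upSet, downSet, welch = TRUE) {
  expr <- as.matrix(expr)
  .stopIfNot(ncol(expr) >= 2, "degenerate input: need >= 2 samples")
  up <- intersect(upSet, rownames(expr))
  dn <- intersect(downSet, rownames(expr))
  .stopIfNot(length(up) >= 2 && length(dn) >= 2,
             "need >= 2 genes from each of upSet and downSet")
  z <- .zscoreRows(expr)
  drop <- rownames(z)[!apply(z, 1L, function(r) all(is.finite(r)))]
  up <- setdiff(up, drop); dn <- setdiff(dn, drop)
  .stopIfNot(length(up) >= 2 && length(dn) >= 2,
             "zero-variance genes left < 2 usable genes in a group")
  score <- vapply(colnames(z), function(s) {
    u <- z[up, s]; d <- z[dn, s]
    if (stats::sd(u) == 0 || stats::sd(d) == 0)
      stop("degenerate input: zero within-group variance in sample ", s)
    unname(stats::t.test(u, d, var.equal = !welch)$statistic)
  }, numeric(1))
  data.frame(sample_id = colnames(z), set_name = "pax7", score = score,
             n_genes_used = length(up) + length(dn), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Monte-Carlo Dunnett many-to-one adjusted p-values
#'
#' Given observed many-to-one t statistics from a one-way layout, the
#' family-wise adjusted p-value of comparison *i* is
#' \eqn{P(\max_j |T_j| \ge |t_i|)} under the joint null, where
#' \eqn{(T_1,...,T_k)} follows the multivariate t distribution with the
#' Dunnett correlation structure
#' \eqn{\rho_{ij} = \sqrt{n_i n_j / ((n_i+n_0)(n_j+n_0))}} and the residual
#' degrees of freedom. The tail probability is estimated by Monte-Carlo
#' integration.
#'
#' @param tstats observed t statistics (one per treated group vs control).
#' @param ns per-treated-group sample sizes (same order as `tstats`).
#' @param n0 control group sample size.
#' @param df residual degrees of freedom of the pooled variance.
#' @param nsim number of Monte-Carlo draws (default 1e5).
#' @param seed optional integer seed for the draws.
#' @return Vector of two-sided family-wise adjusted p-values.
#' @export
dunnettPValues <- function(tstats, ns, n0, df, nsim = 1e5, seed = NULL) {
  .stopIfNot(length(ns) == length(tstats), "ns must parallel tstats")
  .stopIfNot(df >= 1, "need residual degrees of freedom >= 1")
  if (!is.null(seed)) set.seed(seed)
  k <- length(tstats)
  R <- sqrt(outer(ns, ns) / outer(ns + n0, ns + n0))
  diag(R) <- 1
  L <- chol(R)
  Z <- matrix(stats::rnorm(nsim * k), nsim, k) %*% L
  W <- sqrt(stats::rchisq(nsim, df) / df)
  maxT <- apply(abs(Z) / W, 1L, max)
  vapply(abs(tstats), function(t0) mean(maxT >= t0), numeric(1))
}

#' Compare composite scores between groups
#'
#' One-way ANOVA over the groups plus many-to-one comparisons against the
#' control: Dunnett-adjusted p-values via [dunnettPValues()] when there are
#' three or more groups, or the unpaired two-sided Student t-test when there
#' are exactly two. Run separately for each `set_name` in the score table.
#'
#' @param scores score table from [dux4Score()]/[pax7Score()] (columns
#'   `sample_id`, `set_name`, `score`), or a numeric vector named by sample.
#' @param groups group label per sample: either a named vector/factor, or the
#'   name of a column to take from `sheet`.
#' @param control label of the control group (default `"vehicle"`).
#' @param sheet optional sample sheet (`data.frame` with `sample_id`) when
#'   `groups` is a column name.
#' @param nsim,seed Monte-Carlo settings for the Dunnett adjustment.
#' @return `data.frame` with one row per (set, group): `set_name`, `group`,
#'   `n`, `mean`, `sem`, `f_stat`, `p_anova` (repeated within a set), and
#'   `p_adj` (NA for the control row).
#' @export
compareScores <- function(scores, groups, control = "vehicle", sheet = NULL,
                          nsim = 1e5, seed = NULL) {
  if (is.numeric(scores))
    scores <- data.frame(sample_id = names(scores), set_name = "score",
                         score = unname(scores), stringsAsFactors = FALSE)
  if (length(groups) == 1L && is.character(groups) && !is.null(sheet)) {
    g <- stats::setNames(as.character(sheet[[groups]]), sheet$sample_id)
  } else {
    g <- stats::setNames(as.character(groups),
                         if (!is.null(names(groups))) names(groups)
                         else unique(scores$sample_id))
  }
  out <- lapply(split(scores, scores$set_name), function(tab) {
    grp <- g[tab$sample_id]
    .stopIfNot(!any(is.na(grp)), "group label missing for some sample")
    .stopIfNot(control %in% grp, "control group absent")
    sizes <- table(grp)
    .stopIfNot(length(sizes) >= 2, "need >= 2 groups")
    .stopIfNot(all(sizes >= 2), "degenerate input: a group has < 2 samples")
    grp <- factor(grp, levels = c(control, setdiff(unique(grp), control)))
    fit <- stats::lm(tab$score ~ grp)
    av <- stats::anova(fit)
    mse <- av["Residuals", "Mean Sq"]
    dfres <- av["Residuals", "Df"]
    means <- tapply(tab$score, grp, mean)
    sems <- tapply(tab$score, grp, .sem)
    trt <- levels(grp)[-1]
    n0 <- sizes[[control]]
    ns <- as.numeric(sizes[trt])
    tstats <- (means[trt] - means[[control]]) /
      sqrt(mse * (1 / ns + 1 / n0))
    padj <- if (length(trt) == 1L) {
      stats::t.test(tab$score[grp == trt], tab$score[grp == control],
                    var.equal = TRUE)$p.value
    } else {
      dunnettPValues(tstats, ns, n0, dfres, nsim = nsim, seed = seed)
    }
    data.frame(set_name = tab$set_name[1L],
               group = levels(grp),
               n = as.integer(sizes[levels(grp)]),
               mean = as.numeric(means[levels(grp)]),
               sem = as.numeric(sems[levels(grp)]),
               f_stat = av["grp", "F value"],
               p_anova = av["grp", "Pr(>F)"],
               p_adj = c(NA_real_, as.numeric(padj)),
               row.names = NULL, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
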