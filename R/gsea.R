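#' Rank genes by a signed metric
#'
#' Builds the ranked list fed to the enrichment score: descending by metric,
#' ties broken by gene id in lexicographic (C-locale) order so the ranking is
#' deterministic and invariant to input row order.
#'
#' @param x either a DE table from [nbWaldTest()] (uses the column named by
#'   `metric`) or a named numeric vector of per-gene metric values.
#' @param metric column to rank by when `x` is a DE table: `"wald"` (default),
#'   `"log2FC"`, or `"signedP"` (sign(log2FC) * -log10 p).
#' @return Named numeric vector, sorted; names are the gene ids.
#' @export
rankGenes <- function(x, metric = c("wald", "log2FC", "signedP")) {
  metric <- match.arg(metric)
  if (is.data.frame(x)) {
    v <- switch(metric,
                wald = x$wald,
                log2FC = x$log2FC,
                signedP = sign(x$log2FC) * -log10(pmax(x$p, 1e-300)))
    names(v) <- x$gene
    if (any(!is.finite(v))) {
      warning(sum(!is.finite(v)),
              " gene(s) without a finite metric dropped from the ranking")
      v <- v[is.finite(v)]
    }
  } else {
    v <- x
  }
  .stopIfNot(!is.null(names(v)) && all(nzchar(names(v))),
             "genes must be named")
  if (anyDuplicated(names(v))) stop("duplicate gene in ranking input")
  if (any(!is.finite(v))) stop("every gene needs one finite metric value")
  ord <- order(-v, names(v), method = "radix")
  v[ord]
}

#' Weighted running-sum enrichment score
#'
#' Walks the ranked list from top to bottom; at a set member ("hit") the
#' running sum increases by \eqn{|m_i|^p} normalized by the total over hits,
#' at a non-member it decreases by \eqn{1/(N - N_{hits})}. The enrichment
#' score is the signed extremum of the running sum, in \[-1, 1\]: positive
#' when the set concentrates at the top of the ranking, negative at the
#' bottom.
#'
#' @param ranked named metric vector from [rankGenes()].
#' @param set character vector of gene ids; its intersection with the ranking
#'   must be non-empty and proper.
#' @param weightP hit-weight exponent p >= 0 (default 1; 0 gives the
#'   unweighted Kolmogorov-Smirnov-like statistic).
#' @return List with `es` and the full `running` sum (length of the ranking).
#' @export
enrichmentScore <- function(ranked, set, weightP = 1) {
  .stopIfNot(weightP >= 0, "weightP must be >= 0")
  N <- length(ranked)
  hit <- names(ranked) %in% set
  nh <- sum(hit)
  if (nh == 0L || nh == N)
    stop("degenerate set: intersection with the ranking is empty or full")
  w <- abs(ranked)^weightP
  incr <- numeric(N)
  incr[hit] <- w[hit] / sum(w[hit])
  incr[!hit] <- -1 / (N - nh)
  running <- cumsum(incr)
  top <- max(running); bot <- min(running)
  es <- if (abs(top) >= abs(bot)) top else bot  # positive wins exact ties
  list(es = es, running = running)
}

# extremum of the running sum for a hit-position vector, O(k log k);
# used for the permutation null. w = |metric|^p over the whole ranking.
.esFromPositions <- function(pos, w, N) {
  pos <- sort.int(pos)
  k <- length(pos)
  hitw <- w[pos]
  cumhit <- cumsum(hitw) / sum(hitw)
  dec <- 1 / (N - k)
  miss <- (pos - seq_len(k)) * dec   # decrement accumulated before each hit
  top <- max(cumhit - miss)          # running sum just after each hit
  bot <- min(cumhit - miss - hitw / sum(hitw))  # just before each hit
  # the path is piecewise linear toward 0 outside hits, so the global
  # extrema lie at these hit boundaries
  if (abs(top) >= abs(bot)) top else bot
}

#' Permutation NES, nominal p and FDR q for a gene-set collection
#'
#' Null enrichment scores are generated by gene-set permutation: for each
#' observed set size, `nPerm` random sets of that size are drawn from the
#' ranking and scored. The normalized enrichment score divides the observed
#' ES by the mean |null ES| of matching sign; the nominal p-value is the
#' one-sided tail frequency with +1 smoothing. FDR q-values follow the
#' NES-pooling rule: the fraction of pooled null NES at least as extreme
#' (same sign) over the fraction of observed NES at least as extreme,
#' clamped to \[0, 1\]. A set is flagged significant when nominal p < 0.05
#' and q < 0.25.
#'
#' Gene-set permutation (rather than phenotype permutation) is the
#' appropriate null at triplicate scale, where only 10 distinct 3-vs-3
#' relabelings exist.
#'
#' @param ranked named metric vector from [rankGenes()].
#' @param sets a [GeneSetCollection-class] or named list of gene-id vectors.
#' @param weightP hit-weight exponent (default 1).
#' @param nPerm permutations per set size (default 1000, minimum 100).
#' @param seed optional integer seed for the permutations.
#' @return `data.frame` with columns `set_name`, `size` (genes in the
#'   ranking), `es`, `nes`, `p_nominal`, `fdr_q`, `n_permutations`,
#'   `significant`.
#' @export
gseaSignificance <- function(ranked, sets, weightP = 1, nPerm = 1000,
                             seed = NULL) {
  .stopIfNot(nPerm >= 100, "need nPerm >= 100")
  if (methods::is(sets, "GeneSetCollection")) sets <- geneSets(sets)
  if (!is.null(seed)) set.seed(seed)
  N <- length(ranked)
  w <- abs(ranked)^weightP
  sizes <- vapply(sets, function(s) sum(names(ranked) %in% s), integer(1))
  if (any(sizes == 0L | sizes >= N))
    stop("degenerate set(s): ",
         paste(names(sets)[sizes == 0L | sizes >= N], collapse = ", "))
  obs <- vapply(sets, function(s) enrichmentScore(ranked, s, weightP)$es,
                numeric(1))
  # one null ES matrix per distinct set size
  nullES <- list()
  for (k in unique(sizes)) {
    nullES[[as.character(k)]] <- vapply(seq_len(nPerm), function(i)
      .esFromPositions(sample.int(N, k), w, N), numeric(1))
  }
  normalize <- function(es, null) {
    posm <- mean(null[null > 0]); negm <- mean(abs(null[null < 0]))
    ifelse(es >= 0, es / posm, es / negm)
  }
  nes <- numeric(length(sets)); pnom <- numeric(length(sets))
  nullNES <- list()
  for (i in seq_along(sets)) {
    null <- nullES[[as.character(sizes[i])]]
    same <- if (obs[i] >= 0) null[null >= 0] else null[null < 0]
    pnom[i] <- (1 + sum(abs(same) >= abs(obs[i]))) / (1 + length(same))
    nes[i] <- normalize(obs[i], null)
  }
  for (k in names(nullES)) nullNES[[k]] <- normalize(nullES[[k]], nullES[[k]])
  pooledNull <- unlist(nullNES[as.character(sizes)], use.names = FALSE)
  fdr <- vapply(seq_along(sets), function(i) {
    n0 <- nes[i]
    if (n0 >= 0) {
      num <- mean(pooledNull[pooledNull >= 0] >= n0)
      den <- mean(nes[nes >= 0] >= n0)
    } else {
      num <- mean(pooledNull[pooledNull < 0] <= n0)
      den <- mean(nes[nes < 0] <= n0)
    }
    if (!is.finite(num / den)) return(1)
    min(1, max(0, num / den))
  }, numeric(1))
  data.frame(set_name = names(sets), size = as.integer(sizes), es = obs,
             nes = nes, p_nominal = pnom, fdr_q = fdr,
             n_permutations = as.integer(nPerm),
             significant = pnom < 0.05 & fdr < 0.25,
             row.names = NULL, stringsAsFactors = FALSE)
}
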