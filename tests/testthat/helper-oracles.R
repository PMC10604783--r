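# Independent brute-force oracles and fixture builders used across suites.
# Each oracle follows the textbook definition step by step and shares no code
# with the implementation it checks.

# median-of-ratios size factors: explicit loops, no log-space tricks
oracleSizeFactors <- function(m) {
  gm <- numeric(nrow(m))
  for (g in seq_len(nrow(m))) {
    row <- m[g, ]
    gm[g] <- if (any(row <= 0)) NA else prod(row)^(1 / length(row))
  }
  ref <- which(!is.na(gm) & gm > 0)
  sf <- numeric(ncol(m))
  for (j in seq_len(ncol(m))) sf[j] <- median(m[ref, j] / gm[ref])
  sf
}

# Benjamini-Hochberg step-up by direct definition
oracleBH <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  ranked <- p[ord] * m / seq_len(m)
  # step-up monotonicity: cumulative min from the largest rank down
  for (i in seq_len(m)) adj[i] <- min(ranked[i:m], 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}

# weighted running-sum ES walked one gene at a time; extremes kept separately
# so tests can recognize exact positive/negative magnitude ties
oracleES <- function(ranked, set, p = 1) {
  N <- length(ranked)
  hits <- names(ranked) %in% set
  nr <- sum(abs(ranked[hits])^p)
  run <- 0
  top <- 0; bot <- 0
  for (i in seq_len(N)) {
    if (hits[i]) run <- run + abs(unname(ranked[i]))^p / nr
    else run <- run - 1 / (N - sum(hits))
    if (run > top) top <- run
    if (run < bot) bot <- run
  }
  es <- if (abs(top) >= abs(bot)) top else bot
  attr(es, "top") <- top
  attr(es, "bot") <- bot
  es
}

# ES comparison that tolerates an exact magnitude tie between the positive
# and negative extreme (the signed extremum is then ambiguous at 1 ulp)
expect_es_equal <- function(es, oracle, tol = 1e-9) {
  top <- attr(oracle, "top"); bot <- attr(oracle, "bot")
  if (abs(abs(top) - abs(bot)) < tol) {
    expect_equal(abs(es), abs(as.numeric(oracle)), tolerance = tol)
  } else {
    expect_equal(es, as.numeric(oracle), tolerance = tol)
  }
}

# Venn region counts by per-gene membership bitmask
oracleVenn <- function(sets) {
  nm <- names(sets)
  genes <- unique(unlist(sets))
  key <- vapply(genes, function(g) {
    paste(nm[vapply(sets, function(s) g %in% s, logical(1))],
          collapse = "&")
  }, character(1))
  table(key)
}

# NB two-group fit by direct numeric likelihood maximization + numeric Hessian
oracleNBWald <- function(y, s, alpha, idxA, idxB) {
  nll <- function(beta, yy, ss) {
    mu <- ss * exp(beta)
    -sum(dnbinom(yy, mu = mu, size = 1 / alpha, log = TRUE))
  }
  fitGroup <- function(yy, ss) {
    o <- optim(log(sum(yy) / sum(ss)), nll, yy = yy, ss = ss,
               method = "Brent", lower = -30, upper = 30)
    h <- optimHess(o$par, nll, yy = yy, ss = ss)
    list(beta = o$par, info = as.numeric(h))
  }
  fa <- fitGroup(y[idxA], s[idxA])
  fb <- fitGroup(y[idxB], s[idxB])
  lfc <- (fb$beta - fa$beta) / log(2)
  se <- sqrt(1 / fa$info + 1 / fb$info) / log(2)
  list(log2FC = lfc, se = se, wald = lfc / se)
}

# textbook Welch t statistic
oracleWelch <- function(x, y) {
  (mean(x) - mean(y)) / sqrt(var(x) / length(x) + var(y) / length(y))
}

# random small count fixture with dimnames
randomCounts <- function(nGenes, nSamples, lambda = 20) {
  m <- matrix(rpois(nGenes * nSamples, lambda), nGenes, nSamples,
              dimnames = list(paste0("g", seq_len(nGenes)),
                              paste0("s", seq_len(nSamples))))
  m
}

# small simulation used by several suites (fast: few hundred genes)
smallSim <- function(seed = 7, nGenes = 800) {
  simulateExperiment(simulationConfig(
    nGenes = nGenes,
    programSizes = c(dux4_1 = 40, dux4_2 = 30, dux4_3 = 20,
                     pax7_up = 15, pax7_down = 15, differentiation = 30),
    seed = seed))
}
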