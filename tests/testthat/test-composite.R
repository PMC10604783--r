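exprFixture <- function(nGenes = 10, nSamples = 4, seed = 31) {
  set.seed(seed)
  matrix(rnorm(nGenes * nSamples, 5, 2), nGenes, nSamples,
         dimnames = list(paste0("g", seq_len(nGenes)),
                         paste0("s", seq_len(nSamples))))
}

test_that("dux4Score is the mean of per-gene z-scores", {
  ex <- exprFixture()
  sc <- dux4Score(ex, list(myset = c("g1", "g2", "g3")))
  # brute-force: z-then-mean computed directly
  z <- t(apply(ex[c("g1", "g2", "g3"), ], 1,
               function(r) (r - mean(r)) / sd(r)))
  expect_equal(sc$score, unname(colMeans(z)))
  expect_equal(sc$n_genes_used, rep(3L, 4))
  # z-score identity: scores sum to zero over the comparison's samples
  expect_equal(sum(sc$score), 0)
  # single-gene set reduces to that gene's z-score
  one <- dux4Score(ex, list(s = "g5"))
  expect_equal(one$score, unname((ex["g5", ] - mean(ex["g5", ])) /
                                   sd(ex["g5", ])))
})

test_that("dux4Score is invariant to per-gene shift and positive rescale", {
  ex <- exprFixture(8, 5)
  set.seed(32)
  shifted <- ex + rnorm(nrow(ex))          # per-gene constant added
  scaled <- ex * runif(nrow(ex), 0.5, 3)   # per-gene positive rescale
  s0 <- dux4Score(ex, list(s = rownames(ex)[1:4]))
  expect_equal(dux4Score(shifted, list(s = rownames(ex)[1:4]))$score,
               s0$score)
  expect_equal(dux4Score(scaled, list(s = rownames(ex)[1:4]))$score,
               s0$score)
})

test_that("dux4Score handles missing and degenerate genes", {
  ex <- exprFixture()
  # absent genes dropped, n_genes_used reports the remainder
  sc <- dux4Score(ex, list(s = c("g1", "g2", "nope")))
  expect_equal(sc$n_genes_used, rep(2L, 4))
  expect_error(dux4Score(ex, list(s = c("absent1", "absent2"))), "no gene")
  expect_error(dux4Score(ex[, 1, drop = FALSE], list(s = "g1")),
               "degenerate")
  flat <- ex
  flat["g1", ] <- 7  # zero variance
  expect_warning(scF <- dux4Score(flat, list(s = c("g1", "g2"))),
                 "zero-variance")
  expect_equal(scF$n_genes_used, rep(1L, 4))
  # plain-mean reading via zscore = FALSE
  pm <- dux4Score(ex, list(s = c("g1", "g2")), zscore = FALSE)
  expect_equal(pm$score, unname(colMeans(ex[c("g1", "g2"), ])))
})

test_that("pax7Score equals the textbook Welch t on z-scored genes", {
  ex <- exprFixture(12, 5)
  up <- paste0("g", 1:4); dn <- paste0("g", 5:9)
  sc <- pax7Score(ex, up, dn)
  z <- t(apply(ex, 1, function(r) (r - mean(r)) / sd(r)))
  for (j in seq_len(ncol(ex))) {
    expect_equal(sc$score[j], oracleWelch(z[up, j], z[dn, j]))
  }
  # antisymmetry under swapping the up and down programs
  swapped <- pax7Score(ex, dn, up)
  expect_equal(swapped$score, -sc$score)
  # pooled-variance variant differs but matches t.test
  scP <- pax7Score(ex, up, dn, welch = FALSE)
  expect_equal(scP$score[1],
               unname(t.test(z[up, 1], z[dn, 1],
                             var.equal = TRUE)$statistic))
})

test_that("pax7Score rejects degenerate groups", {
  ex <- exprFixture(6, 4)
  expect_error(pax7Score(ex, "g1", c("g2", "g3")), ">= 2 genes")
  # force equal z-values within the up group for one sample: duplicate rows
  ex2 <- ex
  ex2["g2", ] <- ex2["g1", ]  # identical genes -> identical z columns
  expect_error(pax7Score(ex2, c("g1", "g2"), c("g3", "g4")),
               "zero within-group variance")
})

test_that("identical groups give F = 0, p = 1", {
  scores <- data.frame(sample_id = paste0("s", 1:6), set_name = "d",
                       score = rep(c(1, 2, 3), 2))
  groups <- setNames(rep(c("vehicle", "drug"), each = 3), paste0("s", 1:6))
  # assign so both groups hold {1,2,3}
  scores$score <- c(1, 2, 3, 1, 2, 3)
  cmp <- compareScores(scores, groups, control = "vehicle")
  expect_equal(cmp$f_stat[1], 0)
  expect_equal(cmp$p_anova[1], 1)
})

test_that("Dunnett MC with one comparison reduces to the Student t-test", {
  set.seed(33)
  x <- rnorm(4); y <- rnorm(4) + 1
  tt <- t.test(y, x, var.equal = TRUE)
  tstat <- unname(tt$statistic)
  p <- dunnettPValues(tstat, ns = 4, n0 = 4, df = 6, nsim = 2e5, seed = 1)
  expect_equal(p, tt$p.value, tolerance = 0.02)
})

test_that("Dunnett MC agrees with multcomp on a 3-group fixture", {
  skip_if_not_installed("multcomp")
  set.seed(34)
  d <- data.frame(g = factor(rep(c("ctrl", "a", "b"), each = 4),
                             levels = c("ctrl", "a", "b")),
                  y = rnorm(12) + rep(c(0, 0.8, 1.6), each = 4))
  fit <- aov(y ~ g, data = d)
  gl <- summary(multcomp::glht(fit, linfct = multcomp::mcp(g = "Dunnett")))
  pRef <- as.numeric(gl$test$pvalues)
  msq <- summary(fit)[[1]]["Residuals", "Mean Sq"]
  means <- tapply(d$y, d$g, mean)
  tst <- (means[c("a", "b")] - means["ctrl"]) / sqrt(msq * (1/4 + 1/4))
  pMC <- dunnettPValues(tst, ns = c(4, 4), n0 = 4, df = 9,
                        nsim = 2e5, seed = 2)
  expect_equal(unname(pMC), pRef, tolerance = 0.02)
})

test_that("compareScores runs per set and flags treated groups only", {
  set.seed(35)
  scores <- data.frame(
    sample_id = rep(paste0("s", 1:9), 2),
    set_name = rep(c("d1", "d2"), each = 9),
    score = rnorm(18) + rep(rep(c(0, 2, 4), each = 3), 2))
  groups <- setNames(rep(c("vehicle", "lo", "hi"), each = 3),
                     paste0("s", 1:9))
  cmp <- compareScores(scores, groups, control = "vehicle",
                       nsim = 2e4, seed = 3)
  expect_equal(nrow(cmp), 6)  # 2 sets x 3 groups
  expect_true(all(is.na(cmp$p_adj[cmp$group == "vehicle"])))
  expect_true(all(cmp$p_adj[cmp$group == "hi"] < 0.05))
  expect_error(compareScores(scores[1:3, ], groups, control = "vehicle"),
               ">= 2 groups")
})
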