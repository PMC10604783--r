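test_that("dispersion floor engages for constant and Poisson counts", {
  m <- matrix(rep(c(10L, 20L), each = 6), 2, 6, byrow = TRUE,
              dimnames = list(c("g1", "g2"), paste0("s", 1:6)))
  groups <- rep(c("a", "b"), each = 3)
  d <- estimateNBDispersions(m, rep(1, 6), groups, shrink = 0)
  expect_equal(unname(d$genewise), rep(1e-8, 2))  # zero variance -> floor
  set.seed(41)
  mp <- matrix(rpois(2000 * 6, 50), 2000, 6,
               dimnames = list(sprintf("g%04d", 1:2000), paste0("s", 1:6)))
  dp <- estimateNBDispersions(mp, rep(1, 6), groups, shrink = 0)
  expect_lte(median(dp$genewise), 2e-8)  # sub-Poisson estimates hit the floor
})

test_that("dispersion estimates recover a known alpha", {
  set.seed(42)
  mu <- exp(runif(1500, log(200), log(2000)))
  m <- matrix(rnbinom(1500 * 12, mu = rep(mu, 12), size = 1 / 0.2),
              1500, 12, dimnames = list(sprintf("g%04d", 1:1500),
                                        paste0("s", 1:12)))
  groups <- rep(c("a", "b"), each = 6)
  d <- estimateNBDispersions(m, rep(1, 12), groups)
  expect_gt(median(d$alpha), 0.15)
  expect_lt(median(d$alpha), 0.25)
})

test_that("NB Wald test matches the brute-force likelihood optimizer", {
  set.seed(43)
  for (i in 1:30) {
    y <- rpois(6, sample(5:50, 1)) + 1L
    s <- exp(runif(6, -0.3, 0.3))
    alpha <- runif(1, 0.05, 0.5)
    m <- matrix(y, 1, 6, dimnames = list("g1", paste0("s", 1:6)))
    res <- nbWaldTest(m, setNames(s, colnames(m)), alpha,
                      paste0("s", 1:3), paste0("s", 4:6))
    ora <- oracleNBWald(y, s, alpha, 1:3, 4:6)
    expect_equal(res$log2FC, ora$log2FC, tolerance = 1e-5)
    expect_equal(res$se, ora$se, tolerance = 1e-4)
    expect_equal(res$wald, ora$wald, tolerance = 1e-4)
  }
})

test_that("NB Wald is antisymmetric and handles degenerate genes", {
  set.seed(44)
  m <- randomCounts(50, 6, lambda = 30)
  m[1, ] <- 0L                      # all-zero gene
  m[2, 1:3] <- 0L; m[2, 4:6] <- 9L  # zero in one group
  sf <- setNames(rep(1, 6), colnames(m))
  a <- colnames(m)[1:3]; b <- colnames(m)[4:6]
  alpha <- rep(0.1, 50)
  ab <- nbWaldTest(m, sf, alpha, a, b)
  ba <- nbWaldTest(m, sf, alpha, b, a)
  ok <- ab$flag == "ok"
  expect_equal(ab$log2FC[ok], -ba$log2FC[ok], tolerance = 1e-8)
  expect_equal(ab$p[ok], ba$p[ok], tolerance = 1e-8)
  expect_equal(ab$flag[1], "all_zero")
  expect_equal(ab$log2FC[1], 0)
  expect_equal(ab$p[1], 1)
  expect_equal(ab$flag[2], "zero_in_one_group")
  expect_equal(ab$log2FC[2], Inf)
  expect_equal(ab$p[2], 1)
  # identical counts in both groups -> lfc 0, wald 0, p 1
  mm <- matrix(rep(c(7L, 8L, 9L), 2), 1, 6,
               dimnames = list("g", paste0("s", 1:6)))
  same <- nbWaldTest(mm, setNames(rep(1, 6), colnames(mm)), 0.1,
                     paste0("s", 1:3), paste0("s", 4:6))
  expect_equal(same$log2FC, 0, tolerance = 1e-8)
  expect_equal(same$p, 1, tolerance = 1e-6)
})

test_that("BH adjustment matches the step-up oracle", {
  expect_equal(adjustBH(0.04), 0.04)
  expect_equal(adjustBH(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(45)
  for (i in 1:20) {
    p <- runif(sample(3:40, 1))^sample(1:3, 1)
    expect_equal(adjustBH(p), oracleBH(p))
  }
  expect_error(adjustBH(c(0.5, 1.2)), "within")
  expect_error(adjustBH(c(0.5, NA)), "finite")
})

test_that("calling rule uses strict inequalities at both thresholds", {
  res <- data.frame(gene = paste0("g", 1:5),
                    log2FC = c(1.0, -1.5, 2.0, 1.2, -0.4),
                    p = rep(0.001, 5),
                    padj = c(0.001, 0.01, 0.05, 0.01, 0.001))
  out <- callDE(res)
  expect_equal(out$call, c("ns",    # log2FC exactly 1.0 -> not called
                           "down",
                           "ns",    # padj exactly 0.05 -> not called
                           "up",
                           "ns"))
  expect_equal(attr(out, "n_called"), c(up = 1L, down = 1L))
})

test_that("overlapSummary counts Venn regions like the bitmask oracle", {
  s <- overlapSummary(list(one = c("A", "B"), two = c("B", "C")))
  expect_equal(s$count[s$region == "one"], 1L)
  expect_equal(s$count[s$region == "two"], 1L)
  expect_equal(s$count[s$region == "one&two"], 1L)
  same <- overlapSummary(list(x = c("A", "B"), y = c("A", "B")))
  expect_equal(same$count[same$region == "x&y"], 2L)
  expect_equal(sum(same$count[same$region %in% c("x", "y")]), 0L)
  set.seed(46)
  for (i in 1:10) {
    sets <- lapply(1:4, function(k) sample(paste0("G", 1:30),
                                           sample(5:15, 1)))
    names(sets) <- paste0("set", 1:4)
    out <- overlapSummary(sets)
    ora <- oracleVenn(sets)
    for (r in names(ora))
      expect_equal(out$count[out$region == r], as.integer(ora[[r]]),
                   info = r)
    # per-set totals are preserved by the partition
    for (nm in names(sets)) {
      inRegion <- vapply(strsplit(out$region, "&", fixed = TRUE),
                         function(x) nm %in% x, logical(1))
      expect_equal(sum(out$count[inRegion]), length(sets[[nm]]))
    }
  }
  expect_error(overlapSummary(list(a = c("A", "A"), b = "B")), "duplicate")
})

test_that("planted DUX4 effects are recalled at the published calling rule", {
  sim <- smallSim(seed = 48, nGenes = 1500)
  ex <- experiment(sim); sh <- sampleSheet(ex)
  sf <- computeSizeFactors(ex)
  cond <- paste(sh$state, sh$treatment, sh$dose)
  disp <- estimateNBDispersions(ex, sf, cond)
  mb <- sh$sample_id[sh$state == "myoblast"]
  mt <- sh$sample_id[sh$state == "myotube" & sh$treatment == "vehicle"]
  de <- callDE(nbWaldTest(ex, sf, disp, mb, mt))
  gs <- geneSets(simGeneSets(sim))
  targets <- unique(unlist(gs[c("dux4_1", "dux4_2", "dux4_3")]))
  recall <- mean(de$call[de$gene %in% targets] == "up")
  expect_gt(recall, 0.7)
  # background false calls stay rare
  bg <- setdiff(de$gene, unique(unlist(gs)))
  expect_lt(mean(de$call[de$gene %in% bg] != "ns"), 0.02)
})
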