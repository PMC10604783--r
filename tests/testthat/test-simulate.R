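test_that("the generator is bit-identical under a fixed seed", {
  a <- smallSim(seed = 81, nGenes = 400)
  b <- smallSim(seed = 81, nGenes = 400)
  expect_identical(SummarizedExperiment::assay(experiment(a)),
                   SummarizedExperiment::assay(experiment(b)))
  expect_identical(simTruth(a)$activity, simTruth(b)$activity)
  c <- smallSim(seed = 82, nGenes = 400)
  expect_false(identical(SummarizedExperiment::assay(experiment(a)),
                         SummarizedExperiment::assay(experiment(c))))
})

test_that("config invariants are enforced", {
  expect_error(simulationConfig(burstProb = 1.5), "burstProb")
  expect_error(simulationConfig(nGenes = 100), "fit into nGenes")
  expect_error(simulationConfig(drugs = list(x = list(
    ic50 = -1, hill = 1, doses = c(1, 2, 3, 4, 5)))), "ic50")
  expect_error(simulationConfig(drugs = list(x = list(
    ic50 = 1, hill = 1, doses = c(5, 1, 2)))), "increasing")
})

test_that("latent activity follows the burst-times-inhibition model", {
  sim <- smallSim(seed = 83)
  truth <- simTruth(sim)
  sh <- sampleSheet(experiment(sim))
  a <- truth$activity[sh$sample_id]
  expect_true(all(a[sh$state == "myoblast"] == 0))
  veh <- sh$state == "myotube" & sh$treatment == "vehicle"
  expect_equal(unname(a[veh]), unname(truth$burst[sh$sample_id][veh]))
  # treated activity = burst / (1 + (dose/ic50)^hill), non-increasing in dose
  trt <- sh$treatment == "apabetalone"
  expected <- truth$burst[sh$sample_id][trt] /
    (1 + (sh$dose[trt] / truth$drugs$apabetalone$ic50)^
       truth$drugs$apabetalone$hill)
  expect_equal(unname(a[trt]), unname(expected))
  byDose <- tapply(a[trt], sh$dose[trt], mean)
  expect_true(all(diff(byDose[order(as.numeric(names(byDose)))]) <= 0))
})

test_that("a null DUX4 effect leaves target expression flat", {
  cfg <- simulationConfig(
    nGenes = 3000,
    programSizes = c(dux4_1 = 400, dux4_2 = 300, dux4_3 = 200,
                     pax7_up = 30, pax7_down = 30, differentiation = 50),
    dux4EffectBeta = 0, librarySizeSpread = 1, seed = 84)
  sim <- simulateExperiment(cfg)
  ex <- experiment(sim); sh <- sampleSheet(ex)
  m <- SummarizedExperiment::assay(ex)
  gs <- geneSets(simGeneSets(sim))
  targets <- unique(unlist(gs[c("dux4_1", "dux4_2", "dux4_3")]))
  mb <- sh$sample_id[sh$state == "myoblast"]
  mt <- sh$sample_id[sh$state == "myotube" & sh$treatment == "vehicle"]
  lr <- log2((rowMeans(m[targets, mt]) + 0.5) /
               (rowMeans(m[targets, mb]) + 0.5))
  expect_lt(abs(mean(lr)), 0.1)
})

test_that("beta = 2 with certain bursting yields a 4-fold target ratio", {
  cfg <- simulationConfig(
    nGenes = 2000, nReplicates = 10,
    programSizes = c(dux4_1 = 250, dux4_2 = 150, dux4_3 = 100,
                     pax7_up = 30, pax7_down = 30, differentiation = 50),
    dux4EffectBeta = 2, burstProb = 1, librarySizeSpread = 1,
    drugs = list(), seed = 85)
  sim <- simulateExperiment(cfg)
  ex <- experiment(sim); sh <- sampleSheet(ex)
  m <- SummarizedExperiment::assay(ex)
  gs <- geneSets(simGeneSets(sim))
  targets <- unique(unlist(gs[c("dux4_1", "dux4_2", "dux4_3")]))
  mb <- sh$sample_id[sh$state == "myoblast"]
  mt <- sh$sample_id[sh$state == "myotube"]
  lr <- log2(rowMeans(m[targets, mt]) + 0.5) -
    log2(rowMeans(m[targets, mb]) + 0.5)
  expect_equal(mean(lr), 2, tolerance = 0.1)
})

test_that("counts reproduce the NB mean-variance law", {
  cfg <- simulationConfig(
    nGenes = 600, nReplicates = 50,
    programSizes = c(dux4_1 = 10, dux4_2 = 10, dux4_3 = 10,
                     pax7_up = 10, pax7_down = 10, differentiation = 10),
    librarySizeSpread = 1, drugs = list(), seed = 86)
  sim <- simulateExperiment(cfg)
  ex <- experiment(sim); sh <- sampleSheet(ex)
  m <- SummarizedExperiment::assay(ex)
  truth <- simTruth(sim)
  mb <- sh$sample_id[sh$state == "myoblast"]
  gs <- unique(unlist(geneSets(simGeneSets(sim))))
  bg <- setdiff(rownames(m), gs)
  mu <- truth$baseline_mean[bg]
  alpha <- truth$dispersion[bg]
  keep <- mu > 5  # moment checks need non-trivial counts
  vObs <- apply(m[bg, mb], 1, var)[keep]
  vExp <- (mu + alpha * mu^2)[keep]
  expect_equal(median(vObs / vExp), 1, tolerance = 0.15)
})

test_that("qPCR tables invert back to the simulated abundances", {
  sim <- smallSim(seed = 87, nGenes = 400)
  gs <- geneSets(simGeneSets(sim))
  markers <- gs$dux4_1[1:2]
  # zero noise: CT difference is exactly -log2(relative abundance)
  ct0 <- simulateQpcr(sim, markers, noiseSd = 0, seed = 1)
  expect_equal(ct0$ct_marker - ct0$ct_ref,
               -log2(ct0$true_relative_abundance))
  r0 <- qpcrRelativeExpression(ct0$ct_ref, ct0$ct_marker)
  expect_equal(r0, ct0$true_relative_abundance)
  # default noise: recovery within a few noise sds on the log2 scale
  ct <- simulateQpcr(sim, markers, seed = 2)
  r <- qpcrRelativeExpression(ct$ct_ref, ct$ct_marker)
  err <- log2(r) - log2(ct$true_relative_abundance)
  expect_lt(max(abs(err)), 5 * 0.15)
  expect_error(simulateQpcr(sim, "not-a-gene"), "unknown marker")
})

test_that("differentiation raises DUX4 scores in the simulated system", {
  # mirrors the differentiation contrast: vehicle myotubes vs myoblasts
  hits <- 0L
  for (seed in 88:92) {
    sim <- smallSim(seed = seed)
    ex <- experiment(sim); sh <- sampleSheet(ex)
    ln <- logTransform(normalizeCounts(ex, computeSizeFactors(ex)))
    veh <- sh$sample_id[sh$treatment == "vehicle"]
    sc <- suppressWarnings(  # rare all-zero genes drop with a warning
      dux4Score(ln[, veh],
                geneSets(simGeneSets(sim))[c("dux4_1", "dux4_2",
                                             "dux4_3")]))
    st <- sh$state[match(sc$sample_id, sh$sample_id)]
    up <- tapply(sc$score, list(sc$set_name, st), mean)
    if (all(up[, "myotube"] > up[, "myoblast"])) hits <- hits + 1L
  }
  expect_equal(hits, 5L)
})
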