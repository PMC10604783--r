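#' Configuration for the synthetic FSHD myotube experiment
#'
#' Bundles and validates every parameter of the generator. Defaults describe
#' the study conditions the pipeline is meant for: 5,000 genes, triplicate
#' myoblast and myotube samples, one apabetalone-like compound on an
#' eight-point geometric dose grid spanning 0.02-50 micromolar with a true
#' IC50 of 1 micromolar, three overlapping DUX4 target programs, PAX7
#' up/down programs, a differentiation program, and negative-binomial count
#' noise with a 1/mu + constant dispersion trend.
#'
#' @param nGenes number of genes (default 5000).
#' @param nReplicates replicates per condition (default 3).
#' @param programSizes named integer vector with entries `dux4_1`, `dux4_2`,
#'   `dux4_3`, `pax7_up`, `pax7_down`, `differentiation`.
#' @param dux4Overlap pairwise overlap fraction between the DUX4 sets
#'   (default 0.3).
#' @param baselineLog2Mean,baselineLog2Sd distribution of per-gene baseline
#'   log2 expression (default mean 5, sd 2).
#' @param dispersionA0,dispersionA1 dispersion trend alpha(mu) = a0/mu + a1
#'   (defaults 2 and 0.05, both >= 0).
#' @param dux4EffectBeta log2 activation of DUX4 targets at full latent
#'   activity (default 2).
#' @param pax7EffectGamma log2 effect on the PAX7 programs (up-set scales by
#'   2^(-gamma a), down-set by 2^(+gamma a); default 1).
#' @param diffEffect log2 activation of differentiation genes in all
#'   myotubes (default 2).
#' @param burstProb probability a myotube replicate's DUX4 program is "on"
#'   (default 1; sporadic bursting is a modeling choice, see the vignette).
#' @param drugs named list; each element a list with `ic50` (> 0), `hill`
#'   (> 0) and `doses` (strictly increasing positive micromolar grid).
#'   Default: one apabetalone-like drug, ic50 1, hill 1, 8-point 0.02-50
#'   grid.
#' @param librarySizeSpread multiplicative size-factor range; per-sample
#'   factors are log-uniform in \[1/spread, spread\] (default 1.5).
#' @param seed integer seed (default 1).
#' @return Validated list of class `"SimulationConfig"`.
#' @export
simulationConfig <- function(nGenes = 5000, nReplicates = 3,
                             programSizes = c(dux4_1 = 150, dux4_2 = 100,
                                              dux4_3 = 80, pax7_up = 50,
                                              pax7_down = 50,
                                              differentiation = 100),
                             dux4Overlap = 0.3,
                             baselineLog2Mean = 5, baselineLog2Sd = 2,
                             dispersionA0 = 2, dispersionA1 = 0.05,
                             dux4EffectBeta = 2, pax7EffectGamma = 1,
                             diffEffect = 2, burstProb = 1,
                             drugs = list(apabetalone = list(
                               ic50 = 1, hill = 1,
                               doses = 10^seq(log10(0.02), log10(50),
                                              length.out = 8))),
                             librarySizeSpread = 1.5, seed = 1L) {
  cfg <- list(nGenes = as.integer(nGenes),
              nReplicates = as.integer(nReplicates),
              programSizes = programSizes, dux4Overlap = dux4Overlap,
              baselineLog2Mean = baselineLog2Mean,
              baselineLog2Sd = baselineLog2Sd,
              dispersionA0 = dispersionA0, dispersionA1 = dispersionA1,
              dux4EffectBeta = dux4EffectBeta,
              pax7EffectGamma = pax7EffectGamma,
              diffEffect = diffEffect, burstProb = burstProb,
              drugs = drugs, librarySizeSpread = librarySizeSpread,
              seed = as.integer(seed))
  need <- c("dux4_1", "dux4_2", "dux4_3", "pax7_up", "pax7_down",
            "differentiation")
  .stopIfNot(all(need %in% names(programSizes)),
             paste("programSizes needs entries:",
                   paste(need, collapse = ", ")))
  .stopIfNot(cfg$nGenes >= sum(programSizes),
             "config error: programs do not fit into nGenes")
  .stopIfNot(cfg$nReplicates >= 1, "config error: nReplicates >= 1")
  .stopIfNot(burstProb >= 0 && burstProb <= 1,
             "config error: burstProb must be in [0, 1]")
  .stopIfNot(dux4Overlap >= 0 && dux4Overlap < 1,
             "config error: dux4Overlap must be in [0, 1)")
  .stopIfNot(dispersionA0 >= 0 && dispersionA1 >= 0,
             "config error: dispersion coefficients must be >= 0")
  .stopIfNot(librarySizeSpread >= 1,
             "config error: librarySizeSpread must be >= 1")
  for (dn in names(drugs)) {
    d <- drugs[[dn]]
    .stopIfNot(is.numeric(d$ic50) && d$ic50 > 0,
               paste0("config error: drug ", dn, " needs true ic50 > 0"))
    .stopIfNot(is.numeric(d$hill) && d$hill > 0,
               paste0("config error: drug ", dn, " needs hill > 0"))
    .stopIfNot(all(d$doses > 0) && !is.unsorted(d$doses, strictly = TRUE),
               paste0("config error: drug ", dn,
                      " needs a strictly increasing positive dose grid"))
  }
  class(cfg) <- "SimulationConfig"
  cfg
}

# draw the program memberships; dux4 sets share ~overlap fraction pairwise,
# the other programs are disjoint from them and from each other
.assignPrograms <- function(cfg, genes) {
  ps <- cfg$programSizes
  f <- cfg$dux4Overlap
  pool <- genes
  take <- function(n, from) sample(from, n)
  d1 <- take(ps[["dux4_1"]], pool)
  n2sh <- round(f * ps[["dux4_2"]])
  d2 <- c(take(n2sh, d1), take(ps[["dux4_2"]] - n2sh, setdiff(pool, d1)))
  n3sh <- round(f * ps[["dux4_3"]])
  d3 <- c(take(n3sh, union(d1, d2)),
          take(ps[["dux4_3"]] - n3sh, setdiff(pool, union(d1, d2))))
  used <- union(union(d1, d2), d3)
  rest <- setdiff(pool, used)
  pu <- take(ps[["pax7_up"]], rest);   rest <- setdiff(rest, pu)
  pd <- take(ps[["pax7_down"]], rest); rest <- setdiff(rest, pd)
  df <- take(ps[["differentiation"]], rest)
  list(dux4_1 = d1, dux4_2 = d2, dux4_3 = d3,
       pax7_up = pu, pax7_down = pd, differentiation = df)
}

#' Simulate the full FSHD myotube counting experiment
#'
#' Generates a gene-by-sample count matrix with the structure the analysis
#' layer assumes. Per sample, a latent DUX4 activity \eqn{a \in [0,1]} is
#' drawn: myoblasts have a = 0; vehicle myotubes have a = burst indicator
#' (Bernoulli with `burstProb`); drug-treated myotubes have
#' \eqn{a = burst / (1 + (dose/IC_{50})^{hill})}, so activity is
#' non-increasing in dose. Gene means scale by \eqn{2^{\beta a}} for DUX4
#' targets, \eqn{2^{-\gamma a}} / \eqn{2^{+\gamma a}} for the PAX7 up/down
#' programs, and \eqn{2^{diffEffect}} for differentiation genes in all
#' myotubes; counts are NB draws with mean
#' \eqn{s_j \mu_g 2^{effects}} and dispersion \eqn{\alpha(\mu_g)}.
#' Identical config (including seed) reproduces the output bit for bit.
#'
#' @param config a `"SimulationConfig"` from [simulationConfig()].
#' @return A [DuxSimulation-class]: the experiment, the program gene sets,
#'   and the truth ledger.
#' @export
simulateExperiment <- function(config) {
  .stopIfNot(inherits(config, "SimulationConfig"),
             "config must come from simulationConfig()")
  set.seed(config$seed)
  genes <- sprintf("gene%05d", seq_len(config$nGenes))
  programs <- .assignPrograms(config, genes)
  dux4All <- unique(unlist(programs[c("dux4_1", "dux4_2", "dux4_3")]))

  baseLog2 <- stats::rnorm(config$nGenes, config$baselineLog2Mean,
                           config$baselineLog2Sd)
  names(baseLog2) <- genes
  muBase <- 2^baseLog2
  alpha <- config$dispersionA0 / muBase + config$dispersionA1

  reps <- seq_len(config$nReplicates)
  sheet <- rbind(
    data.frame(sample_id = sprintf("myoblast_vehicle_r%d", reps),
               state = "myoblast", treatment = "vehicle", dose = 0,
               replicate = reps, stringsAsFactors = FALSE),
    data.frame(sample_id = sprintf("myotube_vehicle_r%d", reps),
               state = "myotube", treatment = "vehicle", dose = 0,
               replicate = reps, stringsAsFactors = FALSE))
  for (dn in names(config$drugs)) {
    d <- config$drugs[[dn]]
    for (i in seq_along(d$doses)) {
      sheet <- rbind(sheet, data.frame(
        sample_id = sprintf("myotube_%s_d%02d_r%d", dn, i, reps),
        state = "myotube", treatment = dn, dose = d$doses[i],
        replicate = reps, stringsAsFactors = FALSE))
    }
  }
  n <- nrow(sheet)

  burst <- ifelse(sheet$state == "myotube",
                  stats::rbinom(n, 1L, config$burstProb), 0L)
  inhib <- rep(1, n)
  for (dn in names(config$drugs)) {
    sel <- sheet$treatment == dn
    d <- config$drugs[[dn]]
    inhib[sel] <- 1 / (1 + (sheet$dose[sel] / d$ic50)^d$hill)
  }
  activity <- burst * ifelse(sheet$treatment == "vehicle", 1, inhib)
  activity[sheet$state == "myoblast"] <- 0

  spread <- config$librarySizeSpread
  sf <- exp(stats::runif(n, -log(spread), log(spread)))
  names(sf) <- sheet$sample_id

  isDux4 <- genes %in% dux4All
  isUp <- genes %in% programs$pax7_up
  isDn <- genes %in% programs$pax7_down
  isDiff <- genes %in% programs$differentiation

  counts <- matrix(0, config$nGenes, n, dimnames = list(genes,
                                                        sheet$sample_id))
  for (j in seq_len(n)) {
    a <- activity[j]
    eff <- numeric(config$nGenes)
    eff[isDux4] <- eff[isDux4] + config$dux4EffectBeta * a
    eff[isUp] <- eff[isUp] - config$pax7EffectGamma * a
    eff[isDn] <- eff[isDn] + config$pax7EffectGamma * a
    if (sheet$state[j] == "myotube")
      eff[isDiff] <- eff[isDiff] + config$diffEffect
    mu <- sf[j] * muBase * 2^eff
    counts[, j] <- stats::rnbinom(config$nGenes, mu = mu, size = 1 / alpha)
  }

  mtVeh <- sheet$state == "myotube" & sheet$treatment == "vehicle"
  aBar <- mean(activity[mtVeh])
  lfcDiff <- numeric(config$nGenes); names(lfcDiff) <- genes
  lfcDiff[isDux4] <- lfcDiff[isDux4] + config$dux4EffectBeta * aBar
  lfcDiff[isUp] <- lfcDiff[isUp] - config$pax7EffectGamma * aBar
  lfcDiff[isDn] <- lfcDiff[isDn] + config$pax7EffectGamma * aBar
  lfcDiff[isDiff] <- lfcDiff[isDiff] + config$diffEffect

  truth <- list(
    activity = stats::setNames(activity, sheet$sample_id),
    pax7_activity = stats::setNames(1 - activity, sheet$sample_id),
    burst = stats::setNames(burst, sheet$sample_id),
    log2fc = list(myotube_vs_myoblast = lfcDiff),
    drugs = lapply(config$drugs, function(d) d[c("ic50", "hill")]),
    size_factors = sf, baseline_mean = muBase, dispersion = alpha,
    seed = config$seed, config = config)

  gsc <- GeneSetCollection(programs,
                           descriptions = rep("simulated program",
                                              length(programs)))
  new("DuxSimulation",
      experiment = DuxExperiment(counts, sheet),
      geneSets = gsc, truth = truth)
}

#' Simulate a qPCR CT table for marker genes
#'
#' For each sample and marker, the expected (size-factor-free) transcript
#' abundance from the simulated model is converted to a relative abundance
#' r against a constant reference abundance (the endogenous cyclophilin-A
#' control), and the marker CT is \eqn{CT_{ref} - \log_2 r} plus Gaussian
#' cycle noise. The reference CT is constant per sample, so
#' [qpcrRelativeExpression()] inverts the table back to r up to noise.
#'
#' @param sim a [DuxSimulation-class] from [simulateExperiment()].
#' @param markers gene ids present in the simulated transcriptome.
#' @param ctRef reference-gene CT (default 20 cycles).
#' @param noiseSd Gaussian CT noise, cycles (default 0.15; 0 for noise-free).
#' @param refAbundance abundance assigned to the reference gene (default
#'   1000; r = mu / refAbundance).
#' @param seed optional seed for the noise draws.
#' @return `data.frame` with columns `sample_id`, `marker`, `ct_ref`,
#'   `ct_marker`, `true_relative_abundance`.
#' @export
simulateQpcr <- function(sim, markers, ctRef = 20, noiseSd = 0.15,
                         refAbundance = 1000, seed = NULL) {
  .stopIfNot(methods::is(sim, "DuxSimulation"), "sim must be a DuxSimulation")
  ex <- experiment(sim)
  unknown <- setdiff(markers, rownames(ex))
  if (length(unknown))
    stop("unknown marker(s): ", paste(unknown, collapse = ", "))
  if (!is.null(seed)) set.seed(seed)
  sheet <- sampleSheet(ex)
  # expected size-factor-free mean for each (marker, sample)
  mu <- .expectedMeans(sim, markers)
  out <- expand.grid(sample_id = sheet$sample_id, marker = markers,
                     stringsAsFactors = FALSE)
  r <- mu[cbind(out$marker, out$sample_id)] / refAbundance
  ct <- ctRef - log2(r) + stats::rnorm(nrow(out), 0, noiseSd)
  data.frame(out, ct_ref = ctRef, ct_marker = ct,
             true_relative_abundance = r, stringsAsFactors = FALSE)
}

# expected mean (no size factor, no count noise) per gene x sample;
# the effect model mirrors simulateExperiment exactly
.expectedMeans <- function(sim, genes) {
  truth <- simTruth(sim)
  cfg <- truth$config
  sheet <- sampleSheet(experiment(sim))
  gsets <- geneSets(simGeneSets(sim))
  dux4All <- unique(unlist(gsets[c("dux4_1", "dux4_2", "dux4_3")]))
  a <- truth$activity[sheet$sample_id]
  isMt <- sheet$state == "myotube"
  mu <- matrix(NA_real_, length(genes), nrow(sheet),
               dimnames = list(genes, sheet$sample_id))
  for (i in seq_along(genes)) {
    g <- genes[i]
    eff <- rep(0, nrow(sheet))
    if (g %in% dux4All) eff <- eff + cfg$dux4EffectBeta * a
    if (g %in% gsets$pax7_up) eff <- eff - cfg$pax7EffectGamma * a
    if (g %in% gsets$pax7_down) eff <- eff + cfg$pax7EffectGamma * a
    if (g %in% gsets$differentiation) eff <- eff + cfg$diffEffect * isMt
    mu[i, ] <- truth$baseline_mean[[g]] * 2^eff
  }
  mu
}

#' Simulate per-image fusion nuclei tallies
#'
#' Per image, total nuclei are Poisson with mean `meanNuclei` and fused
#' nuclei are Binomial(total, miTrue/100); by default three imaging fields
#' per sample are drawn.
#'
#' @param miTrue true myofusion index in percent, named per sample id.
#' @param nImages imaging fields per sample (default 3).
#' @param meanNuclei Poisson mean of nuclei per field (default 100).
#' @param seed optional seed.
#' @return `data.frame` with columns `sample_id`, `image_id`,
#'   `n_nuclei_total`, `n_nuclei_fused`.
#' @export
simulateFusionCounts <- function(miTrue, nImages = 3, meanNuclei = 100,
                                 seed = NULL) {
  .stopIfNot(all(miTrue >= 0 & miTrue <= 100),
             "config error: miTrue must be within [0, 100]")
  .stopIfNot(!is.null(names(miTrue)), "miTrue must be named by sample id")
  if (!is.null(seed)) set.seed(seed)
  out <- do.call(rbind, lapply(names(miTrue), function(s) {
    tot <- stats::rpois(nImages, meanNuclei)
    fus <- stats::rbinom(nImages, tot, miTrue[[s]] / 100)
    data.frame(sample_id = s, image_id = seq_len(nImages),
               n_nuclei_total = tot, n_nuclei_fused = fus,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
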