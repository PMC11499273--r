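rt <- 0.001987 * 303

test_that("two-state fraction folded matches closed forms and is monotone", {
  expect_equal(fractionFolded(0), 0.5)
  expect_equal(fractionFolded(-rt * log(3)), 0.75)
  expect_lt(fractionFolded(10), 1e-6)

  dg <- seq(-8, 8, length.out = 200)
  p <- fractionFolded(dg)
  expect_true(all(diff(p) < 0))
  expect_true(all(p > 0 & p < 1))
})

test_that("three-state probabilities equal Boltzmann partition enumeration", {
  expect_equal(fractionBound(0, 0, c = 1), 1 / 3)
  expect_equal(fractionBound(0, -rt * log(2), c = 1), 0.5)
  expect_equal(fractionBound(-50, -50, c = 1), 1, tolerance = 1e-12)
  expect_error(fractionBound(0, 0, c = 0), "c must be")

  # grid check against explicit state enumeration (u/f and uu/fu/fb),
  # including a non-unit ligand concentration folded into the state energy
  grid <- expand.grid(f = seq(-5, 5, length.out = 25),
                      b = seq(-5, 5, length.out = 25))
  for (cc in c(1, 0.2)) {
    for (i in seq_len(nrow(grid))) {
      dgf <- grid$f[i]; dgb <- grid$b[i]
      pf <- bfStateProb(c(0, dgf), 2)
      pfb <- bfStateProb(c(0, dgf, dgf + dgb - rt * log(cc)), 3)
      expect_equal(fractionFolded(dgf), pf, tolerance = 1e-12)
      expect_equal(fractionBound(dgf, dgb, c = cc), pfb, tolerance = 1e-12)
      # the three state probabilities sum to one and p_fb <= p_f overall
      puu <- bfStateProb(c(0, dgf, dgf + dgb - rt * log(cc)), 1)
      pfu <- bfStateProb(c(0, dgf, dgf + dgb - rt * log(cc)), 2)
      expect_equal(puu + pfu + fractionBound(dgf, dgb, c = cc), 1,
                   tolerance = 1e-12)
    }
  }

  # monotone decreasing in each argument
  dg <- seq(-6, 6, length.out = 100)
  expect_true(all(diff(fractionBound(dg, 0.7)) < 0))
  expect_true(all(diff(fractionBound(0.7, dg)) < 0))
})

test_that("variant free energies sum the included coefficients", {
  set.seed(42)
  ddg <- rnorm(3); coup <- rnorm(3)
  m <- energyModel(paste0("s", 1:3), dgwt = c(folding = -1.5),
                   ddg = list(folding = ddg),
                   couplings = list(folding = coup))
  expect_equal(variantFreeEnergy(m, c(0, 0, 0)), -1.5)
  expect_equal(variantFreeEnergy(m, c(0, 1, 0)), -1.5 + ddg[2])
  # brute-force coefficient enumeration over every genotype of the cube
  g <- sampleGenotypeLibrary(3, scheme = "exhaustive")
  for (i in seq_len(nrow(g)))
    expect_equal(variantFreeEnergy(m, g[i, ]),
                 bfFreeEnergy(-1.5, ddg, coup, g[i, ]))
  expect_error(variantFreeEnergy(m, c(1, 0)), "dimension")
  expect_error(variantFreeEnergy(m, c(1, 0, 0), trait = "binding"),
               "unknown trait")
})

test_that("fitness predictions pass through the affine transform", {
  m <- energyModel(c("s1", "s2"), dgwt = c(folding = 0),
                   ddg = list(folding = c(1, 30)),
                   affine = list(abundance = c(a = -0.1, b = 1.2)))
  # identity-transform model: fitness equals the state probability
  m0 <- energyModel(c("s1", "s2"), dgwt = c(folding = 0),
                    ddg = list(folding = c(1, 30)))
  expect_equal(predictFitness(m0, c(0, 0)), 0.5)
  # hand computation through p for a mid-range variant
  expect_equal(predictFitness(m, c(1, 0)),
               -0.1 + 1.2 * fractionFolded(1))
  # deeply unfolded variants collapse onto the lower plateau a
  expect_equal(predictFitness(m, c(1, 1)), -0.1, tolerance = 1e-8)
  expect_error(predictFitness(m, c(1, 0), "binding"), "unknown phenotype")
})

test_that("the weighted MAE loss follows its closed form", {
  expect_equal(weightedMaeLoss(1:5, 1:5, rep(1, 5), lambda2 = 0), 0)
  expect_equal(weightedMaeLoss(0.5, 1, 0.5, lambda2 = 0), 1.0)
  # lambda2 = 1e-6 with theta = (1000, 0, ...) adds exactly 1 to the data
  # term
  expect_equal(weightedMaeLoss(0.5, 1, 0.5, theta = c(1000, 0, 0),
                               lambda2 = 1e-6), 2.0)
  # permutation invariance
  set.seed(1)
  y <- rnorm(20); yh <- rnorm(20); s <- runif(20, 0.5, 1)
  p <- sample(20)
  expect_equal(weightedMaeLoss(yh, y, s), weightedMaeLoss(yh[p], y[p], s[p]))
  expect_error(weightedMaeLoss(1, 1, 0), "positive")
  expect_error(weightedMaeLoss(1:2, 1, 1), "equal length")
})

test_that("variant splits have the right sizes, keep the wild type in
          training, and are seed-reproducible", {
  s1 <- splitVariants(1000L, seed = 7)
  expect_equal(as.integer(table(s1)), c(700L, 200L, 100L))
  expect_identical(s1, splitVariants(1000L, seed = 7))
  expect_false(identical(s1, splitVariants(1000L, seed = 8)))

  spec <- truthSpec(K = 6, seed = 1)
  sim <- simulateDataset(spec, n = 64, scheme = "exhaustive")
  for (seed in 1:20) {
    sp <- splitVariants(sim$table, seed = seed)
    expect_equal(sp[mutantOrder(sim$table) == 0L], factor("train",
      levels = c("train", "validation", "test")))
  }
  expect_error(splitVariants(5L), "at least 10")
})

test_that("fitness resampling draws from the per-variant error
          distribution", {
  set.seed(3)
  n <- 100000L
  fit <- matrix(rnorm(n), ncol = 1, dimnames = list(NULL, "abundance"))
  sig <- matrix(runif(n, 0.2, 2), ncol = 1,
                dimnames = list(NULL, "abundance"))
  gg <- sampleGenotypeLibrary(17, n, seed = 5)
  tab <- genotypeTable(gg, fit, sig)
  res <- resampleTraining(tab, seed = 11)
  zn <- (fitnessMatrix(res) - fit) / sig
  expect_equal(sd(zn), 1, tolerance = 0.02)
  expect_equal(mean(zn), 0, tolerance = 0.02)
  # reproducible, and rows outside `rows` untouched
  res2 <- resampleTraining(tab, seed = 11)
  expect_identical(fitnessMatrix(res), fitnessMatrix(res2))
  part <- resampleTraining(tab, seed = 11, rows = 1:10)
  expect_identical(fitnessMatrix(part)[11:20, ], fit[11:20, ])
})

test_that("noise-free first-order data is recovered to 0.05 kcal/mol", {
  spec <- truthSpec(K = 8, ddgF = c(0.4, 0.4), couplingSparsity = 0,
                    sigma0 = 0.005, seed = 7)
  sim <- simulateDataset(spec, n = 256, scheme = "exhaustive")
  cfg <- fitConfig(maxInteractionOrder = 1, batchSizeGrid = 128L, seed = 3,
                   resample = FALSE)
  res <- fitEnergyModel(sim$table, config = cfg)
  m <- fittedModel(res)
  expect_true(all(abs(ddgTerms(m)[, 1] - ddgTerms(sim$truth)[, 1]) < 0.05))
  expect_lt(abs(wtEnergies(m)[[1]] - wtEnergies(sim$truth)[[1]]), 0.05)
  expect_gt(heldOutR2(res)[["abundance"]], 0.99)
  # training history is recorded and the loss trend decreases
  h <- trainingHistory(res)
  expect_gt(nrow(h), 10)
  expect_lt(mean(tail(h$train_loss, 5)), mean(head(h$train_loss, 5)))
})

test_that("fitting is deterministic for a fixed seed and rejects
          unidentifiable or ill-posed setups", {
  spec <- truthSpec(K = 5, couplingSparsity = 0, seed = 2)
  sim <- simulateDataset(spec, n = 32, scheme = "exhaustive")
  cfg <- fitConfig(maxInteractionOrder = 1, batchSizeGrid = 16L, seed = 9,
                   maxEpochs = 50L)
  r1 <- fitEnergyModel(sim$table, config = cfg)
  r2 <- fitEnergyModel(sim$table, config = cfg)
  expect_identical(ddgTerms(fittedModel(r1)), ddgTerms(fittedModel(r2)))
  expect_identical(affineParams(fittedModel(r1)),
                   affineParams(fittedModel(r2)))

  # order-2 model on 15 variants: more parameters (18) than data rows
  cfg2 <- fitConfig(maxInteractionOrder = 2, batchSizeGrid = 16L)
  small <- genotypeTable(genotypes(sim$table)[1:15, ],
                         fitnessMatrix(sim$table)[1:15, , drop = FALSE],
                         sigmaMatrix(sim$table)[1:15, , drop = FALSE])
  expect_error(fitEnergyModel(small, config = cfg2), "unidentifiable")

  # binding phenotype requires the abundance phenotype alongside
  tabB <- genotypeTable(genotypes(sim$table),
                        list(binding = fitnessMatrix(sim$table)[, 1]),
                        list(binding = sigmaMatrix(sim$table)[, 1]))
  expect_error(fitEnergyModel(tabB, config = cfg), "abundance")
})

test_that("a second-order model over 34 substitutions carries 561
          couplings", {
  m <- generateTruth(truthSpec(K = 34, seed = 1))
  expect_equal(nrow(couplingTerms(m)), 561L)
  expect_equal(length(pairIds(m)), 561L)
})

test_that("canonicalization flips the gauge without changing predictions", {
  set.seed(8)
  ddg <- rnorm(4); coup <- rnorm(6, 0, 0.2)
  m <- energyModel(paste0("s", 1:4), dgwt = c(folding = 1.2),
                   ddg = list(folding = -ddg),
                   couplings = list(folding = -coup),
                   affine = list(abundance = c(a = 1.1, b = -1)))
  mc <- canonicalizeModel(m)
  expect_gt(affineParams(mc)$abundance[["b"]], 0)
  g <- sampleGenotypeLibrary(4, scheme = "exhaustive")
  expect_equal(predictFitness(mc, g), predictFitness(m, g),
               tolerance = 1e-12)
  # an already-canonical model is untouched
  expect_identical(canonicalizeModel(mc), mc)
})

test_that("linear baselines count parameters correctly and tie the energy
          model on additive data", {
  expect_equal(fitLinearBaseline(toyTable(), maxOrder = 1)$nParams, 5L)
  # 1 + C(34,1) = 35 parameters for a first-order model over 34 sites
  K <- 34L
  expect_equal(1L + sum(choose(K, 1)), 35L)

  # fitness generated additively (no nonlinearity): both model families
  # explain it equally well
  g <- sampleGenotypeLibrary(8, scheme = "exhaustive")
  beta <- seq(-0.04, 0.03, length.out = 8)
  y <- 0.8 + as.vector(g %*% beta)
  set.seed(4)
  fit <- matrix(y + rnorm(256, 0, 0.01), ncol = 1,
                dimnames = list(NULL, "abundance"))
  sig <- matrix(0.01, 256, 1, dimnames = list(NULL, "abundance"))
  tab <- genotypeTable(g, fit, sig)
  cfg <- fitConfig(maxInteractionOrder = 1, batchSizeGrid = 128L, seed = 5,
                   resample = FALSE)
  eres <- fitEnergyModel(tab, config = cfg)
  lres <- fitLinearBaseline(tab, maxOrder = 1, config = cfg,
                            split = splitAssignment(eres))
  expect_lt(abs(heldOutR2(eres)[["abundance"]] - lres$r2[["abundance"]]),
            0.01)
  expect_error(fitLinearBaseline(toyTable(), maxOrder = 3),
               "underdetermined")
})

test_that("variance explained matches its definition", {
  tab <- toyTable()
  y <- fitnessMatrix(tab)[, 1]
  # a model predicting the observations exactly is impossible to build by
  # hand here, so check the two degenerate identities on a fixture model
  m <- energyModel(substitutionIds(tab), dgwt = c(folding = -1),
                   ddg = list(folding = rep(0.5, 4)))
  yhat <- predictFitness(m, genotypes(tab))
  expect_equal(varianceExplained(m, tab)[["abundance"]],
               1 - sum((y - yhat)^2) / sum((y - mean(y))^2))
  one <- genotypeTable(genotypes(tab),
                       matrix(yhat, ncol = 1,
                              dimnames = list(NULL, "abundance")),
                       sigmaMatrix(tab))
  expect_equal(varianceExplained(m, one)[["abundance"]], 1)
})

test_that("classification flags and the wild-type z-test behave at the
          boundaries", {
  g <- rbind(c(0L, 0L), c(1L, 0L), c(0L, 1L), c(1L, 1L))
  colnames(g) <- c("s1", "s2")
  # s1 exactly neutralizes dgwt -> p = 0.5 tie classified as not folded
  m <- energyModel(c("s1", "s2"), dgwt = c(folding = -1),
                   ddg = list(folding = c(1, 8)))
  fit <- matrix(c(1, 1, 0.2, 1 + 1.96 * sqrt(2) * 0.1), ncol = 1,
                dimnames = list(NULL, "abundance"))
  sig <- matrix(0.1, 4, 1, dimnames = list(NULL, "abundance"))
  tab <- genotypeTable(g, fit, sig)
  out <- classifyAndTest(tab, m)
  expect_equal(out$folded, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(out$p_abundance[1], 1)            # y = y_wt
  expect_true(out$wt_indistinguishable_abundance[1])
  expect_equal(out$p_abundance[4], 0.05, tolerance = 1e-3)  # z = 1.96
  expect_false(out$wt_indistinguishable_abundance[3])
})

test_that("energy models serialize to JSON and back exactly", {
  spec <- truthSpec(K = 5, binding = TRUE, seed = 13)
  m <- generateTruth(spec)
  path <- tempfile(fileext = ".json")
  writeEnergyModel(m, path, config = fitConfig(seed = 4))
  back <- readEnergyModel(path)
  expect_equal(wtEnergies(back), wtEnergies(m))
  expect_equal(ddgTerms(back), ddgTerms(m))
  expect_equal(couplingTerms(back), couplingTerms(m))
  expect_equal(affineParams(back), affineParams(m))
  expect_equal(modelConstants(back), modelConstants(m))
})

test_that("Monte Carlo uncertainty reports calibrated intervals that widen
          with noise", {
  g <- sampleGenotypeLibrary(6, scheme = "exhaustive")
  truth <- generateTruth(truthSpec(K = 6, ddgF = c(0.4, 0.4),
                                   couplingSparsity = 0, seed = 3))
  cfg <- fitConfig(maxInteractionOrder = 1, batchSizeGrid = 32L, seed = 11,
                   nMcModels = 10L)
  lo <- simulateMeasurements(truth, g, sigma0 = 0.001, seed = 17)
  hi <- simulateMeasurements(truth, g, sigma0 = 0.1, seed = 17)
  mcLo <- monteCarloUncertainty(lo, config = cfg)
  mcHi <- monteCarloUncertainty(hi, config = cfg)
  expect_true(all(mcLo$ci95_width < 0.1))
  expect_true(all(mcLo$confident))
  expect_gt(mean(mcHi$ci95_width), mean(mcLo$ci95_width))
  # the confident rule is exactly CI width < 1 kcal/mol
  expect_identical(mcHi$confident, mcHi$ci95_width < 1)
  # truth lies inside most intervals at low noise
  ddgRows <- mcLo$term == "ddg"
  truthVals <- ddgTerms(truth)[mcLo$id[ddgRows], "folding"]
  cover <- truthVals >= mcLo$ci95_lo[ddgRows] - 0.02 &
    truthVals <= mcLo$ci95_hi[ddgRows] + 0.02
  expect_gte(mean(cover), 0.8)
  expect_error(monteCarloUncertainty(lo, config = fitConfig(nMcModels = 1L)),
               "nMcModels")
})
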