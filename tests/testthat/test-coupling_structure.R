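test_that("minimal side-chain distances match brute-force atom
          enumeration", {
  struct <- toyStructure()
  atoms <- toyStructureAtoms()

  # single-CB residues at (0,0,0) and (3,4,0): the 3-4-5 triangle
  expect_equal(as.numeric(minSidechainDistance(struct, 1, 2)), 5.0)
  # a residue against itself
  expect_equal(as.numeric(minSidechainDistance(struct, 1, 1)), 0)
  # symmetry and agreement with exhaustive enumeration over all atom pairs
  for (i in 1:4) for (j in 1:4) {
    dij <- minSidechainDistance(struct, i, j)
    dji <- minSidechainDistance(struct, j, i)
    expect_equal(as.numeric(dij), as.numeric(dji))
    expect_equal(as.numeric(dij), bfMinDist(atoms, i, j), tolerance = 1e-9)
  }
  # glycine falls back to its C-alpha and is flagged
  expect_true(attr(minSidechainDistance(struct, 2, 3), "fallback"))
  expect_false(attr(minSidechainDistance(struct, 1, 2), "fallback"))
  expect_error(minSidechainDistance(struct, 1, 9), "not found")
})

test_that("contact maps apply the distance threshold and long-range mask", {
  struct <- toyStructure()
  cm <- contactMap(struct, 1:4, threshold = 8, backboneCutoff = 2)
  expect_true(isSymmetric(cm$contacts))
  expect_false(any(diag(cm$contacts)))
  expect_true(cm$contacts["1", "2"])    # 5.0 < 8
  expect_equal(cm$distance["1", "2"], 5.0)
  expect_identical(cm$longRange, abs(outer(1:4, 1:4, "-")) > 2)

  # a chain with every side chain >= 10 apart yields an empty map
  far <- toyStructureAtoms()
  far$x <- far$x + 20 * (far$resno - 1)
  cmFar <- contactMap(readStructure(writeToyPdb(far), chain = "A"), 1:4,
                      threshold = 8)
  expect_false(any(cmFar$contacts))
  expect_error(contactMap(struct, 1:4, threshold = -1), "positive")
})

test_that("GetContacts tables are parsed, mapped and counted literally", {
  path <- writeToyContacts(c(
    "0\tsb\tA:ASP:1:OD1\tA:LYS:4:NZ",
    "0\tsb\tA:ASP:1:OD1\tA:LYS:4:NZ",          # duplicate -> counts twice
    "0\thbbb\tA:ALA:2:N\tA:GLY:3:O",
    "0\tweird\tA:ALA:2:N\tA:GLY:3:O"))
  expect_warning(contacts <- readContactsFile(path), "weird")
  expect_equal(nrow(contacts), 3L)
  expect_equal(contacts$type,
               c("salt_bridge", "salt_bridge", "hbond_bb_bb"))
  expect_equal(contacts$pos_i, c(1L, 1L, 2L))
  expect_equal(contacts$pos_j, c(4L, 4L, 3L))

  coup <- data.frame(pos_i = c(1, 2), pos_j = c(4, 3),
                     coupling = c(-0.5, 0.2))
  feat <- buildPairFeatures(coup, toyAnnotations(), toyStructure(),
                            contacts)
  expect_equal(feat$salt_bridge, c(2L, 0L))
  expect_equal(feat$hbond_bb_bb, c(0L, 1L))
  expect_equal(feat$strength, c(0.5, 0.2))
})

test_that("the pair feature table has exactly the 12 features with
          hand-assembled values", {
  ann <- toyAnnotations()
  struct <- toyStructure()
  coup <- data.frame(pos_i = c(2, 1, 1), pos_j = c(1, 3, 4),
                     coupling = c(0.3, -0.1, 0.05))
  feat <- buildPairFeatures(coup, ann, struct, contacts = NULL)

  featureCols <- c("backbone_distance", "scha_distance", "n_core",
                   "n_interface", "n_strand", "hbond_bb_bb", "hbond_sc_bb",
                   "hbond_sc_sc", "pi_cation", "pi_stacking", "salt_bridge",
                   "van_der_waals")
  expect_true(all(featureCols %in% names(feat)))
  expect_equal(length(featureCols), 12L)

  # pair (1,2): adjacent; residue 1 is core (rsasa 0.1) and interface
  # (3.2 < 5), both strand
  row12 <- feat[feat$pos_i == 1 & feat$pos_j == 2, ]
  expect_equal(row12$backbone_distance, 1)
  expect_equal(row12$scha_distance, 5.0)
  expect_equal(row12$n_core, 1)
  expect_equal(row12$n_interface, 1)
  expect_equal(row12$n_strand, 2)
  expect_true(all(row12[, c("hbond_bb_bb", "salt_bridge")] == 0))

  # pair order is normalized (the (2,1) input landed as (1,2))
  expect_true(all(feat$pos_i < feat$pos_j))
  # pair (1,4): both interface (3.2, 4.4 < 5), one core, one strand
  row14 <- feat[feat$pos_i == 1 & feat$pos_j == 4, ]
  expect_equal(row14$n_interface, 2)
  expect_equal(row14$n_core, 1)
  expect_equal(row14$n_strand, 1)

  expect_error(buildPairFeatures(data.frame(pos_i = 1, pos_j = 9,
                                            coupling = 1),
                                 ann, struct), "without annotations")
})

test_that("the 12-feature regression recovers known coefficients", {
  betas <- c(-0.15, -0.2, 0.05, 0, 0.1, 0.08, 0, 0.04, 0, 0, 0.12, 0.06)
  train <- syntheticPairTable(120, betas, seed = 5)
  fit <- fitCouplingStrengthModel(train)
  est <- fit$coefficients$estimate[-1]          # drop intercept
  big <- abs(betas) >= 0.05
  expect_true(all(sign(est[big]) == sign(betas[big])))
  pred <- predict(fit$fit)
  expect_gt(cor(pred, train$strength), 0.95)
  # significant features get small p-values
  expect_true(all(fit$coefficients$p_value[-1][abs(betas) >= 0.1] < 0.01))
  expect_error(fitCouplingStrengthModel(train[1:10, ]), "at least 20")
})

test_that("standardized regression is invariant to feature rescaling and
          pair order", {
  betas <- c(-0.15, -0.2, 0.05, 0, 0.1, 0.08, 0, 0.04, 0, 0, 0.12, 0.06)
  train <- syntheticPairTable(100, betas, seed = 8)
  test <- syntheticPairTable(100, betas, seed = 9)
  test$pos_i <- test$pos_i + 1000  # disjoint pair keys

  fit <- fitCouplingStrengthModel(train)
  base <- evaluateCouplingModel(fit, test)

  # affine rescaling of a raw feature unit (Angstrom -> nm) leaves
  # predictions identical
  train2 <- train; train2$scha_distance <- train2$scha_distance / 10
  test2 <- test; test2$scha_distance <- test2$scha_distance / 10
  fit2 <- fitCouplingStrengthModel(train2)
  expect_equal(evaluateCouplingModel(fit2, test2), base, tolerance = 1e-9)

  # permuting the row order of the training pairs leaves the fit invariant
  fit3 <- fitCouplingStrengthModel(train[sample(nrow(train)), ])
  expect_equal(sort(fit3$coefficients$estimate),
               sort(fit$coefficients$estimate), tolerance = 1e-12)
})

test_that("held-out evaluation refuses overlapping pairs and scores a
          perfect model at 1", {
  betas <- c(-0.15, -0.2, 0.05, 0, 0.1, 0.08, 0, 0.04, 0, 0, 0.12, 0.06)
  train <- syntheticPairTable(80, betas, seed = 2)
  fit <- fitCouplingStrengthModel(train)
  expect_error(evaluateCouplingModel(fit, train), "overlap")

  noiseless <- syntheticPairTable(80, betas, noiseSd = 1e-12, seed = 3)
  noiseless$pos_i <- noiseless$pos_i + 500
  fitN <- fitCouplingStrengthModel(noiseless)
  held <- syntheticPairTable(80, betas, noiseSd = 1e-12, seed = 4)
  held$pos_i <- held$pos_i + 9000
  ev <- evaluateCouplingModel(fitN, held)
  expect_equal(unname(ev["r"]), 1, tolerance = 1e-4)
  expect_equal(unname(ev["r2"]), 1, tolerance = 1e-3)
})

test_that("coupling-distance statistics apply the documented masks", {
  # strictly decreasing strength in distance -> rho = -1 on every slice
  tab <- data.frame(strength = seq(1, 0.1, length.out = 12),
                    scha_distance = seq(2, 24, length.out = 12),
                    backbone_distance = c(1:6, 8, 10, 12, 14, 16, 18))
  st <- couplingDistanceStats(tab)
  expect_equal(unname(st$rho["scha_all"]), -1)
  expect_equal(unname(st$rho["scha_longrange"]), -1)

  # hand-checked restriction masks on a toy table
  tab2 <- data.frame(strength = c(0.9, 0.8, 0.1, 0.2, 0.3, 0.4),
                     scha_distance = c(3, 4, 10, 12, 6, 7),
                     backbone_distance = c(1, 2, 9, 11, 7, 8))
  st2 <- couplingDistanceStats(tab2)
  longR <- tab2$backbone_distance > 5
  expect_equal(unname(st2$rho["scha_longrange"]),
               cor(tab2$strength[longR], tab2$scha_distance[longR],
                   method = "spearman"))
  nonC <- tab2$scha_distance >= 5
  expect_equal(unname(st2$rho["backbone_noncontact"]),
               cor(tab2$strength[nonC], tab2$backbone_distance[nonC],
                   method = "spearman"))

  # independent strengths give rho near zero on average across replicates
  set.seed(12)
  rhos <- replicate(200, {
    t3 <- data.frame(strength = runif(30),
                     scha_distance = runif(30, 2, 20),
                     backbone_distance = sample(1:20, 30, TRUE))
    couplingDistanceStats(t3)$rho[["scha_all"]]
  })
  expect_lt(abs(mean(rhos)), 0.05)

  # fewer than 3 pairs after restriction is an error
  tiny <- data.frame(strength = c(1, 0.5, 0.2),
                     scha_distance = c(2, 3, 4),
                     backbone_distance = c(1, 2, 3))
  expect_error(couplingDistanceStats(tiny), "fewer than 3")

  # Monte Carlo replicate bands are attached to the binned means
  mc <- matrix(rep(tab$strength, 10), ncol = 10) +
    matrix(rnorm(120, 0, 0.01), ncol = 10)
  stMc <- couplingDistanceStats(tab, mcStrengths = mc)
  expect_true(all(c("ci95_lo", "ci95_hi") %in% names(stMc$binned)))
  expect_true(all(stMc$binned$ci95_lo <= stMc$binned$ci95_hi))
})

test_that("folding couplings are compared with binding couplings by a
          Mann-Whitney test", {
  set.seed(9)
  out <- compareCouplingStrengths(rnorm(100, 0, 0.25), rnorm(100, 0, 0.05))
  expect_lt(out$p_value, 1e-4)
  expect_gt(out$auc, 0.5)
  expect_gt(out$folding[["mean"]], out$binding[["mean"]])
})
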