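# a small candidate set with known energies over a 6-substitution model
designFixture <- function(ddgF = c(0, 0.3, 0.6, 0.9, 1.2, 1.5),
                          ddgB = rep(0.2, 6), binding = TRUE) {
  ids <- paste0(c("A", "C", "D", "E", "F", "G"), 1:6, "V")
  cand <- data.frame(id = ids, position = 1:6,
                     wt_aa = c("A", "C", "D", "E", "F", "G"),
                     mut_aa = "V", stringsAsFactors = FALSE)
  dgwt <- c(folding = -2, binding = if (binding) -1 else NULL)
  ddg <- list(folding = ddgF)
  if (binding) {
    ddg$binding <- ddgB
    dgwt <- c(folding = -2, binding = -1)
  } else dgwt <- c(folding = -2)
  model <- energyModel(ids, dgwt = dgwt, ddg = ddg)
  list(cand = cand, model = model)
}

test_that("candidate filtering applies the confidence, background and
          reachability rules", {
  effects <- data.frame(
    id = c("P2A", "P2T", "A5V", "R7Q", "W10L", "W10C"),
    position = c(2, 2, 5, 7, 10, 10),
    wt_aa = c("P", "P", "A", "R", "W", "W"),
    mut_aa = c("A", "T", "V", "Q", "L", "C"),
    ddg_f = rnorm(6),
    ci95_f = c(0.4, 1.2, 0.8, 0.99, 0.5, 0.3),   # P2T fails (>= 1)
    n_backgrounds = c(25, 30, 19, 20, 40, 21),   # A5V fails (< 20)
    nt_reachable = TRUE)
  kept <- filterCandidates(effects, traits = "folding")
  expect_equal(kept$id, c("P2A", "R7Q", "W10L", "W10C"))

  # boundary checks: ci 1.2 excluded, backgrounds 19 excluded / 20 kept
  expect_false("P2T" %in% kept$id)
  expect_false("A5V" %in% kept$id)
  expect_true("R7Q" %in% kept$id)

  # reachability computed from the nucleotide sequence when supplied
  eff2 <- data.frame(id = c("P2A", "P2W"), position = 2, wt_aa = "P",
                     mut_aa = c("A", "W"), ddg_f = 0, ci95_f = 0.1,
                     n_backgrounds = 50)
  kept2 <- filterCandidates(eff2, wt_nt_seq = "ATGCCT", traits = "folding")
  expect_equal(kept2$id, "P2A")  # CCT reaches GCT (Ala) but not TGG (Trp)

  expect_error(filterCandidates(effects[, -6], traits = "folding"),
               "confidence-interval")
})

test_that("an exactly neutral candidate is always chosen first", {
  fx <- designFixture(ddgF = c(0.8, 0, 0.5, 1, 1.5, 2), ddgB = rep(0, 6))
  tr <- greedyDesign(fx$cand$id[1], fx$cand, fx$model)
  expect_equal(tr@steps$id[2], fx$cand$id[2])   # the ddg = 0 candidate
})

test_that("each greedy step equals the exhaustive per-step argmax", {
  set.seed(31)
  for (rep in 1:3) {
    K <- 8
    ids <- paste0("A", 1:K, "V")
    cand <- data.frame(id = ids, position = 1:K, wt_aa = "A", mut_aa = "V")
    model <- energyModel(ids,
                         dgwt = c(folding = -2, binding = -1),
                         ddg = list(folding = rnorm(K, 0.5, 0.5),
                                    binding = rnorm(K, 0.3, 0.3)))
    tr <- greedyDesign(ids[1], cand, model)
    phen <- c("abundance", "binding")
    gm <- function(sel) {
      g <- matrix(0, 1, K, dimnames = list(NULL, ids))
      g[, match(sel, ids)] <- 1
      exp(mean(log(pmax(vapply(phen, function(ph)
        predictFitness(model, g, ph), 0), 1e-6))))
    }
    sel <- ids[1]
    for (s in 2:K) {
      open <- setdiff(ids, sel)
      objs <- vapply(open, function(id) gm(c(sel, id)), 0)
      best <- open[which.max(objs)]
      expect_equal(tr@steps$id[s], best)
      expect_equal(tr@steps$objective[s], max(objs), tolerance = 1e-12)
      sel <- c(sel, best)
    }
  }
})

test_that("ties fall back to the deterministic candidate order and
          trajectories never revisit a position", {
  fx <- designFixture(ddgF = rep(1, 6), ddgB = rep(0.5, 6))
  tr <- greedyDesign(fx$cand$id[3], fx$cand, fx$model)
  # all equally destabilizing: remaining picks follow position order
  expect_equal(tr@steps$id, fx$cand$id[c(3, 1, 2, 4, 5, 6)])
  expect_equal(anyDuplicated(tr@steps$position), 0L)
  expect_lte(nrow(tr@steps), 6L)

  # objective is non-increasing when every candidate destabilizes
  expect_true(all(diff(tr@steps$objective) <= 1e-12))
  expect_error(greedyDesign("A1V", fx$cand[0, ], fx$model), "empty")
})

test_that("library growth simulation matches exhaustive enumeration on a
          3-substitution set", {
  fx <- designFixture()
  ids3 <- fx$cand$id[1:3]
  med <- simulateLibraryGrowth(ids3, fx$model, n = 10000, seed = 1)
  g <- sampleGenotypeLibrary(3, scheme = "exhaustive", subIds = ids3)
  gg <- matrix(0, 8, 6, dimnames = list(NULL, substitutionIds(fx$model)))
  gg[, 1:3] <- g
  for (ph in c("abundance", "binding"))
    expect_equal(med[[ph]], median(predictFitness(fx$model, gg, ph)))

  # a neutral set leaves the medians at the wild-type predictions
  neutral <- designFixture(ddgF = rep(0, 6), ddgB = rep(0, 6))
  medN <- simulateLibraryGrowth(neutral$cand$id[1:4], neutral$model,
                                n = 500, seed = 2)
  wt <- matrix(0, 1, 6, dimnames = list(NULL, substitutionIds(neutral$model)))
  expect_equal(medN[["abundance"]],
               predictFitness(neutral$model, wt, "abundance"))
  # the default sample size follows the published protocol
  expect_equal(formals(simulateLibraryGrowth)$n, 10000L)
})

test_that("the largest viable library is selected by the 70% rule", {
  neutral <- designFixture(ddgF = rep(0, 6), ddgB = rep(0, 6))
  trajs <- designLibrary(neutral$cand, neutral$model, n = 200, seed = 5)
  chosen <- selectLargestViable(trajs)
  expect_equal(attr(chosen, "size"), 6L)  # all-neutral: everything viable

  # constructed case: mild candidates stay viable, harsh ones do not
  mixed <- designFixture(ddgF = c(0, 0.1, 0.2, 3, 3, 3), ddgB = rep(0, 6))
  trajs2 <- designLibrary(mixed$cand, mixed$model, n = 400, seed = 5)
  chosen2 <- selectLargestViable(trajs2)
  expect_lt(attr(chosen2, "size"), 6L)
  expect_true(all(c("A1V", "C2V", "D3V") %in% chosen2))

  # reproducibility of the full design
  trajs3 <- designLibrary(mixed$cand, mixed$model, n = 400, seed = 5)
  expect_identical(lapply(trajs2, function(t) t@steps),
                   lapply(trajs3, function(t) t@steps))

  # no viable library -> error
  dead <- designFixture(ddgF = rep(8, 6), ddgB = rep(8, 6))
  trajsD <- designLibrary(dead$cand, dead$model, n = 100, seed = 1)
  expect_error(selectLargestViable(trajsD), "no viable")
})

test_that("greedy solutions are close to the exhaustive subset optimum on
          small instances", {
  set.seed(77)
  K <- 10
  ids <- paste0("A", 1:K, "V")
  cand <- data.frame(id = ids, position = 1:K, wt_aa = "A", mut_aa = "V")
  model <- energyModel(ids, dgwt = c(folding = -2),
                       ddg = list(folding = rnorm(K, 0.6, 0.6)))
  targetSize <- 4L
  # exhaustive search over all size-4 subsets
  best <- -Inf
  cmb <- combn(K, targetSize)
  for (i in seq_len(ncol(cmb))) {
    g <- matrix(0, 1, K, dimnames = list(NULL, ids))
    g[, cmb[, i]] <- 1
    best <- max(best, predictFitness(model, g, "abundance"))
  }
  # greedy from every start, take its best size-4 prefix objective
  greedyBest <- max(vapply(ids, function(s) {
    tr <- greedyDesign(s, cand, model, phenotypes = "abundance")
    tr@steps$objective[targetSize]
  }, 0))
  gap <- best - greedyBest
  expect_gte(gap, -1e-12)      # greedy cannot beat the optimum
  expect_lt(gap, 0.05)         # and lands close to it here
})

test_that("sliding windows count flagged candidate positions", {
  effects <- data.frame(position = 1:30,
                        fitness = c(rep(0, 9), rep(0.02, 15), rep(0.5, 6)),
                        nt_reachable = c(rep(FALSE, 9), rep(TRUE, 15),
                                         rep(TRUE, 6)))
  # 15 mild reachable positions at 10..24 inside one 22-mer window
  win <- windowDesignFilter(effects, protLength = 30,
                            wtFitness = 0, fitnessBand = 0.05,
                            requiredCount = 15)
  expect_true(all(win$n_candidates >= 15))
  expect_true(any(win$width == 22 & win$start <= 10 & win$end >= 24))
  expect_equal(sort(unique(windowDesignFilter(effects, 30)$width)),
               c(20L, 21L, 22L))

  # interface exclusion removes otherwise-mild positions
  ld <- setNames(rep(10, 30), 1:30); ld["12"] <- 2
  win2 <- windowDesignFilter(effects, 30, wtFitness = 0, fitnessBand = 0.05,
                             ligandDistance = ld, requiredCount = 15)
  expect_equal(nrow(win2), 0L)

  expect_error(windowDesignFilter(effects, protLength = 10), "longer")
  none <- effects; none$nt_reachable <- FALSE
  expect_equal(sum(windowDesignFilter(none, 30, wtFitness = 0,
                                      fitnessBand = 0.05)$n_candidates), 0L)
})
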