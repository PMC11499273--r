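#' Draw a ground-truth energy model
#'
#' Samples an [EnergyModel-class] from a [TruthSpec-class]: first-order
#' folding ddG values from a destabilization-biased normal distribution
#' (default Normal(+1, 1) kcal/mol), zero-centred pairwise couplings
#' (default Normal(0, 0.25)) with a sparsity mask setting a fraction of
#' pairs exactly to zero, and, when the binding trait is on, milder
#' destabilization-biased binding effects. Reproducible for a fixed seed.
#'
#' @param spec a [TruthSpec-class].
#' @param subIds optional substitution identifiers (default `"s1".."sK"`).
#' @return A ground-truth [EnergyModel-class].
#' @export
generateTruth <- function(spec, subIds = NULL) {
  K <- spec@K
  if (is.null(subIds)) subIds <- paste0("s", seq_len(K))
  npair <- K * (K - 1L) / 2L
  withSeed(spec@seed, {
    traits <- c("folding", if (spec@binding) "binding")
    ddg <- matrix(stats::rnorm(K, spec@ddgF[1L], spec@ddgF[2L]),
                  dimnames = list(NULL, "folding"))
    dgwt <- c(folding = spec@dgwtF)
    mask <- stats::runif(npair) < spec@couplingSparsity
    coup <- matrix(ifelse(mask,
                          stats::rnorm(npair, 0, spec@couplingScale), 0),
                   dimnames = list(NULL, "folding"))
    if (spec@binding) {
      ddg <- cbind(ddg,
                   binding = stats::rnorm(K, spec@ddgB[1L], spec@ddgB[2L]))
      maskB <- stats::runif(npair) < spec@couplingSparsity
      coup <- cbind(coup,
                    binding = ifelse(maskB,
                                     stats::rnorm(npair, 0,
                                                  spec@couplingScale), 0))
      dgwt <- c(dgwt, binding = spec@dgwtB)
    }
    energyModel(subIds, dgwt = dgwt, ddg = ddg, couplings = coup,
                affine = spec@affine)
  })
}

#' Sample genotypes from a 2^K combinatorial space
#'
#' @param K number of substitutions.
#' @param n number of genotypes (ignored for `"exhaustive"`).
#' @param scheme `"uniform_space"` (uniform draws from the 2^K space,
#'   distinct unless `replace = TRUE`), `"per_order"` (equal counts per
#'   Hamming order where possible) or `"exhaustive"` (all 2^K).
#' @param seed integer seed.
#' @param subIds optional column names.
#' @param replace for `"uniform_space"`: allow repeated genotypes (a
#'   multiset of draws), permitting measurement budgets n > 2^K;
#'   downstream, [simulateMeasurements()] collapses duplicates into extra
#'   replicate measurements of the same genotype.
#' @return Integer n x K binary matrix.
#' @export
sampleGenotypeLibrary <- function(K, n = NULL,
                                  scheme = c("uniform_space", "per_order",
                                             "exhaustive"),
                                  seed = 1L, subIds = NULL, replace = FALSE) {
  scheme <- match.arg(scheme)
  K <- as.integer(K)
  if (is.null(subIds)) subIds <- paste0("s", seq_len(K))
  size <- 2^K
  fromCodes <- function(codes) {
    g <- matrix(0L, length(codes), K, dimnames = list(NULL, subIds))
    for (j in seq_len(K))
      g[, j] <- as.integer((codes %/% 2^(j - 1)) %% 2)
    g
  }
  if (scheme == "exhaustive") {
    if (K > 25L) stop("exhaustive enumeration limited to K <= 25")
    return(fromCodes(0:(size - 1L)))
  }
  if (is.null(n)) stop("n is required for sampling schemes")
  if (scheme == "uniform_space") {
    if (!replace && n > size)
      stop("n exceeds 2^K; use replace = TRUE for a multiset of draws")
    return(withSeed(seed, {
      if (K <= 25L && !replace) {
        fromCodes(sample.int(size, n) - 1)
      } else {
        # draw bits independently: exactly uniform over the 2^K space for
        # any K (indexing the space by a single number would exceed the
        # RNG's integer resolution for large K)
        draw <- function(m) matrix(as.integer(stats::runif(m * K) < 0.5),
                                   m, K)
        g <- draw(n)
        if (!replace) {
          g <- g[!duplicated(apply(g, 1L, paste, collapse = "")), ,
                 drop = FALSE]
          while (nrow(g) < n) {
            g <- rbind(g, draw(n - nrow(g)))
            g <- g[!duplicated(apply(g, 1L, paste, collapse = "")), ,
                   drop = FALSE]
          }
        }
        colnames(g) <- subIds
        g
      }
    }))
  }
  # per_order: equal counts per Hamming order 0..K where possible, with
  # the excess of saturated orders redistributed to orders with capacity
  withSeed(seed, {
    cap <- choose(K, 0:K)
    if (n > sum(cap)) stop("n exceeds 2^K")
    alloc <- integer(K + 1L); left <- n
    while (left > 0L) {
      open <- which(alloc < cap)
      per <- left %/% length(open)
      if (per == 0L) {
        alloc[open[seq_len(left)]] <- alloc[open[seq_len(left)]] + 1L
        left <- 0L
      } else {
        add <- pmin(cap[open] - alloc[open], per)
        alloc[open] <- alloc[open] + as.integer(add)
        left <- left - as.integer(sum(add))
      }
    }
    rows <- list()
    for (k in 0:K) {
      avail <- cap[k + 1L]
      take <- alloc[k + 1L]
      if (take == 0L) next
      if (avail <= 1e6) {
        sets <- utils::combn(K, k)
        pickIdx <- if (take == avail) seq_len(avail)
                   else sample.int(avail, take)
        g <- matrix(0L, take, K)
        for (i in seq_len(take))
          if (k > 0) g[i, sets[, pickIdx[i]]] <- 1L
      } else {
        g <- matrix(0L, 0L, K)
        while (nrow(g) < take) {
          cand <- t(vapply(seq_len(take - nrow(g)), function(i) {
            v <- integer(K); v[sample.int(K, k)] <- 1L; v
          }, integer(K)))
          g <- unique(rbind(g, cand))
        }
      }
      rows[[length(rows) + 1L]] <- g
    }
    g <- do.call(rbind, rows)
    colnames(g) <- subIds
    g
  })
}

#' Simulate measurement tables from a ground-truth model
#'
#' Simulates `R` replicate fitness measurements per genotype:
#' `replicate = predictFitness + Normal(0, sigma_v)` i.i.d., with
#' heteroscedastic per-variant noise
#' `sigma_v = sigma0 + sigma1 * (0.5 - |p - 0.5|)` mimicking a bounded
#' growth assay that is most uncertain mid-range (set `sigma1 = 0` for
#' constant noise). Aggregate fitness is the replicate mean and the table
#' sigma is `sigma_v / sqrt(R)`. Duplicate genotype rows (from multiset
#' sampling) are collapsed: a genotype drawn m times receives `m * R`
#' replicate draws, so its sigma shrinks by a further `sqrt(m)`.
#'
#' @param truth a ground-truth [EnergyModel-class].
#' @param genotypes binary genotype matrix (duplicates allowed).
#' @param sigma0 noise floor (fitness units, > 0).
#' @param sigma1 heteroscedastic slope (>= 0).
#' @param replicates number of replicates R.
#' @param seed integer seed.
#' @return A [GenotypeTable-class] with per-replicate values (padded with
#'   `NA` where collapsed genotypes differ in draw count).
#' @export
simulateMeasurements <- function(truth, genotypes, sigma0 = 0.05,
                                 sigma1 = 0, replicates = 3L, seed = 1L) {
  phen <- names(affineParams(truth))
  key <- apply(genotypes, 1L, paste, collapse = "")
  mult <- table(key)[unique(key)]
  uniq <- genotypes[!duplicated(key), , drop = FALSE]
  m <- as.integer(mult)  # draw multiplicity per unique genotype
  nU <- nrow(uniq)
  fit <- sig <- matrix(NA_real_, nU, length(phen),
                       dimnames = list(NULL, phen))
  reps <- list()
  maxDraws <- max(m) * replicates
  withSeed(seed, {
    for (ph in phen) {
      mu <- predictFitness(truth, uniq, ph)
      sv <- sigma0 + sigma1 * (0.5 - abs(scaleToProb(truth, mu, ph) - 0.5))
      draws <- matrix(NA_real_, nU, maxDraws)
      for (i in seq_len(nU)) {
        k <- m[i] * replicates
        draws[i, seq_len(k)] <- mu[i] + stats::rnorm(k, 0, sv[i])
      }
      fit[, ph] <- rowMeans(draws, na.rm = TRUE)
      sig[, ph] <- sv / sqrt(m * replicates)
      reps[[ph]] <- draws[, seq_len(min(maxDraws, replicates)), drop = FALSE]
    }
  })
  genotypeTable(uniq, fit, sig, replicates = reps, phenotypes = phen)
}

## invert the affine transform to recover the state probability underlying
## a predicted fitness (used only to shape heteroscedastic noise)
scaleToProb <- function(model, fitness, phenotype) {
  ab <- affineParams(model)[[phenotype]]
  pmin(pmax((fitness - ab[["a"]]) / ab[["b"]], 0), 1)
}

#' Simulate a measurement table directly from a TruthSpec
#'
#' Convenience wrapper: draws the truth model, samples genotypes and
#' simulates measurements, all seeded from the spec.
#'
#' @param spec a [TruthSpec-class].
#' @param n number of genotypes.
#' @param scheme sampling scheme, see [sampleGenotypeLibrary()].
#' @param replicates number of replicates.
#' @param replace allow multiset genotype draws (n > 2^K).
#' @return List with elements `truth` ([EnergyModel-class]) and `table`
#'   ([GenotypeTable-class]).
#' @export
simulateDataset <- function(spec, n, scheme = "uniform_space",
                            replicates = 3L, replace = FALSE) {
  truth <- generateTruth(spec)
  g <- sampleGenotypeLibrary(spec@K, n, scheme,
                             seed = deriveSeed(spec@seed, "genotypes"),
                             replace = replace)
  tab <- simulateMeasurements(truth, g, sigma0 = spec@sigma0,
                              sigma1 = spec@sigma1, replicates = replicates,
                              seed = deriveSeed(spec@seed, "noise"))
  list(truth = truth, table = tab)
}

#' Expected percentage of folded variants by mutant order
#'
#' For each requested mutant order k, draws random k-subsets of the
#' single-substitution folding ddG table, sums them onto the wild-type
#' folding energy (assuming additivity) and reports the percentage of
#' variants whose predicted fraction folded exceeds the threshold.
#'
#' @param ddg numeric vector of single-substitution folding ddG values
#'   (kcal/mol).
#' @param dgwt wild-type folding free energy (kcal/mol).
#' @param orders integer vector of mutant orders k.
#' @param nPerOrder random k-subsets drawn per order.
#' @param threshold fraction-folded classification threshold (strict >).
#' @param seed integer seed.
#' @param constants thermodynamic constants.
#' @return `data.frame` with columns `order` and `pct_folded` (0-100).
#' @export
foldedFractionByOrder <- function(ddg, dgwt, orders = 1:10,
                                  nPerOrder = 10000L, threshold = 0.5,
                                  seed = 1L,
                                  constants = c(R = GAS_CONSTANT,
                                                T = DEFAULT_TEMPERATURE)) {
  if (max(orders) > length(ddg))
    stop("requested order exceeds the number of available substitutions")
  withSeed(seed, {
    pct <- vapply(orders, function(k) {
      sums <- vapply(seq_len(nPerOrder), function(i)
        sum(ddg[sample.int(length(ddg), k)]), 0)
      100 * mean(fractionFolded(dgwt + sums, constants) > threshold)
    }, 0)
    data.frame(order = orders, pct_folded = pct)
  })
}
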