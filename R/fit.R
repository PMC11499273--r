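#' Split variants into training, validation and test sets
#'
#' Randomly partitions variants 70/20/10 by default. The split is
#' reproducible for a fixed seed and the wild-type row (mutant order 0), if
#' present, is always assigned to training.
#'
#' @param table a [GenotypeTable-class] (or an integer row count plus
#'   `wtRow`).
#' @param fractions train/validation/test fractions summing to 1.
#' @param seed integer seed.
#' @return Factor of `"train"/"validation"/"test"`, one per variant.
#' @export
splitVariants <- function(table, fractions = c(0.7, 0.2, 0.1), seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1")
  if (is(table, "GenotypeTable")) {
    n <- nrow(genotypes(table))
    wt <- which(mutantOrder(table) == 0L)
  } else {
    n <- as.integer(table); wt <- integer()
  }
  if (n < 10L) stop("table must contain at least 10 variants")
  lab <- withSeed(seed, {
    perm <- sample.int(n)
    nval <- round(fractions[2L] * n)
    ntest <- round(fractions[3L] * n)
    lab <- rep("train", n)
    lab[perm[seq_len(nval)]] <- "validation"
    lab[perm[nval + seq_len(ntest)]] <- "test"
    lab
  })
  if (length(wt) == 1L && lab[wt] != "train") {
    # swap wild type into training with the first training row
    swap <- which(lab == "train")[1L]
    lab[swap] <- lab[wt]
    lab[wt] <- "train"
  }
  factor(lab, levels = c("train", "validation", "test"))
}

#' Resample fitness values from their error distribution
#'
#' Replaces fitness with a random draw `fitness + Normal(0, sigma)` per
#' variant and phenotype (the measurement-error distribution is taken as
#' Gaussian with the variant's standard error). Used to propagate
#' measurement uncertainty into refits; validation and test data are left
#' unaltered by the fitting protocol, which only resamples training rows.
#'
#' @param table a [GenotypeTable-class].
#' @param seed integer seed.
#' @param rows integer indices of rows to resample (default: all).
#' @return A resampled copy of `table`.
#' @export
resampleTraining <- function(table, seed = 1L, rows = NULL) {
  fit <- fitnessMatrix(table)
  sig <- sigmaMatrix(table)
  if (is.null(rows)) rows <- seq_len(nrow(fit))
  fit[rows, ] <- withSeed(seed, {
    fit[rows, , drop = FALSE] +
      matrix(stats::rnorm(length(rows) * ncol(fit)), length(rows)) *
        sig[rows, , drop = FALSE]
  })
  genotypeTable(genotypes(table), fit, sig,
                replicates = replicateValues(table),
                phenotypes = phenotypeNames(table))
}

## ---- internal parameter bookkeeping -----------------------------------
## Flat parameter vector (theta, dimensionless energies; affine in fitness
## units): for each trait [wt, ddg (K), couplings (npair)], then for each
## phenotype [a, b].
paramLayout <- function(K, traits, phenotypes, order) {
  npair <- if (order == 2L) K * (K - 1L) / 2L else 0L
  idx <- list(); at <- 0L
  for (tr in traits) {
    idx[[tr]] <- list(wt = at + 1L, ddg = at + 1L + seq_len(K),
                      coup = if (npair) at + 1L + K + seq_len(npair)
                             else integer())
    at <- at + 1L + K + npair
  }
  for (ph in phenotypes) {
    idx[[paste0("affine_", ph)]] <- c(a = at + 1L, b = at + 2L)
    at <- at + 2L
  }
  list(idx = idx, n = at, K = K, npair = npair)
}

## Stable three-state probabilities and partials, given dimensionless
## theta_f, theta_b (log c absorbed by caller).
threeStateProbs <- function(thf, thb) {
  # log-weights of states uu, fu, fb
  l1 <- rep(0, length(thf)); l2 <- -thf; l3 <- -thf - thb
  m <- pmax(l1, l2, l3)
  e1 <- exp(l1 - m); e2 <- exp(l2 - m); e3 <- exp(l3 - m)
  z <- e1 + e2 + e3
  list(puu = e1 / z, pfu = e2 / z, pfb = e3 / z)
}

## One gradient evaluation over a set of variant rows.
## env carries: X, Xp, y (list per phenotype), sig (list), traits,
## phenotypes, layout, logc, lambda2
fitGradient <- function(theta, rows, env) {
  L <- env$layout; idx <- L$idx
  X <- env$X[rows, , drop = FALSE]
  Xp <- if (!is.null(env$Xp)) env$Xp[rows, , drop = FALSE] else NULL
  nobs <- length(rows) * length(env$phenotypes)
  grad <- 2 * env$lambda2 * theta
  loss <- env$lambda2 * sum(theta^2)

  thf <- theta[idx$folding$wt] + as.vector(X %*% theta[idx$folding$ddg])
  if (length(idx$folding$coup))
    thf <- thf + as.vector(Xp %*% theta[idx$folding$coup])
  sf <- numeric(length(rows))  # dL/d thf accumulator
  sb <- NULL

  sse <- isTRUE(env$sse)  # squared-error mode used only by the pre-fit
  if ("abundance" %in% env$phenotypes) {
    ab <- theta[idx$affine_abundance]
    pf <- stats::plogis(-thf)
    yhat <- ab[1L] + ab[2L] * pf
    res <- env$y$abundance[rows] - yhat
    w <- 1 / env$sig$abundance[rows]
    if (sse) {
      loss <- loss + sum(res^2 * w^2) / nobs
      r <- -2 * res * w^2 / nobs
    } else {
      loss <- loss + sum(abs(res) * w) / nobs
      r <- -sign(res) * w / nobs         # dL/dyhat
    }
    grad[idx$affine_abundance["a"]] <- grad[idx$affine_abundance["a"]] + sum(r)
    grad[idx$affine_abundance["b"]] <- grad[idx$affine_abundance["b"]] +
      sum(r * pf)
    sf <- sf + r * ab[2L] * (-pf * (1 - pf))
  }
  if ("binding" %in% env$phenotypes) {
    thb <- theta[idx$binding$wt] + as.vector(X %*% theta[idx$binding$ddg]) -
      env$logc
    if (length(idx$binding$coup))
      thb <- thb + as.vector(Xp %*% theta[idx$binding$coup])
    ps <- threeStateProbs(thf, thb)
    ab <- theta[idx$affine_binding]
    yhat <- ab[1L] + ab[2L] * ps$pfb
    res <- env$y$binding[rows] - yhat
    w <- 1 / env$sig$binding[rows]
    if (sse) {
      loss <- loss + sum(res^2 * w^2) / nobs
      r <- -2 * res * w^2 / nobs
    } else {
      loss <- loss + sum(abs(res) * w) / nobs
      r <- -sign(res) * w / nobs
    }
    grad[idx$affine_binding["a"]] <- grad[idx$affine_binding["a"]] + sum(r)
    grad[idx$affine_binding["b"]] <- grad[idx$affine_binding["b"]] +
      sum(r * ps$pfb)
    sf <- sf + r * ab[2L] * (-ps$pfb * ps$puu)
    sb <- r * ab[2L] * (-ps$pfb * (1 - ps$pfb))
  }

  grad[idx$folding$wt] <- grad[idx$folding$wt] + sum(sf)
  grad[idx$folding$ddg] <- grad[idx$folding$ddg] + as.vector(crossprod(X, sf))
  if (length(idx$folding$coup))
    grad[idx$folding$coup] <- grad[idx$folding$coup] +
      as.vector(crossprod(Xp, sf))
  if (!is.null(sb)) {
    grad[idx$binding$wt] <- grad[idx$binding$wt] + sum(sb)
    grad[idx$binding$ddg] <- grad[idx$binding$ddg] +
      as.vector(crossprod(X, sb))
    if (length(idx$binding$coup))
      grad[idx$binding$coup] <- grad[idx$binding$coup] +
        as.vector(crossprod(Xp, sb))
  }
  list(loss = loss, grad = grad)
}

## Weighted MAE data term (plus L2) over a row subset, no gradient.
fitLoss <- function(theta, rows, env) {
  fitGradient(theta, rows, env)$loss
}

## Adam training loop. Returns theta, history, stopped-epoch.
adamTrain <- function(theta, trainIdx, valIdx, env, config, batchSize,
                      maxEpochs, seed, rt) {
  m <- v <- numeric(length(theta))
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  lr <- config@initialLr
  t <- 0L
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric(), lr = numeric())
  wtHist <- matrix(numeric(), 0L, length(env$traits),
                   dimnames = list(NULL, env$traits))
  # ring buffer of epoch-end parameters: the returned estimate is the
  # average over the final ten epochs (the same stability window used by
  # the early-stopping rule), which removes the stochastic-gradient jitter
  # around the optimum
  tailBuf <- matrix(NA_real_, 10L, length(theta))
  withSeed(seed, {
    for (epoch in seq_len(maxEpochs)) {
      perm <- sample(trainIdx)
      starts <- seq(1L, length(perm), by = batchSize)
      for (s in starts) {
        rows <- perm[s:min(s + batchSize - 1L, length(perm))]
        fg <- fitGradient(theta, rows, env)
        if (!is.finite(fg$loss))
          stop("training diverged (non-finite loss); config: lr=",
               config@initialLr, " batch=", batchSize)
        t <- t + 1L
        m <- beta1 * m + (1 - beta1) * fg$grad
        v <- beta2 * v + (1 - beta2) * fg$grad^2
        mhat <- m / (1 - beta1^t); vhat <- v / (1 - beta2^t)
        theta <- theta - lr * mhat / (sqrt(vhat) + eps)
      }
      trainLoss <- fitLoss(theta, trainIdx, env)
      valLoss <- if (length(valIdx)) fitLoss(theta, valIdx, env) else trainLoss
      history[epoch, ] <- list(epoch, trainLoss, valLoss, lr)
      tailBuf[1L + (epoch - 1L) %% 10L, ] <- theta
      wtHist <- rbind(wtHist, vapply(env$traits, function(tr)
        theta[env$layout$idx[[tr]]$wt] * rt, 0))
      # exponential lr decay when validation loss has stalled over 10 epochs
      if (epoch >= 20L) {
        recent <- mean(history$val_loss[(epoch - 9L):epoch])
        before <- mean(history$val_loss[(epoch - 19L):(epoch - 10L)])
        if (recent >= before) lr <- lr * config@lrDecay
      }
      # early stop: wild-type free energies stable over the last 10 epochs
      if (epoch >= 10L) {
        sds <- apply(wtHist[(epoch - 9L):epoch, , drop = FALSE], 2L, stats::sd)
        if (all(sds <= config@earlyStopSd)) break
      }
    }
  })
  keep <- stats::complete.cases(tailBuf)
  if (any(keep)) theta <- colMeans(tailBuf[keep, , drop = FALSE])
  list(theta = theta, history = history)
}

## Build the environment of fixed quantities used by the gradient.
buildFitEnv <- function(table, config) {
  phenotypes <- phenotypeNames(table)
  if ("binding" %in% phenotypes && !"abundance" %in% phenotypes)
    stop("fitting the binding phenotype requires the abundance phenotype ",
         "(joint three-state fit)")
  traits <- c("folding", if ("binding" %in% phenotypes) "binding")
  X <- genotypes(table)
  storage.mode(X) <- "double"
  order <- config@maxInteractionOrder
  Xp <- if (order == 2L) pairwiseProducts(X) else NULL
  layout <- paramLayout(ncol(X), traits, phenotypes, order)
  y <- sig <- list()
  for (ph in phenotypes) {
    y[[ph]] <- fitnessMatrix(table)[, ph]
    sig[[ph]] <- sigmaMatrix(table)[, ph]
  }
  list(X = X, Xp = Xp, y = y, sig = sig, traits = traits,
       phenotypes = phenotypes, layout = layout,
       logc = log(config@ligandConc), lambda2 = config@lambda2)
}

## Initialization by inverse-link regression: estimate the affine
## transform from the 1%/99% fitness quantiles, map training fitness back
## to an approximate state probability, invert the Boltzmann link, and
## regress the resulting per-variant dimensionless energies on the
## genotype matrix (weighted by p(1-p), which downweights plateau rows
## where the inversion is ill-conditioned). This lands the optimizer in
## the basin of the thermodynamically oriented solution; Adam refines
## from there. Couplings start at (near) zero.
initTheta <- function(env, trainIdx, seed) {
  L <- env$layout
  X1 <- cbind(1, env$X[trainIdx, , drop = FALSE])
  clip <- function(p) pmin(pmax(p, 0.02), 0.98)
  # plateau rows (clipped) are excluded from the warm-start regression:
  # their inverted energies are censored, not measured
  bandWeight <- function(p) ifelse(p <= 0.02 | p >= 0.98, 0, p * (1 - p))
  withSeed(seed, {
    theta <- stats::rnorm(L$n, 0, 0.01)

    ya <- env$y$abundance[trainIdx]
    a <- stats::quantile(ya, 0.01, names = FALSE)
    b <- stats::quantile(ya, 0.99, names = FALSE) - a
    if (b <= 0) b <- 1
    theta[L$idx[[paste0("affine_", "abundance")]]] <- c(a, b)
    p0 <- (ya - a) / b
    p <- clip(p0)
    z <- -stats::qlogis(p)                  # approximate theta_f per variant
    w <- bandWeight(p0)
    beta <- tryCatch(
      stats::lm.wfit(X1, z, w)$coefficients,
      error = function(e) rep(0, ncol(X1)))
    beta[is.na(beta)] <- 0
    theta[L$idx$folding$wt] <- beta[1L]
    theta[L$idx$folding$ddg] <- beta[-1L]

    if ("binding" %in% env$phenotypes) {
      yb <- env$y$binding[trainIdx]
      ab <- stats::quantile(yb, 0.01, names = FALSE)
      bb <- stats::quantile(yb, 0.99, names = FALSE) - ab
      if (bb <= 0) bb <- 1
      theta[L$idx[[paste0("affine_", "binding")]]] <- c(ab, bb)
      pfb0 <- (yb - ab) / bb
      pfb <- clip(pfb0)
      thf <- as.vector(X1 %*% beta)
      # p_fb = 1/(e^{thb}(1 + e^{thf}) + 1)  =>  thb from pfb and thf
      zb <- log((1 / pfb - 1) / (1 + exp(thf))) + env$logc
      wb <- bandWeight(pfb0)
      betab <- tryCatch(
        stats::lm.wfit(X1, zb, wb)$coefficients,
        error = function(e) rep(0, ncol(X1)))
      betab[is.na(betab)] <- 0
      theta[L$idx$binding$wt] <- betab[1L]
      theta[L$idx$binding$ddg] <- betab[-1L]
    }
    theta
  })
}

## Second initialization stage: deterministic BFGS minimization of the
## precision-weighted squared error of the full nonlinear model on the
## training rows. This hands the stochastic (Adam/MAE) protocol a start in
## the immediate neighbourhood of the optimum, so its role reduces to
## refinement under the stated loss.
lsPreFit <- function(theta, trainIdx, env, maxit = 200L) {
  env2 <- env; env2$sse <- TRUE
  out <- tryCatch(
    stats::optim(theta,
                 fn = function(th) fitGradient(th, trainIdx, env2)$loss,
                 gr = function(th) fitGradient(th, trainIdx, env2)$grad,
                 method = "BFGS", control = list(maxit = maxit)),
    error = function(e) NULL)
  if (is.null(out) || !all(is.finite(out$par))) theta else out$par
}

thetaToModel <- function(theta, env, config) {
  L <- env$layout; rt <- GAS_CONSTANT * DEFAULT_TEMPERATURE
  subIds <- colnames(env$X)
  dgwt <- vapply(env$traits, function(tr) theta[L$idx[[tr]]$wt] * rt, 0)
  ddg <- vapply(env$traits, function(tr) theta[L$idx[[tr]]$ddg] * rt,
                numeric(L$K))
  if (L$K == 1L) ddg <- matrix(ddg, 1L, dimnames = list(NULL, env$traits))
  coup <- if (L$npair) {
    vapply(env$traits, function(tr) theta[L$idx[[tr]]$coup] * rt,
           numeric(L$npair))
  } else NULL
  if (!is.null(coup) && L$npair == 1L)
    coup <- matrix(coup, 1L, dimnames = list(NULL, env$traits))
  affine <- lapply(env$phenotypes, function(ph) {
    ab <- theta[L$idx[[paste0("affine_", ph)]]]
    c(a = ab[[1L]], b = ab[[2L]])
  })
  names(affine) <- env$phenotypes
  energyModel(subIds, dgwt = dgwt, ddg = ddg, couplings = coup,
              affine = affine,
              constants = c(R = GAS_CONSTANT, T = DEFAULT_TEMPERATURE,
                            c = config@ligandConc))
}

#' Canonicalize an energy model's sign convention
#'
#' The two-state logistic has an exact discrete symmetry: negating all
#' folding energies while replacing the affine transform `(a, b)` by
#' `(a + b, -b)` leaves every prediction unchanged. Reported models are
#' therefore canonicalized so that the abundance slope `b` is positive
#' (more folded = fitter), which makes recovered parameters comparable to a
#' generator's truth without gauge drift. The symmetry is broken by the
#' three-state likelihood, so models with a binding trait are returned
#' unchanged.
#'
#' @param model an [EnergyModel-class].
#' @return The canonicalized model (predictions identical).
#' @export
canonicalizeModel <- function(model) {
  if ("binding" %in% model@traits) return(model)
  ab <- model@affine[["abundance"]]
  if (is.null(ab) || ab[["b"]] > 0) return(model)
  model@affine[["abundance"]] <- c(a = ab[["a"]] + ab[["b"]], b = -ab[["b"]])
  model@dgwt <- -model@dgwt
  model@ddg <- -model@ddg
  if (nrow(model@couplings)) model@couplings <- -model@couplings
  model
}

#' Fit a thermodynamic energy model
#'
#' Fits the two-state (abundance only) or joint three-state (abundance +
#' binding) Boltzmann model to a variant fitness table by stochastic
#' gradient descent on the weighted, L2-regularized mean absolute error,
#' using the Adam optimizer. The protocol: a 70/20/10
#' train/validation/test split (wild type kept in training); training
#' fitness optionally resampled from its error distribution; batch size
#' selected on the validation loss after 100 epochs when a grid is given;
#' at most 1000 epochs with the learning rate decayed exponentially
#' (gamma = 0.98) whenever the validation loss of the last ten epochs has
#' not improved on the preceding ten; early stopping once the wild-type
#' free energies are stable (sd <= 1e-3 kcal/mol over ten epochs). Model
#' parameters are dimensionless energies theta with `dG = theta * RT`
#' (T = 303 K, R = 0.001987 kcal/K/mol); the returned model is in kcal/mol
#' and canonicalized via [canonicalizeModel()].
#'
#' @param table a [GenotypeTable-class].
#' @param lib optional [LibraryDefinition-class] (checked for consistency).
#' @param config a [FitConfig-class].
#' @return A [FitResult-class]: fitted model, training history, split
#'   assignment and held-out (test) R^2 per phenotype.
#' @export
fitEnergyModel <- function(table, lib = NULL, config = fitConfig()) {
  if (!is.null(lib) &&
      !identical(substitutionIds(lib), substitutionIds(table)))
    stop("table substitutions do not match the library definition")
  env <- buildFitEnv(table, config)
  n <- nrow(env$X)
  if (n < env$layout$n)
    stop(sprintf("unidentifiable model: %d variants < %d parameters",
                 n, env$layout$n))
  split <- splitVariants(table, config@splitFractions,
                         deriveSeed(config@seed, "split"))
  trainIdx <- which(split == "train")
  valIdx <- which(split == "validation")
  testIdx <- which(split == "test")

  fitTable <- if (config@resample) {
    resampleTraining(table, deriveSeed(config@seed, "resample"),
                     rows = trainIdx)
  } else table
  for (ph in env$phenotypes) env$y[[ph]] <- fitnessMatrix(fitTable)[, ph]

  rt <- GAS_CONSTANT * DEFAULT_TEMPERATURE
  theta0 <- initTheta(env, trainIdx, deriveSeed(config@seed, "init"))
  theta0 <- lsPreFit(theta0, trainIdx, env)

  grid <- pmin(config@batchSizeGrid, length(trainIdx))
  grid <- sort(unique(grid))
  batchSize <- grid[1L]
  if (length(grid) > 1L) {
    valAfter <- vapply(grid, function(bs) {
      fit <- adamTrain(theta0, trainIdx, valIdx, env, config, bs,
                       config@hyperEpochs, deriveSeed(config@seed, "hyper"),
                       rt)
      utils::tail(fit$history$val_loss, 1L)
    }, 0)
    batchSize <- grid[which.min(valAfter)]
  }

  fit <- adamTrain(theta0, trainIdx, valIdx, env, config, batchSize,
                   config@maxEpochs, deriveSeed(config@seed, "train"), rt)
  model <- canonicalizeModel(thetaToModel(fit$theta, env, config))

  r2 <- vapply(env$phenotypes, function(ph) {
    y <- fitnessMatrix(table)[testIdx, ph]
    yhat <- predictFitness(model, env$X[testIdx, , drop = FALSE], ph)
    1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  }, 0)

  new("FitResult", model = model, history = fit$history, split = split,
      r2 = r2, config = config, batchSize = as.integer(batchSize))
}

#' Fit a linear genetic-interaction baseline
#'
#' Ordinary least squares of fitness on genotype indicator products up to
#' `maxOrder` (1 + sum_k C(K, k) parameters), fitted per phenotype on the
#' same train/validation/test split as the energy model for comparability.
#' This is the additive-at-the-phenotype-level null that the thermodynamic
#' model is compared against.
#'
#' @param table a [GenotypeTable-class].
#' @param maxOrder interaction order 1, 2 or 3.
#' @param config a [FitConfig-class] (supplies split fractions and seed).
#' @param split optional precomputed split factor (to share an energy
#'   model's split exactly).
#' @return An object of class `"LinearBaseline"`: list with `coefficients`
#'   (per phenotype), `split`, `r2` (test R^2 per phenotype), `maxOrder`,
#'   `nParams`, and a `predict` method.
#' @export
fitLinearBaseline <- function(table, maxOrder = 1L, config = fitConfig(),
                              split = NULL) {
  stopifnot(maxOrder %in% 1:3)
  X <- genotypes(table); storage.mode(X) <- "double"
  K <- ncol(X)
  design <- X
  if (maxOrder >= 2L) design <- cbind(design, pairwiseProducts(X))
  if (maxOrder == 3L) {
    cmb <- utils::combn(K, 3L)
    trip <- X[, cmb[1L, ], drop = FALSE] * X[, cmb[2L, ], drop = FALSE] *
      X[, cmb[3L, ], drop = FALSE]
    colnames(trip) <- apply(cmb, 2L, function(j)
      paste(colnames(X)[j], collapse = ":"))
    design <- cbind(design, trip)
  }
  design <- cbind(`(Intercept)` = 1, design)
  if (is.null(split))
    split <- splitVariants(table, config@splitFractions,
                           deriveSeed(config@seed, "split"))
  trainIdx <- which(split == "train"); testIdx <- which(split == "test")
  if (length(trainIdx) < ncol(design))
    stop("underdetermined design matrix: ", ncol(design), " parameters, ",
         length(trainIdx), " training variants")
  coefs <- list(); r2 <- numeric(0)
  for (ph in phenotypeNames(table)) {
    y <- fitnessMatrix(table)[, ph]
    beta <- stats::lm.fit(design[trainIdx, , drop = FALSE], y[trainIdx])$coefficients
    beta[is.na(beta)] <- 0
    coefs[[ph]] <- beta
    yhat <- as.vector(design[testIdx, , drop = FALSE] %*% beta)
    r2[ph] <- 1 - sum((y[testIdx] - yhat)^2) /
      sum((y[testIdx] - mean(y[testIdx]))^2)
  }
  structure(list(coefficients = coefs, split = split, r2 = r2,
                 maxOrder = as.integer(maxOrder), nParams = ncol(design)),
            class = "LinearBaseline")
}

#' Predict from a linear baseline
#'
#' @param object a `"LinearBaseline"` fit.
#' @param genotypes binary genotype matrix.
#' @param phenotype phenotype name.
#' @param ... unused.
#' @return Predicted fitness vector.
#' @export
predict.LinearBaseline <- function(object, genotypes,
                                   phenotype = "abundance", ...) {
  beta <- object$coefficients[[phenotype]]
  X <- genotypes; storage.mode(X) <- "double"
  K <- ncol(X)
  design <- X
  if (object$maxOrder >= 2L) design <- cbind(design, pairwiseProducts(X))
  if (object$maxOrder == 3L) {
    cmb <- utils::combn(K, 3L)
    design <- cbind(design,
                    X[, cmb[1L, ], drop = FALSE] *
                      X[, cmb[2L, ], drop = FALSE] *
                      X[, cmb[3L, ], drop = FALSE])
  }
  design <- cbind(1, design)
  as.vector(design %*% beta)
}

#' Monte Carlo uncertainty of inferred free energies
#'
#' Refits the model `nMcModels` times (default ten), each refit using an
#' independent random train/validation/test split and an independent random
#' resample of the training fitness values from their error distributions.
#' Per coefficient, reports the across-refit mean, sd, 95% confidence
#' interval (2.5/97.5 percentiles) and a `confident` flag (CI width
#' < 1 kcal/mol).
#'
#' @param table a [GenotypeTable-class].
#' @param lib optional [LibraryDefinition-class].
#' @param config a [FitConfig-class]; `nMcModels >= 2`.
#' @return `data.frame` with columns `id`, `trait`, `term`, `mean`, `sd`,
#'   `ci95_lo`, `ci95_hi`, `ci95_width`, `confident`; attribute
#'   `"perModel"` holds the per-refit coefficient matrix and `"nFailed"`
#'   the number of failed refits.
#' @export
monteCarloUncertainty <- function(table, lib = NULL, config = fitConfig()) {
  if (config@nMcModels < 2L) stop("nMcModels must be >= 2")
  draws <- vector("list", config@nMcModels)
  failures <- character(0)
  for (k in seq_len(config@nMcModels)) {
    cfgk <- config
    cfgk@seed <- deriveSeed(config@seed, "mc", k)
    cfgk@resample <- TRUE
    res <- tryCatch(fitEnergyModel(table, lib, cfgk),
                    error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, conditionMessage(res))
      next
    }
    model <- fittedModel(res)
    vals <- numeric(0)
    for (tr in modelTraits(model)) {
      v <- c(wtEnergies(model)[[tr]], ddgTerms(model)[, tr])
      names(v) <- paste(c("WT", substitutionIds(model)), tr, sep = "|")
      if (model@order == 2L) {
        cv <- couplingTerms(model)[, tr]
        names(cv) <- paste(pairIds(model), tr, sep = "|")
        v <- c(v, cv)
      }
      vals <- c(vals, v)
    }
    draws[[k]] <- vals
  }
  ok <- !vapply(draws, is.null, TRUE)
  minOk <- max(2L, config@nMcModels - 2L)
  if (sum(ok) < minOk)
    stop(sum(!ok), " of ", config@nMcModels, " refits failed: ",
         paste(unique(failures), collapse = "; "))
  if (any(!ok))
    warning(sum(!ok), " refit(s) failed; intervals computed on ",
            sum(ok), " survivors")
  mat <- do.call(rbind, draws[ok])
  key <- do.call(rbind, strsplit(colnames(mat), "|", fixed = TRUE))
  qs <- apply(mat, 2L, stats::quantile, probs = c(0.025, 0.975))
  out <- data.frame(
    id = key[, 1L], trait = key[, 2L],
    term = ifelse(key[, 1L] == "WT", "wt",
                  ifelse(grepl(":", key[, 1L]), "coupling", "ddg")),
    mean = colMeans(mat), sd = apply(mat, 2L, stats::sd),
    ci95_lo = qs[1L, ], ci95_hi = qs[2L, ],
    row.names = NULL, stringsAsFactors = FALSE)
  out$ci95_width <- out$ci95_hi - out$ci95_lo
  out$confident <- out$ci95_width < 1
  attr(out, "perModel") <- mat
  attr(out, "nFailed") <- sum(!ok)
  out
}

#' Export a coefficient table
#'
#' Writes the Monte Carlo coefficient summary as a tab-separated table with
#' columns `id`, `trait`, `term`, `mean`, `sd`, `ci95_lo`, `ci95_hi`,
#' `confident`.
#'
#' @param coefTable output of [monteCarloUncertainty()].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
exportCoefficients <- function(coefTable, path) {
  cols <- c("id", "trait", "term", "mean", "sd", "ci95_lo", "ci95_hi",
            "confident")
  utils::write.table(coefTable[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
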