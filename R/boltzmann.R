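#' Boltzmann state probabilities
#'
#' Two-state folding equilibrium: `p_f = K_f / (1 + K_f)` with
#' `K_f = exp(-dG_f / RT)`. Three-state folding + binding equilibrium over
#' states unfolded-unbound, folded-unbound and folded-bound (the
#' unfolded-bound state is assumed negligible):
#' `p_fb = K_f K_b c / (1 + K_f + K_f K_b c)` with
#' `K_b = exp(-dG_b / RT)` and dimensionless ligand concentration `c`.
#' Both are computed in a saturation-safe form and are strictly decreasing
#' in each free energy.
#'
#' @param dg_f,dg_b free energies of folding / binding (kcal/mol);
#'   vectorized.
#' @param c ligand concentration (dimensionless, > 0).
#' @param constants named numeric `c(R =, T =)` (and optionally `c`).
#' @return Probabilities in (0, 1).
#' @examples
#' fractionFolded(0)                      # 0.5
#' fractionBound(0, 0)                    # 1/3
#' @export
fractionFolded <- function(dg_f, constants = c(R = GAS_CONSTANT,
                                               T = DEFAULT_TEMPERATURE)) {
  rt <- constants[["R"]] * constants[["T"]]
  stats::plogis(-dg_f / rt)
}

#' @rdname fractionFolded
#' @export
fractionBound <- function(dg_f, dg_b, c = 1,
                          constants = c(R = GAS_CONSTANT,
                                        T = DEFAULT_TEMPERATURE)) {
  if (any(c <= 0)) stop("ligand concentration c must be > 0")
  rt <- constants[["R"]] * constants[["T"]]
  # p_fb = 1 / (exp((dg_f + dg_b)/RT)/c + exp(dg_b/RT)/c + 1)
  tf <- dg_f / rt; tb <- dg_b / rt - log(c)
  1 / (exp(tf + tb) + exp(tb) + 1)
}

#' Free energy of a variant under an additive model with couplings
#'
#' Sums the wild-type free energy, the ddG terms of the substitutions
#' present, and (for second-order models) the couplings of the substitution
#' pairs present: `dG = dG_wt + sum_i x_i ddg_i + sum_{i<j} x_i x_j dddg_ij`.
#'
#' @param model an [EnergyModel-class].
#' @param genotype binary length-K vector or n x K matrix.
#' @param trait `"folding"` or `"binding"`.
#' @return Free energy (kcal/mol), one value per genotype row.
#' @export
variantFreeEnergy <- function(model, genotype, trait = "folding") {
  if (!trait %in% modelTraits(model)) stop("unknown trait: ", trait)
  g <- if (is.null(dim(genotype))) matrix(genotype, nrow = 1L) else genotype
  if (ncol(g) != length(model@subIds))
    stop("genotype length does not match model dimension K")
  dg <- model@dgwt[[trait]] + as.vector(g %*% model@ddg[, trait])
  if (model@order == 2L) {
    gp <- pairwiseProducts(g)
    dg <- dg + as.vector(gp %*% model@couplings[, trait])
  }
  dg
}

## n x K(K-1)/2 matrix of pairwise genotype products, combn(K, 2) order
pairwiseProducts <- function(g) {
  K <- ncol(g)
  cmb <- utils::combn(K, 2L)
  gp <- g[, cmb[1L, ], drop = FALSE] * g[, cmb[2L, ], drop = FALSE]
  colnames(gp) <- if (!is.null(colnames(g)))
    paste(colnames(g)[cmb[1L, ]], colnames(g)[cmb[2L, ]], sep = ":")
  gp
}

#' Predict assay fitness from an energy model
#'
#' Applies the phenotype's affine transform `a + b * p` to the Boltzmann
#' state probability: fraction folded for `"abundance"`, fraction
#' folded-and-bound for `"binding"`.
#'
#' @param model an [EnergyModel-class].
#' @param genotype binary length-K vector or n x K matrix.
#' @param phenotype `"abundance"` or `"binding"`.
#' @return Predicted fitness, one value per genotype row.
#' @export
predictFitness <- function(model, genotype, phenotype = "abundance") {
  if (!phenotype %in% names(model@affine))
    stop("unknown phenotype: ", phenotype)
  cst <- model@constants
  dgf <- variantFreeEnergy(model, genotype, "folding")
  p <- if (phenotype == "abundance") {
    fractionFolded(dgf, cst)
  } else {
    dgb <- variantFreeEnergy(model, genotype, "binding")
    fractionBound(dgf, dgb, c = cst[["c"]], cst)
  }
  ab <- model@affine[[phenotype]]
  ab[["a"]] + ab[["b"]] * p
}

#' Weighted, regularized mean absolute error
#'
#' `L = (1/N) sum_n |y_n - yhat_n| / sigma_n + lambda2 * ||theta||^2`:
#' each variant's absolute error is down-weighted by its measurement
#' standard error, plus a light L2 penalty on the model parameters.
#'
#' @param predicted,observed numeric vectors of equal length.
#' @param sigmas per-variant standard errors (> 0).
#' @param theta parameter vector entering the penalty (dimensionless).
#' @param lambda2 L2 penalty weight.
#' @return Non-negative scalar loss.
#' @export
weightedMaeLoss <- function(predicted, observed, sigmas, theta = numeric(),
                            lambda2 = 1e-6) {
  if (length(predicted) != length(observed) ||
      length(observed) != length(sigmas))
    stop("predicted, observed and sigmas must have equal length")
  if (any(sigmas <= 0)) stop("sigmas must be positive")
  mean(abs(observed - predicted) / sigmas) + lambda2 * sum(theta^2)
}

#' Proportion of fitness variance explained
#'
#' `R^2 = 1 - SS_res / SS_tot` of model predictions against observed
#' fitness, per phenotype.
#'
#' @param model an [EnergyModel-class].
#' @param table a [GenotypeTable-class] (or subset thereof).
#' @param phenotypes phenotypes to evaluate (default: all in the table that
#'   the model can predict).
#' @return Named numeric of R^2 values.
#' @export
varianceExplained <- function(model, table, phenotypes = NULL) {
  if (is.null(phenotypes))
    phenotypes <- intersect(phenotypeNames(table), names(model@affine))
  if (nrow(genotypes(table)) == 0L) stop("empty table subset")
  out <- numeric(0)
  for (ph in phenotypes) {
    y <- fitnessMatrix(table)[, ph]
    if (stats::var(y) == 0) stop("zero fitness variance for ", ph)
    yhat <- predictFitness(model, genotypes(table), ph)
    out[ph] <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  }
  out
}

#' Classify variants and test indistinguishability from wild type
#'
#' For each variant: `folded` = predicted fraction folded > 0.5, `bound` =
#' predicted fraction folded-and-bound > 0.5 (ties at exactly 0.5 classify
#' negative), and `wt_indistinguishable_<phenotype>` = two-sided z-test
#' p-value `2 * pnorm(-|z|) > 0.05` with
#' `z = (y_v - y_wt) / sqrt(sigma_v^2 + sigma_wt^2)`.
#'
#' @param table a [GenotypeTable-class] containing the wild-type row
#'   (order 0), unless `wtRow` is given.
#' @param model an [EnergyModel-class].
#' @param wtRow optional index of the wild-type row.
#' @param alpha significance level for the z-test.
#' @return `data.frame` of flags and p-values, one row per variant.
#' @export
classifyAndTest <- function(table, model, wtRow = NULL, alpha = 0.05) {
  if (is.null(wtRow)) {
    wtRow <- which(mutantOrder(table) == 0L)
    if (length(wtRow) != 1L)
      stop("wild-type row not found; supply wtRow explicitly")
  }
  g <- genotypes(table)
  out <- data.frame(row.names = NULL,
                    order = as.integer(rowSums(g)))
  dgf <- variantFreeEnergy(model, g, "folding")
  out$p_folded <- fractionFolded(dgf, model@constants)
  out$folded <- out$p_folded > 0.5
  if ("binding" %in% modelTraits(model)) {
    dgb <- variantFreeEnergy(model, g, "binding")
    out$p_bound <- fractionBound(dgf, dgb, model@constants[["c"]],
                                 model@constants)
    out$bound <- out$p_bound > 0.5
  }
  for (ph in phenotypeNames(table)) {
    y <- fitnessMatrix(table)[, ph]; s <- sigmaMatrix(table)[, ph]
    if (anyNA(s)) stop("missing sigma for phenotype ", ph)
    z <- (y - y[wtRow]) / sqrt(s^2 + s[wtRow]^2)
    p <- 2 * stats::pnorm(-abs(z))
    out[[paste0("z_", ph)]] <- z
    out[[paste0("p_", ph)]] <- p
    out[[paste0("wt_indistinguishable_", ph)]] <- p > alpha
  }
  out
}
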