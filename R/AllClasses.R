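#' @import methods
NULL

AA_ONE_LETTER <- c("A","C","D","E","F","G","H","I","K","L",
                   "M","N","P","Q","R","S","T","V","W","Y")

GAS_CONSTANT <- 0.001987  # kcal K^-1 mol^-1
DEFAULT_TEMPERATURE <- 303 # K

#' Library of substitutions subjected to combinatorial mutagenesis
#'
#' A `LibraryDefinition` records the wild-type amino-acid sequence, optionally
#' its coding nucleotide sequence, and the ordered set of K single amino-acid
#' substitutions (at most one per residue position) whose 2^K combinations
#' make up a combinatorial library, together with the molecular phenotypes
#' ("abundance", "binding") assayed on it.
#'
#' @slot wtAaSeq single-character string, wild-type amino-acid sequence.
#' @slot wtNtSeq single-character string or `NA`, wild-type coding sequence
#'   (length exactly 3x the protein length when present).
#' @slot substitutions `data.frame` with one row per substitution: columns
#'   `id`, `position`, `wt_aa`, `mut_aa` and optionally energies
#'   (`ddg_f`, `ci95_f`, `n_backgrounds`, `ddg_b`, `ci95_b`) and
#'   `nt_reachable`.
#' @slot phenotypes character, subset of `c("abundance", "binding")`.
#'
#' @exportClass LibraryDefinition
setClass("LibraryDefinition",
  representation(wtAaSeq = "character", wtNtSeq = "character",
                 substitutions = "data.frame", phenotypes = "character"))

setValidity("LibraryDefinition", function(object) {
  msg <- character()
  s <- object@substitutions
  if (nrow(s) < 1L) msg <- c(msg, "library must contain at least one substitution")
  need <- c("id", "position", "wt_aa", "mut_aa")
  if (!all(need %in% names(s)))
    return(paste("substitutions must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(s$position))
    msg <- c(msg, "at most one substitution per residue position")
  if (any(s$wt_aa == s$mut_aa))
    msg <- c(msg, "wt_aa must differ from mut_aa")
  aa <- strsplit(object@wtAaSeq, "")[[1]]
  if (any(s$position < 1L) || any(s$position > length(aa)))
    msg <- c(msg, "substitution positions outside wild-type sequence")
  else if (any(aa[s$position] != s$wt_aa))
    msg <- c(msg, "substitution wt_aa does not match wild-type sequence")
  if (!is.na(object@wtNtSeq) && nchar(object@wtNtSeq) != 3L * length(aa))
    msg <- c(msg, "wtNtSeq length must be 3x protein length")
  if (!all(object@phenotypes %in% c("abundance", "binding")))
    msg <- c(msg, "phenotypes must be a subset of c('abundance', 'binding')")
  if (length(msg)) msg else TRUE
})

#' Construct a LibraryDefinition
#'
#' @param wtAaSeq wild-type amino-acid sequence (single string).
#' @param substitutions `data.frame` of substitutions (see
#'   [LibraryDefinition-class]); an `id` column is added from
#'   `<wt_aa><position><mut_aa>` if absent.
#' @param phenotypes assayed phenotypes, subset of `c("abundance","binding")`.
#' @param wtNtSeq optional wild-type coding nucleotide sequence.
#' @return A [LibraryDefinition-class] object.
#' @examples
#' lib <- libraryDefinition("MGDK",
#'   data.frame(position = c(2, 4), wt_aa = c("G", "K"), mut_aa = c("A", "R")))
#' @export
libraryDefinition <- function(wtAaSeq, substitutions,
                              phenotypes = "abundance", wtNtSeq = NA_character_) {
  substitutions <- as.data.frame(substitutions)
  if (is.null(substitutions$id))
    substitutions$id <- paste0(substitutions$wt_aa, substitutions$position,
                               substitutions$mut_aa)
  substitutions$position <- as.integer(substitutions$position)
  substitutions <- substitutions[order(substitutions$position), , drop = FALSE]
  rownames(substitutions) <- NULL
  new("LibraryDefinition", wtAaSeq = wtAaSeq, wtNtSeq = wtNtSeq,
      substitutions = substitutions, phenotypes = phenotypes)
}

#' Genotype table: binary genotypes with per-phenotype fitness
#'
#' Holds an n x K binary genotype matrix over a library's K substitutions,
#' together with per-phenotype aggregate fitness, its standard error sigma,
#' and (optionally partial) per-replicate fitness values.
#'
#' @slot genotypes integer n x K matrix of 0/1, columns named by
#'   substitution id.
#' @slot phenotypes character, phenotypes with measurements.
#' @slot fitness numeric n x P matrix, columns named by phenotype.
#' @slot sigma numeric n x P matrix of standard errors (> 0).
#' @slot replicates named list, one n x R numeric matrix per phenotype
#'   (may contain `NA`); may be empty.
#'
#' @exportClass GenotypeTable
setClass("GenotypeTable",
  representation(genotypes = "matrix", phenotypes = "character",
                 fitness = "matrix", sigma = "matrix", replicates = "list"))

setValidity("GenotypeTable", function(object) {
  msg <- character()
  g <- object@genotypes
  if (!all(g %in% c(0L, 1L))) msg <- c(msg, "genotypes must be binary")
  if (anyDuplicated(apply(g, 1L, paste, collapse = "")))
    msg <- c(msg, "duplicate genotype rows are not allowed")
  if (nrow(object@fitness) != nrow(g) || nrow(object@sigma) != nrow(g))
    msg <- c(msg, "fitness/sigma row count must match genotypes")
  if (!all(object@phenotypes %in% colnames(object@fitness)))
    msg <- c(msg, "fitness must have one column per phenotype")
  sig <- object@sigma[, object@phenotypes, drop = FALSE]
  if (any(!is.na(sig) & sig <= 0))
    msg <- c(msg, "sigma must be > 0 for every retained row")
  if (length(msg)) msg else TRUE
})

#' Construct a GenotypeTable
#'
#' @param genotypes binary n x K matrix (column names = substitution ids).
#' @param fitness numeric n x P matrix or named list of numeric vectors.
#' @param sigma numeric n x P matrix or named list, standard errors.
#' @param replicates optional named list of n x R replicate-fitness matrices.
#' @param phenotypes phenotype names; defaults to `colnames(fitness)`.
#' @return A [GenotypeTable-class] object.
#' @export
genotypeTable <- function(genotypes, fitness, sigma, replicates = list(),
                          phenotypes = NULL) {
  toMat <- function(x) {
    if (is.list(x)) x <- do.call(cbind, x)
    if (is.null(dim(x))) x <- matrix(x, ncol = 1L,
                                     dimnames = list(NULL, "abundance"))
    as.matrix(x)
  }
  fitness <- toMat(fitness); sigma <- toMat(sigma)
  if (is.null(phenotypes)) phenotypes <- colnames(fitness)
  storage.mode(genotypes) <- "integer"
  new("GenotypeTable", genotypes = genotypes, phenotypes = phenotypes,
      fitness = fitness, sigma = sigma, replicates = replicates)
}

#' Thermodynamic energy model
#'
#' A two-state (folding) or three-state (folding + binding) Boltzmann model.
#' Each trait has a wild-type free energy, a length-K vector of additive
#' single-substitution free energy changes (ddG), and, for second-order
#' models, a length K(K-1)/2 vector of pairwise energetic couplings (dddG),
#' all in kcal/mol. Each phenotype has an affine transform `a + b * p`
#' mapping a state probability (fraction folded for abundance; fraction
#' folded-and-bound for binding) to assay fitness.
#'
#' @slot traits character, subset of `c("folding", "binding")`.
#' @slot order integer, 1 (additive) or 2 (with pairwise couplings).
#' @slot subIds character K, substitution identifiers.
#' @slot dgwt named numeric, wild-type free energy per trait (kcal/mol).
#' @slot ddg numeric K x traits matrix (kcal/mol).
#' @slot couplings numeric npair x traits matrix (kcal/mol); 0 rows when
#'   `order == 1`.
#' @slot pairIds character npair, `"<id_i>:<id_j>"` for i < j.
#' @slot affine named list per phenotype, each `c(a = , b = )` with `b != 0`.
#' @slot constants named numeric `c(R = , T = , c = )`: gas constant
#'   (kcal/K/mol), temperature (K), ligand concentration (dimensionless).
#'
#' @exportClass EnergyModel
setClass("EnergyModel",
  representation(traits = "character", order = "integer", subIds = "character",
                 dgwt = "numeric", ddg = "matrix", couplings = "matrix",
                 pairIds = "character", affine = "list", constants = "numeric"))

setValidity("EnergyModel", function(object) {
  msg <- character()
  K <- length(object@subIds)
  npair <- K * (K - 1L) / 2L
  if (!all(object@traits %in% c("folding", "binding")))
    msg <- c(msg, "traits must be a subset of c('folding', 'binding')")
  if ("binding" %in% object@traits && !"folding" %in% object@traits)
    msg <- c(msg, "binding trait requires the folding trait")
  if (!object@order %in% c(1L, 2L)) msg <- c(msg, "order must be 1 or 2")
  if (nrow(object@ddg) != K) msg <- c(msg, "ddg must have K rows")
  if (object@order == 2L && nrow(object@couplings) != npair)
    msg <- c(msg, sprintf("order-2 model must carry %d coupling rows", npair))
  if (object@order == 1L && nrow(object@couplings) != 0L)
    msg <- c(msg, "order-1 model must not carry couplings")
  for (ph in names(object@affine)) {
    ab <- object@affine[[ph]]
    if (!all(c("a", "b") %in% names(ab)) || ab[["b"]] == 0)
      msg <- c(msg, sprintf("affine transform for '%s' needs a and nonzero b", ph))
  }
  cst <- object@constants
  if (cst[["R"]] * cst[["T"]] <= 0) msg <- c(msg, "RT must be positive")
  if (cst[["c"]] <= 0) msg <- c(msg, "ligand concentration must be positive")
  if (length(msg)) msg else TRUE
})

#' Construct an EnergyModel
#'
#' @param subIds substitution identifiers (length K).
#' @param dgwt named numeric, wild-type free energy per trait (kcal/mol),
#'   e.g. `c(folding = -2)`.
#' @param ddg K x traits matrix, or named list of length-K numeric vectors.
#' @param couplings npair x traits matrix / named list, or `NULL` for an
#'   additive model. Pair order is `combn(K, 2)` column order (i < j).
#' @param affine named list per phenotype of `c(a =, b =)`; default identity.
#' @param constants named numeric `c(R =, T =, c =)`.
#' @return An [EnergyModel-class] object.
#' @examples
#' m <- energyModel(c("P11A", "G18C"), dgwt = c(folding = -2),
#'                  ddg = list(folding = c(1.2, 0.4)))
#' @export
energyModel <- function(subIds, dgwt, ddg, couplings = NULL,
                        affine = NULL,
                        constants = c(R = GAS_CONSTANT, T = DEFAULT_TEMPERATURE,
                                      c = 1)) {
  traits <- names(dgwt)
  toMat <- function(x) {
    if (is.null(x)) return(matrix(numeric(), 0L, length(traits),
                                  dimnames = list(NULL, traits)))
    if (is.list(x)) x <- do.call(cbind, x)
    if (is.null(dim(x))) x <- matrix(x, dimnames = list(NULL, traits))
    as.matrix(x)[, traits, drop = FALSE]
  }
  ddg <- toMat(ddg); couplings <- toMat(couplings)
  K <- length(subIds)
  pairIds <- if (K >= 2L) {
    cmb <- utils::combn(K, 2L)
    paste(subIds[cmb[1L, ]], subIds[cmb[2L, ]], sep = ":")
  } else character()
  order <- if (nrow(couplings) > 0L) 2L else 1L
  if (order == 1L) pairIds <- character()
  if (is.null(affine)) {
    phen <- c(if ("folding" %in% traits) "abundance",
              if ("binding" %in% traits) "binding")
    affine <- stats::setNames(rep(list(c(a = 0, b = 1)), length(phen)), phen)
  }
  new("EnergyModel", traits = traits, order = order, subIds = subIds,
      dgwt = dgwt, ddg = ddg, couplings = couplings, pairIds = pairIds,
      affine = affine, constants = constants)
}

#' Training configuration for thermodynamic model fitting
#'
#' Collects every hyperparameter of the gradient-based fitting protocol.
#' Defaults follow the reference protocol: Adam with initial learning rate
#' 0.05, exponential decay gamma = 0.98 when the validation loss stalls over
#' ten epochs, at most 1000 epochs, batch size tuned over a grid by the
#' validation loss after 100 epochs, L2 penalty 1e-6, 70/20/10
#' train/validation/test split, ten Monte Carlo refits, and early stopping
#' when the wild-type free energies are stable (sd <= 1e-3 kcal/mol over ten
#' epochs).
#'
#' @slot maxInteractionOrder integer, 1 or 2.
#' @slot initialLr numeric, Adam initial learning rate.
#' @slot lrDecay numeric, exponential decay factor gamma.
#' @slot maxEpochs integer.
#' @slot hyperEpochs integer, epochs used for batch-size selection.
#' @slot batchSizeGrid integer vector of candidate batch sizes.
#' @slot lambda2 numeric, L2 regularization penalty.
#' @slot splitFractions numeric length 3 (train, validation, test), sums to 1.
#' @slot nMcModels integer, number of Monte Carlo refits.
#' @slot seed integer.
#' @slot earlyStopSd numeric, kcal/mol.
#' @slot resample logical, resample training fitness from its error
#'   distribution before fitting.
#' @slot ligandConc numeric, dimensionless ligand concentration.
#'
#' @exportClass FitConfig
setClass("FitConfig",
  representation(maxInteractionOrder = "integer", initialLr = "numeric",
                 lrDecay = "numeric", maxEpochs = "integer",
                 hyperEpochs = "integer", batchSizeGrid = "integer",
                 lambda2 = "numeric", splitFractions = "numeric",
                 nMcModels = "integer", seed = "integer",
                 earlyStopSd = "numeric", resample = "logical",
                 ligandConc = "numeric"))

setValidity("FitConfig", function(object) {
  msg <- character()
  if (!object@maxInteractionOrder %in% c(1L, 2L))
    msg <- c(msg, "maxInteractionOrder must be 1 or 2")
  if (abs(sum(object@splitFractions) - 1) > 1e-8)
    msg <- c(msg, "splitFractions must sum to 1")
  if (any(c(object@initialLr, object@lrDecay, object@earlyStopSd) <= 0) ||
      object@lambda2 < 0)
    msg <- c(msg, "learning rate, decay and tolerances must be positive")
  if (object@ligandConc <= 0) msg <- c(msg, "ligand concentration must be > 0")
  if (length(msg)) msg else TRUE
})

#' Construct a FitConfig
#'
#' @param maxInteractionOrder 1 for an additive model, 2 to add pairwise
#'   energetic couplings.
#' @param initialLr Adam initial learning rate (0.05 default; 0.005 is the
#'   conservative alternative for very large libraries).
#' @param lrDecay exponential learning-rate decay factor.
#' @param maxEpochs,hyperEpochs maximum training epochs, and epochs used
#'   when selecting the batch size.
#' @param batchSizeGrid candidate batch sizes; a length-1 grid skips tuning.
#' @param lambda2 L2 regularization penalty on model parameters.
#' @param splitFractions train/validation/test fractions.
#' @param nMcModels number of Monte Carlo refits for uncertainty estimates.
#' @param seed integer seed controlling splits, resampling and initialization.
#' @param earlyStopSd early-stopping threshold on the sd of the wild-type
#'   free energies over the last ten epochs (kcal/mol).
#' @param resample resample training fitness from per-variant errors.
#' @param ligandConc dimensionless ligand concentration.
#' @return A [FitConfig-class] object.
#' @export
fitConfig <- function(maxInteractionOrder = 1L, initialLr = 0.05,
                      lrDecay = 0.98, maxEpochs = 1000L, hyperEpochs = 100L,
                      batchSizeGrid = c(512L, 1024L, 2048L), lambda2 = 1e-6,
                      splitFractions = c(0.7, 0.2, 0.1), nMcModels = 10L,
                      seed = 1L, earlyStopSd = 1e-3, resample = TRUE,
                      ligandConc = 1) {
  new("FitConfig", maxInteractionOrder = as.integer(maxInteractionOrder),
      initialLr = initialLr, lrDecay = lrDecay,
      maxEpochs = as.integer(maxEpochs), hyperEpochs = as.integer(hyperEpochs),
      batchSizeGrid = as.integer(batchSizeGrid), lambda2 = lambda2,
      splitFractions = splitFractions, nMcModels = as.integer(nMcModels),
      seed = as.integer(seed), earlyStopSd = earlyStopSd, resample = resample,
      ligandConc = ligandConc)
}

#' Result of fitting a thermodynamic model
#'
#' @slot model the fitted [EnergyModel-class] (energies in kcal/mol,
#'   canonicalized).
#' @slot history `data.frame` with per-epoch training loss, validation loss
#'   and learning rate.
#' @slot split factor of `"train"/"validation"/"test"` per variant.
#' @slot r2 named numeric, held-out (test) R^2 per phenotype.
#' @slot config the [FitConfig-class] used.
#' @slot batchSize integer, selected batch size.
#'
#' @exportClass FitResult
setClass("FitResult",
  representation(model = "EnergyModel", history = "data.frame",
                 split = "factor", r2 = "numeric", config = "FitConfig",
                 batchSize = "integer"))

setValidity("FitResult", function(object) {
  if (nrow(object@history) == 0L) return("training history must be non-empty")
  if (!all(levels(object@split) %in% c("train", "validation", "test")))
    return("split labels must be train/validation/test")
  TRUE
})

#' Ground-truth specification for the synthetic-data generator
#'
#' Describes the distributions from which a ground-truth [EnergyModel-class]
#' is drawn. Defaults encode the qualitative regime of real combinatorial
#' stability data: first-order folding ddG values biased towards
#' destabilization (Normal(+1, 1) kcal/mol), sparse zero-centred pairwise
#' couplings (Normal(0, 0.25), 25% of pairs nonzero), and milder
#' destabilization-biased binding effects (Normal(+0.5, 0.5)).
#'
#' @slot K integer, number of substitutions (>= 2).
#' @slot ddgF numeric `c(location, scale)` for folding ddG draws (kcal/mol).
#' @slot couplingScale numeric, sd of nonzero couplings (kcal/mol).
#' @slot couplingSparsity numeric in `[0, 1]`, fraction of nonzero pairs.
#' @slot binding logical, include the binding trait.
#' @slot ddgB numeric `c(location, scale)` for binding ddG draws.
#' @slot dgwtF,dgwtB numeric, wild-type free energies (kcal/mol).
#' @slot affine named list per phenotype of `c(a =, b =)`.
#' @slot sigma0 numeric > 0, noise floor (fitness units).
#' @slot sigma1 numeric >= 0, heteroscedastic slope: replicate sd is
#'   `sigma0 + sigma1 * (0.5 - |p - 0.5|)`, largest mid-range where a
#'   bounded growth assay is least certain.
#' @slot seed integer.
#'
#' @exportClass TruthSpec
setClass("TruthSpec",
  representation(K = "integer", ddgF = "numeric", couplingScale = "numeric",
                 couplingSparsity = "numeric", binding = "logical",
                 ddgB = "numeric", dgwtF = "numeric", dgwtB = "numeric",
                 affine = "list", sigma0 = "numeric", sigma1 = "numeric",
                 seed = "integer"))

setValidity("TruthSpec", function(object) {
  msg <- character()
  if (object@K < 2L) msg <- c(msg, "K must be >= 2")
  if (object@couplingSparsity < 0 || object@couplingSparsity > 1)
    msg <- c(msg, "couplingSparsity must lie in [0, 1]")
  if (object@sigma0 <= 0) msg <- c(msg, "sigma0 must be > 0")
  if (object@sigma1 < 0) msg <- c(msg, "sigma1 must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a TruthSpec
#'
#' @param K number of substitutions.
#' @param ddgF location and scale of folding ddG draws (kcal/mol).
#' @param couplingScale sd of nonzero pairwise couplings (kcal/mol).
#' @param couplingSparsity fraction of pairs with a nonzero coupling.
#' @param binding simulate the binding trait as well.
#' @param ddgB location and scale of binding ddG draws (kcal/mol).
#' @param dgwtF,dgwtB wild-type folding/binding free energies (kcal/mol).
#' @param affine per-phenotype affine transforms `c(a =, b =)`.
#' @param sigma0 replicate noise floor (fitness units).
#' @param sigma1 heteroscedastic noise slope (fitness units).
#' @param seed integer seed.
#' @return A [TruthSpec-class] object.
#' @export
truthSpec <- function(K, ddgF = c(1, 1), couplingScale = 0.25,
                      couplingSparsity = 0.25, binding = FALSE,
                      ddgB = c(0.5, 0.5), dgwtF = -2, dgwtB = -1,
                      affine = NULL, sigma0 = 0.05, sigma1 = 0, seed = 1L) {
  if (is.null(affine)) {
    phen <- c("abundance", if (binding) "binding")
    affine <- stats::setNames(rep(list(c(a = 0, b = 1)), length(phen)), phen)
  }
  new("TruthSpec", K = as.integer(K), ddgF = ddgF,
      couplingScale = couplingScale, couplingSparsity = couplingSparsity,
      binding = binding, ddgB = ddgB, dgwtF = dgwtF, dgwtB = dgwtB,
      affine = affine, sigma0 = sigma0, sigma1 = sigma1,
      seed = as.integer(seed))
}

#' Greedy library-design trajectory
#'
#' One trajectory of the greedy fold/function-preserving design: a starting
#' substitution and the ordered substitutions added at each step, with the
#' predicted phenotype growth rates of the cumulative mutant and, when
#' simulated, the per-size median growth rates and viability flag.
#'
#' @slot start character, starting substitution id.
#' @slot steps `data.frame`: `step`, `id`, `position`, objective and
#'   per-phenotype predicted values of the cumulative mutant; optionally
#'   per-size simulated medians and `viable`.
#'
#' @exportClass DesignTrajectory
setClass("DesignTrajectory",
  representation(start = "character", steps = "data.frame"))

setValidity("DesignTrajectory", function(object) {
  if (anyDuplicated(object@steps$position))
    return("trajectory positions must be distinct")
  TRUE
})

## ---- show methods -----------------------------------------------------

setMethod("show", "LibraryDefinition", function(object) {
  cat(sprintf("LibraryDefinition: %d substitutions over %d residues; phenotypes: %s\n",
              nrow(object@substitutions), nchar(object@wtAaSeq),
              paste(object@phenotypes, collapse = ", ")))
  cat("  ids:", paste(utils::head(object@substitutions$id, 8L), collapse = " "),
      if (nrow(object@substitutions) > 8L) "..." else "", "\n")
})

setMethod("show", "GenotypeTable", function(object) {
  cat(sprintf("GenotypeTable: %d variants x %d substitutions; phenotypes: %s\n",
              nrow(object@genotypes), ncol(object@genotypes),
              paste(object@phenotypes, collapse = ", ")))
  ord <- rowSums(object@genotypes)
  cat(sprintf("  mutant order: %d-%d (median %g)\n",
              min(ord), max(ord), stats::median(ord)))
})

setMethod("show", "EnergyModel", function(object) {
  cat(sprintf("EnergyModel (order %d): traits %s; K = %d substitutions%s\n",
              object@order, paste(object@traits, collapse = "+"),
              length(object@subIds),
              if (object@order == 2L)
                sprintf("; %d couplings", nrow(object@couplings)) else ""))
  cat(sprintf("  dG_wt: %s kcal/mol; RT = %.4f kcal/mol\n",
              paste(sprintf("%s=%.3f", names(object@dgwt), object@dgwt),
                    collapse = ", "),
              object@constants[["R"]] * object@constants[["T"]]))
})

setMethod("show", "FitResult", function(object) {
  cat(sprintf("FitResult: %d epochs; batch size %d; held-out R2: %s\n",
              nrow(object@history), object@batchSize,
              paste(sprintf("%s=%.3f", names(object@r2), object@r2),
                    collapse = ", ")))
})
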