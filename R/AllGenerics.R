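#' Accessors for thermodms classes
#'
#' Small accessor generics for the package's S4 containers: the binary
#' genotype matrix, per-variant mutant order (Hamming weight), fitness and
#' sigma matrices, substitution and pair identifiers, energy terms, affine
#' transforms and thermodynamic constants.
#'
#' @param x a [GenotypeTable-class], [EnergyModel-class],
#'   [LibraryDefinition-class] or [FitResult-class] object, as applicable.
#' @return The requested component (matrix, numeric vector, list or
#'   `data.frame`).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))
#' @rdname accessors
#' @export
setMethod("genotypes", "GenotypeTable", function(x) x@genotypes)

#' @rdname accessors
#' @export
setGeneric("mutantOrder", function(x) standardGeneric("mutantOrder"))
#' @rdname accessors
#' @export
setMethod("mutantOrder", "GenotypeTable",
          function(x) as.integer(rowSums(x@genotypes)))

#' @rdname accessors
#' @export
setGeneric("fitnessMatrix", function(x) standardGeneric("fitnessMatrix"))
#' @rdname accessors
#' @export
setMethod("fitnessMatrix", "GenotypeTable", function(x) x@fitness)

#' @rdname accessors
#' @export
setGeneric("sigmaMatrix", function(x) standardGeneric("sigmaMatrix"))
#' @rdname accessors
#' @export
setMethod("sigmaMatrix", "GenotypeTable", function(x) x@sigma)

#' @rdname accessors
#' @export
setGeneric("replicateValues", function(x) standardGeneric("replicateValues"))
#' @rdname accessors
#' @export
setMethod("replicateValues", "GenotypeTable", function(x) x@replicates)

#' @rdname accessors
#' @export
setGeneric("phenotypeNames", function(x) standardGeneric("phenotypeNames"))
#' @rdname accessors
#' @export
setMethod("phenotypeNames", "GenotypeTable", function(x) x@phenotypes)
#' @rdname accessors
#' @export
setMethod("phenotypeNames", "LibraryDefinition", function(x) x@phenotypes)

#' @rdname accessors
#' @export
setGeneric("substitutionIds", function(x) standardGeneric("substitutionIds"))
#' @rdname accessors
#' @export
setMethod("substitutionIds", "GenotypeTable", function(x) colnames(x@genotypes))
#' @rdname accessors
#' @export
setMethod("substitutionIds", "EnergyModel", function(x) x@subIds)
#' @rdname accessors
#' @export
setMethod("substitutionIds", "LibraryDefinition",
          function(x) x@substitutions$id)

#' @rdname accessors
#' @export
setGeneric("substitutionTable", function(x) standardGeneric("substitutionTable"))
#' @rdname accessors
#' @export
setMethod("substitutionTable", "LibraryDefinition", function(x) x@substitutions)

#' @rdname accessors
#' @export
setGeneric("wtAaSequence", function(x) standardGeneric("wtAaSequence"))
#' @rdname accessors
#' @export
setMethod("wtAaSequence", "LibraryDefinition", function(x) x@wtAaSeq)

#' @rdname accessors
#' @export
setGeneric("wtNtSequence", function(x) standardGeneric("wtNtSequence"))
#' @rdname accessors
#' @export
setMethod("wtNtSequence", "LibraryDefinition", function(x) x@wtNtSeq)

#' @rdname accessors
#' @export
setGeneric("modelTraits", function(x) standardGeneric("modelTraits"))
#' @rdname accessors
#' @export
setMethod("modelTraits", "EnergyModel", function(x) x@traits)

#' @rdname accessors
#' @export
setGeneric("wtEnergies", function(x) standardGeneric("wtEnergies"))
#' @rdname accessors
#' @export
setMethod("wtEnergies", "EnergyModel", function(x) x@dgwt)

#' @rdname accessors
#' @export
setGeneric("ddgTerms", function(x) standardGeneric("ddgTerms"))
#' @rdname accessors
#' @export
setMethod("ddgTerms", "EnergyModel", function(x) {
  m <- x@ddg; rownames(m) <- x@subIds; m
})

#' @rdname accessors
#' @export
setGeneric("couplingTerms", function(x) standardGeneric("couplingTerms"))
#' @rdname accessors
#' @export
setMethod("couplingTerms", "EnergyModel", function(x) {
  m <- x@couplings
  if (nrow(m)) rownames(m) <- x@pairIds
  m
})

#' @rdname accessors
#' @export
setGeneric("pairIds", function(x) standardGeneric("pairIds"))
#' @rdname accessors
#' @export
setMethod("pairIds", "EnergyModel", function(x) x@pairIds)

#' @rdname accessors
#' @export
setGeneric("affineParams", function(x) standardGeneric("affineParams"))
#' @rdname accessors
#' @export
setMethod("affineParams", "EnergyModel", function(x) x@affine)

#' @rdname accessors
#' @export
setGeneric("modelConstants", function(x) standardGeneric("modelConstants"))
#' @rdname accessors
#' @export
setMethod("modelConstants", "EnergyModel", function(x) x@constants)

#' @rdname accessors
#' @export
setGeneric("fittedModel", function(x) standardGeneric("fittedModel"))
#' @rdname accessors
#' @export
setMethod("fittedModel", "FitResult", function(x) x@model)

#' @rdname accessors
#' @export
setGeneric("trainingHistory", function(x) standardGeneric("trainingHistory"))
#' @rdname accessors
#' @export
setMethod("trainingHistory", "FitResult", function(x) x@history)

#' @rdname accessors
#' @export
setGeneric("splitAssignment", function(x) standardGeneric("splitAssignment"))
#' @rdname accessors
#' @export
setMethod("splitAssignment", "FitResult", function(x) x@split)

#' @rdname accessors
#' @export
setGeneric("heldOutR2", function(x) standardGeneric("heldOutR2"))
#' @rdname accessors
#' @export
setMethod("heldOutR2", "FitResult", function(x) x@r2)
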