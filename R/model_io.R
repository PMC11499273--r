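#' Write / read an energy model as structured JSON
#'
#' Serializes an [EnergyModel-class] to a JSON file: traits, coefficient
#' tables keyed by substitution id and id pair, affine transforms,
#' thermodynamic constants and the package version. `readEnergyModel()`
#' inverts it exactly.
#'
#' @param model an [EnergyModel-class].
#' @param path file path.
#' @param config optional [FitConfig-class] echoed into the file.
#' @return `writeEnergyModel`: invisibly, `path`; `readEnergyModel`: the
#'   [EnergyModel-class].
#' @export
writeEnergyModel <- function(model, path, config = NULL) {
  obj <- list(
    format = "thermodms-energy-model",
    version = as.character(utils::packageVersion("thermodms")),
    traits = modelTraits(model),
    order = model@order,
    substitutions = substitutionIds(model),
    dg_wt = as.list(wtEnergies(model)),
    ddg = stats::setNames(
      lapply(seq_along(substitutionIds(model)),
             function(i) as.list(model@ddg[i, , drop = TRUE])),
      substitutionIds(model)),
    couplings = if (model@order == 2L) stats::setNames(
      lapply(seq_along(pairIds(model)),
             function(i) as.list(model@couplings[i, , drop = TRUE])),
      pairIds(model)) else NULL,
    affine = lapply(affineParams(model), as.list),
    constants = as.list(modelConstants(model)))
  if (!is.null(config))
    obj$config <- list(maxInteractionOrder = config@maxInteractionOrder,
                       initialLr = config@initialLr, lrDecay = config@lrDecay,
                       maxEpochs = config@maxEpochs,
                       batchSizeGrid = config@batchSizeGrid,
                       lambda2 = config@lambda2,
                       splitFractions = config@splitFractions,
                       nMcModels = config@nMcModels, seed = config@seed,
                       earlyStopSd = config@earlyStopSd,
                       resample = config@resample,
                       ligandConc = config@ligandConc)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname writeEnergyModel
#' @export
readEnergyModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(obj$format, "thermodms-energy-model"))
    stop("not a thermodms energy-model file: ", path)
  traits <- unlist(obj$traits)
  subIds <- unlist(obj$substitutions)
  pick <- function(lst) {
    m <- matrix(0, length(lst), length(traits),
                dimnames = list(NULL, traits))
    for (i in seq_along(lst)) m[i, ] <- unlist(lst[[i]])[traits]
    m
  }
  ddg <- pick(obj$ddg)
  coup <- if (!is.null(obj$couplings) && length(obj$couplings))
    pick(obj$couplings) else NULL
  energyModel(subIds,
              dgwt = unlist(obj$dg_wt)[traits],
              ddg = ddg, couplings = coup,
              affine = lapply(obj$affine, function(x)
                c(a = x$a, b = x$b)),
              constants = unlist(obj$constants)[c("R", "T", "c")])
}
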