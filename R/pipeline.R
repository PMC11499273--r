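## config handling: a run config is a named list; file form is YAML.
## CLI/arg overrides take precedence over file values.
loadRunConfig <- function(config = list(), overrides = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  utils::modifyList(config, overrides)
}

cfgGet <- function(config, key, default) {
  if (!is.null(config[[key]])) config[[key]] else default
}

fitConfigFromList <- function(config, seed) {
  fitConfig(
    maxInteractionOrder = cfgGet(config, "max_interaction_order", 1L),
    initialLr = cfgGet(config, "initial_lr", 0.05),
    lrDecay = cfgGet(config, "lr_decay", 0.98),
    maxEpochs = cfgGet(config, "max_epochs", 1000L),
    hyperEpochs = cfgGet(config, "hyperparameter_epochs", 100L),
    batchSizeGrid = cfgGet(config, "batch_size_grid", c(512L, 1024L, 2048L)),
    lambda2 = cfgGet(config, "lambda2", 1e-6),
    splitFractions = cfgGet(config, "split_fractions", c(0.7, 0.2, 0.1)),
    nMcModels = cfgGet(config, "n_mc_models", 10L),
    seed = seed,
    earlyStopSd = cfgGet(config, "early_stop_sd", 1e-3),
    resample = cfgGet(config, "resample", TRUE),
    ligandConc = cfgGet(config, "ligand_concentration", 1))
}

writeManifest <- function(outDir, subcommand, config, seed, artifacts,
                          extra = list(), t0) {
  manifest <- c(list(
    subcommand = subcommand,
    seed = seed,
    version = as.character(utils::packageVersion("thermodms")),
    config = config,
    artifacts = artifacts,
    wall_time_s = round(as.numeric(Sys.time()) - t0, 3)), extra)
  path <- file.path(outDir, paste0(subcommand, "_manifest.json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  path
}

#' Run a pipeline stage
#'
#' End-to-end orchestration of the analysis: `simulate` (ground-truth model
#' + variant table), `fit` (thermodynamic model), `uncertainty` (Monte
#' Carlo confidence intervals), `design` (greedy fold/function-preserving
#' library design), `features` (structural pair-feature table) and
#' `couplings-report` (coupling strength vs distance statistics and the
#' folding-vs-binding comparison). Every stochastic stage derives its seed
#' deterministically from the global `seed`; each stage writes its
#' artifacts plus a JSON run manifest (inputs, seeds, package version, wall
#' time) into `outDir`, and consumes only user inputs or files produced by
#' earlier stages.
#'
#' @param subcommand one of `"simulate"`, `"fit"`, `"uncertainty"`,
#'   `"design"`, `"features"`, `"couplings-report"`.
#' @param config named list of options or path to a YAML file; entries are
#'   stage-specific (see the pipeline vignette). `overrides` (e.g. from
#'   command-line flags) take precedence over file values.
#' @param seed global integer seed.
#' @param outDir output directory (created if needed).
#' @param overrides named list overriding `config` entries.
#' @param quiet suppress progress messages.
#' @return Invisibly, a list with the written artifact paths and the
#'   manifest path.
#' @export
runPipeline <- function(subcommand = c("simulate", "fit", "uncertainty",
                                       "design", "features",
                                       "couplings-report"),
                        config = list(), seed = 1L, outDir = ".",
                        overrides = list(), quiet = FALSE) {
  subcommand <- match.arg(subcommand)
  config <- loadRunConfig(config, overrides)
  seed <- as.integer(seed)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  t0 <- as.numeric(Sys.time())
  say <- function(...) if (!quiet) message("[", subcommand, "] ", ...)
  artifacts <- character(0)

  if (subcommand == "simulate") {
    spec <- truthSpec(
      K = cfgGet(config, "K", 10L),
      ddgF = cfgGet(config, "ddg_f", c(1, 1)),
      couplingScale = cfgGet(config, "coupling_scale", 0.25),
      couplingSparsity = cfgGet(config, "coupling_sparsity", 0.25),
      binding = cfgGet(config, "binding", FALSE),
      ddgB = cfgGet(config, "ddg_b", c(0.5, 0.5)),
      dgwtF = cfgGet(config, "dg_wt_f", -2),
      dgwtB = cfgGet(config, "dg_wt_b", -1),
      sigma0 = cfgGet(config, "sigma0", 0.05),
      sigma1 = cfgGet(config, "sigma1", 0),
      seed = deriveSeed(seed, "truth"))
    n <- cfgGet(config, "n", 20000L)
    sim <- simulateDataset(spec, n = n,
                           scheme = cfgGet(config, "scheme", "uniform_space"),
                           replicates = cfgGet(config, "replicates", 3L),
                           replace = n > 2^spec@K)
    subs <- substitutionIds(sim$truth)
    lib <- syntheticLibrary(spec@K, subs,
                            phenotypes = names(affineParams(sim$truth)))
    tabPath <- file.path(outDir, "variants.tsv")
    writeVariantTable(sim$table, tabPath)
    truthPath <- file.path(outDir, "truth_model.json")
    writeEnergyModel(sim$truth, truthPath)
    libPath <- file.path(outDir, "library.json")
    jsonlite::write_json(list(wt_aa_seq = wtAaSequence(lib),
                              substitutions = substitutionTable(lib),
                              phenotypes = phenotypeNames(lib)),
                         libPath, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    artifacts <- c(tabPath, truthPath, libPath)
    say(nrow(genotypes(sim$table)), " unique variants written")
  } else if (subcommand %in% c("fit", "uncertainty")) {
    libInfo <- jsonlite::read_json(cfgGet(config, "library",
                                          file.path(outDir, "library.json")),
                                   simplifyVector = TRUE)
    lib <- libraryDefinition(libInfo$wt_aa_seq,
                             as.data.frame(libInfo$substitutions),
                             phenotypes = libInfo$phenotypes)
    tab <- readVariantTable(cfgGet(config, "variants",
                                   file.path(outDir, "variants.tsv")), lib)
    fcfg <- fitConfigFromList(config, deriveSeed(seed, subcommand))
    if (subcommand == "fit") {
      res <- fitEnergyModel(tab, lib, fcfg)
      modelPath <- file.path(outDir, "fitted_model.json")
      writeEnergyModel(fittedModel(res), modelPath, config = fcfg)
      histPath <- file.path(outDir, "training_history.tsv")
      utils::write.table(trainingHistory(res), histPath, sep = "\t",
                         quote = FALSE, row.names = FALSE)
      artifacts <- c(modelPath, histPath)
      say("held-out R2: ",
          paste(sprintf("%s=%.3f", names(heldOutR2(res)), heldOutR2(res)),
                collapse = ", "))
      return(invisible(list(
        artifacts = artifacts, result = res,
        manifest = writeManifest(outDir, subcommand, config, seed, artifacts,
                                 list(r2 = as.list(heldOutR2(res)),
                                      inputs = list(
                                        variants = cfgGet(config, "variants",
                                          file.path(outDir, "variants.tsv")))),
                                 t0))))
    }
    mc <- monteCarloUncertainty(tab, lib, fcfg)
    coefPath <- file.path(outDir, "coefficients.tsv")
    exportCoefficients(mc, coefPath)
    artifacts <- coefPath
    say(sum(mc$confident), "/", nrow(mc), " coefficients confident")
  } else if (subcommand == "design") {
    effects <- readEffectTable(cfgGet(config, "effects",
                                      file.path(outDir, "effects.tsv")))
    model <- readEnergyModel(cfgGet(config, "model",
                                    file.path(outDir, "fitted_model.json")))
    cand <- filterCandidates(effects,
                             wt_nt_seq = cfgGet(config, "wt_nt_seq", NULL),
                             traits = modelTraits(model),
                             ciMax = cfgGet(config, "ci_max", 1),
                             minBackgrounds = cfgGet(config,
                                                     "min_backgrounds", 20L))
    trajs <- designLibrary(cand, model,
                           n = cfgGet(config, "n_sim", 10000L),
                           seed = deriveSeed(seed, "design"),
                           threshold = cfgGet(config, "threshold", 0.7),
                           maximal = cfgGet(config, "maximal", "wildtype"))
    trajTab <- do.call(rbind, lapply(trajs, function(tr)
      cbind(start = tr@start, tr@steps)))
    trajPath <- file.path(outDir, "trajectories.tsv")
    utils::write.table(trajTab, trajPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    chosen <- selectLargestViable(trajs)
    chosenPath <- file.path(outDir, "chosen_library.txt")
    writeLines(chosen, chosenPath)
    artifacts <- c(trajPath, chosenPath)
    say("largest viable library: ", length(chosen), " substitutions")
  } else if (subcommand == "features") {
    struct <- readStructure(config$structure,
                            chain = cfgGet(config, "chain", NULL),
                            offset = cfgGet(config, "offset", 0L))
    ann <- readResidueAnnotations(config$annotations)
    contacts <- if (!is.null(config$contacts))
      readContactsFile(config$contacts,
                       offset = cfgGet(config, "offset", 0L)) else NULL
    coup <- utils::read.delim(config$couplings, stringsAsFactors = FALSE)
    feat <- buildPairFeatures(coup, ann, struct, contacts)
    featPath <- file.path(outDir, "pair_features.tsv")
    utils::write.table(feat, featPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    artifacts <- featPath
    say(nrow(feat), " residue pairs featurized")
  } else if (subcommand == "couplings-report") {
    feat <- utils::read.delim(cfgGet(config, "features",
                                     file.path(outDir, "pair_features.tsv")),
                              stringsAsFactors = FALSE)
    stats_ <- couplingDistanceStats(
      feat,
      backboneCutoff = cfgGet(config, "backbone_cutoff", 5L),
      contactMax = cfgGet(config, "contact_max", 5))
    rhoPath <- file.path(outDir, "coupling_distance_rho.tsv")
    utils::write.table(data.frame(statistic = names(stats_$rho),
                                  spearman_rho = stats_$rho),
                       rhoPath, sep = "\t", quote = FALSE, row.names = FALSE)
    binPath <- file.path(outDir, "coupling_distance_binned.tsv")
    utils::write.table(stats_$binned, binPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    artifacts <- c(rhoPath, binPath)
    say("Spearman rho (all couplings vs 3D distance): ",
        round(stats_$rho[["scha_all"]], 3))
  }

  manifest <- writeManifest(outDir, subcommand, config, seed, artifacts,
                            t0 = t0)
  invisible(list(artifacts = artifacts, manifest = manifest))
}

## synthetic wild-type sequence/library over generated substitution ids
syntheticLibrary <- function(K, subIds, phenotypes = "abundance") {
  wt <- paste(rep("A", K), collapse = "")
  libraryDefinition(wt,
                    data.frame(id = subIds, position = seq_len(K),
                               wt_aa = "A", mut_aa = "V",
                               stringsAsFactors = FALSE),
                    phenotypes = phenotypes)
}
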