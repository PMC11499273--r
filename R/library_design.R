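#' Filter candidate substitutions for combinatorial library design
#'
#' Keeps substitutions whose inferred free energy changes are confident
#' (95% confidence interval < 1 kcal/mol on every trait in use), that were
#' measured in at least `minBackgrounds` genetic backgrounds, and that are
#' reachable by a single-nucleotide change in the wild-type coding
#' sequence.
#'
#' @param effects substitution-effect `data.frame` (columns `id`,
#'   `position`, `wt_aa`, `mut_aa`, `ci95_f`, `n_backgrounds`, and
#'   `ci95_b` when binding is used).
#' @param wt_nt_seq wild-type coding sequence; `NULL` skips the
#'   reachability filter (e.g. when `effects` already carries
#'   `nt_reachable`).
#' @param traits traits whose confidence intervals are enforced.
#' @param ciMax confidence-interval threshold (kcal/mol, strict <).
#' @param minBackgrounds minimum background count (inclusive).
#' @param code genetic-code table.
#' @return The filtered `data.frame`.
#' @export
filterCandidates <- function(effects, wt_nt_seq = NULL,
                             traits = c("folding", "binding"), ciMax = 1,
                             minBackgrounds = 20L, code = geneticCode()) {
  ciCols <- c(folding = "ci95_f", binding = "ci95_b")[traits]
  ciCols <- ciCols[!is.na(ciCols)]
  miss <- setdiff(ciCols, names(effects))
  if (length(miss))
    stop("missing confidence-interval column(s): ",
         paste(miss, collapse = ", "))
  keep <- rep(TRUE, nrow(effects))
  for (cc in ciCols) keep <- keep & !is.na(effects[[cc]]) &
    effects[[cc]] < ciMax
  keep <- keep & effects$n_backgrounds >= minBackgrounds
  if (!is.null(wt_nt_seq)) {
    effects <- annotateReachability(effects, wt_nt_seq, code)
  } else if (is.null(effects$nt_reachable)) {
    stop("supply wt_nt_seq or an nt_reachable column")
  }
  keep <- keep & effects$nt_reachable
  effects[keep, , drop = FALSE]
}

## deterministic candidate ordering used for every tie-break:
## lowest position first, then alphabetical mutant amino acid
tieBreakOrder <- function(cand) order(cand$position, cand$mut_aa)

#' Greedy design of a fold/function-preserving combinatorial library
#'
#' Starting from one substitution, iteratively adds the substitution (at a
#' not-yet-mutated position) that maximizes the objective of the cumulative
#' highest-order mutant: the geometric mean of the model-predicted growth
#' rates over the declared phenotypes (a single phenotype reduces to that
#' growth rate alone). Predicted growth rates are clamped at 1e-6 before
#' the geometric mean. Ties are broken by lowest position, then
#' alphabetical mutant amino acid. Repeating the procedure over all
#' possible starting substitutions is the caller's loop (see
#' [designLibrary()]).
#'
#' @param start substitution id to start from.
#' @param candidates filtered candidate `data.frame` (must contain
#'   `start`); several candidates may share a position, in which case each
#'   is considered and the argmax taken over all.
#' @param model additive [EnergyModel-class] over the candidate ids.
#' @param phenotypes phenotypes entering the objective (default: the
#'   model's).
#' @return A [DesignTrajectory-class].
#' @export
greedyDesign <- function(start, candidates, model, phenotypes = NULL) {
  if (nrow(candidates) == 0L) stop("empty candidate set")
  if (is.null(phenotypes)) phenotypes <- names(affineParams(model))
  candidates <- candidates[tieBreakOrder(candidates), , drop = FALSE]
  if (!start %in% candidates$id) stop("start not among candidates: ", start)
  ids <- substitutionIds(model)
  if (!all(candidates$id %in% ids))
    stop("candidates missing from model: ",
         paste(setdiff(candidates$id, ids), collapse = ", "))

  objective <- function(sel) {
    g <- matrix(0, 1L, length(ids), dimnames = list(NULL, ids))
    g[1L, match(sel, ids)] <- 1
    vapply(phenotypes, function(ph) predictFitness(model, g, ph), 0)
  }

  startRow <- candidates[candidates$id == start, , drop = FALSE][1L, ]
  sel <- start
  preds <- objective(sel)
  steps <- data.frame(step = 0L, id = start, position = startRow$position,
                      objective = geomMean(preds))
  for (ph in phenotypes) steps[[paste0("pred_", ph)]] <- preds[[ph]]

  repeat {
    open <- candidates[!candidates$position %in% steps$position, ,
                       drop = FALSE]
    if (nrow(open) == 0L) break
    objs <- vapply(seq_len(nrow(open)), function(i)
      geomMean(objective(c(sel, open$id[i]))), 0)
    best <- which(objs == max(objs))[1L]  # rows already in tie-break order
    sel <- c(sel, open$id[best])
    preds <- objective(sel)
    row <- data.frame(step = nrow(steps), id = open$id[best],
                      position = open$position[best],
                      objective = geomMean(preds))
    for (ph in phenotypes) row[[paste0("pred_", ph)]] <- preds[[ph]]
    steps <- rbind(steps, row)
  }
  new("DesignTrajectory", start = start, steps = steps)
}

#' Simulate median growth rates of a candidate combinatorial library
#'
#' Samples `n` genotypes uniformly from the 2^m combinations of a mutation
#' set (exhaustively when 2^m <= n) and returns the per-phenotype median of
#' the model-predicted growth rates.
#'
#' @param mutationSet character vector of substitution ids.
#' @param model an [EnergyModel-class] covering the ids.
#' @param n sample size (default 10,000).
#' @param seed integer seed.
#' @param phenotypes phenotypes to simulate (default: the model's).
#' @return Named numeric of per-phenotype median predicted growth rates.
#' @export
simulateLibraryGrowth <- function(mutationSet, model, n = 10000L, seed = 1L,
                                  phenotypes = NULL) {
  if (is.null(phenotypes)) phenotypes <- names(affineParams(model))
  ids <- substitutionIds(model)
  m <- length(mutationSet)
  sub <- if (m == 0L) {
    matrix(0, 1L, 0L)
  } else if (2^m <= n) {
    sampleGenotypeLibrary(m, scheme = "exhaustive", subIds = mutationSet)
  } else {
    sampleGenotypeLibrary(m, n, scheme = "uniform_space", seed = seed,
                          subIds = mutationSet, replace = TRUE)
  }
  g <- matrix(0, nrow(sub), length(ids), dimnames = list(NULL, ids))
  if (m > 0L) g[, match(mutationSet, ids)] <- sub
  vapply(phenotypes, function(ph)
    stats::median(predictFitness(model, g, ph)), 0)
}

#' Run the greedy design over all starting substitutions
#'
#' Calls [greedyDesign()] once per candidate start and attaches per-size
#' simulated median growth rates and viability flags to each trajectory.
#'
#' @param candidates filtered candidate `data.frame`.
#' @param model additive [EnergyModel-class].
#' @param n variants sampled per library simulation.
#' @param seed integer seed.
#' @param phenotypes phenotypes entering objective and viability.
#' @param threshold viability threshold (fraction of the maximal value).
#' @param maximal `"wildtype"` (geometric mean of the wild-type-predicted
#'   growth rates) or `"max"` (maximum over all simulated sizes and
#'   starts).
#' @return List of [DesignTrajectory-class] objects, one per start.
#' @export
designLibrary <- function(candidates, model, n = 10000L, seed = 1L,
                          phenotypes = NULL, threshold = 0.7,
                          maximal = c("wildtype", "max")) {
  maximal <- match.arg(maximal)
  if (is.null(phenotypes)) phenotypes <- names(affineParams(model))
  candidates <- candidates[tieBreakOrder(candidates), , drop = FALSE]
  trajs <- lapply(candidates$id, greedyDesign, candidates = candidates,
                  model = model, phenotypes = phenotypes)
  for (ti in seq_along(trajs)) {
    steps <- trajs[[ti]]@steps
    med <- matrix(NA_real_, nrow(steps), length(phenotypes),
                  dimnames = list(NULL, paste0("median_", phenotypes)))
    for (s in seq_len(nrow(steps)))
      med[s, ] <- simulateLibraryGrowth(steps$id[seq_len(s)], model, n,
                                        deriveSeed(seed, "libsim",
                                                   ti * 1000L + s),
                                        phenotypes)
    steps <- cbind(steps, med)
    steps$sim_objective <- apply(med, 1L, geomMean)
    trajs[[ti]]@steps <- steps
  }
  maxVal <- if (maximal == "wildtype") {
    geomMean(vapply(phenotypes, function(ph)
      simulateLibraryGrowth(character(), model, n, seed, ph), 0))
  } else {
    max(vapply(trajs, function(tr) max(tr@steps$sim_objective), 0))
  }
  for (ti in seq_along(trajs)) {
    trajs[[ti]]@steps$viable <-
      trajs[[ti]]@steps$sim_objective >= threshold * maxVal
  }
  attr(trajs, "maximalValue") <- maxVal
  trajs
}

#' Select the largest viable combinatorial library
#'
#' A library of size m along a trajectory is viable when the geometric mean
#' of its simulated median growth rates is at least `threshold` (default
#' 70%) of the maximal value. Returns the mutation set of the largest
#' viable size over all trajectories; ties go to the trajectory whose start
#' comes first in the deterministic candidate order.
#'
#' @param trajectories output of [designLibrary()] (steps must carry
#'   `sim_objective` and `viable`).
#' @param threshold viability threshold; only used to recompute flags if
#'   absent.
#' @return Character vector of substitution ids (the chosen library), with
#'   attributes `start` and `size`.
#' @export
selectLargestViable <- function(trajectories, threshold = 0.7) {
  best <- NULL; bestSize <- -1L
  for (tr in trajectories) {
    steps <- tr@steps
    if (is.null(steps$viable))
      stop("trajectories lack viability flags; run designLibrary()")
    viable <- which(steps$viable)
    if (!length(viable)) next
    size <- max(viable)  # library size = number of substitutions
    if (size > bestSize) { bestSize <- size; best <- tr }
  }
  if (is.null(best)) stop("no viable library at any size")
  ids <- best@steps$id[seq_len(bestSize)]
  structure(ids, start = best@start, size = bestSize)
}

#' Sliding-window candidate counting for window-constrained designs
#'
#' For the window-and-saturation style designs: flags positions whose
#' substitutions have mild effects (|fitness - wild type| within a band),
#' are nucleotide-reachable and avoid binding-interface residues (ligand
#' distance below a cutoff), then counts flagged positions in every
#' sliding window of the requested widths.
#'
#' @param effects substitution-effect `data.frame` with a per-substitution
#'   `fitness` column (or precomputed logical `candidate` column).
#' @param protLength protein length (residues).
#' @param widths window widths (default `c(20, 21, 22)`).
#' @param wtFitness wild-type fitness.
#' @param fitnessBand half-width of the mild-effect band in fitness units
#'   (e.g. one-third of the interquartile range).
#' @param ligandDistance optional named numeric of per-position minimal
#'   side-chain heavy-atom distances to the ligand.
#' @param interfaceMax interface exclusion cutoff (strict <) in Angstrom.
#' @param requiredCount report only windows attaining this many candidate
#'   positions (default: report all).
#' @return `data.frame` with columns `width`, `start`, `end`,
#'   `n_candidates`.
#' @export
windowDesignFilter <- function(effects, protLength, widths = c(20L, 21L, 22L),
                               wtFitness = NULL, fitnessBand = NULL,
                               ligandDistance = NULL, interfaceMax = 5,
                               requiredCount = NULL) {
  if (max(widths) > protLength) stop("window longer than protein")
  if (is.null(effects$candidate)) {
    cand <- rep(TRUE, nrow(effects))
    if (!is.null(wtFitness) && !is.null(fitnessBand))
      cand <- cand & abs(effects$fitness - wtFitness) <= fitnessBand
    if (!is.null(effects$nt_reachable)) cand <- cand & effects$nt_reachable
    if (!is.null(ligandDistance))
      cand <- cand &
        !(ligandDistance[as.character(effects$position)] < interfaceMax)
    effects$candidate <- cand
  }
  flagged <- sort(unique(effects$position[effects$candidate]))
  out <- do.call(rbind, lapply(widths, function(w) {
    starts <- seq_len(protLength - w + 1L)
    data.frame(width = w, start = starts, end = starts + w - 1L,
               n_candidates = vapply(starts, function(s)
                 sum(flagged >= s & flagged <= s + w - 1L), 0L))
  }))
  if (!is.null(requiredCount))
    out <- out[out$n_candidates >= requiredCount, , drop = FALSE]
  rownames(out) <- NULL
  out
}
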