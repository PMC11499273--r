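## Backbone atom names; everything else heavy is side chain.
BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

## GetContacts interaction-type labels -> feature column names
CONTACT_TYPE_MAP <- c(
  hbbb = "hbond_bb_bb",   # backbone-backbone hydrogen bond
  hbsb = "hbond_sc_bb",   # side chain-backbone hydrogen bond
  hbss = "hbond_sc_sc",   # side chain-side chain hydrogen bond
  pc   = "pi_cation",
  ps   = "pi_stacking",
  sb   = "salt_bridge",
  vdw  = "van_der_waals")

PAIR_FEATURES <- c("backbone_distance", "scha_distance", "n_core",
                   "n_interface", "n_strand", unname(CONTACT_TYPE_MAP))

#' Read a protein structure (PDB)
#'
#' Thin wrapper around [bio3d::read.pdb()] keeping a single model and,
#' optionally, one chain. Residues are addressed by their `resno` plus an
#' optional explicit offset mapping structure numbering to domain-local
#' 1-based sequence positions.
#'
#' @param path PDB file path.
#' @param chain optional chain identifier.
#' @param offset integer added to sequence positions to obtain structure
#'   `resno` (structure resno = position + offset).
#' @return List with the `bio3d` pdb object, `chain` and `offset`.
#' @export
readStructure <- function(path, chain = NULL, offset = 0L) {
  pdb <- bio3d::read.pdb(path, multi = FALSE)
  atoms <- pdb$atom[pdb$atom$type %in% c("ATOM", "HETATM"), , drop = FALSE]
  if (!is.null(chain))
    atoms <- atoms[atoms$chain == chain, , drop = FALSE]
  list(atom = atoms, chain = chain, offset = as.integer(offset))
}

## heavy side-chain atom coordinates of one residue; glycine (or any
## residue with no side-chain heavy atoms) falls back to its CA, flagged
## via the "fallback" attribute
sidechainCoords <- function(struct, position) {
  resno <- position + struct$offset
  at <- struct$atom[struct$atom$resno == resno, , drop = FALSE]
  if (nrow(at) == 0L) stop("residue not found in structure: ", position)
  heavy <- at[!grepl("^H", at$elesy) & !at$elety %in% BACKBONE_ATOMS, ,
              drop = FALSE]
  fallback <- FALSE
  if (nrow(heavy) == 0L) {
    heavy <- at[at$elety == "CA", , drop = FALSE]
    fallback <- TRUE
    if (nrow(heavy) == 0L)
      stop("no side-chain heavy atoms and no CA for residue ", position)
  }
  structure(cbind(heavy$x, heavy$y, heavy$z), fallback = fallback)
}

#' Minimal side-chain heavy-atom distance between two residues
#'
#' Minimum Euclidean distance over all pairs of side-chain heavy atoms of
#' the two residues. Glycine carries no side-chain heavy atoms and falls
#' back to its C-alpha (flagged in the `"fallback"` attribute).
#'
#' @param struct output of [readStructure()].
#' @param res_i,res_j 1-based sequence positions.
#' @return Distance in Angstrom (attribute `"fallback"` marks CA
#'   fallback).
#' @export
minSidechainDistance <- function(struct, res_i, res_j) {
  a <- sidechainCoords(struct, res_i)
  b <- sidechainCoords(struct, res_j)
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  structure(sqrt(max(min(d2), 0)),
            fallback = attr(a, "fallback") || attr(b, "fallback"))
}

#' Residue-residue contact map
#'
#' Boolean symmetric matrix of residue pairs whose minimal side-chain
#' heavy-atom distance is below a threshold (default 8 Angstrom), diagonal
#' excluded, plus a long-range mask for pairs distal in the primary
#' sequence (backbone distance strictly greater than `backboneCutoff`,
#' default 5 residues).
#'
#' @param struct output of [readStructure()].
#' @param positions 1-based sequence positions to include.
#' @param threshold contact threshold in Angstrom (strict <).
#' @param backboneCutoff long-range backbone-distance cutoff (strict >).
#' @return List with `contacts` and `longRange` logical matrices and the
#'   numeric `distance` matrix.
#' @export
contactMap <- function(struct, positions, threshold = 8,
                       backboneCutoff = 5L) {
  if (threshold <= 0) stop("threshold must be positive")
  n <- length(positions)
  d <- matrix(0, n, n, dimnames = list(positions, positions))
  for (i in seq_len(n)) for (j in seq_len(n)) if (j > i)
    d[i, j] <- d[j, i] <- minSidechainDistance(struct, positions[i],
                                               positions[j])
  contacts <- d < threshold
  diag(contacts) <- FALSE
  bb <- abs(outer(positions, positions, "-"))
  list(contacts = contacts, longRange = bb > backboneCutoff, distance = d)
}

#' Read per-residue structural annotations
#'
#' Tab-separated file with columns `position`, `rsasa` (fraction in
#' `[0, 1]`), `ss` (secondary-structure label: `strand`, `helix`, `loop`)
#' and `ligand_distance` (minimal side-chain heavy-atom distance to the
#' ligand, Angstrom).
#'
#' @param path file path.
#' @return Annotation `data.frame`.
#' @export
readResidueAnnotations <- function(path) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("position", "rsasa", "ss", "ligand_distance")
  miss <- setdiff(need, names(ann))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (any(ann$rsasa < 0 | ann$rsasa > 1)) stop("rsasa must lie in [0, 1]")
  if (any(ann$ligand_distance < 0)) stop("distances must be >= 0")
  ann
}

#' Read a GetContacts-style contacts table
#'
#' Tab-separated with columns frame, interaction type and two atom
#' identifiers `chain:resname:resid:atomname` (comment lines starting with
#' `#` are skipped). Interaction types are mapped to the package's seven
#' bond-count features via a fixed dictionary (`hbbb`, `hbsb`, `hbss`,
#' `pc`, `ps`, `sb`, `vdw`); unknown labels are dropped with a warning.
#' Each listed contact contributes one count, so duplicated lines count
#' twice.
#'
#' @param path file path.
#' @param offset structure-numbering offset (resid = position + offset).
#' @return `data.frame` with columns `pos_i`, `pos_j` (i < j), `type`
#'   (feature column name).
#' @export
readContactsFile <- function(path, offset = 0L) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t")
  short <- vapply(parts, length, 1L) < 4L
  if (any(short)) stop("malformed contacts line(s): ",
                       paste(which(short), collapse = ", "))
  type <- vapply(parts, `[`, "", 2L)
  known <- type %in% names(CONTACT_TYPE_MAP)
  if (any(!known)) {
    warning("ignoring unknown interaction type(s): ",
            paste(unique(type[!known]), collapse = ", "))
    parts <- parts[known]; type <- type[known]
  }
  resid <- function(atom) as.integer(vapply(strsplit(atom, ":"), `[`, "", 3L))
  ri <- resid(vapply(parts, `[`, "", 3L)) - offset
  rj <- resid(vapply(parts, `[`, "", 4L)) - offset
  data.frame(pos_i = pmin(ri, rj), pos_j = pmax(ri, rj),
             type = unname(CONTACT_TYPE_MAP[type]),
             stringsAsFactors = FALSE)
}

#' Assemble the 12-feature table for mutated-residue pairs
#'
#' For every coupling pair (i < j): backbone distance `|i - j|`; minimal
#' side-chain heavy-atom distance; number of core residues in the pair
#' (RSASA < 0.25); number of binding-interface residues (ligand distance
#' < 5 Angstrom); number of beta-strand residues; and seven chemical-bond
#' counts from a contacts table (pairs absent from the table have zero
#' counts). The response is the coupling strength `|dddG_f|`.
#'
#' @param couplings `data.frame` with columns `pos_i`, `pos_j` and
#'   `coupling` (folding coupling dddG, kcal/mol).
#' @param annotations annotation `data.frame`
#'   ([readResidueAnnotations()]).
#' @param struct output of [readStructure()].
#' @param contacts contacts `data.frame` ([readContactsFile()]) or `NULL`
#'   for all-zero bond counts.
#' @param coreRsasa core cutoff (strict <).
#' @param interfaceMax interface cutoff in Angstrom (strict <).
#' @return `data.frame`: pair ids, the 12 features, and `strength`.
#' @export
buildPairFeatures <- function(couplings, annotations, struct,
                              contacts = NULL, coreRsasa = 0.25,
                              interfaceMax = 5) {
  i <- pmin(couplings$pos_i, couplings$pos_j)
  j <- pmax(couplings$pos_i, couplings$pos_j)
  ann <- annotations[match(c(i, j), annotations$position), , drop = FALSE]
  if (anyNA(ann$position))
    stop("coupling pair without annotations at position(s): ",
         paste(unique(c(i, j)[is.na(ann$position)]), collapse = ", "))
  n <- length(i)
  annI <- ann[seq_len(n), ]; annJ <- ann[n + seq_len(n), ]
  out <- data.frame(
    pos_i = i, pos_j = j,
    backbone_distance = abs(j - i),
    scha_distance = vapply(seq_len(n), function(k)
      as.numeric(minSidechainDistance(struct, i[k], j[k])), 0),
    n_core = (annI$rsasa < coreRsasa) + (annJ$rsasa < coreRsasa),
    n_interface = (annI$ligand_distance < interfaceMax) +
      (annJ$ligand_distance < interfaceMax),
    n_strand = (annI$ss == "strand") + (annJ$ss == "strand"))
  for (tp in unname(CONTACT_TYPE_MAP)) out[[tp]] <- 0L
  if (!is.null(contacts) && nrow(contacts)) {
    key <- paste(out$pos_i, out$pos_j)
    ckey <- paste(pmin(contacts$pos_i, contacts$pos_j),
                  pmax(contacts$pos_i, contacts$pos_j))
    for (k in seq_len(nrow(contacts))) {
      hit <- which(key == ckey[k])
      if (length(hit))
        out[hit, contacts$type[k]] <- out[hit, contacts$type[k]] + 1L
    }
  }
  out$strength <- abs(couplings$coupling)
  stopifnot(identical(intersect(PAIR_FEATURES, names(out)), PAIR_FEATURES))
  out
}

#' Linear model of energetic coupling strength from structural features
#'
#' Ordinary least squares of coupling strength `|dddG_f|` on the 12
#' structural features (z-scored, plus intercept), with uncorrected
#' two-sided t-test p-values per coefficient. Standardization makes the
#' coefficient ranking scale-free; predictions are invariant to affine
#' rescaling of the raw feature units.
#'
#' @param train feature table from [buildPairFeatures()] (>= 20 pairs).
#' @return Object of class `"CouplingStrengthModel"`: `fit` (the `lm`),
#'   `coefficients` `data.frame` (estimate, p-value), `center`/`scale` used
#'   for standardization, and `trainPairs` keys.
#' @export
fitCouplingStrengthModel <- function(train) {
  if (nrow(train) < 20L) stop("need at least 20 training pairs")
  X <- as.matrix(train[, PAIR_FEATURES])
  ctr <- colMeans(X)
  scl <- apply(X, 2L, stats::sd)
  if (any(scl == 0)) {
    # constant columns carry no information; keep them at zero after
    # centring so lm reports them as aliased rather than erroring
    scl[scl == 0] <- 1
  }
  Z <- scale(X, center = ctr, scale = scl)
  df <- data.frame(strength = train$strength, Z, check.names = FALSE)
  fit <- stats::lm(strength ~ ., data = df)
  if (any(is.na(stats::coef(fit))))
    stop("rank-deficient design; collinear feature(s): ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
               collapse = ", "))
  sm <- summary(fit)$coefficients
  structure(list(
    fit = fit,
    coefficients = data.frame(feature = rownames(sm),
                              estimate = sm[, "Estimate"],
                              p_value = sm[, "Pr(>|t|)"],
                              row.names = NULL),
    center = ctr, scale = scl,
    trainPairs = paste(train$pos_i, train$pos_j)),
    class = "CouplingStrengthModel")
}

#' Evaluate a coupling-strength model on held-out pairs
#'
#' Requires the test pairs to be disjoint from the training pairs (an
#' overlapping evaluation is refused).
#'
#' @param model a `"CouplingStrengthModel"`.
#' @param test feature table of held-out pairs.
#' @return Named numeric: Pearson `r` and `r2` between predicted and
#'   observed strength.
#' @export
evaluateCouplingModel <- function(model, test) {
  testPairs <- paste(test$pos_i, test$pos_j)
  if (length(intersect(testPairs, model$trainPairs)))
    stop("test pairs overlap the training pairs")
  Z <- scale(as.matrix(test[, PAIR_FEATURES]),
             center = model$center, scale = model$scale)
  pred <- stats::predict(model$fit,
                         newdata = as.data.frame(Z))
  y <- test$strength
  c(r = stats::cor(pred, y),
    r2 = 1 - sum((y - pred)^2) / sum((y - mean(y))^2))
}

#' Coupling strength versus distance statistics
#'
#' Spearman correlations of coupling strength with (a) 3D side-chain
#' heavy-atom distance, overall and restricted to pairs distal in the
#' primary sequence (backbone distance > `backboneCutoff`), and (b)
#' backbone distance, overall and excluding direct physical contacts
#' (side-chain distance < `contactMax`); plus binned strength means with
#' 95% bands (2.5/97.5 percentiles) across Monte Carlo refit replicates
#' when supplied.
#'
#' @param pairTable `data.frame` with `strength`, `scha_distance`,
#'   `backbone_distance`.
#' @param mcStrengths optional pairs x replicates matrix of per-refit
#'   coupling strengths for the confidence bands.
#' @param backboneCutoff long-range cutoff in residues (strict >).
#' @param contactMax direct-contact exclusion in Angstrom (strict <).
#' @param bins breakpoints for the distance binning.
#' @return List with `rho` (named numeric of the four Spearman
#'   coefficients) and `binned` (`data.frame` per bin).
#' @export
couplingDistanceStats <- function(pairTable, mcStrengths = NULL,
                                  backboneCutoff = 5L, contactMax = 5,
                                  bins = c(0, 5, 8, 12, 16, Inf)) {
  sp <- function(x, y) {
    if (length(x) < 3L) stop("fewer than 3 pairs after restriction")
    stats::cor(x, y, method = "spearman")
  }
  longR <- pairTable$backbone_distance > backboneCutoff
  nonContact <- pairTable$scha_distance >= contactMax
  rho <- c(
    scha_all = sp(pairTable$strength, pairTable$scha_distance),
    scha_longrange = sp(pairTable$strength[longR],
                        pairTable$scha_distance[longR]),
    backbone_all = sp(pairTable$strength, pairTable$backbone_distance),
    backbone_noncontact = sp(pairTable$strength[nonContact],
                             pairTable$backbone_distance[nonContact]))
  bin <- cut(pairTable$scha_distance, bins, include.lowest = TRUE)
  binned <- do.call(rbind, lapply(levels(bin), function(b) {
    idx <- which(bin == b)
    if (!length(idx)) return(NULL)
    row <- data.frame(bin = b, n = length(idx),
                      mean_strength = mean(pairTable$strength[idx]))
    if (!is.null(mcStrengths)) {
      repMeans <- colMeans(mcStrengths[idx, , drop = FALSE])
      qs <- stats::quantile(repMeans, c(0.025, 0.975))
      row$ci95_lo <- qs[[1L]]; row$ci95_hi <- qs[[2L]]
    }
    row
  }))
  list(rho = rho, binned = binned)
}

#' Compare folding and binding coupling strengths
#'
#' Side-by-side report of `|dddG_f|` versus `|dddG_b|` with a stock
#' two-sided Mann-Whitney U test.
#'
#' @param couplingsF,couplingsB numeric vectors of folding / binding
#'   couplings (kcal/mol).
#' @return List with per-trait mean and sd of the strengths, the
#'   `wilcox.test` p-value and the AUC-style effect size.
#' @export
compareCouplingStrengths <- function(couplingsF, couplingsB) {
  sf <- abs(couplingsF); sb <- abs(couplingsB)
  wt <- stats::wilcox.test(sf, sb, exact = FALSE)
  auc <- wt$statistic / (length(sf) * length(sb))
  list(folding = c(mean = mean(sf), sd = stats::sd(sf)),
       binding = c(mean = mean(sb), sd = stats::sd(sb)),
       p_value = wt$p.value, auc = unname(auc))
}
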