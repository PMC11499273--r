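#' Parse a substitution code
#'
#' Parses a code such as `"P11A"` (wild-type amino acid, 1-based residue
#' position, mutant amino acid) into its components. Positions refer to the
#' domain-local wild-type sequence in use, not to any external renumbering.
#'
#' @param code character vector of substitution codes.
#' @return A `data.frame` with columns `id`, `position`, `wt_aa`, `mut_aa`
#'   (energies absent).
#' @examples
#' parseSubstitution(c("P11A", "G18C"))
#' @export
parseSubstitution <- function(code) {
  m <- regmatches(code, regexec("^([A-Y])([0-9]+)([A-Y])$", code))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad))
    stop("malformed substitution code(s): ", paste(code[bad], collapse = ", "))
  wt <- vapply(m, `[`, "", 2L)
  pos <- as.integer(vapply(m, `[`, "", 3L))
  mut <- vapply(m, `[`, "", 4L)
  ok <- wt %in% AA_ONE_LETTER & mut %in% AA_ONE_LETTER
  if (!all(ok))
    stop("invalid amino-acid letter in: ", paste(code[!ok], collapse = ", "))
  if (any(pos < 1L)) stop("positions must be >= 1")
  if (any(wt == mut))
    stop("identity substitution(s) not allowed: ",
         paste(code[wt == mut], collapse = ", "))
  data.frame(id = code, position = pos, wt_aa = wt, mut_aa = mut,
             stringsAsFactors = FALSE)
}

#' Standard (or user-supplied) genetic code
#'
#' Returns the codon-to-amino-acid table used for nucleotide reachability.
#' Defaults to the standard genetic code; a 64-row tab-separated file with
#' columns `codon` and `aa` (stop = `"*"`) can override it.
#'
#' @param path optional path to a 64-row TSV override.
#' @return Named character vector of length 64: codon (DNA) -> one-letter
#'   amino acid, stop codons as `"*"`.
#' @export
geneticCode <- function(path = NULL) {
  if (is.null(path)) {
    gc <- Biostrings::GENETIC_CODE
    return(stats::setNames(as.character(gc), names(gc)))
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("codon", "aa") %in% names(tab)) || nrow(tab) != 64L)
    stop("genetic-code override must be a 64-row table with columns codon, aa")
  stats::setNames(toupper(tab$aa), toupper(tab$codon))
}

#' Single-nucleotide reachability of an amino-acid substitution
#'
#' Tests whether `target_aa` can be reached from `wt_codon` by mutating
#' exactly one nucleotide. Synonymous targets (the codon's own amino acid)
#' return `FALSE`: candidates for library design are amino-acid
#' substitutions, so identity targets are not substitutions.
#'
#' @param wt_codon 3-letter DNA codon (A/C/G/T).
#' @param target_aa one-letter amino-acid target.
#' @param code genetic-code table from [geneticCode()].
#' @return `TRUE` iff some single-nucleotide neighbour of `wt_codon`
#'   translates to `target_aa`.
#' @examples
#' singleNtReachable("CCT", "A")  # GCT = Ala
#' singleNtReachable("CCT", "W")  # FALSE
#' @export
singleNtReachable <- function(wt_codon, target_aa, code = geneticCode()) {
  wt_codon <- toupper(wt_codon)
  if (nchar(wt_codon) != 3L || grepl("[^ACGT]", wt_codon))
    stop("wt_codon must be a 3-letter A/C/G/T codon")
  if (target_aa == "*") stop("stop codons are not valid substitution targets")
  if (!target_aa %in% AA_ONE_LETTER) stop("invalid target amino acid")
  if (code[[wt_codon]] == target_aa) return(FALSE)
  nts <- c("A", "C", "G", "T")
  base <- strsplit(wt_codon, "")[[1]]
  for (i in 1:3) {
    for (nt in setdiff(nts, base[i])) {
      nb <- base; nb[i] <- nt
      if (code[[paste(nb, collapse = "")]] == target_aa) return(TRUE)
    }
  }
  FALSE
}

#' Annotate substitutions with nucleotide reachability
#'
#' Looks up each substitution's wild-type codon in the library's nucleotide
#' sequence and records whether the mutant amino acid is reachable by a
#' single-nucleotide change.
#'
#' @param lib a [LibraryDefinition-class] with `wtNtSeq` present, or a
#'   substitution `data.frame` plus `wt_nt_seq`.
#' @param wt_nt_seq coding sequence when `lib` is a plain `data.frame`.
#' @param code genetic-code table.
#' @return The substitution table with a logical `nt_reachable` column.
#' @export
annotateReachability <- function(lib, wt_nt_seq = NULL, code = geneticCode()) {
  if (is(lib, "LibraryDefinition")) {
    subs <- lib@substitutions
    wt_nt_seq <- lib@wtNtSeq
  } else subs <- as.data.frame(lib)
  if (is.null(wt_nt_seq) || is.na(wt_nt_seq))
    stop("a wild-type nucleotide sequence is required")
  codonAt <- function(p) substr(wt_nt_seq, 3L * p - 2L, 3L * p)
  subs$nt_reachable <- mapply(function(p, aa)
    singleNtReachable(codonAt(p), aa, code), subs$position, subs$mut_aa)
  subs
}

#' Encode variants as a binary genotype matrix
#'
#' Maps substitution sets onto rows of an n x K binary matrix over the
#' library's K substitutions (the package's canonical internal variant
#' representation).
#'
#' @param variants list of character vectors of substitution ids (an empty
#'   vector is the wild type).
#' @param lib a [LibraryDefinition-class].
#' @return Integer n x K matrix with columns named by substitution id.
#' @examples
#' lib <- libraryDefinition("MGDK",
#'   data.frame(position = c(2, 4), wt_aa = c("G", "K"), mut_aa = c("A", "R")))
#' encodeGenotypes(list(character(), "G2A", c("G2A", "K4R")), lib)
#' @export
encodeGenotypes <- function(variants, lib) {
  ids <- substitutionIds(lib)
  g <- matrix(0L, nrow = length(variants), ncol = length(ids),
              dimnames = list(NULL, ids))
  for (i in seq_along(variants)) {
    v <- variants[[i]]
    if (length(v) == 0L) next
    j <- match(v, ids)
    if (anyNA(j))
      stop("substitution(s) not in library: ",
           paste(v[is.na(j)], collapse = ", "))
    g[i, j] <- 1L
  }
  g
}

#' Decode genotype rows back to substitution codes
#'
#' @param genotypes binary matrix with substitution-id column names.
#' @return List of character vectors of substitution ids per row.
#' @export
decodeGenotypes <- function(genotypes) {
  ids <- colnames(genotypes)
  lapply(seq_len(nrow(genotypes)), function(i) ids[genotypes[i, ] == 1L])
}

## variant-string <-> genotype helpers for the two table dialects
aaSeqToVariant <- function(seq, lib) {
  wt <- strsplit(wtAaSequence(lib), "")[[1]]
  vs <- strsplit(seq, "")[[1]]
  if (length(vs) != length(wt)) stop("variant sequence length mismatch")
  diff <- which(vs != wt)
  subs <- substitutionTable(lib)
  ids <- character(0)
  for (p in diff) {
    hit <- which(subs$position == p & subs$mut_aa == vs[p])
    if (length(hit) != 1L)
      stop(sprintf("sequence differs from wild type at position %d (%s->%s), which is not a library substitution",
                   p, wt[p], vs[p]))
    ids <- c(ids, subs$id[hit])
  }
  ids
}

variantToAaSeq <- function(ids, lib) {
  wt <- strsplit(wtAaSequence(lib), "")[[1]]
  subs <- substitutionTable(lib)
  j <- match(ids, subs$id)
  wt[subs$position[j]] <- subs$mut_aa[j]
  paste(wt, collapse = "")
}

#' Read a variant fitness table
#'
#' Reads a tab-separated variant table with header columns `variant`,
#' `order`, and per phenotype `fitness_<phenotype>`, `sigma_<phenotype>` and
#' optional `rep1_<phenotype>..repR_<phenotype>`. Two `variant` dialects are
#' accepted: a full amino-acid sequence per row, or comma-separated
#' substitution codes (empty string = wild type). Rows lacking a positive
#' sigma for any declared phenotype are dropped with a message; by default
#' rows with missing replicate values are retained as long as the aggregate
#' fitness and sigma are present (set `completeReplicatesOnly = TRUE` to
#' restrict to variants measured in all replicates).
#'
#' @param path file path.
#' @param lib a [LibraryDefinition-class].
#' @param dialect `"codes"`, `"aaseq"` or `"auto"` (default: detect).
#' @param completeReplicatesOnly drop rows with any missing replicate value.
#' @return A [GenotypeTable-class].
#' @export
readVariantTable <- function(path, lib, dialect = c("auto", "codes", "aaseq"),
                             completeReplicatesOnly = FALSE) {
  dialect <- match.arg(dialect)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  phen <- phenotypeNames(lib)
  fitCols <- paste0("fitness_", phen)
  sigCols <- paste0("sigma_", phen)
  miss <- setdiff(c("variant", fitCols, sigCols), names(tab))
  if (length(miss))
    stop("missing mandatory column(s): ", paste(miss, collapse = ", "))
  tab$variant[is.na(tab$variant)] <- ""
  if (dialect == "auto") {
    nonwt <- tab$variant[nzchar(tab$variant)]
    dialect <- if (length(nonwt) &&
                   all(nchar(nonwt) == nchar(wtAaSequence(lib))) &&
                   !any(grepl("[0-9,]", nonwt))) "aaseq" else "codes"
  }
  variants <- if (dialect == "aaseq") {
    lapply(tab$variant, aaSeqToVariant, lib = lib)
  } else {
    lapply(strsplit(tab$variant, ","), function(v) v[nzchar(trimws(v))])
  }
  g <- encodeGenotypes(variants, lib)

  sig <- as.matrix(tab[, sigCols, drop = FALSE])
  colnames(sig) <- phen
  fit <- as.matrix(tab[, fitCols, drop = FALSE])
  colnames(fit) <- phen
  keep <- rowSums(is.na(sig) | sig <= 0 | is.na(fit)) == 0L

  reps <- list()
  for (ph in phen) {
    rc <- grep(paste0("^rep[0-9]+_", ph, "$"), names(tab), value = TRUE)
    if (length(rc)) {
      rm_ <- as.matrix(tab[, rc, drop = FALSE])
      reps[[ph]] <- rm_
      if (completeReplicatesOnly) keep <- keep & rowSums(is.na(rm_)) == 0L
    }
  }
  if (any(!keep))
    message(sum(!keep), " row(s) dropped (missing or non-positive sigma",
            if (completeReplicatesOnly) " or incomplete replicates", ")")
  g <- g[keep, , drop = FALSE]
  reps <- lapply(reps, function(m) m[keep, , drop = FALSE])
  genotypeTable(g, fit[keep, , drop = FALSE], sig[keep, , drop = FALSE],
                replicates = reps, phenotypes = phen)
}

#' Write a variant fitness table
#'
#' Writes the tab-separated form read by [readVariantTable()], using the
#' comma-separated substitution-code dialect.
#'
#' @param table a [GenotypeTable-class].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
writeVariantTable <- function(table, path) {
  codes <- vapply(decodeGenotypes(genotypes(table)),
                  paste, "", collapse = ",")
  out <- data.frame(variant = codes, order = mutantOrder(table),
                    check.names = FALSE)
  for (ph in phenotypeNames(table)) {
    out[[paste0("fitness_", ph)]] <- fitnessMatrix(table)[, ph]
    out[[paste0("sigma_", ph)]] <- sigmaMatrix(table)[, ph]
    reps <- replicateValues(table)[[ph]]
    if (!is.null(reps))
      for (r in seq_len(ncol(reps)))
        out[[paste0("rep", r, "_", ph)]] <- reps[, r]
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a substitution-effect table
#'
#' Tab-separated tables of single-substitution free energy changes with
#' columns `id`, `position`, `wt_aa`, `mut_aa`, `ddg_f`, `ci95_f`,
#' `n_backgrounds` and, when the binding trait was assayed, `ddg_b`,
#' `ci95_b`.
#'
#' @param path file path.
#' @return `readEffectTable`: a `data.frame` of substitution effects.
#' @export
readEffectTable <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "position", "wt_aa", "mut_aa", "ddg_f")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("missing mandatory column(s): ", paste(miss, collapse = ", "))
  if (any(tab$wt_aa == tab$mut_aa)) stop("identity substitutions in table")
  ci <- intersect(c("ci95_f", "ci95_b"), names(tab))
  for (cc in ci) if (any(tab[[cc]] < 0, na.rm = TRUE))
    stop("negative confidence-interval width in ", cc)
  tab
}

#' @rdname readEffectTable
#' @param effects substitution-effect `data.frame`.
#' @export
writeEffectTable <- function(effects, path) {
  utils::write.table(effects, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
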