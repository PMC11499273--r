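# Fixtures and independent oracles shared across test files. Everything is
# generated in code; no binary data.

# small library over a 12-residue synthetic wild type
toyLibrary <- function(phenotypes = "abundance") {
  libraryDefinition(
    "MPDKAGRSTWYV",
    data.frame(position = c(2L, 5L, 7L, 10L),
               wt_aa = c("P", "A", "R", "W"),
               mut_aa = c("A", "V", "Q", "L")),
    phenotypes = phenotypes)
}

toyTable <- function(lib = toyLibrary(), seed = 1) {
  g <- sampleGenotypeLibrary(4, scheme = "exhaustive",
                             subIds = substitutionIds(lib))
  set.seed(seed)
  n <- nrow(g)
  fit <- matrix(stats::runif(n), ncol = 1,
                dimnames = list(NULL, "abundance"))
  sig <- matrix(stats::runif(n, 0.05, 0.1), ncol = 1,
                dimnames = list(NULL, "abundance"))
  genotypeTable(g, fit, sig)
}

# independent Boltzmann oracle: explicit partition-sum enumeration over the
# state energy vector (0 for the reference state)
bfStateProb <- function(stateEnergies, which, rt = 0.001987 * 303) {
  w <- exp(-stateEnergies / rt)
  w[which] / sum(w)
}

# brute-force free energy of a genotype by explicit coefficient enumeration
bfFreeEnergy <- function(dgwt, ddg, coup, x) {
  val <- dgwt + sum(ddg * x)
  K <- length(x)
  k <- 0
  for (i in seq_len(K - 1)) for (j in (i + 1):K) {
    k <- k + 1
    val <- val + coup[k] * x[i] * x[j]
  }
  unname(val)
}

# independent single-nucleotide reachability oracle built on Biostrings
# translation of explicitly constructed neighbour codons
bfReachable <- function(codon, aa) {
  nts <- c("A", "C", "G", "T")
  base <- strsplit(codon, "")[[1]]
  hits <- character(0)
  for (i in 1:3) for (nt in nts) {
    if (nt == base[i]) next
    nb <- base; nb[i] <- nt
    hits <- c(hits, paste(nb, collapse = ""))
  }
  tr <- as.character(Biostrings::translate(Biostrings::DNAStringSet(hits),
                                           no.init.codon = TRUE))
  wtAa <- as.character(Biostrings::translate(Biostrings::DNAString(codon),
                                             no.init.codon = TRUE))
  aa != wtAa && aa %in% tr
}

# minimal PDB writer for synthetic toy structures
writeToyPdb <- function(atoms, path = tempfile(fileext = ".pdb")) {
  lines <- vapply(seq_len(nrow(atoms)), function(i) {
    a <- atoms[i, ]
    sprintf("ATOM  %5d %-4s %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            i, a$elety, a$resname, a$chain, a$resno,
            a$x, a$y, a$z, 1, 0, a$elesy)
  }, "")
  writeLines(c(lines, "END"), path)
  path
}

# toy 4-residue structure: single-CB side chains at known coordinates and a
# glycine (residue 3) with only backbone atoms (CA fallback case)
toyStructureAtoms <- function() {
  mk <- function(resno, resname, elety, elesy, x, y, z)
    data.frame(resno = resno, resname = resname, elety = elety,
               elesy = elesy, chain = "A", x = x, y = y, z = z,
               stringsAsFactors = FALSE)
  rbind(
    mk(1, "ALA", "N", "N", -1, 0, 0), mk(1, "ALA", "CA", "C", -0.5, 0, 0),
    mk(1, "ALA", "C", "C", -0.2, 0, 0), mk(1, "ALA", "O", "O", -0.1, 0, 0),
    mk(1, "ALA", "CB", "C", 0, 0, 0),
    mk(2, "ALA", "N", "N", 2, 4, 0), mk(2, "ALA", "CA", "C", 2.5, 4, 0),
    mk(2, "ALA", "C", "C", 2.8, 4, 0), mk(2, "ALA", "O", "O", 2.9, 4, 0),
    mk(2, "ALA", "CB", "C", 3, 4, 0),
    mk(3, "GLY", "N", "N", 5.5, 0, 0), mk(3, "GLY", "CA", "C", 6, 0, 0),
    mk(3, "GLY", "C", "C", 6.4, 0, 0), mk(3, "GLY", "O", "O", 6.5, 0, 0),
    mk(4, "LYS", "N", "N", 9.5, 0, 1), mk(4, "LYS", "CA", "C", 10, 0, 1),
    mk(4, "LYS", "C", "C", 10.4, 0, 1), mk(4, "LYS", "O", "O", 10.5, 0, 1),
    mk(4, "LYS", "CB", "C", 10, 0, 0), mk(4, "LYS", "NZ", "N", 11, 0, 0))
}

toyStructure <- function() {
  path <- writeToyPdb(toyStructureAtoms())
  readStructure(path, chain = "A")
}

# brute-force minimal side-chain heavy-atom distance straight off the atom
# table (independent of the package's selection logic)
bfMinDist <- function(atoms, ri, rj, backbone = c("N", "CA", "C", "O", "OXT")) {
  pick <- function(r) {
    at <- atoms[atoms$resno == r & atoms$elesy != "H" &
                  !atoms$elety %in% backbone, , drop = FALSE]
    if (nrow(at) == 0)
      at <- atoms[atoms$resno == r & atoms$elety == "CA", , drop = FALSE]
    at
  }
  a <- pick(ri); b <- pick(rj)
  best <- Inf
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    d <- sqrt((a$x[i] - b$x[j])^2 + (a$y[i] - b$y[j])^2 +
                (a$z[i] - b$z[j])^2)
    best <- min(best, d)
  }
  best
}

toyAnnotations <- function() {
  data.frame(position = 1:4,
             rsasa = c(0.1, 0.6, 0.4, 0.8),
             ss = c("strand", "strand", "loop", "helix"),
             ligand_distance = c(3.2, 6.1, 12.0, 4.4),
             stringsAsFactors = FALSE)
}

writeToyContacts <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(c("# total_frames:1 beg:0 end:0", lines), path)
  path
}

# a synthetic pair-feature table with a known linear response
syntheticPairTable <- function(n, betas, noiseSd = 0.02, seed = 1) {
  set.seed(seed)
  pos <- t(combn(ceiling((1 + sqrt(1 + 8 * n)) / 2) + 1, 2))[1:n, ]
  X <- cbind(
    backbone_distance = abs(pos[, 1] - pos[, 2]),
    scha_distance = runif(n, 2, 20),
    n_core = sample(0:2, n, TRUE),
    n_interface = sample(0:2, n, TRUE),
    n_strand = sample(0:2, n, TRUE),
    hbond_bb_bb = rpois(n, 0.5), hbond_sc_bb = rpois(n, 0.3),
    hbond_sc_sc = rpois(n, 0.3), pi_cation = rpois(n, 0.2),
    pi_stacking = rpois(n, 0.2), salt_bridge = rpois(n, 0.3),
    van_der_waals = rpois(n, 3))
  # fixed per-feature scales so the raw-coefficient mapping is identical
  # across independently generated tables
  scales <- c(4, 5.2, 0.8, 0.8, 0.8, 0.7, 0.55, 0.55, 0.3, 0.3, 0.45, 1.7)
  y <- 0.5 + as.vector(X %*% (betas / scales)) + rnorm(n, 0, noiseSd)
  data.frame(pos_i = pos[, 1], pos_j = pos[, 2], X, strength = y)
}
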