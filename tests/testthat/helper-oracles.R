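# Independent oracles used to freeze expected values. These deliberately
# avoid the package's own constants and algorithms: masses are summed from
# elemental compositions and IUPAC atomic masses; digestion is re-derived
# by checking every substring against the cleavage rule directly.

# IUPAC monoisotopic atomic masses (Da)
.ELEMENT <- c(H = 1.0078250319, C = 12.0, N = 14.0030740052,
              O = 15.9949146221, S = 31.97207069)

# residue elemental compositions (C, H, N, O, S)
.RESIDUE_FORMULA <- list(
  G = c(2, 3, 1, 1, 0),  A = c(3, 5, 1, 1, 0),  S = c(3, 5, 1, 2, 0),
  P = c(5, 7, 1, 1, 0),  V = c(5, 9, 1, 1, 0),  T = c(4, 7, 1, 2, 0),
  C = c(3, 5, 1, 1, 1),  L = c(6, 11, 1, 1, 0), I = c(6, 11, 1, 1, 0),
  N = c(4, 6, 2, 2, 0),  D = c(4, 5, 1, 3, 0),  Q = c(5, 8, 2, 2, 0),
  K = c(6, 12, 2, 1, 0), E = c(5, 7, 1, 3, 0),  M = c(5, 9, 1, 1, 1),
  H = c(6, 7, 3, 1, 0),  F = c(9, 9, 1, 1, 0),  R = c(6, 12, 4, 1, 0),
  Y = c(9, 9, 1, 2, 0),  W = c(11, 10, 2, 1, 0))

formulaMass <- function(C = 0, H = 0, N = 0, O = 0, S = 0) {
  sum(c(C, H, N, O, S) * .ELEMENT[c("C", "H", "N", "O", "S")])
}

oracleWater <- formulaMass(H = 2, O = 1)

oraclePeptideMass <- function(sequence) {
  res <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  sum(vapply(res, function(a) {
    f <- .RESIDUE_FORMULA[[a]]
    formulaMass(f[1], f[2], f[3], f[4], f[5])
  }, 0)) + oracleWater
}

# Brute-force digestion: every substring whose two ends are valid
# boundaries (terminus or cleavage site) and whose internal cleavage-site
# count is <= maxMissed.
oracleDigest <- function(sequence, cleaveAfter, exceptionNext, maxMissed) {
  res <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  n <- length(res)
  isCut <- function(i) {  # cut after position i?
    i >= 1 && i < n && res[i] %in% cleaveAfter && !res[i + 1] %in% exceptionNext
  }
  boundary <- function(i) i == 0 || i == n || isCut(i)
  out <- list()
  for (s in 1:n) for (e in s:n) {
    if (!boundary(s - 1) || !boundary(e)) next
    internal <- if (e > s) sum(vapply(s:(e - 1), isCut, TRUE)) else 0L
    if (internal <= maxMissed)
      out[[length(out) + 1L]] <- data.frame(
        start = s, end = e, missed = internal,
        sequence = paste(res[s:e], collapse = ""))
  }
  do.call(rbind, out)
}

# Random peptide-like sequence generator for property tests
randomSequence <- function(len, alphabet = names(.RESIDUE_FORMULA)) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# A symmetric MS-cleavable test linker (equal remnants), used to check the
# one-variant-per-fragment rule.
symmetricTestLinker <- function() {
  new("CrossLinker", name = "SYMTEST", siteA = "K", siteB = "K",
      ntermReactive = FALSE, spacerArm = 10, cleavable = TRUE,
      intactDelta = 100, remnantA = 50, remnantB = 50)
}

# Small two-protein universe in which both peptides carry >= 2 linkable
# sites, exercising all four product classes.
twoPeptideUniverse <- function(linker = loadLinkerCatalog()[["DSSO"]]) {
  mk <- function(seqn, accession) {
    peps <- S4Vectors::DataFrame(
      parent_accession = accession, sequence = seqn,
      start = 1L, end = nchar(seqn),
      missed_cleavages = 1L, is_protein_nterm = FALSE,
      is_protein_cterm = TRUE)
    modformTable(peps, defaultModifications())
  }
  list(A = mk("AKAKAE", "PRA"), B = mk("GKGKGE", "PRB"), linker = linker)
}
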