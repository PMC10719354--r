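## Monoisotopic mass bookkeeping: residue masses, peptide neutral mass,
## modification handling and m/z conversion. All masses are monoisotopic
## daltons; SRM transition lists are always computed on the monoisotopic
## scale.

## Residue monoisotopic masses (Da) for the 20 standard amino acids,
## standard IUPAC/Unimod values. Covered by an elemental-composition
## oracle in the test suite; do not edit one without the other.
.RESIDUE_MASS <- c(
  G = 57.02146372, A = 71.03711379, S = 87.03202841, P = 97.05276385,
  V = 99.06841391, T = 101.04767847, C = 103.00918448, L = 113.08406398,
  I = 113.08406398, N = 114.04292745, D = 115.02694303, Q = 128.05857751,
  K = 128.09496302, E = 129.04259309, M = 131.04048460, H = 137.05891186,
  F = 147.06841391, R = 156.10111103, Y = 163.06332854, W = 186.07931295
)

.WATER_MASS  <- 18.0105646863
.PROTON_MASS <- 1.00727646688

#' Monoisotopic mass table
#'
#' Returns the immutable monoisotopic mass constants used throughout the
#' package: the residue masses of the 20 standard amino acids, the mass of
#' water (added once per peptide for the terminal H/OH) and the proton mass
#' used for m/z conversion.
#'
#' @return A list with elements `residues` (named numeric vector of 20
#'   residue masses in Da), `water` and `proton` (Da).
#' @examples
#' massTable()$residues[["G"]]
#' @export
massTable <- function() {
  list(residues = .RESIDUE_MASS, water = .WATER_MASS, proton = .PROTON_MASS)
}

#' Neutral monoisotopic mass of a peptide
#'
#' Sums residue masses plus one water, plus any applied modification deltas.
#'
#' @param sequence Character scalar over the 20 standard residue letters.
#' @param modDeltas Numeric vector of modification mass deltas (Da) already
#'   applied to this peptide form; may be empty.
#' @return Neutral monoisotopic mass in Da.
#' @examples
#' peptideNeutralMass("PEPTIDE")
#' @export
peptideNeutralMass <- function(sequence, modDeltas = numeric()) {
  stopifnot(is.character(sequence), length(sequence) == 1L, nzchar(sequence))
  res <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  bad <- which(!res %in% names(.RESIDUE_MASS))
  if (length(bad))
    stop("unknown residue '", res[bad[1L]], "' at position ", bad[1L],
         " in peptide '", sequence, "'")
  sum(.RESIDUE_MASS[res]) + .WATER_MASS + sum(modDeltas)
}

#' Convert a neutral mass to m/z
#'
#' @param neutralMass Neutral monoisotopic mass (Da).
#' @param z Positive integer charge.
#' @return (M + z * proton) / z.
#' @examples
#' mz(1000, 2)
#' @export
mz <- function(neutralMass, z) {
  if (any(z < 1) || any(z != as.integer(z)))
    stop("charge must be a positive integer, got ", paste(z, collapse = ","))
  (neutralMass + z * .PROTON_MASS) / z
}

## ---- modifications ---------------------------------------------------

.parseTargets <- function(x) {
  ## "CM" or "C,M"; "Nterm" token marks the peptide N-terminus
  toks <- strsplit(gsub(",", "", x), "", fixed = TRUE)[[1L]]
  toks[toks %in% names(.RESIDUE_MASS)]
}

#' Default modification set
#'
#' Carbamidomethylation of cysteine (static, +57.02146 Da) and oxidation of
#' methionine (variable, +15.99491 Da), the two modifications most commonly
#' carried in targeted XL-MS searches.
#'
#' @return data.frame with columns `name`, `targets`, `delta_mass`, `mode`.
#' @export
defaultModifications <- function() {
  data.frame(
    name = c("carbamidomethyl", "oxidation"),
    targets = c("C", "M"),
    delta_mass = c(57.02146372, 15.99491462),
    mode = c("static", "variable"),
    stringsAsFactors = FALSE
  )
}

#' Load a modification table from CSV
#'
#' The CSV must have columns `name,targets,delta_mass,mode` with `targets` a
#' string of residue letters (e.g. "STY") and `mode` either "static" or
#' "variable". Users can extend the two defaults this way.
#'
#' @param path Path to a CSV file.
#' @return data.frame in the same shape as [defaultModifications()].
#' @export
loadModifications <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("name", "targets", "delta_mass", "mode")
  if (!all(need %in% names(df)))
    stop("modification CSV must have columns: ", paste(need, collapse = ", "))
  if (!all(df$mode %in% c("static", "variable")))
    stop("modification mode must be 'static' or 'variable'")
  df[need]
}

## Eligible sites (1-based positions) of one modification on a sequence.
.modSites <- function(sequence, targets) {
  res <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  which(res %in% .parseTargets(targets))
}

#' Enumerate modification forms of a peptide
#'
#' Static modifications are applied unconditionally at every eligible site.
#' Each variable modification is expanded over all subsets of its eligible
#' sites, so a peptide with k variable-eligible sites yields 2^k forms.
#' Forms are ordered unmodified-first, then by the site indices of the
#' applied variable modifications.
#'
#' @param sequence Peptide sequence.
#' @param modifications data.frame as returned by [defaultModifications()].
#' @param cap Maximum number of forms; expansion beyond it is an error.
#' @return data.frame with one row per form: `annotated` (bracket notation,
#'   e.g. `"PEPTM[+15.99491]K"`), `mod_sites` (encoded `site:name:delta`
#'   triples separated by `;`, `""` for the bare form), `neutral_mass` (Da).
#' @examples
#' enumerateModForms("ACDM", defaultModifications())
#' @export
enumerateModForms <- function(sequence, modifications = defaultModifications(),
                              cap = 1024L) {
  stopifnot(is.data.frame(modifications))
  static <- modifications[modifications$mode == "static", , drop = FALSE]
  variable <- modifications[modifications$mode == "variable", , drop = FALSE]

  staticApplied <- list()
  for (i in seq_len(nrow(static))) {
    for (s in .modSites(sequence, static$targets[i]))
      staticApplied[[length(staticApplied) + 1L]] <-
        list(site = s, name = static$name[i], delta = static$delta_mass[i])
  }

  ## variable sites: one entry per (mod, site)
  varApplied <- list()
  for (i in seq_len(nrow(variable))) {
    for (s in .modSites(sequence, variable$targets[i]))
      varApplied[[length(varApplied) + 1L]] <-
        list(site = s, name = variable$name[i], delta = variable$delta_mass[i])
  }
  k <- length(varApplied)
  nForms <- 2^k
  if (nForms > cap)
    stop("variable-modification expansion of '", sequence, "' yields ",
         nForms, " forms (k = ", k, "), exceeding the cap of ", cap)

  ## subsets ordered by (size, site indices): bare form first
  subsets <- list(integer(0))
  if (k > 0) {
    all <- unlist(lapply(seq_len(k), function(m)
      utils::combn(k, m, simplify = FALSE)), recursive = FALSE)
    subsets <- c(subsets, all)
  }

  baseMass <- peptideNeutralMass(sequence)
  rows <- lapply(subsets, function(idx) {
    applied <- c(staticApplied, varApplied[idx])
    if (length(applied)) {
      ord <- order(vapply(applied, `[[`, 0, "site"))
      applied <- applied[ord]
    }
    deltas <- vapply(applied, `[[`, 0, "delta")
    enc <- paste(vapply(applied, function(a)
      sprintf("%d:%s:%.8f", a$site, a$name, a$delta), ""), collapse = ";")
    data.frame(
      annotated = .annotateSequence(sequence, applied),
      mod_sites = enc,
      neutral_mass = baseMass + sum(deltas),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

## "PEPTM[+15.99491]K" style annotation; applied sorted by site.
.annotateSequence <- function(sequence, applied) {
  if (!length(applied)) return(sequence)
  res <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  for (a in applied)
    res[a$site] <- sprintf("%s[%+.5f]", res[a$site], a$delta)
  paste(res, collapse = "")
}

## Decode a mod_sites string back into a data.frame(site, name, delta).
.decodeModSites <- function(enc) {
  if (!nzchar(enc))
    return(data.frame(site = integer(), name = character(),
                      delta = numeric(), stringsAsFactors = FALSE))
  parts <- strsplit(strsplit(enc, ";", fixed = TRUE)[[1L]], ":", fixed = TRUE)
  data.frame(
    site = vapply(parts, function(p) as.integer(p[1L]), 0L),
    name = vapply(parts, `[[`, "", 2L),
    delta = vapply(parts, function(p) as.numeric(p[3L]), 0),
    stringsAsFactors = FALSE
  )
}
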