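## In-silico enzymatic digestion with exception rules, missed cleavages
## and length filtering.

#' Enzyme specificity
#'
#' Cleavage occurs after a residue in `cleaveAfter` unless the following
#' residue is in `exceptionNext` (the classical "no cleavage before
#' proline" rule for both shipped enzymes).
#'
#' @slot name Enzyme name.
#' @slot cleaveAfter Residues cleaved after (P1 side).
#' @slot exceptionNext Residues blocking cleavage when next (P1' side).
#' @export
setClass("EnzymeSpec",
  slots = c(name = "character", cleaveAfter = "character",
            exceptionNext = "character"))

setValidity("EnzymeSpec", function(object) {
  if (!length(object@cleaveAfter)) return("cleaveAfter must be non-empty")
  if (!all(c(object@cleaveAfter, object@exceptionNext) %in% .STANDARD_RESIDUES))
    return("specificity residues must be standard amino acids")
  TRUE
})

setMethod("show", "EnzymeSpec", function(object) {
  cat("EnzymeSpec:", object@name, "- cleaves after [",
      paste(object@cleaveAfter, collapse = ""), "] except before [",
      paste(object@exceptionNext, collapse = ""), "]\n")
})

#' Built-in enzymes
#'
#' Trypsin cleaves C-terminal to K/R, chymotrypsin (high specificity)
#' C-terminal to F/W/Y; neither cleaves before proline. Custom
#' specificities can be built directly with `new("EnzymeSpec", ...)`.
#'
#' @param name `"trypsin"` or `"chymotrypsin"`.
#' @return An [EnzymeSpec].
#' @examples
#' enzymeSpec("trypsin")
#' @export
enzymeSpec <- function(name = c("trypsin", "chymotrypsin")) {
  name <- match.arg(name)
  switch(name,
    trypsin = methods::new("EnzymeSpec", name = "trypsin",
      cleaveAfter = c("K", "R"), exceptionNext = "P"),
    chymotrypsin = methods::new("EnzymeSpec", name = "chymotrypsin",
      cleaveAfter = c("F", "W", "Y"), exceptionNext = "P"))
}

## 0-based cut positions: cut after position i (1..n-1) when residue i is in
## cleaveAfter and residue i+1 is not in exceptionNext.
.cleavageSites <- function(residues, enzyme) {
  n <- length(residues)
  if (n < 2L) return(integer())
  i <- seq_len(n - 1L)
  i[residues[i] %in% enzyme@cleaveAfter &
    !residues[i + 1L] %in% enzyme@exceptionNext]
}

#' Digest a protein in silico
#'
#' Enumerates every peptide bounded by valid cleavage positions (or the
#' protein termini) spanning at most `maxMissed` internal cleavage sites.
#' The C-terminal peptide is emitted even when very short; length filtering
#' is a separate stage ([filterByLength()]).
#'
#' @param sequence Protein sequence, or a [Proteome] plus `accession`.
#' @param enzyme An [EnzymeSpec].
#' @param maxMissed Maximum missed cleavages (default 2: cross-linked
#'   lysines suppress tryptic cleavage, so linkable peptides usually carry
#'   missed cleavages).
#' @param accession Parent accession recorded on each peptide row.
#' @return A `DataFrame` with columns `parent_accession`, `sequence`,
#'   `start`, `end` (1-based inclusive), `missed_cleavages`,
#'   `is_protein_nterm`, `is_protein_cterm`.
#' @examples
#' digest("AKRPKE", enzymeSpec("trypsin"), maxMissed = 0)
#' @export
digest <- function(sequence, enzyme = enzymeSpec("trypsin"), maxMissed = 2L,
                   accession = NA_character_) {
  if (methods::is(sequence, "Proteome")) {
    stopifnot(!is.na(accession))
    sequence <- proteinSequence(sequence, accession)
  }
  stopifnot(is.character(sequence), length(sequence) == 1L, maxMissed >= 0)
  res <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  n <- length(res)
  cuts <- .cleavageSites(res, enzyme)
  bounds <- c(0L, cuts, n)          # peptide spans are (bounds[i], bounds[j]]
  nb <- length(bounds)
  rows <- vector("list", 0L)
  for (i in seq_len(nb - 1L)) {
    for (j in (i + 1L):min(nb, i + 1L + maxMissed)) {
      start <- bounds[i] + 1L
      end <- bounds[j]
      rows[[length(rows) + 1L]] <- c(start, end, j - i - 1L)
    }
  }
  m <- do.call(rbind, rows)
  m <- unique(m)
  DataFrame(
    parent_accession = accession,
    sequence = substring(sequence, m[, 1L], m[, 2L]),
    start = m[, 1L], end = m[, 2L],
    missed_cleavages = m[, 3L],
    is_protein_nterm = m[, 1L] == 1L,
    is_protein_cterm = m[, 2L] == n
  )
}

#' Filter peptides by length
#'
#' @param peptides Peptide `DataFrame` from [digest()].
#' @param minLen,maxLen Inclusive length bounds (`1 <= minLen <= maxLen`).
#' @return Rows whose sequence length lies in `[minLen, maxLen]`, order
#'   preserved.
#' @export
filterByLength <- function(peptides, minLen, maxLen) {
  if (minLen < 1 || minLen > maxLen)
    stop("need 1 <= minLen <= maxLen, got [", minLen, ", ", maxLen, "]")
  len <- nchar(peptides$sequence)
  peptides[len >= minLen & len <= maxLen, , drop = FALSE]
}
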