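## Proteome container and UniProt-dialect FASTA I/O.

#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

.STANDARD_RESIDUES <- c("G","A","S","P","V","T","C","L","I","N","D","Q",
                        "K","E","M","H","F","R","Y","W")

## UniProt accession grammar (e.g. P02649, Q6ZWK4, A0A024R161), optional
## "-<n>" isoform suffix.
.ACCESSION_RE <- "^[OPQ][0-9][A-Z0-9]{3}[0-9]|^[A-NR-Z][0-9]([A-Z][A-Z0-9]{2}[0-9]){1,2}"

#' Proteome of reviewed protein entries
#'
#' Holds an [Biostrings::AAStringSet] of sequences together with per-entry
#' metadata parsed from UniProt-dialect FASTA headers
#' (`>sp|ACCESSION|ENTRY_NAME description`).
#'
#' @slot sequences An `AAStringSet`, one element per entry, named by accession.
#' @slot meta A `DataFrame` with columns `accession`, `entry_name`, `db_tag`
#'   (`"sp"`, `"tr"` or `""` for bare-accession headers) and `description`.
#' @export
setClass("Proteome",
  slots = c(sequences = "AAStringSet", meta = "DataFrame"))

setValidity("Proteome", function(object) {
  msgs <- character()
  if (length(object@sequences) != nrow(object@meta))
    msgs <- c(msgs, "sequences and meta must have equal length")
  seqs <- as.character(object@sequences)
  if (any(!nzchar(seqs)))
    msgs <- c(msgs, "sequences must be non-empty")
  bad <- grepl(paste0("[^", paste(.STANDARD_RESIDUES, collapse = ""), "]"), seqs)
  if (any(bad))
    msgs <- c(msgs, paste0("non-standard residues in entry ",
                           object@meta$accession[which(bad)[1L]]))
  if (length(msgs)) msgs else TRUE
})

#' @describeIn Proteome number of entries
#' @param x A `Proteome`.
#' @export
setMethod("length", "Proteome", function(x) length(x@sequences))

setMethod("show", "Proteome", function(object) {
  cat("Proteome with", length(object), "entries\n")
  n <- min(length(object), 5L)
  if (n > 0)
    cat(paste0("  ", object@meta$accession[seq_len(n)], " (",
               object@meta$entry_name[seq_len(n)], "), ",
               width(object@sequences)[seq_len(n)], " aa",
               collapse = "\n"), "\n")
  if (length(object) > n) cat("  ...\n")
})

#' Accessors for Proteome metadata
#'
#' @param x A `Proteome`.
#' @return `accessions()` the accession vector; `proteomeMeta()` the metadata
#'   `DataFrame`; `proteinSequence()` the sequence of one accession as a
#'   character scalar.
#' @export
accessions <- function(x) x@meta$accession

#' @rdname accessions
#' @export
proteomeMeta <- function(x) x@meta

#' @rdname accessions
#' @param accession Accession of the entry to extract.
#' @export
proteinSequence <- function(x, accession) {
  i <- match(accession, x@meta$accession)
  if (is.na(i)) stop("accession '", accession, "' not in proteome")
  as.character(x@sequences[[i]])
}

.parseHeader <- function(header, lineno) {
  ## header excludes the leading ">"
  if (grepl("^(sp|tr)\\|", header)) {
    fields <- strsplit(sub("\\s.*$", "", header), "|", fixed = TRUE)[[1L]]
    if (length(fields) < 3L)
      stop("malformed UniProt header at line ", lineno, ": '>", header,
           "' (expected >sp|ACCESSION|ENTRY_NAME)")
    desc <- sub("^\\S+\\s*", "", header)
    list(db_tag = fields[1L], accession = fields[2L],
         entry_name = fields[3L], description = desc)
  } else {
    acc <- sub("\\s.*$", "", header)
    desc <- sub("^\\S+\\s*", "", header)
    list(db_tag = "", accession = acc, entry_name = acc, description = desc)
  }
}

#' Read a proteome from UniProt-dialect FASTA
#'
#' Accepts both `>sp|ACC|ENTRY_NAME description` / `>tr|...` headers and
#' bare `>ACC` headers. Sequences are whitespace-stripped and uppercased;
#' entry order is preserved. Non-standard residue codes (B, J, O, U, X, Z)
#' and `*` stop characters are rejected so that every downstream mass is
#' exact, naming the offending entry and position.
#'
#' @param path Path to a FASTA file.
#' @return A [Proteome].
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">sp|P99999|TEST_HUMAN Test protein", "PEPTIDEK"), fa)
#' readProteome(fa)
#' @export
readProteome <- function(path) {
  lines <- readLines(path, warn = FALSE)
  headerAt <- grep("^>", lines)
  if (length(lines) && !length(headerAt))
    stop("not a FASTA file: no '>' header found in ", path)
  ## validate headers with their line numbers before handing to Biostrings
  meta <- lapply(seq_along(headerAt), function(i)
    .parseHeader(sub("^>", "", lines[headerAt[i]]), headerAt[i]))

  if (!length(headerAt)) {
    return(methods::new("Proteome",
      sequences = Biostrings::AAStringSet(),
      meta = DataFrame(accession = character(), entry_name = character(),
                       db_tag = character(), description = character())))
  }

  ## sequences are assembled from the raw lines (not readAAStringSet,
  ## which silently drops invalid letters we must reject with a position)
  bounds <- c(headerAt, length(lines) + 1L)
  seqs <- vapply(seq_along(headerAt), function(i) {
    block <- lines[seq(bounds[i] + 1L, length.out = bounds[i + 1L] - bounds[i] - 1L)]
    toupper(gsub("\\s", "", paste(block, collapse = "")))
  }, "")
  for (i in seq_along(seqs)) {
    res <- strsplit(seqs[i], "", fixed = TRUE)[[1L]]
    bad <- which(!res %in% .STANDARD_RESIDUES)
    if (length(bad))
      stop("illegal residue '", res[bad[1L]], "' at position ", bad[1L],
           " of entry ", meta[[i]]$accession)
    if (!nzchar(seqs[i]))
      stop("empty sequence for entry ", meta[[i]]$accession)
  }
  metaDF <- DataFrame(
    accession = vapply(meta, `[[`, "", "accession"),
    entry_name = vapply(meta, `[[`, "", "entry_name"),
    db_tag = vapply(meta, `[[`, "", "db_tag"),
    description = vapply(meta, `[[`, "", "description")
  )
  out <- Biostrings::AAStringSet(seqs)
  names(out) <- metaDF$accession
  methods::new("Proteome", sequences = out, meta = metaDF)
}

#' Write a proteome back to FASTA
#'
#' Emits the same UniProt header dialect [readProteome()] reads, so
#' write/read is the identity on records.
#'
#' @param proteome A [Proteome].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeProteome <- function(proteome, path) {
  m <- proteome@meta
  hdr <- ifelse(nzchar(m$db_tag),
    paste0(m$db_tag, "|", m$accession, "|", m$entry_name,
           ifelse(nzchar(m$description), paste0(" ", m$description), "")),
    paste0(m$accession,
           ifelse(nzchar(m$description), paste0(" ", m$description), "")))
  con <- file(path, "w")
  on.exit(close(con))
  seqs <- as.character(proteome@sequences)
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", hdr[i]), con)
    writeLines(gsub("(.{60})", "\\1\n", seqs[i]), con)
  }
  invisible(path)
}

#' Classify a UniProt accession as canonical or isoform
#'
#' UniProt distinguishes the canonical sequence of an entry from its
#' isoforms by a dash suffix in the accession ("P02649" vs "P02649-2").
#'
#' @param accession Non-empty accession string.
#' @return A list with `kind` (`"canonical"` or `"isoform"`) and
#'   `base_accession` (the part before the dash; the accession itself when
#'   canonical).
#' @examples
#' classifyAccession("P02649-2")
#' @export
classifyAccession <- function(accession) {
  stopifnot(is.character(accession), length(accession) == 1L, nzchar(accession))
  if (grepl("-", accession, fixed = TRUE)) {
    list(kind = "isoform",
         base_accession = sub("-.*$", "", accession))
  } else {
    list(kind = "canonical", base_accession = accession)
  }
}
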