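## STRING-dialect interaction tables, accession mapping and interactor
## ranking with confidence tiers.

#' Load a STRING-style interaction table
#'
#' Whitespace-separated three-column records `protein1 protein2
#' combined_score`, optional header line. STRING distribution files store
#' the combined score as an integer 0-999; with
#' `scoreScale = "string_integer"` scores are divided by 1000 onto the unit
#' interval, with `"unit"` reals in `[0,1]` pass through. Duplicate
#' symmetric rows are deduplicated keeping the maximum score (and the
#' earlier position in the file).
#'
#' @param path Path to the table.
#' @param scoreScale `"string_integer"` or `"unit"`.
#' @return data.frame with `protein_a`, `protein_b`, `combined_score`
#'   (in `[0,1]`) and `input_order` (first-appearance rank of the
#'   undirected edge in the file, used as the deterministic tie-break).
#' @export
loadPPITable <- function(path, scoreScale = c("string_integer", "unit")) {
  scoreScale <- match.arg(scoreScale)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) && grepl("protein1", lines[1L], fixed = TRUE))
    lines <- lines[-1L]
  if (!length(lines))
    return(data.frame(protein_a = character(), protein_b = character(),
                      combined_score = numeric(), input_order = integer()))
  fields <- strsplit(trimws(lines), "\\s+")
  nf <- lengths(fields)
  if (any(nf != 3L))
    stop("line ", which(nf != 3L)[1L] + 1L,
         ": expected 3 whitespace-separated columns, got ", nf[nf != 3L][1L])
  a <- vapply(fields, `[[`, "", 1L)
  b <- vapply(fields, `[[`, "", 2L)
  s <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  if (anyNA(s)) stop("non-numeric combined score at line ", which(is.na(s))[1L])
  if (scoreScale == "string_integer") {
    if (any(s < 0 | s > 999 | s != floor(s)))
      stop("combined score outside 0..999 at line ",
           which(s < 0 | s > 999 | s != floor(s))[1L])
    s <- s / 1000
  } else if (any(s < 0 | s > 1)) {
    stop("combined score outside [0,1] at line ", which(s < 0 | s > 1)[1L])
  }
  if (any(a == b)) stop("self-interaction at line ", which(a == b)[1L])
  df <- data.frame(protein_a = a, protein_b = b, combined_score = s,
                   input_order = seq_along(a), stringsAsFactors = FALSE)
  ## undirected dedup: keep the max score, earliest appearance
  key <- ifelse(df$protein_a < df$protein_b,
                paste(df$protein_a, df$protein_b),
                paste(df$protein_b, df$protein_a))
  keep <- !duplicated(key)
  best <- tapply(df$combined_score, key, max)
  df <- df[keep, , drop = FALSE]
  df$combined_score <- as.numeric(best[ifelse(df$protein_a < df$protein_b,
                                              paste(df$protein_a, df$protein_b),
                                              paste(df$protein_b, df$protein_a))])
  df$input_order <- seq_len(nrow(df))
  rownames(df) <- NULL
  df
}

#' Load a UniProt-to-STRING accession map
#'
#' Two-column TSV `uniprot_accession<TAB>string_id`; many UniProt accessions
#' may map to one STRING identifier. Isoform accessions resolve through
#' their base accession (canonical and isoform share one STRING id).
#'
#' @param path Path to the TSV.
#' @return data.frame with `uniprot` and `string_id`.
#' @export
loadAccessionMap <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          comment.char = "#")
  if (ncol(df) != 2L)
    stop("accession map must have exactly 2 tab-separated columns")
  names(df) <- c("uniprot", "string_id")
  df
}

.mapToString <- function(accession, map) {
  hit <- map$string_id[match(accession, map$uniprot)]
  if (is.na(hit))  # isoform falls back to its base accession
    hit <- map$string_id[match(classifyAccession(accession)$base_accession,
                               map$uniprot)]
  hit
}

#' Confidence tier of a combined score
#'
#' STRING-style tiers with strict thresholds: highest (> 0.9), high
#' (> 0.7), medium (> 0.4), low (> 0.15); anything at or below 0.15 is
#' `below_cutoff`.
#'
#' @param score Numeric vector in `[0,1]`.
#' @return Character vector of tiers.
#' @examples
#' confidenceTier(c(0.999, 0.7, 0.1))
#' @export
confidenceTier <- function(score) {
  if (any(score < 0 | score > 1)) stop("score must lie in [0,1]")
  ifelse(score > 0.9, "highest",
    ifelse(score > 0.7, "high",
      ifelse(score > 0.4, "medium",
        ifelse(score > 0.15, "low", "below_cutoff"))))
}

#' Rank the interactors of a target protein
#'
#' Collects every edge touching the target's STRING id (the table is
#' undirected: the target may appear in either column), maps partners back
#' to UniProt labels `db|ACC|ENTRY_NAME`, sorts by combined score
#' descending -- ties keep their first-appearance order in the interaction
#' table, mirroring STRING's own ranked export -- and truncates to `topN`.
#' Partners with no reverse mapping are kept under their raw STRING id with
#' a warning.
#'
#' @param targetAccession UniProt accession of the target; isoforms resolve
#'   via their base accession.
#' @param edges data.frame from [loadPPITable()].
#' @param map data.frame from [loadAccessionMap()].
#' @param topN Non-negative truncation length.
#' @param proteome Optional [Proteome] used to fill `db_tag` and entry names
#'   in the labels.
#' @return data.frame with `rank`, `label`, `accession`, `combined_score`,
#'   `tier`.
#' @export
queryInteractors <- function(targetAccession, edges, map, topN = 10L,
                             proteome = NULL) {
  stopifnot(topN >= 0)
  tid <- .mapToString(targetAccession, map)
  if (is.na(tid))
    stop("unknown target: accession '", targetAccession,
         "' has no STRING mapping")
  hitA <- edges$protein_a == tid
  hitB <- edges$protein_b == tid
  partner <- c(edges$protein_b[hitA], edges$protein_a[hitB])
  score <- c(edges$combined_score[hitA], edges$combined_score[hitB])
  orderIn <- c(edges$input_order[hitA], edges$input_order[hitB])

  ## reverse map STRING -> UniProt (canonical accessions only)
  canon <- map[!grepl("-", map$uniprot, fixed = TRUE), , drop = FALSE]
  acc <- canon$uniprot[match(partner, canon$string_id)]
  unmapped <- is.na(acc)
  if (any(unmapped)) {
    warning("no UniProt mapping for ", sum(unmapped),
            " partner(s): ", paste(partner[unmapped], collapse = ", "),
            "; kept under raw STRING id")
    acc[unmapped] <- partner[unmapped]
  }
  label <- acc
  if (!is.null(proteome)) {
    m <- proteomeMeta(proteome)
    i <- match(acc, m$accession)
    ok <- !is.na(i)
    label[ok] <- paste0(ifelse(nzchar(m$db_tag[i[ok]]), m$db_tag[i[ok]], "sp"),
                        "|", acc[ok], "|", m$entry_name[i[ok]])
  }
  ord <- order(-score, orderIn)
  n <- min(topN, length(ord))
  ord <- ord[seq_len(n)]
  data.frame(
    rank = seq_len(n),
    label = label[ord],
    accession = acc[ord],
    combined_score = score[ord],
    tier = confidenceTier(score[ord]),
    stringsAsFactors = FALSE
  )
}
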