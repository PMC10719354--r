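## Assembly and CSV export of the SRM transition list.

## Fixed 12-column schema of the transition table.
.TRANSITION_COLUMNS <- c(
  "combined_score", "protein_a_peptide", "cross_linker", "protein_b_peptide",
  "precursor_charge", "precursor_mz", "protein_a_ion", "protein_a_ion_type",
  "protein_b_ion", "protein_b_ion_type", "product_charge", "product_mz")

#' Transition table column names
#' @return The fixed 12-column schema, in order.
#' @export
transitionColumns <- function() .TRANSITION_COLUMNS

.emptyTransitions <- function() data.frame(
  combined_score = numeric(), protein_a_peptide = character(),
  cross_linker = character(), protein_b_peptide = character(),
  precursor_charge = integer(), precursor_mz = numeric(),
  protein_a_ion = character(), protein_a_ion_type = character(),
  protein_b_ion = character(), protein_b_ion_type = character(),
  product_charge = integer(), product_mz = numeric(),
  stringsAsFactors = FALSE)

#' Build the transition table
#'
#' Fans every product out over its fragment ions: one row per (product,
#' fragment-variant, product charge). Peptides are printed with mass-delta
#' bracket annotations (e.g. `"PEPTM[+15.99491]K"`), so each variable
#' modification form appears as its own block of rows. Peptides of products
#' confined to the target alone (A-side loop/mono) leave the protein-B
#' columns empty and carry an `NA` combined score. m/z values are rounded
#' to 6 decimals, the precision the CSV prints.
#'
#' @param products Product `DataFrame` from [enumerateLinkProducts()], with
#'   an optional `combined_score` column attached (NA otherwise).
#' @param linker The [CrossLinker] used for the products.
#' @param productCharges Integer vector of fragment charges.
#' @return data.frame in the fixed 12-column schema, ordered by score
#'   descending (NA last), kind, position, charge.
#' @export
buildTransitionTable <- function(products, linker, productCharges = c(1L, 2L)) {
  if (nrow(products) == 0L) return(.emptyTransitions())
  score <- if ("combined_score" %in% colnames(products))
    products$combined_score else rep(NA_real_, nrow(products))
  ## score descending, NA (target-only products) last; ties keep the
  ## deterministic product order established by enumerateLinkProducts()
  ord <- order(is.na(score), -ifelse(is.na(score), 0, score))
  products <- as.data.frame(products)[ord, , drop = FALSE]
  score <- score[ord]

  blocks <- lapply(seq_len(nrow(products)), function(i) {
    p <- lapply(products, `[[`, i)
    fr <- .fragmentIonsCore(p, linker, productCharges)
    if (nrow(fr) == 0L) return(NULL)
    ## route the carrying peptide / fragments to the A or B columns
    bSide <- p$kind %in% c("loop_link_B", "mono_link") && p$of_protein == "B"
    pepA <- if (bSide) "" else p$alpha_annotated
    pepB <- if (p$kind == "inter_link") p$beta_annotated
            else if (bSide) p$alpha_annotated else ""
    fromA <- if (bSide) rep(FALSE, nrow(fr)) else fr$of_peptide == "alpha"
    list(
      combined_score = rep(score[i], nrow(fr)),
      protein_a_peptide = rep(pepA, nrow(fr)),
      cross_linker = rep(p$linker, nrow(fr)),
      protein_b_peptide = rep(pepB, nrow(fr)),
      precursor_charge = rep(p$precursor_charge, nrow(fr)),
      precursor_mz = rep(round(p$precursor_mz, 6), nrow(fr)),
      protein_a_ion = ifelse(fromA, fr$ion_label, ""),
      protein_a_ion_type = ifelse(fromA, fr$series, ""),
      protein_b_ion = ifelse(fromA, "", fr$ion_label),
      protein_b_ion_type = ifelse(fromA, "", fr$series),
      product_charge = fr$charge,
      product_mz = round(fr$mz, 6))
  })
  blocks <- Filter(Negate(is.null), blocks)
  if (!length(blocks)) return(.emptyTransitions())
  out <- data.frame(
    lapply(stats::setNames(nm = .TRANSITION_COLUMNS), function(col)
      unlist(lapply(blocks, `[[`, col), use.names = FALSE)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

.fmt6 <- function(x) ifelse(is.na(x), "", sprintf("%.6f", x))

#' Export a transition table to CSV
#'
#' RFC 4180 CSV, UTF-8, header row with the 12 column names, m/z printed
#' as 6-decimal fixed point. An optional vector of externally supplied
#' peptide-response scores (e.g. Prego output) can be passed through as a
#' 13th `response_score` column; it is never computed internally.
#'
#' @param rows data.frame from [buildTransitionTable()].
#' @param path Output path.
#' @param responseScores Optional numeric vector, one per row.
#' @return `path`, invisibly.
#' @export
exportTransitions <- function(rows, path, responseScores = NULL) {
  out <- rows[, .TRANSITION_COLUMNS, drop = FALSE]
  out$precursor_mz <- .fmt6(out$precursor_mz)
  out$product_mz <- .fmt6(out$product_mz)
  out$combined_score <- ifelse(is.na(out$combined_score), "",
                               format(out$combined_score, trim = TRUE))
  if (!is.null(responseScores)) {
    stopifnot(length(responseScores) == nrow(out))
    out$response_score <- responseScores
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' Read a transition table back from CSV
#'
#' Inverse of [exportTransitions()]: `readTransitions(exportTransitions(x))`
#' reproduces `x`.
#'
#' @param path CSV path.
#' @return data.frame in the 12-column schema.
#' @export
readTransitions <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("combined_score", "precursor_mz", "product_mz"))
    df[[col]] <- as.numeric(df[[col]])
  for (col in c("precursor_charge", "product_charge"))
    df[[col]] <- as.integer(df[[col]])
  for (col in c("protein_a_peptide", "protein_b_peptide", "protein_a_ion",
                "protein_a_ion_type", "protein_b_ion", "protein_b_ion_type"))
    df[[col]] <- ifelse(is.na(df[[col]]), "", as.character(df[[col]]))
  df
}

#' Export the ranked interactor table
#'
#' Writes the interactor list (rank, label, combined score, confidence
#' tier) as its own CSV, mirroring the two-table result layout.
#'
#' @param interactors data.frame from [queryInteractors()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
exportInteractors <- function(interactors, path) {
  utils::write.csv(interactors[, c("rank", "label", "combined_score", "tier")],
                   path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
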