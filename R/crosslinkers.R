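## Cross-linker catalog and reactive-site location.
##
## A linker is described by five attributes: reactive specificity per side,
## spacer arm length, cleavability, and its mass values, split between the
## intact (non-cleaved) delta and the remnant masses left on each peptide
## by gas-phase cleavage of an MS-cleavable spacer.

#' Cross-linker
#'
#' @slot name Linker name (e.g. "DSSO").
#' @slot siteA,siteB Residue letters reactive on each side.
#' @slot ntermReactive When `TRUE`, amine-reactive sides (those targeting K)
#'   also react with the protein N-terminal alpha-amine.
#' @slot spacerArm Spacer arm length in Angstrom (metadata only; no distance
#'   filtering is performed).
#' @slot cleavable Whether the spacer fragments in the mass spectrometer.
#' @slot intactDelta Mass added when both sides are conjugated (Da).
#' @slot remnantA,remnantB Parallel vectors of remnant masses per cleavage
#'   channel; `remnantA[i] + remnantB[i] == intactDelta` (conservation).
#'   Empty for non-cleavable linkers.
#' @export
setClass("CrossLinker",
  slots = c(name = "character", siteA = "character", siteB = "character",
            ntermReactive = "logical", spacerArm = "numeric",
            cleavable = "logical", intactDelta = "numeric",
            remnantA = "numeric", remnantB = "numeric"))

setValidity("CrossLinker", function(object) {
  msgs <- character()
  if (length(object@remnantA) != length(object@remnantB))
    msgs <- c(msgs, "remnantA and remnantB must be parallel")
  if (object@cleavable && !length(object@remnantA))
    msgs <- c(msgs, "cleavable linker must have at least one remnant pair")
  if (!object@cleavable && length(object@remnantA))
    msgs <- c(msgs, "non-cleavable linker must have no remnant pairs")
  bad <- abs(object@remnantA + object@remnantB - object@intactDelta) > 1e-3
  if (any(bad))
    msgs <- c(msgs, paste0("remnant pair ", which(bad)[1L], " of ",
                           object@name, " does not sum to the intact delta"))
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "CrossLinker", function(object) {
  cat("CrossLinker:", object@name,
      sprintf("(%+.5f Da, %s)", object@intactDelta,
              if (object@cleavable) "MS-cleavable" else "non-cleavable"), "\n")
  cat("  side A: [", paste(object@siteA, collapse = ""),
      "]  side B: [", paste(object@siteB, collapse = ""), "]",
      if (object@ntermReactive) " + protein N-terminus", "\n", sep = "")
  if (object@cleavable)
    cat("  remnant pairs:",
        paste(sprintf("%.5f/%.5f", object@remnantA, object@remnantB),
              collapse = ", "), "\n")
})

#' Is a cleavable linker symmetric?
#'
#' A cleavable linker is symmetric when every remnant pair deposits the same
#' mass on both peptides; the fragment arithmetic then needs only one
#' remnant variant per link-spanning fragment.
#'
#' @param linker A [CrossLinker].
#' @return Logical scalar; `FALSE` for non-cleavable linkers.
#' @export
isSymmetric <- function(linker) {
  linker@cleavable && all(abs(linker@remnantA - linker@remnantB) < 1e-6)
}

.parseRemnants <- function(x) {
  ## "a1:b1;a2:b2" -> list(A = ..., B = ...)
  if (is.na(x) || !nzchar(x)) return(list(A = numeric(), B = numeric()))
  pairs <- strsplit(strsplit(x, ";", fixed = TRUE)[[1L]], ":", fixed = TRUE)
  list(A = vapply(pairs, function(p) as.numeric(p[1L]), 0),
       B = vapply(pairs, function(p) as.numeric(p[2L]), 0))
}

#' Load a cross-linker catalog from CSV
#'
#' Schema: `name,site_a,site_b,nterm_reactive,spacer_arm_A,cleavable,`
#' `intact_delta,remnant_pairs` with `remnant_pairs` encoded `a1:b1;a2:b2`.
#' The remnant conservation invariant (each pair sums to the intact delta)
#' is checked at load and violations abort with the linker's name. When
#' `merge` is TRUE the rows are merged over the bundled catalog by name, so
#' users can override or extend shipped linkers.
#'
#' @param path CSV path; `NULL` loads only the bundled catalog.
#' @param merge Merge user rows over the bundled catalog (default TRUE when
#'   `path` is given).
#' @return Named list of [CrossLinker] objects.
#' @examples
#' cat <- loadLinkerCatalog()
#' cat[["DSSO"]]
#' @export
loadLinkerCatalog <- function(path = NULL, merge = !is.null(path)) {
  bundled <- system.file("extdata", "crosslinkers.csv", package = "xlinkr",
                         mustWork = TRUE)
  df <- utils::read.csv(bundled, stringsAsFactors = FALSE, comment.char = "#")
  if (!is.null(path)) {
    user <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
    df <- if (merge) rbind(df[!df$name %in% user$name, ], user) else user
  }
  linkers <- lapply(seq_len(nrow(df)), function(i) {
    rem <- .parseRemnants(df$remnant_pairs[i])
    lk <- try(methods::new("CrossLinker",
      name = df$name[i],
      siteA = .parseTargets(df$site_a[i]),
      siteB = .parseTargets(df$site_b[i]),
      ntermReactive = as.logical(df$nterm_reactive[i]),
      spacerArm = as.numeric(df$spacer_arm_A[i]),
      cleavable = as.logical(df$cleavable[i]),
      intactDelta = as.numeric(df$intact_delta[i]),
      remnantA = rem$A, remnantB = rem$B), silent = TRUE)
    if (inherits(lk, "try-error"))
      stop("invalid catalog entry '", df$name[i], "': ",
           attr(lk, "condition")$message)
    lk
  })
  names(linkers) <- df$name
  linkers
}

#' Locate linkable sites on a peptide
#'
#' Returns every position whose residue is in the chosen side's target set,
#' with two boundary rules: (1) the peptide's C-terminal residue is excluded
#' when that position was produced by enzymatic cleavage on it (a conjugated
#' lysine blocks trypsin, so a cleaved site cannot also carry the linker;
#' disable with `excludeCleavedCterm = FALSE`); (2) position 0 denotes the
#' protein N-terminal alpha-amine and is included when the peptide starts
#' the protein and the linker side is amine-reactive.
#'
#' @param peptide One row of the [digest()] `DataFrame` (or a list with the
#'   same fields).
#' @param linker A [CrossLinker].
#' @param side `"A"` or `"B"`.
#' @param excludeCleavedCterm Apply rule (1) (default TRUE).
#' @return Integer vector of positions (0 = protein N-terminus).
#' @export
linkableSites <- function(peptide, linker, side = c("A", "B"),
                          excludeCleavedCterm = TRUE) {
  side <- match.arg(side)
  targets <- if (side == "A") linker@siteA else linker@siteB
  seq <- peptide$sequence
  res <- strsplit(seq, "", fixed = TRUE)[[1L]]
  n <- length(res)
  hits <- which(res %in% targets)
  if (excludeCleavedCterm && !isTRUE(peptide$is_protein_cterm))
    hits <- hits[hits != n]
  amine <- "K" %in% targets && linker@ntermReactive
  if (amine && isTRUE(peptide$is_protein_nterm))
    hits <- c(0L, hits)
  as.integer(hits)
}
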