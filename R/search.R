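## End-to-end search: configuration object and pipeline orchestration.

#' Search configuration
#'
#' Mirrors the search form of a targeted XL-MS transition calculator: the
#' target, the digestion and linking chemistry, peptide length window,
#' interactor ranking depth, charge sets, modifications, and input paths.
#'
#' @slot targetAccession UniProt accession of the target protein.
#' @slot enzyme Enzyme name ("trypsin" or "chymotrypsin").
#' @slot linker Cross-linker name (resolved against the catalog).
#' @slot minLen,maxLen Peptide length window (inclusive).
#' @slot topN Number of ranked interactors to keep.
#' @slot precursorCharges,productCharges Integer charge sets; they may
#'   overlap.
#' @slot modifications Modification table (see [defaultModifications()]).
#' @slot maxMissed Maximum missed cleavages.
#' @slot proteomePath,ppiPath,mapPath Input file paths.
#' @slot linkerCatalogPath Optional user linker catalog CSV (merged over
#'   the bundled one); `NA` for bundled only.
#' @slot scoreScale Score scale of the interaction table
#'   ("string_integer" or "unit").
#' @slot allowHomodimers Emit A-A / B-B inter-links too.
#' @export
setClass("SearchConfig",
  slots = c(targetAccession = "character", enzyme = "character",
            linker = "character", minLen = "integer", maxLen = "integer",
            topN = "integer", precursorCharges = "integer",
            productCharges = "integer", modifications = "data.frame",
            maxMissed = "integer", proteomePath = "character",
            ppiPath = "character", mapPath = "character",
            linkerCatalogPath = "character", scoreScale = "character",
            allowHomodimers = "logical"))

setValidity("SearchConfig", function(object) {
  msgs <- character()
  if (!nzchar(object@targetAccession)) msgs <- c(msgs, "target is required")
  if (object@minLen < 1 || object@minLen > object@maxLen)
    msgs <- c(msgs, "need 1 <= minLen <= maxLen")
  if (object@topN < 0) msgs <- c(msgs, "topN must be >= 0")
  if (any(object@precursorCharges < 1) || any(object@productCharges < 1))
    msgs <- c(msgs, "charges must be positive integers")
  if (object@maxMissed < 0) msgs <- c(msgs, "maxMissed must be >= 0")
  if (!object@scoreScale %in% c("string_integer", "unit"))
    msgs <- c(msgs, "scoreScale must be 'string_integer' or 'unit'")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "SearchConfig", function(object) {
  cat("SearchConfig: target", object@targetAccession,
      "|", object@enzyme, "|", object@linker, "\n")
  cat("  peptide length", object@minLen, "-", object@maxLen,
      "| top", object@topN, "interactors | <=",
      object@maxMissed, "missed cleavages\n")
  cat("  precursor z {", paste(object@precursorCharges, collapse = ","),
      "} product z {", paste(object@productCharges, collapse = ","), "}\n")
})

#' Build a search configuration
#'
#' @param targetAccession Target UniProt accession (e.g. "P02649").
#' @param proteome,ppi,map Paths to the proteome FASTA, interaction table
#'   and accession-map TSV.
#' @param enzyme,linker Enzyme and cross-linker names.
#' @param minLen,maxLen Peptide length window (default 6-10).
#' @param topN Ranked interactors to keep (default 10).
#' @param precursorCharges,productCharges Charge sets (defaults 2,3 / 1,2).
#' @param modifications Modification table (default: carbamidomethyl
#'   static + oxidation variable).
#' @param maxMissed Missed-cleavage ceiling (default 2: a conjugated lysine
#'   blocks trypsin, so linkable peptides need missed cleavages).
#' @param linkerCatalog Optional user catalog CSV path.
#' @param scoreScale Interaction-table score scale.
#' @param allowHomodimers Emit homodimeric inter-links (default FALSE).
#' @return A validated [SearchConfig].
#' @export
searchConfig <- function(targetAccession, proteome, ppi, map,
                         enzyme = "trypsin", linker = "DSSO",
                         minLen = 6L, maxLen = 10L, topN = 10L,
                         precursorCharges = c(2L, 3L),
                         productCharges = c(1L, 2L),
                         modifications = defaultModifications(),
                         maxMissed = 2L, linkerCatalog = NA_character_,
                         scoreScale = "string_integer",
                         allowHomodimers = FALSE) {
  methods::new("SearchConfig",
    targetAccession = targetAccession, enzyme = enzyme, linker = linker,
    minLen = as.integer(minLen), maxLen = as.integer(maxLen),
    topN = as.integer(topN),
    precursorCharges = as.integer(precursorCharges),
    productCharges = as.integer(productCharges),
    modifications = as.data.frame(modifications),
    maxMissed = as.integer(maxMissed),
    proteomePath = proteome, ppiPath = ppi, mapPath = map,
    linkerCatalogPath = linkerCatalog, scoreScale = scoreScale,
    allowHomodimers = allowHomodimers)
}

.configError <- function(...) {
  stop(structure(class = c("xlinkr_config_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

#' Run a full transition-list search
#'
#' The pipeline: rank interactors -> digest and length-filter the target
#' and each interactor -> expand modification forms -> locate linkable
#' sites -> enumerate the four product classes -> generate b/y fragments ->
#' assemble the two result tables. Target-only loop/mono products are
#' emitted once (not per interactor) and carry an `NA` combined score.
#' Re-running with identical inputs is byte-identical: the pipeline has no
#' randomness.
#'
#' @param config A [SearchConfig].
#' @param verbose Log per-stage counts to stderr.
#' @return List with `interactors` (ranked table), `transitions` (12-column
#'   transition table), `products` (product `DataFrame` with scores) and
#'   `log` (named stage counts).
#' @export
runSearch <- function(config, verbose = FALSE) {
  stopifnot(methods::is(config, "SearchConfig"))
  methods::validObject(config)
  note <- function(...) if (verbose) message("[xlinkr] ", ...)

  if (!config@enzyme %in% c("trypsin", "chymotrypsin"))
    .configError("unknown enzyme '", config@enzyme,
                 "'; valid: trypsin, chymotrypsin")
  catalog <- loadLinkerCatalog(
    if (is.na(config@linkerCatalogPath)) NULL else config@linkerCatalogPath)
  if (!config@linker %in% names(catalog))
    .configError("unknown cross-linker '", config@linker, "'; valid: ",
                 paste(names(catalog), collapse = ", "))
  linker <- catalog[[config@linker]]
  enzyme <- enzymeSpec(config@enzyme)

  proteome <- readProteome(config@proteomePath)
  edges <- loadPPITable(config@ppiPath, config@scoreScale)
  map <- loadAccessionMap(config@mapPath)
  note("loaded ", length(proteome), " proteins, ", nrow(edges), " edges")

  if (!config@targetAccession %in% accessions(proteome))
    stop("target '", config@targetAccession, "' not found in the proteome")

  interactors <- queryInteractors(config@targetAccession, edges, map,
                                  config@topN, proteome)
  note("ranked ", nrow(interactors), " interactors")

  modforms <- function(acc) {
    peps <- digest(proteome, enzyme, config@maxMissed, accession = acc)
    peps <- filterByLength(peps, config@minLen, config@maxLen)
    modformTable(peps, config@modifications)
  }
  mfA <- modforms(config@targetAccession)
  note("target: ", nrow(mfA), " peptide modification forms in length window")

  emptyMf <- mfA[0L, , drop = FALSE]

  ## target-only loop/mono products, once
  productBlocks <- list()
  pA <- enumerateLinkProducts(mfA, emptyMf, linker, config@precursorCharges,
                              allowHomodimers = FALSE,
                              singleSides = "A")
  if (nrow(pA)) pA$combined_score <- NA_real_
  productBlocks[["target"]] <- pA

  for (i in seq_len(nrow(interactors))) {
    acc <- interactors$accession[i]
    if (!acc %in% accessions(proteome)) {
      warning("interactor ", acc, " has no proteome entry; skipped")
      next
    }
    mfB <- modforms(acc)
    p <- enumerateLinkProducts(mfA, mfB, linker, config@precursorCharges,
                               allowHomodimers = config@allowHomodimers,
                               singleSides = "B")
    if (nrow(p)) {
      p$combined_score <- interactors$combined_score[i]
      productBlocks[[acc]] <- p
    }
    note("interactor ", acc, ": ", nrow(mfB), " forms, ", nrow(p), " products")
  }
  products <- do.call(rbind, productBlocks)
  if (is.null(products)) {
    products <- .emptyProducts()
    products$combined_score <- numeric()
  }

  transitions <- buildTransitionTable(products, linker, config@productCharges)
  note(nrow(products), " products -> ", nrow(transitions), " transition rows")

  log <- c(n_proteins = length(proteome), n_edges = nrow(edges),
           n_interactors = nrow(interactors),
           n_target_modforms = nrow(mfA),
           n_products = nrow(products),
           n_inter_link = sum(products$kind == "inter_link"),
           n_loop_link = sum(products$kind %in% c("loop_link_A", "loop_link_B")),
           n_mono_link = sum(products$kind == "mono_link"),
           n_transitions = nrow(transitions))
  list(interactors = interactors, transitions = transitions,
       products = products, log = log)
}
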