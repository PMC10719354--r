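## Self-contained test inputs: a desk-scale bundle around the APOE top-10
## interactor table, and seeded synthetic proteomes. Nothing is downloaded.

## The published APOE (P02649) top-10 interactor list with its STRING
## combined scores, in printed rank order. Sequences bundled with it are
## synthetic stand-ins (see apoeFixture); only accessions, entry names and
## scores are real.
.APOE_TABLE <- data.frame(
  rank = 1:10,
  accession = c("Q07954", "Q14114", "P04114", "P05067", "P01130",
                "P02647", "P10636", "P98155", "Q9NZC2", "Q92673"),
  entry_name = c("LRP1_HUMAN", "LRP8_HUMAN", "APOB_HUMAN", "A4_HUMAN",
                 "LDLR_HUMAN", "APOA1_HUMAN", "TAU_HUMAN", "VLDLR_HUMAN",
                 "TREM2_HUMAN", "SORL_HUMAN"),
  combined_score = c(0.999, 0.999, 0.998, 0.998, 0.998,
                     0.997, 0.997, 0.997, 0.995, 0.995),
  stringsAsFactors = FALSE
)

## Deterministic synthetic stand-in sequence for fixture protein i.
## Each contains the tryptic 9-mer "xxMKxxxER" (i = 0, the target) or
## "xxxKxxxER" with an internal, linkable lysine reachable with one missed
## cleavage, plus a cysteine so static carbamidomethylation is exercised.
.standInSequence <- function(i) {
  fill <- c("A", "S", "T", "V", "L", "I", "G", "N", "Q", "D", "E")
  a <- fill[(i %% 11L) + 1L]
  b <- fill[((i + 3L) %% 11L) + 1L]
  core <- if (i == 0L) paste0("AAMK", "DDD", "ER")      # M: variable oxidation
          else paste0(a, a, b, "K", b, a, b, "ER")       # length 9, K at 4
  paste0("MG", a, "CR", core, "GG", b, "K")
}

#' The bundled APOE fixture
#'
#' Writes a deterministic, byte-stable bundle emulating the published APOE
#' worked example: an 11-entry proteome FASTA (APOE plus its ten top-ranked
#' partners; the sequences are short synthetic stand-ins with controlled
#' lysine placement, NOT the real proteins), a STRING-dialect interaction
#' table carrying the ten published combined scores in printed rank order
#' (integer 0-999 scale) plus one partner-partner distractor edge, and a
#' UniProt-to-STRING accession map.
#'
#' @param dir Directory to write into (created if needed).
#' @return List with `proteome`, `ppi`, `map` (file paths), `table1` (the
#'   published rank/accession/score table) and `provenance` (per-record
#'   origin: `"paper_table_1"` for accessions/scores, `"synthetic"` for all
#'   sequences).
#' @examples
#' fx <- apoeFixture(tempfile("apoe"))
#' readProteome(fx$proteome)
#' @export
apoeFixture <- function(dir = tempfile("apoe_fixture")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tab <- .APOE_TABLE
  acc <- c("P02649", tab$accession)
  entry <- c("APOE_HUMAN", tab$entry_name)
  stringId <- sprintf("9606.ENSPSYN%05d", seq_along(acc) - 1L)

  fasta <- character()
  for (i in seq_along(acc)) {
    fasta <- c(fasta,
      paste0(">sp|", acc[i], "|", entry[i],
             " synthetic stand-in sequence (fixture)"),
      .standInSequence(i - 1L))
  }
  proteomePath <- file.path(dir, "proteome.fasta")
  writeLines(fasta, proteomePath)

  ## target-partner edges in printed rank order + one distractor edge
  ppi <- c("protein1 protein2 combined_score",
           paste(stringId[1L], stringId[-1L],
                 as.integer(round(tab$combined_score * 1000))),
           paste(stringId[2L], stringId[3L], 900L))
  ppiPath <- file.path(dir, "ppi_links.txt")
  writeLines(ppi, ppiPath)

  mapPath <- file.path(dir, "accession_map.tsv")
  writeLines(paste(acc, stringId, sep = "\t"), mapPath)

  list(proteome = proteomePath, ppi = ppiPath, map = mapPath,
       table1 = tab,
       provenance = data.frame(
         accession = acc,
         scores = c(NA, rep("paper_table_1", nrow(tab))),
         sequence = "synthetic", stringsAsFactors = FALSE))
}

#' Generate a seeded synthetic proteome
#'
#' Random sequences over the 20 standard residues with controllable
#' frequencies for chosen residues (typically the cleavage/linkage-relevant
#' K, R, F, W, Y), so digestion and site-location tests have predictable
#' structure. Reproducible: the same `(seed, parameters)` always yield the
#' same proteome; the caller's RNG state is left untouched.
#'
#' @param n Number of proteins (>= 1).
#' @param lengthRange Inclusive length bounds.
#' @param density Named numeric vector of per-position probabilities for
#'   specific residues (e.g. `c(K = 0.1, R = 0.05)`); the remaining
#'   probability mass is spread uniformly over the unnamed residues. Values
#'   must be in `[0, 1)` and sum to less than 1.
#' @param seed Integer seed.
#' @return A [Proteome] with accessions `P0S001`, `P0S002`, ...
#' @examples
#' synthProteome(3, c(20, 40), c(K = 0.1), seed = 1)
#' @export
synthProteome <- function(n, lengthRange = c(30L, 60L),
                          density = c(K = 0.08, R = 0.08), seed = 1L) {
  stopifnot(n >= 1, length(lengthRange) == 2L,
            lengthRange[1L] >= 1, lengthRange[1L] <= lengthRange[2L])
  if (length(density)) {
    if (is.null(names(density)) || !all(names(density) %in% .STANDARD_RESIDUES))
      stop("density must be named by standard residue letters")
    if (any(density < 0 | density >= 1) || sum(density) >= 1)
      stop("density values must lie in [0,1) and sum to < 1")
  }
  probs <- stats::setNames(rep(0, 20L), .STANDARD_RESIDUES)
  probs[names(density)] <- density
  rest <- setdiff(.STANDARD_RESIDUES, names(density))
  probs[rest] <- (1 - sum(density)) / length(rest)

  oldSeed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(oldSeed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", oldSeed, envir = globalenv())
  })
  set.seed(seed)

  lens <- sample(seq(lengthRange[1L], lengthRange[2L]), n, replace = TRUE)
  seqs <- vapply(lens, function(L)
    paste(sample(.STANDARD_RESIDUES, L, replace = TRUE, prob = probs),
          collapse = ""), "")
  accs <- sprintf("P0S%03d", seq_len(n))
  aa <- Biostrings::AAStringSet(seqs)
  names(aa) <- accs
  methods::new("Proteome", sequences = aa,
    meta = DataFrame(accession = accs,
                     entry_name = sprintf("SYN%03d_TEST", seq_len(n)),
                     db_tag = "sp",
                     description = sprintf("synthetic protein (seed %d)",
                                           as.integer(seed))))
}
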