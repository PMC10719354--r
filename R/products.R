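## Enumeration of the four cross-link product classes and their b/y
## fragment ions, including MS-cleavable remnant arithmetic.
##
## Product classes for a target (protein A) / interactor (protein B) pair:
##   inter_link  - two peptides joined through the linker
##   loop_link_A - both linker ends on one protein-A peptide
##   loop_link_B - both linker ends on one protein-B peptide
##   mono_link   - one end conjugated, the other hydrolyzed (dead-end)

#' Expand digested peptides into modification forms
#'
#' Applies [enumerateModForms()] to every peptide row, carrying the
#' peptide's coordinates and terminal flags onto each form.
#'
#' @param peptides `DataFrame` from [digest()]/[filterByLength()].
#' @param modifications Modification table ([defaultModifications()]).
#' @param cap Per-peptide expansion cap.
#' @return `DataFrame` with the peptide columns plus `annotated`,
#'   `mod_sites` and `neutral_mass` (one row per form).
#' @export
modformTable <- function(peptides, modifications = defaultModifications(),
                         cap = 1024L) {
  if (nrow(peptides) == 0L) {
    return(DataFrame(parent_accession = character(), sequence = character(),
                     start = integer(), end = integer(),
                     missed_cleavages = integer(),
                     is_protein_nterm = logical(), is_protein_cterm = logical(),
                     annotated = character(), mod_sites = character(),
                     neutral_mass = numeric()))
  }
  out <- lapply(seq_len(nrow(peptides)), function(i) {
    forms <- enumerateModForms(peptides$sequence[i], modifications, cap)
    cbind(peptides[rep(i, nrow(forms)), , drop = FALSE], DataFrame(forms))
  })
  do.call(rbind, out)
}

.emptyProducts <- function() DataFrame(
  kind = character(), of_protein = character(),
  alpha_sequence = character(), alpha_annotated = character(),
  alpha_mods = character(), alpha_mass = numeric(),
  alpha_accession = character(), site1 = integer(), site2 = integer(),
  beta_sequence = character(), beta_annotated = character(),
  beta_mods = character(), beta_mass = numeric(),
  beta_accession = character(),
  linker = character(), neutral_mass = numeric(),
  precursor_charge = integer(), precursor_mz = numeric())

.productRow <- function(kind, ofProtein, alpha, site1, site2 = NA_integer_,
                        beta = NULL, linker, neutralMass) {
  list(
    kind = kind, of_protein = ofProtein,
    alpha_sequence = alpha$sequence, alpha_annotated = alpha$annotated,
    alpha_mods = alpha$mod_sites, alpha_mass = alpha$neutral_mass,
    alpha_accession = alpha$parent_accession,
    site1 = as.integer(site1), site2 = as.integer(site2),
    beta_sequence = if (is.null(beta)) NA_character_ else beta$sequence,
    beta_annotated = if (is.null(beta)) NA_character_ else beta$annotated,
    beta_mods = if (is.null(beta)) NA_character_ else beta$mod_sites,
    beta_mass = if (is.null(beta)) NA_real_ else beta$neutral_mass,
    beta_accession = if (is.null(beta)) NA_character_ else beta$parent_accession,
    linker = linker@name, neutral_mass = neutralMass,
    precursor_charge = NA_integer_, precursor_mz = NA_real_)
}

## bind a list of .productRow() lists into one DataFrame
.bindProductRows <- function(rows) {
  col <- function(name, how) vapply(rows, `[[`, how, name)
  DataFrame(
    kind = col("kind", ""), of_protein = col("of_protein", ""),
    alpha_sequence = col("alpha_sequence", ""),
    alpha_annotated = col("alpha_annotated", ""),
    alpha_mods = col("alpha_mods", ""),
    alpha_mass = col("alpha_mass", 0),
    alpha_accession = col("alpha_accession", ""),
    site1 = col("site1", 0L), site2 = col("site2", 0L),
    beta_sequence = col("beta_sequence", ""),
    beta_annotated = col("beta_annotated", ""),
    beta_mods = col("beta_mods", ""),
    beta_mass = col("beta_mass", 0),
    beta_accession = col("beta_accession", ""),
    linker = col("linker", ""), neutral_mass = col("neutral_mass", 0),
    precursor_charge = col("precursor_charge", 0L),
    precursor_mz = col("precursor_mz", 0))
}

## loop-link site pairs on one peptide: one side-A site and one distinct
## side-B site, deduplicated as unordered pairs.
.loopPairs <- function(sitesA, sitesB) {
  if (!length(sitesA) || !length(sitesB)) return(NULL)
  grid <- expand.grid(a = sitesA, b = sitesB)
  grid <- grid[grid$a != grid$b, , drop = FALSE]
  if (!nrow(grid)) return(NULL)
  lo <- pmin(grid$a, grid$b); hi <- pmax(grid$a, grid$b)
  unique(data.frame(s1 = lo, s2 = hi))
}

#' Enumerate cross-link products over two peptide universes
#'
#' Builds every inter-link over (A-site x B-site) pairs, every loop-link
#' over single peptides carrying two distinct reactive sites, and every
#' mono-link (dead-end) over single peptides with at least one site, each
#' replicated over the requested precursor charges. A mono-link's mass adds
#' the intact linker delta plus water for the hydrolyzed free end. Output
#' order is deterministic: kind, accession, position, charge.
#'
#' @param modformsA,modformsB Modform `DataFrame`s ([modformTable()]) for
#'   the target (A) and one interactor (B); `modformsB` may have zero rows,
#'   yielding only A-side loop/mono products.
#' @param linker A [CrossLinker].
#' @param precursorCharges Integer vector of precursor charges.
#' @param allowHomodimers Also emit A-A and B-B inter-links (default FALSE;
#'   the default reproduces the target-by-interactor table).
#' @param excludeCleavedCterm Passed to [linkableSites()].
#' @param singleSides Which sides contribute single-peptide (loop/mono)
#'   products; subset of `c("A", "B")`. Orchestration uses this to emit
#'   target-only products once rather than once per interactor.
#' @return Product `DataFrame`; see package vignette for the column schema.
#' @export
enumerateLinkProducts <- function(modformsA, modformsB, linker,
                                  precursorCharges = c(2L, 3L),
                                  allowHomodimers = FALSE,
                                  excludeCleavedCterm = TRUE,
                                  singleSides = c("A", "B")) {
  water <- .WATER_MASS
  rows <- list()
  addRow <- function(x) rows[[length(rows) + 1L]] <<- x

  siteCache <- function(modforms) {
    lapply(seq_len(nrow(modforms)), function(i) {
      p <- as.list(modforms[i, , drop = FALSE])
      list(A = linkableSites(p, linker, "A", excludeCleavedCterm),
           B = linkableSites(p, linker, "B", excludeCleavedCterm))
    })
  }
  sA <- siteCache(modformsA)
  sB <- siteCache(modformsB)

  interOver <- function(mfX, sX, mfY, sY) {
    for (i in seq_len(nrow(mfX))) {
      if (!length(sX[[i]]$A)) next
      for (j in seq_len(nrow(mfY))) {
        if (!length(sY[[j]]$B)) next
        a <- as.list(mfX[i, , drop = FALSE])
        b <- as.list(mfY[j, , drop = FALSE])
        for (pa in sX[[i]]$A) for (pb in sY[[j]]$B)
          addRow(.productRow("inter_link", "AB", a, pa, pb, b, linker,
                             a$neutral_mass + b$neutral_mass +
                               linker@intactDelta))
      }
    }
  }
  interOver(modformsA, sA, modformsB, sB)
  if (allowHomodimers) {
    interOver(modformsA, sA, modformsA, sA)
    interOver(modformsB, sB, modformsB, sB)
  }

  loopMono <- function(modforms, sites, loopKind, ofProtein) {
    for (i in seq_len(nrow(modforms))) {
      p <- as.list(modforms[i, , drop = FALSE])
      pairs <- .loopPairs(sites[[i]]$A, sites[[i]]$B)
      for (r in seq_len(NROW(pairs)))
        addRow(.productRow(loopKind, ofProtein, p, pairs$s1[r], pairs$s2[r],
                           NULL, linker,
                           p$neutral_mass + linker@intactDelta))
      for (s in sort(unique(c(sites[[i]]$A, sites[[i]]$B))))
        addRow(.productRow("mono_link", ofProtein, p, s, NA_integer_,
                           NULL, linker,
                           p$neutral_mass + linker@intactDelta + water))
    }
  }
  if ("A" %in% singleSides) loopMono(modformsA, sA, "loop_link_A", "A")
  if ("B" %in% singleSides) loopMono(modformsB, sB, "loop_link_B", "B")

  if (!length(rows)) return(.emptyProducts())
  prod <- .bindProductRows(rows)

  ## cross with precursor charges, then order deterministically
  z <- as.integer(sort(unique(precursorCharges)))
  prod <- prod[rep(seq_len(nrow(prod)), each = length(z)), , drop = FALSE]
  prod$precursor_charge <- rep(z, length.out = nrow(prod))
  prod$precursor_mz <- mz(prod$neutral_mass, prod$precursor_charge)
  ord <- order(match(prod$kind, c("inter_link", "loop_link_A", "loop_link_B",
                                  "mono_link")),
               prod$alpha_accession, prod$alpha_sequence, prod$alpha_annotated,
               prod$site1, prod$site2, prod$beta_accession, prod$beta_annotated,
               prod$precursor_charge)
  prod[ord, , drop = FALSE]
}

.spanContains <- function(site, series, index, n) {
  ## site 0 = protein N-terminal amine, attached to residue 1
  if (is.na(site)) return(FALSE)
  if (series == "b") { lo <- 1L; hi <- index } else { lo <- n - index + 1L; hi <- n }
  if (site == 0L) return(lo == 1L)
  site >= lo & site <= hi
}

#' Fragment ions of one cross-link product
#'
#' Generates the b/y series of each constituent peptide at every requested
#' product charge. Fragments not spanning a linked site carry their bare
#' mass. Link-spanning fragments follow the linker chemistry:
#' \itemize{
#'   \item MS-cleavable inter-link: one variant per remnant assignment; for
#'     asymmetric remnant pairs both orientations are emitted (the alpha
#'     fragment with the side-A remnant and with the side-B remnant), for
#'     symmetric pairs a single variant.
#'   \item Non-cleavable inter-link: the fragment carries the intact linker
#'     delta plus the full partner peptide's neutral mass.
#'   \item Loop-link: fragments spanning both sites carry the intact delta;
#'     fragments spanning exactly one site are suppressed (the ring cannot
#'     open without spacer cleavage).
#'   \item Mono-link: link-spanning fragments carry the intact delta plus
#'     water (the hydrolyzed free end).
#' }
#'
#' @param product One product row from [enumerateLinkProducts()] (subset a
#'   single row, or pass a list with the same fields).
#' @param linker The [CrossLinker] used to build the product.
#' @param productCharges Integer vector of fragment charges.
#' @return `DataFrame` with columns `of_peptide` ("alpha"/"beta"), `series`,
#'   `index`, `ion_label`, `carries_link`, `remnant_delta`, `charge`,
#'   `neutral_mass`, `mz`.
#' @export
fragmentIons <- function(product, linker, productCharges = c(1L, 2L)) {
  if (is(product, "DataFrame") || is.data.frame(product)) {
    stopifnot(nrow(product) == 1L)
    product <- as.list(product[1L, , drop = FALSE])
  }
  DataFrame(.fragmentIonsCore(product, linker, productCharges))
}

## plain-data.frame worker; kept S4-free because it runs once per product
.fragmentIonsCore <- function(product, linker, productCharges) {
  if (any(productCharges < 1)) stop("product charge must be >= 1")
  z <- as.integer(sort(unique(productCharges)))
  kind <- product$kind
  water <- .WATER_MASS

  acc <- new.env(parent = emptyenv())
  acc$rows <- list()
  emit <- function(which, series, index, siteHit, remnant, nm) {
    acc$rows[[length(acc$rows) + 1L]] <- list(
      of_peptide = which, series = series, index = index,
      ion_label = paste0(series, index), carries_link = siteHit,
      remnant_delta = remnant, neutral_mass = nm)
  }

  peptideFragments <- function(which) {
    seq <- product[[paste0(which, "_sequence")]]
    mods <- product[[paste0(which, "_mods")]]
    n <- nchar(seq)
    if (n < 2L) return(invisible())
    res <- strsplit(seq, "", fixed = TRUE)[[1L]]
    pre <- cumsum(.RESIDUE_MASS[res])          # residue-mass prefix sums
    md <- .decodeModSites(mods)
    modvec <- numeric(n)
    if (nrow(md)) for (r in seq_len(nrow(md)))
      modvec[md$site[r]] <- modvec[md$site[r]] + md$delta[r]
    mpre <- cumsum(modvec)
    for (series in c("b", "y")) for (index in seq_len(n - 1L)) {
      bare <- if (series == "b") pre[index] + mpre[index]
              else (pre[n] - pre[n - index]) + (mpre[n] - mpre[n - index]) +
                   .WATER_MASS
      hit1 <- .spanContains(product$site1, series, index, n)
      hit2 <- .spanContains(product$site2, series, index, n)
      ## site1 sits on alpha, site2 on beta for inter-links; both on the
      ## single carrying peptide otherwise
      siteHit <- if (kind == "inter_link") {
        if (which == "alpha") hit1 else hit2
      } else hit1 || hit2
      vDelta <- 0; vRemnant <- 0
      if (siteHit) {
        if (kind == "inter_link") {
          if (linker@cleavable) {
            ## both orientations for asymmetric pairs; unique() collapses
            ## symmetric pairs to a single variant
            rem <- unique(if (which == "alpha")
              c(rbind(linker@remnantA, linker@remnantB))
            else c(rbind(linker@remnantB, linker@remnantA)))
            vDelta <- rem; vRemnant <- rem
          } else {
            partner <- if (which == "alpha") product$beta_mass
                       else product$alpha_mass
            vDelta <- linker@intactDelta + partner
            vRemnant <- linker@intactDelta
          }
        } else if (kind %in% c("loop_link_A", "loop_link_B")) {
          if (xor(hit1, hit2)) next  # ring spans the cut: suppressed
          vDelta <- vRemnant <- linker@intactDelta
        } else {  # mono_link: hydrolyzed dead-end keeps linker + water
          vDelta <- vRemnant <- linker@intactDelta + water
        }
      }
      for (v in seq_along(vDelta))
        emit(which, series, index, siteHit,
             if (siteHit) vRemnant[v] else 0, bare + vDelta[v])
    }
    invisible()
  }

  peptideFragments("alpha")
  if (kind == "inter_link") peptideFragments("beta")
  rows <- acc$rows
  if (!length(rows))
    return(data.frame(of_peptide = character(), series = character(),
                      index = integer(), ion_label = character(),
                      carries_link = logical(), remnant_delta = numeric(),
                      charge = integer(), neutral_mass = numeric(),
                      mz = numeric(), stringsAsFactors = FALSE))
  col <- function(name, how) vapply(rows, `[[`, how, name)
  ## cross every fragment with every requested product charge
  rep2 <- function(x) rep(x, each = length(z))
  nm <- rep2(col("neutral_mass", 0))
  zz <- rep(z, times = length(rows))
  data.frame(
    of_peptide = rep2(col("of_peptide", "")),
    series = rep2(col("series", "")),
    index = rep2(col("index", 0L)),
    ion_label = rep2(col("ion_label", "")),
    carries_link = rep2(col("carries_link", TRUE)),
    remnant_delta = rep2(col("remnant_delta", 0)),
    charge = zz, neutral_mass = nm, mz = mz(nm, zz),
    stringsAsFactors = FALSE)
}
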