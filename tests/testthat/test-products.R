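# Product-class enumeration and fragment remnant arithmetic.

test_that("one site per peptide yields inter- and mono-links only", {
  lk <- loadLinkerCatalog()[["DSSO"]]
  mk <- function(seqn, acc) modformTable(S4Vectors::DataFrame(
    parent_accession = acc, sequence = seqn, start = 1L, end = nchar(seqn),
    missed_cleavages = 0L, is_protein_nterm = FALSE, is_protein_cterm = TRUE),
    defaultModifications()[0, ])
  pr <- enumerateLinkProducts(mk("PEPKIDE", "PRA"), mk("GGKGGE", "PRB"),
                              lk, precursorCharges = 2L)
  expect_setequal(unique(pr$kind), c("inter_link", "mono_link"))
  expect_equal(sum(pr$kind == "inter_link"), 1L)
  expect_equal(sum(pr$kind == "mono_link"), 2L)   # one dead-end per peptide
})

test_that("two sites per peptide realize all four product kinds", {
  u <- twoPeptideUniverse()
  pr <- enumerateLinkProducts(u$A, u$B, u$linker, precursorCharges = 2L)
  expect_setequal(unique(pr$kind),
                  c("inter_link", "loop_link_A", "loop_link_B", "mono_link"))
})

test_that("product census matches a brute-force site-combination count", {
  lk <- loadLinkerCatalog()[["DSSO"]]
  set.seed(505)
  for (rep in 1:10) {
    nA <- sample(1:3, 1); nB <- sample(0:3, 1)
    mkp <- function(n, tag) {
      if (n == 0) return(modformTable(digest("AAA", accession = "Z")[0, ],
                                      defaultModifications()[0, ]))
      peps <- do.call(rbind, lapply(seq_len(n), function(i) {
        s <- paste0(randomSequence(sample(2:6, 1), c("A", "G", "S", "K")), "E")
        S4Vectors::DataFrame(parent_accession = paste0(tag, i), sequence = s,
                             start = 1L, end = nchar(s),
                             missed_cleavages = 0L, is_protein_nterm = FALSE,
                             is_protein_cterm = TRUE)
      }))
      modformTable(peps, defaultModifications()[0, ])
    }
    mfA <- mkp(nA, "A"); mfB <- mkp(nB, "B")
    zs <- sample(1:3, sample(1:2, 1))
    pr <- enumerateLinkProducts(mfA, mfB, lk, precursorCharges = zs)
    # brute-force expected counts from per-peptide K tallies
    kcount <- function(mf) vapply(seq_len(nrow(mf)), function(i)
      length(linkableSites(as.list(mf[i, , drop = FALSE]), lk, "A")), 0L)
    kA <- kcount(mfA); kB <- kcount(mfB)
    nz <- length(unique(zs))
    expect_equal(sum(pr$kind == "inter_link"), sum(kA) * sum(kB) * nz)
    expect_equal(sum(pr$kind == "loop_link_A"), sum(choose(kA, 2)) * nz)
    expect_equal(sum(pr$kind == "loop_link_B"), sum(choose(kB, 2)) * nz)
    expect_equal(sum(pr$kind == "mono_link"), (sum(kA) + sum(kB)) * nz)
  }
})

test_that("product masses follow the class arithmetic", {
  u <- twoPeptideUniverse()
  lk <- u$linker
  pr <- enumerateLinkProducts(u$A, u$B, lk, precursorCharges = 2L)
  mA <- u$A$neutral_mass[1]; mB <- u$B$neutral_mass[1]
  w <- massTable()$water
  inter <- pr[pr$kind == "inter_link", ][1, ]
  expect_equal(inter$neutral_mass, mA + mB + lk@intactDelta, tolerance = 1e-6)
  loopA <- pr[pr$kind == "loop_link_A", ][1, ]
  expect_equal(loopA$neutral_mass, mA + lk@intactDelta, tolerance = 1e-6)
  mono <- pr[pr$kind == "mono_link" & pr$of_protein == "A", ][1, ]
  expect_equal(mono$neutral_mass, mA + lk@intactDelta + w, tolerance = 1e-6)
  # m/z positive, finite, decreasing with charge
  expect_true(all(is.finite(pr$precursor_mz) & pr$precursor_mz > 0))
  pr2 <- enumerateLinkProducts(u$A, u$B, lk, precursorCharges = c(2L, 3L))
  one <- pr2[pr2$kind == "inter_link" & pr2$site1 == 2 & pr2$site2 == 2, ]
  expect_true(all(diff(one$precursor_mz[order(one$precursor_charge)]) < 0))
})

test_that("empty site universes give empty output, not an error", {
  lk <- loadLinkerCatalog()[["DSSO"]]
  mk <- modformTable(S4Vectors::DataFrame(
    parent_accession = "PRA", sequence = "PEPTIDE", start = 1L, end = 7L,
    missed_cleavages = 0L, is_protein_nterm = FALSE, is_protein_cterm = TRUE),
    defaultModifications()[0, ])
  pr <- enumerateLinkProducts(mk, mk, lk, precursorCharges = 2L)
  expect_equal(nrow(pr), 0L)
})

test_that("b/y complementarity holds for bare fragments", {
  lk <- loadLinkerCatalog()[["DSS"]]
  set.seed(606)
  for (i in 1:25) {
    s <- paste0(randomSequence(sample(2:19, 1),
                               setdiff(names(.RESIDUE_FORMULA), "K")), "E")
    mf <- modformTable(S4Vectors::DataFrame(
      parent_accession = "PRA", sequence = s, start = 1L, end = nchar(s),
      missed_cleavages = 0L, is_protein_nterm = FALSE,
      is_protein_cterm = TRUE), defaultModifications()[0, ])
    # no K: use a mono-link-free route by fragmenting a fake product with
    # no linked site
    p <- list(kind = "mono_link", alpha_sequence = s, alpha_mods = "",
              site1 = NA_integer_, site2 = NA_integer_)
    fr <- as.data.frame(fragmentIons(p, lk, productCharges = 1L))
    n <- nchar(s)
    M <- peptideNeutralMass(s)
    for (idx in seq_len(n - 1)) {
      b <- fr$neutral_mass[fr$series == "b" & fr$index == idx]
      y <- fr$neutral_mass[fr$series == "y" & fr$index == n - idx]
      expect_equal(b + y, M, tolerance = 1e-6)
    }
  }
})

test_that("DSSO inter-link fragments carry both remnant orientations", {
  u <- twoPeptideUniverse()
  pr <- enumerateLinkProducts(u$A, u$B, u$linker, precursorCharges = 2L)
  inter <- pr[pr$kind == "inter_link", ][1, ]
  fr <- as.data.frame(fragmentIons(inter, u$linker, productCharges = 1L))
  linked <- fr[fr$carries_link & fr$of_peptide == "alpha", ]
  expect_equal(sort(unique(linked$remnant_delta)),
               c(54.010565, 103.993200), tolerance = 1e-5)
  # the two orientations of one fragment sum to bare + bare + intact
  one <- linked[linked$series == "y" & linked$index == max(linked$index), ]
  expect_equal(sum(unique(one$remnant_delta)), u$linker@intactDelta,
               tolerance = 1e-6)
})

test_that("cleavable remnant conservation: peptide pairs sum to precursor", {
  u <- twoPeptideUniverse()
  lk <- u$linker
  pr <- enumerateLinkProducts(u$A, u$B, lk, precursorCharges = 2L)
  inter <- pr[pr$kind == "inter_link", ]
  for (i in seq_len(nrow(inter))) {
    p <- inter[i, ]
    for (ch in seq_along(lk@remnantA))
      expect_equal((p$alpha_mass + lk@remnantA[ch]) +
                     (p$beta_mass + lk@remnantB[ch]),
                   p$neutral_mass, tolerance = 1e-6)
  }
})

test_that("symmetric cleavable linkers emit one remnant variant", {
  lk <- symmetricTestLinker()
  mk <- function(seqn, acc) modformTable(S4Vectors::DataFrame(
    parent_accession = acc, sequence = seqn, start = 1L, end = nchar(seqn),
    missed_cleavages = 0L, is_protein_nterm = FALSE, is_protein_cterm = TRUE),
    defaultModifications()[0, ])
  pr <- enumerateLinkProducts(mk("AKAE", "PRA"), mk("GKGE", "PRB"), lk,
                              precursorCharges = 2L)
  inter <- pr[pr$kind == "inter_link", ][1, ]
  fr <- as.data.frame(fragmentIons(inter, lk, productCharges = 1L))
  linked <- fr[fr$carries_link, ]
  # exactly one variant per (peptide, series, index): no duplicated labels
  key <- paste(linked$of_peptide, linked$ion_label)
  expect_equal(anyDuplicated(key), 0L)
  expect_true(all(linked$remnant_delta == 50))
})

test_that("non-cleavable inter-link fragments carry linker + partner mass", {
  lk <- loadLinkerCatalog()[["DSS"]]
  mk <- function(seqn, acc) modformTable(S4Vectors::DataFrame(
    parent_accession = acc, sequence = seqn, start = 1L, end = nchar(seqn),
    missed_cleavages = 0L, is_protein_nterm = FALSE, is_protein_cterm = TRUE),
    defaultModifications()[0, ])
  pr <- enumerateLinkProducts(mk("AKAE", "PRA"), mk("GKGE", "PRB"), lk,
                              precursorCharges = 2L)
  inter <- pr[pr$kind == "inter_link", ][1, ]
  fr <- as.data.frame(fragmentIons(inter, lk, productCharges = 1L))
  b2 <- fr[fr$of_peptide == "alpha" & fr$series == "b" & fr$index == 2, ]
  bare <- peptideNeutralMass("AK") - massTable()$water
  expect_equal(b2$neutral_mass,
               bare + lk@intactDelta + inter$beta_mass, tolerance = 1e-6)
})

test_that("loop-link fragments spanning one of two sites are suppressed", {
  lk <- loadLinkerCatalog()[["DSSO"]]
  p <- list(kind = "loop_link_A", alpha_sequence = "AKAKAE",
            alpha_mods = "", site1 = 2L, site2 = 4L)
  fr <- as.data.frame(fragmentIons(p, lk, productCharges = 1L))
  # b2, b3 contain only site 2; y3, y4 contain only site 4: all dropped
  expect_false(any(fr$series == "b" & fr$index %in% c(2, 3)))
  expect_false(any(fr$series == "y" & fr$index %in% c(3, 4)))
  # fragments spanning both sites carry the intact (ring) delta
  b5 <- fr[fr$series == "b" & fr$index == 5, ]
  expect_true(all(b5$carries_link))
  expect_equal(unique(b5$remnant_delta), lk@intactDelta)
  # fragments with neither site are bare
  expect_false(any(fr[fr$series == "b" & fr$index == 1, "carries_link"]))
})

test_that("homodimer enumeration is off by default and flag-enabled", {
  u <- twoPeptideUniverse()
  pr0 <- enumerateLinkProducts(u$A, u$B, u$linker, precursorCharges = 2L)
  expect_false(any(pr0$kind == "inter_link" &
                     pr0$alpha_accession == pr0$beta_accession))
  pr1 <- enumerateLinkProducts(u$A, u$B, u$linker, precursorCharges = 2L,
                               allowHomodimers = TRUE)
  expect_true(any(pr1$kind == "inter_link" &
                    pr1$alpha_accession == pr1$beta_accession &
                    pr1$alpha_accession == "PRA"))
})
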