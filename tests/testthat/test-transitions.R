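# Transition-table assembly, the 12-column contract and CSV round trips.

test_that("the export schema is the fixed 12-column census, in order", {
  expect_equal(transitionColumns(), c(
    "combined_score", "protein_a_peptide", "cross_linker",
    "protein_b_peptide", "precursor_charge", "precursor_mz",
    "protein_a_ion", "protein_a_ion_type", "protein_b_ion",
    "protein_b_ion_type", "product_charge", "product_mz"))
  # empty export still writes exactly that header
  path <- tempfile(fileext = ".csv")
  lk <- loadLinkerCatalog()[["DSSO"]]
  exportTransitions(buildTransitionTable(
    enumerateLinkProducts(modformTable(digest("AAA", accession = "Z")[0, ]),
                          modformTable(digest("AAA", accession = "Z")[0, ]),
                          lk, 2L), lk, 1L), path)
  expect_equal(strsplit(readLines(path)[1], ",")[[1]],
               paste0('"', transitionColumns(), '"'))
})

test_that("rows fan out per fragment and share precursor columns", {
  u <- twoPeptideUniverse()
  pr <- enumerateLinkProducts(u$A, u$B, u$linker, precursorCharges = 2L)
  inter1 <- pr[pr$kind == "inter_link", ][1, , drop = FALSE]
  tt <- buildTransitionTable(inter1, u$linker, productCharges = 1L)
  nfr <- nrow(fragmentIons(inter1, u$linker, productCharges = 1L))
  expect_equal(nrow(tt), nfr)
  expect_equal(length(unique(tt$precursor_mz)), 1L)
  expect_equal(unique(tt$protein_a_peptide), inter1$alpha_annotated)
  expect_equal(unique(tt$protein_b_peptide), inter1$beta_annotated)
  # each row names an ion on exactly one side
  aSide <- nzchar(tt$protein_a_ion)
  bSide <- nzchar(tt$protein_b_ion)
  expect_true(all(xor(aSide, bSide)))
  expect_equal(tt$protein_a_ion_type[aSide],
               substr(tt$protein_a_ion[aSide], 1, 1))
})

test_that("variable modification forms appear as separate row blocks", {
  lk <- loadLinkerCatalog()[["DSSO"]]
  mf <- modformTable(S4Vectors::DataFrame(
    parent_accession = "PRA", sequence = "AMKAE", start = 1L, end = 5L,
    missed_cleavages = 0L, is_protein_nterm = FALSE, is_protein_cterm = TRUE))
  expect_equal(nrow(mf), 2L)  # oxidized and bare
  pr <- enumerateLinkProducts(mf, mf[0, ], lk, 2L, singleSides = "A")
  tt <- buildTransitionTable(pr, lk, 1L)
  expect_true(any(tt$protein_a_peptide == "AMKAE"))
  expect_true(any(tt$protein_a_peptide == "AM[+15.99491]KAE"))
  # the two lines differ by the oxidation delta at the precursor level
  m0 <- unique(tt$precursor_mz[tt$protein_a_peptide == "AMKAE"])
  m1 <- unique(tt$precursor_mz[tt$protein_a_peptide == "AM[+15.99491]KAE"])
  expect_equal(sort(m1 - m0), rep(15.99491462 / 2, length(m0)),
               tolerance = 1e-4)
})

test_that("export -> import round trip is the identity", {
  u <- twoPeptideUniverse()
  pr <- enumerateLinkProducts(u$A, u$B, u$linker, precursorCharges = c(2L, 3L))
  pr$combined_score <- 0.997
  tt <- buildTransitionTable(pr, u$linker, productCharges = c(1L, 2L))
  path <- tempfile(fileext = ".csv")
  exportTransitions(tt, path)
  back <- readTransitions(path)
  expect_identical(names(back), transitionColumns())
  expect_equal(back, tt)
})

test_that("m/z prints as 6-decimal fixed point", {
  u <- twoPeptideUniverse()
  pr <- enumerateLinkProducts(u$A, u$B, u$linker, precursorCharges = 2L)
  pr$combined_score <- 0.5
  tt <- buildTransitionTable(pr[1, , drop = FALSE], u$linker, 1L)
  path <- tempfile(fileext = ".csv")
  exportTransitions(tt, path)
  line2 <- strsplit(readLines(path)[2], ",")[[1]]
  expect_match(line2[6], '^"?[0-9]+\\.[0-9]{6}"?$')   # precursor m/z
  expect_match(line2[12], '^"?[0-9]+\\.[0-9]{6}"?$')  # product m/z
  # the formatting rule itself
  expect_equal(xlinkr:::.fmt6(501.0072846), "501.007285")
})

test_that("exported m/z values re-derive from their peptides and linker", {
  u <- twoPeptideUniverse()
  lk <- u$linker
  pr <- enumerateLinkProducts(u$A, u$B, lk, precursorCharges = 2L)
  tt <- buildTransitionTable(pr, lk, productCharges = 1L)
  inter <- tt[nzchar(tt$protein_b_peptide) & nzchar(tt$protein_a_peptide), ]
  row <- inter[1, ]
  mA <- peptideNeutralMass(gsub("\\[.*?\\]", "", row$protein_a_peptide))
  mB <- peptideNeutralMass(gsub("\\[.*?\\]", "", row$protein_b_peptide))
  expect_equal(row$precursor_mz,
               mz(mA + mB + lk@intactDelta, row$precursor_charge),
               tolerance = 1e-4)
})

test_that("response scores pass through as an extra column when supplied", {
  u <- twoPeptideUniverse()
  pr <- enumerateLinkProducts(u$A, u$B, u$linker, precursorCharges = 2L)
  tt <- buildTransitionTable(pr[1, , drop = FALSE], u$linker, 1L)
  path <- tempfile(fileext = ".csv")
  exportTransitions(tt, path, responseScores = rep(0.8, nrow(tt)))
  got <- utils::read.csv(path)
  expect_true("response_score" %in% names(got))
  expect_equal(unique(got$response_score), 0.8)
})

test_that("interactor tables export with rank, label, score and tier", {
  df <- data.frame(rank = 1:2, label = c("sp|Q07954|LRP1_HUMAN", "x"),
                   accession = c("Q07954", "X"),
                   combined_score = c(0.999, 0.5),
                   tier = c("highest", "medium"))
  path <- tempfile(fileext = ".csv")
  exportInteractors(df, path)
  back <- utils::read.csv(path)
  expect_equal(names(back), c("rank", "label", "combined_score", "tier"))
  expect_equal(back$combined_score, c(0.999, 0.5))
})
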