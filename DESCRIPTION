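Package: xlinkr
Title: Transition Lists for Targeted Cross-Linking Mass Spectrometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Generates SRM/PRM-ready transition lists for cross-linking
    mass spectrometry (XL-MS). Given a target protein, a proteome in
    UniProt FASTA dialect, a STRING-style interaction table and an
    accession mapping, the package ranks candidate interactors by
    combined score, digests target and interactors in silico (trypsin or
    chymotrypsin with missed cleavages), locates cross-linker reactive
    sites, enumerates every theoretical cross-linked species (inter-link,
    loop-link, mono-link) with exact monoisotopic precursor and b/y
    fragment m/z including MS-cleavable linker remnant arithmetic (e.g.
    DSSO alkene/sulfenic-acid pairs), and exports a 12-column CSV
    transition list.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
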