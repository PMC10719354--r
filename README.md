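# xlinkr

Transition lists for targeted cross-linking mass spectrometry (XL-MS).

## What it does, and for whom

Cross-linking MS identifies physical protein-protein interactions by
covalently bridging proximal residues (typically lysines) with a
bifunctional reagent, digesting, and detecting the linked peptides.
Following up a candidate interaction by SRM/PRM requires a *transition
list*: every theoretical cross-linked precursor with its product-ion
m/z values. Building one by hand means enumerating peptide pairs ×
reactive sites × product classes × modification forms × remnant
channels × charge states — this package does that, exactly and
reproducibly, for proteomics groups running targeted XL-MS assays.

Given a target protein, a proteome (UniProt-dialect FASTA), a
STRING-style interaction table and a UniProt↔STRING accession map,
`xlinkr`:

1. ranks the target's interactors by STRING combined score
   (tiered: highest > 0.9, high > 0.7, medium > 0.4, low > 0.15);
2. digests target and interactors in silico (trypsin or chymotrypsin,
   no cleavage before proline, missed cleavages up to a ceiling);
3. expands static/variable modifications (carbamidomethyl-C and
   oxidation-M by default; a peptide with k variable sites yields
   2^k forms);
4. locates linker-reactive sites and enumerates the four product
   classes, with monoisotopic neutral masses

   | class | neutral mass |
   |---|---|
   | inter-link (A×B) | m_A + m_B + Δ_linker |
   | loop-link (A or B, 2 sites) | m + Δ_linker |
   | mono-link / dead-end | m + Δ_linker + H₂O |

5. generates b/y fragment ions at each product charge, with
   MS-cleavable remnant arithmetic — e.g. DSSO (Δ = 158.00376 Da)
   cleaves into the alkene/sulfenic-acid pair 54.01057 + 103.99320,
   and every remnant pair must sum to the intact delta (checked at
   catalog load);
6. exports the ranked interactor list and a 12-column, Skyline-friendly
   CSV transition list, with m/z = (M + z·1.00727646688)/z at six
   decimals.

## Worked example

The package bundles a deterministic fixture around the published APOE
(P02649) top-10 interactor search — the real accessions, entry names and
combined scores, with short synthetic stand-in sequences (controlled
lysine placement; clearly labelled, not the real proteins):

```r
library(xlinkr)
fx  <- apoeFixture()
cfg <- searchConfig("P02649", fx$proteome, fx$ppi, fx$map,
                    enzyme = "trypsin", linker = "DSSO",
                    minLen = 9, maxLen = 9, topN = 10,
                    precursorCharges = c(2, 3), productCharges = c(1, 2))
res <- runSearch(cfg)
head(res$interactors, 3)
#>   rank                label accession combined_score    tier
#> 1    1 sp|Q07954|LRP1_HUMAN    Q07954          0.999 highest
#> 2    2 sp|Q14114|LRP8_HUMAN    Q14114          0.999 highest
#> 3    3 sp|P04114|APOB_HUMAN    P04114          0.998 highest
res$log
#>        n_proteins           n_edges     n_interactors n_target_modforms
#>                11                11                10                 7
#>        n_products      n_inter_link       n_loop_link       n_mono_link
#>               654               560                 0                94
#>     n_transitions
#>             56768
```

All ten partners score above 0.9 ("highest confidence"); rank 10 is
sp|Q92673|SORL_HUMAN at 0.995. Each of the 654 products (560
inter-links across the ten partners, 94 dead-ends) fans out over its
b/y fragments and charges into 56,768 transition rows:

```r
res$transitions[1:2, c(1, 2, 4, 5, 6, 7, 11, 12)]
#>  combined_score    protein_a_peptide               protein_b_peptide
#>           0.999 AAM[+15.99491]KDDDER M[+15.99491]GSC[+57.02146]RSSLK
#>           0.999 AAM[+15.99491]KDDDER M[+15.99491]GSC[+57.02146]RSSLK
#>  precursor_charge precursor_mz protein_a_ion product_charge product_mz
#>                 2     1132.966            b1              1   72.04439
#>                 2     1132.966            b1              2   36.52583
```

Bracket annotations are modification mass deltas (here oxidized
methionine and carbamidomethylated cysteine); variable modifications
produce separate rows with and without the shift. Write both tables
with `exportInteractors()` / `exportTransitions()`.

A shell front-end wraps the same pipeline:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "xlinkr.R", package = "xlinkr"))') \
  --target P02649 --proteome proteome.fasta --ppi links.txt --map map.tsv \
  --enzyme trypsin --linker DSSO --min-len 9 --max-len 9 --top-n 10 \
  --precursor-charge 2,3 --product-charge 1,2 --out results/
```

Exit codes: 0 success, 2 configuration error, 1 runtime error.

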