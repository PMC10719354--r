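---
title: "Computing SRM transition lists for cross-linking mass spectrometry"
author: "xlinkr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Computing SRM transition lists for cross-linking mass spectrometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xlinkr)
```

## The problem

Cross-linking mass spectrometry (XL-MS) probes physical protein-protein
interactions by covalently bridging spatially proximal residues with a
bifunctional reagent, digesting the complex, and identifying the linked
peptide pairs by MS. Targeted follow-up by selected or parallel reaction
monitoring (SRM/PRM) needs a precomputed *transition list*: every
plausible precursor ion (the cross-linked peptide species) paired with
its product ions (backbone fragments), each with an exact monoisotopic
m/z. Enumerating these species by hand is impractical because each
target-interactor pair fans out over peptide pairs, reactive-site
combinations, product classes, modification forms, remnant-mass channels
and charge states.

`xlinkr` automates the whole chain for one target protein: it ranks
candidate interactors from a STRING-style interaction table, digests
target and interactors in silico, locates linker-reactive sites,
enumerates every theoretical cross-linked species, and exports an
SRM-ready CSV.

## Interactor ranking

Interactions are read from a whitespace-separated three-column table
(`protein1 protein2 combined_score`). STRING distribution files store
the combined score as an integer 0-999; `loadPPITable()` divides by
1000 so the displayed values live on the unit interval. The table is
treated as undirected and symmetric duplicates collapse to the maximum
score. The target's UniProt accession resolves to its STRING identifier
through a two-column mapping; an isoform accession (dash-suffixed, e.g.
`P02649-2`) falls back to its base accession, because canonical and
isoform forms share a single STRING identifier and cannot be
distinguished at that level.

Partners are sorted by combined score descending. **Ties keep their
first-appearance order in the interaction table.** We considered
breaking ties alphabetically by partner accession, but published ranked
interactor lists (including the APOE example the bundled fixture
reproduces) are not alphabetical within tied scores; a stable sort over
the source table reproduces the upstream resource's own ranking while
remaining fully deterministic for a given input file.

Confidence tiers follow the conventional STRING cut-offs with strict
inequalities: highest (> 0.9), high (> 0.7), medium (> 0.4), low
(> 0.15); at or below 0.15 a partner is below the reporting cutoff. The
threshold value itself always belongs to the lower tier, so 0.7 is
"medium", not "high".

## Digestion

`digest()` implements cleavage-rule digestion with missed cleavages.
Trypsin cleaves C-terminal to K/R, chymotrypsin C-terminal to F/W/Y;
both obey the classical high-specificity exception of no cleavage
before proline. Chymotrypsin is deliberately fixed to the F/W/Y
high-specificity rule rather than the broader F/W/Y/L/M set: the narrow
rule is deterministic and the specificity is user-configurable through
`EnzymeSpec` for anyone who needs the broader one.

The default missed-cleavage ceiling is 2, and it matters chemically: a
lysine carrying the cross-linker blocks tryptic cleavage at that
residue, so any linkable tryptic peptide *must* survive with at least
one missed cleavage. With a ceiling of 0 a tryptic search could report
only N-terminal and arginine-flanked sites. Length filtering
(`filterByLength()`, default window 6-10) is a separate stage, so the
digest itself always emits every peptide, including a length-1
C-terminal fragment.

## Mass bookkeeping

All arithmetic is monoisotopic: SRM assays target the monoisotopic
peak. Residue masses are the standard IUPAC/Unimod values, water is
18.0105647 Da and the proton 1.00727646688 Da; the test suite re-derives
every shipped constant from elemental compositions and IUPAC atomic
masses, so a typo in one table cannot survive. A peptide's neutral mass
is the residue sum plus one water plus applied modification deltas;
`mz(M, z) = (M + z * proton) / z`.

Two modifications ship by default: carbamidomethylation of cysteine
(+57.02146 Da, static) and oxidation of methionine (+15.99491 Da,
variable), the pair most commonly carried in this kind of search.
Static modifications apply to every eligible site unconditionally.
Each variable modification expands over all subsets of its eligible
sites, so k sites yield 2^k forms; a peptide's oxidized and unoxidized
forms therefore appear as separate output lines. The expansion is
capped at 1024 forms per peptide (an error, not a silent truncation)
because a long methionine-rich peptide can otherwise explode
combinatorially. Further modifications load from a small CSV
(`name,targets,delta_mass,mode`).

## Cross-linkers

A catalog entry records the five attributes that drive the arithmetic:
per-side residue specificity, spacer arm length (Angstrom, metadata
only - no distance filtering is attempted), cleavability, the intact
mass delta added when both sides are conjugated, and for MS-cleavable
linkers the remnant-mass pairs left on the two peptides when the spacer
fragments. The load-time invariant `remnant_A + remnant_B =
intact_delta` (to 1e-3 Da) is what makes downstream fragment arithmetic
conservative by construction; a catalog row violating it is rejected
with the linker named.

The bundled catalog is a representative subset - DSSO and DSBU
(MS-cleavable), DSS and BS3 (non-cleavable NHS esters), sulfo-SDA
(photo-chemistry, modelled as a mass entry only) and EDC (zero-length,
negative delta from the condensation) - chosen to span the
cleavable/non-cleavable and symmetric/asymmetric axes. DSSO cleaves at
its C-S bonds into the alkene (54.010565 Da) / sulfenic-acid
(103.993200 Da) pair; the alternative thiol channel (85.982635 Da,
paired with alkene plus retained water, 72.021129 Da) also satisfies
conservation and can be enabled by appending it to `remnant_pairs` in a
user catalog, which merges over the bundled one by name.

Site location applies two boundary rules. First, the C-terminal K/R of
a tryptic peptide is **not** linkable (configurable off): in a real
sample the cleavage happened because that lysine was unmodified, so the
same residue cannot also carry the linker. Second, amine-reactive
linker sides also react with the protein N-terminal alpha-amine, which
is reported as site position 0 on a peptide that starts the protein.

## Product classes and fragments

For a target (protein A) / interactor (protein B) peptide universe,
four product classes are enumerated:

* **inter-link**: one A-peptide and one B-peptide joined through the
  linker; neutral mass `m_A + m_B + intact_delta`;
* **loop-link** on A or on B: both linker ends on one peptide, two
  distinct sites; `m + intact_delta`;
* **mono-link** (dead-end): one end conjugated, the other hydrolyzed;
  `m + intact_delta + water`.

The water term on mono-links reflects the hydrolyzed NHS end; it also
keeps fragment complementarity exact, which is why link-carrying
fragments of a mono-link carry `intact_delta + water` as well.
Homodimeric A-A / B-B inter-links exist behind a flag (default off) so
the default output is the target-by-interactor table.

Fragments are the b/y series (the CID/HCD convention SRM assays use) of
each constituent peptide at each requested product charge. A fragment
not spanning a linked site is bare. For a spanning fragment:

* *cleavable inter-link*: one variant per remnant assignment. For an
  asymmetric pair both orientations are emitted (the A-fragment with
  the side-A remnant and with the side-B remnant), because which
  remnant stays on which peptide is not determined a priori; symmetric
  pairs collapse to a single variant. The two orientations of a pair
  always sum to the intact delta.
* *non-cleavable inter-link*: the fragment carries the intact delta
  plus the entire partner peptide's neutral mass.
* *loop-link*: a fragment spanning both sites carries the intact delta;
  one spanning exactly one site is suppressed, because the ring cannot
  open without spacer cleavage.

Precursor and product charge sets come straight from configuration and
may overlap.

## Output

The transition table has a fixed 12-column schema: combined score,
protein A peptide, cross-linker, protein B peptide, precursor charge,
precursor m/z, protein A ion, protein A ion type, protein B ion,
protein B ion type, product charge, product m/z. Peptides print with
mass-delta bracket annotations (`AM[+15.99491]KAE`) rather than
modification names - unambiguous, and directly digestible by Skyline.
m/z values are fixed to 6 decimals at assembly, so the CSV
round-trips bit-exactly (`readTransitions(exportTransitions(x)) == x`).
The ranked interactor list (rank, `db|ACC|ENTRY_NAME` label, score,
tier) exports as its own CSV, mirroring the two-table result layout. An
optional pass-through column carries externally supplied peptide
response scores (e.g. Prego predictions); the package never computes
them.

Rows are ordered by combined score descending with target-only products
(NA score) last, then by the deterministic product order (class,
accession, position, charge). Re-running an identical configuration is
byte-identical: nothing in the pipeline is randomized.

## The bundled fixture and the synthetic generator

`apoeFixture()` writes a deterministic desk-scale bundle around the
published APOE (P02649) worked example: the ten top-ranked partners
with their exact combined scores (0.999 down to 0.995, all "highest"
tier) in printed rank order, a matching accession map, and an 11-entry
proteome. The *sequences* in that proteome are short synthetic
stand-ins with controlled lysine placement - each protein contains a
tryptic 9-mer with an internal lysine reachable at one missed cleavage,
plus a cysteine and (for the target) a methionine so both default
modifications are exercised. They are labelled synthetic in every
FASTA header and are not the real proteins; reproducing the published
interactor ranking needs only the score table, not the sequences.

`synthProteome(n, lengthRange, density, seed)` generates random
proteomes with controllable per-residue frequencies (default K and R at
0.08, roughly their natural abundance) for property tests: digestion
against a brute-force oracle, site scans, binomial checks on residue
frequency. What neither fixture emulates: real sequence composition and
homology, isoform sequence variation, protease kinetics, spectral
intensities, or the scale of a full proteome and interactome. Passing
tests therefore demonstrate the correctness of the combinatorics and
the mass arithmetic, not retention-time or detectability behaviour on
real samples.

## Numerical choices and degenerate inputs

* Remnant-pair conservation is checked at 1e-3 Da on load (catalog
  values are printed to 5-6 decimals); internal consistency of
  enumerated products is tested at 1e-6 Da.
* Residues B, J, O, U, X, Z and `*` are rejected at parse time with the
  record and position named, never silently mass-defaulted: one
  ambiguous residue would corrupt every downstream m/z.
* An empty site universe yields an empty product table, not an error.
* Loop-links require two distinct sites; adjacent residues are allowed
  (the spacer arm is metadata, not a geometric filter).
* Problem sizes in the shipped tests are desk-scale by design - an
  11-protein fixture, random sequences up to length 50, universes of a
  few peptides - chosen so every oracle can be brute-force.

## Limitations

* Only b/y fragment series are generated (the SRM norm); c/z or a-ion
  support would be an enum extension.
* No isotope envelopes, average masses, or neutral losses other than
  linker cleavage.
* The interaction table and mapping are file-based subsets; there are
  no live STRING/UniProt queries.
* Prego-style response prediction is out of scope; a pass-through
  column is the only integration point.
* The bundled linker catalog is a representative subset; the CSV
  schema, not the census, is the contract.
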