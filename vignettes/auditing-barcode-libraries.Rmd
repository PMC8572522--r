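---
title: "Auditing DNA barcode reference libraries with refgap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing DNA barcode reference libraries with refgap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refgap)
```

`refgap` audits a DNA barcode reference library — a table of specimen
records carrying COI sequences, BIN (Barcode Index Number) cluster
assignments, rank-structured taxonomy and geography — against an accepted
species checklist. This vignette is the package's account of the methods:
what each stage assumes, which parameters matter, and where the design was
genuinely open.

## The audit model

The unit of curation is the **record**; the unit of identification is the
**BIN**, an algorithmically delimited sequence cluster treated as a
putative species; the unit of quality assessment is the **nominal
species**. The pipeline moves through these three levels in order, and
every stage is a pure function of its inputs, so reruns are stable.

### Record curation

Four filters apply in a fixed order: marker, sequence quality, duplicate
collapse, explicit exclusions. The order matters only for attribution —
each removed record is logged exactly once, at the first stage that
rejects it — and re-running curation on its own output removes nothing.

Quality semantics are deliberately boundary-explicit:

* *Length*: gap characters (`-`, `.`) are stripped first; a 500 bp
  sequence is kept, 499 bp is removed.
* *Ambiguity*: every non-ACGT IUPAC letter counts (N, R, Y, ...), gaps
  count toward neither numerator nor denominator; exactly 1% is kept,
  anything above is removed. A sequence that is all gaps is a degenerate
  input and an error, not a silent zero.
* *BIN requirement*: records without a BIN URI are removed by default.
  The three clauses combine as OR — repositories typically withhold BINs
  from sequences that fail their own screens, so the clauses are
  correlated in real data; an AND combination is available
  (`curation_config(qc_combine = "and")`) for stricter readings.

Duplicate collapse targets one specific artefact: repository updates of
harvested GenBank accessions leave pairs whose sample IDs differ only by a
`.1` suffix and whose identifications agree. Identification matching
compares only ranks populated on both sides — real exports are
rank-ragged, and an absent rank is missing information, not disagreement.
The pair member with more detailed geography wins (coordinates = 2,
country = 1, neither = 0); ties keep the `.1` member, which is the later
revision. Suffix triples (`X`, `X.1`, `X.2`) fall outside the rule and are
left alone with a warning rather than guessed at.

### Identification levels and BIN consensus

Each record is classified on the ordered scale
`order < family < subfamily < genus < temporary < species`. *Temporary*
names — morphospecies placeholders like "Genus sp. 3" — sit between genus
and species: they delimit a taxon more precisely than a bare genus but do
not tie it to a described species, and they are detected by configurable
regular expressions (`temporary_name_patterns()`) because no authoritative
pattern list exists. Open-nomenclature qualifiers ("cf.", "aff.") are
treated as full species identifications by default; this is a documented
simplification (most such records cluster around a handful of well-studied
genera), and `cf_as_species = FALSE` reverses it.

Within a BIN, the most detailed identification is propagated to all
members. When names conflict at the deepest shared level, the policy
applies three branches in a fixed order:

1. **Majority rule** — at most `outlier_max` (default 1) minority records
   against at least `majority_min` (default 3) concordant ones: the
   minority is demoted, as a presumed misidentification, to the deepest
   rank congruent with the majority (genus if genera agree, else family,
   else order). Demoted records keep their original taxonomy in the output
   with a `demoted_to` annotation — auditability beats in-place editing.
   Ties between equally large name groups never trigger this branch.
2. **Trusted-identifier priority** — if exactly one conflicting name was
   assigned by a determiner on the user-supplied trusted list, it wins.
   The shipped default list is empty: who counts as a specialist is a
   judgement the package cannot make.
3. **Congruent-rank fallback** — the BIN is assigned the deepest rank on
   which all members agree and flagged as an unresolved conflict.

Putting majority rule ahead of identifier priority is a design choice, not
an established convention: a 9-to-1 split is stronger evidence than any
single determiner's authority, and the precedence is deterministic where
manual case-by-case review is not. The consequence worth knowing: after
resolution every BIN carries at most one species name, so grade E
(discordant species in one BIN) cannot occur downstream — the test suite
asserts this on libraries with deliberately planted misidentifications and
shared BINs.

Resolution is invariant under permutation of record order; all counting
uses deterministic alphabetical tie-breaks.

### Realm assignment

BINs are assigned to marine / freshwater / terrestrial by habitat-map
lookup at species, then genus, then family rank. Two conventions are baked
in: brackish-capable taxa must be pre-merged into marine or freshwater
when the map is built (each taxon carries exactly one realm), and the
family Talitridae is terrestrial by a built-in rule that an explicit
species-level entry can still override (with a warning, as for any
cross-rank conflict — the deeper rank is more specific information).

BINs with no taxon hit fall back to user-supplied geographic hints:
country tokens and/or coordinate boxes mapped to realms. Member records
vote; the modal realm wins; an exact tie leaves the BIN unassigned rather
than inventing a tie-break — in manual audits such cases are resolved by
reading the source publication, which is not automatable. No coastline
polygons or gazetteers are bundled: the package stays download-free, and a
point-in-polygon marine test would dominate its footprint while replacing
a judgement the hint table expresses directly. Unassigned BINs appear in
the realm tallies and are then excluded from grading and coverage.

### Grading and coverage

Grades follow the five-class BAGS-style scheme (A: one BIN, > 10
sequences; B: one BIN, 3–10; C: several BINs; D: one BIN, < 3; E: shared
BIN), with precedence E > C > A/B/D. Counts use curated records; records
demoted during resolution do not count toward the majority species'
sequence total. Temporary-name taxa are not graded — the scheme is defined
for nominal species — but appear in the identification-level tables.
Open-nomenclature records are graded under their cleaned canonical name
together with clean conspecific records, consistent with their treatment
as species identifications.

A species whose BINs span realms is counted in every realm it occurs in
but once in the all-species row, so per-realm grade counts may sum to more
than the global species total; the package reports both numbers rather
than forcing agreement.

Family coverage uses distinct canonical species names (a species split
across many BINs counts once), and unmatched names (misspellings,
synonyms, checklist absences) are excluded from coverage numerators but
reported in full. Richness categories are ≤ 10 / 11–30 / 31–100 / > 100
accepted species — the "up to 10" reading of the low boundary. Mean
coverage per category is computed over represented families only, and a
property test verifies that inflating an unrepresented family cannot move
it. Families appearing in BIN taxonomy but absent from the checklist
(incertae-sedis groupings and the like) are listed as pseudo-families with
coverage undefined.

Identification-level summaries count each record at its BIN's consensus
level — the propagation step means the best identification in a BIN
applies to all its records — and each BIN once. Geographic completeness
classes (coordinates / country-only / neither) are mutually exclusive with
coordinates taking precedence; country normalization is lexical only
(whitespace, case, optional alias table), never a reverse geocode.

## The synthetic-library generator

`generate_library()` exists so that every stage is testable with known
truth. Its defaults are fixed study conditions, not tuning knobs:

| parameter | default | rationale |
|---|---|---|
| `n_families`, `family_size_law` | 239 families, lognormal(2.3, 1.8) | heavy-tailed checklist populating all four richness categories |
| `n_species_sampled` | 1000 | order of magnitude of a well-studied invertebrate library's species count |
| `realm_mix` | 0.50 / 0.45 / 0.05 | near-equal marine and freshwater contributions, small terrestrial fraction |
| `seqs_per_species_law` | zero-truncated geometric, P(1) = 0.55 | singleton-dominated depth distribution |
| `p_split` | 0.3 | roughly a third of species split over multiple BINs |
| `p_merge` | 0.02 | BIN sharing is rare (order of 2% of clusters) |
| `id_loss` | marine ≫ freshwater | marine identification loss substantially higher, at every rank |
| `p_coords` | 0.71 / 0.47 / 0.50 | coordinates most complete for marine records |
| `dup_rate`, `qc_fail_rate` | 0.05, 0.09 | a few percent duplicates; just under a tenth failing quality |
| `misid_rate` | 0.02 | occasional lone wrong name inside a large BIN |

Realms are assigned per *family* and identification loss per *species*.
Both are deliberate simplifications: family-level realms make habitat
lookups consistent at every rank (so ground-truth realm recovery is
exact), and species-level identification loss keeps the graded subset an
unbiased sample of the grade law — which is what makes the closed-form
oracle below valid. Real libraries violate both (families straddle realms;
deeply sequenced species are better identified), so tests passing on
synthetic data demonstrate the pipeline's bookkeeping, not robustness to
those correlations. Other non-emulated features: sequences are uniform
random ACGT (the audit never reads sequence content beyond length and
ambiguity), BIN URIs are random codes with no clustering model behind
them, country pools per realm are disjoint (so the emitted hint table
resolves exactly), and all taxon names are pronounceable synthetic strings
that cannot collide with real taxa.

With no BIN sharing (`p_merge = 0`) the grade profile has a closed form:
a split species is C; an unsplit one is graded by its record count
*n* ~ 1 + Geometric(p). `expected_grade_profile()` returns these
probabilities, and an acceptance test checks the empirical frequencies on
a 2,000-species library against an independently enumerated version of the
same law within three binomial standard errors. Misidentification planting
is left at its default there; it can shift a grade only when a demotion
crosses the n = 3 or n = 11 boundary, a perturbation two orders of
magnitude below the tolerance.

## Numerical and degenerate-input conventions

* Absent values: empty strings, `"NA"`, `"None"` all normalize to missing
  on input; coordinates must be decimal degrees, parse as a pair, and lie
  in range, else geography is dropped with a warning (degree-minute
  strings are rejected, not guessed).
* Empty inputs propagate: a header-only record file yields an empty
  curated set, empty grade tables write header-only CSVs, and tallies of
  empty scopes are zero-filled rather than absent.
* All output tables have fixed column order and fixed row sort keys, so
  identical inputs produce byte-identical files.
* Test problem sizes: unit fixtures use hand-built BINs of 1–12 records;
  property and recovery tests use libraries of 30 families / 120 species
  across multiple seeds; the grade-profile check uses 2,000 species. These
  sizes give every branch (merges, misidentifications, unassigned BINs,
  duplicate ties) non-trivial occupancy while keeping the suite fast.

## Known limitations

* Synonymy is out of scope: checklist matching is exact on canonical
  names, and historical genus transfers are visible as unmatched names
  unless the user supplies an alias table.
* The trusted-identifier mechanism is exact string matching on the
  determiner field; spelling variants of the same person are different
  identifiers.
* Realm assignment cannot recover information that exists only in source
  publications; such BINs stay unassigned unless hinted.
* The temporary-name detector is regex-based and will misclassify exotic
  placeholder formats; the pattern list is user-extensible.
* BIN delimitation itself is taken as given; the package audits the
  clusters it is handed and does not re-cluster sequences.
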