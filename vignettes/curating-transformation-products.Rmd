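---
title: "Curating transformation-product reactions from text-mined annotations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating transformation-product reactions from text-mined annotations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Knowledge about transformation products (TPs) — the chemicals formed when a
parent compound is metabolized, hydrolyzed or photolyzed — is mostly locked
up in prose: toxicology database excerpts, metabolism sections, reaction
schemes in figures. Text-mining engines can recognize chemical names in such
prose and link them to compound identifiers, but a recognized name is not a
reaction: most names in a metabolism paragraph are co-administered drugs,
assay reagents, or incompletely recognized fragments. Turning markup into a
reaction library therefore requires a curation step in which a human (or a
recorded set of human verdicts) decides, for each mined name, whether it is
a TP of the input compound, a parent of it, or neither.

`tpcurate` is the headless half of that workflow: everything downstream of
name recognition, scriptable and reproducible. It parses annotation JSON
with markup spans, flattens it to a candidate table, applies a declarative
decision file, validates the resulting directed reactions, deduplicates
them against an existing transformations library, exports a suspect list,
and finally labels TPs among identified compounds, links parent–TP pairs
and compares their octanol–water partitioning.

## Data model and curation semantics

A **candidate** is one (excerpt, markup span) pair: the input compound the
excerpt is about, the matched name and its linked CID, and the evidence
text. Candidate identifiers are content hashes of
`(input CID, source id, span start, matched CID)`, so re-extracting the
same document reproduces the same ids and a decisions file survives
re-extraction byte-for-byte.

A **decision** carries a verdict from the closed set
`product` / `parent` / `reject`. `product` orients the reaction
input → matched, `parent` orients it matched → input; metadata (biosystem,
enzyme, transformation type) is copied verbatim from the decision. Reversing
a verdict swaps the two sides and changes nothing else. Candidates without
a decision are never dropped silently: they block finalization unless
`allow_undecided` is set, and always appear in the rejection ledger. If one
candidate receives several decisions, the last in file order wins and a
warning is raised — a convention, chosen because decision files are
append-mostly artifacts.

Multi-step chains mentioned in one excerpt (A → B → C) are represented as
two pairwise reactions; the library schema is pairwise and no chain object
exists.

## Structure handling

Canonical SMILES, InChIKey and Hill formula come from OpenBabel (batched
through the `obabel` executable, which preserves stereocentres); the
monoisotopic mass comes from OpenBabel's exact-mass calculator. Three match
levels formalize the usual review questions:

* **exact** — full InChIKey equality;
* **skeleton** — equality of the first 14-character InChIKey block, which
  hashes the stereo- and isotope-agnostic connectivity; a pair that matches
  at skeleton but not exact level differs only in stereochemistry or
  isotope labelling;
* **desalted** — exact equality after salt stripping on both sides.

Salt stripping keeps the largest *organic* component (most heavy atoms
among carbon-containing components), breaking ties by larger monoisotopic
mass and then by lexicographically smallest canonical SMILES — a
deterministic version of the standard desalting convention. Because
removing a counterion leaves a bare ion whose InChIKey charge layer would
never match the free acid or base, the kept component is neutralized before
canonicalization. Single-component structures pass through unchanged, and
an all-inorganic multi-component input is an error: there is no organic
parent to keep.

Reaction validation reports from a closed vocabulary
(`salt_component`, `stereo_only_difference`, `identical_sides`,
`missing_metadata`, `unresolved_cid`) and never mutates records; what to
fix and what to discard is a curation decision, not a library operation.
`missing_metadata` fires only when biosystem, enzyme *and* transformation
type are all absent — any one of them is enough context to keep.

XlogP values are consumed from input tables when present. The package can
compute an OpenBabel logP estimate (`estimate_logp()`), but it is exposed
under its own name and never silently substituted, because tabulated XlogP
and atom-contribution logP estimates are not interchangeable.

## Library semantics

A transformations library is a multiset of directed reactions. Uniqueness
is reckoned on the (predecessor CID, successor CID) pair, with the InChIKey
pair as fallback when either CID is absent. Deduplication classifies each
incoming reaction as:

* `exact_duplicate` — structure pair present with identical normalized
  metadata (case and surrounding whitespace ignored; no synonym
  resolution, so "liver" ≠ "hepatic" by design);
* `metadata_variant` — structure pair present, metadata differs;
* `novel` — structure pair absent.

Differences confined to the evidence text count as exact duplicates: the
evidence is provenance, not reaction identity. The three classes always
partition the input, merging adds novel pairs (optionally variants) exactly
once, and merging the same set twice is a no-op the second time.

Suspect lists contain one entry per distinct successor structure, with
predecessor InChIKeys accumulated across all producing reactions —
so a TP reachable from two parents yields a single suspect entry with two
predecessor links. Masses and formulas are recomputed from the structures
rather than copied, because downstream suspect screening depends on mass
accuracy. Entries are sorted by InChIKey so exports are byte-stable.

## The parent–TP comparison

TPs tend to be more polar than their parents, so the screening stage tests
the one-sided hypothesis that TP XlogP is lower, pairing each labeled TP
with its identified parent. The statistic is the Wilcoxon signed rank; the
implementation:

* drops pairs missing either XlogP value (counted, reported);
* drops zero differences;
* uses the **exact** null distribution when at most 25 usable pairs remain,
  computed from the generating function of the signed-rank sum over
  midranks (doubled to stay integer), so tied absolute differences are
  handled exactly rather than by falling back to an approximation;
* uses the normal approximation with continuity correction beyond 25 pairs;
* reports the two-sided p-value alongside the one-sided one for
  transparency.

Gaussian kernel densities with Silverman's rule-of-thumb bandwidth
(`bw.nrd0`) are returned for both groups for plotting. Zero usable pairs is
an error, not a NaN-filled summary.

## What the fixture generators emulate

The generators plant ground truth so every stage is testable offline, with
all randomness flowing from one seed (`withr::with_seed`; the global RNG is
untouched).

* `gen_annotation_fixture()` emulates a text-mined metabolism corpus:
  50 compounds × 3 excerpts and 400 spans by default, of which a
  `true_fraction` of 0.2 are genuine transformation mentions — the rate at
  which mined chemical names correspond to valid reactions in curated
  metabolism text — 5% point at structures deliberately missing from the
  structure index (the unresolved path), and the rest are distractor
  mentions. True mentions cycle through a primary TP, a known precursor
  (parent verdict) and a secondary TP, so both reaction directions occur.
* `gen_library_fixture()` plants exact counts of novel, exact-duplicate
  and metadata-variant candidates against a 200-entry library.
* `gen_screening_fixture()` defaults to 436 identified compounds with 72
  planted TPs, 36 of them with an identified parent and 36 orphans,
  mirroring a wastewater-sample screening campaign; TP XlogP equals parent
  XlogP − 1.0 with Gaussian noise (sd 0.5), and parents draw from
  N(3, 1.5), typical of moderately lipophilic environmental organics.

Fixture chemistry uses homologous series of real, simple structures
(1-alkanols, n-alkanoic acids, n-alkylbenzenes, 1-aminoalkanes and their
oxidation/hydroxylation/acetylation/hydrolysis partners) mutated only in
chain length, because random SMILES strings are mostly invalid. The
excerpts are templated sentences. Consequently the fixtures exercise
parsing, span arithmetic, canonicalization, mass computation, dedup and
linkage exactly, but they do **not** probe named-entity-recognition errors,
genuinely ambiguous prose, exotic chemistry (organometallics, polymers,
isotope labels) or wrong identifier mappings; passing tests show the
pipeline is faithful to its inputs, not that the inputs are right.

## Numerical and design choices

* Offsets in markup spans are 0-based, length-counted, in Unicode code
  points; every span is verified against its excerpt at parse time and
  overlapping spans are allowed (real markup nests names).
* Candidate ids use a 32-bit FNV-1a hash; collisions are checked at table
  construction and would be an error, not a silent merge.
* CSV artifacts write `NA` as the empty field and enforce fixed column
  sets; unknown columns are an error listing the offenders.
* Decision conflicts: last in file order wins, with a warning (see above).
* Desalting tie-breaks: heavy atoms, then mass, then lexicographic SMILES.
* Test problem sizes: the suite runs the annotation fixture at 400 spans,
  library fixtures at 40–200 entries, the screening fixture at its default
  436 compounds across 20 seeds, and the calibration/power simulations at
  1000/500 replicates of 36 pairs — sizes chosen to pin every planted count
  exactly while keeping a full run around half a minute.

## Limitations

* Direction is never guessed from sentence grammar, and transformation
  types are never inferred from structure pairs; both are curator input.
* Metadata comparison is lexical; synonym dictionaries are out of scope.
* The salt-stripping/neutralization pair handles the common
  counterion-plus-organic case; zwitterions and multi-organic mixtures
  where the "parent" is not the largest fragment need manual curation.
* Matching in the screening stage is identifier-based (InChIKey); matching
  by accurate mass or spectra belongs to the upstream screening tool.
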