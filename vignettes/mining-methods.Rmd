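---
title: "Methods: typed protein co-occurrence mining from abstract corpora"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: typed protein co-occurrence mining from abstract corpora}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(litcooc)
```

## The procedure and its assumptions

litcooc extracts candidate protein–protein interactions from the titles and
abstracts of PubMed/MEDLINE articles by dictionary co-occurrence, not by
parsing syntax. The pipeline is:

1. **Parse** PubMed XML into records (PMID, title, abstract) and segment the
   mined text into sentences. The mined text is `title + " " + abstract`:
   titles frequently state the key relation, and mining them maximizes
   recall; the choice is recorded here because mining only the abstract is
   equally defensible.
2. **Tag** bioentity names (proteins, genes, taxa, tissues, cell types),
   biointeraction trigger terms ("activates", "encoding", ...) and
   biological-concept terms against fully in-memory lexicons.
3. **Classify** every unordered pair of distinct normalized protein/gene
   names co-mentioned in an abstract into a reliability type:
   - **type 1** — both names in one sentence with an exact trigger term
     strictly *between* them ("rbcL *activates* psbA");
   - **type 2** — both names in one sentence, exact trigger anywhere in it;
   - **type 3** — both names in one sentence, trigger found only
     *permissively* (stem-prefix match, e.g. "activation" for
     "activates");
   - **type 4** — both names in the same abstract only.
   Lower types are more likely to reflect a real interaction; even type-1
   hits are co-occurrences, and manual curation is expected before any
   pathway claim.
4. **Report**: summary files with absolute and non-redundant counts,
   taxon-filtered subsets, and weighted co-occurrence networks.

The core assumption is the standard co-occurrence-mining one: if two
protein names are mentioned close together, and a relational trigger word
sits near (ideally between) them, the sentence probably describes a
relation. The method does not attempt negation handling, coreference, or
directionality.

## Key rules and tie-breaks

*Text normalization.* All text is Unicode NFC-normalized; offsets are
0-based, half-open, counted in code points. All ordering that reaches an
output file uses C collation (radix sort), never the session locale, so
results are byte-identical across machines.

*Sentence splitting* is rule-based and deterministic: a run of `.!?`
followed by whitespace and an alphanumeric character ends a sentence,
unless the preceding word is a known abbreviation or a single letter. We
deliberately allow a lowercase follower to start a sentence — gene symbols
such as "matK" regularly open sentences in this literature, and requiring a
capital follower would silently glue such sentences together. The
single-letter veto still protects "E. coli"; the abbreviation list protects
"Fig. 2", "et al. 2019" and similar.

*Tokenization* keeps internal hyphens and periods ("PR-1", "PDF1.2",
"glutathione S-transferase" stays two tokens with "S-transferase" intact).
Entity matching is case-insensitive, whole-token anchored, left-to-right
longest match with ties to the leftmost; matched tokens are consumed, so
entity mentions never overlap. Multi-word entries must be separated by
exactly one space in the text.

*Permissive trigger matching* is concretized as stem-prefix matching: one
conventional suffix (`-ation, -tion, -ion, -ing, -es, -ed, -s`, longest
first) is stripped from the dictionary term provided the stem keeps ≥ 4
characters, and a token matches permissively when its case-folded form
begins with that stem. This makes permissive matching a superset of exact
matching by construction — a property the type hierarchy (1 ⇒ 2 ⇒ 3)
relies on. Terms too short to stem fall back to themselves (permissive =
exact for them). Each matched span is reported once with the strongest
mode; when several dictionary terms match the same span in the same mode
the lexicographically smallest term labels the mention.

*Pair classification.* "Between" means the trigger span lies inside the
open interval after the earlier mention's end and before the later
mention's start; when a name is mentioned several times in a sentence, any
mention combination may satisfy the rule. The reported type of a pair is
the minimum over all same-sentence combinations, the evidence sentence is
the earliest sentence achieving that minimum, and a same-sentence pair
with no trigger at all falls through to type 4 (the permissive tier
requires at least a permissive trigger, not mere adjacency). Self-pairs
are excluded: homodimers cannot be recovered from name pairs.

*Event unit.* Exactly one co-occurrence record exists per (PMID, pair),
at the minimal type. Absolute tallies count these records — so the
absolute protein count is two per record — and "non-redundant" always
means distinct names/pairs/terms. The original reports never define the
event unit; this choice makes absolute and non-redundant tallies exactly
reproducible and is stated in every summary header.

*Imported tags.* When an external tagger's output is supplied, its
mentions **replace** dictionary tagging for the records it covers (strict
hand-off, reproducible provenance); they are validated against sentence
boundaries and the closed entity-class vocabulary, and invalid rows are
dropped with warnings rather than repaired.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `max_type` | 4 | keep pairs with type ≤ this; use 1 for pathway building |
| `tax_id` | none | keep only abstracts with a taxon mention resolving to this NCBI id |
| `poorly_max` | 2 | items counted ≤ this are flagged "poorly described" |
| `top_k` | 10 | length of the top listings in summaries |
| `jobs` | 1 | forked workers; output provably independent of this |
| minimum stem length | 4 | shorter stems over-match; fixed, not exposed |

## The synthetic corpus generator

`generate_corpus()` emits real PubMed XML plus a ground-truth table. Each
planted abstract instantiates one type rule with a template that makes the
planted type *minimal* by construction: type-2 templates place the trigger
outside the between-interval, type-3 templates use a derived stem-variant
surface that matches no dictionary term exactly, type-4 templates split the
names across sentences with no trigger anywhere. Filler words are checked
against the lexicon at generation time (including stem prefixes), and decoy
tokens are random strings verified absent from the lexicon, so decoys can
never tag. Taxon mentions are appended as their own sentences; by default
each abstract carries at most one planted pair so that minimal-type
reasoning is airtight, while *hard mode* scrambles several names, triggers
and fillers per sentence and is validated against a brute-force enumerator
instead of a ground-truth table.

What the generator does **not** emulate: MEDLINE-scale vocabulary,
structured-abstract section labels, ambiguous or overlapping names,
cross-species homonyms, and the error profile of a statistical entity
recognizer. A green planted-recovery test therefore establishes that the
classification rules and plumbing are correct — not that recall or
precision on real literature is 1. Corpus-scale counts of any real corpus
depend on the dictionaries used and are not comparable across lexicons.

## Parallel execution model

The parallel unit is the input file: each forked worker processes whole
files, loads its own read-only lexicon copy, and writes one TSV per input
file. No shared mutable state exists, sharding is deterministic
round-robin, and after canonical sorting the concatenated outputs are
byte-identical for any worker count — the package's tests assert this for
1, 2 and 4 workers over a 50-file corpus. Every stage is also exposed as a
CLI subcommand on single files, so an external scheduler (e.g. GNU
parallel over a path-list file) can replace the built-in sharding.

## Degenerate inputs and numerical choices

Empty lexicons, empty abstracts, abstracts without a PMID (skipped with a
warning), corrupt XML files (skipped and logged at the run level, fatal at
the single-file level), unknown tax-IDs (legally select nothing) and empty
result folders (an error naming the folder) are all exercised in the test
suite. The lexicon store rejects taxon synonyms mapped to two different
ids and resolves duplicate bioentity surfaces deterministically (C-sorted
first entry), so loading is order-independent.

## Known limitations

- Dictionary tagging cannot find names absent from the lexicon; the
  bundled plant lexicon is a small demonstration stand-in, not a
  production dictionary.
- Genes and proteins with identical names remain distinct normalized
  entities only if the lexicon says so; the store itself maps one surface
  to one entry.
- Co-occurrence is not interaction: even type 1 only asserts that a
  trigger term sits between two names in one sentence.
- Only titles and abstracts are mined; relations described solely in full
  text are invisible, and an interaction absent from abstracts will appear
  "poorly described" regardless of its real support.
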