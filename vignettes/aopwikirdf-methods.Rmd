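---
title: "From AOP-Wiki XML to a linked-data knowledge graph: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From AOP-Wiki XML to a linked-data knowledge graph: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aopwikirdf)
```

## The conversion model

An adverse outcome pathway (AOP) is a directed chain of key events (KEs)
from a molecular initiating event (MIE), usually the chemical perturbation
of a protein, to an adverse outcome (AO), with each edge a key event
relationship (KER) carrying evidence text. `aopwikirdf` turns an
AOP-Wiki-style XML dump of such pathways into an RDF knowledge graph in
three stages: a typed in-memory knowledge model, identifier enrichment, and
deterministic Turtle emission.

Every emitted statement is governed by two declarative tables shipped with
the package rather than by code: a prefix registry (`vocab_registry()`)
that fixes each namespace's base IRI and category (metadata vocabulary,
domain ontology, or identifier namespace), and a per-entity predicate
schema (`schema_for()`) listing, in serialization order, each predicate
CURIE, its object kind (IRI reference, literal, typed literal, URL) and
cardinality. The AOP slice has 26 predicate rows; KEs, KERs, stressors,
chemicals, annotation terms and text-mapped genes have their own slices.
Extending the schema is a data edit, not a code change.

Identifier IRIs follow identifiers.org compact-identifier patterns
(`aop:38` → `https://identifiers.org/aop/38`), which keeps every subject
resolvable. Ontology terms use their conventional bases (OBO PURLs for CL,
Uberon, GO, PATO, PR and relatives; the CHEMINF and NCI Thesaurus bases for
chemical and thesaurus terms). One deliberate exception: ChEBI appears both
as an annotation ontology (biological objects) and as a chemical identifier
database. A registry prefix can have only one expansion, so `chebi:` always
resolves through identifiers.org; the consequence is that ChEBI terms count
as identifier links, not as an extra ontology namespace, in the statistics.

## Parsing and the dialect escape hatch

The wiki's quarterly dump has no published schema, and its element names
are not stable API. The parser therefore reads a documented fixture dialect
(`<data><aop id="38"><title>…`) whose element names map one-to-one onto the
model fields, and takes a YAML dialect file that overrides any element or
attribute name, so a real dump can be adapted without touching code.

Validation during parsing is deliberately tolerant, because the live wiki
contains work in progress: entities missing an id or title are skipped with
a warning (and counted, so nothing is lost silently); an MIE or AO id
outside its AOP's KE list is dropped with a warning; a KER linking a key
event to itself is rejected; cross-references to unknown entities are
retained but logged as dangling. CAS numbers must match the loose
`\d{2,7}-\d{2}-\d` pattern and InChIKeys the `14-10-1` uppercase block
structure; violations drop the offending value, not the entity. Timestamps
are kept as ISO-8601 strings (the printed form has no timezone);
lexicographic comparison is sound for this format and avoids timezone
mangling on re-emission.

## Gene text mapping

KE and KER free text is scanned for human gene mentions against a
dictionary built from an HGNC table: approved symbols, full names, alias
symbols and alias names. Exactly five fields are scanned: the KE
description, the MIE/AO-specific sections of KEs, the KER description, and
the biological-plausibility and empirical-support sections of KERs.

The matching contract is *boundary-aware exact matching*: a surface form
matches only where it is flanked by separator characters — whitespace plus
`()[]{}.,;:/"'-` — or by the string boundaries. This is equivalent to
enumerating all separator-delimited variants of every symbol but without
the combinatorial dictionary blow-up, and it makes the no-partial-word
property (`UROD` never matches inside `sURODx`) provable. Three tunables
matter:

* **Case rules.** Symbols and alias symbols match case-sensitively; full
  names and multi-word aliases case-insensitively. Gene symbols collide
  with ordinary abbreviations far more often than full names do, and case
  sensitivity removes most of those false hits while costing little recall
  in practice.
* **Minimum form length** (default 2 characters) and a **stop list**
  (default empty) for symbols known to be ambiguous in a corpus. The
  defaults are permissive by design — dictionary matching on free text
  will always pick up some abbreviation collisions, and the audit table of
  matches (with character spans) exists so downstream users can filter.
* **Collision resolution.** When two HGNC records share a surface form,
  the form is assigned deterministically: approved symbol beats name beats
  alias symbol beats alias name; remaining ties go to the lower numeric
  HGNC id. Every collision is logged on the dictionary object.

Character spans are 0-based and half-open, and the scanner finds
overlapping occurrences (relevant for forms containing separator
characters). The test suite checks equivalence against an independent
regex-lookaround oracle on random 10 kb texts.

## Identifier enrichment

Two independent routes add gene/protein identifiers. PRotein Ontology
terms used as KE biological objects are mapped through a promapping-style
table to UniProt, HGNC and NCBI Gene; these links live in the main graph on
the term subjects. Text-mapped HGNC genes are expanded to NCBI Gene,
UniProt and Ensembl; these links live in the separate gene graph, keeping
the dictionary-derived (and thus noisier) content cleanly separable from
wiki-native content.

Chemicals expand from CAS numbers to nine databases (ChEBI, ChemSpider,
Wikidata, ChEMBL, PubChem, DrugBank, KEGG, LIPID MAPS, HMDB). All
expansion goes through a pluggable backend contract: the default is a
static four-column table (deterministic, offline), and a BridgeDb-style
HTTP client is available opt-in, translating BridgeDb data-source names to
registry tokens through a shipped declarative map. Backends that return
out-of-scope databases are filtered with a log message; transport failures
raise a distinct error class so callers can retry without mistaking
"service down" for "no mapping". Only direct lookups are performed — no
transitive mapping chains. Stressors can carry several CAS numbers; each is
mapped independently.

## Emission and serialization

Each entity subject receives one `rdf:type` triple (chemicals two: chemical
entity and CAS registry number), one triple per populated field in schema
order, and `dcterms:isPartOf` links to every referencing parent. Link
objects are restricted to entities actually present in the model, which
makes referential closure (every internally linked IRI is a typed subject)
an invariant rather than a hope. Free-text annotations without ontology ids
— biological actions like `"WIKI:2"`, taxonomy entries like `"WCS_9606"` —
are emitted as plain literals under the same predicate as their
ontology-backed siblings.

Literals are plain strings except creation/modification timestamps
(`xsd:dateTime`) and the VoID counts (`xsd:integer`); no language tags are
used (the wiki is English-only). Identifier nodes are typed with their
database class (CHEMINF for the 12 chemical databases, EDAM for the 4
gene/protein databases) so link-outs can be counted per database by a
single query.

R has no installed RDF stack, so the triple container, Turtle writer and
Turtle reader are part of the package. The writer is deterministic by
construction — prefixes in registry order, subjects sorted, predicates in
schema order with `rdf:type` first, objects sorted, bytes identical across
runs — which makes diff-based regression testing and the
serialize→parse→serialize fixed-point test possible. The reader covers the
emitted subset plus the common core of Turtle (prefixed names, both literal
quoting forms, escapes, datatypes, object/predicate lists); blank nodes and
language tags are rejected with located errors, which is a feature for a
validator. The gene graph is written to its own file, VoID metadata (two
`void:Dataset` descriptions with title, license, creation date, source
snapshot, triple/subject/object counts, and link-out counts as a
`void:Linkset`) to a third. The VoID creation date defaults to the XML
snapshot date so that re-running a conversion is byte-identical; pass an
explicit `created` to record wall-clock provenance instead.

## Validation and statistics

`validate_files()` re-implements the error classes of a standalone Turtle
validator: syntax errors with file/line positions, XSD datatype lexical
checks (dateTime, date, integer, decimal, double, boolean), and dangling
internal links (AOP-Wiki entity IRIs used as objects but never defined).
`compute_stats()` computes totals, subjects per type, predicate frequency,
link-outs per database and ontology-namespace usage by direct triple
iteration; the shipped SPARQL catalog (`query_catalog()`) expresses the
same statistics for use against any endpoint, and the test suite runs every
non-federated query through an independent SPARQL engine (python rdflib)
and checks agreement with the R implementation. The federated WikiPathways
template is shipped with a `SERVICE` clause but is never executed offline.

The ontology-usage statistic counts non-identifier registry namespaces
appearing among predicate IRIs and the IRIs participating in `rdf:type`
statements — i.e. the vocabularies doing semantic work, as opposed to
identifier namespaces that merely name entities. On a fully annotated
conversion this covers the 16 core vocabularies plus the KE-component
annotation ontologies (CL, Uberon, MI, MP, MeSH, HP, PCO, NBO, VT, PR,
FMA).

## The synthetic fixture generator

`generate_fixture()` emulates the structure of a dump: linear KE chains per
AOP (first KE the MIE, last the AO), consecutive KERs, stressors attached
round-robin of which 63% carry chemicals (the proportion reported for the
live wiki), on average two gene symbols planted per scanned text field
(Poisson), and decoy tokens that embed symbols inside longer words at rate
0.5 to exercise the matcher's boundary rules. Symbols come from a bundled
50-symbol mini HGNC table of real public gene nomenclature. Generation is
truth-first: symbols are planted and recorded, so the truth object
enumerates every expected match exactly, and the end-to-end test is an
equality, not a tolerance. The same seed yields byte-identical bundles.

What the generator does *not* emulate: realistic prose (filler text is a
fixed word list, so name/alias matching hits far less often than on real
descriptions), gene-symbol/abbreviation homonyms, the wiki's scale (a few
hundred AOPs, thousands of KEs/KERs), markup inside descriptions, or
incomplete in-progress entries. Passing tests therefore demonstrate the
correctness of the mechanics — parsing, matching semantics, mapping joins,
schema conformance, serialization — not the precision of dictionary
matching on real wiki prose, which is known to produce some false
positives.

A hand-written canonical fixture complements the random ones: it mirrors
well-known wiki records (AOP 38 with every schema field populated, KE 1502,
KER 865 with its UROD mention, stressor 208, acetaminophen with
cross-references to all nine chemical databases) and is the basis for the
exemplar-triple tests and the acceptance script.

## Problem sizes and limitations

The test suite runs the canonical fixture (3 AOPs, 8 KEs, ~460 triples)
plus several seeded random fixtures, 100 random 10 kb texts for the matcher
oracle, and completes in well under a minute on one CPU; these sizes were
chosen because every property tested is size-invariant (set semantics,
closure, equality against truth), so larger fixtures add runtime, not
coverage.

Known limitations: exact dialect fidelity to any particular real quarterly
dump cannot be asserted without that dump (the dialect file is the
adapter); matching is exact-dictionary only — no NER, no disambiguation,
human genes only; the Turtle reader is not a full Turtle 1.1 parser (no
blank nodes, collections, or language tags); and the HTTP backend is
exercised against recorded responses, not a live BridgeDb instance.
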