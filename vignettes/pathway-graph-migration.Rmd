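---
title: "Migrating a frame-based pathway knowledgebase to a property graph"
author: "kbgraph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Migrating a frame-based pathway knowledgebase to a property graph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kbgraph)
```

## The model

Curated pathway knowledgebases in the Reactome tradition use a
frame-based knowledge representation: a hierarchy of classes with typed
slots, instantiated as objects whose slots hold either primitives
(strings, numbers, booleans) or references to other instances. Two
families of classes dominate. *Events* are the building blocks of
biological processes: `Pathway` objects group ordered events through
`hasEvent`, and `ReactionLikeEvent`s (RLEs) — `Reaction`,
`FailedReaction`, `Polymerisation`, `Depolymerisation`,
`BlackBoxEvent` — are single-step molecular transformations with ordered
`input` and `output` participants. *PhysicalEntities* (PEs) are those
participants: `SimpleEntity` for chemicals,
`EntityWithAccessionedSequence` for proteins, `Complex` for
multi-molecular assemblies (`hasComponent`), and `EntitySet` for
functional groupings (`hasMember`, plus `hasCandidate` for uncertain
members). Catalysis and regulation are modelled through intermediate
objects — `CatalystActivity.physicalEntity` and `Regulation.regulator` —
rather than direct RLE→PE edges, which keeps role metadata extensible
and mirrors how the production schema draws those relationships.

The built-in schema (`builtinSchema()`) fixes a deliberately minimal
core: the full production schema has on the order of ninety classes, but
every query this package implements needs only event containment,
reaction participation, catalysis/regulation, and entity composition.
The schema is extensible at run time (`extendSchema()`) but built-in
classes are frozen — extensions can add, never redefine.

In a relational layout every many-to-many slot needs a junction table,
and the retrieval queries become chains of joins. The same content maps
naturally onto a labelled property graph by two rules: primitive slots
become node properties, and reference slots become typed directed edges.
That migration, its verification, and the traversal queries it enables
are the subject of this package.

## Representation choices

**Labels.** Every node carries its full class ancestor chain as labels,
concrete class first (`Reaction`, `ReactionLikeEvent`, `Event`,
`DatabaseObject`). Label lookup thereby implements polymorphic class
queries — `findNodes(g, "label", "PhysicalEntity")` returns every
entity regardless of concrete subtype — the same way multi-label nodes
are used in Neo4j deployments of this data.

**Edge order and stoichiometry.** Ordered multi-valued slots (pathway
events, reaction inputs/outputs, complex components) keep their
insertion order in a 0-based `order` edge property, contiguous within
each (source, type) group. An entity consumed twice appears as two
distinct ordered edges, each also carrying a `stoichiometry` count; the
production data admits either reading (repeated edges or a counter), so
both are populated and consumers choose.

**Identity.** `dbId` doubles as the node id, and the store-wide unique
`stId` is an opaque indexed string — it is treated purely as a lookup
key, with no checksum semantics.

## The importer

Conversion walks the store depth-first from the top-level pathways,
iteratively with an explicit stack (deep event nests must not exhaust
the call stack), keyed on `dbId` for the visit-once guarantee: each
instance materializes exactly one node no matter how many references
point at it, and instances met again contribute edges only. Edges are
created at the moment their source instance is expanded — targets are
materialized before the edge — so the graph never holds a dangling edge
at any intermediate point.

Instances unreachable from the top-level pathways ("orphans") are
excluded by default, matching what a traversal-driven migration
naturally does, but the exclusion is never silent: the `ImportReport`
lists them, the integrity module counts them as an informational note,
and `includeOrphans = TRUE` imports them in a second pass. Reachability
is defined solely from top-level pathways, so instances referenced only
by unreachable instances are orphans too.

## Queries

All node-set results are sorted by `dbId`, and chains by (length,
lexicographic id sequence): determinism is preferred over "natural"
order everywhere, which is what makes results comparable across
insertion orders and storage layouts.

Decisions where the behaviour was genuinely open:

* **Participants.** "Participating molecules" of a pathway includes
  inputs, outputs, catalyst PEs and regulators by default; flags
  (`includeCatalysts`, `includeRegulators`) allow the narrower reading.
  Participants are reported either as stated PEs (`decompose = FALSE`)
  or expanded to leaf molecules (`decompose = TRUE`; the CLI default,
  since "molecules" suggests the leaf level).
* **Candidates.** `hasCandidate` members of entity sets are uncertain
  members and are excluded from decomposition by default,
  includable by flag. A leaf is a node with no outgoing composition
  edges *among the active types*: a set whose only children are
  candidates is, under the members-only view, an empty container and
  therefore its own leaf.
* **Inverse lookup.** `pathwaysForEntity()` is defined as the exact
  inverse image of `pathwayParticipants()` and implemented by upward
  traversal (composition edges inward, then reaction-role edges inward,
  then `hasEvent` closure inward). A sharp edge follows from the
  definition: with `leafMatch = TRUE` only leaf molecules can match, so
  a complex queried with `leafMatch = TRUE` returns the empty set — use
  `leafMatch = FALSE` for entities stated directly as participants. The
  tests verify the duality exhaustively over every (pathway, entity)
  pair.
* **Reaction chains.** The cascade query names a use case but not a
  linkage rule; the default links consecutive reactions when an output
  of one is an input of the next (`link = "sharedEntity"`), with
  explicit `precedingEvent` edges available as an alternative mode.
  Chains are acyclic by construction, every suffix of a cascade is
  itself a chain, and `maxLength` (default 5) bounds the enumeration.
* **Lazy loading.** `fetchObject()` honours the lazy-loading contract:
  shallow fetches return `list(ref = dbId)` placeholders whose
  on-demand resolution yields exactly the values an eager fetch
  produces. Full fetches expand the closure, emitting a placeholder
  only where a reference cycles back onto the current expansion path —
  so `precedingEvent` feedback terminates. Value-level lazy/eager
  equivalence holds everywhere; deep structural equality of a resolved
  subtree additionally holds on acyclic neighbourhoods (all composition
  structures, which are DAGs by construction).

## Integrity verification

After migration, `verifyAll()` re-derives content from both sides and
compares: the count of top-level pathways (graph side: `Pathway` nodes
with no incoming `hasEvent`); ancestor chains of every pathway computed
by graph traversal versus directly over reversed store slots; the
content of every complex and set under both candidate settings and in
both readings (leaf decomposition and direct children); and conservation
— the reachable instance set against the node set, and every reference
slot value against the exact edge tuple set (source, type, order,
target). Comparing tuples rather than counts is what makes every
single-element mutation (node or edge added, deleted, retargeted)
detectable, which the tests confirm with randomized mutation sweeps.
Orphans excluded on purpose are reported as notes, not failures. A
seeded sampling mode exists because checking every pathway is expensive
at production scale; samples are reproducible by construction.

## The synthetic generator

`generateKB()` emulates the structure the production content has — a
forest of pathways nested to bounded depth, reactions over a pool of
proteins and chemicals, nested complexes and entity sets, catalysts,
regulators, shared entities, feedback — with every answer the test suite
needs recorded *while building* (participant sets per flag combination,
leaf decompositions, ancestor chains, the reachable/orphan partition),
independently of the importer and query code under test. Defaults: 3
top-level pathways, nesting depth ≤ 3, 2–5 reactions per pathway, 50
proteins + 20 chemicals, complexes over a quarter and sets over a tenth
of the leaf pool, composition nesting ≤ 3, catalyst probability 0.3,
regulator probability 0.2, shared-entity probability 0.3 (so visit-once
deduplication is genuinely exercised), feedback cycle probability 0.1.
These yield knowledgebases of roughly 130–200 instances — large enough
to contain every structural motif, small enough that brute-force oracle
enumeration stays trivially fast.

Two constraints are deliberate. Composition structures are DAGs: a
complex containing itself is biologically impossible and would leave
"leaf molecule" undefined, so cycles are injected only into
`precedingEvent`, where the domain admits feedback. And every
non-orphan entity is made reachable (leftover pool entities are
attached as inputs of random reactions) so that `orphanCount` is exact.
What the generator does *not* emulate: real curation noise, species
annotations beyond a constant, literature references, kinetics, and
production scale (tens of thousands of instances). Passing tests
therefore demonstrate structural correctness of migration and queries,
not performance or robustness to malformed curation.

The fixed `workedToy()` knowledgebase (19 instances exercising every
edge type) anchors the documentation; its expected decompositions,
chains and participant sets are hand-enumerated in
`inst/extdata/worked_toy_expected.json`.

## Benchmark harness

`runSequential()` and `runConcurrent()` mirror the two classic
stress-test designs — one user querying distinct reactions in a fixed
seeded sequence (no repeats, so caching gives no backend an advantage),
and the same workload partitioned over increasing worker counts — at
desk scale: 500 queries and 1–8 workers in the shipped checks, against
a generated knowledgebase with 500+ reactions. Each query marshals the
complete reaction object (`fetch` depth full; the marshalling depth of
the production services is unstated, so it is fixed and documented
here). Two backends answer the same contract: join-style access over
the relational tables (class located via the `database_object` table,
references resolved through junction tables) versus graph traversal.

Correctness is the testable claim: both backends and all concurrency
levels must return identical marshalled objects. Latency and TPS are
reported, never asserted — wall-clock figures are hardware-bound, and a
desk-scale in-memory comparison says nothing about the relative
performance of production database servers; the harness measures usage
patterns, not storage technologies.

## Numerical and degenerate-input conventions

Traversals are breadth-first with a visited set; a node's depth is its
minimum depth; traversal results are independent of start ordering.
Start nodes appear in a closure only if re-reached by a nonzero-length
path. Unknown identifiers yield typed not-found errors in queries but
empty results in index lookups; a reaction id passed where a pathway is
required is a typed error, not an empty answer. Dump round trips are
byte-stable under canonical ordering (instances by dbId, slots
alphabetically, edges by source/type/order/target); GraphML numeric
properties round-trip through declared key types, with mixed-type keys
degrading to strings.

## Problem sizes used in the shipped checks

The test suite and `scripts/acceptance.R` run 20 seeded knowledgebases
(~130–200 instances each) for conservation, soundness, and
query/ground-truth agreement; randomized mutation sweeps per seed;
exhaustive duality over every (pathway, entity) pair on five of them;
and the 500-query benchmark workload above. These sizes keep brute-force
oracles exact and the whole suite comfortably fast while covering every
structural motif the generator can produce.

## Known limitations

No Cypher parser (the Cypher export is write-only); no transactions or
on-disk storage; no incremental release-to-release diffing; no species
orthology projection; the relational dialect is the package's own CSV
layout rather than a live curation database. The schema core is minimal
by design — users needing more classes extend it at run time.
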