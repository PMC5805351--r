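# kbgraph

Pathway knowledgebases such as Reactome store their content in a
frame-based model — classes ("frames") like `Pathway`,
`ReactionLikeEvent` and `PhysicalEntity` with typed attributes ("slots")
holding primitives or references to other instances — traditionally
persisted in a relational database where every many-to-many slot needs a
junction table. Queries that matter to pathway biology (recursively
collecting the reactions of a pathway, enumerating participating
molecules, deconstructing a complex or set into its leaf molecules,
tracing the cascade of reactions that forms a signalling complex)
traverse this highly interconnected data and degrade into long chains of
joins. The same content stored as a labelled property graph answers
those questions by direct traversal.

`kbgraph` is a self-contained R implementation of that migration and
query ecosystem, aimed at bioinformatics developers who want to
experiment with graph-based pathway storage without standing up a
database server:

* **model** — the frame-based schema machinery and a built-in
  Reactome-style pathway schema (`DatabaseObject` → `Event` →
  {`Pathway`, `ReactionLikeEvent` → `Reaction`, `FailedReaction`,
  `Polymerisation`, `Depolymerisation`, `BlackBoxEvent`} and
  `DatabaseObject` → `PhysicalEntity` → {`SimpleEntity`,
  `EntityWithAccessionedSequence`, `Complex`, `EntitySet`}, plus
  `CatalystActivity` and `Regulation`), with instance and store
  validation.
* **graphstore** — an embedded labelled property graph: multi-label
  nodes carrying the class ancestor chain, typed directed edges with
  per-slot `order` and `stoichiometry` properties, dbId/stId/label
  indexes, BFS traversal, and GraphML / JSON / Cypher-script
  serialization.
* **importer** — relational CSV dump (entity tables + junction tables)
  or JSON object-store in, property graph out, by the classic two
  conversion rules: primitive slots become node properties, reference
  slots become relationships. The walk is depth-first from the top-level
  pathways with a visit-once guarantee; unreachable instances are
  reported as orphans (importable by flag, never silently dropped).
* **query** — `reactionIO()`, `pathwayEvents()`,
  `pathwayParticipants()`, `decomposeEntity()`, `pathwaysForEntity()`,
  `eventAncestors()`, `reactionChainsTo()` and a lazy/eager
  `fetchObject()` with reference placeholders.
* **integrity** — post-migration verification that both representations
  carry the same content: top-level pathway counts, ancestor chains,
  complex content, and element-by-element conservation of instances and
  reference values (`verifyAll()`).
* **synthdata** — a seeded generator of Reactome-shaped synthetic
  knowledgebases with construction-time ground truth
  (`generateKB()`, `synthConfig()`), plus a fixed hand-written toy
  (`workedToy()`).
* **bench** — a desk-scale stress-test harness comparing join-style
  relational access against graph traversal (`runSequential()`,
  `runConcurrent()`), reporting latency and throughput.

## Worked example

```r
library(kbgraph)

toy <- workedToy()                      # 19-instance hand-written KB
res <- importKnowledgebase(toy$store)
res$report
#> ImportReport: 19 instances seen, 19 nodes, 26 edges, 0 orphans (excluded)

g <- res$graph
reactionIO(g, 3)                        # ligand + receptor -> bound receptor
#> $inputs
#> [1] 6 7
#> $outputs
#> [1] 12

decomposeEntity(g, 15)                  # signalling complex -> leaf molecules
#> [1]  8  9 10

pathwaysForEntity(g, 9, leafMatch = TRUE)   # scaffold protein, only inside
#> [1] 1                                    # the complex: found as a leaf

overallPass(verifyAll(toy$store, g))    # store and graph carry equal content
#> [1] TRUE
```

The numbers are dbIds: entity 15 is the two-level signalling complex
whose leaves are proteins 8, 9 and 10; pathway 1 is the toy's top-level
pathway. A larger seeded knowledgebase comes from
`generateKB(synthConfig(seed = 1))`.

A thin command-line wrapper is installed at
`system.file("cli", "kbgraph", package = "kbgraph")` with subcommands
`generate`, `import`, `export`, `query`, `verify` and `bench`.

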