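#' @import methods
NULL

#' SlotDefinition: a typed attribute of a schema class
#'
#' A slot holds either primitive values (string, number, boolean) or
#' references to instances of another class. Multi-valued reference slots
#' may declare that insertion order is meaningful (e.g. the events of a
#' pathway).
#'
#' @slot name identifier string.
#' @slot cardinality `"one"` or `"many"`.
#' @slot valueKind `"string"`, `"number"`, `"boolean"` or `"reference"`.
#' @slot targetClass for reference slots, the name of the class the slot
#'   points at; `NA` for primitive slots.
#' @slot ordered logical; ordered multi-valued reference slots preserve
#'   insertion order.
#' @exportClass SlotDefinition
setClass("SlotDefinition",
  representation(
    name = "character",
    cardinality = "character",
    valueKind = "character",
    targetClass = "character",
    ordered = "logical"
  ),
  prototype(targetClass = NA_character_, ordered = FALSE)
)

setValidity("SlotDefinition", function(object) {
  msgs <- character()
  if (length(object@name) != 1L || !nzchar(object@name))
    msgs <- c(msgs, "slot name must be a single non-empty string")
  if (!object@cardinality %in% c("one", "many"))
    msgs <- c(msgs, "cardinality must be 'one' or 'many'")
  if (!object@valueKind %in% c("string", "number", "boolean", "reference"))
    msgs <- c(msgs, "valueKind must be string/number/boolean/reference")
  if (object@valueKind == "reference" && is.na(object@targetClass))
    msgs <- c(msgs, "reference slots must name a target class")
  if (object@valueKind != "reference" && !is.na(object@targetClass))
    msgs <- c(msgs, "primitive slots never reference a class")
  if (length(msgs)) msgs else TRUE
})

#' SchemaClass: a frame in the knowledge model
#'
#' @slot name class name.
#' @slot parent parent class name, or `NA` for the root class.
#' @slot slots list of [SlotDefinition-class] objects defined on this
#'   class (inherited slots are resolved through the schema).
#' @exportClass SchemaClass
setClass("SchemaClass",
  representation(
    name = "character",
    parent = "character",
    slots = "list"
  ),
  prototype(parent = NA_character_, slots = list())
)

setValidity("SchemaClass", function(object) {
  msgs <- character()
  if (length(object@name) != 1L || !nzchar(object@name))
    msgs <- c(msgs, "class name must be a single non-empty string")
  if (!all(vapply(object@slots, is, logical(1), class2 = "SlotDefinition")))
    msgs <- c(msgs, "slots must all be SlotDefinition objects")
  if (length(msgs)) msgs else TRUE
})

#' Schema: a collection of classes forming a single-rooted hierarchy
#'
#' @slot classes named list of [SchemaClass-class] objects, keyed by
#'   class name.
#' @exportClass Schema
setClass("Schema", representation(classes = "list"))

setValidity("Schema", function(object) {
  msgs <- character()
  cls <- object@classes
  nms <- vapply(cls, function(c) c@name, character(1))
  if (!identical(unname(nms), names(cls) %||% character()) && length(cls))
    msgs <- c(msgs, "classes must be keyed by their own name")
  parents <- vapply(cls, function(c) c@parent, character(1))
  roots <- sum(is.na(parents))
  if (length(cls) && roots != 1L)
    msgs <- c(msgs, "class hierarchy must have exactly one root")
  bad <- parents[!is.na(parents) & !parents %in% nms]
  if (length(bad))
    msgs <- c(msgs, paste0("unresolved parent class(es): ",
                           paste(unique(bad), collapse = ", ")))
  ## cycle check by walking every parent chain
  for (n in nms) {
    seen <- character()
    p <- n
    while (!is.na(p)) {
      if (p %in% seen) { msgs <- c(msgs, "inheritance cycle detected"); break }
      seen <- c(seen, p)
      p <- if (p %in% nms) cls[[p]]@parent else NA_character_
    }
  }
  if (length(msgs)) unique(msgs) else TRUE
})

#' Instance: one knowledgebase object
#'
#' @slot dbId positive integer identifier, unique knowledgebase-wide.
#' @slot stId stable identifier string (e.g. `"R-XXX-nnnnn"`), unique.
#' @slot className name of a schema class.
#' @slot displayName human-readable name.
#' @slot slotValues named list mapping slot names to primitive values or
#'   integer vectors of referenced dbIds.
#' @exportClass Instance
setClass("Instance",
  representation(
    dbId = "integer",
    stId = "character",
    className = "character",
    displayName = "character",
    slotValues = "list"
  ),
  prototype(slotValues = list())
)

setValidity("Instance", function(object) {
  msgs <- character()
  if (length(object@dbId) != 1L || is.na(object@dbId) || object@dbId <= 0L)
    msgs <- c(msgs, "dbId must be a single positive integer")
  if (length(object@stId) != 1L || !nzchar(object@stId))
    msgs <- c(msgs, "stId must be a single non-empty string")
  if (length(object@className) != 1L)
    msgs <- c(msgs, "className must be a single string")
  sv <- object@slotValues
  if (length(sv) && (is.null(names(sv)) || any(!nzchar(names(sv)))))
    msgs <- c(msgs, "slotValues must be a named list")
  if (length(msgs)) msgs else TRUE
})

#' ObjectStore: the relational/object-side view of a knowledgebase
#'
#' Holds a schema, all instances keyed by dbId, and the list of top-level
#' pathways that root the event forest.
#'
#' @slot schema a [Schema-class].
#' @slot instances named list of [Instance-class] objects; names are the
#'   dbIds as strings.
#' @slot topLevelPathways integer vector of Pathway dbIds with no parent.
#' @exportClass ObjectStore
setClass("ObjectStore",
  representation(
    schema = "Schema",
    instances = "list",
    topLevelPathways = "integer"
  ),
  prototype(instances = list(), topLevelPathways = integer())
)

#' PropertyGraph: an embedded labelled property graph
#'
#' Nodes carry an ordered label set (concrete class first, then its
#' ancestors) and a map of primitive properties. Edges are typed and
#' directed, carry a 0-based `order` index within their (source, type)
#' group and a `stoichiometry` count.
#'
#' @slot nodes named list keyed by node id (as string); each element is a
#'   list with `node_id`, `labels`, `properties`.
#' @slot edges data.frame with columns `source`, `target`, `type`,
#'   `order`, `stoichiometry`.
#' @slot stIdIndex named integer vector mapping stId -> node id.
#' @slot labelIndex named list mapping label -> integer vector of node ids.
#' @exportClass PropertyGraph
setClass("PropertyGraph",
  representation(
    nodes = "list",
    edges = "data.frame",
    stIdIndex = "integer",
    labelIndex = "list"
  )
)

#' ImportReport: bookkeeping from a knowledgebase import
#'
#' @slot instancesSeen number of instances in the source store.
#' @slot nodesCreated nodes materialised in the graph.
#' @slot edgesCreated edges materialised in the graph.
#' @slot orphanInstances dbIds not reachable from the top-level pathways.
#' @slot perClassCounts named integer vector of node counts per concrete
#'   class.
#' @slot includeOrphans whether orphans were imported in a second pass.
#' @exportClass ImportReport
setClass("ImportReport",
  representation(
    instancesSeen = "integer",
    nodesCreated = "integer",
    edgesCreated = "integer",
    orphanInstances = "integer",
    perClassCounts = "integer",
    includeOrphans = "logical"
  )
)

#' IntegrityReport: result of post-migration verification
#'
#' @slot checks data.frame with columns `name`, `pass`, `detail`.
#' @slot overallPass TRUE iff every check passed.
#' @slot notes informational messages (e.g. orphans intentionally
#'   excluded) that do not fail verification.
#' @exportClass IntegrityReport
setClass("IntegrityReport",
  representation(
    checks = "data.frame",
    overallPass = "logical",
    notes = "character"
  ),
  prototype(notes = character())
)

setValidity("IntegrityReport", function(object) {
  if (!identical(object@overallPass, all(object@checks$pass)))
    "overallPass must equal all(checks$pass)" else TRUE
})

#' SynthConfig: parameters of the synthetic knowledgebase generator
#'
#' @slot seed integer RNG seed; identical config+seed gives identical
#'   output.
#' @slot nTopPathways number of top-level pathways.
#' @slot maxPathwayDepth maximum nesting depth of sub-pathways.
#' @slot reactionsPerPathway integer range (lo, hi) of reactions per
#'   pathway.
#' @slot nProteins,nChemicals sizes of the leaf-molecule pools.
#' @slot complexFraction,setFraction number of complexes / entity sets as
#'   a fraction of the leaf pool.
#' @slot maxComplexNesting maximum depth of the composition DAG.
#' @slot membersPerSet integer range of members per entity set.
#' @slot catalystProbability,regulatorProbability per-reaction chance of
#'   a catalyst activity / regulation.
#' @slot sharedEntityProbability chance a reaction participant is drawn
#'   from already-used entities (exercises visit-once deduplication).
#' @slot cycleProbability chance of a feedback cycle in precedingEvent
#'   (the only relation where cycles are injected).
#' @slot orphanCount instances generated unreachable from top-level
#'   pathways.
#' @exportClass SynthConfig
setClass("SynthConfig",
  representation(
    seed = "integer",
    nTopPathways = "integer",
    maxPathwayDepth = "integer",
    reactionsPerPathway = "integer",
    nProteins = "integer",
    nChemicals = "integer",
    complexFraction = "numeric",
    maxComplexNesting = "integer",
    setFraction = "numeric",
    membersPerSet = "integer",
    catalystProbability = "numeric",
    regulatorProbability = "numeric",
    sharedEntityProbability = "numeric",
    cycleProbability = "numeric",
    orphanCount = "integer"
  )
)

setValidity("SynthConfig", function(object) {
  msgs <- character()
  counts <- c(object@nTopPathways, object@maxPathwayDepth, object@nProteins,
              object@nChemicals, object@maxComplexNesting, object@orphanCount)
  if (any(is.na(counts)) || any(counts < 0L))
    msgs <- c(msgs, "all counts must be >= 0")
  probs <- c(object@complexFraction, object@setFraction,
             object@catalystProbability, object@regulatorProbability,
             object@sharedEntityProbability, object@cycleProbability)
  if (any(is.na(probs)) || any(probs < 0) || any(probs > 1))
    msgs <- c(msgs, "probabilities/fractions must lie in [0, 1]")
  for (r in list(object@reactionsPerPathway, object@membersPerSet)) {
    if (length(r) != 2L || any(is.na(r)) || r[1] > r[2] || r[1] < 0L)
      msgs <- c(msgs, "ranges must be integer (lo, hi) with 0 <= lo <= hi")
  }
  if (length(msgs)) unique(msgs) else TRUE
})

#' BenchResult: one benchmark run on one backend
#'
#' @slot backend backend label (`"graph"` or `"relational"`).
#' @slot scenario `"sequential"` or `"concurrent"`.
#' @slot nQueries number of queries executed.
#' @slot nWorkers number of concurrent workers (1 for sequential).
#' @slot latenciesMs per-query latency in milliseconds.
#' @slot meanMs,sdMs,tps,elapsedSec summary statistics; always equal to
#'   their recomputation from `latenciesMs` / `elapsedSec`.
#' @slot results marshalled object views, keyed by queried dbId (kept for
#'   cross-backend correctness checks).
#' @exportClass BenchResult
setClass("BenchResult",
  representation(
    backend = "character",
    scenario = "character",
    nQueries = "integer",
    nWorkers = "integer",
    latenciesMs = "numeric",
    meanMs = "numeric",
    sdMs = "numeric",
    tps = "numeric",
    elapsedSec = "numeric",
    results = "list"
  )
)

setValidity("BenchResult", function(object) {
  msgs <- character()
  if (object@nQueries != length(object@latenciesMs))
    msgs <- c(msgs, "nQueries must equal length(latenciesMs)")
  if (length(msgs)) msgs else TRUE
})
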