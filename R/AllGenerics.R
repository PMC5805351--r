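#' @name kbgraph-accessors
#' @title Accessors for kbgraph S4 objects
#' @description Read-only accessors for the core containers.
#' @param x an object.
#' @return the corresponding slot value.
NULL

#' @rdname kbgraph-accessors
#' @export
setGeneric("dbId", function(x) standardGeneric("dbId"))

#' @rdname kbgraph-accessors
#' @export
setGeneric("stId", function(x) standardGeneric("stId"))

#' @rdname kbgraph-accessors
#' @export
setGeneric("className", function(x) standardGeneric("className"))

#' @rdname kbgraph-accessors
#' @export
setGeneric("displayName", function(x) standardGeneric("displayName"))

#' @rdname kbgraph-accessors
#' @export
setGeneric("slotValues", function(x) standardGeneric("slotValues"))

#' @rdname kbgraph-accessors
#' @export
setGeneric("schemaOf", function(x) standardGeneric("schemaOf"))

#' @rdname kbgraph-accessors
#' @export
setGeneric("instances", function(x) standardGeneric("instances"))

#' @rdname kbgraph-accessors
#' @export
setGeneric("topLevelPathways", function(x) standardGeneric("topLevelPathways"))

#' @rdname kbgraph-accessors
#' @export
setGeneric("graphNodes", function(x) standardGeneric("graphNodes"))

#' @rdname kbgraph-accessors
#' @export
setGeneric("graphEdges", function(x) standardGeneric("graphEdges"))

#' @rdname kbgraph-accessors
#' @export
setGeneric("nodeCount", function(x) standardGeneric("nodeCount"))

#' @rdname kbgraph-accessors
#' @export
setGeneric("edgeCount", function(x) standardGeneric("edgeCount"))

#' @rdname kbgraph-accessors
#' @export
setGeneric("overallPass", function(x) standardGeneric("overallPass"))

setMethod("dbId", "Instance", function(x) x@dbId)
setMethod("stId", "Instance", function(x) x@stId)
setMethod("className", "Instance", function(x) x@className)
setMethod("displayName", "Instance", function(x) x@displayName)
setMethod("slotValues", "Instance", function(x) x@slotValues)
setMethod("schemaOf", "ObjectStore", function(x) x@schema)
setMethod("instances", "ObjectStore", function(x) x@instances)
setMethod("topLevelPathways", "ObjectStore", function(x) x@topLevelPathways)
setMethod("graphNodes", "PropertyGraph", function(x) x@nodes)
setMethod("graphEdges", "PropertyGraph", function(x) x@edges)
setMethod("nodeCount", "PropertyGraph", function(x) length(x@nodes))
setMethod("edgeCount", "PropertyGraph", function(x) nrow(x@edges))
setMethod("overallPass", "IntegrityReport", function(x) x@overallPass)

setMethod("show", "Schema", function(object) {
  cat("Schema with", length(object@classes), "classes:",
      paste(utils::head(names(object@classes), 8), collapse = ", "),
      if (length(object@classes) > 8) "..." else "", "\n")
})

setMethod("show", "Instance", function(object) {
  cat(sprintf("<%s> dbId=%d stId=%s \"%s\"\n", object@className,
              object@dbId, object@stId, object@displayName))
})

setMethod("show", "ObjectStore", function(object) {
  cat(sprintf("ObjectStore: %d instances, %d top-level pathways\n",
              length(object@instances), length(object@topLevelPathways)))
})

setMethod("show", "PropertyGraph", function(object) {
  cat(sprintf("PropertyGraph: %d nodes, %d edges, %d labels\n",
              length(object@nodes), nrow(object@edges),
              length(object@labelIndex)))
})

setMethod("show", "ImportReport", function(object) {
  cat(sprintf(
    "ImportReport: %d instances seen, %d nodes, %d edges, %d orphans (%s)\n",
    object@instancesSeen, object@nodesCreated, object@edgesCreated,
    length(object@orphanInstances),
    if (object@includeOrphans) "imported" else "excluded"))
})

setMethod("show", "IntegrityReport", function(object) {
  cat(sprintf("IntegrityReport: %s (%d/%d checks passed)\n",
              if (object@overallPass) "PASS" else "FAIL",
              sum(object@checks$pass), nrow(object@checks)))
  bad <- object@checks[!object@checks$pass, , drop = FALSE]
  if (nrow(bad)) {
    for (i in seq_len(nrow(bad)))
      cat("  FAIL", bad$name[i], "-", bad$detail[i], "\n")
  }
  for (n in object@notes) cat("  note:", n, "\n")
})

setMethod("show", "BenchResult", function(object) {
  cat(sprintf(
    "BenchResult[%s/%s]: n=%d workers=%d mean=%.3f ms (sd %.3f), %.1f TPS\n",
    object@backend, object@scenario, object@nQueries, object@nWorkers,
    object@meanMs, object@sdMs, object@tps))
})

setMethod("show", "SynthConfig", function(object) {
  cat(sprintf(
    "SynthConfig: seed=%d, %d top pathways (depth<=%d), %d proteins, %d chemicals\n",
    object@seed, object@nTopPathways, object@maxPathwayDepth,
    object@nProteins, object@nChemicals))
})
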