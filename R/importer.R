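## Relational/object store -> property graph migration.
##
## Conversion rules: slots with primitive value types become node
## properties; slots holding instances of another class become typed
## directed edges. The walk is depth-first from the top-level pathways
## with a visit-once guarantee: every instance materializes exactly one
## node no matter how many references point at it.

nodePropertiesOf <- function(store, inst) {
  props <- list(dbId = inst@dbId, stId = inst@stId,
                displayName = inst@displayName)
  eff <- effectiveSlots(store@schema, inst@className)
  for (nm in names(eff)) {
    if (eff[[nm]]@valueKind == "reference") next
    if (nm %in% c("displayName", "stId")) next
    v <- inst@slotValues[[nm]]
    if (!is.null(v) && !is.na(v[1])) props[[nm]] <- v[1]
  }
  props
}

#' Convert an object store into a property graph
#'
#' Walks the store depth-first (iteratively, with an explicit stack)
#' starting from the top-level pathways. On first visit of an instance a
#' node is created whose labels are the class ancestor chain (concrete
#' class first) and whose properties are exactly the primitive slot
#' values; every reference slot value becomes one typed edge carrying
#' its 0-based `order` index and a `stoichiometry` count (how often that
#' target occurs in the slot). Already-visited instances contribute
#' edges only, never duplicate nodes, and the walk terminates on cyclic
#' references.
#'
#' Instances unreachable from the top-level pathways are orphans: they
#' are excluded by default (and listed in the report so the exclusion is
#' never silent), or imported in a second pass when
#' `includeOrphans = TRUE`.
#'
#' @param store an [ObjectStore-class].
#' @param includeOrphans import unreachable instances in a second pass.
#' @return list with `graph` (a [PropertyGraph-class]) and `report` (an
#'   [ImportReport-class]).
#' @export
importKnowledgebase <- function(store, includeOrphans = FALSE) {
  schema <- store@schema
  visited <- new.env(parent = emptyenv())
  nodes <- list()
  eSrc <- integer(); eTgt <- integer(); eType <- character()
  eOrd <- integer(); eSto <- integer()

  visit <- function(id) {
    inst <- getInstance(store, id)
    nodes[[length(nodes) + 1L]] <<- list(
      node_id = inst@dbId,
      labels = classAncestors(schema, inst@className),
      properties = nodePropertiesOf(store, inst))
    assign(as.character(id), TRUE, envir = visited)
  }
  seen <- function(id) !is.null(get0(as.character(id), envir = visited))

  walk <- function(roots) {
    for (r in roots) {
      if (seen(r)) next
      if (is.null(getInstance(store, r)))
        stopf("top-level pathway %d absent from store", r,
              class = "kbgraph_import_error")
      visit(r)
      stack <- list(r)
      while (length(stack)) {
        id <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        inst <- getInstance(store, id)
        refs <- referenceValues(store, inst)
        for (slot in names(refs)) {
          vals <- refs[[slot]]
          sto <- table(vals)
          for (k in seq_along(vals)) {
            tgt <- vals[k]
            if (is.null(getInstance(store, tgt)))
              stopf("instance %d slot %s references missing dbId %d",
                    id, slot, tgt, class = "kbgraph_import_error")
            if (!seen(tgt)) {
              visit(tgt)
              stack[[length(stack) + 1L]] <- tgt
            }
            n <- length(eSrc) + 1L
            eSrc[n] <<- id; eTgt[n] <<- tgt; eType[n] <<- slot
            eOrd[n] <<- k - 1L
            eSto[n] <<- as.integer(sto[[as.character(tgt)]])
          }
        }
      }
    }
  }

  walk(store@topLevelPathways)
  allIds <- idSort(vapply(store@instances, function(i) i@dbId, integer(1)))
  reached <- idSort(as.integer(ls(visited)))
  orphans <- setdiff(allIds, reached)
  if (includeOrphans) walk(orphans)

  edges <- data.frame(source = eSrc, target = eTgt, type = eType,
                      order = eOrd, stoichiometry = eSto,
                      stringsAsFactors = FALSE)
  graph <- buildGraph(nodes, edges)
  cls <- vapply(nodes, function(n) n$labels[1], character(1))
  perClass <- table(cls)
  report <- new("ImportReport",
                instancesSeen = length(store@instances),
                nodesCreated = length(nodes),
                edgesCreated = nrow(edges),
                orphanInstances = orphans,
                perClassCounts = stats::setNames(as.integer(perClass),
                                                 names(perClass)),
                includeOrphans = includeOrphans)
  list(graph = graph, report = report)
}
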