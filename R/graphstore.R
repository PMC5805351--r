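## Embedded labelled property graph: typed directed edges, identifier
## indexes, bounded pattern matching. The artifact's analogue of the
## graph-storage layer the migrated knowledgebase lives in.

emptyEdges <- function() {
  data.frame(source = integer(), target = integer(), type = character(),
             order = integer(), stoichiometry = integer(),
             stringsAsFactors = FALSE)
}

#' Create an empty property graph
#'
#' @return a [PropertyGraph-class] with no nodes or edges.
#' @export
emptyGraph <- function() {
  new("PropertyGraph", nodes = list(), edges = emptyEdges(),
      stIdIndex = stats::setNames(integer(), character()),
      labelIndex = list())
}

## internal bulk constructor: nodes is a list of node records, edges a
## data.frame; indexes are built in one pass
buildGraph <- function(nodes, edges = emptyEdges()) {
  names(nodes) <- vapply(nodes, function(n) as.character(n$node_id),
                         character(1))
  stIds <- vapply(nodes, function(n) n$properties$stId %||% NA_character_,
                  character(1))
  ids <- vapply(nodes, function(n) n$node_id, integer(1))
  stIdIndex <- stats::setNames(ids[!is.na(stIds)], stIds[!is.na(stIds)])
  labelIndex <- list()
  if (length(nodes)) {
    lab <- data.frame(
      label = unlist(lapply(nodes, function(n) n$labels), use.names = FALSE),
      id = rep(ids, vapply(nodes, function(n) length(n$labels), integer(1))))
    labelIndex <- lapply(split(lab$id, lab$label), idSort)
  }
  rownames(edges) <- NULL
  g <- new("PropertyGraph", nodes = nodes, edges = edges,
           stIdIndex = stIdIndex, labelIndex = labelIndex)
  miss <- setdiff(c(edges$source, edges$target), ids)
  if (length(miss))
    stopf("dangling edge endpoint(s): %s", paste(miss, collapse = ", "))
  g
}

#' Add a node to a property graph
#'
#' @param graph a [PropertyGraph-class].
#' @param nodeId integer node id (the source instance dbId).
#' @param labels ordered character vector; the first label is the
#'   concrete class, followed by its ancestors.
#' @param properties named list of primitive values (never references).
#' @return the updated graph.
#' @export
addNode <- function(graph, nodeId, labels, properties = list()) {
  nodeId <- as.integer(nodeId)
  key <- as.character(nodeId)
  if (!is.null(graph@nodes[[key]]))
    stopf("duplicate node id %d", nodeId, class = "kbgraph_duplicate_node")
  if (!length(labels)) stopf("labels must be non-empty")
  for (p in properties) if (!isScalarPrimitive(p))
    stopf("node properties must be scalar primitives")
  graph@nodes[[key]] <- list(node_id = nodeId, labels = as.character(labels),
                             properties = properties)
  if (!is.null(properties$stId)) graph@stIdIndex[[properties$stId]] <- nodeId
  for (l in labels) graph@labelIndex[[l]] <- idSort(c(graph@labelIndex[[l]], nodeId))
  graph
}

#' Add a typed directed edge
#'
#' @param graph a [PropertyGraph-class].
#' @param source,target existing node ids.
#' @param type edge type (slot name).
#' @param order 0-based index within the (source, type) group; when
#'   `NULL`, the next free index is used so that order values stay
#'   contiguous.
#' @param stoichiometry optional positive integer.
#' @return the updated graph.
#' @export
addEdge <- function(graph, source, target, type, order = NULL,
                    stoichiometry = NA_integer_) {
  source <- as.integer(source); target <- as.integer(target)
  for (ep in c(source, target)) {
    if (is.null(graph@nodes[[as.character(ep)]]))
      stopf("dangling endpoint: node %d does not exist", ep,
            class = "kbgraph_dangling_endpoint")
  }
  grp <- graph@edges$source == source & graph@edges$type == type
  if (is.null(order)) order <- sum(grp)
  order <- as.integer(order)
  if (any(grp & graph@edges$order == order))
    stopf("edge (%d,%s,order=%d) already exists", source, type, order)
  graph@edges <- rbind(graph@edges, data.frame(
    source = source, target = target, type = type, order = order,
    stoichiometry = as.integer(stoichiometry), stringsAsFactors = FALSE))
  rownames(graph@edges) <- NULL
  graph
}

#' Look up nodes by dbId, stId or label
#'
#' dbId/stId lookups return zero or one node; label lookup returns all
#' nodes carrying the label, including through ancestor labels (a
#' `"PhysicalEntity"` query matches every Complex, EntitySet,
#' SimpleEntity and EntityWithAccessionedSequence node). An absent key
#' gives an empty result, never an error.
#'
#' @param graph a [PropertyGraph-class].
#' @param by one of `"dbId"`, `"stId"`, `"label"`.
#' @param key the lookup key.
#' @return list of node records (possibly empty).
#' @export
findNodes <- function(graph, by = c("dbId", "stId", "label"), key) {
  by <- match.arg(by)
  ids <- switch(by,
    dbId = {
      n <- graph@nodes[[as.character(as.integer(key))]]
      if (is.null(n)) integer() else n$node_id
    },
    stId = {
      hit <- graph@stIdIndex[as.character(key)]
      if (length(hit) == 0L || is.na(hit)) integer() else unname(hit)
    },
    label = graph@labelIndex[[key]] %||% integer()
  )
  unname(graph@nodes[as.character(ids)])
}

getNode <- function(graph, nodeId) {
  n <- graph@nodes[[as.character(as.integer(nodeId))]]
  if (is.null(n))
    stopf("node %s not found", nodeId, class = "kbgraph_not_found")
  n
}

nodeHasLabel <- function(graph, nodeId, label)
  label %in% getNode(graph, nodeId)$labels

#' Resolve a dbId or stId to a node id
#'
#' @param graph a [PropertyGraph-class].
#' @param id integer dbId or character stId.
#' @return integer node id; errors with class `kbgraph_not_found` if
#'   unresolved.
#' @export
resolveNodeId <- function(graph, id) {
  if (is.character(id) && !grepl("^[0-9]+$", id)) {
    hit <- graph@stIdIndex[id]
    if (length(hit) == 0L || is.na(hit))
      stopf("no node with stId %s", id, class = "kbgraph_not_found")
    return(unname(hit))
  }
  getNode(graph, as.integer(id))$node_id
}

#' Edges and neighbor nodes of a node
#'
#' @param graph a [PropertyGraph-class].
#' @param nodeId an existing node id (errors otherwise).
#' @param edgeTypes character vector of edge types, or `NULL` for all.
#' @param direction `"out"` (edges leaving `nodeId`) or `"in"` (edges
#'   whose target is `nodeId`).
#' @return data.frame of edge rows (`source`, `target`, `type`, `order`,
#'   `stoichiometry`) plus a `neighbor` column, sorted by (type, order,
#'   neighbor) so ordered slots come back in their declared order.
#' @export
nodeNeighbors <- function(graph, nodeId, edgeTypes = NULL,
                          direction = c("out", "in")) {
  direction <- match.arg(direction)
  nodeId <- getNode(graph, nodeId)$node_id
  e <- graph@edges
  e <- if (direction == "out") e[e$source == nodeId, , drop = FALSE]
       else e[e$target == nodeId, , drop = FALSE]
  if (!is.null(edgeTypes)) e <- e[e$type %in% edgeTypes, , drop = FALSE]
  e$neighbor <- if (direction == "out") e$target else e$source
  e <- e[order(e$type, e$order, e$neighbor), , drop = FALSE]
  rownames(e) <- NULL
  e
}

#' Breadth-first transitive closure over selected edge types
#'
#' Start nodes are excluded from the result unless reached again by a
#' path of nonzero length; the depth of a node is its minimum depth.
#' Terminates on cyclic graphs.
#'
#' @param graph a [PropertyGraph-class].
#' @param start integer vector of existing node ids.
#' @param edgeTypes character vector of edge types, or `NULL` for all.
#' @param direction `"out"` or `"in"`.
#' @param maxDepth maximum path length to expand (default unbounded).
#' @return list with `ids` (sorted integer vector of reached node ids)
#'   and `depths` (named integer vector, names are node ids).
#' @export
traverseGraph <- function(graph, start, edgeTypes = NULL,
                          direction = c("out", "in"), maxDepth = Inf) {
  direction <- match.arg(direction)
  start <- vapply(start, function(s) getNode(graph, s)$node_id, integer(1))
  e <- graph@edges
  if (!is.null(edgeTypes)) e <- e[e$type %in% edgeTypes, , drop = FALSE]
  from <- if (direction == "out") e$source else e$target
  to <- if (direction == "out") e$target else e$source
  depths <- integer()
  frontier <- idSort(start)
  d <- 0L
  while (length(frontier) && d < maxDepth) {
    d <- d + 1L
    nxt <- unique(to[from %in% frontier])
    nxt <- nxt[!as.character(nxt) %in% names(depths)]
    if (!length(nxt)) break
    depths[as.character(nxt)] <- d
    frontier <- nxt
  }
  list(ids = idSort(as.integer(names(depths))), depths = depths)
}

## ---- canonical form and equality -------------------------------------------

#' Canonicalize a property graph
#'
#' Nodes sorted by id with alphabetically sorted property names; edges
#' sorted by (source, type, order, target). Numeric properties are
#' normalised to double. Two graphs with the same content have identical
#' canonical forms.
#'
#' @param graph a [PropertyGraph-class].
#' @return a plain list with `nodes` and `edges`.
#' @export
canonicalGraph <- function(graph) {
  ids <- idSort(vapply(graph@nodes, function(n) n$node_id, integer(1)))
  nodes <- lapply(as.character(ids), function(k) {
    n <- graph@nodes[[k]]
    props <- n$properties[order(names(n$properties))]
    props <- lapply(props, function(p) if (is.numeric(p)) as.double(p) else p)
    list(node_id = n$node_id, labels = n$labels, properties = props)
  })
  e <- graph@edges
  e <- e[order(e$source, e$type, e$order, e$target), , drop = FALSE]
  rownames(e) <- NULL
  list(nodes = nodes, edges = e)
}

#' Compare two property graphs for content equality
#'
#' @param g1,g2 [PropertyGraph-class] objects.
#' @return logical.
#' @export
graphsEqual <- function(g1, g2) {
  isTRUE(all.equal(canonicalGraph(g1), canonicalGraph(g2),
                   check.attributes = TRUE))
}

#' Top-level pathway nodes of a graph
#'
#' Pathway-labelled nodes with no incoming `hasEvent` edge, i.e. the
#' roots of the event forest as seen from the graph side.
#'
#' @param graph a [PropertyGraph-class].
#' @return sorted integer vector of node ids.
#' @export
topLevelPathwayIds <- function(graph) {
  pw <- graph@labelIndex[["Pathway"]] %||% integer()
  withParent <- graph@edges$target[graph@edges$type == "hasEvent"]
  idSort(setdiff(pw, withParent))
}
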