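# Shared fixtures built in code, plus a single-element graph mutator for
# integrity sensitivity sweeps.

toyKB <- function() workedToy()

toyGraph <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- importKnowledgebase(workedToy()$store)$graph
    cache
  }
})

synthKB <- local({
  cache <- list()
  function(seed, ...) {
    key <- paste0(seed, "|", paste(deparse(list(...)), collapse = ""))
    if (is.null(cache[[key]]))
      cache[[key]] <<- generateKB(synthConfig(seed = seed, ...))
    cache[[key]]
  }
})

# a store whose event hierarchy, precedingEvent relation and (illegally,
# for stress only) composition relation all contain cycles
adversarialCyclicGraph <- function() {
  g <- emptyGraph()
  lab <- function(cls) c(cls, switch(cls,
    Pathway = c("Event", "DatabaseObject"),
    Reaction = c("ReactionLikeEvent", "Event", "DatabaseObject"),
    Complex = c("PhysicalEntity", "DatabaseObject"),
    EntitySet = c("PhysicalEntity", "DatabaseObject"),
    EntityWithAccessionedSequence = c("PhysicalEntity", "DatabaseObject")))
  addN <- function(g, id, cls) addNode(g, id, lab(cls), list(
    dbId = as.integer(id), stId = sprintf("R-CYC-%03d", id),
    displayName = sprintf("%s %d", cls, id)))
  g <- addN(g, 1L, "Pathway"); g <- addN(g, 2L, "Pathway")
  g <- addN(g, 3L, "Reaction"); g <- addN(g, 4L, "Reaction")
  g <- addN(g, 5L, "Complex"); g <- addN(g, 6L, "EntitySet")
  g <- addN(g, 7L, "EntityWithAccessionedSequence")
  # hasEvent cycle between two pathways
  g <- addEdge(g, 1L, 2L, "hasEvent"); g <- addEdge(g, 2L, 1L, "hasEvent")
  g <- addEdge(g, 1L, 3L, "hasEvent"); g <- addEdge(g, 2L, 4L, "hasEvent")
  # precedingEvent cycle between two reactions
  g <- addEdge(g, 3L, 4L, "precedingEvent")
  g <- addEdge(g, 4L, 3L, "precedingEvent")
  # artificial composition cycle complex <-> set, with one true leaf
  g <- addEdge(g, 5L, 6L, "hasComponent")
  g <- addEdge(g, 6L, 5L, "hasMember")
  g <- addEdge(g, 6L, 7L, "hasMember")
  # reactions touch the cyclic entities
  g <- addEdge(g, 3L, 5L, "input"); g <- addEdge(g, 3L, 7L, "output")
  g <- addEdge(g, 4L, 7L, "input"); g <- addEdge(g, 4L, 5L, "output")
  g
}

# apply one random single-element mutation to a graph; returns the
# mutated graph and a label for diagnostics
mutateGraph <- function(graph, seed) {
  set.seed(seed)
  nodes <- graphNodes(graph)
  edges <- graphEdges(graph)
  ids <- vapply(nodes, function(n) n$node_id, integer(1))
  kind <- sample(c("add_node", "delete_node", "add_edge", "delete_edge",
                   "retarget_edge"), 1)
  if (kind == "add_node") {
    newId <- max(ids) + sample(1:1000, 1)
    g <- addNode(graph, newId,
                 c("EntityWithAccessionedSequence", "PhysicalEntity",
                   "DatabaseObject"),
                 list(dbId = as.integer(newId),
                      stId = sprintf("R-MUT-%d", newId),
                      displayName = "mutant"))
    return(list(graph = g, kind = kind))
  }
  if (kind == "delete_node") {
    victim <- sample(ids, 1)
    keep <- edges[edges$source != victim & edges$target != victim, ,
                  drop = FALSE]
    nodes[[as.character(victim)]] <- NULL
    return(list(graph = kbgraph:::buildGraph(unname(nodes), keep),
                kind = kind))
  }
  if (kind == "add_edge") {
    src <- sample(ids, 1); tgt <- sample(ids, 1)
    g <- addEdge(graph, src, tgt, "input")
    return(list(graph = g, kind = kind))
  }
  if (kind == "delete_edge") {
    if (!nrow(edges)) return(mutateGraph(graph, seed + 1))
    drop <- sample(nrow(edges), 1)
    return(list(graph = kbgraph:::buildGraph(unname(nodes),
                                             edges[-drop, , drop = FALSE]),
                kind = kind))
  }
  # retarget_edge
  if (!nrow(edges)) return(mutateGraph(graph, seed + 1))
  row <- sample(nrow(edges), 1)
  others <- setdiff(ids, edges$target[row])
  if (!length(others)) return(mutateGraph(graph, seed + 1))
  edges$target[row] <- sample(others, 1)
  list(graph = kbgraph:::buildGraph(unname(nodes), edges),
       kind = "retarget_edge")
}
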