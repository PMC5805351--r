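test_that("node add/lookup round-trips and duplicates are rejected", {
  g <- emptyGraph()
  g <- addNode(g, 1L, c("Reaction", "ReactionLikeEvent", "Event",
                        "DatabaseObject"),
               list(dbId = 1L, stId = "R-TST-1", displayName = "r1"))
  hits <- findNodes(g, "dbId", 1L)
  expect_length(hits, 1L)
  expect_identical(hits[[1]]$properties$displayName, "r1")
  expect_identical(findNodes(g, "stId", "R-TST-1")[[1]]$node_id, 1L)
  expect_error(addNode(g, 1L, "Reaction"), class = "kbgraph_duplicate_node")
  for (i in 2:10) g <- addNode(g, i, "DatabaseObject", list(dbId = i))
  expect_identical(nodeCount(g), 10L)
  # absent keys give empty results, not errors
  expect_length(findNodes(g, "dbId", 999L), 0L)
  expect_length(findNodes(g, "stId", "nope"), 0L)
  expect_length(findNodes(g, "label", "NotALabel"), 0L)
})

test_that("edges require existing endpoints and keep order contiguous", {
  g <- emptyGraph()
  g <- addNode(g, 1L, "Reaction", list(dbId = 1L))
  g <- addNode(g, 2L, "PhysicalEntity", list(dbId = 2L))
  expect_error(addEdge(g, 1L, 99L, "input"),
               class = "kbgraph_dangling_endpoint")
  g <- addEdge(g, 1L, 2L, "input")
  g <- addEdge(g, 1L, 2L, "input")   # stoichiometric repeat, next order
  expect_identical(graphEdges(g)$order, c(0L, 1L))
  expect_error(addEdge(g, 1L, 2L, "input", order = 1L), "exists")
})

test_that("label lookup is polymorphic through ancestor labels", {
  g <- importKnowledgebase(synthKB(3)$store)$graph
  pes <- findNodes(g, "label", "PhysicalEntity")
  cls <- vapply(pes, function(n) n$labels[1], character(1))
  expect_setequal(unique(cls),
                  intersect(c("SimpleEntity", "EntityWithAccessionedSequence",
                              "Complex", "EntitySet"), unique(cls)))
  expect_true(all(cls %in% c("SimpleEntity", "EntityWithAccessionedSequence",
                             "Complex", "EntitySet")))
  # Event count = Pathway count + RLE count, by direct class enumeration
  classes <- vapply(instances(synthKB(3)$store), className, character(1))
  nEvents <- sum(classes == "Pathway") +
    sum(classes %in% setdiff(RLE_CLASSES, "ReactionLikeEvent"))
  expect_length(findNodes(g, "label", "Event"), nEvents)
})

test_that("neighbors respect declared edge order and direction", {
  g <- emptyGraph()
  for (i in 1:4) g <- addNode(g, i, if (i == 1) "Reaction" else
                              "PhysicalEntity", list(dbId = i))
  g <- addEdge(g, 1L, 3L, "input")  # order 0
  g <- addEdge(g, 1L, 2L, "input")  # order 1
  g <- addEdge(g, 1L, 4L, "output")
  out <- nodeNeighbors(g, 1L, "input", "out")
  expect_identical(out$neighbor, c(3L, 2L))  # declared order, not id order
  inc <- nodeNeighbors(g, 3L, "input", "in")
  expect_identical(inc$neighbor, 1L)
  expect_error(nodeNeighbors(g, 99L), class = "kbgraph_not_found")
})

test_that("every edge appears exactly once in out- and in-neighbors", {
  g <- importKnowledgebase(synthKB(4)$store)$graph
  e <- graphEdges(g)
  for (i in sample(nrow(e), min(nrow(e), 40))) {
    out <- nodeNeighbors(g, e$source[i], e$type[i], "out")
    inc <- nodeNeighbors(g, e$target[i], e$type[i], "in")
    key <- function(d) sprintf("%d|%s|%d|%d", d$source, d$type, d$order,
                               d$target)
    this <- sprintf("%d|%s|%d|%d", e$source[i], e$type[i], e$order[i],
                    e$target[i])
    expect_identical(sum(key(out) == this), 1L)
    expect_identical(sum(key(inc) == this), 1L)
  }
})

test_that("traversal matches a naive fixed-point oracle and igraph", {
  g <- importKnowledgebase(synthKB(5)$store)$graph
  e <- graphEdges(g)
  types <- c("hasEvent", "input", "output")
  sub <- e[e$type %in% types, , drop = FALSE]
  starts <- topLevelPathwayIds(g)
  got <- traverseGraph(g, starts, types, "out")$ids
  # naive fixed point of one-step expansion
  reach <- starts
  repeat {
    nxt <- unique(sub$target[sub$source %in% reach])
    if (all(nxt %in% reach)) break
    reach <- union(reach, nxt)
  }
  expected <- sort(setdiff(reach,
                           setdiff(starts, sub$target[sub$source %in% reach])))
  expect_identical(got, expected)
  # igraph as an independent implementation
  ig <- igraph::graph_from_data_frame(
    data.frame(from = as.character(sub$source), to = as.character(sub$target)),
    vertices = as.character(vapply(graphNodes(g), function(n) n$node_id,
                                   integer(1))))
  igReach <- sort(unique(unlist(lapply(as.character(starts), function(s)
    as.integer(names(igraph::subcomponent(ig, s, mode = "out")))))))
  expect_identical(sort(union(got, setdiff(starts, got))), igReach)
})

test_that("traversal terminates on cycles and excludes unreached starts", {
  g <- emptyGraph()
  g <- addNode(g, 1L, "Pathway", list(dbId = 1L))
  g <- addNode(g, 2L, "Pathway", list(dbId = 2L))
  g <- addEdge(g, 1L, 2L, "hasEvent")
  g <- addEdge(g, 2L, 1L, "hasEvent")
  res <- traverseGraph(g, 1L, "hasEvent", "out")
  expect_identical(res$ids, c(1L, 2L))  # start re-reached via the cycle
  # leaf start over the same type: empty
  g <- addNode(g, 3L, "Reaction", list(dbId = 3L))
  expect_identical(traverseGraph(g, 3L, "hasEvent", "out")$ids, integer())
  # depth map: minimum depths
  expect_identical(unname(res$depths[c("2", "1")]), c(1L, 2L))
  # maxDepth bound
  expect_identical(traverseGraph(g, 1L, "hasEvent", "out", maxDepth = 1)$ids,
                   2L)
})

test_that("traversal is independent of start ordering", {
  g <- importKnowledgebase(synthKB(6)$store)$graph
  starts <- topLevelPathwayIds(g)
  a <- traverseGraph(g, starts, "hasEvent", "out")$ids
  b <- traverseGraph(g, rev(starts), "hasEvent", "out")$ids
  expect_identical(a, b)
})

test_that("indexes stay consistent under random mutation sequences", {
  set.seed(42)
  for (rep in 1:5) {
    g <- emptyGraph()
    ids <- integer()
    for (step in 1:30) {
      if (!length(ids) || runif(1) < 0.5) {
        id <- (length(ids) + 1L) * 7L
        g <- addNode(g, id, sample(c("Pathway", "Reaction", "Complex"), 1),
                     list(dbId = id, stId = sprintf("R-IDX-%d", id)))
        ids <- c(ids, id)
      } else {
        g <- addEdge(g, ids[sample.int(length(ids), 1)],
                     ids[sample.int(length(ids), 1)], "precedingEvent")
      }
    }
    # stId index agrees with node properties
    for (n in graphNodes(g))
      expect_identical(findNodes(g, "stId", n$properties$stId)[[1]]$node_id,
                       n$node_id)
    # label index agrees with per-node labels
    for (lab in names(g@labelIndex)) {
      fromNodes <- sort(unname(vapply(Filter(function(n) lab %in% n$labels,
                                             graphNodes(g)),
                                      function(n) n$node_id, integer(1))))
      expect_identical(g@labelIndex[[lab]], fromNodes)
    }
    # no dangling edges
    e <- graphEdges(g)
    expect_true(all(c(e$source, e$target) %in% ids))
  }
})
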