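test_that("relational dump round-trips and junction order is honoured", {
  # hand-written dump in the junction-table layout: a reaction with
  # ordered inputs and one output
  dir <- tempfile()
  dir.create(dir)
  write.csv(data.frame(db_id = 1L, st_id = "R-TOY-1", display_name = "r1",
                       species_name = NA),
            file.path(dir, "reaction.csv"), row.names = FALSE)
  write.csv(data.frame(db_id = c(2L, 3L, 4L), st_id = paste0("R-TOY-", 2:4),
                       display_name = c("A", "B", "C"), species_name = NA),
            file.path(dir, "simple_entity.csv"), row.names = FALSE)
  # rows deliberately shuffled: slot_order must drive the slot value order
  write.csv(data.frame(source_id = c(1L, 1L), target_id = c(3L, 2L),
                       slot_order = c(1L, 0L)),
            file.path(dir, "reaction_input.csv"), row.names = FALSE)
  write.csv(data.frame(source_id = 1L, target_id = 4L, slot_order = 0L),
            file.path(dir, "reaction_output.csv"), row.names = FALSE)
  store <- readRelationalDump(dir)
  expect_length(instances(store), 4L)
  inst <- instances(store)[["1"]]
  expect_identical(slotValues(inst)$input, c(2L, 3L))
  expect_identical(slotValues(inst)$output, 4L)

  # write-read round trip on synthetic stores
  for (seed in c(2, 11)) {
    kb <- synthKB(seed)
    d <- tempfile()
    writeRelationalDump(kb$store, d)
    back <- readRelationalDump(d)
    expect_identical(as.character(storeToJson(back)),
                     as.character(storeToJson(kb$store)))
  }
})

test_that("dump edge cases: empty store, missing columns, dangling FKs", {
  d <- tempfile()
  writeRelationalDump(newObjectStore(), d)
  empty <- readRelationalDump(d)
  expect_length(instances(empty), 0L)
  expect_true(validateStore(empty)$ok)

  d2 <- tempfile(); dir.create(d2)
  write.csv(data.frame(db_id = 1L), file.path(d2, "reaction.csv"),
            row.names = FALSE)
  expect_error(readRelationalDump(d2), class = "kbgraph_schema_error")

  # foreign key to an absent row: surfaces via validateStore, not a throw
  d3 <- tempfile(); dir.create(d3)
  write.csv(data.frame(db_id = 1L, st_id = "R-X-1", display_name = "r",
                       species_name = NA),
            file.path(d3, "reaction.csv"), row.names = FALSE)
  write.csv(data.frame(source_id = 1L, target_id = 99L, slot_order = 0L),
            file.path(d3, "reaction_input.csv"), row.names = FALSE)
  store <- readRelationalDump(d3)
  rep <- validateStore(store)
  expect_identical(unname(rep$countsByRule["dangling_reference"]), 1L)
})

test_that("JSON object-store dump round-trips", {
  kb <- synthKB(2, orphanCount = 3L)
  js <- storeToJson(kb$store)
  back <- storeFromJson(js)
  expect_identical(as.character(storeToJson(back)), as.character(js))
  expect_identical(topLevelPathways(back), topLevelPathways(kb$store))
})

test_that("a reaction with all four outgoing slot kinds becomes one node with typed edges", {
  res <- importKnowledgebase(workedToy()$store)
  g <- res$graph
  # reaction 4 fills input, output, catalystActivity, precedingEvent
  out <- nodeNeighbors(g, 4L, NULL, "out")
  expect_setequal(unique(out$type),
                  c("input", "output", "catalystActivity", "precedingEvent"))
  # reaction 5 carries the regulatedBy edge
  expect_true("regulatedBy" %in% nodeNeighbors(g, 5L, NULL, "out")$type)
  # primitive slots became node properties, references did not
  n <- findNodes(g, "dbId", 7L)[[1]]
  expect_identical(n$properties$speciesName, "Homo sapiens")
  expect_false("input" %in% names(n$properties))
  expect_identical(n$labels, c("EntityWithAccessionedSequence",
                               "PhysicalEntity", "DatabaseObject"))
})

test_that("visit-once: a shared entity yields one node with two incoming edges", {
  # protein 8 is input of reaction 4, component of complex 15 and member
  # of set 16 in the toy store
  g <- toyGraph()
  expect_length(findNodes(g, "dbId", 8L), 1L)
  inc <- nodeNeighbors(g, 8L, NULL, "in")
  expect_setequal(inc$type, c("input", "hasComponent", "hasMember"))
  # one node per instance overall
  expect_identical(nodeCount(g), length(instances(workedToy()$store)))
})

test_that("import terminates on a pathway hasEvent cycle", {
  p1 <- newInstance(1L, "Pathway", "a", slotValues = list(hasEvent = 2L))
  p2 <- newInstance(2L, "Pathway", "b", slotValues = list(hasEvent = 1L))
  store <- newObjectStore(list(p1, p2), 1L)
  res <- importKnowledgebase(store)
  expect_identical(res$report@nodesCreated, 2L)
  expect_identical(res$report@edgesCreated, 2L)
})

test_that("import conservation matches independent store enumeration", {
  for (seed in c(1, 5, 9, 13, 17)) {
    kb <- synthKB(seed, orphanCount = seed %% 3L)
    res <- importKnowledgebase(kb$store)
    reachable <- oracleReachable(kb$store)
    expect_identical(res$report@nodesCreated, length(reachable))
    expect_identical(res$report@edgesCreated,
                     oracleRefCount(kb$store, reachable))
    # every reference slot value of every reachable instance corresponds
    # to exactly one edge, and vice versa
    expected <- kbgraph:::storeEdgeTuples(kb$store, reachable)
    expect_identical(kbgraph:::graphEdgeTuples(res$graph), expected)
    # per-class counts sum to the node count
    expect_identical(sum(res$report@perClassCounts),
                     res$report@nodesCreated)
  }
})

test_that("orphans are excluded by default, reported, and importable", {
  kb <- generateKB(synthConfig(seed = 21, orphanCount = 5L))
  res <- importKnowledgebase(kb$store)
  allIds <- sort(vapply(instances(kb$store), dbId, integer(1)))
  expect_identical(res$report@orphanInstances,
                   setdiff(allIds, oracleReachable(kb$store)))
  expect_length(res$report@orphanInstances, 5L)
  expect_identical(res$report@nodesCreated, length(allIds) - 5L)
  expect_identical(res$report@instancesSeen, length(allIds))

  withOrphans <- importKnowledgebase(kb$store, includeOrphans = TRUE)
  expect_identical(withOrphans$report@nodesCreated, length(allIds))
  expect_identical(withOrphans$report@orphanInstances,
                   res$report@orphanInstances)
})

test_that("import is deterministic and invariant to top-level ordering", {
  kb <- synthKB(12)
  g1 <- importKnowledgebase(kb$store)$graph
  permuted <- newObjectStore(rev(unname(instances(kb$store))),
                             rev(topLevelPathways(kb$store)))
  g2 <- importKnowledgebase(permuted)$graph
  expect_true(graphsEqual(g1, g2))
  f1 <- tempfile(); f2 <- tempfile()
  exportGraph(g1, f1, "json")
  exportGraph(g2, f2, "json")
  expect_identical(readLines(f1), readLines(f2))
})

test_that("a reference to a missing dbId aborts with source and slot named", {
  store <- newObjectStore(list(
    newInstance(1L, "Pathway", "p", slotValues = list(hasEvent = 2L)),
    newInstance(2L, "Reaction", "r", slotValues = list(input = 42L))), 1L)
  expect_error(importKnowledgebase(store), "instance 2 slot input",
               class = "kbgraph_import_error")
})
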