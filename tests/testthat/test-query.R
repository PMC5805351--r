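test_that("reactionIO follows edge order and repeats stoichiometric entities", {
  g <- toyGraph()
  io <- reactionIO(g, 3L)
  expect_identical(io, list(inputs = c(6L, 7L), outputs = 12L))
  # stId lookup works too
  expect_identical(reactionIO(g, "R-SYN-000003"), io)
  # no-input reaction
  g2 <- emptyGraph()
  g2 <- addNode(g2, 1L, c("Reaction", "ReactionLikeEvent", "Event",
                          "DatabaseObject"), list(dbId = 1L))
  g2 <- addNode(g2, 2L, c("SimpleEntity", "PhysicalEntity",
                          "DatabaseObject"), list(dbId = 2L))
  g2 <- addEdge(g2, 1L, 2L, "output")
  expect_identical(reactionIO(g2, 1L), list(inputs = integer(),
                                            outputs = 2L))
  # type / resolution errors
  expect_error(reactionIO(g, 1L), class = "kbgraph_type_error")
  expect_error(reactionIO(g, 999L), class = "kbgraph_not_found")
  # stoichiometric repeat: same entity twice in input
  g2 <- addEdge(g2, 1L, 2L, "input", stoichiometry = 2L)
  g2 <- addEdge(g2, 1L, 2L, "input", stoichiometry = 2L)
  expect_identical(reactionIO(g2, 1L)$inputs, c(2L, 2L))
})

test_that("pathwayEvents: direct children vs recursive closure", {
  g <- toyGraph()
  expect_identical(pathwayEvents(g, 1L, recursive = FALSE), c(2L, 5L))
  expect_identical(pathwayEvents(g, 1L, recursive = TRUE),
                   c(2L, 3L, 4L, 5L))
  expect_identical(pathwayEvents(g, 2L, recursive = TRUE), c(3L, 4L))
  expect_error(pathwayEvents(g, 6L), class = "kbgraph_type_error")
})

test_that("decomposeEntity handles leaves, nesting, sets and candidates", {
  g <- toyGraph()
  expect_identical(decomposeEntity(g, 7L), 7L)        # leaf -> itself
  expect_identical(decomposeEntity(g, 14L), c(9L, 10L))
  expect_identical(decomposeEntity(g, 15L), c(8L, 9L, 10L))
  expect_identical(decomposeEntity(g, 16L), c(7L, 8L))
  expect_identical(decomposeEntity(g, 16L, includeCandidates = TRUE),
                   c(7L, 8L, 11L))
  expect_error(decomposeEntity(g, 1L), class = "kbgraph_type_error")
  # nested complex-of-complex with a set inside, plus shared substructure
  kb <- synthKB(14)
  gg <- importKnowledgebase(kb$store)$graph
  classes <- vapply(instances(kb$store), className, character(1))
  containers <- vapply(instances(kb$store), dbId, integer(1))[
    classes %in% c("Complex", "EntitySet")]
  for (id in containers) {
    for (cand in c(FALSE, TRUE))
      expect_identical(decomposeEntity(gg, id, cand),
                       oracleDecompose(kb$store, id, cand),
                       label = sprintf("decompose %d cand=%s", id, cand))
  }
})

test_that("pathwayParticipants reports roles, provenance and flags", {
  g <- toyGraph()
  # single-reaction pathway A+B -> C pattern (subpathway 2, reaction 3)
  p <- pathwayParticipants(g, 2L, includeCatalysts = FALSE,
                           includeRegulators = FALSE)
  ids <- vapply(p, `[[`, integer(1), "entity")
  expect_identical(ids, c(6L, 7L, 8L, 12L, 13L))
  rec6 <- p[[1]]
  expect_identical(rec6$roles, "input")
  expect_identical(rec6$viaReactions, 3L)
  rec12 <- p[[which(ids == 12L)]]
  expect_setequal(rec12$roles, c("input", "output"))  # produced then consumed
  # catalyst flag pulls in the catalyst PE with the catalyst role
  pc <- pathwayParticipants(g, 2L, includeCatalysts = TRUE,
                            includeRegulators = FALSE)
  idsc <- vapply(pc, `[[`, integer(1), "entity")
  expect_true(18L %in% idsc)
  expect_identical(pc[[which(idsc == 18L)]]$roles, "catalyst")
  # records non-empty by construction
  for (r in pc) {
    expect_gt(length(r$roles), 0)
    expect_gt(length(r$viaReactions), 0)
  }
})

test_that("pathwayParticipants equals the brute-force oracle for all flags", {
  for (seed in c(3, 15)) {
    kb <- synthKB(seed)
    g <- importKnowledgebase(kb$store)$graph
    classes <- vapply(instances(kb$store), className, character(1))
    pws <- vapply(instances(kb$store), dbId, integer(1))[classes == "Pathway"]
    for (pid in pws) {
      for (cats in c(FALSE, TRUE)) for (regs in c(FALSE, TRUE))
        for (dec in c(FALSE, TRUE)) {
          expect_identical(
            pathwayParticipants(g, pid, cats, regs, dec),
            oracleParticipants(kb$store, pid, cats, regs, dec),
            label = sprintf("seed %d pathway %d c%d r%d d%d", seed, pid,
                            cats, regs, dec))
        }
    }
  }
})

test_that("pathwaysForEntity distinguishes stated and leaf participation", {
  g <- toyGraph()
  # chemical 6 is a stated input of reaction 3 (pathway 2, under 1)
  expect_identical(pathwaysForEntity(g, 6L, leafMatch = FALSE), c(1L, 2L))
  # protein 9 only occurs inside complex 14 inside complex 15 (reaction 5
  # in pathway 1): found as leaf, invisible as stated participant
  expect_identical(pathwaysForEntity(g, 9L, leafMatch = TRUE), 1L)
  expect_identical(pathwaysForEntity(g, 9L, leafMatch = FALSE), integer())
  # a complex is never a leaf molecule
  expect_identical(pathwaysForEntity(g, 15L, leafMatch = TRUE), integer())
  expect_identical(pathwaysForEntity(g, 15L, leafMatch = FALSE), 1L)
  expect_error(pathwaysForEntity(g, 999L), class = "kbgraph_not_found")
})

test_that("eventAncestors returns all root-first chains, diamonds included", {
  g <- toyGraph()
  expect_identical(eventAncestors(g, 1L), list(1L))           # top level
  expect_identical(eventAncestors(g, 4L), list(c(1L, 2L, 4L)))
  # diamond: one reaction under two parent pathways
  gd <- emptyGraph()
  labP <- c("Pathway", "Event", "DatabaseObject")
  labR <- c("Reaction", "ReactionLikeEvent", "Event", "DatabaseObject")
  gd <- addNode(gd, 1L, labP, list(dbId = 1L))
  gd <- addNode(gd, 2L, labP, list(dbId = 2L))
  gd <- addNode(gd, 3L, labR, list(dbId = 3L))
  gd <- addEdge(gd, 1L, 3L, "hasEvent")
  gd <- addEdge(gd, 2L, 3L, "hasEvent")
  expect_identical(eventAncestors(gd, 3L), list(c(1L, 3L), c(2L, 3L)))
})

test_that("eventAncestors matches the reversed-slot DFS oracle", {
  for (seed in c(6, 18)) {
    kb <- synthKB(seed)
    g <- importKnowledgebase(kb$store)$graph
    classes <- vapply(instances(kb$store), className, character(1))
    events <- vapply(instances(kb$store), dbId, integer(1))[
      classes == "Pathway" | classes %in% RLE_CLASSES]
    for (ev in events)
      expect_identical(eventAncestors(g, ev), oracleAncestors(kb$store, ev),
                       label = sprintf("seed %d event %d", seed, ev))
  }
})

test_that("reactionChainsTo enumerates cascades incl. suffixes", {
  g <- toyGraph()
  chains <- reactionChainsTo(g, 15L, maxLength = 3L)
  expect_identical(lapply(chains, `[[`, "reactions"),
                   list(5L, c(4L, 5L), c(3L, 4L, 5L)))
  expect_true(all(vapply(chains, `[[`, integer(1), "entity") == 15L))
  # max length truncates
  expect_identical(lapply(reactionChainsTo(g, 15L, maxLength = 2L),
                          `[[`, "reactions"),
                   list(5L, c(4L, 5L)))
  # never-produced entity: empty
  expect_identical(reactionChainsTo(g, 6L), list())
  # single producing reaction with no predecessors
  expect_identical(lapply(reactionChainsTo(g, 12L), `[[`, "reactions"),
                   list(3L))
})

test_that("reactionChainsTo matches brute-force path enumeration on a cascade", {
  # 15-reaction cascade with branches: r_i consumes e_{i-1}, produces e_i;
  # every third reaction also consumes an earlier product (extra linkage)
  insts <- list()
  mkE <- function(id) newInstance(id, "EntityWithAccessionedSequence",
                                  sprintf("e%d", id))
  mkR <- function(id, ins, outs) newInstance(
    id, "Reaction", sprintf("r%d", id),
    slotValues = list(input = ins, output = outs))
  ents <- 100L + 0:15
  for (e in ents) insts[[length(insts) + 1]] <- mkE(e)
  rxns <- 1:15
  for (i in rxns) {
    ins <- 100L + i - 1L
    if (i %% 3L == 0L && i > 3L) ins <- c(ins, 100L + i - 3L)
    insts[[length(insts) + 1]] <- mkR(i, ins, 100L + i)
  }
  insts[[length(insts) + 1]] <- newInstance(
    200L, "Pathway", "cascade", slotValues = list(hasEvent = rxns))
  store <- newObjectStore(insts, 200L)
  g <- importKnowledgebase(store)$graph
  for (target in c(115L, 109L, 105L)) {
    got <- lapply(reactionChainsTo(g, target, maxLength = 6L),
                  `[[`, "reactions")
    expect_identical(got, oracleChainsTo(store, target, maxLength = 6L),
                     label = sprintf("chains to %d", target))
  }
})

test_that("query results are invariant to store insertion order", {
  kb <- synthKB(10)
  g1 <- importKnowledgebase(kb$store)$graph
  g2 <- importKnowledgebase(newObjectStore(
    rev(unname(instances(kb$store))),
    rev(topLevelPathways(kb$store))))$graph
  classes <- vapply(instances(kb$store), className, character(1))
  ids <- vapply(instances(kb$store), dbId, integer(1))
  pid <- min(ids[classes == "Pathway"])
  expect_identical(pathwayParticipants(g1, pid),
                   pathwayParticipants(g2, pid))
  ent <- min(ids[classes == "EntityWithAccessionedSequence"])
  expect_identical(pathwaysForEntity(g1, ent), pathwaysForEntity(g2, ent))
})

test_that("fetch: lazy placeholders resolve to eager values", {
  g <- toyGraph()
  shallow <- fetchObject(g, 4L, "shallow")
  expect_identical(shallow$properties$displayName, "Receptor activation")
  expect_true(all(vapply(shallow$refs$input, isRefPlaceholder, logical(1))))
  full <- fetchObject(g, 4L, "full")
  # resolving a placeholder then reading displayName equals the full
  # fetch's value
  ph <- shallow$refs$input[[1]]
  resolved <- resolveRef(g, ph)
  expect_identical(resolved$properties$displayName,
                   full$refs$input[[1]]$properties$displayName)
  expect_identical(resolved$properties, full$refs$input[[1]]$properties)
  # bounded depth 2 equals the full view truncated at depth 2
  expect_identical(fetchObject(g, 1L, 2L), truncateView(fetchObject(g, 1L,
                   "full"), 2L))
  expect_error(fetchObject(g, 999L), class = "kbgraph_not_found")
})

test_that("bounded fetch equals truncated full fetch on synthetic KBs", {
  for (seed in c(7, 16)) {
    kb <- synthKB(seed)
    g <- importKnowledgebase(kb$store)$graph
    ids <- sort(vapply(graphNodes(g), function(n) n$node_id, integer(1)))
    for (id in ids[seq(1, length(ids), by = 17)]) {
      full <- fetchObject(g, id, "full")
      expect_identical(fetchObject(g, id, 2L), truncateView(full, 2L))
      expect_identical(fetchObject(g, id, 0L), truncateView(full, 0L))
    }
  }
})
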