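test_that("generation is deterministic under (config, seed)", {
  cfg <- synthConfig(seed = 31, orphanCount = 2L)
  a <- generateKB(cfg)
  b <- generateKB(cfg)
  expect_identical(as.character(storeToJson(a$store)),
                   as.character(storeToJson(b$store)))
  expect_identical(a$truth, b$truth)
  # a different seed changes the content
  c <- generateKB(synthConfig(seed = 32, orphanCount = 2L))
  expect_false(identical(as.character(storeToJson(a$store)),
                         as.character(storeToJson(c$store))))
  # generation does not disturb the caller's RNG stream
  set.seed(123); before <- runif(3)
  set.seed(123); invisible(generateKB(cfg)); after <- runif(3)
  expect_identical(before, after)
})

test_that("orphanCount yields exactly that many unreachable instances", {
  for (k in c(0L, 5L)) {
    kb <- generateKB(synthConfig(seed = 40 + k, orphanCount = k))
    reach <- oracleReachable(kb$store)
    allIds <- sort(vapply(instances(kb$store), dbId, integer(1)))
    expect_length(setdiff(allIds, reach), k)
    expect_identical(kb$truth$orphans, setdiff(allIds, reach))
    expect_identical(kb$truth$reachable, reach)
  }
})

test_that("structural bounds are respected", {
  cfg <- synthConfig(seed = 33, maxPathwayDepth = 2L, maxComplexNesting = 2L,
                     reactionsPerPathway = c(1L, 3L))
  kb <- generateKB(cfg)
  store <- kb$store
  classes <- vapply(instances(store), className, character(1))
  ids <- vapply(instances(store), dbId, integer(1))
  # every reaction has >= 1 input and >= 1 output
  for (r in ids[classes %in% setdiff(RLE_CLASSES, "ReactionLikeEvent")]) {
    expect_gte(length(oSlot(store, r, "input")), 1L)
    expect_gte(length(oSlot(store, r, "output")), 1L)
  }
  # pathway nesting depth bound (chain of pathways in the ancestor line)
  for (p in ids[classes == "Pathway"]) {
    for (ch in oracleAncestors(store, p))
      expect_lte(length(ch), cfg@maxPathwayDepth)
  }
  # composition DAG depth bound
  compDepth <- function(id) {
    kids <- c(oSlot(store, id, "hasComponent"), oSlot(store, id, "hasMember"),
              oSlot(store, id, "hasCandidate"))
    if (!length(kids)) return(0L)
    1L + max(vapply(kids, compDepth, integer(1)))
  }
  for (cx in ids[classes %in% c("Complex", "EntitySet")])
    expect_lte(compDepth(cx), cfg@maxComplexNesting)
})

test_that("construction-time ground truth agrees with post-hoc oracles", {
  for (seed in c(1, 9)) {
    kb <- synthKB(seed)
    store <- kb$store
    # decompositions (double-entry bookkeeping)
    for (k in names(kb$truth$decompositions)) {
      expect_identical(kb$truth$decompositions[[k]]$excl,
                       oracleDecompose(store, as.integer(k), FALSE),
                       label = sprintf("seed %d decomp %s", seed, k))
      expect_identical(kb$truth$decompositions[[k]]$incl,
                       oracleDecompose(store, as.integer(k), TRUE))
    }
    # ancestor chains (the generator's forest gives one chain per event)
    for (k in names(kb$truth$ancestors))
      expect_identical(list(kb$truth$ancestors[[k]]),
                       oracleAncestors(store, as.integer(k)))
    # participant sets for every flag combination
    for (pk in names(kb$truth$participants)) {
      for (cats in 0:1) for (regs in 0:1) for (dec in 0:1) {
        key <- sprintf("cat%d_reg%d_dec%d", cats, regs, dec)
        expect_identical(
          kb$truth$participants[[pk]][[key]],
          oracleParticipantIds(store, as.integer(pk), cats == 1, regs == 1,
                               dec == 1),
          label = sprintf("seed %d pathway %s %s", seed, pk, key))
      }
    }
  }
})

test_that("infeasible configurations are rejected", {
  expect_error(generateKB(synthConfig(seed = 1, nProteins = 0L,
                                      nChemicals = 0L,
                                      complexFraction = 0.5)),
               class = "kbgraph_config_error")
  expect_error(generateKB(synthConfig(seed = 1, nProteins = 0L,
                                      nChemicals = 0L, complexFraction = 0,
                                      setFraction = 0)),
               class = "kbgraph_config_error")
  expect_error(synthConfig(seed = 1, catalystProbability = 1.5))
})

test_that("worked toy matches its committed hand-enumerated fixture", {
  kb <- workedToy()
  expect_identical(topLevelPathways(kb$store), 1L)
  expect_true(validateStore(kb$store)$ok)
  res <- importKnowledgebase(kb$store)
  expect_identical(res$report@nodesCreated, length(instances(kb$store)))
  expect_identical(res$report@orphanInstances, integer())
  g <- res$graph

  fixture <- jsonlite::fromJSON(
    system.file("extdata", "worked_toy_expected.json", package = "kbgraph"),
    simplifyVector = TRUE)
  for (k in names(fixture$decompositions)) {
    expect_identical(decomposeEntity(g, as.integer(k)),
                     as.integer(fixture$decompositions[[k]]$excl))
    expect_identical(decomposeEntity(g, as.integer(k),
                                     includeCandidates = TRUE),
                     as.integer(fixture$decompositions[[k]]$incl))
  }
  for (k in names(fixture$ancestors))
    expect_identical(eventAncestors(g, as.integer(k)),
                     list(as.integer(fixture$ancestors[[k]])))
  for (pk in names(fixture$participants)) {
    for (key in names(fixture$participants[[pk]])) {
      flags <- as.integer(strsplit(gsub("[a-z_]+", " ", key), " +")[[1]][-1])
      got <- pathwayParticipants(g, as.integer(pk),
                                 includeCatalysts = flags[1] == 1,
                                 includeRegulators = flags[2] == 1,
                                 decompose = flags[3] == 1)
      expect_identical(vapply(got, `[[`, integer(1), "entity"),
                       as.integer(fixture$participants[[pk]][[key]]),
                       label = sprintf("toy pathway %s %s", pk, key))
    }
  }
  chains <- reactionChainsTo(g, 15L, maxLength = 3L)
  expect_identical(lapply(chains, function(ch) ch$reactions),
                   lapply(fixture$reaction_chains_to_15$max_length_3,
                          as.integer))
})
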