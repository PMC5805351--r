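## Seeded generator of Reactome-like synthetic knowledgebases: a forest
## of pathways containing reaction-like events whose participants are
## physical entities, including nested complexes and entity sets over
## proteins and chemicals. Ground truth (participant sets, leaf
## decompositions, ancestor chains, reachable/orphan partition) is
## recorded while the store is built, independently of the importer and
## query modules it later tests.

withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv())
  on.exit(if (had) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  expr
}

#' Configure the synthetic knowledgebase generator
#'
#' Defaults model a small but structurally complete pathway
#' knowledgebase: a forest of 3 top-level pathways nested up to depth 3,
#' 2-5 reactions per pathway over a pool of 50 proteins and 20
#' chemicals, a quarter of the leaf pool wrapped into complexes (nested
#' up to 3 deep) and a tenth into entity sets, roughly a third of
#' participant picks reusing an already-used entity (so visit-once
#' deduplication is exercised), and feedback cycles only in
#' `precedingEvent`.
#'
#' @param seed integer RNG seed.
#' @param nTopPathways,maxPathwayDepth,reactionsPerPathway pathway
#'   forest shape; `reactionsPerPathway` is an inclusive `(lo, hi)`
#'   range.
#' @param nProteins,nChemicals leaf molecule pool sizes.
#' @param complexFraction,setFraction number of complexes / sets as a
#'   fraction of the leaf pool.
#' @param maxComplexNesting maximum composition depth.
#' @param membersPerSet inclusive `(lo, hi)` members per entity set.
#' @param catalystProbability,regulatorProbability per-reaction chance
#'   of a catalyst activity / regulation.
#' @param sharedEntityProbability chance a participant pick reuses an
#'   already-used entity.
#' @param cycleProbability chance of a `precedingEvent` feedback cycle
#'   per pathway.
#' @param orphanCount instances generated unreachable from the top-level
#'   pathways.
#' @return a [SynthConfig-class].
#' @export
synthConfig <- function(seed = 1L, nTopPathways = 3L, maxPathwayDepth = 3L,
                        reactionsPerPathway = c(2L, 5L), nProteins = 50L,
                        nChemicals = 20L, complexFraction = 0.25,
                        maxComplexNesting = 3L, setFraction = 0.1,
                        membersPerSet = c(2L, 4L),
                        catalystProbability = 0.3,
                        regulatorProbability = 0.2,
                        sharedEntityProbability = 0.3,
                        cycleProbability = 0.1, orphanCount = 0L) {
  new("SynthConfig", seed = as.integer(seed),
      nTopPathways = as.integer(nTopPathways),
      maxPathwayDepth = as.integer(maxPathwayDepth),
      reactionsPerPathway = as.integer(reactionsPerPathway),
      nProteins = as.integer(nProteins), nChemicals = as.integer(nChemicals),
      complexFraction = complexFraction,
      maxComplexNesting = as.integer(maxComplexNesting),
      setFraction = setFraction, membersPerSet = as.integer(membersPerSet),
      catalystProbability = catalystProbability,
      regulatorProbability = regulatorProbability,
      sharedEntityProbability = sharedEntityProbability,
      cycleProbability = cycleProbability,
      orphanCount = as.integer(orphanCount))
}

#' Generate a synthetic knowledgebase with ground truth
#'
#' Identical config and seed give byte-identical output. The emitted
#' store always passes [validateStore()]; composition structures are
#' DAGs (a physical containment cycle would leave "leaf molecule"
#' undefined), and cycles are injected only into `precedingEvent`.
#'
#' @param config a [SynthConfig-class].
#' @return list with `store` (an [ObjectStore-class]) and `truth`, a
#'   ground-truth list with elements `reachable`, `orphans`,
#'   `topLevelPathways`, `decompositions` (per entity: `excl` / `incl`
#'   candidate leaf sets), `ancestors` (per event: root-first chain) and
#'   `participants` (per pathway: participant id sets per flag
#'   combination, keys `cat<0|1>_reg<0|1>_dec<0|1>`).
#' @export
generateKB <- function(config) {
  validObject(config)
  withSeed(config@seed, generateImpl(config))
}

generateImpl <- function(cfg) {
  recs <- list()          # id (chr) -> record
  nextId <- 0L
  mk <- function(className, displayName, slotValues = list(),
                 speciesName = NULL) {
    nextId <<- nextId + 1L
    if (!is.null(speciesName)) slotValues$speciesName <- speciesName
    recs[[as.character(nextId)]] <<- list(
      dbId = nextId, className = className, displayName = displayName,
      slotValues = slotValues)
    nextId
  }

  nLeaves <- cfg@nProteins + cfg@nChemicals
  nComplexes <- round(cfg@complexFraction * nLeaves)
  nSets <- round(cfg@setFraction * nLeaves)
  if ((nComplexes + nSets) > 0 && nLeaves == 0)
    stopf("infeasible config: composites requested over an empty leaf pool",
          class = "kbgraph_config_error")
  if ((nComplexes + nSets) > 0 && cfg@maxComplexNesting < 1)
    stopf("infeasible config: composites need maxComplexNesting >= 1",
          class = "kbgraph_config_error")
  wantReactions <- cfg@nTopPathways > 0 && cfg@reactionsPerPathway[2] > 0
  if (wantReactions && nLeaves == 0)
    stopf("infeasible config: reactions need a non-empty entity pool",
          class = "kbgraph_config_error")

  proteins <- vapply(seq_len(cfg@nProteins), function(i)
    mk("EntityWithAccessionedSequence", sprintf("Protein %d", i),
       speciesName = "Homo sapiens"), integer(1))
  chemicals <- vapply(seq_len(cfg@nChemicals), function(i)
    mk("SimpleEntity", sprintf("Chemical %d", i)), integer(1))
  leaves <- c(proteins, chemicals)

  decompE <- list(); decompI <- list(); cdepth <- list()
  for (l in leaves) {
    decompE[[as.character(l)]] <- l
    decompI[[as.character(l)]] <- l
    cdepth[[as.character(l)]] <- 0L
  }
  pool <- leaves
  kinds <- samplePick(c(rep("Complex", nComplexes), rep("EntitySet", nSets)),
                      nComplexes + nSets)
  for (kind in kinds) {
    depths <- vapply(as.character(pool), function(k) cdepth[[k]], integer(1))
    eligible <- pool[depths < cfg@maxComplexNesting]
    if (!length(eligible)) eligible <- leaves
    if (kind == "Complex") {
      k <- min(sample(2:4, 1L), length(eligible))
      comps <- samplePick(eligible, k)
      if (stats::runif(1) < 0.2) comps <- c(comps, comps[1])  # stoichiometry 2
      id <- mk("Complex", sprintf("Complex %d", nextId + 1L),
               list(hasComponent = comps))
      kids <- comps; cands <- integer()
    } else {
      k <- min(samplePick(cfg@membersPerSet[1]:cfg@membersPerSet[2]),
               length(eligible))
      members <- samplePick(eligible, max(k, 1L))
      cands <- integer()
      rest <- setdiff(eligible, members)
      if (length(rest) && stats::runif(1) < 0.3)
        cands <- samplePick(rest, min(2L, length(rest)))
      sv <- list(hasMember = members)
      if (length(cands)) sv$hasCandidate <- cands
      id <- mk("EntitySet", sprintf("Set %d", nextId + 1L), sv)
      kids <- members
    }
    key <- as.character(id)
    decompE[[key]] <- if (length(kids))
      idSort(unlist(decompE[as.character(unique(kids))])) else id
    allKids <- unique(c(kids, cands))
    decompI[[key]] <- if (length(allKids))
      idSort(unlist(decompI[as.character(allKids)])) else id
    cdepth[[key]] <- 1L + max(vapply(as.character(unique(allKids)),
                                     function(k) cdepth[[k]], integer(1)))
    pool <- c(pool, id)
  }
  entities <- pool

  usedEntities <- integer()
  parentOf <- list()     # event id -> parent pathway id
  rxnInfo <- list()      # rxn id -> inputs/outputs/cat/reg
  pwSubs <- list(); pwRxns <- list()
  allRxns <- integer()
  rleClasses <- c("Reaction", "BlackBoxEvent", "Polymerisation",
                  "Depolymerisation", "FailedReaction")
  pickEntity <- function() {
    if (length(usedEntities) && stats::runif(1) < cfg@sharedEntityProbability)
      return(samplePick(usedEntities))
    unused <- setdiff(entities, usedEntities)
    if (length(unused)) samplePick(unused) else samplePick(entities)
  }
  buildPathway <- function(level) {
    pid <- mk("Pathway", sprintf("Pathway %d", nextId + 1L))
    nSub <- if (level < cfg@maxPathwayDepth) sample(0:2, 1L) else 0L
    subs <- vapply(seq_len(nSub), function(i) buildPathway(level + 1L),
                   integer(1))
    nR <- samplePick(cfg@reactionsPerPathway[1]:cfg@reactionsPerPathway[2])
    rxns <- integer()
    for (j in seq_len(nR)) {
      cls <- sample(rleClasses, 1L, prob = c(0.8, 0.05, 0.05, 0.05, 0.05))
      ins <- vapply(seq_len(sample(1:3, 1L)), function(i) pickEntity(),
                    integer(1))
      if (stats::runif(1) < 0.15) ins <- c(ins, ins[1])  # stoichiometry 2
      outs <- vapply(seq_len(sample(1:2, 1L)), function(i) pickEntity(),
                     integer(1))
      rid <- mk(cls, sprintf("%s %d", cls, nextId + 1L),
                list(input = ins, output = outs))
      usedEntities <<- union(usedEntities, c(ins, outs))
      cat <- integer(); reg <- integer()
      if (stats::runif(1) < cfg@catalystProbability) {
        pe <- pickEntity()
        ca <- mk("CatalystActivity", sprintf("Catalysis %d", nextId + 1L),
                 list(physicalEntity = pe))
        recs[[as.character(rid)]]$slotValues$catalystActivity <<- ca
        usedEntities <<- union(usedEntities, pe)
        cat <- pe
      }
      if (stats::runif(1) < cfg@regulatorProbability) {
        pe <- pickEntity()
        rg <- mk("Regulation", sprintf("Regulation %d", nextId + 1L),
                 list(regulator = pe))
        recs[[as.character(rid)]]$slotValues$regulatedBy <<- rg
        usedEntities <<- union(usedEntities, pe)
        reg <- pe
      }
      rxnInfo[[as.character(rid)]] <<- list(inputs = ins, outputs = outs,
                                            cat = cat, reg = reg)
      rxns <- c(rxns, rid)
    }
    for (j in seq_along(rxns)) {
      if (j >= 2L && stats::runif(1) < 0.6)
        recs[[as.character(rxns[j])]]$slotValues$precedingEvent <<- rxns[j - 1L]
    }
    if (length(rxns) >= 2L && stats::runif(1) < cfg@cycleProbability) {
      first <- as.character(rxns[1])
      recs[[first]]$slotValues$precedingEvent <<-
        unique(c(recs[[first]]$slotValues$precedingEvent, rxns[length(rxns)]))
    }
    kids <- c(subs, rxns)
    if (length(kids)) recs[[as.character(pid)]]$slotValues$hasEvent <<- kids
    for (k in kids) parentOf[[as.character(k)]] <<- pid
    pwSubs[[as.character(pid)]] <<- subs
    pwRxns[[as.character(pid)]] <<- rxns
    allRxns <<- c(allRxns, rxns)
    pid
  }
  roots <- vapply(seq_len(cfg@nTopPathways), function(i) buildPathway(1L),
                  integer(1))

  ## every non-orphan entity must be reachable: attach leftover entities
  ## (and thereby their composition descendants) as inputs of random
  ## reactions
  compDescendants <- function(id) {
    out <- integer(); stack <- id
    while (length(stack)) {
      cur <- stack[[1]]; stack <- stack[-1]
      if (cur %in% out) next
      out <- c(out, cur)
      sv <- recs[[as.character(cur)]]$slotValues
      stack <- c(stack, as.integer(unlist(
        sv[c("hasComponent", "hasMember", "hasCandidate")])))
    }
    out
  }
  if (length(allRxns)) {
    reach <- localClosure(recs, roots)
    unreached <- setdiff(entities, reach)
    depths <- vapply(as.character(unreached), function(k) cdepth[[k]],
                     integer(1))
    covered <- integer()
    for (e in unreached[order(-depths)]) {
      if (e %in% covered) next
      rid <- samplePick(allRxns)
      key <- as.character(rid)
      recs[[key]]$slotValues$input <- c(recs[[key]]$slotValues$input, e)
      rxnInfo[[key]]$inputs <- c(rxnInfo[[key]]$inputs, e)
      covered <- c(covered, compDescendants(e))
    }
  }

  ## orphans: deliberately unreachable instances
  orphanIds <- integer()
  for (i in seq_len(cfg@orphanCount)) {
    id <- if (i %% 2L == 1L || !length(entities)) {
      mk("EntityWithAccessionedSequence", sprintf("Orphan protein %d", i),
         speciesName = "Homo sapiens")
    } else {
      mk("Reaction", sprintf("Orphan reaction %d", i),
         list(input = samplePick(entities), output = samplePick(entities)))
    }
    orphanIds <- c(orphanIds, id)
  }

  ## ---- ground truth (from the builder's own records) ----
  allIds <- idSort(vapply(recs, function(r) r$dbId, integer(1)))
  reachable <- localClosure(recs, roots)
  decompositions <- lapply(as.character(entities), function(k)
    list(excl = idSort(decompE[[k]]), incl = idSort(decompI[[k]])))
  names(decompositions) <- as.character(entities)
  events <- c(unlist(lapply(names(pwSubs), as.integer)), allRxns)
  ancestors <- lapply(events, function(ev) {
    chain <- ev
    p <- parentOf[[as.character(ev)]]
    while (!is.null(p)) {
      chain <- c(p, chain)
      p <- parentOf[[as.character(p)]]
    }
    chain
  })
  names(ancestors) <- as.character(events)
  subtreeRxns <- function(pid) {
    out <- pwRxns[[as.character(pid)]]
    for (s in pwSubs[[as.character(pid)]]) out <- c(out, subtreeRxns(s))
    out
  }
  participants <- lapply(names(pwSubs), function(pk) {
    rxns <- subtreeRxns(as.integer(pk))
    info <- rxnInfo[as.character(rxns)]
    base <- idSort(unlist(lapply(info, function(x) c(x$inputs, x$outputs))))
    cats <- idSort(unlist(lapply(info, `[[`, "cat")))
    regs <- idSort(unlist(lapply(info, `[[`, "reg")))
    out <- list()
    for (ct in c(0L, 1L)) for (rg in c(0L, 1L)) {
      stated <- idSort(c(base, if (ct) cats, if (rg) regs))
      dec <- idSort(unlist(decompE[as.character(stated)]))
      out[[sprintf("cat%d_reg%d_dec0", ct, rg)]] <- stated
      out[[sprintf("cat%d_reg%d_dec1", ct, rg)]] <- dec
    }
    out
  })
  names(participants) <- names(pwSubs)

  insts <- lapply(as.character(allIds), function(k) {
    r <- recs[[k]]
    newInstance(r$dbId, r$className, r$displayName, slotValues = r$slotValues)
  })
  store <- newObjectStore(insts, roots)
  truth <- list(reachable = reachable,
                orphans = idSort(setdiff(allIds, reachable)),
                topLevelPathways = roots,
                decompositions = decompositions,
                ancestors = ancestors,
                participants = participants)
  list(store = store, truth = truth, config = cfg)
}

## reference closure over builder records (generator-local, not the
## store-side or graph-side implementations under test)
localClosure <- function(recs, roots) {
  refSlots <- c("hasEvent", "input", "output", "catalystActivity",
                "precedingEvent", "regulatedBy", "physicalEntity",
                "regulator", "hasComponent", "hasMember", "hasCandidate")
  seen <- integer()
  stack <- as.integer(roots)
  while (length(stack)) {
    cur <- stack[[1]]; stack <- stack[-1]
    if (cur %in% seen) next
    seen <- c(seen, cur)
    sv <- recs[[as.character(cur)]]$slotValues
    stack <- c(stack, as.integer(unlist(sv[refSlots])))
  }
  idSort(seen)
}
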