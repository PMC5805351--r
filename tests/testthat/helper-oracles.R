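# Independent brute-force oracles over the ObjectStore: naive recursions
# over instance slot values, deliberately separate from both the graph
# traversal implementations and the package's store-side integrity code.

orElse <- function(a, b) if (is.null(a)) b else a

oInst <- function(store, id) instances(store)[[as.character(id)]]

oSlot <- function(store, id, slot) {
  inst <- oInst(store, id)
  if (is.null(inst)) return(integer())
  as.integer(orElse(slotValues(inst)[[slot]], integer()))
}

oClass <- function(store, id) className(oInst(store, id))

RLE_CLASSES <- c("Reaction", "FailedReaction", "Polymerisation",
                 "Depolymerisation", "BlackBoxEvent", "ReactionLikeEvent")
ALL_REF_SLOTS <- c("hasEvent", "input", "output", "catalystActivity",
                   "precedingEvent", "regulatedBy", "physicalEntity",
                   "regulator", "hasComponent", "hasMember", "hasCandidate")

oRefValues <- function(store, id) {
  sv <- slotValues(oInst(store, id))
  lapply(sv[intersect(names(sv), ALL_REF_SLOTS)], as.integer)
}

oracleReactionIO <- function(store, rid) {
  list(inputs = oSlot(store, rid, "input"),
       outputs = oSlot(store, rid, "output"))
}

# fixed-point closure over hasEvent
oracleEventClosure <- function(store, pid, recursive = TRUE) {
  if (!recursive) return(sort(unique(oSlot(store, pid, "hasEvent"))))
  reached <- integer()
  frontier <- pid
  repeat {
    nxt <- sort(unique(unlist(lapply(frontier, oSlot, store = store,
                                     slot = "hasEvent"))))
    nxt <- setdiff(nxt, reached)
    if (!length(nxt)) break
    reached <- c(reached, nxt)
    frontier <- nxt
  }
  sort(reached)
}

oracleDecompose <- function(store, id, includeCandidates = FALSE) {
  slots <- c("hasComponent", "hasMember",
             if (includeCandidates) "hasCandidate")
  kidsOf <- function(x) unlist(lapply(slots, oSlot, store = store, id = x))
  leaves <- integer(); seen <- integer()
  walk <- function(x) {
    if (x %in% seen) return(invisible())
    seen <<- c(seen, x)
    kids <- kidsOf(x)
    if (!length(kids)) leaves <<- c(leaves, x)
    else for (k in kids) walk(k)
  }
  walk(as.integer(id))
  sort(unique(leaves))
}

# participants with role and reaction provenance
oracleParticipants <- function(store, pid, includeCatalysts = TRUE,
                               includeRegulators = TRUE, decompose = FALSE,
                               includeCandidates = FALSE) {
  events <- oracleEventClosure(store, pid, recursive = TRUE)
  rles <- events[vapply(events, function(e) oClass(store, e) %in% RLE_CLASSES,
                        logical(1))]
  roles <- list(); via <- list()
  note <- function(ent, role, rle) {
    k <- as.character(ent)
    roles[[k]] <<- union(orElse(roles[[k]], character()), role)
    via[[k]] <<- union(orElse(via[[k]], integer()), rle)
  }
  for (r in rles) {
    for (e in unique(oSlot(store, r, "input"))) note(e, "input", r)
    for (e in unique(oSlot(store, r, "output"))) note(e, "output", r)
    if (includeCatalysts)
      for (ca in oSlot(store, r, "catalystActivity"))
        for (e in oSlot(store, ca, "physicalEntity")) note(e, "catalyst", r)
    if (includeRegulators)
      for (rg in oSlot(store, r, "regulatedBy"))
        for (e in oSlot(store, rg, "regulator")) note(e, "regulator", r)
  }
  if (decompose) {
    roles2 <- list(); via2 <- list()
    for (k in names(roles)) {
      for (leaf in oracleDecompose(store, as.integer(k), includeCandidates)) {
        lk <- as.character(leaf)
        roles2[[lk]] <- union(orElse(roles2[[lk]], character()), roles[[k]])
        via2[[lk]] <- union(orElse(via2[[lk]], integer()), via[[k]])
      }
    }
    roles <- roles2; via <- via2
  }
  ids <- sort(as.integer(names(roles)))
  lapply(ids, function(ent) list(
    entity = ent, roles = sort(roles[[as.character(ent)]]),
    viaReactions = sort(unique(via[[as.character(ent)]]))))
}

oracleParticipantIds <- function(...) {
  vapply(oracleParticipants(...), `[[`, integer(1), "entity")
}

oracleAncestors <- function(store, event) {
  parents <- list()
  for (inst in instances(store)) {
    for (k in as.integer(orElse(slotValues(inst)[["hasEvent"]], integer())))
      parents[[as.character(k)]] <- union(parents[[as.character(k)]],
                                          dbId(inst))
  }
  chains <- list()
  climb <- function(node, below) {
    ps <- sort(setdiff(orElse(parents[[as.character(node)]], integer()),
                       c(node, below)))
    if (!length(ps)) chains[[length(chains) + 1L]] <<- c(node, below)
    else for (p in ps) climb(p, c(node, below))
  }
  climb(as.integer(event), integer())
  keys <- vapply(chains, function(ch)
    sprintf("%04d|%s", length(ch),
            paste(sprintf("%012d", ch), collapse = ",")), character(1))
  chains[order(keys)]
}

oracleReachable <- function(store) {
  seen <- integer(); stack <- as.integer(topLevelPathways(store))
  while (length(stack)) {
    cur <- stack[[1]]; stack <- stack[-1]
    if (cur %in% seen) next
    seen <- c(seen, cur)
    stack <- c(stack, unlist(oRefValues(store, cur)))
  }
  sort(seen)
}

# total reference-slot value count over the given instances
oracleRefCount <- function(store, ids) {
  sum(vapply(ids, function(id) length(unlist(oRefValues(store, id))),
             integer(1)))
}

oracleChainsTo <- function(store, target, maxLength = 5L) {
  # restricted to the reachable partition, i.e. the content a default
  # (orphan-excluding) import materializes
  allIds <- intersect(vapply(instances(store), dbId, integer(1)),
                      oracleReachable(store))
  rxns <- allIds[vapply(allIds, function(i)
    oClass(store, i) %in% RLE_CLASSES, logical(1))]
  producersOf <- function(ent)
    sort(unique(rxns[vapply(rxns, function(r)
      ent %in% oSlot(store, r, "output"), logical(1))]))
  predsOf <- function(r) {
    ins <- oSlot(store, r, "input")
    sort(unique(unlist(lapply(unique(ins), producersOf))))
  }
  chains <- list()
  extend <- function(chain) {
    chains[[length(chains) + 1L]] <<- chain
    if (length(chain) >= maxLength) return(invisible())
    for (p in setdiff(predsOf(chain[1]), chain)) extend(c(p, chain))
  }
  for (t in producersOf(as.integer(target))) extend(t)
  chains <- unique(chains)
  keys <- vapply(chains, function(ch)
    sprintf("%04d|%s", length(ch),
            paste(sprintf("%012d", ch), collapse = ",")), character(1))
  chains[order(keys)]
}
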