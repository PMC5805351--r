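## Traversal queries over the migrated property graph: the use cases a
## pathway knowledgebase serves — recursive event retrieval, reaction
## inputs/outputs, participant enumeration, complex/set decomposition,
## inverse entity-to-pathway lookup, ancestor chains, and reaction
## cascades. All node-set results are returned sorted by dbId; chains
## are sorted by (length, lexicographic id sequence).

assertLabel <- function(graph, nodeId, label, what) {
  if (!nodeHasLabel(graph, nodeId, label))
    stopf("node %d is not a %s (%s expected)", nodeId,
          label, what, class = "kbgraph_type_error")
}

compositionTypes <- function(includeCandidates)
  c("hasComponent", "hasMember", if (includeCandidates) "hasCandidate")

#' Inputs and outputs of a reaction-like event
#'
#' Entities follow edge order; an entity consumed or produced with
#' stoichiometry > 1 appears repeatedly.
#'
#' @param graph a [PropertyGraph-class].
#' @param reaction dbId or stId of a ReactionLikeEvent node.
#' @return list with ordered integer vectors `inputs` and `outputs`.
#' @export
reactionIO <- function(graph, reaction) {
  id <- resolveNodeId(graph, reaction)
  assertLabel(graph, id, "ReactionLikeEvent", "reactionIO")
  io <- nodeNeighbors(graph, id, c("input", "output"), "out")
  list(inputs = io$neighbor[io$type == "input"],
       outputs = io$neighbor[io$type == "output"])
}

#' Events of a pathway
#'
#' @param graph a [PropertyGraph-class].
#' @param pathway dbId or stId of a Pathway node.
#' @param recursive when `TRUE`, the transitive closure over `hasEvent`
#'   (sub-pathways and their events included); otherwise direct children
#'   only. Terminates on cyclic event hierarchies.
#' @return sorted integer vector of event node ids.
#' @export
pathwayEvents <- function(graph, pathway, recursive = TRUE) {
  id <- resolveNodeId(graph, pathway)
  assertLabel(graph, id, "Pathway", "pathwayEvents")
  if (recursive)
    traverseGraph(graph, id, "hasEvent", "out")$ids
  else
    idSort(nodeNeighbors(graph, id, "hasEvent", "out")$neighbor)
}

## catalyst / regulator physical entities of one RLE, with the
## intermediate CatalystActivity / Regulation hop
rleRolePEs <- function(graph, rle, viaType, peSlot) {
  mids <- nodeNeighbors(graph, rle, viaType, "out")$neighbor
  out <- integer()
  for (m in mids)
    out <- c(out, nodeNeighbors(graph, m, peSlot, "out")$neighbor)
  idSort(out)
}

#' Participating molecules of a pathway
#'
#' Union over all reaction-like events of the pathway's recursive event
#' closure of their inputs, outputs and (per flags) catalyst physical
#' entities and regulators. With `decompose = TRUE` every stated
#' participant is expanded to its leaf molecules via
#' [decomposeEntity()], and records are merged per leaf with role and
#' reaction provenance unioned.
#'
#' @param graph a [PropertyGraph-class].
#' @param pathway dbId or stId of a Pathway node.
#' @param includeCatalysts,includeRegulators include the physical
#'   entities reached through `catalystActivity` / `regulatedBy`.
#' @param decompose report leaf molecules instead of the stated
#'   physical entities.
#' @param includeCandidates treat entity-set candidates as members
#'   during decomposition.
#' @return list of participant records, sorted by entity dbId; each is a
#'   list with `entity` (node id), `roles` (sorted character subset of
#'   input/output/catalyst/regulator) and `viaReactions` (sorted integer
#'   vector).
#' @export
pathwayParticipants <- function(graph, pathway, includeCatalysts = TRUE,
                                includeRegulators = TRUE, decompose = FALSE,
                                includeCandidates = FALSE) {
  id <- resolveNodeId(graph, pathway)
  assertLabel(graph, id, "Pathway", "pathwayParticipants")
  events <- pathwayEvents(graph, id, recursive = TRUE)
  rles <- events[vapply(events, nodeHasLabel, logical(1),
                        graph = graph, label = "ReactionLikeEvent")]
  acc <- list()  # key: entity id -> list(roles, via)
  note <- function(entity, role, rle) {
    key <- as.character(entity)
    rec <- acc[[key]] %||% list(roles = character(), via = integer())
    rec$roles <- union(rec$roles, role)
    rec$via <- union(rec$via, rle)
    acc[[key]] <<- rec
  }
  for (rle in rles) {
    io <- reactionIO(graph, rle)
    for (ent in unique(io$inputs)) note(ent, "input", rle)
    for (ent in unique(io$outputs)) note(ent, "output", rle)
    if (includeCatalysts)
      for (ent in rleRolePEs(graph, rle, "catalystActivity", "physicalEntity"))
        note(ent, "catalyst", rle)
    if (includeRegulators)
      for (ent in rleRolePEs(graph, rle, "regulatedBy", "regulator"))
        note(ent, "regulator", rle)
  }
  if (decompose) {
    leafAcc <- list()
    for (key in names(acc)) {
      leaves <- decomposeEntity(graph, as.integer(key), includeCandidates)
      for (leaf in leaves) {
        lk <- as.character(leaf)
        rec <- leafAcc[[lk]] %||% list(roles = character(), via = integer())
        rec$roles <- union(rec$roles, acc[[key]]$roles)
        rec$via <- union(rec$via, acc[[key]]$via)
        leafAcc[[lk]] <- rec
      }
    }
    acc <- leafAcc
  }
  ids <- idSort(as.integer(names(acc)))
  lapply(ids, function(ent) {
    rec <- acc[[as.character(ent)]]
    list(entity = ent, roles = sort(rec$roles), viaReactions = idSort(rec$via))
  })
}

#' Decompose a complex or set into its leaf molecules
#'
#' Transitive closure over the composition edges `hasComponent`,
#' `hasMember` and (when `includeCandidates = TRUE`) `hasCandidate`.
#' Leaves are nodes with no outgoing edges among the active composition
#' types — simple entities, proteins, or containers that are empty under
#' the chosen candidate setting. A leaf input returns itself. Terminates
#' on shared and (artificially) cyclic substructure.
#'
#' @param graph a [PropertyGraph-class].
#' @param entity dbId or stId of a PhysicalEntity node.
#' @param includeCandidates follow `hasCandidate` edges too.
#' @return sorted integer vector of leaf molecule node ids.
#' @export
decomposeEntity <- function(graph, entity, includeCandidates = FALSE) {
  id <- resolveNodeId(graph, entity)
  assertLabel(graph, id, "PhysicalEntity", "decomposeEntity")
  types <- compositionTypes(includeCandidates)
  reached <- union(id, traverseGraph(graph, id, types, "out")$ids)
  compSources <- unique(graph@edges$source[graph@edges$type %in% types])
  idSort(setdiff(reached, compSources))
}

#' Pathways in which an entity participates
#'
#' The inverse image of [pathwayParticipants()]: every pathway `p` such
#' that `entity` is in `pathwayParticipants(p, decompose = leafMatch)`.
#' Implemented by upward traversal: composition edges inward (when
#' `leafMatch`), then reaction-role edges inward, then the `hasEvent`
#' closure inward. Note that with `leafMatch = TRUE` only leaf molecules
#' can match (a complex is never a leaf of any decomposition), so a
#' non-leaf entity yields an empty set; use `leafMatch = FALSE` to match
#' entities stated directly as reaction participants.
#'
#' @param graph a [PropertyGraph-class].
#' @param entity dbId or stId of a PhysicalEntity node.
#' @param leafMatch match the entity as a leaf molecule inside arbitrary
#'   containers (complexes/sets) rather than only as a stated
#'   participant.
#' @param includeCatalysts,includeRegulators,includeCandidates mirror
#'   the [pathwayParticipants()] flags.
#' @return sorted integer vector of Pathway node ids (ancestor pathways
#'   included).
#' @export
pathwaysForEntity <- function(graph, entity, leafMatch = TRUE,
                              includeCatalysts = TRUE,
                              includeRegulators = TRUE,
                              includeCandidates = FALSE) {
  id <- resolveNodeId(graph, entity)
  if (is.null(graph@nodes[[as.character(id)]]))
    stopf("node %s not found", entity, class = "kbgraph_not_found")
  types <- compositionTypes(includeCandidates)
  if (leafMatch) {
    isLeaf <- !id %in% graph@edges$source[graph@edges$type %in% types]
    if (!isLeaf) return(integer())
    carriers <- union(id, traverseGraph(graph, id, types, "in")$ids)
  } else {
    carriers <- id
  }
  e <- graph@edges
  rles <- e$source[e$type %in% c("input", "output") & e$target %in% carriers]
  if (includeCatalysts) {
    cas <- e$source[e$type == "physicalEntity" & e$target %in% carriers]
    rles <- c(rles, e$source[e$type == "catalystActivity" & e$target %in% cas])
  }
  if (includeRegulators) {
    regs <- e$source[e$type == "regulator" & e$target %in% carriers]
    rles <- c(rles, e$source[e$type == "regulatedBy" & e$target %in% regs])
  }
  rles <- idSort(rles)
  if (!length(rles)) return(integer())
  up <- traverseGraph(graph, rles, "hasEvent", "in")$ids
  pw <- graph@labelIndex[["Pathway"]] %||% integer()
  idSort(intersect(up, pw))
}

#' Ancestor chains of an event
#'
#' All distinct root-to-event chains following `hasEvent` inward to the
#' top of the event forest, cycle-safe, each chain ordered root-first
#' and ending at the event itself. A top-level pathway yields the single
#' chain containing itself; an event under two parent pathways yields
#' two chains.
#'
#' @param graph a [PropertyGraph-class].
#' @param event dbId or stId of an Event node.
#' @return list of integer vectors, sorted by (length, lexicographic id
#'   sequence).
#' @export
eventAncestors <- function(graph, event) {
  id <- resolveNodeId(graph, event)
  assertLabel(graph, id, "Event", "eventAncestors")
  e <- graph@edges[graph@edges$type == "hasEvent", , drop = FALSE]
  chains <- list()
  climb <- function(node, below) {
    parents <- idSort(e$source[e$target == node])
    parents <- setdiff(parents, c(node, below))  # cycle guard
    if (!length(parents)) {
      chains[[length(chains) + 1L]] <<- c(node, below)
      return(invisible())
    }
    for (p in parents) climb(p, c(node, below))
  }
  climb(id, integer())
  sortChains(chains)
}

sortChains <- function(chains) {
  if (!length(chains)) return(chains)
  keys <- vapply(chains, function(ch)
    sprintf("%04d|%s", length(ch),
            paste(sprintf("%012d", ch), collapse = ",")), character(1))
  chains[order(keys)]
}

#' Reaction cascades producing an entity
#'
#' All acyclic chains `r1, ..., rk` (`k <= maxLength`) of reaction-like
#' events where `rk` outputs the target entity and consecutive reactions
#' are linked: by default an output of `ri` is an input of `ri+1`
#' (`link = "sharedEntity"`); alternatively explicit `precedingEvent`
#' edges are honoured (`link = "precedingEvent"`). Every suffix of a
#' longer cascade is itself reported as a chain. An entity never
#' produced by a reaction gives an empty list.
#'
#' @param graph a [PropertyGraph-class].
#' @param target dbId or stId of the produced PhysicalEntity.
#' @param maxLength maximum chain length.
#' @param link linkage rule between consecutive reactions.
#' @return list of chains sorted by (length, lexicographic id sequence);
#'   each chain is a list with `reactions` (ordered integer vector) and
#'   `entity` (the terminal entity node id).
#' @export
reactionChainsTo <- function(graph, target, maxLength = 5L,
                             link = c("sharedEntity", "precedingEvent")) {
  link <- match.arg(link)
  id <- resolveNodeId(graph, target)
  assertLabel(graph, id, "PhysicalEntity", "reactionChainsTo")
  e <- graph@edges
  terminals <- idSort(e$source[e$type == "output" & e$target == id])
  predsOf <- function(r) {
    if (link == "sharedEntity") {
      ins <- e$target[e$type == "input" & e$source == r]
      idSort(e$source[e$type == "output" & e$target %in% ins])
    } else {
      prev <- e$target[e$type == "precedingEvent" & e$source == r]
      prev[vapply(prev, nodeHasLabel, logical(1),
                  graph = graph, label = "ReactionLikeEvent")]
    }
  }
  chains <- list()
  extend <- function(chain) {
    chains[[length(chains) + 1L]] <<- chain
    if (length(chain) >= maxLength) return(invisible())
    for (p in setdiff(predsOf(chain[1]), chain)) extend(c(p, chain))
  }
  for (t in terminals) extend(t)
  raw <- sortChains(unique(chains))
  lapply(raw, function(ch) list(reactions = ch, entity = id))
}
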