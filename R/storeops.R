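## Direct enumeration over the ObjectStore slots — the "relational side"
## of the post-migration integrity checks. These walk instance slot
## values only and never touch the property graph.

#' Instances reachable from the top-level pathways
#'
#' Transitive closure over all reference slot values.
#'
#' @param store an [ObjectStore-class].
#' @return sorted integer vector of reachable dbIds (top-level pathways
#'   included).
#' @export
storeReachable <- function(store) {
  frontier <- as.integer(store@topLevelPathways)
  seen <- new.env(parent = emptyenv())
  for (f in frontier) assign(as.character(f), TRUE, envir = seen)
  while (length(frontier)) {
    nxt <- integer()
    for (id in frontier) {
      inst <- getInstance(store, id)
      if (is.null(inst)) next
      for (v in referenceValues(store, inst)) nxt <- c(nxt, v)
    }
    nxt <- unique(nxt)
    nxt <- nxt[!vapply(as.character(nxt), exists, logical(1), envir = seen,
                       inherits = FALSE)]
    for (f in nxt) assign(as.character(f), TRUE, envir = seen)
    frontier <- nxt
  }
  idSort(as.integer(ls(seen)))
}

#' Ancestor chains computed over store slots
#'
#' Same contract as [eventAncestors()] but walks reversed `hasEvent`
#' slot values of the store directly.
#'
#' @param store an [ObjectStore-class].
#' @param event dbId of an event instance.
#' @return list of integer chains, root-first, sorted like
#'   [eventAncestors()].
#' @export
storeAncestors <- function(store, event) {
  ## reversed hasEvent: child -> parents
  parentsOf <- list()
  for (inst in store@instances) {
    kids <- inst@slotValues[["hasEvent"]]
    for (k in as.integer(kids))
      parentsOf[[as.character(k)]] <-
        union(parentsOf[[as.character(k)]], inst@dbId)
  }
  chains <- list()
  climb <- function(node, below) {
    parents <- idSort(parentsOf[[as.character(node)]] %||% integer())
    parents <- setdiff(parents, c(node, below))
    if (!length(parents)) {
      chains[[length(chains) + 1L]] <<- c(node, below)
      return(invisible())
    }
    for (p in parents) climb(p, c(node, below))
  }
  climb(as.integer(event), integer())
  sortChains(chains)
}

#' Decomposition computed over store slots
#'
#' Naive recursive expansion of `hasComponent` / `hasMember` (and
#' optionally `hasCandidate`) slot values; same leaf rule as
#' [decomposeEntity()].
#'
#' @param store an [ObjectStore-class].
#' @param entity dbId of a physical entity instance.
#' @param includeCandidates follow `hasCandidate` values too.
#' @return sorted integer vector of leaf dbIds.
#' @export
storeDecompose <- function(store, entity, includeCandidates = FALSE) {
  slots <- compositionTypes(includeCandidates)
  childrenOf <- function(id) {
    inst <- getInstance(store, id)
    if (is.null(inst)) return(integer())
    idSort(unlist(lapply(slots, function(s)
      as.integer(inst@slotValues[[s]] %||% integer()))))
  }
  leaves <- integer()
  seen <- integer()
  walk <- function(id) {
    if (id %in% seen) return(invisible())
    seen <<- c(seen, id)
    kids <- childrenOf(id)
    if (!length(kids)) leaves <<- c(leaves, id)
    else for (k in kids) walk(k)
  }
  walk(as.integer(entity))
  idSort(leaves)
}

## direct composition children on each side (used by the "direct" mode
## of the complex-content check)
storeDirectChildren <- function(store, entity, includeCandidates = FALSE) {
  inst <- getInstance(store, entity)
  if (is.null(inst)) return(integer())
  idSort(unlist(lapply(compositionTypes(includeCandidates), function(s)
    as.integer(inst@slotValues[[s]] %||% integer()))))
}

graphDirectChildren <- function(graph, entity, includeCandidates = FALSE) {
  idSort(nodeNeighbors(graph, entity, compositionTypes(includeCandidates),
                       "out")$neighbor)
}

## every reference slot value of the given instances as canonical
## "source|type|order|target" edge tuples
storeEdgeTuples <- function(store, ids) {
  out <- character()
  for (id in ids) {
    inst <- getInstance(store, id)
    refs <- referenceValues(store, inst)
    for (slot in names(refs)) {
      v <- refs[[slot]]
      out <- c(out, sprintf("%d|%s|%d|%d", id, slot, seq_along(v) - 1L, v))
    }
  }
  sort(out)
}

graphEdgeTuples <- function(graph) {
  e <- graph@edges
  sort(sprintf("%d|%s|%d|%d", e$source, e$type, e$order, e$target))
}
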