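## Post-migration verification that the property graph and the source
## object store carry identical content: top-level pathway counts,
## ancestor chains, complex content, and element-by-element conservation
## of instances and reference slot values.

checkResult <- function(name, pass, detail) {
  data.frame(name = name, pass = pass, detail = detail,
             stringsAsFactors = FALSE)
}

#' Compare top-level pathway counts
#'
#' Passes iff the number of top-level pathways in the graph (Pathway
#' nodes with no incoming `hasEvent`) equals the number recorded in the
#' store.
#'
#' @param store an [ObjectStore-class].
#' @param graph the [PropertyGraph-class] produced from it.
#' @return one-row check data.frame (`name`, `pass`, `detail`).
#' @export
checkTopLevelCount <- function(store, graph) {
  nStore <- length(unique(store@topLevelPathways))
  nGraph <- length(topLevelPathwayIds(graph))
  checkResult("top_level_count", nStore == nGraph,
              sprintf("store=%d graph=%d", nStore, nGraph))
}

#' Compare ancestor chains of one pathway/event
#'
#' Passes iff [eventAncestors()] on the graph equals the chain set
#' computed directly over store slots by [storeAncestors()].
#'
#' @inheritParams checkTopLevelCount
#' @param pathway dbId of the event to check.
#' @return one-row check data.frame.
#' @export
checkAncestors <- function(store, graph, pathway) {
  name <- sprintf("ancestors_%d", pathway)
  inStore <- !is.null(getInstance(store, pathway))
  inGraph <- !is.null(graph@nodes[[as.character(pathway)]])
  if (!inStore || !inGraph)
    return(checkResult(name, FALSE,
                       sprintf("present in store=%s graph=%s", inStore, inGraph)))
  gr <- eventAncestors(graph, pathway)
  st <- storeAncestors(store, pathway)
  ok <- identical(gr, st)
  checkResult(name, ok,
              if (ok) sprintf("%d chain(s) agree", length(gr))
              else sprintf("graph %d chain(s) != store %d chain(s)",
                           length(gr), length(st)))
}

#' Compare the content of one complex/set
#'
#' Runs both readings of "content": the leaf-molecule decomposition
#' ([decomposeEntity()] vs [storeDecompose()]) and the direct
#' composition children, each under both candidate settings.
#'
#' @inheritParams checkTopLevelCount
#' @param complex dbId of the Complex/EntitySet to check.
#' @return one-row check data.frame.
#' @export
checkComplexContent <- function(store, graph, complex) {
  name <- sprintf("complex_content_%d", complex)
  inStore <- !is.null(getInstance(store, complex))
  inGraph <- !is.null(graph@nodes[[as.character(complex)]])
  if (!inStore || !inGraph)
    return(checkResult(name, FALSE,
                       sprintf("present in store=%s graph=%s", inStore, inGraph)))
  for (cand in c(FALSE, TRUE)) {
    g <- decomposeEntity(graph, complex, includeCandidates = cand)
    s <- storeDecompose(store, complex, includeCandidates = cand)
    if (!identical(g, s))
      return(checkResult(name, FALSE, sprintf(
        "leaf content differs (includeCandidates=%s): graph {%s} store {%s}",
        cand, paste(g, collapse = ","), paste(s, collapse = ","))))
    gd <- graphDirectChildren(graph, complex, includeCandidates = cand)
    sd <- storeDirectChildren(store, complex, includeCandidates = cand)
    if (!identical(gd, sd))
      return(checkResult(name, FALSE, sprintf(
        "direct children differ (includeCandidates=%s)", cand)))
  }
  checkResult(name, TRUE, "leaf and direct content agree")
}

## conservation: node set vs reachable instances, edge tuples vs
## reference slot values. Orphans imported on purpose are noted, never
## failed.
checkConservation <- function(store, graph) {
  reachable <- storeReachable(store)
  gIds <- idSort(vapply(graph@nodes, function(n) n$node_id, integer(1)))
  allIds <- idSort(vapply(store@instances, function(i) i@dbId, integer(1)))
  orphans <- setdiff(allIds, reachable)
  missing <- setdiff(reachable, gIds)
  extra <- setdiff(gIds, reachable)
  alien <- setdiff(extra, orphans)      # in graph but in no store partition
  orphansIn <- intersect(extra, orphans)
  notes <- character()
  if (length(orphansIn))
    notes <- c(notes, sprintf("%d orphan instance(s) imported by request",
                              length(orphansIn)))
  orphansOut <- setdiff(orphans, gIds)
  if (length(orphansOut))
    notes <- c(notes, sprintf("%d orphan instance(s) excluded from the graph",
                              length(orphansOut)))
  nodesOk <- length(missing) == 0L && length(alien) == 0L
  nodeCheck <- checkResult(
    "conservation_nodes", nodesOk,
    sprintf("reachable=%d graph=%d missing=%d alien=%d orphans=%d",
            length(reachable), length(gIds), length(missing), length(alien),
            length(orphans)))
  expected <- storeEdgeTuples(store, intersect(gIds, allIds))
  got <- graphEdgeTuples(graph)
  edgesOk <- identical(expected, got)
  edgeCheck <- checkResult(
    "conservation_edges", edgesOk,
    if (edgesOk) sprintf("%d edge(s) agree", length(got))
    else sprintf("store expects %d edge tuple(s), graph has %d (%d differ)",
                 length(expected), length(got),
                 length(union(setdiff(expected, got), setdiff(got, expected)))))
  list(checks = rbind(nodeCheck, edgeCheck), notes = notes)
}

#' Run the full post-migration integrity suite
#'
#' Executes the top-level-pathway count check, instance/edge
#' conservation, ancestor-chain checks over all (or a seeded sample of)
#' pathways, and complex-content checks over all (or a sample of)
#' complexes and entity sets. Deterministic given `seed`.
#'
#' @param store an [ObjectStore-class].
#' @param graph the [PropertyGraph-class] produced from it.
#' @param sample `"all"` or a positive integer: how many pathways /
#'   complexes to check.
#' @param seed RNG seed for sampling (required when `sample` is a
#'   number).
#' @return an [IntegrityReport-class].
#' @export
verifyAll <- function(store, graph, sample = "all", seed = 1L) {
  checks <- checkTopLevelCount(store, graph)
  cons <- checkConservation(store, graph)
  checks <- rbind(checks, cons$checks)
  classes <- vapply(store@instances, function(i) i@className, character(1))
  ids <- vapply(store@instances, function(i) i@dbId, integer(1))
  isContainer <- classes %in% c("Complex", "EntitySet")
  pathways <- idSort(ids[classes == "Pathway"])
  containers <- idSort(ids[isContainer])
  if (!identical(sample, "all")) {
    n <- as.integer(sample)
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    set.seed(as.integer(seed))
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    pathways <- sort(samplePick(pathways, min(n, length(pathways))))
    containers <- sort(samplePick(containers, min(n, length(containers))))
  }
  for (p in pathways) checks <- rbind(checks, checkAncestors(store, graph, p))
  for (cx in containers)
    checks <- rbind(checks, checkComplexContent(store, graph, cx))
  rownames(checks) <- NULL
  new("IntegrityReport", checks = checks, overallPass = all(checks$pass),
      notes = cons$notes)
}

#' Render an integrity report as a list (for JSON output)
#'
#' @param report an [IntegrityReport-class].
#' @return plain list.
#' @export
integrityAsList <- function(report) {
  list(overall_pass = report@overallPass,
       n_checks = nrow(report@checks),
       n_failed = sum(!report@checks$pass),
       notes = as.list(report@notes),
       checks = lapply(seq_len(nrow(report@checks)), function(i)
         list(name = report@checks$name[i], pass = report@checks$pass[i],
              detail = report@checks$detail[i])))
}
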