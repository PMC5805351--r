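## Object marshalling with a lazy-loading contract: a shallow fetch
## returns reference placeholders that resolve on demand to exactly the
## values an eager (full) fetch would have produced.

#' Is a view element an unresolved reference placeholder?
#'
#' @param x an element of a fetched view's `refs`.
#' @return logical.
#' @export
isRefPlaceholder <- function(x) is.list(x) && identical(names(x), "ref")

makeView <- function(class, properties, refs) {
  if (length(properties)) properties <- properties[order(names(properties))]
  if (length(refs)) refs <- refs[order(names(refs))]
  list(class = class, properties = properties, refs = refs)
}

#' Fetch an object view from the graph
#'
#' `depth = "shallow"` returns node properties with every reference as a
#' placeholder (`list(ref = dbId)`); an integer depth materializes
#' references that many levels down; `depth = "full"` expands the
#' complete closure, emitting a placeholder only where a reference
#' cycles back onto the current expansion path (so cyclic
#' `precedingEvent` feedback terminates). Resolving a placeholder with
#' [resolveRef()] yields the same values as eager retrieval.
#'
#' @param graph a [PropertyGraph-class].
#' @param id dbId or stId.
#' @param depth `"shallow"`, `"full"`, or a non-negative integer.
#' @return a view: list with `class` (concrete class label),
#'   `properties` (named list, names sorted) and `refs` (named by edge
#'   type, each an ordered list of nested views or placeholders).
#' @export
fetchObject <- function(graph, id, depth = "shallow") {
  maxDepth <- if (identical(depth, "shallow")) 0
              else if (identical(depth, "full")) Inf
              else as.numeric(depth)
  if (is.na(maxDepth) || maxDepth < 0)
    stopf("depth must be 'shallow', 'full' or a non-negative integer")
  nid <- resolveNodeId(graph, id)
  fetchRec(graph, nid, maxDepth, integer())
}

fetchRec <- function(graph, nid, maxDepth, path) {
  node <- getNode(graph, nid)
  out <- nodeNeighbors(graph, nid, NULL, "out")
  refs <- list()
  for (tp in unique(out$type)) {
    rows <- out[out$type == tp, , drop = FALSE]
    refs[[tp]] <- lapply(seq_len(nrow(rows)), function(i) {
      tgt <- rows$neighbor[i]
      if (maxDepth <= 0 || tgt %in% path) list(ref = tgt)
      else fetchRec(graph, tgt, maxDepth - 1, c(path, nid))
    })
  }
  makeView(node$labels[1], node$properties, refs)
}

#' Resolve a reference placeholder
#'
#' @param graph a [PropertyGraph-class].
#' @param placeholder a `list(ref = dbId)` element from a shallow or
#'   bounded fetch.
#' @param depth expansion depth for the resolved object (default full).
#' @return the fetched view of the referenced object.
#' @export
resolveRef <- function(graph, placeholder, depth = "full") {
  if (!isRefPlaceholder(placeholder))
    stopf("not a reference placeholder")
  fetchObject(graph, placeholder$ref, depth)
}

#' Truncate a fully expanded view at a given depth
#'
#' Replaces every nested view deeper than `depth` with its placeholder;
#' used to compare bounded and full fetches.
#'
#' @param view a view from [fetchObject()].
#' @param depth non-negative integer.
#' @return the truncated view.
#' @export
truncateView <- function(view, depth) {
  if (isRefPlaceholder(view)) return(view)
  if (depth <= 0) {
    view$refs <- lapply(view$refs, function(items) lapply(items, function(it)
      if (isRefPlaceholder(it)) it else list(ref = it$properties$dbId)))
    return(view)
  }
  view$refs <- lapply(view$refs, function(items)
    lapply(items, function(it)
      if (isRefPlaceholder(it)) it else truncateView(it, depth - 1)))
  view
}
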