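## Desk-scale stress-test harness over two retrieval backends: join-style
## access to the relational table layout versus traversal over the
## property graph. Queried reactions are distinct and visited in a fixed
## seeded sequence so caching gives neither backend an advantage; each
## query marshals the full reaction object. Latency and throughput are
## reported, never asserted against thresholds — they are
## hardware-dependent by design; correctness (identical marshalled
## objects across backends and concurrency levels) is the testable
## contract.

#' Graph retrieval backend
#'
#' Answers full-object fetches by traversal over the property graph.
#'
#' @param graph a [PropertyGraph-class].
#' @return a backend: list with `label` and `fetch(id)`.
#' @export
graphBackend <- function(graph) {
  structure(list(label = "graph",
                 fetch = function(id) fetchObject(graph, id, "full")),
            class = "kbBackend")
}

#' Relational retrieval backend
#'
#' Answers full-object fetches by join-style access over the relational
#' table layout: the class of an id is looked up in `database_object`,
#' its row located in the class's entity table, and every reference slot
#' resolved through the corresponding junction table — recursively, as
#' the classic many-to-many retrieval would.
#'
#' @param tables named list of data.frames from [relationalTables()].
#' @param schema the [Schema-class] of the dumped store.
#' @return a backend: list with `label` and `fetch(id)`.
#' @export
relationalBackend <- function(tables, schema = builtinSchema()) {
  dbo <- tables[["database_object"]]
  fetchRel <- function(id, path) {
    cls <- dbo$class_name[dbo$db_id == id]
    if (!length(cls))
      stopf("node %s not found", id, class = "kbgraph_not_found")
    tab <- tables[[snakeCase(cls)]]
    row <- tab[tab$db_id == id, , drop = FALSE]
    eff <- effectiveSlots(schema, cls)
    props <- list(dbId = as.integer(id), stId = row$st_id,
                  displayName = row$display_name)
    for (nm in names(eff)) {
      if (eff[[nm]]@valueKind == "reference") next
      if (nm %in% c("displayName", "stId")) next
      col <- snakeCase(nm)
      if (col %in% names(row) && !is.na(row[[col]]))
        props[[nm]] <- row[[col]]
    }
    refs <- list()
    for (nm in names(eff)) {
      if (eff[[nm]]@valueKind != "reference") next
      jt <- tables[[paste(snakeCase(cls), snakeCase(nm), sep = "_")]]
      rows <- jt[jt$source_id == id, , drop = FALSE]
      if (!nrow(rows)) next
      rows <- rows[order(rows$slot_order), , drop = FALSE]
      refs[[nm]] <- lapply(rows$target_id, function(tgt) {
        if (tgt %in% path) list(ref = as.integer(tgt))
        else fetchRel(tgt, c(path, id))
      })
    }
    makeView(cls, props, refs)
  }
  structure(list(label = "relational",
                 fetch = function(id) fetchRel(as.integer(id), integer())),
            class = "kbBackend")
}

nowMs <- function() as.numeric(Sys.time()) * 1000

benchResult <- function(backend, scenario, nWorkers, latencies, elapsedSec,
                        results) {
  new("BenchResult", backend = backend, scenario = scenario,
      nQueries = length(latencies), nWorkers = as.integer(nWorkers),
      latenciesMs = latencies,
      meanMs = mean(latencies),
      sdMs = if (length(latencies) > 1) stats::sd(latencies) else 0,
      tps = length(latencies) / elapsedSec,
      elapsedSec = elapsedSec, results = results)
}

timedFetch <- function(backend, ids) {
  lat <- numeric(length(ids))
  res <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    t0 <- nowMs()
    res[[i]] <- backend$fetch(ids[i])
    lat[i] <- nowMs() - t0
  }
  names(res) <- as.character(ids)
  list(latencies = lat, results = res)
}

## the fixed query sequence: n distinct reactions, seeded shuffle
benchWorkload <- function(reactionIds, n, seed) {
  reactionIds <- idSort(reactionIds)
  if (n > length(reactionIds))
    stopf("workload needs %d distinct reactions, only %d available",
          n, length(reactionIds), class = "kbgraph_bench_error")
  withSeed(seed, samplePick(reactionIds, n))
}

#' Sequential single-user stress test
#'
#' One user querying `n` distinct reactions in a fixed seeded sequence
#' with no repeats; each query marshals the full reaction object.
#'
#' @param backend a backend from [graphBackend()] or
#'   [relationalBackend()].
#' @param reactionIds pool of reaction dbIds.
#' @param n number of queries (default: all of them).
#' @param seed seed for the workload order (not the latencies).
#' @return a [BenchResult-class].
#' @export
runSequential <- function(backend, reactionIds, n = length(reactionIds),
                          seed = 1L) {
  ids <- benchWorkload(reactionIds, n, seed)
  t0 <- nowMs()
  out <- timedFetch(backend, ids)
  elapsed <- (nowMs() - t0) / 1000
  benchResult(backend$label, "sequential", 1L, out$latencies, elapsed,
              out$results)
}

#' Concurrent multi-user stress test
#'
#' For each worker count the same seeded workload is partitioned across
#' workers without repeats (forked processes via
#' [parallel::mclapply()]); per-query latencies, mean, sd and
#' transactions-per-second are reported per worker count. Both backends
#' are read-only, so concurrent access must return results identical to
#' sequential execution.
#'
#' @inheritParams runSequential
#' @param nQueries total queries per worker-count run.
#' @param workers integer vector of worker counts (e.g. `1:8`).
#' @return list of [BenchResult-class], one per worker count.
#' @export
runConcurrent <- function(backend, reactionIds, nQueries, workers = 1:4,
                          seed = 1L) {
  ids <- benchWorkload(reactionIds, nQueries, seed)
  lapply(workers, function(w) {
    chunks <- split(ids, sort(rep_len(seq_len(w), length(ids))))
    t0 <- nowMs()
    parts <- parallel::mclapply(chunks, function(chunk)
      timedFetch(backend, chunk), mc.cores = w)
    elapsed <- (nowMs() - t0) / 1000
    lat <- unlist(lapply(parts, `[[`, "latencies"), use.names = FALSE)
    res <- do.call(c, lapply(parts, `[[`, "results"))
    names(res) <- sub("^[0-9]+\\.", "", names(res))
    benchResult(backend$label, "concurrent", w, lat, elapsed, res)
  })
}

#' Summarise benchmark results as a long-format table
#'
#' @param results a [BenchResult-class] or list of them.
#' @return data.frame with one row per run: backend, scenario, workers,
#'   queries, mean/sd latency (ms), TPS, elapsed seconds.
#' @export
benchSummary <- function(results) {
  if (is(results, "BenchResult")) results <- list(results)
  do.call(rbind, lapply(results, function(r)
    data.frame(backend = r@backend, scenario = r@scenario,
               workers = r@nWorkers, queries = r@nQueries,
               mean_ms = r@meanMs, sd_ms = r@sdMs, tps = r@tps,
               elapsed_sec = r@elapsedSec, stringsAsFactors = FALSE)))
}
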