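## Standard-format import/export for property graphs: JSON, GraphML
## (XML dialect with declared data keys) and a write-only Cypher script
## so third parties can load the same content into a Neo4j instance.

propType <- function(v) {
  if (is.logical(v)) "boolean"
  else if (is.numeric(v)) if (is.integer(v)) "long" else "double"
  else "string"
}

#' Export a property graph
#'
#' JSON and GraphML round-trip exactly (under canonical ordering);
#' the Cypher script is write-only and emits one `CREATE` statement per
#' node and per edge after a uniqueness-constraint preamble on `dbId`.
#'
#' @param graph a [PropertyGraph-class].
#' @param file destination path.
#' @param format `"json"`, `"graphml"` or `"cypher"`.
#' @return `file`, invisibly.
#' @export
exportGraph <- function(graph, file, format = c("json", "graphml", "cypher")) {
  format <- match.arg(format)
  switch(format,
         json = exportGraphJson(graph, file),
         graphml = exportGraphml(graph, file),
         cypher = exportCypher(graph, file))
  invisible(file)
}

#' Import a property graph
#'
#' @param file source path.
#' @param format `"json"` or `"graphml"` (the Cypher export has no
#'   reader).
#' @return a [PropertyGraph-class].
#' @export
importGraph <- function(file, format = c("json", "graphml")) {
  format <- match.arg(format)
  switch(format,
         json = importGraphJson(file),
         graphml = importGraphml(file))
}

## ---- JSON ------------------------------------------------------------------

graphAsList <- function(graph) {
  cg <- canonicalGraph(graph)
  ## keep original (typed) property values, canonical ordering
  ids <- vapply(cg$nodes, function(n) n$node_id, integer(1))
  nodes <- lapply(as.character(ids), function(k) {
    n <- graph@nodes[[k]]
    list(id = n$node_id, labels = as.list(n$labels),
         properties = n$properties[order(names(n$properties))])
  })
  e <- cg$edges
  edges <- lapply(seq_len(nrow(e)), function(i) {
    out <- list(source = e$source[i], target = e$target[i], type = e$type[i],
                order = e$order[i])
    if (!is.na(e$stoichiometry[i])) out$stoichiometry <- e$stoichiometry[i]
    out
  })
  list(nodes = nodes, edges = edges)
}

exportGraphJson <- function(graph, file) {
  jsonlite::write_json(graphAsList(graph), file, auto_unbox = TRUE,
                       digits = NA)
}

importGraphJson <- function(file) {
  doc <- tryCatch(jsonlite::fromJSON(file, simplifyVector = FALSE),
                  error = function(e) stopf(
                    "malformed JSON graph document (%s): %s", file,
                    conditionMessage(e), class = "kbgraph_parse_error"))
  if (is.null(doc$nodes) || is.null(doc$edges))
    stopf("malformed graph document %s: missing nodes/edges", file,
          class = "kbgraph_parse_error")
  nodes <- lapply(doc$nodes, function(n) {
    props <- lapply(n$properties, function(p)
      if (is.numeric(p) && p == round(p) && abs(p) < .Machine$integer.max)
        as.integer(p) else p)
    list(node_id = as.integer(n$id),
         labels = as.character(unlist(n$labels)),
         properties = props)
  })
  e <- doc$edges
  edges <- data.frame(
    source = vapply(e, function(x) as.integer(x$source), integer(1)),
    target = vapply(e, function(x) as.integer(x$target), integer(1)),
    type = vapply(e, function(x) as.character(x$type), character(1)),
    order = vapply(e, function(x) as.integer(x$order), integer(1)),
    stoichiometry = vapply(e, function(x)
      as.integer(x$stoichiometry %||% NA_integer_), integer(1)),
    stringsAsFactors = FALSE)
  buildGraph(nodes, edges)
}

## ---- GraphML ---------------------------------------------------------------

GRAPHML_NS <- "http://graphml.graphdrawing.org/xmlns"

exportGraphml <- function(graph, file) {
  cg <- canonicalGraph(graph)
  ## collect property keys and their types across all nodes
  keyTypes <- list()
  for (n in cg$nodes) {
    raw <- graph@nodes[[as.character(n$node_id)]]$properties
    for (nm in names(raw)) {
      tp <- propType(raw[[nm]])
      if (!is.null(keyTypes[[nm]]) && keyTypes[[nm]] != tp)
        keyTypes[[nm]] <- "string"  # mixed types degrade to string
      else keyTypes[[nm]] <- tp
    }
  }
  if (length(keyTypes)) keyTypes <- keyTypes[order(names(keyTypes))]
  doc <- xml2::xml_new_root("graphml", xmlns = GRAPHML_NS)
  addKey <- function(id, domain, name, type) {
    xml2::xml_add_child(doc, "key", id = id, "for" = domain,
                        attr.name = name, attr.type = type)
  }
  addKey("labels", "node", "labels", "string")
  for (i in seq_along(keyTypes))
    addKey(paste0("p", i - 1L), "node", names(keyTypes)[i], keyTypes[[i]])
  addKey("e_type", "edge", "type", "string")
  addKey("e_order", "edge", "order", "long")
  addKey("e_stoich", "edge", "stoichiometry", "long")
  gx <- xml2::xml_add_child(doc, "graph", id = "G", edgedefault = "directed")
  keyId <- stats::setNames(paste0("p", seq_along(keyTypes) - 1L),
                           names(keyTypes))
  fmtProp <- function(v) {
    if (is.logical(v)) tolower(as.character(v))
    else if (is.double(v)) format(v, digits = 17)
    else as.character(v)
  }
  for (n in cg$nodes) {
    raw <- graph@nodes[[as.character(n$node_id)]]
    nx <- xml2::xml_add_child(gx, "node", id = paste0("n", n$node_id))
    xml2::xml_add_child(nx, "data", paste(raw$labels, collapse = "|"),
                        key = "labels")
    for (nm in sort(names(raw$properties)))
      xml2::xml_add_child(nx, "data", fmtProp(raw$properties[[nm]]),
                          key = keyId[[nm]])
  }
  e <- cg$edges
  for (i in seq_len(nrow(e))) {
    ex <- xml2::xml_add_child(gx, "edge",
                              source = paste0("n", e$source[i]),
                              target = paste0("n", e$target[i]))
    xml2::xml_add_child(ex, "data", e$type[i], key = "e_type")
    xml2::xml_add_child(ex, "data", as.character(e$order[i]), key = "e_order")
    if (!is.na(e$stoichiometry[i]))
      xml2::xml_add_child(ex, "data", as.character(e$stoichiometry[i]),
                          key = "e_stoich")
  }
  xml2::write_xml(doc, file)
}

importGraphml <- function(file) {
  doc <- tryCatch(xml2::read_xml(file),
                  error = function(e) stopf(
                    "malformed GraphML document (%s): %s", file,
                    conditionMessage(e), class = "kbgraph_parse_error"))
  ns <- c(g = GRAPHML_NS)
  keys <- xml2::xml_find_all(doc, ".//g:key", ns)
  keyName <- stats::setNames(xml2::xml_attr(keys, "attr.name"),
                             xml2::xml_attr(keys, "id"))
  keyType <- stats::setNames(xml2::xml_attr(keys, "attr.type"),
                             xml2::xml_attr(keys, "id"))
  parseVal <- function(txt, type) {
    switch(type,
           boolean = identical(txt, "true"),
           long = as.integer(txt),
           int = as.integer(txt),
           double = as.double(txt),
           float = as.double(txt),
           txt)
  }
  nodes <- lapply(xml2::xml_find_all(doc, ".//g:node", ns), function(nx) {
    id <- as.integer(sub("^n", "", xml2::xml_attr(nx, "id")))
    props <- list()
    labels <- character()
    for (dx in xml2::xml_find_all(nx, "./g:data", ns)) {
      k <- xml2::xml_attr(dx, "key")
      txt <- xml2::xml_text(dx)
      if (identical(keyName[[k]], "labels"))
        labels <- strsplit(txt, "|", fixed = TRUE)[[1]]
      else props[[keyName[[k]]]] <- parseVal(txt, keyType[[k]])
    }
    list(node_id = id, labels = labels, properties = props)
  })
  erows <- lapply(xml2::xml_find_all(doc, ".//g:edge", ns), function(ex) {
    vals <- list(source = as.integer(sub("^n", "", xml2::xml_attr(ex, "source"))),
                 target = as.integer(sub("^n", "", xml2::xml_attr(ex, "target"))),
                 type = NA_character_, order = NA_integer_,
                 stoichiometry = NA_integer_)
    for (dx in xml2::xml_find_all(ex, "./g:data", ns)) {
      nm <- keyName[[xml2::xml_attr(dx, "key")]]
      vals[[nm]] <- parseVal(xml2::xml_text(dx),
                             keyType[[xml2::xml_attr(dx, "key")]])
    }
    vals
  })
  edges <- if (length(erows)) data.frame(
    source = vapply(erows, `[[`, integer(1), "source"),
    target = vapply(erows, `[[`, integer(1), "target"),
    type = vapply(erows, `[[`, character(1), "type"),
    order = vapply(erows, `[[`, integer(1), "order"),
    stoichiometry = vapply(erows, `[[`, integer(1), "stoichiometry"),
    stringsAsFactors = FALSE) else emptyEdges()
  buildGraph(nodes, edges)
}

## ---- Cypher script (write-only) --------------------------------------------

cypherQuote <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  paste0("\"", x, "\"")
}

cypherValue <- function(v) {
  if (is.logical(v)) tolower(as.character(v))
  else if (is.numeric(v)) format(v, digits = 17)
  else cypherQuote(as.character(v))
}

exportCypher <- function(graph, file) {
  cg <- canonicalGraph(graph)
  con <- file(file, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("CREATE CONSTRAINT IF NOT EXISTS FOR (n:DatabaseObject) REQUIRE n.dbId IS UNIQUE;",
             con)
  propStr <- function(props) {
    if (!length(props)) return("")
    paste0(" {", paste(sprintf("%s: %s", names(props),
                               vapply(props, cypherValue, character(1))),
                       collapse = ", "), "}")
  }
  for (n in cg$nodes) {
    raw <- graph@nodes[[as.character(n$node_id)]]
    props <- raw$properties
    props$dbId <- raw$node_id
    props <- props[order(names(props))]
    writeLines(sprintf("CREATE (:%s%s);",
                       paste(raw$labels, collapse = ":"), propStr(props)), con)
  }
  e <- cg$edges
  for (i in seq_len(nrow(e))) {
    eprops <- list(order = e$order[i])
    if (!is.na(e$stoichiometry[i])) eprops$stoichiometry <- e$stoichiometry[i]
    writeLines(sprintf(
      "MATCH (a {dbId: %d}), (b {dbId: %d}) CREATE (a)-[:%s%s]->(b);",
      e$source[i], e$target[i], e$type[i], propStr(eprops)), con)
  }
}
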