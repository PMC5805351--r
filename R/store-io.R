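## ObjectStore serialization: a JSON object-store dump and the
## relational CSV dialect (one entity table per class, one junction
## table per reference slot, as in the classic junction-table modelling
## of many-to-many pathway relations).

## ---- JSON object-store dump ------------------------------------------------

#' Serialize an object store to JSON
#'
#' Canonical (instances sorted by dbId) and round-trip stable:
#' `storeFromJson(storeToJson(x))` reproduces `x`.
#'
#' @param store an [ObjectStore-class].
#' @param file optional destination path.
#' @param metadata optional named list written under `"metadata"` (the
#'   CLI records the seed here).
#' @return JSON string (invisibly when `file` is given).
#' @export
storeToJson <- function(store, file = NULL, metadata = NULL) {
  ids <- idSort(vapply(store@instances, function(i) i@dbId, integer(1)))
  insts <- lapply(as.character(ids), function(k) {
    i <- store@instances[[k]]
    sv <- i@slotValues
    if (length(sv)) sv <- sv[order(names(sv))]  # canonical slot order
    else names(sv) <- character()               # always serialize as {}
    list(db_id = i@dbId, st_id = i@stId, class_name = i@className,
         display_name = i@displayName,
         slot_values = lapply(sv, function(v)
           if (is.numeric(v)) as.list(as.integer(v)) else v))
  })
  doc <- list()
  if (!is.null(metadata)) doc$metadata <- metadata
  doc$schema <- jsonlite::fromJSON(schemaToJson(store@schema),
                                   simplifyVector = FALSE)
  doc$top_level_pathways <- as.list(store@topLevelPathways)
  doc$instances <- insts
  js <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
  if (!is.null(file)) { writeLines(js, file); return(invisible(js)) }
  js
}

#' Read an object store from a JSON dump
#'
#' @param source JSON string or file path.
#' @return an [ObjectStore-class].
#' @export
storeFromJson <- function(source) {
  doc <- jsonlite::fromJSON(source, simplifyVector = FALSE)
  schema <- newSchema(lapply(doc$schema$classes, function(c) {
    parent <- c$parent
    if (is.null(parent) || !length(parent)) parent <- NA_character_
    schemaClass(c$name, parent,
                lapply(c$slots, function(s)
                  slotDef(s$name, s$cardinality, s$value_kind,
                          s$target_class %||% NA_character_,
                          isTRUE(s$ordered))))
  }))
  insts <- lapply(doc$instances, function(x) {
    sv <- lapply(names(x$slot_values) %||% character(), function(nm) {
      def <- effectiveSlot(schema, x$class_name, nm)
      v <- x$slot_values[[nm]]
      if (!is.null(def) && def@valueKind == "reference")
        as.integer(unlist(v)) else unlist(v)
    })
    names(sv) <- names(x$slot_values) %||% character()
    newInstance(x$db_id, x$class_name, x$display_name %||% "",
                stId = x$st_id, slotValues = sv)
  })
  newObjectStore(insts, as.integer(unlist(doc$top_level_pathways)),
                 schema = schema)
}

## ---- relational tables -----------------------------------------------------

## In-memory view of the relational dump: a named list of data.frames.
## Layout: database_object (db_id, class_name); top_level_pathways
## (db_id); one entity table per concrete class (db_id, st_id,
## display_name, <primitive slot columns>); one junction table per
## (concrete class, reference slot) pair named snake(class)_snake(slot)
## with columns (source_id, target_id, slot_order).

#' Build the relational table layout of a store
#'
#' @param store an [ObjectStore-class].
#' @return named list of data.frames (the in-memory relational dump).
#' @export
relationalTables <- function(store) {
  schema <- store@schema
  ids <- idSort(vapply(store@instances, function(i) i@dbId, integer(1)))
  insts <- store@instances[as.character(ids)]
  classes <- vapply(insts, function(i) i@className, character(1))
  tabs <- list()
  tabs[["database_object"]] <- data.frame(
    db_id = ids, class_name = unname(classes), stringsAsFactors = FALSE)
  tabs[["top_level_pathways"]] <- data.frame(db_id = store@topLevelPathways)
  for (cn in sort(unique(classes))) {
    members <- insts[classes == cn]
    eff <- effectiveSlots(schema, cn)
    primSlots <- setdiff(
      names(eff)[vapply(eff, function(s) s@valueKind != "reference",
                        logical(1))],
      c("displayName", "stId"))
    tab <- data.frame(
      db_id = vapply(members, function(i) i@dbId, integer(1)),
      st_id = vapply(members, function(i) i@stId, character(1)),
      display_name = vapply(members, function(i) i@displayName, character(1)),
      stringsAsFactors = FALSE)
    for (ps in primSlots) {
      tab[[snakeCase(ps)]] <- vapply(members, function(i) {
        v <- i@slotValues[[ps]]
        if (is.null(v)) NA_character_ else as.character(v)
      }, character(1))
    }
    rownames(tab) <- NULL
    tabs[[snakeCase(cn)]] <- tab
    refSlots <- names(eff)[vapply(eff, function(s)
      s@valueKind == "reference", logical(1))]
    for (rs in refSlots) {
      rows <- lapply(members, function(i) {
        v <- i@slotValues[[rs]]
        if (!length(v)) return(NULL)
        data.frame(source_id = i@dbId, target_id = as.integer(v),
                   slot_order = seq_along(v) - 1L)
      })
      jt <- do.call(rbind, c(rows, list(data.frame(
        source_id = integer(), target_id = integer(),
        slot_order = integer()))))
      jt <- jt[order(jt$source_id, jt$slot_order), , drop = FALSE]
      rownames(jt) <- NULL
      tabs[[paste(snakeCase(cn), snakeCase(rs), sep = "_")]] <- jt
    }
  }
  tabs
}

#' Write a relational CSV dump
#'
#' Emits the table layout [readRelationalDump()] accepts, plus
#' `schema.json`; `readRelationalDump(writeRelationalDump(x))` is the
#' identity.
#'
#' @param store an [ObjectStore-class].
#' @param dir destination directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeRelationalDump <- function(store, dir) {
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE)
  if (!ok) stopf("cannot create dump directory %s", dir,
                 class = "kbgraph_io_error")
  tabs <- relationalTables(store)
  schemaToJson(store@schema, file.path(dir, "schema.json"))
  for (nm in names(tabs))
    utils::write.csv(tabs[[nm]], file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  invisible(dir)
}

#' Read a relational CSV dump
#'
#' Expects the dialect written by [writeRelationalDump()]: one entity
#' table per class, one junction table per reference slot (rows become
#' ordered slot values), `top_level_pathways.csv`, and optionally
#' `schema.json`. Foreign keys to absent rows are kept as-is so that
#' [validateStore()] reports them as dangling references rather than
#' this function throwing.
#'
#' @param dir dump directory.
#' @return an [ObjectStore-class].
#' @export
readRelationalDump <- function(dir) {
  if (!dir.exists(dir)) stopf("no such dump directory: %s",
                              dir, class = "kbgraph_io_error")
  schemaFile <- file.path(dir, "schema.json")
  schema <- if (file.exists(schemaFile)) schemaFromJson(schemaFile)
            else builtinSchema()
  ## name maps from the schema: junction names take precedence
  entityOf <- stats::setNames(names(schema@classes),
                              snakeCase(names(schema@classes)))
  junctionOf <- list()
  for (cn in names(schema@classes)) {
    eff <- effectiveSlots(schema, cn)
    for (s in eff) {
      if (s@valueKind != "reference") next
      junctionOf[[paste(snakeCase(cn), snakeCase(s@name), sep = "_")]] <-
        list(class = cn, slot = s@name)
    }
  }
  files <- sort(list.files(dir, pattern = "\\.csv$"))
  reserved <- c("database_object", "top_level_pathways")
  recs <- list()   # db_id (chr) -> list(inst fields)
  refRows <- list()  # accumulated junction rows per (source, slot)
  for (f in files) {
    base <- sub("\\.csv$", "", f)
    if (base %in% reserved) next
    tab <- utils::read.csv(file.path(dir, f), stringsAsFactors = FALSE)
    if (!is.null(junctionOf[[base]])) {
      need <- c("source_id", "target_id", "slot_order")
      if (!all(need %in% names(tab)))
        stopf("junction table %s lacks column(s): %s", f,
              paste(setdiff(need, names(tab)), collapse = ", "),
              class = "kbgraph_schema_error")
      slot <- junctionOf[[base]]$slot
      tab <- tab[order(tab$source_id, tab$slot_order), , drop = FALSE]
      for (src in unique(tab$source_id)) {
        key <- as.character(src)
        vals <- as.integer(tab$target_id[tab$source_id == src])
        refRows[[key]][[slot]] <- c(refRows[[key]][[slot]], vals)
      }
    } else if (base %in% names(entityOf)) {
      cn <- entityOf[[base]]
      need <- c("db_id", "st_id", "display_name")
      if (!all(need %in% names(tab)))
        stopf("entity table %s lacks column(s): %s", f,
              paste(setdiff(need, names(tab)), collapse = ", "),
              class = "kbgraph_schema_error")
      eff <- effectiveSlots(schema, cn)
      primSlots <- setdiff(
        names(eff)[vapply(eff, function(s) s@valueKind != "reference",
                          logical(1))],
        c("displayName", "stId"))
      for (i in seq_len(nrow(tab))) {
        sv <- list()
        for (ps in primSlots) {
          col <- snakeCase(ps)
          if (col %in% names(tab) && !is.na(tab[[col]][i]))
            sv[[ps]] <- tab[[col]][i]
        }
        recs[[as.character(tab$db_id[i])]] <- list(
          dbId = as.integer(tab$db_id[i]), stId = tab$st_id[i],
          className = cn, displayName = tab$display_name[i],
          slotValues = sv)
      }
    } else {
      stopf("unrecognised table %s in dump %s", f, dir,
            class = "kbgraph_schema_error")
    }
  }
  for (key in names(refRows)) {
    if (is.null(recs[[key]])) next  # junction row for absent source
    for (slot in names(refRows[[key]]))
      recs[[key]]$slotValues[[slot]] <- refRows[[key]][[slot]]
  }
  insts <- lapply(recs, function(r)
    newInstance(r$dbId, r$className, r$displayName, stId = r$stId,
                slotValues = r$slotValues))
  tlpFile <- file.path(dir, "top_level_pathways.csv")
  tlp <- if (file.exists(tlpFile))
    as.integer(utils::read.csv(tlpFile)$db_id) else integer()
  newObjectStore(unname(insts), tlp, schema = schema)
}
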