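#' Create an instance
#'
#' @param dbId positive integer identifier, unique knowledgebase-wide.
#' @param className schema class name.
#' @param displayName human-readable name.
#' @param stId stable identifier string; defaults to `"R-SYN-<dbId>"`.
#' @param slotValues named list of slot values: primitives for primitive
#'   slots, integer dbId vectors for reference slots.
#' @return an [Instance-class].
#' @export
newInstance <- function(dbId, className, displayName = "",
                        stId = sprintf("R-SYN-%06d", dbId),
                        slotValues = list()) {
  new("Instance", dbId = as.integer(dbId), stId = stId,
      className = className, displayName = displayName,
      slotValues = slotValues)
}

#' Create an object store
#'
#' @param instances list of [Instance-class] objects.
#' @param topLevelPathways integer vector of root Pathway dbIds.
#' @param schema a [Schema-class]; defaults to [builtinSchema()].
#' @return an [ObjectStore-class].
#' @export
newObjectStore <- function(instances = list(), topLevelPathways = integer(),
                           schema = builtinSchema()) {
  names(instances) <- vapply(instances, function(i) as.character(i@dbId),
                             character(1))
  new("ObjectStore", schema = schema, instances = instances,
      topLevelPathways = as.integer(topLevelPathways))
}

getInstance <- function(store, dbId) store@instances[[as.character(dbId)]]

## reference slot values of an instance as a named list of integer vectors,
## in effective-slot order (root-first); only filled slots appear
referenceValues <- function(store, inst) {
  eff <- effectiveSlots(store@schema, inst@className)
  out <- list()
  for (nm in names(eff)) {
    if (eff[[nm]]@valueKind != "reference") next
    v <- inst@slotValues[[nm]]
    if (length(v)) out[[nm]] <- as.integer(v)
  }
  out
}

#' Validate a single instance against the schema and store
#'
#' Checks that the class resolves, every filled slot exists on the
#' effective slot set, cardinality-one slots hold at most one value,
#' reference values point at existing instances of the slot's target
#' class (or a descendant), and primitive slots hold scalar primitives.
#'
#' @param inst an [Instance-class].
#' @param schema a [Schema-class].
#' @param store an [ObjectStore-class] used to resolve references; may be
#'   `NULL` to skip existence/type checks on targets.
#' @return data.frame of violations with columns `dbId`, `slot`, `rule`,
#'   `detail`; zero rows iff the instance is valid.
#' @export
validateInstance <- function(inst, schema, store = NULL) {
  v <- list()
  bad <- function(slot, rule, detail)
    v[[length(v) + 1L]] <<- data.frame(dbId = inst@dbId, slot = slot,
                                       rule = rule, detail = detail,
                                       stringsAsFactors = FALSE)
  if (!inst@className %in% names(schema@classes)) {
    bad(NA_character_, "unknown_class",
        sprintf("class %s not in schema", inst@className))
    return(do.call(rbind, v))
  }
  eff <- effectiveSlots(schema, inst@className)
  for (nm in names(inst@slotValues)) {
    val <- inst@slotValues[[nm]]
    def <- eff[[nm]]
    if (is.null(def)) {
      bad(nm, "unknown_slot",
          sprintf("slot %s not on class %s", nm, inst@className))
      next
    }
    if (def@cardinality == "one" && length(val) > 1L)
      bad(nm, "cardinality", sprintf("slot %s holds %d values", nm, length(val)))
    if (def@valueKind == "reference") {
      if (!is.numeric(val)) {
        bad(nm, "value_type", sprintf("slot %s must hold dbIds", nm))
        next
      }
      if (!is.null(store)) {
        for (tid in as.integer(val)) {
          target <- getInstance(store, tid)
          if (is.null(target)) {
            bad(nm, "dangling_reference",
                sprintf("slot %s references missing dbId %d", nm, tid))
          } else if (!isSubclassOf(schema, target@className, def@targetClass)) {
            bad(nm, "reference_target_class",
                sprintf("slot %s expects %s, got %s (dbId %d)",
                        nm, def@targetClass, target@className, tid))
          }
        }
      }
    } else {
      for (x in val) if (!isScalarPrimitive(x) && !is.na(x))
        bad(nm, "value_type", sprintf("slot %s must hold primitives", nm))
    }
  }
  if (length(v)) do.call(rbind, v) else
    data.frame(dbId = integer(), slot = character(), rule = character(),
               detail = character(), stringsAsFactors = FALSE)
}

#' Validate a whole object store
#'
#' Aggregates [validateInstance()] over all instances and adds
#' store-level checks: duplicate dbId / stId, dangling references, and
#' top-level pathways that are not Pathway instances. Idempotent and
#' side-effect free.
#'
#' @param store an [ObjectStore-class].
#' @return list with elements `violations` (data.frame), `countsByRule`
#'   (named integer), `nInstances`, and `ok` (TRUE iff no violations).
#' @export
validateStore <- function(store) {
  template <- data.frame(dbId = integer(), slot = character(),
                         rule = character(), detail = character(),
                         stringsAsFactors = FALSE)
  parts <- lapply(store@instances, validateInstance,
                  schema = store@schema, store = store)
  viol <- do.call(rbind, c(unname(parts), list(template)))
  ids <- vapply(store@instances, function(i) i@dbId, integer(1))
  sts <- vapply(store@instances, function(i) i@stId, character(1))
  extra <- list()
  addv <- function(dbId, slot, rule, detail)
    extra[[length(extra) + 1L]] <<- data.frame(
      dbId = dbId, slot = slot, rule = rule, detail = detail,
      stringsAsFactors = FALSE)
  for (d in unique(ids[duplicated(ids)]))
    addv(d, NA_character_, "duplicate_db_id", sprintf("dbId %d repeated", d))
  for (s in unique(sts[duplicated(sts)]))
    addv(NA_integer_, NA_character_, "duplicate_st_id",
         sprintf("stId %s repeated", s))
  for (p in store@topLevelPathways) {
    inst <- getInstance(store, p)
    if (is.null(inst))
      addv(p, NA_character_, "dangling_reference",
           sprintf("top-level pathway %d missing", p))
    else if (!isSubclassOf(store@schema, inst@className, "Pathway"))
      addv(p, NA_character_, "top_level_not_pathway",
           sprintf("top-level %d has class %s", p, inst@className))
  }
  viol <- rbind(viol, do.call(rbind, c(extra, list(viol[0, ]))))
  rownames(viol) <- NULL
  counts <- if (nrow(viol)) table(viol$rule) else table(character())
  list(violations = viol,
       countsByRule = stats::setNames(as.integer(counts), names(counts)),
       nInstances = length(store@instances),
       ok = nrow(viol) == 0L)
}
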