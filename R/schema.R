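## Frame-based knowledge model: classes (frames) with typed slots, and the
## built-in Reactome-style pathway schema.

#' Define a slot
#'
#' @param name slot name.
#' @param cardinality `"one"` or `"many"`.
#' @param valueKind `"string"`, `"number"`, `"boolean"` or `"reference"`.
#' @param targetClass target class name for reference slots.
#' @param ordered whether a multi-valued reference slot preserves
#'   insertion order.
#' @return a [SlotDefinition-class].
#' @export
slotDef <- function(name, cardinality = c("one", "many"),
                    valueKind = c("string", "number", "boolean", "reference"),
                    targetClass = NA_character_, ordered = FALSE) {
  new("SlotDefinition", name = name, cardinality = match.arg(cardinality),
      valueKind = match.arg(valueKind),
      targetClass = as.character(targetClass), ordered = ordered)
}

#' Define a schema class
#'
#' @param name class name.
#' @param parent parent class name (`NA` for the root).
#' @param slots list of [SlotDefinition-class] objects.
#' @return a [SchemaClass-class].
#' @export
schemaClass <- function(name, parent = NA_character_, slots = list()) {
  new("SchemaClass", name = name, parent = as.character(parent), slots = slots)
}

#' Assemble a schema from classes
#'
#' Validates that all parents resolve, the hierarchy is a tree with a
#' single root, and slot names are unique within each effective slot set.
#'
#' @param classes list of [SchemaClass-class] objects.
#' @return a [Schema-class].
#' @export
newSchema <- function(classes) {
  names(classes) <- vapply(classes, function(c) c@name, character(1))
  sch <- new("Schema", classes = classes)
  for (nm in names(classes)) {
    eff <- effectiveSlots(sch, nm)
    nms <- vapply(eff, function(s) s@name, character(1))
    if (anyDuplicated(nms))
      stopf("duplicate slot name(s) in effective slot set of %s: %s", nm,
            paste(unique(nms[duplicated(nms)]), collapse = ", "))
    for (s in eff) {
      if (s@valueKind == "reference" && !s@targetClass %in% names(classes))
        stopf("slot %s of %s references unknown class %s",
              s@name, nm, s@targetClass)
    }
  }
  sch
}

#' Register additional classes on a schema
#'
#' The built-in schema is frozen: extension may add classes and slots but
#' must not redefine or remove built-in classes.
#'
#' @param schema a [Schema-class].
#' @param classes list of [SchemaClass-class] objects to add.
#' @return the extended [Schema-class].
#' @export
extendSchema <- function(schema, classes) {
  nms <- vapply(classes, function(c) c@name, character(1))
  clash <- nms[nms %in% names(schema@classes)]
  if (length(clash))
    stopf("cannot redefine existing class(es): %s", paste(clash, collapse = ", "))
  newSchema(c(schema@classes, classes))
}

#' Ancestor chain of a class
#'
#' @param schema a [Schema-class].
#' @param class class name.
#' @return character vector: the class itself first, then its ancestors
#'   up to the root.
#' @export
classAncestors <- function(schema, class) {
  if (!class %in% names(schema@classes)) stopf("unknown class: %s", class)
  chain <- character()
  p <- class
  while (!is.na(p)) {
    chain <- c(chain, p)
    p <- schema@classes[[p]]@parent
  }
  chain
}

#' Test subclass relationship (reflexive)
#'
#' @inheritParams classAncestors
#' @param ancestor candidate ancestor class name.
#' @return logical.
#' @export
isSubclassOf <- function(schema, class, ancestor) {
  ancestor %in% classAncestors(schema, class)
}

#' Effective slot set of a class
#'
#' Own slots plus all inherited slots, root-first, with no duplicates
#' (slot inheritance is monotone: a class's effective set is a superset
#' of its parent's).
#'
#' @inheritParams classAncestors
#' @return list of [SlotDefinition-class] objects, named by slot name.
#' @export
effectiveSlots <- function(schema, class) {
  chain <- rev(classAncestors(schema, class))  # root first
  out <- list()
  for (cn in chain) {
    for (s in schema@classes[[cn]]@slots) out[[s@name]] <- s
  }
  out
}

## look up one slot definition on the effective set, or NULL
effectiveSlot <- function(schema, class, slot) {
  effectiveSlots(schema, class)[[slot]]
}

#' The built-in pathway schema
#'
#' A minimal core of the Reactome-style frame hierarchy:
#' `DatabaseObject` -> `Event` -> {`Pathway`, `ReactionLikeEvent` ->
#' {`Reaction`, `FailedReaction`, `Polymerisation`, `Depolymerisation`,
#' `BlackBoxEvent`}} and `DatabaseObject` -> `PhysicalEntity` ->
#' {`SimpleEntity`, `EntityWithAccessionedSequence`, `Complex`,
#' `EntitySet`}, plus the intermediate `CatalystActivity` and
#' `Regulation` classes that link a reaction-like event to the physical
#' entity acting as its catalyst or regulator.
#'
#' Core slots: `Pathway.hasEvent` (many, ordered, -> Event);
#' `ReactionLikeEvent.input`/`.output` (many, ordered, -> PhysicalEntity),
#' `.catalystActivity` (-> CatalystActivity), `.precedingEvent`
#' (-> Event), `.regulatedBy` (-> Regulation);
#' `CatalystActivity.physicalEntity` and `Regulation.regulator` (one,
#' -> PhysicalEntity); `Complex.hasComponent` (many, ordered),
#' `EntitySet.hasMember`/`.hasCandidate` (many); and on every class the
#' primitives `displayName`, `stId`, `speciesName`.
#'
#' @return a [Schema-class].
#' @export
builtinSchema <- function() {
  cached <- get0(".builtinSchema", envir = .kbgraphCache)
  if (!is.null(cached)) return(cached)
  ref <- function(name, target, ordered = FALSE, cardinality = "many")
    slotDef(name, cardinality, "reference", target, ordered)
  prim <- function(name) slotDef(name, "one", "string")
  classes <- list(
    schemaClass("DatabaseObject", NA, list(
      prim("displayName"), prim("stId"), prim("speciesName"))),
    schemaClass("Event", "DatabaseObject"),
    schemaClass("Pathway", "Event", list(
      ref("hasEvent", "Event", ordered = TRUE))),
    schemaClass("ReactionLikeEvent", "Event", list(
      ref("input", "PhysicalEntity", ordered = TRUE),
      ref("output", "PhysicalEntity", ordered = TRUE),
      ref("catalystActivity", "CatalystActivity"),
      ref("precedingEvent", "Event"),
      ref("regulatedBy", "Regulation"))),
    schemaClass("Reaction", "ReactionLikeEvent"),
    schemaClass("FailedReaction", "ReactionLikeEvent"),
    schemaClass("Polymerisation", "ReactionLikeEvent"),
    schemaClass("Depolymerisation", "ReactionLikeEvent"),
    schemaClass("BlackBoxEvent", "ReactionLikeEvent"),
    schemaClass("PhysicalEntity", "DatabaseObject"),
    schemaClass("SimpleEntity", "PhysicalEntity"),
    schemaClass("EntityWithAccessionedSequence", "PhysicalEntity"),
    schemaClass("Complex", "PhysicalEntity", list(
      ref("hasComponent", "PhysicalEntity", ordered = TRUE))),
    schemaClass("EntitySet", "PhysicalEntity", list(
      ref("hasMember", "PhysicalEntity"),
      ref("hasCandidate", "PhysicalEntity"))),
    schemaClass("CatalystActivity", "DatabaseObject", list(
      ref("physicalEntity", "PhysicalEntity", cardinality = "one"))),
    schemaClass("Regulation", "DatabaseObject", list(
      ref("regulator", "PhysicalEntity", cardinality = "one")))
  )
  sch <- newSchema(classes)
  assign(".builtinSchema", sch, envir = .kbgraphCache)
  sch
}

.kbgraphCache <- new.env(parent = emptyenv())

## ---- JSON serialization (round-trip stable) --------------------------------

#' Serialize a schema to JSON
#'
#' @param schema a [Schema-class].
#' @param file optional path; when given, the JSON is written there.
#' @return the JSON string, invisibly when `file` is given.
#' @export
schemaToJson <- function(schema, file = NULL) {
  cls <- lapply(schema@classes[order(names(schema@classes))], function(c) {
    list(
      name = c@name,
      parent = if (is.na(c@parent)) NULL else c@parent,
      slots = lapply(c@slots, function(s) {
        out <- list(name = s@name, cardinality = s@cardinality,
                    value_kind = s@valueKind, ordered = s@ordered)
        if (!is.na(s@targetClass)) out$target_class <- s@targetClass
        out
      })
    )
  })
  js <- jsonlite::toJSON(list(classes = unname(cls)), auto_unbox = TRUE,
                         null = "null", pretty = TRUE)
  if (!is.null(file)) { writeLines(js, file); return(invisible(js)) }
  js
}

#' Read a schema from JSON
#'
#' @param source a JSON string or a file path.
#' @return a [Schema-class].
#' @export
schemaFromJson <- function(source) {
  doc <- jsonlite::fromJSON(source, simplifyVector = FALSE)
  classes <- lapply(doc$classes, function(c) {
    schemaClass(c$name, c$parent %||% NA_character_,
                lapply(c$slots, function(s) {
                  slotDef(s$name, s$cardinality, s$value_kind,
                          s$target_class %||% NA_character_,
                          isTRUE(s$ordered))
                }))
  })
  newSchema(classes)
}
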