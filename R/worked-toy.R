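#' A fixed hand-written toy knowledgebase
#'
#' One top-level pathway with a sub-pathway, three reactions in a
#' cascade, a two-level complex, an entity set with members and a
#' candidate, one catalyst activity and one regulation — together
#' exercising every edge type of the built-in schema. Used in the
#' documentation and in golden tests; its expected decompositions,
#' ancestor chains and participant sets are committed as a plain-text
#' fixture (`inst/extdata/worked_toy_expected.json`, hand-enumerated).
#'
#' Layout (dbIds): pathway 1 contains sub-pathway 2 and reaction 5;
#' pathway 2 contains reactions 3 and 4. Reaction 3: chemical 6 +
#' protein 7 -> protein 12. Reaction 4: 12 + protein 8 -> protein 13,
#' catalysed by protein 18 (via catalyst activity 17). Reaction 5: 13 +
#' set 16 -> complex 15, regulated by chemical 6 (via regulation 19).
#' Complex 15 = [protein 8, complex 14]; complex 14 = [proteins 9, 10].
#' Set 16 has members {7, 8} and candidate {11}.
#'
#' @return list with `store` (an [ObjectStore-class]) and `truth` in the
#'   same shape as [generateKB()]'s ground truth.
#' @export
workedToy <- function() {
  mk <- newInstance
  insts <- list(
    mk(1L, "Pathway", "Toy signalling pathway",
       slotValues = list(hasEvent = c(2L, 5L))),
    mk(2L, "Pathway", "Ligand processing subpathway",
       slotValues = list(hasEvent = c(3L, 4L))),
    mk(3L, "Reaction", "Ligand binds receptor",
       slotValues = list(input = c(6L, 7L), output = 12L)),
    mk(4L, "Reaction", "Receptor activation",
       slotValues = list(input = c(12L, 8L), output = 13L,
                         catalystActivity = 17L, precedingEvent = 3L)),
    mk(5L, "Reaction", "Signalling complex formation",
       slotValues = list(input = c(13L, 16L), output = 15L,
                         regulatedBy = 19L, precedingEvent = 4L)),
    mk(6L, "SimpleEntity", "Ligand chemical"),
    mk(7L, "EntityWithAccessionedSequence", "Receptor protein",
       slotValues = list(speciesName = "Homo sapiens")),
    mk(8L, "EntityWithAccessionedSequence", "Adaptor protein",
       slotValues = list(speciesName = "Homo sapiens")),
    mk(9L, "EntityWithAccessionedSequence", "Scaffold protein A",
       slotValues = list(speciesName = "Homo sapiens")),
    mk(10L, "EntityWithAccessionedSequence", "Scaffold protein B",
       slotValues = list(speciesName = "Homo sapiens")),
    mk(11L, "EntityWithAccessionedSequence", "Candidate paralogue",
       slotValues = list(speciesName = "Homo sapiens")),
    mk(12L, "EntityWithAccessionedSequence", "Bound receptor",
       slotValues = list(speciesName = "Homo sapiens")),
    mk(13L, "EntityWithAccessionedSequence", "Active receptor",
       slotValues = list(speciesName = "Homo sapiens")),
    mk(14L, "Complex", "Scaffold core complex",
       slotValues = list(hasComponent = c(9L, 10L))),
    mk(15L, "Complex", "Signalling complex",
       slotValues = list(hasComponent = c(8L, 14L))),
    mk(16L, "EntitySet", "Receptor-family set",
       slotValues = list(hasMember = c(7L, 8L), hasCandidate = 11L)),
    mk(17L, "CatalystActivity", "Kinase activity",
       slotValues = list(physicalEntity = 18L)),
    mk(18L, "EntityWithAccessionedSequence", "Kinase protein",
       slotValues = list(speciesName = "Homo sapiens")),
    mk(19L, "Regulation", "Negative feedback by ligand",
       slotValues = list(regulator = 6L))
  )
  store <- newObjectStore(insts, 1L)
  leafSelf <- function(ids) {
    out <- lapply(ids, function(i) list(excl = i, incl = i))
    names(out) <- as.character(ids)
    out
  }
  decompositions <- c(
    leafSelf(c(6L:13L, 18L)),
    list(
      "14" = list(excl = c(9L, 10L), incl = c(9L, 10L)),
      "15" = list(excl = c(8L, 9L, 10L), incl = c(8L, 9L, 10L)),
      "16" = list(excl = c(7L, 8L), incl = c(7L, 8L, 11L))
    ))
  ancestors <- list(
    "1" = 1L, "2" = c(1L, 2L),
    "3" = c(1L, 2L, 3L), "4" = c(1L, 2L, 4L), "5" = c(1L, 5L))
  ## stated participants: P1 spans reactions 3,4,5; P2 spans 3,4
  p1base <- c(6L, 7L, 8L, 12L, 13L, 15L, 16L)
  p2base <- c(6L, 7L, 8L, 12L, 13L)
  p1dec <- c(6L, 7L, 8L, 9L, 10L, 12L, 13L)
  participants <- list(
    "1" = list(
      cat0_reg0_dec0 = p1base, cat0_reg0_dec1 = p1dec,
      cat0_reg1_dec0 = p1base, cat0_reg1_dec1 = p1dec,
      cat1_reg0_dec0 = sort(c(p1base, 18L)),
      cat1_reg0_dec1 = sort(c(p1dec, 18L)),
      cat1_reg1_dec0 = sort(c(p1base, 18L)),
      cat1_reg1_dec1 = sort(c(p1dec, 18L))),
    "2" = list(
      cat0_reg0_dec0 = p2base, cat0_reg0_dec1 = p2base,
      cat0_reg1_dec0 = p2base, cat0_reg1_dec1 = p2base,
      cat1_reg0_dec0 = sort(c(p2base, 18L)),
      cat1_reg0_dec1 = sort(c(p2base, 18L)),
      cat1_reg1_dec0 = sort(c(p2base, 18L)),
      cat1_reg1_dec1 = sort(c(p2base, 18L)))
  )
  truth <- list(
    reachable = 1L:19L,
    orphans = integer(),
    topLevelPathways = 1L,
    decompositions = decompositions,
    ancestors = ancestors,
    participants = participants)
  list(store = store, truth = truth)
}
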