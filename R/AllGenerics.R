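#' @include AllClasses.R
NULL

#' Accessors for clonalProvenance objects
#'
#' Small accessor generics so downstream code never touches slots
#' directly: `patientId()` returns the patient identifier;
#' `presenceStates()`, `presenceVAF()` and `isGermline()` expose the
#' per-tissue call matrix, the observed VAF matrix and the germline flag
#' of a [PresenceCalls-class]; `patternLabel()` and `patternRationale()`
#' expose a [RecurrenceCall-class]; `treeClusters()`, `treeEdges()` and
#' `sumRuleViolations()` expose a [LineageTree-class]; `variantTable()`,
#' `truthCategories()` and `truthPattern()` expose a
#' [PatientDataset-class].
#'
#' @param x the object.
#' @return The slot content described above.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("patientId", function(x) standardGeneric("patientId"))
#' @rdname accessors
#' @export
setGeneric("presenceStates", function(x) standardGeneric("presenceStates"))
#' @rdname accessors
#' @export
setGeneric("presenceVAF", function(x) standardGeneric("presenceVAF"))
#' @rdname accessors
#' @export
setGeneric("isGermline", function(x) standardGeneric("isGermline"))
#' @rdname accessors
#' @export
setGeneric("patternLabel", function(x) standardGeneric("patternLabel"))
#' @rdname accessors
#' @export
setGeneric("patternRationale", function(x) standardGeneric("patternRationale"))
#' @rdname accessors
#' @export
setGeneric("treeClusters", function(x) standardGeneric("treeClusters"))
#' @rdname accessors
#' @export
setGeneric("treeEdges", function(x) standardGeneric("treeEdges"))
#' @rdname accessors
#' @export
setGeneric("sumRuleViolations", function(x) standardGeneric("sumRuleViolations"))
#' @rdname accessors
#' @export
setGeneric("variantTable", function(x) standardGeneric("variantTable"))
#' @rdname accessors
#' @export
setGeneric("truthCategories", function(x) standardGeneric("truthCategories"))
#' @rdname accessors
#' @export
setGeneric("truthPattern", function(x) standardGeneric("truthPattern"))

#' @rdname accessors
setMethod("patientId", "PatientManifest", function(x) x@patientId)
#' @rdname accessors
setMethod("patientId", "PatientDataset", function(x) x@patientId)
#' @rdname accessors
setMethod("patientId", "RecurrenceCall", function(x) x@patientId)

#' @rdname accessors
setMethod("presenceStates", "PresenceCalls", function(x) x@states)
#' @rdname accessors
setMethod("presenceVAF", "PresenceCalls", function(x) x@vaf)
#' @rdname accessors
setMethod("isGermline", "PresenceCalls", function(x) x@germline)

#' @rdname accessors
setMethod("patternLabel", "RecurrenceCall", function(x) x@label)
#' @rdname accessors
setMethod("patternRationale", "RecurrenceCall", function(x) x@rationale)

#' @rdname accessors
setMethod("treeClusters", "LineageTree", function(x) x@clusters)
#' @rdname accessors
setMethod("treeEdges", "LineageTree", function(x) x@edges)
#' @rdname accessors
setMethod("sumRuleViolations", "LineageTree", function(x) x@violations)

#' @rdname accessors
setMethod("variantTable", "PatientDataset", function(x) x@variants)
#' @rdname accessors
setMethod("truthCategories", "PatientDataset", function(x) x@truth$categories)
#' @rdname accessors
setMethod("truthPattern", "PatientDataset", function(x) x@truth$pattern)

setMethod("show", "PresenceParams", function(object) {
  cat("PresenceParams: minAltReads=", object@minAltReads,
      ", alpha=", object@alpha, ", errorRate=", object@errorRate,
      ", vafDetect=", object@vafDetect, ", powerFloor=", object@powerFloor,
      "\n", sep = "")
})

setMethod("show", "PatientManifest", function(object) {
  cat("PatientManifest for", object@patientId, "with",
      nrow(object@samples), "samples:\n")
  print(object@samples, row.names = FALSE)
})

setMethod("show", "SimulationSpec", function(object) {
  cat("SimulationSpec:", length(object@tree@parent), "clones,",
      nrow(object@catalog), "mutations,", nrow(object@samples),
      "samples; errorRate=", object@errorRate,
      if (object@noiseless) "(noiseless)" else "", "\n")
})

setMethod("show", "PresenceCalls", function(object) {
  cat("PresenceCalls:", nrow(object@states), "variants x",
      ncol(object@states), "tissues;", sum(object@germline),
      "germline-flagged\n")
  if (nrow(object@states)) {
    tab <- table(factor(object@states[!object@germline, ],
                        levels = PRESENCE_STATES))
    print(tab)
  }
})

setMethod("show", "LineageTree", function(object) {
  cat("LineageTree:", length(object@clusters), "clusters, tol=",
      object@tol, "\n")
  if (nrow(object@edges))
    cat(paste0("  ", object@edges$parent, " -> ", object@edges$child),
        sep = "\n")
  if (nrow(object@violations))
    cat("  sum-rule violations:", nrow(object@violations), "\n")
})

setMethod("show", "RecurrenceCall", function(object) {
  cat("RecurrenceCall", object@patientId, ":", object@label, "\n")
  r <- object@rationale
  cat("  trunk evidence:", length(r$trunk),
      "| inter-tumor:", length(r$interTumor),
      "| extinct primary-private:", length(r$extinct), "\n")
})
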