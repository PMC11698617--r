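# Generics and accessors for the package's S4 classes.  Accessor functions are
# the supported interface; slot access via @ is internal.

#' @rdname CaseSet-class
#' @param object,x a \code{CaseSet} (or other class as documented).
#' @export
setGeneric("memberIds", function(x) standardGeneric("memberIds"))

#' @rdname CaseSet-class
#' @export
setGeneric("treatedIds", function(x) standardGeneric("treatedIds"))

#' @rdname CaseSet-class
#' @export
setGeneric("untreatedIds", function(x) standardGeneric("untreatedIds"))

#' @rdname CaseSet-class
#' @export
setGeneric("sexSelector", function(x) standardGeneric("sexSelector"))

#' @rdname CaseSet-class
#' @export
setGeneric("cutoffYears", function(x) standardGeneric("cutoffYears"))

#' @rdname CaseSet-class
#' @export
setGeneric("setProjects", function(x) standardGeneric("setProjects"))

#' @rdname CaseSet-class
#' @export
setGeneric("caseSetId", function(x) standardGeneric("caseSetId"))

#' @rdname CaseSet-class
#' @export
setMethod("memberIds", "CaseSet", function(x) x@memberIds)

#' @rdname CaseSet-class
#' @export
setMethod("treatedIds", "CaseSet", function(x) x@treatedIds)

#' @rdname CaseSet-class
#' @export
setMethod("untreatedIds", "CaseSet", function(x) x@untreatedIds)

#' @rdname CaseSet-class
#' @export
setMethod("sexSelector", "CaseSet", function(x) x@sexSelector)

#' @rdname CaseSet-class
#' @export
setMethod("cutoffYears", "CaseSet", function(x) x@cutoffYears)

#' @rdname CaseSet-class
#' @export
setMethod("setProjects", "CaseSet", function(x) x@projects)

#' @rdname CaseSet-class
#' @export
setMethod("caseSetId", "CaseSet", function(x) {
  sprintf("%s_%s_cutoff-%g", paste(x@projects, collapse = "-"),
          x@sexSelector, x@cutoffYears)
})

setMethod("show", "CaseSet", function(object) {
  cat("CaseSet:", caseSetId(object), "\n")
  cat("  projects:    ", paste(object@projects, collapse = ", "), "\n")
  cat("  sex selector:", object@sexSelector, "\n")
  cat("  cutoff [y]:  ", object@cutoffYears, "\n")
  cat(sprintf("  members: %d (treated %d / untreated %d)\n",
              length(object@memberIds), length(object@treatedIds),
              length(object@untreatedIds)))
})

#' @rdname PivotStratification-class
#' @param x a \code{PivotStratification}.
#' @export
setGeneric("pivotValue", function(x) standardGeneric("pivotValue"))

#' @rdname PivotStratification-class
#' @export
setGeneric("strataBounds", function(x) standardGeneric("strataBounds"))

#' @rdname PivotStratification-class
#' @export
setGeneric("upIds", function(x) standardGeneric("upIds"))

#' @rdname PivotStratification-class
#' @export
setGeneric("downIds", function(x) standardGeneric("downIds"))

#' @rdname PivotStratification-class
#' @export
setGeneric("excludedIds", function(x) standardGeneric("excludedIds"))

#' @rdname PivotStratification-class
#' @export
setMethod("pivotValue", "PivotStratification", function(x) x@mom)

#' @rdname PivotStratification-class
#' @export
setMethod("strataBounds", "PivotStratification",
          function(x) c(lower = x@boundL, upper = x@boundU))

#' @rdname PivotStratification-class
#' @export
setMethod("upIds", "PivotStratification", function(x) x@upIds)

#' @rdname PivotStratification-class
#' @export
setMethod("downIds", "PivotStratification", function(x) x@downIds)

#' @rdname PivotStratification-class
#' @export
setMethod("excludedIds", "PivotStratification", function(x) x@excludedIds)

setMethod("show", "PivotStratification", function(object) {
  cat("PivotStratification", if (!is.na(object@featureId)) object@featureId,
      "\n")
  cat(sprintf("  mom %.6g, threshold %g%%, band [%.6g, %.6g]\n",
              object@mom, object@thresholdPct, object@boundL, object@boundU))
  cat(sprintf("  UP %d / DOWN %d / excluded %d\n", length(object@upIds),
              length(object@downIds), length(object@excludedIds)))
})

#' @rdname SyntheticCohort-class
#' @param x a \code{SyntheticCohort}.
#' @export
setGeneric("cohortMetadata", function(x) standardGeneric("cohortMetadata"))

#' @rdname SyntheticCohort-class
#' @export
setGeneric("cohortCounts", function(x) standardGeneric("cohortCounts"))

#' @rdname SyntheticCohort-class
#' @export
setGeneric("cohortBetas", function(x) standardGeneric("cohortBetas"))

#' @rdname SyntheticCohort-class
#' @export
setGeneric("cohortCoords", function(x) standardGeneric("cohortCoords"))

#' @rdname SyntheticCohort-class
#' @export
setGeneric("cohortTruth", function(x) standardGeneric("cohortTruth"))

#' @rdname SyntheticCohort-class
#' @export
setMethod("cohortMetadata", "SyntheticCohort", function(x) x@metadata)

#' @rdname SyntheticCohort-class
#' @export
setMethod("cohortCounts", "SyntheticCohort", function(x) x@counts)

#' @rdname SyntheticCohort-class
#' @export
setMethod("cohortBetas", "SyntheticCohort", function(x) x@betas)

#' @rdname SyntheticCohort-class
#' @export
setMethod("cohortCoords", "SyntheticCohort", function(x) x@coords)

#' @rdname SyntheticCohort-class
#' @export
setMethod("cohortTruth", "SyntheticCohort", function(x) x@truth)

setMethod("show", "SyntheticCohort", function(object) {
  cat("SyntheticCohort:", nrow(object@metadata), "patients,",
      nrow(object@counts), "genes,", nrow(object@betas), "CpG positions\n")
  mk <- object@truth$markers
  if (!is.null(mk) && nrow(mk))
    cat("  planted markers:",
        paste(sprintf("%s=%d", names(table(mk$mechanism)),
                      as.integer(table(mk$mechanism))), collapse = ", "),
        "\n")
  cat("  seed:", object@config$seed, "\n")
})
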